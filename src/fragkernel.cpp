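#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximum-weight colorful subtree by dynamic programming over
// (node, color-subset) states.  Exponential in the number of colors;
// callers guard the color count.  Nodes are 0-based; edges are directed
// parent -> child and must respect the DAG order (strictly decreasing mass,
// checked on the R side).  All DP entries are >= 0 because the empty
// extension (keep the node alone) is always feasible; negative-weight edges
// are therefore never forced in.
// [[Rcpp::export(name = ".colorful_subtree_dp")]]
List colorful_subtree_dp(int n, IntegerVector color, IntegerVector efrom,
                         IntegerVector eto, NumericVector eweight, int root) {
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, color[i] + 1);
  if (k > 24) stop("color count above DP capacity");
  const size_t M = (size_t)1 << k;
  if ((double)n * (double)M > 2.2e8) stop("DP table too large");
  const int ne = efrom.size();

  // out-edges per node
  std::vector<std::vector<int>> out(n);
  for (int e = 0; e < ne; ++e) out[efrom[e]].push_back(e);

  std::vector<double> D((size_t)n * M, 0.0);
  // choice encoding: 0 = base/leaf, 1 = edge (arg = edge id),
  // 2 = merge (arg = submask A excluding own color), 3 = drop color (arg = x)
  std::vector<unsigned char> typ((size_t)n * M, 0);
  std::vector<int> arg((size_t)n * M, -1);

  for (size_t S = 1; S < M; ++S) {
    for (int v = 0; v < n; ++v) {
      const size_t cb = (size_t)1 << color[v];
      if (!(S & cb)) continue;
      const size_t idx = (size_t)v * M + S;
      const size_t Sp = S & ~cb;  // colors available below v
      if (Sp == 0) { D[idx] = 0.0; typ[idx] = 0; continue; }
      double best = 0.0;  // keep v alone
      unsigned char bt = 0; int ba = -1;
      // drop an unused color (monotone lift)
      for (int x = 0; x < k; ++x) {
        const size_t xb = (size_t)1 << x;
        if (!(Sp & xb)) continue;
        const double cand = D[(size_t)v * M + (S & ~xb)];
        if (cand > best) { best = cand; bt = 3; ba = x; }
      }
      // attach a single child edge
      for (int e : out[v]) {
        const int u = eto[e];
        const size_t ub = (size_t)1 << color[u];
        if (!(Sp & ub)) continue;
        const double cand = eweight[e] + D[(size_t)u * M + Sp];
        if (cand > best) { best = cand; bt = 1; ba = e; }
      }
      // merge two subtrees at v: split Sp into A and Sp\A
      for (size_t A = (Sp - 1) & Sp; A > 0; A = (A - 1) & Sp) {
        const size_t B = Sp & ~A;
        if (A > B) continue;  // unordered split
        const double cand = D[(size_t)v * M + (A | cb)] + D[(size_t)v * M + (B | cb)];
        if (cand > best) { best = cand; bt = 2; ba = (int)A; }
      }
      D[idx] = best; typ[idx] = bt; arg[idx] = ba;
    }
  }

  // traceback from (root, full mask)
  std::vector<int> edges;
  std::vector<std::pair<int, size_t>> stack;
  const size_t full = M - 1;
  stack.push_back(std::make_pair(root, full));
  while (!stack.empty()) {
    int v = stack.back().first;
    size_t S = stack.back().second;
    stack.pop_back();
    const size_t idx = (size_t)v * M + S;
    const size_t cb = (size_t)1 << color[v];
    switch (typ[idx]) {
    case 0: break;
    case 1: {
      int e = arg[idx];
      edges.push_back(e + 1);  // 1-based for R
      stack.push_back(std::make_pair((int)eto[e], S & ~cb));
      break;
    }
    case 2: {
      size_t A = (size_t)arg[idx];
      size_t B = (S & ~cb) & ~A;
      stack.push_back(std::make_pair(v, A | cb));
      stack.push_back(std::make_pair(v, B | cb));
      break;
    }
    case 3: {
      size_t xb = (size_t)1 << arg[idx];
      stack.push_back(std::make_pair(v, S & ~xb));
      break;
    }
    }
  }
  std::sort(edges.begin(), edges.end());
  return List::create(_["score"] = D[(size_t)root * M + full],
                      _["edges"] = IntegerVector(edges.begin(), edges.end()));
}

// helper: children lists from a parent vector (parent[i] < i, root = -1)
static std::vector<std::vector<int>> children_of(const IntegerVector &parent) {
  int n = parent.size();
  std::vector<std::vector<int>> ch(n);
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0) ch[parent[i]].push_back(i);
  return ch;
}

// Common-path counting between two loss-labeled rooted trees.
// S[u,v] = sum over children a of u, b of v with equal loss of (1 + S[a,b]).
// root_anchored returns S[r1,r2]; otherwise the sum over all node pairs
// (paths may start anywhere).
// [[Rcpp::export(name = ".cpc_pair_dp")]]
double cpc_pair_dp(IntegerVector parent1, IntegerVector loss1,
                   IntegerVector parent2, IntegerVector loss2,
                   bool root_anchored) {
  int n1 = parent1.size(), n2 = parent2.size();
  std::vector<std::vector<int>> c1 = children_of(parent1), c2 = children_of(parent2);
  std::vector<double> S((size_t)n1 * n2, 0.0);
  for (int u = n1 - 1; u >= 0; --u)
    for (int v = n2 - 1; v >= 0; --v) {
      double s = 0.0;
      for (int a : c1[u])
        for (int b : c2[v])
          if (loss1[a] == loss2[b]) s += 1.0 + S[(size_t)a * n2 + b];
      S[(size_t)u * n2 + v] = s;
    }
  if (root_anchored) return S[0];
  double tot = 0.0;
  for (double x : S) tot += x;
  return tot;
}

// Common paths scored by the probability product kernel of the terminal
// peaks: the "+1" match contribution of CPC is replaced by the 2D
// Gaussian-product score g of the two terminal nodes.
// [[Rcpp::export(name = ".cpk_pair_dp")]]
double cpk_pair_dp(IntegerVector parent1, IntegerVector loss1,
                   NumericVector mz1, NumericVector int1,
                   IntegerVector parent2, IntegerVector loss2,
                   NumericVector mz2, NumericVector int2,
                   double sigma_mass, double sigma_intensity,
                   bool root_anchored) {
  int n1 = parent1.size(), n2 = parent2.size();
  std::vector<std::vector<int>> c1 = children_of(parent1), c2 = children_of(parent2);
  const double norm = 1.0 / (4.0 * M_PI * sigma_mass * sigma_intensity);
  const double dm = 4.0 * sigma_mass * sigma_mass;
  const double di = 4.0 * sigma_intensity * sigma_intensity;
  std::vector<double> S((size_t)n1 * n2, 0.0);
  for (int u = n1 - 1; u >= 0; --u)
    for (int v = n2 - 1; v >= 0; --v) {
      double s = 0.0;
      for (int a : c1[u])
        for (int b : c2[v])
          if (loss1[a] == loss2[b]) {
            double ddm = mz1[a] - mz2[b], ddi = int1[a] - int2[b];
            double g = norm * std::exp(-ddm * ddm / dm - ddi * ddi / di);
            s += g + S[(size_t)a * n2 + b];
          }
      S[(size_t)u * n2 + v] = s;
    }
  if (root_anchored) return S[0];
  double tot = 0.0;
  for (double x : S) tot += x;
  return tot;
}

// Common-subtree counting: for each pair of children with equal loss the
// common subtree can continue below, stop at the edge, or skip the pair;
// the all-skip combination is no subtree at all, hence the minus one.
// Node formulas are unique within a tree, so matching child pairs are
// disjoint and the product form is exact.
// [[Rcpp::export(name = ".csc_pair_dp")]]
double csc_pair_dp(IntegerVector parent1, IntegerVector loss1,
                   IntegerVector parent2, IntegerVector loss2,
                   bool root_anchored) {
  int n1 = parent1.size(), n2 = parent2.size();
  std::vector<std::vector<int>> c1 = children_of(parent1), c2 = children_of(parent2);
  std::vector<double> Mt((size_t)n1 * n2, 0.0);
  for (int u = n1 - 1; u >= 0; --u)
    for (int v = n2 - 1; v >= 0; --v) {
      double prod = 1.0;
      bool matched = false;
      for (int a : c1[u])
        for (int b : c2[v])
          if (loss1[a] == loss2[b]) {
            prod *= Mt[(size_t)a * n2 + b] + 2.0;
            matched = true;
          }
      Mt[(size_t)u * n2 + v] = matched ? prod - 1.0 : 0.0;
    }
  if (root_anchored) return Mt[0];
  double tot = 0.0;
  for (double x : Mt) tot += x;
  return tot;
}
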