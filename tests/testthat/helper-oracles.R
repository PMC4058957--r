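# Independent brute-force oracles and small random generators used across
# the suite.  Everything here is deliberately naive: enumeration and direct
# formula evaluation, no dynamic programming, so the oracles share nothing
# with the implementation they check.

# ---- tree path / subtree enumeration ---------------------------------------

# all downward paths (>= 1 edge) as loss-sequence keys; optionally only the
# paths starting at the root
enum_paths <- function(t, from_root_only = FALSE) {
  n <- length(t$formulas)
  children <- lapply(seq_len(n), function(u) which(!is.na(t$parent) & t$parent == u))
  out <- character(0)
  walk <- function(u, prefix) {
    for (a in children[[u]]) {
      key <- c(prefix, t$loss[a])
      out <<- c(out, paste(key, collapse = "|"))
      walk(a, key)
    }
  }
  starts <- if (from_root_only) 1L else seq_len(n)
  for (u in starts) walk(u, character(0))
  out
}

# paths with their terminal node index, for the PPK-scored path kernel
enum_paths_terminal <- function(t) {
  n <- length(t$formulas)
  children <- lapply(seq_len(n), function(u) which(!is.na(t$parent) & t$parent == u))
  keys <- character(0); terms <- integer(0)
  walk <- function(u, prefix) {
    for (a in children[[u]]) {
      key <- c(prefix, t$loss[a])
      keys <<- c(keys, paste(key, collapse = "|"))
      terms <<- c(terms, a)
      walk(a, key)
    }
  }
  for (u in seq_len(n)) walk(u, character(0))
  list(keys = keys, terminal = terms)
}

oracle_cpc <- function(t1, t2, from_root_only = FALSE) {
  p1 <- table(enum_paths(t1, from_root_only))
  p2 <- table(enum_paths(t2, from_root_only))
  shared <- intersect(names(p1), names(p2))
  if (!length(shared)) return(0)
  sum(as.numeric(p1[shared]) * as.numeric(p2[shared]))
}

oracle_cp2 <- function(t1, t2) {
  two <- function(t) {
    p <- enum_paths(t)
    p[vapply(strsplit(p, "|", fixed = TRUE), length, integer(1)) == 2]
  }
  p1 <- table(two(t1)); p2 <- table(two(t2))
  shared <- intersect(names(p1), names(p2))
  if (!length(shared)) return(0)
  sum(as.numeric(p1[shared]) * as.numeric(p2[shared]))
}

# direct 2D Gaussian-product value (re-stated here, not imported)
oracle_g <- function(mz1, int1, mz2, int2, sm, si) {
  1 / (4 * pi * sm * si) *
    exp(-(mz1 - mz2)^2 / (4 * sm^2) - (int1 - int2)^2 / (4 * si^2))
}

oracle_cpk <- function(t1, t2, sm, si) {
  e1 <- enum_paths_terminal(t1); e2 <- enum_paths_terminal(t2)
  tot <- 0
  for (i in seq_along(e1$keys)) {
    hit <- which(e2$keys == e1$keys[i])
    for (j in hit) {
      a <- e1$terminal[i]; b <- e2$terminal[j]
      tot <- tot + oracle_g(t1$mz[a], t1$intensity[a],
                            t2$mz[b], t2$intensity[b], sm, si)
    }
  }
  tot
}

# every rooted subtree (>= 1 edge) below node u, as a canonical string:
# sorted multiset of per-child entries "loss" (edge stops) or "loss(sub)"
enum_subtrees <- function(t, u, children = NULL) {
  if (is.null(children)) {
    n <- length(t$formulas)
    children <- lapply(seq_len(n), function(v) which(!is.na(t$parent) & t$parent == v))
  }
  kids <- children[[u]]
  if (!length(kids)) return(character(0))
  per_child <- lapply(kids, function(a) {
    subs <- enum_subtrees(t, a, children)
    c(NA_character_,                       # exclude this child entirely
      t$loss[a],                           # edge only
      if (length(subs)) paste0(t$loss[a], "(", subs, ")"))
  })
  combos <- expand.grid(per_child, stringsAsFactors = FALSE)
  out <- apply(combos, 1, function(row) {
    parts <- sort(unlist(row[!is.na(row)]))
    if (!length(parts)) return(NA_character_)
    paste(parts, collapse = ",")
  })
  out[!is.na(out)]
}

oracle_csc <- function(t1, t2, root_anchored = TRUE) {
  count_at <- function(u, v) {
    s1 <- table(enum_subtrees(t1, u))
    s2 <- table(enum_subtrees(t2, v))
    shared <- intersect(names(s1), names(s2))
    if (!length(shared)) return(0)
    sum(as.numeric(s1[shared]) * as.numeric(s2[shared]))
  }
  if (root_anchored) return(count_at(1L, 1L))
  tot <- 0
  for (u in seq_along(t1$formulas)) for (v in seq_along(t2$formulas))
    tot <- tot + count_at(u, v)
  tot
}

# ---- maximum colorful subtree oracle ---------------------------------------

# exhaustive search over node subsets: a subset (plus the root) supports a
# subtree iff every chosen node has an in-neighbor inside, and the best tree
# on a fixed node set takes each node's maximum-weight in-edge (any parent
# choice in the DAG is an arborescence)
oracle_colorful <- function(g, root) {
  n <- nrow(g$nodes)
  others <- setdiff(seq_len(n), root)
  best <- 0
  for (mask in 0:(2^length(others) - 1)) {
    sel <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    nodes <- c(root, sel)
    cols <- g$nodes$color[nodes]
    if (anyDuplicated(cols)) next
    score <- 0
    ok <- TRUE
    for (v in sel) {
      ein <- which(g$edges$to == v & g$edges$from %in% nodes)
      if (!length(ein)) { ok <- FALSE; break }
      score <- score + max(g$edges$weight[ein])
    }
    if (ok && score > best) best <- score
  }
  best
}

# random formula-consistent fragmentation graph: distinct sub-formulas of a
# random root, random colors and Gaussian edge weights
random_fraggraph <- function(n_nodes = 10, n_colors = 6, edge_p = 0.7) {
  alpha <- element_alphabet(c("C", "H", "N", "O"))
  root <- c(C = 12L, H = 16L, N = 2L, O = 5L)
  fs <- format_formula(root)
  counts <- list(root)
  while (length(counts) < n_nodes) {
    f <- vapply(root, function(k) sample(0:k, 1), integer(1))
    if (sum(f) == 0 || all(f == root)) next
    key <- format_formula(f)
    if (key %in% fs) next
    fs <- c(fs, key); counts <- c(counts, list(f))
  }
  masses <- vapply(counts, function(f) sum(f * alpha$masses[names(f)]), numeric(1))
  o <- order(-masses)
  counts <- counts[o]; fs <- fs[o]; masses <- masses[o]
  color <- c(1L, sample(seq_len(n_colors), n_nodes - 1L, replace = TRUE))
  from <- integer(); to <- integer(); loss <- character(); w <- numeric()
  for (u in seq_len(n_nodes)) for (v in seq_len(n_nodes)) {
    if (u == v || color[u] == color[v]) next
    d <- counts[[u]] - counts[[v]]
    if (any(d < 0) || !any(d > 0)) next
    if (stats::runif(1) > edge_p) next
    from <- c(from, u); to <- c(to, v)
    loss <- c(loss, format_formula(d)); w <- c(w, stats::rnorm(1))
  }
  structure(list(nodes = data.frame(formula = fs, color = color, mz = masses,
                                    intensity = stats::runif(n_nodes, 0, 10),
                                    mass = masses, stringsAsFactors = FALSE),
                 edges = data.frame(from = from, to = to, loss = loss,
                                    weight = w, stringsAsFactors = FALSE),
                 precursor_mz = masses[1], id = "random"),
            class = "fraggraph")
}

# ---- misc -------------------------------------------------------------------

small_tree_cfg <- function(...) {
  synthetic_config(n_compounds = 1, max_nodes = 8, max_depth = 3,
                   p_branch = 0.7, ...)
}

# quadrature of the product of two 2D Gaussians (shared diagonal covariance)
quadrature_g <- function(mz1, int1, mz2, int2, sm, si) {
  fx <- function(x) stats::dnorm(x, mz1, sm) * stats::dnorm(x, mz2, sm)
  fy <- function(y) stats::dnorm(y, int1, si) * stats::dnorm(y, int2, si)
  ix <- stats::integrate(fx, min(mz1, mz2) - 10 * sm, max(mz1, mz2) + 10 * sm,
                         rel.tol = 1e-10)$value
  iy <- stats::integrate(fy, min(int1, int2) - 10 * si, max(int1, int2) + 10 * si,
                         rel.tol = 1e-10)$value
  ix * iy
}

# tiny deterministic chain/star builders on a fixed formula backbone
chain_tree <- function(losses, id = "chain", intensities = NULL) {
  alpha <- element_alphabet()
  root <- parse_formula("C20H30N4O10S2")
  counts <- Reduce(function(acc, l) acc - parse_formula(l), losses,
                   accumulate = TRUE, init = root)
  fs <- vapply(counts, format_formula, character(1))
  n <- length(fs)
  if (is.null(intensities)) intensities <- seq(50, 10, length.out = n)
  fragtree(fs, c(NA_integer_, seq_len(n - 1)), intensities, id = id)
}

star_tree <- function(losses, id = "star", intensities = NULL) {
  root <- parse_formula("C20H30N4O10S2")
  counts <- c(list(root), lapply(losses, function(l) root - parse_formula(l)))
  fs <- vapply(counts, format_formula, character(1))
  n <- length(fs)
  if (is.null(intensities)) intensities <- seq(50, 10, length.out = n)
  fragtree(fs, c(NA_integer_, rep(1L, n - 1)), intensities, id = id)
}
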