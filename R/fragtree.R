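# Fragmentation graphs and trees: build the graph of all peak explanations,
# weight its edges on a log-likelihood scale, and extract a maximum-weight
# colorful subtree (one node per peak) as the fragmentation tree.

#' Construct a fragmentation tree
#'
#' Nodes are molecular formulas with peak intensities; each non-root node
#' carries the neutral-loss formula of the edge from its parent. Nodes are
#' re-ordered so that every parent precedes its children and the root is
#' first.
#'
#' @param formulas Character vector of node formulas (Hill strings).
#' @param parent Integer vector of parent indices (`NA` for the root).
#' @param intensity Numeric vector of node peak intensities (percent scale).
#' @param mz Optional numeric vector of observed peak m/z per node; defaults
#'   to the formula masses.
#' @param id Tree identifier.
#' @param score Optional tree score (sum of edge weights).
#' @param alphabet [element_alphabet()] used for loss arithmetic.
#' @return An object of class `fragtree`.
#' @export
fragtree <- function(formulas, parent, intensity, mz = NULL,
                     id = "tree", score = NULL, alphabet = element_alphabet()) {
  n <- length(formulas)
  stopifnot(length(parent) == n, length(intensity) == n)
  if (sum(is.na(parent)) != 1L) stop("exactly one root (NA parent) required")
  if (anyDuplicated(formulas)) stop("node formulas must be unique")
  # topological order: root first, parents before children
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(parent[j])) {
      j <- parent[j]; d <- d + 1L
      if (d > n) stop("parent pointers contain a cycle")
    }
    depth[i] <- d
  }
  o <- order(depth, seq_len(n))
  rank <- match(seq_len(n), o)
  formulas <- formulas[o]
  parent <- ifelse(is.na(parent[o]), NA_integer_, rank[parent[o]])
  intensity <- intensity[o]
  counts <- lapply(formulas, parse_formula, alphabet = alphabet)
  masses <- vapply(counts, function(f) sum(f * alphabet$masses), numeric(1))
  if (is.null(mz)) mz <- masses else mz <- mz[o]
  loss <- rep(NA_character_, n)
  for (i in seq_len(n)[-1]) {
    d <- counts[[parent[i]]] - counts[[i]]
    if (any(d < 0) || !any(d > 0))
      stop("edge ", parent[i], " -> ", i,
           " does not correspond to a valid non-empty loss")
    loss[i] <- format_formula(d)
  }
  structure(list(id = as.character(id), formulas = formulas,
                 parent = as.integer(parent), loss = loss,
                 intensity = as.numeric(intensity), mz = as.numeric(mz),
                 mass = masses, score = score),
            class = "fragtree")
}

#' @export
print.fragtree <- function(x, ...) {
  cat(sprintf("Fragmentation tree '%s': %d node(s), root %s (%.5f Da)%s\n",
              x$id, length(x$formulas), x$formulas[1], x$mass[1],
              if (is.null(x$score)) "" else sprintf(", score %.4f", x$score)))
  if (length(x$formulas) > 1) {
    df <- data.frame(node = x$formulas[-1],
                     parent = x$formulas[x$parent[-1]],
                     loss = x$loss[-1],
                     intensity = round(x$intensity[-1], 3))
    print(utils::head(df, 12), row.names = FALSE)
    if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more edge(s)\n")
  }
  invisible(x)
}

#' Plot a fragmentation tree
#'
#' Simple layered layout: depth on the vertical axis, edges annotated with
#' their loss formulas.
#'
#' @param x A [fragtree()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fragtree <- function(x, ...) {
  n <- length(x$formulas)
  depth <- integer(n)
  for (i in seq_len(n)[-1]) depth[i] <- depth[x$parent[i]] + 1L
  xs <- stats::ave(seq_len(n), depth, FUN = function(v) seq_along(v) / (length(v) + 1))
  graphics::plot(xs, -depth, pch = 19, axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0, 1), main = x$id, ...)
  for (i in seq_len(n)[-1]) {
    graphics::segments(xs[x$parent[i]], -depth[x$parent[i]], xs[i], -depth[i],
                       col = "grey50")
    graphics::text((xs[i] + xs[x$parent[i]]) / 2, -(depth[i] - 0.5),
                   x$loss[i], cex = 0.7, col = "grey30")
  }
  graphics::text(xs, -depth, x$formulas, pos = 3, cex = 0.8)
  invisible(x)
}

#' Validate fragmentation-tree invariants
#'
#' Checks: single root, parents precede children, unique node formulas, every
#' edge loss equal to the element-wise parent minus child difference (valid
#' and non-empty), root formula of maximal mass, intensities within \[0, 100\].
#'
#' @param t A [fragtree()].
#' @param alphabet [element_alphabet()] for the arithmetic.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_fragtree <- function(t, alphabet = element_alphabet()) {
  n <- length(t$formulas)
  if (!is.na(t$parent[1])) stop("first node must be the root")
  if (n > 1 && any(is.na(t$parent[-1]))) stop("multiple roots")
  if (n > 1 && any(t$parent[-1] >= seq_len(n)[-1]))
    stop("parents must precede children")
  if (anyDuplicated(t$formulas)) stop("duplicate node formulas")
  counts <- lapply(t$formulas, parse_formula, alphabet = alphabet)
  masses <- vapply(counts, function(f) sum(f * alphabet$masses), numeric(1))
  if (any(masses > masses[1] + 1e-9)) stop("root formula must have maximal mass")
  for (i in seq_len(n)[-1]) {
    d <- counts[[t$parent[i]]] - counts[[i]]
    if (any(d < 0) || !any(d > 0)) stop("invalid loss on edge into node ", i)
    if (!identical(format_formula(d), t$loss[i]))
      stop("stored loss disagrees with formula difference at node ", i)
  }
  if (any(t$intensity < 0) || any(t$intensity > 100 + 1e-9))
    stop("intensities must lie in [0, 100]")
  invisible(TRUE)
}

#' Edge-weight configuration for fragmentation graphs
#'
#' The edge weight is a sum of log-likelihood-scale terms for the child peak
#' (intensity, mass deviation) and the loss (mass prior, common-loss bonus,
#' radical and chemical-plausibility penalties). The coefficients are
#' deliberately configurable defaults, not fitted values.
#'
#' @param mass_deviation_sigma Gaussian sd of the peak mass deviation (ppm).
#' @param intensity_weight Coefficient of the `log(1 + intensity)` term.
#' @param loss_mass_penalty_scale Penalty per Dalton of loss mass above
#'   `loss_mass_offset` (large neutral losses are unlikely in one step).
#' @param loss_mass_offset Loss mass (Da) where the penalty starts; default
#'   four proton masses.
#' @param common_loss_bonus Named numeric vector of bonuses per loss formula;
#'   defaults to +1 for nine standard small-molecule losses.
#' @param radical_penalty Penalty for radical (half-integer RDBE) or
#'   negative-RDBE losses.
#' @param rdbe_penalty_threshold Child formulas with RDBE below this get the
#'   chemical-implausibility penalty.
#' @param hetero_ratio_max Child formulas with hetero/carbon ratio above this
#'   get the chemical-implausibility penalty.
#' @param chem_penalty Size of the chemical-implausibility penalty.
#' @return An object of class `edge_weight_config`.
#' @export
edge_weight_config <- function(mass_deviation_sigma = 5,
                               intensity_weight = 1,
                               loss_mass_penalty_scale = 0.05,
                               loss_mass_offset = 4 * 1.0078250319,
                               common_loss_bonus = NULL,
                               radical_penalty = 2,
                               rdbe_penalty_threshold = 0,
                               hetero_ratio_max = 6,
                               chem_penalty = 2) {
  stopifnot(mass_deviation_sigma > 0)
  if (is.null(common_loss_bonus))
    common_loss_bonus <- stats::setNames(rep(1, length(common_losses())),
                                         common_losses())
  # canonicalize the loss keys so lookups against edge losses always match
  names(common_loss_bonus) <-
    vapply(names(common_loss_bonus),
           function(s) format_formula(parse_formula(s)), character(1))
  structure(list(mass_deviation_sigma = mass_deviation_sigma,
                 intensity_weight = intensity_weight,
                 loss_mass_penalty_scale = loss_mass_penalty_scale,
                 loss_mass_offset = loss_mass_offset,
                 common_loss_bonus = common_loss_bonus,
                 radical_penalty = radical_penalty,
                 rdbe_penalty_threshold = rdbe_penalty_threshold,
                 hetero_ratio_max = hetero_ratio_max,
                 chem_penalty = chem_penalty),
            class = "edge_weight_config")
}

#' Standard small-molecule neutral losses
#'
#' @return Character vector of the default common-loss formulas.
#' @export
common_losses <- function() {
  # Hill-canonical strings: water, carbon monoxide/dioxide, ammonia,
  # formaldehyde, ethene, formic acid, methanol, hydrogen sulfide
  c("H2O", "CO", "CO2", "H3N", "CH2O", "C2H4", "CH2O2", "CH4O", "H2S")
}

#' Build the fragmentation graph of a spectrum
#'
#' Every decomposition of every peak that is a sub-formula of at least one
#' candidate parent formula becomes a node, colored by its peak index. When a
#' formula explains several peaks only the peak with the smallest mass
#' deviation is kept, so node formulas are unique. All edges permitted by
#' element-wise subtraction (valid, non-empty loss) between nodes of
#' different colors are inserted. If no peak matches the parent mass, a
#' zero-intensity precursor peak is appended so each parent formula is a
#' potential root.
#'
#' @param s A preprocessed [ms_spectrum()].
#' @param parent_formulas List (or vector) of candidate parent formulas,
#'   typically from [decompose_mass()] of the precursor.
#' @param tol_ppm Mass tolerance for peak decomposition (ppm).
#' @param alphabet [element_alphabet()].
#' @return An object of class `fraggraph` with `nodes` and `edges` data
#'   frames (edge weights `NA` until [weight_edges()]).
#' @export
build_fraggraph <- function(s, parent_formulas, tol_ppm = 10,
                            alphabet = element_alphabet()) {
  if (!length(parent_formulas)) stop("no candidate parent formulas")
  if (is.character(parent_formulas)) parent_formulas <- as.list(parent_formulas)
  parents <- lapply(parent_formulas, parse_formula, alphabet = alphabet)
  # per-element bounds from the parent formulas: fragments cannot gain atoms
  parent_max <- Reduce(pmax, parents)
  alphabet <- element_alphabet(alphabet$symbols, alphabet$masses,
                               pmin(alphabet$bounds, parent_max[alphabet$symbols]))
  pk <- s$peaks
  # make sure the precursor itself is explainable as the root peak
  has_prec <- any(abs(pk$mz - s$precursor_mz) <=
                    s$precursor_mz * tol_ppm * 1e-6)
  if (!has_prec) pk <- rbind(pk, data.frame(mz = s$precursor_mz, intensity = 0))
  node_formula <- character(); node_color <- integer()
  node_mz <- numeric(); node_int <- numeric(); node_dev <- numeric()
  for (i in seq_len(nrow(pk))) {
    dec <- decompose_mass(pk$mz[i], tol_ppm, alphabet)
    for (f in dec) {
      ok <- any(vapply(parents, function(p) all(p - f >= 0), logical(1)))
      if (!ok) next
      fs <- format_formula(f)
      dev <- abs(sum(f * alphabet$masses) - pk$mz[i])
      j <- match(fs, node_formula)
      if (is.na(j)) {
        node_formula <- c(node_formula, fs)
        node_color <- c(node_color, i)
        node_mz <- c(node_mz, pk$mz[i])
        node_int <- c(node_int, pk$intensity[i])
        node_dev <- c(node_dev, dev)
      } else if (dev < node_dev[j]) {
        node_color[j] <- i; node_mz[j] <- pk$mz[i]
        node_int[j] <- pk$intensity[i]; node_dev[j] <- dev
      }
    }
  }
  if (!any(node_formula %in% vapply(parents, format_formula, character(1))))
    stop("no decomposition of the parent peak within the tolerance")
  counts <- lapply(node_formula, parse_formula, alphabet = alphabet)
  masses <- vapply(counts, function(f) sum(f * alphabet$masses), numeric(1))
  o <- order(-masses, node_formula)  # DAG order: mass strictly decreasing
  node_formula <- node_formula[o]; node_color <- node_color[o]
  node_mz <- node_mz[o]; node_int <- node_int[o]
  counts <- counts[o]; masses <- masses[o]
  n <- length(node_formula)
  Mcnt <- do.call(rbind, counts)
  from_l <- vector("list", n); to_l <- vector("list", n)
  for (u in seq_len(n)) {
    ok <- rep(TRUE, n)
    for (j in seq_len(ncol(Mcnt))) ok <- ok & Mcnt[, j] <= Mcnt[u, j]
    ok[u] <- FALSE
    ok <- ok & node_color != node_color[u] & masses < masses[u] - 1e-12
    from_l[[u]] <- rep(u, sum(ok)); to_l[[u]] <- which(ok)
  }
  from <- unlist(from_l); to <- unlist(to_l)
  loss <- vapply(seq_along(from), function(e)
    format_formula(stats::setNames(Mcnt[from[e], ] - Mcnt[to[e], ],
                                   colnames(Mcnt))), character(1))
  structure(list(nodes = data.frame(formula = node_formula, color = node_color,
                                    mz = node_mz, intensity = node_int,
                                    mass = masses,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(from = from, to = to, loss = loss,
                                    weight = rep(NA_real_, length(from)),
                                    stringsAsFactors = FALSE),
                 precursor_mz = s$precursor_mz, id = s$id),
            class = "fraggraph")
}

#' @export
print.fraggraph <- function(x, ...) {
  cat(sprintf("Fragmentation graph '%s': %d node(s), %d edge(s), %d color(s)\n",
              x$id, nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$color))))
  invisible(x)
}

#' Weight fragmentation-graph edges
#'
#' Each edge weight is the sum of: the child-peak intensity term
#' `intensity_weight * log(1 + intensity)`; the Gaussian log-likelihood of
#' the child mass deviation in ppm; a linear penalty on loss mass above the
#' offset; the common-loss bonus when listed; the radical penalty when the
#' loss has half-integer or negative RDBE; and chemical-plausibility
#' penalties when the child formula has RDBE below threshold or an extreme
#' hetero/carbon ratio. All terms are finite.
#'
#' @param g A [build_fraggraph()] result.
#' @param cfg An [edge_weight_config()].
#' @param alphabet [element_alphabet()].
#' @return The graph with numeric edge weights.
#' @export
weight_edges <- function(g, cfg = edge_weight_config(),
                         alphabet = element_alphabet()) {
  if (!nrow(g$edges)) return(g)
  child <- g$edges$to
  dev_ppm <- (g$nodes$mz[child] - g$nodes$mass[child]) / g$nodes$mass[child] * 1e6
  w_int <- cfg$intensity_weight * log1p(g$nodes$intensity[child])
  sg <- cfg$mass_deviation_sigma
  # log-likelihood ratio of the observed deviation against a perfectly
  # matching peak: zero at zero deviation, so plausible edges stay positive
  w_dev <- -0.5 * (dev_ppm / sg)^2
  loss_counts <- lapply(g$edges$loss, parse_formula, alphabet = alphabet)
  loss_mass <- vapply(loss_counts, function(f) sum(f * alphabet$masses), numeric(1))
  w_loss <- -cfg$loss_mass_penalty_scale * pmax(0, loss_mass - cfg$loss_mass_offset)
  bonus <- cfg$common_loss_bonus[g$edges$loss]
  bonus[is.na(bonus)] <- 0
  loss_rdbe <- vapply(loss_counts, function(f) rdbe(f, alphabet), numeric(1))
  half_integer <- round(loss_rdbe * 2) %% 2 == 1  # odd-electron (radical) loss
  w_rad <- ifelse(loss_rdbe < 0 | half_integer, -cfg$radical_penalty, 0)
  child_counts <- lapply(g$nodes$formula[child], parse_formula, alphabet = alphabet)
  child_rdbe <- vapply(child_counts, function(f) rdbe(f, alphabet), numeric(1))
  child_hcr <- vapply(child_counts, function(f) hetero_carbon_ratio(f, alphabet),
                      numeric(1))
  w_chem <- ifelse(child_rdbe < cfg$rdbe_penalty_threshold, -cfg$chem_penalty, 0) +
    ifelse(child_hcr > cfg$hetero_ratio_max, -cfg$chem_penalty, 0)
  g$edges$weight <- as.numeric(w_int + w_dev + w_loss + unname(bonus) + w_rad + w_chem)
  g
}

.tree_from_graph <- function(g, root, edge_ids, score) {
  sel <- g$edges[edge_ids, , drop = FALSE]
  keep <- sort(unique(c(root, sel$from, sel$to)))
  remap <- match(seq_len(nrow(g$nodes)), keep)
  parent <- rep(NA_integer_, length(keep))
  parent[remap[sel$to]] <- remap[sel$from]
  t <- fragtree(formulas = g$nodes$formula[keep], parent = parent,
                intensity = g$nodes$intensity[keep], mz = g$nodes$mz[keep],
                id = g$id, score = score)
  t
}

#' Exact maximum-weight colorful subtree
#'
#' Dynamic programming over (node, color-subset) states; exponential in the
#' number of distinct colors. Uses each color at most once and never forces
#' negative-weight edges: a bare root has score 0.
#'
#' @param g A weighted [build_fraggraph()] result.
#' @param root Root node index (row of `g$nodes`), or a formula string.
#' @param exact_color_limit Maximum number of distinct colors accepted
#'   (default 16); larger instances are directed to
#'   [max_colorful_subtree_greedy()].
#' @return A [fragtree()] with the optimal score attached.
#' @export
max_colorful_subtree_exact <- function(g, root, exact_color_limit = 16) {
  if (is.character(root)) root <- match(root, g$nodes$formula)
  stopifnot(!is.na(root), root >= 1, root <= nrow(g$nodes))
  if (any(is.na(g$edges$weight)) && nrow(g$edges))
    stop("graph edges are unweighted; call weight_edges() first")
  # restrict to nodes reachable from the root
  reach <- .reachable(g, root)
  colors <- unique(g$nodes$color[reach])
  if (length(colors) > exact_color_limit)
    stop("instance has ", length(colors), " colors (limit ", exact_color_limit,
         "); use max_colorful_subtree_greedy()")
  sub_nodes <- which(reach)
  eid <- which(g$edges$from %in% sub_nodes & g$edges$to %in% sub_nodes)
  col0 <- match(g$nodes$color[sub_nodes], colors) - 1L
  from0 <- match(g$edges$from[eid], sub_nodes) - 1L
  to0 <- match(g$edges$to[eid], sub_nodes) - 1L
  res <- .colorful_subtree_dp(length(sub_nodes), col0, from0, to0,
                              g$edges$weight[eid],
                              match(root, sub_nodes) - 1L)
  .tree_from_graph(g, root, eid[res$edges], res$score)
}

.reachable <- function(g, root) {
  n <- nrow(g$nodes)
  reach <- rep(FALSE, n); reach[root] <- TRUE
  queue <- root
  adj <- split(g$edges$to, g$edges$from)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nxt <- adj[[as.character(v)]]
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  reach
}

#' Greedy colorful subtree heuristic
#'
#' Best-in heuristic: repeatedly attach the highest positive-weight edge from
#' the current tree to a node whose color is still unused (ties broken by
#' lower child index). Feasible by construction; its score never exceeds the
#' exact optimum.
#'
#' @inheritParams max_colorful_subtree_exact
#' @return A [fragtree()] with the heuristic score attached.
#' @export
max_colorful_subtree_greedy <- function(g, root) {
  if (is.character(root)) root <- match(root, g$nodes$formula)
  stopifnot(!is.na(root), root >= 1, root <= nrow(g$nodes))
  in_tree <- rep(FALSE, nrow(g$nodes)); in_tree[root] <- TRUE
  used_color <- g$nodes$color[root]
  chosen <- integer(); score <- 0
  repeat {
    cand <- which(in_tree[g$edges$from] & !in_tree[g$edges$to] &
                    !(g$nodes$color[g$edges$to] %in% used_color) &
                    g$edges$weight > 0)
    if (!length(cand)) break
    best <- cand[order(-g$edges$weight[cand], g$edges$to[cand])][1]
    chosen <- c(chosen, best)
    score <- score + g$edges$weight[best]
    v <- g$edges$to[best]
    in_tree[v] <- TRUE
    used_color <- c(used_color, g$nodes$color[v])
  }
  .tree_from_graph(g, root, chosen, score)
}

#' Rank candidate parent formulas by best tree score
#'
#' For each candidate parent formula the fragmentation graph is built and
#' the best colorful-subtree score with that formula at the root is computed
#' (exact when the color count permits, greedy otherwise).
#'
#' @param s A preprocessed [ms_spectrum()].
#' @param candidates List of candidate parent formulas (typically
#'   [decompose_mass()] of the precursor).
#' @param cfg [edge_weight_config()].
#' @param tol_ppm Decomposition tolerance (ppm).
#' @param exact_color_limit Color limit for the exact solver.
#' @param alphabet [element_alphabet()].
#' @return Data frame with columns `formula` and `score`, sorted by
#'   descending score.
#' @export
rank_parent_formulas <- function(s, candidates, cfg = edge_weight_config(),
                                 tol_ppm = 10, exact_color_limit = 16,
                                 alphabet = element_alphabet()) {
  if (is.character(candidates)) candidates <- as.list(candidates)
  fml <- vapply(candidates,
                function(f) format_formula(parse_formula(f, alphabet)),
                character(1))
  # one shared graph: nodes are decompositions valid under *some* candidate;
  # solving from a candidate's root restricts to its own sub-formulas because
  # edges encode the subset relation
  g <- tryCatch(build_fraggraph(s, candidates, tol_ppm, alphabet),
                error = function(e) NULL)
  if (!is.null(g)) g <- weight_edges(g, cfg, alphabet)
  scores <- vapply(fml, function(fs) {
    if (is.null(g) || !fs %in% g$nodes$formula) return(-Inf)
    t <- tryCatch(max_colorful_subtree_exact(g, fs, exact_color_limit),
                  error = function(e) max_colorful_subtree_greedy(g, fs))
    t$score
  }, numeric(1))
  out <- data.frame(formula = fml, score = scores, stringsAsFactors = FALSE)
  out[order(-out$score, out$formula), , drop = FALSE]
}

#' Serialize a fragmentation tree to JSON
#'
#' @param t A [fragtree()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
write_tree_json <- function(t, path = NULL) {
  obj <- list(id = t$id, score = t$score,
              nodes = data.frame(formula = t$formulas,
                                 intensity = t$intensity, mz = t$mz),
              edges = if (length(t$formulas) > 1)
                data.frame(parent = t$parent[-1], child = seq_along(t$formulas)[-1],
                           loss = t$loss[-1])
              else data.frame(parent = integer(), child = integer(),
                              loss = character()))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a fragmentation tree from JSON
#'
#' @param path Path to a file written by [write_tree_json()], or a JSON
#'   string.
#' @return A [fragtree()].
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  n <- nrow(obj$nodes)
  parent <- rep(NA_integer_, n)
  if (n > 1 && nrow(obj$edges)) parent[obj$edges$child] <- obj$edges$parent
  fragtree(obj$nodes$formula, parent, obj$nodes$intensity, mz = obj$nodes$mz,
           id = obj$id, score = obj$score)
}

#' Export a fragmentation tree in DOT format
#'
#' @param t A [fragtree()].
#' @return A character scalar with a Graphviz DOT description.
#' @export
tree_to_dot <- function(t) {
  lines <- c(sprintf("digraph \"%s\" {", t$id))
  lines <- c(lines, sprintf("  n%d [label=\"%s\\n%.1f%%\"];",
                            seq_along(t$formulas), t$formulas, t$intensity))
  for (i in seq_along(t$formulas)[-1])
    lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];",
                              t$parent[i], i, t$loss[i]))
  paste(c(lines, "}"), collapse = "\n")
}
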