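# Candidate-structure retrieval: ppm mass windows, Poisson-binomial
# fingerprint scoring and rank curves.

#' Construct a candidate database
#'
#' @param id Character vector of candidate identifiers (unique).
#' @param formula Character vector of molecular formulas.
#' @param mass Numeric vector of monoisotopic masses (Da, positive).
#' @param fingerprints Matrix in \{-1, +1\} (or \{0, 1\}, auto-mapped), one
#'   row per candidate.
#' @return An object of class `candidate_db`.
#' @export
candidate_db <- function(id, formula, mass, fingerprints) {
  id <- as.character(id)
  stopifnot(!anyDuplicated(id), length(formula) == length(id),
            length(mass) == length(id), nrow(fingerprints) == length(id),
            all(mass > 0))
  fingerprints <- as.matrix(fingerprints)
  u <- sort(unique(as.numeric(fingerprints)))
  if (all(u %in% c(0, 1))) fingerprints <- fingerprints * 2 - 1
  if (!all(fingerprints %in% c(-1, 1)))
    stop("fingerprints must be in {-1,+1} or {0,1}")
  rownames(fingerprints) <- id
  structure(list(id = id, formula = as.character(formula),
                 mass = as.numeric(mass), fingerprints = fingerprints),
            class = "candidate_db")
}

#' @export
print.candidate_db <- function(x, ...) {
  cat(sprintf("Candidate database: %d candidate(s), %d fingerprint bit(s)\n",
              length(x$id), ncol(x$fingerprints)))
  invisible(x)
}

#' Filter candidates by a mass window
#'
#' Retains candidates with `|mass - target_mass| <= half_width`, where the
#' half width is `target_mass * delta_ppm * 1e-6` (ppm mode, the default) or
#' `delta_da` Dalton (absolute mode).
#'
#' @param db A [candidate_db()].
#' @param target_mass Query mass (Da).
#' @param delta_ppm Window half-width in ppm.
#' @param delta_da Optional absolute half-width in Da (overrides ppm).
#' @return The filtered [candidate_db()] (possibly empty).
#' @export
mass_window_filter <- function(db, target_mass, delta_ppm = 300,
                               delta_da = NULL) {
  half <- if (!is.null(delta_da)) delta_da else target_mass * delta_ppm * 1e-6
  stopifnot(half > 0)
  keep <- abs(db$mass - target_mass) <= half
  candidate_db(db$id[keep], db$formula[keep], db$mass[keep],
               db$fingerprints[keep, , drop = FALSE])
}

#' Poisson-binomial log-score of a candidate fingerprint
#'
#' Scores a database fingerprint against the predicted one using the
#' per-property reliabilities: positions that agree contribute `log(p_j)`,
#' positions that disagree `log(1 - p_j)`. Reliabilities are clamped to
#' `[eps, 1 - eps]` so perfect cross-validation folds cannot produce
#' infinite scores.
#'
#' @param y Candidate fingerprint in \{-1, +1\}.
#' @param y_hat Predicted fingerprint in \{-1, +1\}.
#' @param p Reliability vector in \[0, 1\].
#' @param eps Clamping constant (default 1e-3).
#' @return The log-probability score.
#' @export
poisson_binomial_score <- function(y, y_hat, p, eps = 1e-3) {
  if (length(y) != length(y_hat) || length(y) != length(p))
    stop("fingerprint/reliability length mismatch")
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(ifelse(y == y_hat, log(p), log1p(-p)))
}

#' Rank database candidates against a predicted fingerprint
#'
#' @param db A [candidate_db()] (non-empty).
#' @param y_hat Predicted fingerprint in \{-1, +1\}.
#' @param p Reliability vector.
#' @param eps Clamping constant passed to [poisson_binomial_score()].
#' @return Data frame `id`, `log_score`, `rank` sorted by descending score;
#'   ties are broken by lexicographic candidate id.
#' @export
rank_candidates <- function(db, y_hat, p, eps = 1e-3) {
  if (!length(db$id)) stop("empty candidate database")
  scores <- vapply(seq_along(db$id), function(i) {
    poisson_binomial_score(db$fingerprints[i, ], y_hat, p, eps)
  }, numeric(1))
  o <- order(-scores, db$id)
  data.frame(id = db$id[o], log_score = scores[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Fraction of compounds at or above each rank
#'
#' @param ranks Integer vector of true-candidate ranks (>= 1).
#' @param max_rank Largest cutoff evaluated.
#' @return Data frame `rank`, `fraction` — a non-decreasing step curve where
#'   `fraction[k]` is the share of compounds with rank `<= k`.
#' @export
rank_curve <- function(ranks, max_rank = max(ranks)) {
  stopifnot(all(ranks >= 1))
  ks <- seq_len(max_rank)
  data.frame(rank = ks,
             fraction = vapply(ks, function(k) mean(ranks <= k), numeric(1)))
}

#' Write a candidate database as TSV
#'
#' Columns: id, formula, mass, then one column per fingerprint bit (0/1).
#'
#' @param db A [candidate_db()].
#' @param path Output path.
#' @export
write_candidate_tsv <- function(db, path) {
  fp01 <- (db$fingerprints + 1) / 2
  df <- data.frame(id = db$id, formula = db$formula,
                   mass = sprintf("%.17g", db$mass), fp01,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate database written by [write_candidate_tsv()]
#'
#' @param path Input path.
#' @return A [candidate_db()].
#' @export
read_candidate_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fp <- as.matrix(df[, -(1:3), drop = FALSE])
  colnames(fp) <- colnames(df)[-(1:3)]
  candidate_db(df$id, df$formula, as.numeric(df$mass), fp)
}
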