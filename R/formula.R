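# Molecular-formula algebra over a fixed element alphabet.
#
# Formulas are plain named integer vectors over the alphabet's symbols; all
# arithmetic is element-wise.  Monoisotopic masses are the CODATA/IUPAC values
# for the principal isotope.

.MONOISOTOPIC <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

#' Element alphabet for formula enumeration
#'
#' Defines the element symbols, their monoisotopic masses, and per-element
#' count upper bounds used by [decompose_mass()].
#'
#' @param symbols Character vector of element symbols (subset of CHNOPS by
#'   default; other symbols need `masses`).
#' @param masses Named numeric vector of monoisotopic masses (Da); defaults to
#'   the built-in table for CHNOPS.
#' @param bounds Named integer vector of maximum counts per element. A single
#'   unnamed value recycles to all elements.
#' @return An object of class `element_alphabet`.
#' @examples
#' element_alphabet(c("C", "H", "O"), bounds = 30)
#' @export
element_alphabet <- function(symbols = c("C", "H", "N", "O", "P", "S"),
                             masses = NULL, bounds = 50L) {
  symbols <- as.character(symbols)
  if (is.null(masses)) {
    unknown <- setdiff(symbols, names(.MONOISOTOPIC))
    if (length(unknown))
      stop("no built-in monoisotopic mass for element(s): ",
           paste(unknown, collapse = ", "))
    masses <- .MONOISOTOPIC[symbols]
  } else {
    masses <- masses[symbols]
  }
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("element masses must be positive and finite")
  if (length(bounds) == 1L && is.null(names(bounds)))
    bounds <- stats::setNames(rep(as.integer(bounds), length(symbols)), symbols)
  bounds <- as.integer(bounds[symbols])
  if (any(is.na(bounds)) || any(bounds < 0))
    stop("bounds must be non-negative integers covering every symbol")
  structure(list(symbols = symbols,
                 masses = stats::setNames(as.numeric(masses), symbols),
                 bounds = stats::setNames(bounds, symbols)),
            class = "element_alphabet")
}

#' @export
print.element_alphabet <- function(x, ...) {
  cat("Element alphabet:",
      paste0(x$symbols, " (", signif(x$masses, 8), " Da, <=", x$bounds, ")",
             collapse = ", "), "\n")
  invisible(x)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-notation formula strings without charges, e.g. `"C6H12O6"`.
#' Parsing and [format_formula()] round-trip.
#'
#' @param x Formula string, or a formula object (returned unchanged after
#'   validation).
#' @param alphabet An [element_alphabet()] giving the allowed symbols.
#' @return Named integer vector over the alphabet symbols.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x, alphabet = element_alphabet()) {
  if (is.numeric(x)) return(as_formula(x, alphabet))
  stopifnot(is.character(x), length(x) == 1L)
  counts <- stats::setNames(integer(length(alphabet$symbols)), alphabet$symbols)
  if (nzchar(x)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    pieces <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x))
      stop("cannot parse formula string: '", x, "'")
    for (p in pieces) {
      sym <- sub("[0-9]*$", "", p)
      num <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(num)) as.integer(num) else 1L
      if (!sym %in% alphabet$symbols)
        stop("element '", sym, "' not in alphabet")
      counts[sym] <- counts[sym] + n
    }
  }
  counts
}

as_formula <- function(x, alphabet = element_alphabet()) {
  counts <- stats::setNames(integer(length(alphabet$symbols)), alphabet$symbols)
  if (length(x)) {
    if (is.null(names(x))) stop("numeric formulas must be named by element")
    bad <- setdiff(names(x), alphabet$symbols)
    if (length(bad)) stop("element(s) not in alphabet: ", paste(bad, collapse = ", "))
    counts[names(x)] <- as.integer(x)
  }
  if (any(counts < 0)) stop("negative element counts")
  counts
}

#' Format a formula as a Hill-notation string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' elements with zero count are omitted; the empty formula formats as `""`.
#'
#' @param f Named integer vector (a parsed formula).
#' @return A character scalar.
#' @export
format_formula <- function(f) {
  f <- f[f > 0]
  if (!length(f)) return("")
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' @param f Formula (string or named counts).
#' @param alphabet [element_alphabet()] supplying the masses.
#' @return Mass in Dalton.
#' @examples
#' formula_mass("H2O")  # 18.010565
#' @export
formula_mass <- function(f, alphabet = element_alphabet()) {
  f <- parse_formula(f, alphabet)
  sum(f * alphabet$masses[names(f)])
}

#' Element-wise formula difference
#'
#' A fragment can never gain atoms of any element, so the difference of a
#' parent and a child formula is valid only when every child count is bounded
#' by the parent count.
#'
#' @param parent,child Formulas (strings or named counts).
#' @param alphabet Shared [element_alphabet()].
#' @return The difference as named counts, or `NULL` when invalid.
#' @examples
#' subtract_formula("C6H6O", "H2O")  # C6H4
#' subtract_formula("C6H6O", "C6H8") # NULL: hydrogen would be gained
#' @export
subtract_formula <- function(parent, child, alphabet = element_alphabet()) {
  p <- parse_formula(parent, alphabet)
  c_ <- parse_formula(child, alphabet)
  d <- p - c_
  if (any(d < 0)) return(NULL)
  d
}

#' Ring double bond equivalent
#'
#' RDBE = C - H/2 + N/2 + P/2 + 1. Divalent elements (O, S) contribute
#' nothing. Radical (odd-electron) species have half-integer RDBE.
#'
#' @inheritParams formula_mass
#' @return Numeric RDBE value; errors when the formula contains elements
#'   outside CHNOPS.
#' @examples
#' rdbe("C6H6") # 4
#' @export
rdbe <- function(f, alphabet = element_alphabet()) {
  f <- parse_formula(f, alphabet)
  outside <- setdiff(names(f)[f > 0], c("C", "H", "N", "O", "P", "S"))
  if (length(outside))
    stop("RDBE undefined for element(s): ", paste(outside, collapse = ", "))
  cnt <- function(s) if (s %in% names(f)) unname(f[s]) else 0L
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + cnt("P") / 2 + 1
}

#' Hetero-to-carbon atom ratio
#'
#' (N + O + P + S) / max(C, 1); the carbon count is clamped to one so
#' carbon-free formulas still score.
#'
#' @inheritParams formula_mass
#' @return Non-negative numeric ratio.
#' @export
hetero_carbon_ratio <- function(f, alphabet = element_alphabet()) {
  f <- parse_formula(f, alphabet)
  cnt <- function(s) if (s %in% names(f)) unname(f[s]) else 0L
  (cnt("N") + cnt("O") + cnt("P") + cnt("S")) / max(cnt("C"), 1L)
}

#' Decompose a mass over an element alphabet
#'
#' Enumerates every formula over the alphabet (within its per-element bounds)
#' whose monoisotopic mass lies within a relative ppm window of the target
#' mass. Enumeration is bounded depth-first search with mass pruning; results
#' are sorted by absolute mass deviation.
#'
#' @param m Target mass (Da, positive).
#' @param tol_ppm Relative tolerance in parts per million (positive).
#' @param alphabet [element_alphabet()] with per-element bounds.
#' @return List of formulas (named integer vectors), possibly empty, sorted
#'   by `|mass - m|`.
#' @examples
#' decompose_mass(18.0106, 5, element_alphabet(c("C","H","N","O"), bounds = 20))
#' @export
decompose_mass <- function(m, tol_ppm = 10, alphabet = element_alphabet()) {
  stopifnot(m > 0, tol_ppm > 0)
  tol <- m * tol_ppm * 1e-6
  lo <- m - tol
  hi <- m + tol
  syms <- alphabet$symbols
  masses <- alphabet$masses
  bounds <- alphabet$bounds
  ord <- order(masses, decreasing = TRUE)  # heaviest first prunes fastest
  syms <- syms[ord]; masses <- masses[ord]; bounds <- bounds[ord]
  k <- length(syms)
  # min remaining mass is 0 (all-zero tail); recurse over counts
  # suffix_max[i]: largest mass attainable with elements i..k at their bounds
  suffix_max <- rev(cumsum(rev(bounds * masses)))
  out <- list()
  counts <- integer(k)
  rec <- function(i, remaining_hi, remaining_lo) {
    # remaining mass window for elements i..k
    if (i > k) {
      if (remaining_lo <= 0 && remaining_hi >= 0)
        out[[length(out) + 1L]] <<- stats::setNames(counts, syms)
      return(invisible(NULL))
    }
    tail_max <- if (i < k) suffix_max[i + 1L] else 0
    # smallest count that can still reach the lower end of the window
    min_n <- max(0L, ceiling((remaining_lo - tail_max) / masses[i] - 1e-12))
    max_n <- min(bounds[i], floor(remaining_hi / masses[i] + 1e-12))
    if (max_n < min_n) return(invisible(NULL))
    for (n in min_n:max_n) {
      used <- n * masses[i]
      counts[i] <<- n
      rec(i + 1L, remaining_hi - used, remaining_lo - used)
      counts[i] <<- 0L
    }
    invisible(NULL)
  }
  rec(1L, hi, lo)
  if (!length(out)) return(out)
  # restore canonical alphabet order in each formula
  out <- lapply(out, function(f) {
    v <- stats::setNames(integer(length(alphabet$symbols)), alphabet$symbols)
    v[names(f)] <- f
    v
  })
  dev <- vapply(out, function(f) abs(sum(f * alphabet$masses) - m), numeric(1))
  out[order(dev)]
}
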