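# MS/MS peak lists: MGF reading/writing, amalgamation across collision
# energies, normalization and peak filtering.

#' Construct an MS/MS spectrum
#'
#' A spectrum is a peak list (m/z, intensity) with a precursor m/z and an
#' identifier. Peaks are stored sorted ascending by m/z; peaks with exactly
#' equal m/z are merged by summing intensities.
#'
#' @param id Spectrum/compound identifier.
#' @param precursor_mz Precursor ion m/z (Da, positive).
#' @param mz Numeric vector of peak m/z values (positive).
#' @param intensity Numeric vector of peak intensities (non-negative).
#' @param collision_energy Optional collision-energy label.
#' @return An object of class `ms_spectrum` with a `peaks` data frame.
#' @export
ms_spectrum <- function(id, precursor_mz, mz = numeric(), intensity = numeric(),
                        collision_energy = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("precursor_mz must be a positive number")
  if (length(mz)) {
    if (any(mz <= 0)) stop("peak m/z must be positive")
    if (any(intensity < 0)) stop("peak intensities must be non-negative")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  structure(list(id = as.character(id),
                 precursor_mz = as.numeric(precursor_mz),
                 peaks = data.frame(mz = as.numeric(mz),
                                    intensity = as.numeric(intensity)),
                 collision_energy = collision_energy),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum '%s': %d peak(s), precursor m/z %.5f%s\n",
              x$id, nrow(x$peaks), x$precursor_mz,
              if (is.null(x$collision_energy)) ""
              else paste0(", CE ", x$collision_energy)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10), row.names = FALSE)
  if (nrow(x$peaks) > 10) cat("  ...", nrow(x$peaks) - 10, "more peak(s)\n")
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

#' Read an MGF peak-list file
#'
#' Parses the standard Mascot generic format dialect: `BEGIN IONS`/`END IONS`
#' blocks with `PEPMASS=<m/z> [intensity]`, optional `TITLE` and
#' `COLLISION_ENERGY`, and one `m/z intensity` pair per line. Peaks are
#' returned sorted ascending by m/z. Blocks without peaks are returned but
#' flagged with a warning.
#'
#' @param path Path to an MGF file.
#' @return List of [ms_spectrum()] objects, one per block.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  pepmass <- NA_real_; title <- NULL; ce <- NULL
  mz <- numeric(); int <- numeric(); block_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF: nested BEGIN IONS at line ", i)
      in_block <- TRUE
      pepmass <- NA_real_; title <- NULL; ce <- NULL
      mz <- numeric(); int <- numeric(); block_start <- i
    } else if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF: END IONS without BEGIN IONS at line ", i)
      if (is.na(pepmass))
        stop("MGF block starting at line ", block_start, " has no PEPMASS")
      id <- if (!is.null(title)) title else paste0("spectrum_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <-
        ms_spectrum(id, pepmass, mz, int, collision_energy = ce)
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") {
        first <- strsplit(trimws(val), "[[:space:]]+")[[1]][1]
        pepmass <- suppressWarnings(as.numeric(first))
        if (is.na(pepmass)) stop("unparseable PEPMASS at line ", i)
      } else if (key == "TITLE") {
        title <- trimws(val)
      } else if (key == "COLLISION_ENERGY") {
        ce <- trimws(val)
      } # other parameters ignored
    } else if (in_block) {
      fields <- strsplit(ln, "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) < 2 || any(is.na(vals[1:2])))
        stop("unparseable peak line ", i, ": '", lines[i], "'")
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    } else {
      stop("unexpected content outside BEGIN IONS/END IONS at line ", i)
    }
  }
  if (in_block) stop("malformed MGF: unterminated block starting at line ", block_start)
  empty <- vapply(spectra, function(s) n_peaks(s) == 0L, logical(1))
  if (any(empty))
    warning("spectra with zero peaks: ",
            paste(vapply(spectra[empty], `[[`, "", "id"), collapse = ", "))
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]; peak values are printed with 17 significant
#' digits so a read/write round trip is bit-exact.
#'
#' @param spectra List of [ms_spectrum()] objects.
#' @param path Output file path.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(paste0("PEPMASS=", sprintf("%.17g", s$precursor_mz)), con)
    if (!is.null(s$collision_energy))
      writeLines(paste0("COLLISION_ENERGY=", s$collision_energy), con)
    if (n_peaks(s))
      writeLines(sprintf("%.17g %.17g", s$peaks$mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Normalize intensities to sum 100
#'
#' @param s An [ms_spectrum()].
#' @return The spectrum with intensities rescaled so they sum to 100
#'   (unchanged if empty or all-zero).
#' @export
normalize_spectrum <- function(s) {
  tot <- sum(s$peaks$intensity)
  if (n_peaks(s) && tot > 0) s$peaks$intensity <- s$peaks$intensity * (100 / tot)
  s
}

#' Amalgamate spectra recorded at different collision energies
#'
#' Each input spectrum is first normalized so its intensities sum to 100.
#' The pooled peaks are then clustered greedily in descending intensity
#' order: the most intense unassigned peak absorbs all peaks within
#' `merge_window` of its m/z, the merged peak keeps the absorber's m/z and
#' sums the member intensities. The result is re-normalized to sum 100.
#'
#' @param spectra Non-empty list of [ms_spectrum()] objects sharing one
#'   precursor (within `merge_window`).
#' @param merge_window Maximum m/z difference (Da) merged into one peak.
#' @return A single amalgamated [ms_spectrum()].
#' @export
amalgamate <- function(spectra, merge_window = 0.1) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("amalgamate() needs at least one spectrum")
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  if (max(prec) - min(prec) > merge_window)
    stop("input spectra disagree on precursor m/z beyond the merge window")
  spectra <- lapply(spectra, normalize_spectrum)
  mz <- unlist(lapply(spectra, function(s) s$peaks$mz))
  int <- unlist(lapply(spectra, function(s) s$peaks$intensity))
  out_mz <- numeric(); out_int <- numeric()
  if (length(mz)) {
    o <- order(-int, mz)  # descending intensity, ties to lower m/z
    mz <- mz[o]; int <- int[o]
    taken <- rep(FALSE, length(mz))
    for (i in seq_along(mz)) {
      if (taken[i]) next
      members <- !taken & abs(mz - mz[i]) <= merge_window
      out_mz <- c(out_mz, mz[i])
      out_int <- c(out_int, sum(int[members]))
      taken <- taken | members
    }
  }
  normalize_spectrum(ms_spectrum(spectra[[1]]$id, mean(prec), out_mz, out_int))
}

#' Filter peaks by rank and relative intensity
#'
#' Keeps the `max_peaks` most intense peaks (ties broken toward lower m/z),
#' then drops peaks with relative intensity below `min_rel_intensity` percent
#' of the 100-sum normalization. The output is sorted by m/z and is *not*
#' re-normalized, so the retained relative intensities stay interpretable.
#'
#' @param s A normalized [ms_spectrum()] (intensity sum 100).
#' @param max_peaks Maximum number of peaks retained (default 30).
#' @param min_rel_intensity Minimum relative intensity in percent
#'   (default 0.5).
#' @return The filtered [ms_spectrum()].
#' @export
filter_peaks <- function(s, max_peaks = 30, min_rel_intensity = 0.5) {
  if (!n_peaks(s)) return(s)
  pk <- s$peaks
  o <- order(-pk$intensity, pk$mz)
  keep <- o[seq_len(min(max_peaks, nrow(pk)))]
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[pk$intensity >= min_rel_intensity, , drop = FALSE]
  pk <- pk[order(pk$mz), , drop = FALSE]
  s$peaks <- data.frame(mz = pk$mz, intensity = pk$intensity)
  s
}

#' Standard preprocessing pipeline
#'
#' Amalgamates, then filters: the composition used throughout the package
#' before tree construction and kernel evaluation.
#'
#' @inheritParams amalgamate
#' @inheritParams filter_peaks
#' @return A preprocessed [ms_spectrum()].
#' @export
preprocess_spectra <- function(spectra, merge_window = 0.1, max_peaks = 30,
                               min_rel_intensity = 0.5) {
  filter_peaks(amalgamate(spectra, merge_window), max_peaks, min_rel_intensity)
}
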