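#' Construct a sample spectrum
#'
#' A sample spectrum is a peak list (m/z, intensity, signal-to-noise) for one
#' sample, stored sorted by ascending m/z, with treatment/day/phase metadata.
#'
#' @param sample_id character scalar.
#' @param peaks data frame with numeric columns \code{mz}, \code{intensity},
#'   \code{snr}.
#' @param metadata named list (e.g. \code{treatment}, \code{day},
#'   \code{phase}); free-form.
#' @return An object of class \code{sample_spectrum}.
#' @export
sample_spectrum <- function(sample_id, peaks, metadata = list()) {
  req <- c("mz", "intensity", "snr")
  missing_cols <- setdiff(req, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak table for '", sample_id, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  peaks <- as.data.frame(peaks)[req]
  for (col in req) {
    if (!is.numeric(peaks[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(peaks[[col]]))))[1]
      stop("non-numeric value in column '", col, "' at row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  if (any(peaks$mz <= 0)) stop("mz must be positive")
  if (any(peaks$intensity < 0) || any(peaks$snr < 0)) {
    stop("intensity and snr must be non-negative")
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, peaks = peaks,
                 metadata = metadata, warnings = character()),
            class = "sample_spectrum")
}

#' @export
print.sample_spectrum <- function(x, ...) {
  cat("sample_spectrum:", x$sample_id, "-", nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param spec a \code{sample_spectrum}.
#' @return Integer count.
#' @export
n_peaks <- function(spec) nrow(spec$peaks)

.replace_peaks <- function(spec, peaks, warn = NULL) {
  spec$peaks <- peaks
  rownames(spec$peaks) <- NULL
  if (!is.null(warn)) spec$warnings <- c(spec$warnings, warn)
  spec
}

#' Read a delimited peak table
#'
#' Reads a TSV/CSV peak list with columns \code{mz}, \code{intensity},
#' \code{snr} into a \code{\link{sample_spectrum}}, sorting by m/z.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param sep field separator; \code{"\t"} for TSV (default) or \code{","}.
#' @param metadata optional metadata list.
#' @return A \code{sample_spectrum}.
#' @export
read_peak_table <- function(path, sample_id = NULL, sep = "\t",
                            metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0) stop("empty peak table: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  sample_spectrum(sample_id, tab, metadata)
}

#' Signal-to-noise filter
#'
#' Retains peaks with S/N strictly greater than the threshold (default 7).
#'
#' @param spec a \code{sample_spectrum}.
#' @param threshold non-negative S/N cutoff.
#' @return Filtered \code{sample_spectrum}.
#' @export
filter_snr <- function(spec, threshold = 7) {
  if (threshold < 0) stop("threshold must be >= 0")
  .replace_peaks(spec, spec$peaks[spec$peaks$snr > threshold, , drop = FALSE])
}

#' m/z analysis-window filter
#'
#' Retains peaks with \code{low <= mz <= high} (closed interval; the default
#' 200--900 window is the usable accurate-mass range of the instrument).
#'
#' @param spec a \code{sample_spectrum}.
#' @param low,high window bounds (Th), \code{low < high}.
#' @return Filtered \code{sample_spectrum}.
#' @export
filter_mz_window <- function(spec, low = 200, high = 900) {
  if (low >= high) stop("low must be < high")
  keep <- spec$peaks$mz >= low & spec$peaks$mz <= high
  .replace_peaks(spec, spec$peaks[keep, , drop = FALSE])
}

#' Absolute intensity filter
#'
#' Optional vendor-style floor on absolute intensity (retains strictly
#' greater values).
#'
#' @param spec a \code{sample_spectrum}.
#' @param threshold intensity floor.
#' @return Filtered \code{sample_spectrum}.
#' @export
filter_intensity <- function(spec, threshold = 100) {
  .replace_peaks(spec,
                 spec$peaks[spec$peaks$intensity > threshold, , drop = FALSE])
}

#' Internal calibration on CH2 homologous series
#'
#' Detects homologous series -- chains of peaks spaced by the exact CH2
#' monoisotopic mass (14.0156501 amu), chained within \code{match_tol_ppm}
#' of the expected partner position -- and anchors each series to a
#' reference CHO formula: the lowest-mass member is assigned within
#' \code{anchor_tol_ppm} over CHO compositions only, the candidate
#' minimizing the worst per-member mass error across the whole series is
#' taken, and each member then yields a reference error
#' \code{(observed / theoretical - 1) * 1e6} ppm. A linear ppm-correction
#' over m/z is fitted to the pooled reference points (constant when they
#' are few or span a narrow mass range) and divided out of every peak.
#' If no anchored series of at least \code{min_series_length} peaks is
#' found the spectrum is returned unchanged with a warning flag.
#'
#' @param spec a \code{sample_spectrum}.
#' @param series_spacing expected spacing (amu); exact CH2 by default.
#' @param min_series_length minimum chain length to use for calibration.
#' @param match_tol_ppm tolerance (ppm of the partner m/z) when chaining.
#' @param anchor_tol_ppm tolerance (ppm) when assigning the series anchor
#'   formula; bounds the largest correctable offset.
#' @return A list with elements \code{spectrum} (corrected
#'   \code{sample_spectrum}), \code{model} (list: \code{intercept_ppm},
#'   \code{slope_ppm_per_mz}, \code{n_points}, \code{series_lengths}) and
#'   \code{calibrated} (logical).
#' @export
calibrate_internal <- function(spec, series_spacing = CH2_MASS,
                               min_series_length = 5, match_tol_ppm = 5,
                               anchor_tol_ppm = 5) {
  mz <- spec$peaks$mz
  if (length(mz) == 0) {
    return(list(spectrum = .replace_peaks(spec, spec$peaks, "no peaks"),
                model = NULL, calibrated = FALSE))
  }
  series <- .detect_series(mz, series_spacing, match_tol_ppm,
                           min_series_length)
  if (length(series) == 0) {
    return(list(spectrum = .replace_peaks(spec, spec$peaks,
                                          "no homologous series found"),
                model = NULL, calibrated = FALSE))
  }
  cho_bounds <- element_bounds(N = c(0L, 0L), S = c(0L, 0L), P = c(0L, 0L))
  ref_mz <- numeric(0); ref_err <- numeric(0)
  used <- integer(0)
  for (chain in series) {
    obs <- mz[chain]
    anchor_neutral <- obs[1] + PROTON_MASS
    cand <- enumerate_candidates(anchor_neutral, anchor_tol_ppm, cho_bounds)
    cand <- cand[cand$plausible, , drop = FALSE]
    if (nrow(cand) == 0) next
    # pick the anchor whose CH2 grid tracks the whole series best
    worst <- vapply(seq_len(nrow(cand)), function(r) {
      theo <- cand$mass[r] - PROTON_MASS +
        series_spacing * (seq_along(obs) - 1)
      max(abs((obs / theo - 1) * 1e6))
    }, numeric(1))
    best <- which.min(worst)
    if (worst[best] > anchor_tol_ppm) next
    theo <- cand$mass[best] - PROTON_MASS +
      series_spacing * (seq_along(obs) - 1)
    ref_mz <- c(ref_mz, obs)
    ref_err <- c(ref_err, (obs / theo - 1) * 1e6)
    used <- c(used, length(chain))
  }
  if (length(ref_err) < min_series_length) {
    return(list(spectrum = .replace_peaks(spec, spec$peaks,
                                          "no anchored series found"),
                model = NULL, calibrated = FALSE))
  }
  if (length(ref_err) >= 8 && diff(range(ref_mz)) > 100) {
    fit <- stats::lm(ref_err ~ ref_mz)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  } else {
    intercept <- mean(ref_err)
    slope <- 0
  }
  corr_ppm <- intercept + slope * mz
  peaks <- spec$peaks
  peaks$mz <- mz / (1 + corr_ppm * 1e-6)
  list(spectrum = .replace_peaks(spec, peaks),
       model = list(intercept_ppm = intercept, slope_ppm_per_mz = slope,
                    n_points = length(ref_err), series_lengths = used),
       calibrated = TRUE)
}

# Maximal CH2-spaced chains in a sorted m/z vector.
.detect_series <- function(mz, spacing, match_tol_ppm, min_len) {
  nxt <- integer(length(mz))
  for (i in seq_along(mz)) {
    target <- mz[i] + spacing
    j <- findInterval(target, mz)
    best <- 0L; bestd <- Inf
    for (cand in c(j, j + 1L)) {
      if (cand >= 1L && cand <= length(mz)) {
        d <- abs(mz[cand] - target)
        if (d < bestd) { bestd <- d; best <- cand }
      }
    }
    tol <- target * match_tol_ppm * 1e-6
    nxt[i] <- if (best > 0L && bestd <= tol) best else 0L
  }
  is_target <- logical(length(mz)); is_target[nxt[nxt > 0]] <- TRUE
  series <- list()
  for (i in seq_along(mz)) {
    if (is_target[i] || nxt[i] == 0L) next
    chain <- i
    while (nxt[chain[length(chain)]] > 0L) {
      chain <- c(chain, nxt[chain[length(chain)]])
    }
    if (length(chain) >= min_len) series[[length(series) + 1]] <- chain
  }
  series
}

#' Remove 13C isotopologue peaks
#'
#' Scans peaks in ascending m/z and removes any peak sitting one
#' 13C-12C mass difference (1.003355 amu) above a retained peak (within
#' \code{tol_ppm}) with intensity below \code{ratio_max} times that parent's
#' intensity. Parents are always retained; the default ceiling 0.6 covers the
#' largest expected 13C/12C intensity ratio (1.1% per carbon, at most ~56 C).
#'
#' @param spec a \code{sample_spectrum}.
#' @param delta isotopologue spacing (amu).
#' @param tol_ppm match tolerance (ppm of the expected partner m/z).
#' @param ratio_max maximum isotopologue/parent intensity ratio.
#' @return Filtered \code{sample_spectrum}.
#' @export
remove_isotopologues <- function(spec, delta = C13_C12_DELTA, tol_ppm = 1.0,
                                 ratio_max = 0.6) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  p <- spec$peaks
  n <- nrow(p)
  if (n < 2) return(spec)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    target <- p$mz[i] - delta
    tol <- (target + delta) * tol_ppm * 1e-6
    lo <- findInterval(target - tol, p$mz) + 1L
    hi <- findInterval(target + tol, p$mz)
    if (lo > hi) next
    parents <- lo:hi
    parents <- parents[keep[parents] & parents != i]
    if (length(parents) > 0 &&
        any(p$intensity[i] < ratio_max * p$intensity[parents])) {
      keep[i] <- FALSE
    }
  }
  .replace_peaks(spec, p[keep, , drop = FALSE])
}

#' Subtract blank (sampling-solution) peaks
#'
#' Removes from each sample every peak within \code{tol_ppm} of any peak
#' detected in the blank spectra. Samples and blanks must share the same
#' calibration state.
#'
#' @param samples list of \code{sample_spectrum}.
#' @param blanks list of \code{sample_spectrum} (the blanks).
#' @param tol_ppm match tolerance (ppm).
#' @return List of filtered \code{sample_spectrum}; if no blank peaks are
#'   supplied the samples are returned unchanged with a warning flag.
#' @export
subtract_blanks <- function(samples, blanks, tol_ppm = 1.0) {
  blank_mz <- sort(unlist(lapply(blanks, function(b) b$peaks$mz)))
  if (length(blank_mz) == 0) {
    return(lapply(samples, function(s) {
      .replace_peaks(s, s$peaks, "no blank peaks; blank subtraction skipped")
    }))
  }
  lapply(samples, function(s) {
    mz <- s$peaks$mz
    if (length(mz) == 0) return(s)
    tol <- blank_mz * tol_ppm * 1e-6
    # a sample peak matches if it falls inside any [blank - tol, blank + tol]
    idx <- findInterval(mz, blank_mz)
    hit <- logical(length(mz))
    for (k in c(0L, 1L)) {
      j <- idx + k
      ok <- j >= 1L & j <= length(blank_mz)
      hit[ok] <- hit[ok] | abs(mz[ok] - blank_mz[j[ok]]) <= tol[j[ok]]
    }
    .replace_peaks(s, s$peaks[!hit, , drop = FALSE])
  })
}
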