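#' Align peaks across samples and apply a prevalence filter
#'
#' Pools all peaks, sorts by m/z, and forms consensus bins by single-linkage
#' in ppm space: a new bin starts wherever the gap to the previous peak
#' exceeds \code{tol_ppm} of the local m/z (left-to-right, deterministic).
#' If a bin receives more than one peak from the same sample the bin is
#' flagged ambiguous, a warning is emitted, and the most intense peak is
#' kept (ties broken toward lower m/z). Bins observed in fewer than
#' \code{min_samples} distinct samples are dropped.
#'
#' @param samples list of \code{\link{sample_spectrum}} (at least 2).
#' @param tol_ppm single-linkage gap tolerance (ppm).
#' @param min_samples minimum number of distinct samples per retained bin.
#' @return An object of class \code{aligned_peaks}: list with \code{mz}
#'   (consensus masses, bin means), \code{intensity} (bins x samples matrix,
#'   0 = absent), \code{n_samples} (per-bin prevalence before filtering,
#'   retained bins only), \code{tol_ppm}, \code{n_bins_prefilter}, and
#'   \code{metadata} (per-sample data frame collected from the spectra).
#' @export
align_and_prevalence_filter <- function(samples, tol_ppm = 1.0,
                                        min_samples = 2) {
  if (length(samples) < 2) stop("need at least 2 samples to align")
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  pooled <- do.call(rbind, lapply(samples, function(s) {
    if (nrow(s$peaks) == 0) return(NULL)
    data.frame(sample = s$sample_id, mz = s$peaks$mz,
               intensity = s$peaks$intensity)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) stop("no peaks to align")
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  gap <- diff(pooled$mz)
  new_bin <- c(TRUE, gap > pooled$mz[-nrow(pooled)] * tol_ppm * 1e-6)
  bin <- cumsum(new_bin)
  n_bins <- max(bin)
  dup <- anyDuplicated(paste(bin, pooled$sample))
  if (dup) {
    warning("ambiguous alignment: some bins merge multiple peaks from one ",
            "sample; keeping the most intense (ties toward lower m/z)")
    ord <- order(bin, pooled$sample, -pooled$intensity, pooled$mz)
    pooled <- pooled[ord, , drop = FALSE]
    bin <- bin[ord]
    keep <- !duplicated(paste(bin, pooled$sample))
    pooled <- pooled[keep, , drop = FALSE]
    bin <- bin[keep]
  }
  consensus <- as.numeric(tapply(pooled$mz, bin, mean))
  mat <- matrix(0, nrow = n_bins, ncol = length(ids),
                dimnames = list(NULL, ids))
  mat[cbind(bin, match(pooled$sample, ids))] <- pooled$intensity
  prevalence <- as.integer(tapply(pooled$sample, bin,
                                  function(s) length(unique(s))))
  keep_bin <- prevalence >= min_samples
  meta <- do.call(rbind, lapply(samples, function(s) {
    md <- s$metadata
    data.frame(sample_id = s$sample_id,
               treatment = if (is.null(md$treatment)) NA else md$treatment,
               day = if (is.null(md$day)) NA else md$day,
               phase = if (is.null(md$phase)) NA else md$phase,
               stringsAsFactors = FALSE)
  }))
  structure(list(mz = consensus[keep_bin],
                 intensity = mat[keep_bin, , drop = FALSE],
                 n_samples = prevalence[keep_bin],
                 tol_ppm = tol_ppm,
                 n_bins_prefilter = n_bins,
                 metadata = meta),
            class = "aligned_peaks")
}

#' @export
print.aligned_peaks <- function(x, ...) {
  cat("aligned_peaks:", length(x$mz), "consensus bins x",
      ncol(x$intensity), "samples\n")
  invisible(x)
}

#' Z-score normalize an aligned intensity table
#'
#' Per feature (bin), present intensities (> 0) are centred and scaled to
#' mean 0, SD 1; absent entries become \code{NA}. Zero-variance features are
#' set to 0 with a warning. The original presence pattern is preserved in
#' the \code{"presence"} attribute so downstream presence/absence analysis
#' is unaffected by normalization.
#'
#' @param table an \code{aligned_peaks} object or a numeric features x
#'   samples matrix with 0 marking absence.
#' @param method currently only \code{"zscore"}.
#' @return Numeric matrix of the same shape, with attribute
#'   \code{"presence"} (logical matrix).
#' @export
normalize_intensities <- function(table, method = "zscore") {
  method <- match.arg(method, "zscore")
  mat <- if (inherits(table, "aligned_peaks")) table$intensity else table
  if (any(mat < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  present <- !is.na(mat) & mat > 0
  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  zero_var <- 0L
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, present[i, ]]
    if (length(v) < 2) {
      out[i, present[i, ]] <- 0
      if (length(v) >= 1) zero_var <- zero_var + 1L
      next
    }
    s <- stats::sd(v)
    if (s == 0) {
      out[i, present[i, ]] <- 0
      zero_var <- zero_var + 1L
    } else {
      out[i, present[i, ]] <- (v - mean(v)) / s
    }
  }
  if (zero_var > 0) {
    warning(zero_var, " feature(s) had zero variance; normalized to 0")
  }
  attr(out, "presence") <- present
  out
}
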