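#' Assemble a pipeline configuration
#'
#' Collects stage parameters for the end-to-end analysis; any subset can be
#' overridden. A configuration can also be read from a YAML file with
#' \code{\link{read_pipeline_config}}.
#'
#' @param snr_threshold S/N cutoff (strict).
#' @param mz_low,mz_high analysis window (Th).
#' @param calibrate run internal CH2-series calibration.
#' @param iso_tol_ppm,iso_ratio_max isotopologue removal parameters.
#' @param blank_tol_ppm blank subtraction tolerance (ppm).
#' @param align_tol_ppm,min_samples alignment parameters.
#' @param assign_tol_ppm assignment tolerance (ppm).
#' @param error_filter_ppm post-assignment |error| ceiling (ppm).
#' @param bounds an \code{\link{element_bounds}}.
#' @param n_perm,n_boot permutation/bootstrap counts.
#' @param seed integer seed used by the stochastic statistics.
#' @return Named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(snr_threshold = 7, mz_low = 200, mz_high = 900,
                            calibrate = TRUE, iso_tol_ppm = 1.0,
                            iso_ratio_max = 0.6, blank_tol_ppm = 1.0,
                            align_tol_ppm = 1.0, min_samples = 2,
                            assign_tol_ppm = 1.0, error_filter_ppm = 0.5,
                            bounds = element_bounds(), n_perm = 999,
                            n_boot = 10000, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys override \code{\link{pipeline_config}} defaults; unknown
#' keys are an error.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes peak QC (S/N filter, m/z window, internal calibration,
#' isotopologue removal, blank subtraction), cross-sample alignment with
#' prevalence filtering, CHNOSP formula assignment, nitrogen-metabolome
#' descriptors and the statistical layer, writing every stage artifact to
#' \code{out_dir} along with a QC funnel report.
#'
#' @param samples list of \code{\link{sample_spectrum}}.
#' @param blanks list of blank \code{sample_spectrum}.
#' @param config a \code{\link{pipeline_config}}.
#' @param quant optional quantitative table (see
#'   \code{\link{exudate_balance}}).
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @return List with \code{aligned}, \code{assignments}, \code{matrix}
#'   (\code{molecule_matrix}), \code{funnel} (stage counts),
#'   \code{ra_series}, \code{class_props}, \code{element_totals},
#'   \code{venn}, \code{important}, \code{permanova} (per phase),
#'   \code{pca}, and (when quant given) \code{balance} and
#'   \code{quant_tests}.
#' @export
run_pipeline <- function(samples, blanks = list(),
                         config = pipeline_config(), quant = NULL,
                         out_dir = NULL) {
  for (s in samples) {
    ok <- inherits(s, "sample_spectrum") && is.data.frame(s$peaks) &&
      all(c("mz", "intensity", "snr") %in% names(s$peaks))
    if (!ok) {
      stop("invalid sample spectrum for sample ",
           if (is.list(s) && !is.null(s$sample_id)) s$sample_id else "?")
    }
  }
  funnel <- list(peaks_detected = sum(vapply(samples, n_peaks, integer(1))))
  stage <- function(f, specs, what) {
    lapply(specs, function(s) {
      tryCatch(f(s), error = function(e) {
        stop("stage '", what, "' failed for sample ", s$sample_id, ": ",
             conditionMessage(e))
      })
    })
  }
  samples <- stage(function(s) filter_snr(s, config$snr_threshold),
                   samples, "snr_filter")
  samples <- stage(function(s) filter_mz_window(s, config$mz_low,
                                                config$mz_high),
                   samples, "mz_window")
  # blank subtraction precedes calibration: blanks carry no homologous
  # series, so both sides must be matched in the same (raw) mass state
  blanks_qc <- lapply(blanks, function(b) {
    filter_mz_window(filter_snr(b, config$snr_threshold),
                     config$mz_low, config$mz_high)
  })
  samples <- subtract_blanks(samples, blanks_qc, config$blank_tol_ppm)
  if (config$calibrate) {
    samples <- stage(function(s) calibrate_internal(s)$spectrum,
                     samples, "calibration")
  }
  samples <- stage(function(s) remove_isotopologues(
    s, tol_ppm = config$iso_tol_ppm, ratio_max = config$iso_ratio_max),
    samples, "isotopologue_removal")
  funnel$peaks_after_qc <- sum(vapply(samples, n_peaks, integer(1)))
  aligned <- align_and_prevalence_filter(samples, config$align_tol_ppm,
                                         config$min_samples)
  funnel$consensus_bins <- length(aligned$mz)
  assignments <- assign_formula(aligned$mz, tol_ppm = config$assign_tol_ppm,
                                bounds = config$bounds,
                                error_filter_ppm = config$error_filter_ppm)
  funnel$molecules_assigned <- sum(assignments$assigned)
  mat <- molecule_matrix(aligned, assignments)
  funnel$molecules_assigned_N <- sum(mat$molecules$N > 0)
  stopifnot(!is.unsorted(-unlist(funnel[c("peaks_detected",
                                          "peaks_after_qc")])))
  ra_series <- tryCatch(response_ratio_series(mat), error = function(e) NULL)
  class_props <- class_proportions(mat)
  etot <- element_totals(mat)
  venn <- tryCatch(venn_partition(mat, phase = "treatment"),
                   error = function(e) NULL)
  important <- if (!is.null(venn)) {
    drought_idx <- which(venn$levels == "drought")
    uniq <- if (drought_idx == 1) venn$unique_A else venn$unique_B
    select_important(mat, uniq)
  } else NULL
  perm <- list()
  for (ph in unique(mat$metadata$phase)) {
    keep <- mat$metadata$phase == ph
    if (sum(keep) < 4) next
    sub <- mat$presence[keep, mat$molecules$N > 0, drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (ncol(sub) < 2) next
    d <- bray_curtis_binary(sub)
    des <- mat$metadata[keep, c("treatment", "day"), drop = FALSE]
    terms <- if (length(unique(des$day)) > 1) {
      c("treatment", "day", "treatment:day")
    } else "treatment"
    perm[[ph]] <- tryCatch(
      permanova(d, des, terms, n_perm = config$n_perm, seed = config$seed),
      error = function(e) NULL)
  }
  pca <- tryCatch(pca_squared_cosines(
    class_props[, ELEMENTAL_CLASSES],
    supplementary = class_props[, c("treatment", "phase")]),
    error = function(e) NULL)
  out <- list(aligned = aligned, assignments = assignments, matrix = mat,
              funnel = funnel, ra_series = ra_series,
              class_props = class_props, element_totals = etot,
              venn = venn, important = important, permanova = perm,
              pca = pca, config = config)
  if (!is.null(quant)) {
    out$balance <- exudate_balance(quant)
    out$quant_tests <- tryCatch(
      quant_tests(out$balance, n_boot = config$n_boot, seed = config$seed),
      error = function(e) NULL)
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline artifacts to disk
#'
#' TSV tables for every stage plus a JSON funnel report echoing the
#' configuration for provenance.
#'
#' @param result list from \code{\link{run_pipeline}}.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, \code{out_dir}.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (is.null(x)) return()
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  aligned_tab <- cbind(data.frame(mz = result$aligned$mz),
                       as.data.frame(result$aligned$intensity))
  w(aligned_tab, "aligned_intensities.tsv")
  w(result$assignments, "assignments.tsv")
  w(result$ra_series, "response_ratio_series.tsv")
  w(result$class_props, "class_proportions.tsv")
  w(result$element_totals, "element_totals.tsv")
  w(result$important, "important_molecules.tsv")
  for (ph in names(result$permanova)) {
    w(result$permanova[[ph]], paste0("permanova_", ph, ".tsv"))
  }
  if (!is.null(result$pca)) {
    w(cbind(variable = rownames(result$pca$sq_cos),
            as.data.frame(result$pca$sq_cos)), "pca_squared_cosines.tsv")
  }
  w(result$balance, "exudate_balance.tsv")
  w(result$quant_tests, "quant_tests.tsv")
  if (!is.null(result$venn)) {
    jsonlite::write_json(result$venn, file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE)
  }
  cfg <- result$config
  cfg$bounds <- unclass(cfg$bounds)
  jsonlite::write_json(list(funnel = result$funnel, config = unclass(cfg)),
                       file.path(out_dir, "funnel_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a dataset and run the pipeline end to end
#'
#' Convenience wrapper: generates a synthetic experiment from
#' \code{\link{sim_config}} and runs \code{\link{run_pipeline}} on it.
#'
#' @param sim_cfg a \code{\link{sim_config}}.
#' @param pipe_cfg a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory.
#' @param quant include the quantitative table.
#' @return The \code{\link{run_pipeline}} result, with the simulation
#'   attached as \code{$sim}.
#' @export
run_synthetic_pipeline <- function(sim_cfg = sim_config(),
                                   pipe_cfg = pipeline_config(
                                     seed = sim_cfg$seed),
                                   out_dir = NULL, quant = TRUE) {
  sim <- simulate_peak_tables(sim_cfg)
  qt <- if (quant) simulate_quant_tables(sim_cfg) else NULL
  res <- run_pipeline(sim$samples, sim$blanks, pipe_cfg, quant = qt,
                      out_dir = out_dir)
  res$sim <- sim
  res
}
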