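#' Build a molecule presence/absence matrix
#'
#' Transforms an aligned intensity table plus formula assignments into a
#' samples x molecules binary matrix restricted to molecules with an
#' assigned formula, carrying the formula table and sample metadata.
#' An entry is 1 iff the intensity is positive and non-missing. If the
#' intensity matrix has a \code{"presence"} attribute (set by
#' \code{\link{normalize_intensities}}), that original pattern is used, so
#' normalization never alters presence/absence.
#'
#' @param intensity molecules x samples numeric matrix (0/\code{NA} =
#'   absent), or an \code{aligned_peaks} object.
#' @param assignments data frame from \code{\link{assign_formula}}, one row
#'   per intensity row; unassigned rows are dropped.
#' @param metadata per-sample data frame with columns \code{sample_id},
#'   \code{treatment}, \code{day}, \code{phase} (taken from the
#'   \code{aligned_peaks} object when available).
#' @return An object of class \code{molecule_matrix}: list with
#'   \code{presence} (samples x molecules 0/1), \code{molecules} (data frame
#'   with m/z, element counts, formula, class) and \code{metadata}.
#' @export
molecule_matrix <- function(intensity, assignments, metadata = NULL) {
  if (inherits(intensity, "aligned_peaks")) {
    if (is.null(metadata)) metadata <- intensity$metadata
    intensity <- intensity$intensity
  }
  pres_attr <- attr(intensity, "presence")
  if (is.null(pres_attr) && any(intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are invalid")
  }
  if (nrow(intensity) != nrow(assignments)) {
    stop("assignments must have one row per intensity row")
  }
  keep <- which(assignments$assigned)
  pres <- if (!is.null(pres_attr)) pres_attr else {
    !is.na(intensity) & intensity > 0
  }
  pres <- t(pres[keep, , drop = FALSE]) * 1L
  mol <- assignments[keep, c("mz", "C", "H", "N", "O", "S", "P",
                             "formula", "error_ppm", "elemental_class")]
  mol$id <- sprintf("M%05d", seq_len(nrow(mol)))
  rownames(mol) <- NULL
  colnames(pres) <- mol$id
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(pres))
  }
  metadata <- metadata[match(rownames(pres), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(presence = pres, molecules = mol, metadata = metadata),
            class = "molecule_matrix")
}

#' @export
print.molecule_matrix <- function(x, ...) {
  cat("molecule_matrix:", nrow(x$presence), "samples x",
      ncol(x$presence), "assigned molecules (",
      sum(x$molecules$N > 0), "N-containing )\n")
  invisible(x)
}

#' Presence/absence transform of an intensity table
#'
#' @param intensity numeric matrix or vector; entries must be >= 0 or
#'   missing.
#' @return Integer 0/1 object of the same shape; 1 iff positive and
#'   non-missing. Idempotent.
#' @export
presence_absence <- function(intensity) {
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are invalid")
  }
  out <- (!is.na(intensity) & intensity > 0) * 1L
  dim(out) <- dim(intensity)
  dimnames(out) <- dimnames(intensity)
  out
}

#' Relative abundance of N-containing molecules
#'
#' Per sample: 100 x (count of N-containing molecules present) / (count of
#' all molecules present).
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param sample_id optional sample subset; all samples by default.
#' @return Data frame with \code{sample_id}, \code{treatment}, \code{day},
#'   \code{phase}, \code{n_present}, \code{n_nitrogen}, \code{RA} (percent;
#'   \code{NA} with \code{flag_empty} when a sample has no molecules).
#' @export
relative_abundance <- function(mat, sample_id = NULL) {
  pres <- mat$presence
  if (!is.null(sample_id)) {
    pres <- pres[rownames(pres) %in% sample_id, , drop = FALSE]
  }
  is_n <- mat$molecules$N > 0
  total <- rowSums(pres)
  n_cont <- rowSums(pres[, is_n, drop = FALSE])
  ra <- ifelse(total > 0, 100 * n_cont / total, NA_real_)
  meta <- mat$metadata[match(rownames(pres), mat$metadata$sample_id), ,
                       drop = FALSE]
  data.frame(sample_id = rownames(pres),
             treatment = meta$treatment, day = meta$day, phase = meta$phase,
             n_present = total, n_nitrogen = n_cont, RA = ra,
             flag_empty = total == 0, row.names = NULL)
}

#' Relative abundance response ratio
#'
#' 100 x (RA_drought - RA_control) / RA_drought, for day-level mean relative
#' abundances; positive values mean drought-enriched nitrogen molecules.
#' Undefined (missing, flagged) when RA_drought is 0, since the ratio
#' normalizes by the drought mean.
#'
#' @param RA_drought,RA_control day-level mean RA values (percent),
#'   vectorised.
#' @return Data frame with \code{response_ratio} (percent) and
#'   \code{flag_undefined}.
#' @export
response_ratio <- function(RA_drought, RA_control) {
  undef <- !is.na(RA_drought) & RA_drought == 0
  rr <- ifelse(undef, NA_real_,
               100 * (RA_drought - RA_control) / RA_drought)
  data.frame(response_ratio = rr, flag_undefined = undef)
}

#' Day-by-day response-ratio time series
#'
#' Averages per-sample RA by day and treatment, then forms the response
#' ratio per day.
#'
#' @param mat a \code{\link{molecule_matrix}} with day and treatment
#'   metadata.
#' @return Data frame with \code{day}, \code{phase}, \code{RA_control},
#'   \code{RA_drought}, \code{response_ratio}.
#' @export
response_ratio_series <- function(mat) {
  ra <- relative_abundance(mat)
  agg <- stats::aggregate(RA ~ day + treatment, data = ra, FUN = mean,
                          na.action = stats::na.omit)
  wide <- stats::reshape(agg, idvar = "day", timevar = "treatment",
                         direction = "wide")
  names(wide) <- sub("^RA\\.", "RA_", names(wide))
  wide <- wide[order(wide$day), ]
  rr <- response_ratio(wide$RA_drought, wide$RA_control)
  data.frame(day = wide$day, phase = day_phase(wide$day),
             RA_control = wide$RA_control, RA_drought = wide$RA_drought,
             response_ratio = rr$response_ratio, row.names = NULL)
}

#' Elemental-class proportions per sample
#'
#' Fraction of each sample's present molecules falling in each elemental
#' group (CHON, CHON-S, CHON-P, CHON-SP, nonN); rows sum to 1.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param sample_id optional sample subset.
#' @return Data frame: \code{sample_id}, metadata columns, one column per
#'   class, \code{n_present}. Samples with nothing present get \code{NA}
#'   proportions.
#' @export
class_proportions <- function(mat, sample_id = NULL) {
  pres <- mat$presence
  if (!is.null(sample_id)) {
    pres <- pres[rownames(pres) %in% sample_id, , drop = FALSE]
  }
  cls <- mat$molecules$elemental_class
  counts <- sapply(ELEMENTAL_CLASSES, function(cl) {
    rowSums(pres[, cls == cl, drop = FALSE])
  })
  counts <- matrix(counts, nrow = nrow(pres),
                   dimnames = list(rownames(pres), ELEMENTAL_CLASSES))
  total <- rowSums(counts)
  prop <- counts / ifelse(total > 0, total, NA_real_)
  meta <- mat$metadata[match(rownames(pres), mat$metadata$sample_id), ,
                       drop = FALSE]
  out <- data.frame(sample_id = rownames(pres), treatment = meta$treatment,
                    day = meta$day, phase = meta$phase, row.names = NULL)
  cbind(out, as.data.frame(prop), n_present = total)
}

#' Occurrence-weighted element totals
#'
#' Groups samples (by phase and/or treatment) and totals molecule
#' occurrences (each molecule counted once per sample where present),
#' N-containing occurrences, summed C and N atom counts, and the
#' element-mass C:N ratio \code{(sum C x 12.011) / (sum N x 14.007)}.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param group_by character vector of metadata columns, default
#'   \code{c("phase","treatment")}; \code{NULL} for a single grand total.
#' @return Data frame with grouping columns, \code{n_molecules},
#'   \code{n_molecules_N}, \code{sum_C}, \code{sum_N}, \code{mass_CN}
#'   (\code{NA} when no N atoms).
#' @export
element_totals <- function(mat, group_by = c("phase", "treatment")) {
  pres <- mat$presence
  mol <- mat$molecules
  meta <- mat$metadata
  grp <- if (is.null(group_by)) rep("total", nrow(pres)) else {
    do.call(paste, c(meta[group_by], sep = "\r"))
  }
  is_n <- mol$N > 0
  res <- lapply(unique(grp), function(g) {
    sub <- pres[grp == g, , drop = FALSE]
    occ <- colSums(sub)
    data.frame(.group = g,
               n_molecules = sum(occ),
               n_molecules_N = sum(occ[is_n]),
               sum_C = sum(occ * mol$C),
               sum_N = sum(occ * mol$N))
  })
  out <- do.call(rbind, res)
  out$mass_CN <- mass_cn_ratio(out$sum_C, out$sum_N)
  if (!is.null(group_by)) {
    keys <- do.call(rbind, strsplit(out$.group, "\r", fixed = TRUE))
    colnames(keys) <- group_by
    out <- cbind(as.data.frame(keys, stringsAsFactors = FALSE),
                 out[, -1, drop = FALSE])
  } else {
    out$.group <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Element-mass C:N ratio from atom counts
#'
#' \code{(sum_C x 12.011) / (sum_N x 14.007)}: the relative elemental mass
#' of C over N carried by the detected molecules.
#'
#' @param sum_C,sum_N summed atom counts (vectorised).
#' @return Numeric ratio; \code{NA} where \code{sum_N} is 0.
#' @examples
#' mass_cn_ratio(875625, 21602)  # 34.8
#' @export
mass_cn_ratio <- function(sum_C, sum_N) {
  ifelse(sum_N > 0,
         (sum_C * AVERAGE_MASS[["C"]]) / (sum_N * AVERAGE_MASS[["N"]]),
         NA_real_)
}

#' Molecular-weight bin of a detected mass
#'
#' Low molecular weight (LMW) covers [200, 600), high molecular weight
#' (HMW) [600, 900]; masses outside the detection window are an error.
#'
#' @param mz deprotonated mass (amu), vectorised.
#' @return Character vector \code{"LMW"}/\code{"HMW"}.
#' @export
mw_bin <- function(mz) {
  if (any(mz < 200 | mz > 900, na.rm = TRUE)) {
    stop("mass outside the 200-900 amu detection window")
  }
  ifelse(mz < 600, "LMW", "HMW")
}

#' Kernel density of N-containing molecule masses by group
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) over the
#' masses of present N-containing molecules, per group; each present
#' occurrence contributes one observation.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param group_by metadata columns defining groups, default
#'   \code{c("phase","treatment")}.
#' @param from,to optional evaluation range (amu); by default the kernel
#'   support is left unclipped so the density integrates to 1.
#' @return Named list of \code{stats::density} objects (\code{NULL} for
#'   groups with fewer than 2 masses), plus a \code{"masses"} attribute
#'   holding the per-group observation vectors.
#' @export
mw_density <- function(mat, group_by = c("phase", "treatment"),
                       from = NULL, to = NULL) {
  meta <- mat$metadata
  grp <- do.call(paste, c(meta[group_by], sep = "."))
  is_n <- mat$molecules$N > 0
  mz <- mat$molecules$mz
  masses <- lapply(unique(grp), function(g) {
    sub <- mat$presence[grp == g, is_n, drop = FALSE]
    rep(mz[is_n], colSums(sub))
  })
  names(masses) <- unique(grp)
  dens <- lapply(masses, function(m) {
    if (length(m) < 2) return(NULL)
    if (is.null(from)) stats::density(m, bw = "nrd0")
    else stats::density(m, bw = "nrd0", from = from, to = to)
  })
  attr(dens, "masses") <- masses
  dens
}

#' Venn partition of molecules between two factor levels
#'
#' Within one experimental phase, splits the molecules observed in any
#' sample into those unique to each level of the factor (default
#' treatment) and those shared; restricted to N-containing molecules by
#' default, matching the nitrogen-metabolome analysis.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param phase phase to restrict to (e.g. \code{"treatment"}).
#' @param factor metadata column with exactly two observed levels.
#' @param nitrogen_only restrict to N-containing molecules.
#' @return List with \code{unique_A}, \code{unique_B}, \code{shared}
#'   (character id vectors), and \code{levels} naming A and B.
#' @export
venn_partition <- function(mat, phase, factor = "treatment",
                           nitrogen_only = TRUE) {
  meta <- mat$metadata
  in_phase <- meta$phase == phase
  lev <- sort(unique(meta[[factor]][in_phase]))
  if (length(lev) != 2) {
    stop("factor '", factor, "' must have exactly two levels in phase '",
         phase, "' (found ", length(lev), ")")
  }
  keep_mol <- if (nitrogen_only) mat$molecules$N > 0 else
    rep(TRUE, ncol(mat$presence))
  ids <- mat$molecules$id[keep_mol]
  seen <- function(l) {
    sub <- mat$presence[in_phase & meta[[factor]] == l, keep_mol,
                        drop = FALSE]
    ids[colSums(sub) > 0]
  }
  a <- seen(lev[1]); b <- seen(lev[2])
  list(unique_A = setdiff(a, b), unique_B = setdiff(b, a),
       shared = intersect(a, b), levels = lev)
}

#' Select drought-important molecules
#'
#' From a set of treatment-unique molecules, selects those present on at
#' least \code{min_days} distinct sampling days of the phase and detected
#' in at least \code{min_occurrence} samples in total.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param unique_set character vector of molecule ids (e.g. the
#'   drought-unique set from \code{\link{venn_partition}}).
#' @param phase phase whose samples are counted.
#' @param min_days minimum distinct days present.
#' @param min_occurrence minimum total sample detections.
#' @return Data frame (Table-style layout): \code{mz}, \code{formula},
#'   \code{days_present}, \code{occurrence}, \code{id}, sorted by m/z;
#'   only selected molecules.
#' @export
select_important <- function(mat, unique_set, phase = "treatment",
                             min_days = 3, min_occurrence = 5) {
  if (length(unique_set) == 0) {
    return(data.frame(mz = numeric(), formula = character(),
                      days_present = integer(), occurrence = integer(),
                      id = character()))
  }
  stopifnot(all(unique_set %in% mat$molecules$id))
  meta <- mat$metadata
  in_phase <- meta$phase == phase
  idx <- match(unique_set, mat$molecules$id)
  sub <- mat$presence[in_phase, idx, drop = FALSE]
  days <- meta$day[in_phase]
  days_present <- apply(sub, 2, function(v) length(unique(days[v > 0])))
  occurrence <- colSums(sub)
  sel <- days_present >= min_days & occurrence >= min_occurrence
  out <- data.frame(mz = mat$molecules$mz[idx][sel],
                    formula = mat$molecules$formula[idx][sel],
                    days_present = days_present[sel],
                    occurrence = occurrence[sel],
                    id = unique_set[sel], row.names = NULL)
  out[order(out$mz), , drop = FALSE]
}

#' KEGG pathway annotation hook
#'
#' Placeholder for pathway mapping of assigned molecules. No N-containing
#' exudate molecules have database matches in this workflow, so the default
#' annotator returns no matches; an external annotator function
#' \code{f(formula_strings)} can be plugged in.
#'
#' @param mat a \code{\link{molecule_matrix}}.
#' @param annotator optional function mapping formula strings to a data
#'   frame of matches.
#' @return Data frame of matches (empty by default).
#' @export
kegg_annotate <- function(mat, annotator = NULL) {
  if (is.null(annotator)) {
    return(data.frame(id = character(), formula = character(),
                      pathway = character()))
  }
  annotator(mat$molecules$formula)
}
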