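#' Derive total organic nitrogen
#'
#' TON = total N minus inorganic N (NO3-N + NH4-N); inorganic nitrate is an
#' artifact of the nutrient solution rinsed from roots during collection.
#' A negative balance is recorded as missing with a flag rather than
#' clamped, so downstream means are not silently biased.
#'
#' @param TN,NO3N,NH4N concentrations in mg/L, all >= 0 (vectorised).
#' @return Data frame with columns \code{TON} (mg/L, \code{NA} when the
#'   balance is negative) and \code{flag_negative} (logical).
#' @examples
#' derive_TON(43.0, 8.6, 0)  # TON 34.4, inorganic fraction 20%
#' @export
derive_TON <- function(TN, NO3N, NH4N = 0) {
  if (any(c(TN, NO3N, NH4N) < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  ton <- TN - NO3N - NH4N
  neg <- !is.na(ton) & ton < 0
  ton[neg] <- NA_real_
  data.frame(TON = ton, flag_negative = neg)
}

#' Mass exuded during collection
#'
#' Concentration times the rinseate volume supplied during exudate
#' collection (128.8 mL by default), in mg.
#'
#' @param conc concentration (mg/L), >= 0.
#' @param volume_mL rinseate volume (mL), > 0.
#' @return Mass in mg (vectorised).
#' @examples
#' mass_exuded(84.2)  # 10.8 mg
#' @export
mass_exuded <- function(conc, volume_mL = 128.8) {
  if (any(conc < 0, na.rm = TRUE)) stop("conc must be >= 0")
  if (any(volume_mL <= 0)) stop("volume must be > 0")
  conc * volume_mL / 1000
}

#' Specific exudation
#'
#' Exuded mass normalized to root dry weight (mg per g root DW).
#'
#' @param mass exuded mass (mg).
#' @param root_dw root dry weight (g), > 0.
#' @return mg/g (vectorised).
#' @export
specific_exudation <- function(mass, root_dw) {
  if (any(root_dw <= 0, na.rm = TRUE)) stop("root_dw must be > 0")
  mass / root_dw
}

#' Carbon-to-nitrogen ratio of exuded masses
#'
#' Ratio of total C exudation to total N exudation. With replicate vectors,
#' \code{"per_replicate_then_mean"} (default) averages the per-replicate
#' ratios, while \code{"ratio_of_means"} divides the mean masses; the two
#' differ whenever replicates vary.
#'
#' @param TOC_mass,TON_mass exuded masses (mg), equal length.
#' @param aggregation \code{"per_replicate_then_mean"} or
#'   \code{"ratio_of_means"}.
#' @return List with \code{cn} (the ratio) and \code{flag_zero_TON}
#'   (logical; any replicate with TON 0 treated as missing).
#' @export
cn_ratio <- function(TOC_mass, TON_mass,
                     aggregation = c("per_replicate_then_mean",
                                     "ratio_of_means")) {
  aggregation <- match.arg(aggregation)
  if (length(TOC_mass) != length(TON_mass)) {
    stop("TOC_mass and TON_mass must have equal length")
  }
  zero <- !is.na(TON_mass) & TON_mass == 0
  TON_mass[zero] <- NA_real_
  cn <- switch(aggregation,
    per_replicate_then_mean = mean(TOC_mass / TON_mass, na.rm = TRUE),
    ratio_of_means = mean(TOC_mass[!is.na(TON_mass)], na.rm = TRUE) /
      mean(TON_mass, na.rm = TRUE))
  if (is.nan(cn)) cn <- NA_real_
  list(cn = cn, flag_zero_TON = any(zero))
}

# Proteinogenic amino acids: N atoms per molecule and average molar mass.
AMINO_ACIDS <- data.frame(
  name = c("alanine", "arginine", "asparagine", "aspartic_acid", "cysteine",
           "glutamic_acid", "glutamine", "glycine", "histidine",
           "isoleucine", "leucine", "lysine", "methionine", "phenylalanine",
           "proline", "serine", "threonine", "tryptophan", "tyrosine",
           "valine"),
  n_count = c(1, 4, 2, 1, 1, 1, 2, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
  molar_mass = c(89.09, 174.20, 132.12, 133.10, 121.16, 147.13, 146.15,
                 75.07, 155.15, 131.17, 131.17, 146.19, 149.21, 165.19,
                 115.13, 105.09, 119.12, 204.23, 181.19, 117.15),
  stringsAsFactors = FALSE)

#' Nitrogen contributed by free amino acids
#'
#' Converts an amino-acid concentration profile (mg/L per amino acid) to
#' total amino-acid nitrogen: each concentration is scaled by
#' \code{n_count * 14.007 / average_molar_mass} from a built-in table of the
#' 20 proteinogenic amino acids.
#'
#' @param profile named numeric vector or list, names being amino acids
#'   (e.g. \code{"glycine"}, \code{"aspartic_acid"}); case-insensitive.
#' @param extra optional data frame with columns \code{name},
#'   \code{n_count}, \code{molar_mass} extending the built-in table.
#' @return Total amino-acid N in mg N/L.
#' @examples
#' amino_acid_nitrogen(c(glycine = 10))      # 1.87 mg N/L
#' amino_acid_nitrogen(c(asparagine = 10))   # 2.12 mg N/L
#' @export
amino_acid_nitrogen <- function(profile, extra = NULL) {
  if (length(profile) == 0) return(0)
  tab <- AMINO_ACIDS
  if (!is.null(extra)) tab <- rbind(tab, extra[, names(tab)])
  nm <- tolower(names(profile))
  unknown <- setdiff(nm, tab$name)
  if (length(unknown) > 0) {
    stop("unknown amino acid(s): ", paste(unknown, collapse = ", "),
         "; accepted names: ", paste(tab$name, collapse = ", "))
  }
  i <- match(nm, tab$name)
  sum(unlist(profile) * tab$n_count[i] * AVERAGE_MASS[["N"]] /
        tab$molar_mass[i])
}

#' Full exudate N/C balance for a quantitative table
#'
#' Applies the TON derivation, mass and specific exudation, C:N and
#' amino-acid N to each record of a quantitative table (as produced by
#' \code{\link{simulate_quant_tables}} or read from TSV).
#'
#' @param quant data frame with columns \code{TOC_conc}, \code{TN_conc},
#'   \code{NO3N_conc}, \code{NH4N_conc}, \code{rinseate_volume_mL},
#'   \code{root_dry_weight_g}, optional \code{aa_*} columns and optional
#'   \code{plants_per_pot}.
#' @param per_plant if \code{TRUE}, masses are additionally divided by
#'   \code{plants_per_pot}; the default \code{FALSE} reports whole-pot
#'   collection masses.
#' @return The input with appended columns \code{TON_conc},
#'   \code{flag_negative_TON}, \code{TOC_mass}, \code{TON_mass},
#'   \code{specific_TOC}, \code{specific_TON}, \code{CN_ratio},
#'   \code{AA_N_conc}.
#' @export
exudate_balance <- function(quant, per_plant = FALSE) {
  ton <- derive_TON(quant$TN_conc, quant$NO3N_conc, quant$NH4N_conc)
  quant$TON_conc <- ton$TON
  quant$flag_negative_TON <- ton$flag_negative
  div <- if (per_plant) {
    if (is.null(quant$plants_per_pot)) stop("plants_per_pot column required")
    quant$plants_per_pot
  } else 1
  quant$TOC_mass <- mass_exuded(quant$TOC_conc,
                                quant$rinseate_volume_mL) / div
  quant$TON_mass <- mass_exuded(ifelse(is.na(quant$TON_conc), 0,
                                       quant$TON_conc),
                                quant$rinseate_volume_mL) / div
  quant$TON_mass[is.na(quant$TON_conc)] <- NA_real_
  quant$specific_TOC <- specific_exudation(quant$TOC_mass,
                                           quant$root_dry_weight_g)
  quant$specific_TON <- specific_exudation(quant$TON_mass,
                                           quant$root_dry_weight_g)
  quant$CN_ratio <- quant$TOC_mass / quant$TON_mass
  aa_cols <- grep("^aa_", names(quant), value = TRUE)
  quant$AA_N_conc <- if (length(aa_cols) > 0) {
    apply(quant[, aa_cols, drop = FALSE], 1, function(v) {
      names(v) <- sub("^aa_", "", aa_cols)
      amino_acid_nitrogen(v)
    })
  } else 0
  quant
}
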