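#' Configuration for the synthetic root-exudate experiment
#'
#' Defines the simulated experiment: an aeroponic time series with two
#' treatments (well-watered control vs progressive drought), nine sampling
#' days (0, 2, 4, 7, 9, 11, 14, 16, 18), five of ten pots sampled per
#' treatment per day, a CHNOSP molecule catalog emitting negative-mode
#' \eqn{[M-H]^-} peaks, instrument noise, 13C isotopologues, blank
#' contaminants, and drought enrichment of N-containing low-molecular-weight
#' molecules in the 275--390 and 450--550 amu windows during the treatment
#' phase (days 2--11) only.
#'
#' @param n_pots_per_treatment pots grown per treatment.
#' @param plants_per_pot plants per pot.
#' @param days sampling days after treatment start; days 2--11 form the
#'   treatment phase, day 0 baseline, later days recovery.
#' @param pots_sampled_per_day pots randomly selected per treatment per day.
#' @param formula_library_size number of distinct catalog molecules.
#' @param n_fraction target fraction of catalog molecules containing N.
#' @param base_presence_range range of per-molecule baseline presence
#'   probabilities (drawn uniformly per molecule).
#' @param n_noise_peaks spurious low-S/N peaks added per sample.
#' @param drought_lmw_windows two-column matrix of (low, high) amu windows
#'   in which drought boosts N-molecule presence.
#' @param drought_presence_boost additive presence-probability increment for
#'   N-containing molecules inside the windows, drought samples, days 2--11.
#' @param quant_effects named list of drought/control mean multipliers per
#'   phase for the quantitative analytes (\code{TOC}, \code{TON},
#'   \code{amino_acids}); defaults reproduce drought effects of the observed
#'   magnitude (TON about +69\%, TOC about +7\% at end of treatment).
#' @param calibration_offset_ppm multiplicative instrument mass error (ppm)
#'   applied to every emitted peak.
#' @param mass_jitter_ppm SD of per-peak random mass error (ppm).
#' @param isotopologue_rate probability a present molecule also emits its
#'   13C isotopologue peak.
#' @param blank_contaminant_count contaminant masses present in blanks (and,
#'   with high probability, in samples).
#' @param n_calibration_series,calibration_series_length number and length
#'   of CH2 homologous series included in the catalog as ever-present,
#'   high-intensity calibrant molecules.
#' @param seed integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_pots_per_treatment = 10,
                       plants_per_pot = 3,
                       days = c(0, 2, 4, 7, 9, 11, 14, 16, 18),
                       pots_sampled_per_day = 5,
                       formula_library_size = 4000,
                       n_fraction = 0.4,
                       base_presence_range = c(0.02, 0.10),
                       n_noise_peaks = 80,
                       drought_lmw_windows = rbind(c(275, 390),
                                                   c(450, 550)),
                       drought_presence_boost = 0.25,
                       quant_effects = list(
                         treatment = c(TOC = 1.066, TON = 1.686,
                                       amino_acids = 6.62),
                         recovery = c(TOC = 1.013, TON = 1.530,
                                      amino_acids = 1.0)),
                       calibration_offset_ppm = 0,
                       mass_jitter_ppm = 0.1,
                       isotopologue_rate = 0.2,
                       blank_contaminant_count = 10,
                       n_calibration_series = 2,
                       calibration_series_length = 10,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(n_fraction, base_presence_range, drought_presence_boost,
             isotopologue_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities (n_fraction, base_presence_range, ",
         "drought_presence_boost, isotopologue_rate) must lie in [0, 1]")
  }
  w <- drought_lmw_windows
  if (!is.matrix(w) || ncol(w) != 2 || any(w < 200) || any(w > 900) ||
      any(w[, 1] >= w[, 2])) {
    stop("drought_lmw_windows must be a 2-column matrix of (low, high) ",
         "intervals within [200, 900]")
  }
  if (formula_library_size < 0) stop("formula_library_size must be >= 0")
  if (pots_sampled_per_day > n_pots_per_treatment) {
    stop("pots_sampled_per_day cannot exceed n_pots_per_treatment")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Experimental phase of a sampling day
#'
#' Day 0 is baseline, days 2--11 the progressive-drought treatment phase,
#' days 14--18 recovery.
#'
#' @param day numeric vector of days after treatment start.
#' @return Character vector over \code{c("baseline","treatment","recovery")}.
#' @export
day_phase <- function(day) {
  ifelse(day == 0, "baseline", ifelse(day <= 11, "treatment", "recovery"))
}

.in_windows <- function(mz, windows) {
  hit <- rep(FALSE, length(mz))
  for (r in seq_len(nrow(windows))) {
    hit <- hit | (mz >= windows[r, 1] & mz <= windows[r, 2])
  }
  hit
}

#' Build the synthetic molecule catalog
#'
#' Draws \code{formula_library_size} distinct CHNOSP formulas by rejection
#' sampling within the element bounds of the assigned exudate metabolome
#' (C 5--56, N 0--3, S 0--3, P 0--2) with \eqn{[M-H]^-} m/z inside
#' [200, 900], integer DBE in [0, 40] and conventional H/C, O/C ranges.
#' About \code{n_fraction} of molecules carry at least one N. CH2 homologous
#' series are appended as CHO calibrant molecules, and specific formulas can
#' be forced into the catalog via \code{force_formulas}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param force_formulas optional character vector of formula strings that
#'   must appear in the catalog (counted toward its size).
#' @return Data frame catalog: \code{id}, element counts, \code{formula},
#'   \code{neutral_mass}, \code{mz} (deprotonated), \code{elemental_class},
#'   \code{in_drought_window}, \code{calibrant}, \code{base_presence}.
#' @export
build_formula_library <- function(config, force_formulas = NULL) {
  size <- config$formula_library_size
  if (size < 1 && length(force_formulas) == 0) {
    stop("configuration error: formula_library_size must be >= 1")
  }
  set.seed(config$seed)
  rows <- list()
  seen <- character()
  add_formula <- function(f, calibrant = FALSE) {
    key <- formula_string(f)
    if (key %in% seen) return(FALSE)
    mz <- sum(f[ELEMENTS] * MONOISOTOPIC_MASS) - PROTON_MASS
    rows[[length(rows) + 1]] <<- data.frame(
      C = f[["C"]], H = f[["H"]], N = f[["N"]], O = f[["O"]],
      S = f[["S"]], P = f[["P"]], formula = key,
      neutral_mass = mz + PROTON_MASS, mz = mz,
      calibrant = calibrant)
    seen <<- c(seen, key)
    TRUE
  }
  for (fs in force_formulas) add_formula(parse_formula(fs))
  # CH2 homologous calibrant series (CHO backbone)
  series_bases <- list(c(C = 10, H = 16, N = 0, O = 5, S = 0, P = 0),
                       c(C = 14, H = 22, N = 0, O = 7, S = 0, P = 0),
                       c(C = 12, H = 20, N = 0, O = 9, S = 0, P = 0))
  n_series <- min(config$n_calibration_series, length(series_bases))
  for (s in seq_len(n_series)) {
    base <- series_bases[[s]]
    for (k in seq_len(config$calibration_series_length) - 1L) {
      f <- base
      f[["C"]] <- f[["C"]] + k
      f[["H"]] <- f[["H"]] + 2L * k
      add_formula(f, calibrant = TRUE)
    }
  }
  n_target <- max(size, length(rows))
  max_iter <- 400L
  iter <- 0L
  while (length(rows) < n_target) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("configuration error: could not draw ", n_target,
           " distinct in-bounds formulas")
    }
    m <- 2L * as.integer(n_target - length(rows)) + 50L
    C <- sample(5:56, m, replace = TRUE)
    N <- sample(0:3, m, replace = TRUE,
                prob = c(1 - config$n_fraction,
                         config$n_fraction * c(0.6, 0.3, 0.1)))
    S <- sample(0:3, m, replace = TRUE, prob = c(0.85, 0.10, 0.04, 0.01))
    P <- sample(0:2, m, replace = TRUE, prob = c(0.92, 0.06, 0.02))
    H <- round(C * stats::runif(m, 0.8, 2.0))
    # force integer DBE: H parity must match N + P parity
    H <- H + ((H + N + P) %% 2L)
    H <- pmin(pmax(H, 4L), 120L)
    O <- round(C * stats::runif(m, 0.05, 0.8))
    O <- pmin(O, 40L)
    mz <- C * MONOISOTOPIC_MASS[["C"]] + H * MONOISOTOPIC_MASS[["H"]] +
      N * MONOISOTOPIC_MASS[["N"]] + O * MONOISOTOPIC_MASS[["O"]] +
      S * MONOISOTOPIC_MASS[["S"]] + P * MONOISOTOPIC_MASS[["P"]] -
      PROTON_MASS
    d <- dbe(C, H, N, P)
    ok <- mz >= 200 & mz <= 900 & d >= 0 & d <= 40 &
      H / C >= 0.3 & H / C <= 2.5 & O / C <= 1.2
    idx <- which(ok)
    for (i in idx) {
      if (length(rows) >= n_target) break
      add_formula(c(C = C[i], H = H[i], N = N[i], O = O[i],
                    S = S[i], P = P[i]))
    }
  }
  cat <- do.call(rbind, rows)
  cat$id <- sprintf("mol%05d", seq_len(nrow(cat)))
  cat$elemental_class <- classify_elemental(cat$N, cat$S, cat$P)
  cat$in_drought_window <- cat$N > 0 &
    .in_windows(cat$mz, config$drought_lmw_windows)
  cat$base_presence <- stats::runif(nrow(cat),
                                    config$base_presence_range[1],
                                    config$base_presence_range[2])
  cat$base_presence[cat$calibrant] <- 1
  rownames(cat) <- NULL
  cat[, c("id", "C", "H", "N", "O", "S", "P", "formula", "neutral_mass",
          "mz", "elemental_class", "in_drought_window", "calibrant",
          "base_presence")]
}

#' Simulate per-sample peak tables with known ground truth
#'
#' Draws the sampling design (five of ten pots per treatment per day),
#' per-sample molecule presence (baseline probability per molecule, plus
#' \code{drought_presence_boost} for N-containing window molecules in
#' drought samples during days 2--11), and emits peak lists: each present
#' molecule gives an \eqn{[M-H]^-} peak at its theoretical m/z scaled by
#' \code{(1 + offset_ppm * 1e-6)} plus random ppm jitter; with probability
#' \code{isotopologue_rate} a 13C partner appears at +1.003355 amu with
#' relative intensity 1.1\% per carbon; uniform noise peaks over
#' [150, 950] carry low S/N; blank contaminants appear in two blank spectra
#' and, with probability 0.9, in each sample.
#'
#' @param config a \code{\link{sim_config}}.
#' @param catalog optional catalog from \code{\link{build_formula_library}}
#'   (built from the config when omitted).
#' @return List with \code{samples} (list of \code{sample_spectrum}),
#'   \code{blanks}, \code{design} (data frame), and \code{ground_truth}
#'   (list: \code{catalog}, \code{presence} samples x molecules 0/1 matrix,
#'   \code{contaminant_mz}, \code{offset_ppm}).
#' @export
simulate_peak_tables <- function(config, catalog = NULL) {
  if (is.null(catalog)) catalog <- build_formula_library(config)
  set.seed(config$seed + 1L)
  design <- do.call(rbind, lapply(config$days, function(d) {
    do.call(rbind, lapply(c("control", "drought"), function(tr) {
      pots <- sort(sample(seq_len(config$n_pots_per_treatment),
                          config$pots_sampled_per_day))
      data.frame(sample_id = sprintf("d%02d_%s_p%02d", d,
                                     substr(tr, 1, 4), pots),
                 treatment = tr, day = d, phase = day_phase(d), pot = pots,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(design) <- NULL
  contaminant_mz <- sort(stats::runif(config$blank_contaminant_count,
                                      210, 890))
  off <- 1 + config$calibration_offset_ppm * 1e-6
  jit <- function(mz) {
    mz * (1 + stats::rnorm(length(mz), 0, config$mass_jitter_ppm * 1e-6))
  }
  n_mol <- nrow(catalog)
  presence <- matrix(0L, nrow(design), n_mol,
                     dimnames = list(design$sample_id, catalog$id))
  samples <- vector("list", nrow(design))
  boosted_day <- design$day >= 2 & design$day <= 11
  for (s in seq_len(nrow(design))) {
    p <- catalog$base_presence
    if (design$treatment[s] == "drought" && boosted_day[s]) {
      p <- pmin(1, p + config$drought_presence_boost *
                  catalog$in_drought_window)
    }
    pres <- stats::runif(n_mol) < p
    presence[s, ] <- as.integer(pres)
    idx <- which(pres)
    inten <- stats::rlnorm(length(idx), meanlog = log(1e6), sdlog = 1)
    inten[catalog$calibrant[idx]] <- inten[catalog$calibrant[idx]] * 5
    peaks <- data.frame(mz = jit(catalog$mz[idx] * off),
                        intensity = inten, snr = inten / 5e4)
    iso <- stats::runif(length(idx)) < config$isotopologue_rate
    if (any(iso)) {
      iso_int <- inten[iso] * 0.011 * catalog$C[idx][iso]
      peaks <- rbind(peaks, data.frame(
        mz = jit((catalog$mz[idx][iso] + C13_C12_DELTA) * off),
        intensity = iso_int, snr = iso_int / 5e4))
    }
    cont <- stats::runif(length(contaminant_mz)) < 0.9
    if (any(cont)) {
      ci <- stats::rlnorm(sum(cont), log(8e5), 0.5)
      peaks <- rbind(peaks, data.frame(mz = jit(contaminant_mz[cont] * off),
                                       intensity = ci, snr = ci / 5e4))
    }
    if (config$n_noise_peaks > 0) {
      ni <- stats::rlnorm(config$n_noise_peaks, log(1e5), 0.6)
      peaks <- rbind(peaks, data.frame(
        mz = stats::runif(config$n_noise_peaks, 150, 950),
        intensity = ni, snr = stats::runif(config$n_noise_peaks, 1, 10)))
    }
    samples[[s]] <- sample_spectrum(design$sample_id[s], peaks,
                                    metadata = list(
                                      treatment = design$treatment[s],
                                      day = design$day[s],
                                      phase = design$phase[s]))
  }
  blanks <- lapply(1:2, function(b) {
    bi <- stats::rlnorm(length(contaminant_mz), log(8e5), 0.5)
    sample_spectrum(paste0("blank", b),
                    data.frame(mz = jit(contaminant_mz * off),
                               intensity = bi, snr = bi / 5e4))
  })
  list(samples = samples, blanks = blanks, design = design,
       ground_truth = list(catalog = catalog, presence = presence,
                           contaminant_mz = contaminant_mz,
                           offset_ppm = config$calibration_offset_ppm))
}

#' Simulate the quantitative exudate chemistry table
#'
#' Generates per-pot analyte concentrations for the two quantitative
#' timepoints (end of treatment, day 11, and end of recovery, day 18).
#' Control means are centred on the observed composition (end of treatment:
#' TOC 79.0 mg/L, TON 20.4 mg/L; recovery: TOC 77.5, TON 23.4), NO3-N is
#' generated so inorganic N is about 20\% of total N, NH4-N is 0 (none was
#' detected), and drought-phase means are scaled by \code{quant_effects}.
#' Free amino acids are generated as a small subfraction so amino-acid N
#' stays well under 5\% of the N balance. Negative draws are clipped to 0
#' and counted in the \code{"n_clipped"} attribute.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Data frame, one row per pot x timepoint, with columns
#'   \code{sample_id}, \code{treatment}, \code{day}, \code{phase},
#'   \code{TOC_conc}, \code{TN_conc}, \code{NO3N_conc}, \code{NH4N_conc},
#'   \code{rinseate_volume_mL}, \code{root_dry_weight_g},
#'   \code{plants_per_pot} and one \code{aa_*} column per amino acid (mg/L).
#' @export
simulate_quant_tables <- function(config) {
  set.seed(config$seed + 2L)
  aa_means <- c(serine = 0.05, aspartic_acid = 0.05, asparagine = 0.04,
                glutamic_acid = 0.06, tryptophan = 0.02, glutamine = 0.04,
                phenylalanine = 0.03, lysine = 0.03, glycine = 0.05,
                proline = 0.03)
  base <- list(
    treatment = c(TOC = 79.0, TOC_sd = 4.2, TON = 20.4, TON_sd = 6.8,
                  root_dw = 3.1, root_dw_sd = 0.3),
    recovery = c(TOC = 77.5, TOC_sd = 0.8, TON = 23.4, TON_sd = 5.2,
                 root_dw = 1.0, root_dw_sd = 0.05))
  timepoints <- data.frame(day = c(11, 18),
                           phase = c("treatment", "recovery"))
  n_clipped <- 0L
  rows <- list()
  for (t in seq_len(nrow(timepoints))) {
    ph <- timepoints$phase[t]
    b <- base[[ph]]
    eff <- config$quant_effects[[ph]]
    for (tr in c("control", "drought")) {
      n <- config$pots_sampled_per_day
      mult <- if (tr == "drought") eff else c(TOC = 1, TON = 1,
                                              amino_acids = 1)
      TOC <- stats::rnorm(n, b[["TOC"]] * mult[["TOC"]], b[["TOC_sd"]])
      TON <- stats::rnorm(n, b[["TON"]] * mult[["TON"]], b[["TON_sd"]])
      n_clipped <- n_clipped + sum(TOC < 0) + sum(TON < 0)
      TOC <- pmax(TOC, 0); TON <- pmax(TON, 0)
      # inorganic N ~ 20% of TN  =>  NO3-N = TON / 4 (with small noise)
      NO3N <- pmax(TON / 4 * (1 + stats::rnorm(n, 0, 0.05)), 0)
      aa <- sapply(names(aa_means), function(a) {
        v <- stats::rnorm(n, aa_means[[a]] * mult[["amino_acids"]],
                          0.3 * aa_means[[a]])
        n_clipped <<- n_clipped + sum(v < 0)
        pmax(v, 0)
      })
      aa <- matrix(aa, nrow = n,
                   dimnames = list(NULL, paste0("aa_", names(aa_means))))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(sample_id = sprintf("q_d%02d_%s_p%02d", timepoints$day[t],
                                       substr(tr, 1, 4), seq_len(n)),
                   treatment = tr, day = timepoints$day[t], phase = ph,
                   TOC_conc = TOC, TN_conc = TON + NO3N, NO3N_conc = NO3N,
                   NH4N_conc = 0,
                   rinseate_volume_mL = 128.8,
                   root_dry_weight_g = pmax(stats::rnorm(
                     n, b[["root_dw"]], b[["root_dw_sd"]]), 0.1),
                   plants_per_pot = config$plants_per_pot,
                   stringsAsFactors = FALSE),
        as.data.frame(aa))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_clipped > 0) {
    warning(n_clipped, " negative generated concentration(s) clipped to 0")
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Write a simulated dataset to disk
#'
#' Writes one TSV peak table per sample (\code{peaks/<sample_id>.tsv}), a
#' blanks TSV, the design table, the quantitative table, and the ground
#' truth as JSON.
#'
#' @param sim result of \code{\link{simulate_peak_tables}}.
#' @param dir output directory (created if missing).
#' @param quant optional result of \code{\link{simulate_quant_tables}}.
#' @return Invisibly, the output directory.
#' @export
write_simulated_dataset <- function(sim, dir, quant = NULL) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  for (s in sim$samples) {
    utils::write.table(s$peaks,
                       file.path(dir, "peaks", paste0(s$sample_id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  blanks <- do.call(rbind, lapply(sim$blanks, function(b) {
    cbind(blank_id = b$sample_id, b$peaks)
  }))
  utils::write.table(blanks, file.path(dir, "blanks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(quant)) {
    utils::write.table(quant, file.path(dir, "quant.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  gt <- sim$ground_truth
  jsonlite::write_json(list(catalog = gt$catalog,
                            presence = as.data.frame(gt$presence),
                            contaminant_mz = gt$contaminant_mz,
                            offset_ppm = gt$offset_ppm),
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Molecule matrix directly from simulation ground truth
#'
#' Bypasses peak emission and QC: builds the presence/absence matrix the
#' pipeline would ideally recover, straight from the simulated ground
#' truth. Used to study descriptor behaviour free of instrument noise.
#'
#' @param sim result of \code{\link{simulate_peak_tables}}.
#' @return A \code{\link{molecule_matrix}}.
#' @export
truth_molecule_matrix <- function(sim) {
  cat <- sim$ground_truth$catalog
  mol <- data.frame(mz = cat$mz, C = cat$C, H = cat$H, N = cat$N,
                    O = cat$O, S = cat$S, P = cat$P, formula = cat$formula,
                    error_ppm = 0, elemental_class = cat$elemental_class,
                    id = cat$id)
  pres <- sim$ground_truth$presence
  colnames(pres) <- mol$id
  meta <- sim$design[, c("sample_id", "treatment", "day", "phase")]
  structure(list(presence = pres, molecules = mol, metadata = meta),
            class = "molecule_matrix")
}
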