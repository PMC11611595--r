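# Shared in-code fixtures for the test suite.

# Tiny spectrum from parallel vectors; snr defaults high so S/N filtering
# is inert unless a test sets it.
mk_spec <- function(mz, intensity = NULL, snr = NULL, id = "s1",
                    metadata = list()) {
  n <- length(mz)
  if (is.null(intensity)) intensity <- rep(1000, n)
  if (is.null(snr)) snr <- rep(50, n)
  sample_spectrum(id, data.frame(mz = mz, intensity = intensity, snr = snr),
                  metadata)
}

# Small random spectrum for property-style checks.
random_spec <- function(n = 50, seed = 1, id = "r1") {
  set.seed(seed)
  mk_spec(sort(runif(n, 150, 950)), intensity = rlnorm(n, 10, 1),
          snr = runif(n, 0, 30), id = id)
}

# Molecule matrix built by hand: presence (samples x molecules), element
# counts per molecule, metadata.
mk_matrix <- function(presence, N, mz = NULL, C = NULL, S = NULL, P = NULL,
                      treatment = NULL, day = NULL, phase = NULL) {
  n_mol <- ncol(presence)
  n_smp <- nrow(presence)
  if (is.null(mz)) mz <- seq(250, 550, length.out = n_mol)
  if (is.null(C)) C <- rep(10L, n_mol)
  if (is.null(S)) S <- rep(0L, n_mol)
  if (is.null(P)) P <- rep(0L, n_mol)
  H <- rep(20L, n_mol); O <- rep(4L, n_mol)
  ids <- sprintf("M%05d", seq_len(n_mol))
  dimnames(presence) <- list(sprintf("s%02d", seq_len(n_smp)), ids)
  if (is.null(treatment)) {
    treatment <- rep(c("control", "drought"), length.out = n_smp)
  }
  if (is.null(day)) day <- rep(2, n_smp)
  if (is.null(phase)) phase <- day_phase(day)
  mol <- data.frame(mz = mz, C = C, H = H, N = N, O = O, S = S, P = P,
                    formula = sprintf("C%dH%dN%dO%d", C, H, N, O),
                    error_ppm = 0,
                    elemental_class = classify_elemental(N, S, P),
                    id = ids)
  structure(list(presence = presence, molecules = mol,
                 metadata = data.frame(sample_id = rownames(presence),
                                       treatment = treatment, day = day,
                                       phase = phase)),
            class = "molecule_matrix")
}

# Exhaustive no-pruning nested enumeration over reduced bounds; the
# independent oracle for candidate enumeration.
brute_force_candidates <- function(neutral_mass, tol_ppm, bC = c(5, 20),
                                   bH = c(4, 40), bN = c(0, 2),
                                   bO = c(0, 12), bS = c(0, 1),
                                   bP = c(0, 1)) {
  g <- expand.grid(C = bC[1]:bC[2], H = bH[1]:bH[2], N = bN[1]:bN[2],
                   O = bO[1]:bO[2], S = bS[1]:bS[2], P = bP[1]:bP[2])
  mass <- g$C * 12 + g$H * 1.0078250319 + g$N * 14.0030740052 +
    g$O * 15.9949146221 + g$S * 31.97207069 + g$P * 30.97376151
  keep <- abs(neutral_mass - mass) <= neutral_mass * tol_ppm * 1e-6
  out <- g[keep, , drop = FALSE]
  out$mass <- mass[keep]
  out[order(out$C, out$H, out$N, out$O, out$S, out$P), , drop = FALSE]
}

reduced_bounds <- function() {
  element_bounds(C = c(5, 20), H = c(4, 40), N = c(0, 2), O = c(0, 12),
                 S = c(0, 1), P = c(0, 1))
}

# Small simulation config used across tests (scaled-down problem size).
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(formula_library_size = 150, n_noise_peaks = 30, seed = seed),
    list(...))
  do.call(sim_config, args)
}
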