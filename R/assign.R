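#' Element count bounds and plausibility rules for formula assignment
#'
#' Default bounds follow the composition of the assigned exudate metabolome
#' (C 5--56, N 0--3) extended with conventional CHNOSP ranges (H 4--120,
#' O 0--40, S 0--3, P 0--2). Plausibility screens are the usual golden-rules
#' style filters: DBE in \code{dbe_range}, elemental ratios H/C in
#' \code{hc_range} and O/C at most \code{oc_max}. Candidates failing a screen
#' are flagged, not silently dropped, so the screens can be audited or
#' disabled.
#'
#' @param C,H,N,O,S,P length-2 integer vectors \code{c(min, max)}.
#' @param dbe_range numeric length 2; allowed double-bond equivalents.
#' @param hc_range numeric length 2; allowed H/C ratio.
#' @param oc_max numeric; maximum O/C ratio.
#' @param apply_plausibility logical; if \code{FALSE} the screens are recorded
#'   but ignored when choosing the best candidate.
#' @return A list of class \code{element_bounds}.
#' @export
element_bounds <- function(C = c(5L, 56L), H = c(4L, 120L), N = c(0L, 3L),
                           O = c(0L, 40L), S = c(0L, 3L), P = c(0L, 2L),
                           dbe_range = c(0, 40), hc_range = c(0.3, 2.5),
                           oc_max = 1.2, apply_plausibility = TRUE) {
  b <- list(C = C, H = H, N = N, O = O, S = S, P = P)
  for (el in names(b)) {
    if (length(b[[el]]) != 2 || any(b[[el]] < 0) || b[[el]][1] > b[[el]][2]) {
      stop("bounds for ", el, " must be c(min, max) with 0 <= min <= max")
    }
    b[[el]] <- as.integer(b[[el]])
  }
  structure(c(b, list(dbe_range = dbe_range, hc_range = hc_range,
                      oc_max = oc_max,
                      apply_plausibility = isTRUE(apply_plausibility))),
            class = "element_bounds")
}

# Grid of (C, N, O, S, P) combinations and their summed monoisotopic mass,
# cached per bounds object within a call chain. H is solved per target mass.
.cnosp_grid <- function(bounds) {
  g <- expand.grid(C = bounds$C[1]:bounds$C[2],
                   N = bounds$N[1]:bounds$N[2],
                   O = bounds$O[1]:bounds$O[2],
                   S = bounds$S[1]:bounds$S[2],
                   P = bounds$P[1]:bounds$P[2],
                   KEEP.OUT.ATTRS = FALSE)
  g$base <- g$C * MONOISOTOPIC_MASS[["C"]] + g$N * MONOISOTOPIC_MASS[["N"]] +
    g$O * MONOISOTOPIC_MASS[["O"]] + g$S * MONOISOTOPIC_MASS[["S"]] +
    g$P * MONOISOTOPIC_MASS[["P"]]
  g <- g[order(g$base), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Rows of a base-sorted grid whose base mass can still reach neutral_mass
# with an in-bounds hydrogen count.
.grid_window <- function(g, neutral_mass, bounds, tol_amu) {
  mH <- MONOISOTOPIC_MASS[["H"]]
  lo <- findInterval(neutral_mass - bounds$H[2] * mH - tol_amu - 1e-9,
                     g$base) + 1L
  hi <- findInterval(neutral_mass - bounds$H[1] * mH + tol_amu + 1e-9,
                     g$base)
  if (lo > hi) return(g[0, , drop = FALSE])
  g[lo:hi, , drop = FALSE]
}

#' Enumerate candidate CHNOSP formulas for a neutral mass
#'
#' Exhaustive search within element bounds: every formula whose neutral
#' monoisotopic mass lies within \code{tol_ppm} of \code{neutral_mass}
#' appears exactly once. The search loops over C, N, O, S, P and solves the
#' hydrogen count from the residual mass; because consecutive H counts are
#' 1.008 amu apart, at most one H value can satisfy a sub-ppm tolerance, and
#' a guard window of a few H units around the rounded solution keeps the
#' enumeration exhaustive at any tolerance.
#'
#' @param neutral_mass neutral monoisotopic mass (amu), in (0, 1000].
#' @param tol_ppm assignment tolerance in ppm of the neutral mass.
#' @param bounds an \code{\link{element_bounds}} object.
#' @return A data frame with columns \code{C,H,N,O,S,P}, \code{mass},
#'   \code{error_ppm} (signed, observed minus theoretical), and
#'   \code{plausible} (logical screen result), sorted by
#'   ascending |error_ppm| with ties broken by fewer S+P, then fewer N, then
#'   lexicographic CHNOSP counts. Zero rows when nothing matches.
#' @export
enumerate_candidates <- function(neutral_mass, tol_ppm = 1.0,
                                 bounds = element_bounds()) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1 ||
      is.na(neutral_mass) || neutral_mass <= 0 || neutral_mass > 1000) {
    stop("neutral_mass must be a single value in (0, 1000]")
  }
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0")
  g <- .cnosp_grid(bounds)
  tol_amu <- neutral_mass * tol_ppm * 1e-6
  g <- .grid_window(g, neutral_mass, bounds, tol_amu)
  mH <- MONOISOTOPIC_MASS[["H"]]
  resid <- neutral_mass - g$base
  h_mid <- round(resid / mH)
  # H guard window: tol_amu/mH extra units cover any tolerance.
  span <- max(0L, ceiling(tol_amu / mH))
  rows <- vector("list", 2L * span + 1L)
  for (k in seq(-span, span)) {
    H <- h_mid + k
    ok <- !is.na(H) & H >= bounds$H[1] & H <= bounds$H[2] &
      abs(resid - H * mH) <= tol_amu
    if (any(ok)) {
      sub <- g[ok, c("C", "N", "O", "S", "P"), drop = FALSE]
      sub$H <- H[ok]
      sub$mass <- g$base[ok] + sub$H * mH
      rows[[k + span + 1L]] <- sub
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(C = integer(), H = integer(), N = integer(),
                      O = integer(), S = integer(), P = integer(),
                      mass = numeric(), error_ppm = numeric(),
                      plausible = logical())
    return(out)
  }
  out <- out[, c("C", "H", "N", "O", "S", "P", "mass")]
  out$error_ppm <- (neutral_mass - out$mass) / out$mass * 1e6
  d <- dbe(out$C, out$H, out$N, out$P)
  hc <- out$H / out$C
  oc <- out$O / out$C
  out$plausible <- d >= bounds$dbe_range[1] & d <= bounds$dbe_range[2] &
    hc >= bounds$hc_range[1] & hc <= bounds$hc_range[2] & oc <= bounds$oc_max
  ord <- order(abs(out$error_ppm), out$S + out$P, out$N,
               out$C, out$H, out$N, out$O, out$S, out$P)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a molecular formula to an observed deprotonated m/z
#'
#' The neutral mass is recovered as \code{observed_mz + 1.0072765} and the
#' best candidate within \code{tol_ppm} is the plausible formula with the
#' smallest |error_ppm| (ties: fewer S+P, then fewer N, then lexicographic
#' CHNOSP). An optional post-assignment error filter drops assignments with
#' |error_ppm| above \code{error_filter_ppm}, mirroring the 0.5 ppm error
#' filtering stage applied after the 1 ppm assignment tolerance.
#'
#' @param observed_mz observed \eqn{[M-H]^-} m/z (Th), vectorised.
#' @param tol_ppm assignment tolerance (ppm).
#' @param bounds an \code{\link{element_bounds}} object.
#' @param error_filter_ppm post-hoc |error| ceiling in ppm, or \code{NULL}
#'   to disable.
#' @return A data frame with one row per input m/z: \code{mz},
#'   \code{neutral_mass}, \code{assigned} (logical), element counts,
#'   \code{formula} (string or \code{NA}), \code{error_ppm} and
#'   \code{elemental_class}.
#' @examples
#' assign_formula(266.1510)$formula  # "C13H21N3O3"
#' @export
assign_formula <- function(observed_mz, tol_ppm = 1.0,
                           bounds = element_bounds(),
                           error_filter_ppm = 0.5) {
  n <- length(observed_mz)
  res <- data.frame(mz = observed_mz,
                    neutral_mass = observed_mz + PROTON_MASS,
                    assigned = FALSE,
                    C = NA_integer_, H = NA_integer_, N = NA_integer_,
                    O = NA_integer_, S = NA_integer_, P = NA_integer_,
                    formula = NA_character_, error_ppm = NA_real_,
                    elemental_class = NA_character_)
  g <- .cnosp_grid(bounds)
  gv <- list(base = g$base, C = g$C, N = g$N, O = g$O, S = g$S, P = g$P)
  mH <- MONOISOTOPIC_MASS[["H"]]
  for (i in seq_len(n)) {
    cand <- .best_candidate(res$neutral_mass[i], tol_ppm, bounds, gv, mH)
    if (is.null(cand)) next
    if (!is.null(error_filter_ppm) &&
        abs(cand$error_ppm) > error_filter_ppm) next
    res$assigned[i] <- TRUE
    res[i, c("C", "H", "N", "O", "S", "P")] <-
      cand[c("C", "H", "N", "O", "S", "P")]
    res$formula[i] <- formula_string(unlist(
      cand[c("C", "H", "N", "O", "S", "P")]))
    res$error_ppm[i] <- cand$error_ppm
    res$elemental_class[i] <- classify_elemental(cand$N, cand$S, cand$P)
  }
  res
}

# Best single candidate for one neutral mass, using precomputed grid
# vectors (base-sorted).
.best_candidate <- function(neutral_mass, tol_ppm, bounds, gv, mH) {
  tol_amu <- neutral_mass * tol_ppm * 1e-6
  # wide tolerances can admit several H per grid row; defer to the full
  # enumeration there
  if (tol_amu > mH / 2) {
    cand <- enumerate_candidates(neutral_mass, tol_ppm, bounds)
    if (bounds$apply_plausibility) cand <- cand[cand$plausible, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    return(as.list(cand[1, ]))
  }
  lo <- findInterval(neutral_mass - bounds$H[2] * mH - tol_amu - 1e-9,
                     gv$base) + 1L
  hi <- findInterval(neutral_mass - bounds$H[1] * mH + tol_amu + 1e-9,
                     gv$base)
  if (lo > hi) return(NULL)
  w <- lo:hi
  resid <- neutral_mass - gv$base[w]
  H <- round(resid / mH)
  ok <- H >= bounds$H[1] & H <= bounds$H[2] & abs(resid - H * mH) <= tol_amu
  if (!any(ok)) return(NULL)
  w <- w[ok]
  cand <- data.frame(C = gv$C[w], N = gv$N[w], O = gv$O[w], S = gv$S[w],
                     P = gv$P[w], H = H[ok])
  cand$mass <- gv$base[w] + cand$H * mH
  cand$error_ppm <- (neutral_mass - cand$mass) / cand$mass * 1e6
  if (bounds$apply_plausibility) {
    d <- dbe(cand$C, cand$H, cand$N, cand$P)
    keep <- d >= bounds$dbe_range[1] & d <= bounds$dbe_range[2] &
      cand$H / cand$C >= bounds$hc_range[1] &
      cand$H / cand$C <= bounds$hc_range[2] &
      cand$O / cand$C <= bounds$oc_max
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(NULL)
  ord <- order(abs(cand$error_ppm), cand$S + cand$P, cand$N,
               cand$C, cand$H, cand$N, cand$O, cand$S, cand$P)
  as.list(cand[ord[1], ])
}
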