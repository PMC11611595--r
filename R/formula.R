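#' Construct a CHNOSP molecular formula
#'
#' A molecular formula is a named integer vector of element counts for
#' C, H, N, O, S and P. At least one atom must be present and all counts
#' must be non-negative.
#'
#' @param C,H,N,O,S,P non-negative integer element counts.
#' @return An object of class \code{molecular_formula}: a named integer
#'   vector over \code{c("C","H","N","O","S","P")}.
#' @examples
#' molecular_formula(C = 13, H = 21, N = 3, O = 3)
#' @export
molecular_formula <- function(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0) {
  f <- c(C = C, H = H, N = N, O = O, S = S, P = P)
  if (any(is.na(f)) || any(f < 0) || any(f != round(f))) {
    stop("element counts must be non-negative integers")
  }
  if (sum(f) == 0) stop("formula must contain at least one atom")
  structure(as.integer(round(f)), names = ELEMENTS,
            class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(formula_string(x), "\n")
  invisible(x)
}

#' Format a formula as a CHNOSP-ordered string
#'
#' Elements appear in the fixed order C, H, N, O, S, P; a unit count is
#' written without the digit and zero counts are omitted (e.g.
#' \code{"C22H43ON"} prints as \code{"C22H43NO"}).
#'
#' @param f a \code{molecular_formula} or named count vector.
#' @return Character scalar.
#' @export
formula_string <- function(f) {
  f <- f[ELEMENTS]
  parts <- vapply(ELEMENTS, function(el) {
    n <- f[[el]]
    if (is.na(n) || n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Parse a formula string into element counts
#'
#' Accepts strings such as \code{"C13H21O3N3"} or \code{"C22H43ON"} in any
#' element order; only C, H, N, O, S, P are allowed.
#'
#' @param x character scalar.
#' @return A \code{molecular_formula}.
#' @export
parse_formula <- function(x) {
  x <- gsub("[_ ]", "", x)
  m <- gregexpr("([CHNOSP])([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (length(tokens) == 0 || sum(nchar(tokens)) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  counts <- stats::setNames(integer(6), ELEMENTS)
  for (tok in tokens) {
    el <- substr(tok, 1, 1)
    n <- if (nchar(tok) > 1) as.integer(substr(tok, 2, nchar(tok))) else 1L
    counts[el] <- counts[el] + n
  }
  do.call(molecular_formula, as.list(counts))
}

#' Mass of a molecular formula
#'
#' Computes the neutral monoisotopic mass, the singly deprotonated ion m/z
#' (\code{neutral - 1.0072765}; negative-mode \eqn{[M-H]^-}, the only adduct
#' considered), or the average mass from standard atomic weights.
#'
#' @param f a \code{molecular_formula} (or named count vector).
#' @param kind one of \code{"neutral_monoisotopic"}, \code{"deprotonated_mz"},
#'   \code{"average"}.
#' @return Numeric mass in amu (or Th for the ion).
#' @examples
#' formula_mass(parse_formula("C13H21O3N3"), "deprotonated_mz")  # 266.151
#' @export
formula_mass <- function(f, kind = c("neutral_monoisotopic",
                                     "deprotonated_mz", "average")) {
  kind <- match.arg(kind)
  f <- f[ELEMENTS]
  if (any(is.na(f))) stop("formula must carry counts for C,H,N,O,S,P")
  if (sum(f) == 0) stop("all-zero formula has no mass")
  switch(kind,
    neutral_monoisotopic = sum(f * MONOISOTOPIC_MASS),
    deprotonated_mz = sum(f * MONOISOTOPIC_MASS) - PROTON_MASS,
    average = sum(f * AVERAGE_MASS)
  )
}

#' Double-bond equivalents of a formula
#'
#' DBE = C - H/2 + N/2 + P/2 + 1, the rings-plus-double-bonds count under
#' standard valences (P treated as trivalent). Used as a chemical
#' plausibility screen for candidate formulas.
#'
#' @param C,H,N,P element counts (vectorised).
#' @return Numeric DBE.
#' @export
dbe <- function(C, H, N = 0, P = 0) {
  C - H / 2 + N / 2 + P / 2 + 1
}

#' Elemental class of an assigned formula
#'
#' Partitions assigned molecules into the five elemental groups used for
#' nitrogen-metabolome composition: \code{nonN} (no nitrogen), \code{CHON}
#' (N only), \code{CHON-S}, \code{CHON-P}, and \code{CHON-SP}.
#'
#' @param N,S,P element counts, or a \code{molecular_formula} as first
#'   argument.
#' @return Character vector over
#'   \code{c("nonN","CHON","CHON-S","CHON-P","CHON-SP")}.
#' @examples
#' classify_elemental(parse_formula("C15H34O2N2S2"))  # "CHON-S"
#' @export
classify_elemental <- function(N, S = NULL, P = NULL) {
  if (inherits(N, "molecular_formula") ||
      (is.null(S) && !is.null(names(N)))) {
    f <- N
    N <- f[["N"]]; S <- f[["S"]]; P <- f[["P"]]
  }
  ifelse(N == 0, "nonN",
    ifelse(S == 0 & P == 0, "CHON",
      ifelse(S > 0 & P == 0, "CHON-S",
        ifelse(S == 0 & P > 0, "CHON-P", "CHON-SP"))))
}

#' @rdname classify_elemental
#' @export
ELEMENTAL_CLASSES <- c("CHON", "CHON-S", "CHON-P", "CHON-SP", "nonN")
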