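#' Bootstrap two-sample t-test
#'
#' Computes the observed Welch t statistic, then builds the null
#' distribution by recentring both groups to the pooled mean and resampling
#' each with replacement \code{n_boot} times; the two-sided p-value is
#' \code{(1 + #{|t*| >= |t_obs|}) / (n_boot + 1)} (add-one smoothing, so p
#' is never 0). Deterministic given \code{seed}.
#'
#' @param x,y numeric sample vectors, each of length >= 2.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return List of class \code{stat_result}: \code{statistic} (Welch t),
#'   \code{df} (Welch-Satterthwaite), \code{p_value}, \code{n_boot},
#'   \code{method}, \code{seed}.
#' @export
bootstrap_t_test <- function(x, y, n_boot = 10000, seed = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (n_boot < 100) stop("n_boot must be >= 100")
  welch <- function(a, b) {
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    (mean(a) - mean(b)) / sqrt(va + vb)
  }
  t_obs <- welch(x, y)
  va <- stats::var(x) / length(x); vb <- stats::var(y) / length(y)
  df <- (va + vb)^2 / (va^2 / (length(x) - 1) + vb^2 / (length(y) - 1))
  pooled <- mean(c(x, y))
  x0 <- x - mean(x) + pooled
  y0 <- y - mean(y) + pooled
  set.seed(seed)
  xs <- matrix(sample(x0, length(x0) * n_boot, replace = TRUE),
               nrow = length(x0))
  ys <- matrix(sample(y0, length(y0) * n_boot, replace = TRUE),
               nrow = length(y0))
  mx <- colMeans(xs); my <- colMeans(ys)
  vx <- (colMeans(xs^2) - mx^2) * length(x0) / (length(x0) - 1)
  vy <- (colMeans(ys^2) - my^2) * length(y0) / (length(y0) - 1)
  t_star <- (mx - my) / sqrt(vx / length(x0) + vy / length(y0))
  t_star <- t_star[is.finite(t_star)]
  p <- (1 + sum(abs(t_star) >= abs(t_obs))) / (length(t_star) + 1)
  structure(list(statistic = t_obs, df = df, p_value = p,
                 n_boot = n_boot, method = "bootstrap Welch t", seed = seed),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 4),
      " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control: \code{adj_i = min_{j >= rank(i)}
#' (p_(j) * m / j)}, capped at 1, returned in the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  adj <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs. The p-value uses the asymptotic Kolmogorov distribution with the
#' usual small-sample correction; for \code{exact = TRUE} (default when
#' \code{min(n, m) <= 10} and there are no ties) the exact null probability
#' is computed by counting lattice paths that stay inside the band.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact logical or \code{NULL} (auto).
#' @return \code{stat_result} with \code{statistic} (D) and \code{p_value}.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  all_v <- sort(unique(c(x, y)))
  d <- max(abs(vapply(all_v, function(v) {
    sum(x <= v) / n - sum(y <= v) / m
  }, numeric(1))))
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(n, m) <= 10 && !ties
  if (exact && !ties) {
    p <- 1 - .ks_path_prob(n, m, d)
  } else {
    en <- n * m / (n + m)
    lambda <- (sqrt(en) + 0.12 + 0.11 / sqrt(en)) * d
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(max(p, 0), 1)
  structure(list(statistic = d, p_value = p, n = n, m = m,
                 method = if (exact && !ties) "exact two-sample KS"
                          else "asymptotic two-sample KS"),
            class = "stat_result")
}

# P(D < d) under the null: fraction of monotone lattice paths from (0,0) to
# (n,m) with |i/n - j/m| < d at every step (no ties assumed).
.ks_path_prob <- function(n, m, d) {
  u <- rep(0, m + 1)
  u[1] <- 1
  inside <- function(i, j) abs(i / n - j / m) < d - 1e-12
  cnt <- matrix(0, n + 1, m + 1)
  cnt[1, 1] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      if (!inside(i, j) && !(i == n && j == m)) {
        # paths may end at (n, m) even though D = 0 there trivially holds
        cnt[i + 1, j + 1] <- 0
        next
      }
      acc <- 0
      if (i > 0) acc <- acc + cnt[i, j + 1]
      if (j > 0) acc <- acc + cnt[i + 1, j]
      cnt[i + 1, j + 1] <- acc
    }
  }
  cnt[n + 1, m + 1] / choose(n + m, n)
}

#' Binary Bray-Curtis dissimilarity
#'
#' For presence/absence rows, \code{d(i, j) = (A + B - 2J) / (A + B)} where
#' A and B are the two samples' presence counts and J the shared count.
#' Two all-empty samples get distance 0 with a warning.
#'
#' @param mat a \code{\link{molecule_matrix}} or a samples x molecules 0/1
#'   matrix.
#' @param nitrogen_only when given a \code{molecule_matrix}, restrict to
#'   N-containing molecules (the nitrogen-metabolome analysis).
#' @return A \code{stats::dist} object with entries in [0, 1].
#' @export
bray_curtis_binary <- function(mat, nitrogen_only = TRUE) {
  if (inherits(mat, "molecule_matrix")) {
    keep <- if (nitrogen_only) mat$molecules$N > 0 else
      rep(TRUE, ncol(mat$presence))
    m <- mat$presence[, keep, drop = FALSE]
  } else {
    m <- mat
  }
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (!all(m %in% c(0, 1))) stop("matrix must be binary (0/1)")
  m <- m * 1
  counts <- rowSums(m)
  J <- tcrossprod(m)
  AB <- outer(counts, counts, "+")
  D <- (AB - 2 * J) / AB
  if (any(AB == 0)) {
    warning("pairs of all-empty samples; their distance is set to 0")
    D[AB == 0] <- 0
  }
  diag(D) <- 0
  stats::as.dist(D)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the distance matrix is
#' Gower-centred (\eqn{G = (I - 11'/n)(-D^2/2)(I - 11'/n)}) and sequential
#' (Type I) sums of squares are taken by projecting onto the cumulative
#' design in the order given in \code{terms}; the pseudo-F per term is
#' \code{(SS_term/df_term)/(SS_res/df_res)} and p-values come from free
#' permutation of sample rows, \code{p = (1 + #{F* >= F}) / (n_perm + 1)}.
#'
#' @param dist a \code{stats::dist} or symmetric matrix of distances.
#' @param design data frame of factors, one row per sample, in distance
#'   order.
#' @param terms character vector of model terms in sequential order, e.g.
#'   \code{c("treatment", "day", "treatment:day")}; main effects must
#'   precede their interactions.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return Data frame (one row per term plus Residual and Total):
#'   \code{term}, \code{df}, \code{SS}, \code{R2}, \code{F},
#'   \code{p_value}; carries attributes \code{n_perm} and \code{seed}.
#' @export
permanova <- function(dist, design, terms, n_perm = 999, seed = 1L) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (nrow(design) != n) stop("design must have one row per sample")
  if (n_perm < 99) stop("n_perm must be >= 99")
  for (v in names(design)) design[[v]] <- factor(design[[v]])
  G <- .gower_center(D)
  # cumulative hat matrices per sequential term
  hats <- vector("list", length(terms) + 1)
  hats[[1]] <- matrix(1 / n, n, n)    # intercept only
  dfs <- integer(length(terms))
  X <- stats::model.matrix(~1, design)
  for (k in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[1:k], collapse = "+")))
    Xk <- tryCatch(stats::model.matrix(f, design), error = function(e) {
      stop("term '", terms[k], "' is aliased (singular design): ",
           conditionMessage(e))
    })
    # aliased columns are harmless for projection; a rank not exceeding the
    # previous cumulative rank means the term is fully aliased
    rk <- qr(Xk)$rank
    prev_rk <- qr(X)$rank
    if (rk == prev_rk) stop("term '", terms[k], "' is aliased (singular ",
                            "design)")
    dfs[k] <- rk - prev_rk
    q <- qr.Q(qr(Xk))[, seq_len(rk), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(q)
    X <- Xk
  }
  df_res <- n - qr(X)$rank
  if (df_res <= 0) stop("no residual degrees of freedom")
  ss_terms <- function(Gp) {
    tot <- sum(diag(Gp))
    ss <- vapply(seq_along(terms), function(k) {
      sum((hats[[k + 1]] - hats[[k]]) * Gp)   # tr(H G) = sum(H * G), H sym
    }, numeric(1))
    c(ss, tot - sum(hats[[length(hats)]] * Gp))
  }
  obs <- ss_terms(G)
  ss <- obs[seq_along(terms)]
  ss_res <- obs[length(obs)]
  ss_tot <- sum(diag(G))
  f_obs <- (ss / dfs) / (ss_res / df_res)
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    sb <- ss_terms(Gp)
    fb <- (sb[seq_along(terms)] / dfs) / (sb[length(sb)] / df_res)
    exceed <- exceed + (fb >= f_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss, ss_res, ss_tot),
    R2 = c(ss, ss_res, ss_tot) / ss_tot,
    F = c(f_obs, NA, NA),
    p_value = c(pvals, NA, NA))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

.gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' PCA with squared cosines and supplementary variables
#'
#' Standardizes the main variables (zero-variance variables dropped with a
#' warning), decomposes by singular values, and reports component scores,
#' loadings, explained-variance fractions and squared cosines: the squared
#' correlation between each variable and each component's scores, which
#' sums to 1 across all components for every main variable. Supplementary
#' categorical variables are one-hot coded and projected the same way
#' without influencing the decomposition.
#'
#' @param x numeric samples x variables matrix or data frame (e.g. the
#'   elemental-class proportions).
#' @param supplementary optional data frame of categorical metadata
#'   (e.g. treatment, phase).
#' @return List of class \code{pca_result}: \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions),
#'   \code{sq_cos} (variables x components), \code{sq_cos_supplementary},
#'   \code{dropped} (zero-variance variable names).
#' @export
pca_squared_cosines <- function(x, supplementary = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 variables with nonzero variance")
  z <- scale(x)
  sv <- svd(z)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  loadings <- sv$v[, 1:k, drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", 1:k)
  expl <- sv$d[1:k]^2 / sum(sv$d^2)
  sqc <- function(vars) {
    # variables x components matrix of squared correlations with scores
    out <- matrix(0, ncol(vars), k,
                  dimnames = list(colnames(vars), paste0("PC", 1:k)))
    for (jv in seq_len(ncol(vars))) {
      v <- vars[, jv]
      s <- stats::sd(v)
      if (is.na(s) || s == 0) next
      for (j in 1:k) {
        out[jv, j] <- suppressWarnings(stats::cor(v, scores[, j]))^2
      }
    }
    out
  }
  sq_cos <- sqc(z)
  sq_sup <- NULL
  if (!is.null(supplementary)) {
    oh <- do.call(cbind, lapply(names(supplementary), function(nm) {
      f <- factor(supplementary[[nm]])
      m <- stats::model.matrix(~ f - 1)
      colnames(m) <- paste0(nm, ":", levels(f))
      m
    }))
    sq_sup <- sqc(oh)
  }
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 sq_cos = sq_cos, sq_cos_supplementary = sq_sup,
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", ncol(x$scores), "components; explained =",
      paste(signif(100 * x$explained, 3), collapse = "% "), "%\n")
  invisible(x)
}

#' Bootstrap tests for all analytes at one timepoint
#'
#' Runs \code{\link{bootstrap_t_test}} (drought vs control) for each analyte
#' column within each timepoint and adjusts p-values by Benjamini-Hochberg
#' within the timepoint (all analytes at a timepoint form one family).
#'
#' @param balance data frame from \code{\link{exudate_balance}} with
#'   \code{treatment} and \code{day} columns.
#' @param analytes character vector of numeric columns to test.
#' @param n_boot,seed passed to \code{\link{bootstrap_t_test}}.
#' @return Data frame: \code{day}, \code{analyte}, \code{statistic},
#'   \code{p_value}, \code{p_adjusted}.
#' @export
quant_tests <- function(balance,
                        analytes = c("TOC_conc", "TON_conc",
                                     "specific_TOC", "specific_TON",
                                     "CN_ratio", "AA_N_conc"),
                        n_boot = 10000, seed = 1L) {
  res <- list()
  for (d in sort(unique(balance$day))) {
    sub <- balance[balance$day == d, ]
    rows <- lapply(analytes, function(a) {
      x <- sub[[a]][sub$treatment == "drought"]
      y <- sub[[a]][sub$treatment == "control"]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      r <- bootstrap_t_test(x, y, n_boot = n_boot,
                            seed = seed + as.integer(d))
      data.frame(day = d, analyte = a, statistic = r$statistic,
                 p_value = r$p_value)
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(rows)) {
      rows$p_adjusted <- bh_adjust(rows$p_value)
      res[[length(res) + 1]] <- rows
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
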