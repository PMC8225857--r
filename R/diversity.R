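## Coverage-based rarefaction and extrapolation of clonotype richness
## (Hill number q = 0) in the Chao-Jost framework, with bootstrap confidence
## intervals and relative diversity at a fixed coverage.
##
## Terminology: an "individual" is a clone (one cell lineage), a "species" is
## a clonotype (a unique receptor sequence).  All estimators operate on an
## abundance vector X_i >= 1 with n = sum(X_i) clones and S_obs clonotypes;
## f_k is the number of clonotypes of abundance exactly k (f_1 = singletons).

#' Construct an abundance vector
#'
#' @param x positive integer clonotype abundances, or a `tcr_catalogue`
#'   (whose `abundance` column is used).
#' @return an `abundance_vector`: list with `X` (sorted decreasing), `n`,
#'   `S_obs`, `f1`, `f2`.
#' @export
abundance_vector <- function(x) {
  if (inherits(x, "abundance_vector")) return(x)
  if (inherits(x, "tcr_catalogue")) x <- as.data.table(x)$abundance
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("abundance vector is empty")
  if (any(is.na(x) | x < 1 | x != floor(x)))
    stopf("abundances must be positive integers")
  X <- sort(x, decreasing = TRUE)
  structure(list(X = X, n = sum(X), S_obs = length(X),
                 f1 = sum(X == 1), f2 = sum(X == 2)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("abundance vector: n = %d clones, S_obs = %d clonotypes, f1 = %d, f2 = %d\n",
              x$n, x$S_obs, x$f1, x$f2))
  invisible(x)
}

#' Chao1-style estimate of the number of undetected clonotypes
#'
#' `f0_hat = ((n-1)/n) f1^2 / (2 f2)` when `f2 > 0`; the bias-corrected form
#' `((n-1)/n) f1 (f1-1) / 2` when `f2 = 0`.
#'
#' @param X an [abundance_vector()] (or coercible input).
#' @return non-negative real.
#' @export
f0_hat <- function(X) {
  X <- abundance_vector(X)
  if (X$f2 > 0) {
    (X$n - 1) / X$n * X$f1^2 / (2 * X$f2)
  } else {
    (X$n - 1) / X$n * X$f1 * (X$f1 - 1) / 2
  }
}

#' Estimated sample coverage at size m
#'
#' Sample coverage is the proportion of all clones -- encountered and
#' unencountered -- in the assemblage that belong to clonotypes encountered
#' in a sample of m clones.  Interpolation (m < n) uses the exact
#' hypergeometric form; `m = n` and extrapolation use the singleton/doubleton
#' estimator.  Binomial coefficients are computed in log space.
#'
#' @param X an [abundance_vector()] (or coercible input).
#' @param m positive clone count(s); may exceed `n` (extrapolation) and may
#'   be non-integer (linear interpolation between adjacent integers).
#' @return coverage value(s) in `[0, 1]`.
#' @export
coverage_hat <- function(X, m) {
  X <- abundance_vector(X)
  if (any(m < 1)) stopf("`m` must be >= 1")
  vapply(m, function(mi) .coverage_one(X, mi), numeric(1))
}

.coverage_one <- function(X, m) {
  if (m != floor(m)) {
    lo <- floor(m)
    return((1 - (m - lo)) * .coverage_one(X, lo) +
             (m - lo) * .coverage_one(X, lo + 1))
  }
  n <- X$n
  if (m < n) {
    w <- exp(lchoose_safe(n - X$X, m) - lchoose_safe(n - 1, m))
    return(1 - sum(X$X / n * w))
  }
  if (X$f1 == 0) return(1)
  A <- (n - 1) * X$f1 / ((n - 1) * X$f1 + 2 * X$f2)
  1 - X$f1 / n * A^(m - n + 1)
}

#' Estimated clonotype richness at size m
#'
#' Rarefaction (`m <= n`) uses the exact expected richness of a subsample of
#' m clones; extrapolation (`m > n`) uses the Chao1-based asymptotic form
#' `S_obs + f0_hat * (1 - (1 - f1/(n f0_hat + f1))^(m - n))`.  `m = Inf`
#' returns the asymptote `S_obs + f0_hat`.
#'
#' @inheritParams coverage_hat
#' @return richness value(s).
#' @export
richness_hat <- function(X, m) {
  X <- abundance_vector(X)
  if (any(m < 1)) stopf("`m` must be >= 1")
  vapply(m, function(mi) .richness_one(X, mi), numeric(1))
}

.richness_one <- function(X, m) {
  n <- X$n
  if (is.infinite(m)) return(X$S_obs + f0_hat(X))
  if (m != floor(m)) {
    lo <- floor(m)
    return((1 - (m - lo)) * .richness_one(X, lo) +
             (m - lo) * .richness_one(X, lo + 1))
  }
  if (m <= n) {
    w <- exp(lchoose_safe(n - X$X, m) - lchoose_safe(n, m))
    return(X$S_obs - sum(w))
  }
  f0 <- f0_hat(X)
  if (f0 == 0 || X$f1 == 0) return(as.numeric(X$S_obs))
  mstar <- m - n
  X$S_obs + f0 * (1 - (1 - X$f1 / (n * f0 + X$f1))^mstar)
}

## Chao-Jost bootstrap assemblage: adjusted detection probabilities for the
## S_obs observed clonotypes plus ceiling(f0_hat) undetected clonotypes that
## share the estimated coverage deficit 1 - C_hat(n) equally.
bootstrap_community <- function(X) {
  X <- abundance_vector(X)
  n <- X$n
  Cn <- .coverage_one(X, n)
  deficit <- 1 - Cn
  p_obs <- X$X / n
  if (deficit > 0 && X$f1 > 0) {
    denom <- sum(p_obs * (1 - p_obs)^n)
    lambda <- if (denom > 0) deficit / denom else 0
    p_seen <- p_obs * (1 - lambda * (1 - p_obs)^n)
    f0 <- max(1L, ceiling(f0_hat(X)))
    p_unseen <- rep(deficit / f0, f0)
    p <- c(p_seen, p_unseen)
  } else {
    p <- p_obs
  }
  p / sum(p)
}

## One multinomial bootstrap replicate: redraw n clones from the bootstrap
## assemblage and return the resulting abundance vector.
bootstrap_replicate <- function(p, n) {
  cnt <- as.vector(rmultinom(1L, n, p))
  abundance_vector(cnt[cnt > 0])
}

#' Rarefaction/extrapolation curve with bootstrap confidence intervals
#'
#' For each clone count in `m_grid`, reports estimated coverage and richness
#' with normal-approximation 95% confidence intervals (richness +/- 1.96 x
#' bootstrap SD).  Each bootstrap replicate redraws n clones multinomially
#' from the Chao-Jost bootstrap assemblage (observed clonotypes with adjusted
#' probabilities plus the estimated undetected clonotypes sharing the
#' coverage deficit).  With the study default of B = 10 replicates, quantile
#' intervals are meaningless; the normal approximation is used instead.
#'
#' @param X an [abundance_vector()] (or coercible input).
#' @param m_grid ascending clone counts; `Inf` entries give the asymptote.
#'   Default: 40 knots evenly spaced up to `2n`.
#' @param B bootstrap replications (>= 2; default 10).
#' @param seed integer seed; the curve is deterministic given the seed.
#' @param conf confidence level (default 0.95).
#' @return a `diversity_curve`: data.table with columns `m`, `coverage`,
#'   `richness`, `ci_lo`, `ci_hi`, `regime`; attributes `q` (0), `B`, `seed`.
#' @export
re_curve_with_bootstrap <- function(X, m_grid = NULL, B = 10L, seed = 1L,
                                    conf = 0.95) {
  X <- abundance_vector(X)
  assert_scalar_int(B, "B", lower = 2)
  if (is.null(m_grid))
    m_grid <- unique(round(seq(1, 2 * X$n, length.out = 40)))
  if (is.unsorted(m_grid)) stopf("`m_grid` must be sorted ascending")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est_r <- richness_hat(X, m_grid)
  est_c <- coverage_hat(X, m_grid)
  p <- bootstrap_community(X)
  boots <- with_seed(child_seed(seed, "re_curve"), {
    vapply(seq_len(B), function(b) {
      Xb <- bootstrap_replicate(p, X$n)
      richness_hat(Xb, m_grid)
    }, numeric(length(m_grid)))
  })
  sds <- apply(matrix(boots, nrow = length(m_grid)), 1, sd)
  regime <- ifelse(m_grid < X$n, "interpolated",
                   ifelse(m_grid == X$n, "observed", "extrapolated"))
  out <- data.table(m = m_grid, coverage = est_c, richness = est_r,
                    ci_lo = est_r - z * sds, ci_hi = est_r + z * sds,
                    regime = regime)
  structure(out, q = 0L, B = as.integer(B), seed = as.integer(seed),
            class = c("diversity_curve", class(out)))
}

## Invert coverage_hat by monotone search: smallest real m in [1, m_max]
## with C_hat(m) >= level, linearly interpolated between adjacent integers.
invert_coverage <- function(X, level, m_max, label = "catalogue") {
  X <- abundance_vector(X)
  if (level <= 0 || level >= 1) stopf("coverage level must be in (0, 1)")
  c_max <- .coverage_one(X, m_max)
  if (c_max < level)
    stopf("coverage level %.6g unreachable for %s within m <= %s (max %.6g)",
          level, label, format(m_max), c_max)
  lo <- 1; hi <- m_max
  if (.coverage_one(X, 1) >= level) return(1)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (.coverage_one(X, mid) >= level) hi <- mid else lo <- mid
  }
  clo <- .coverage_one(X, lo); chi <- .coverage_one(X, hi)
  if (chi == clo) return(hi)
  lo + (level - clo) / (chi - clo)
}

#' Relative clonotype diversity of two catalogues at equal coverage
#'
#' Finds, for each abundance vector, the (real-valued) clone count m at which
#' the estimated coverage reaches `coverage_level`, evaluates richness there,
#' and returns the ratio `S_A / S_B` with a paired-bootstrap confidence
#' interval (normal approximation, as in [re_curve_with_bootstrap()]).
#'
#' @param XA,XB abundance vectors (or coercible inputs).
#' @param coverage_level target coverage in (0, 1); must be reachable by both
#'   curves within the extrapolation range.
#' @param B bootstrap replications (default 10).
#' @param seed integer seed.
#' @param max_extrap extrapolation range as a multiple of each reference
#'   sample size (default 2).
#' @param conf confidence level (default 0.95).
#' @return list with `ratio`, `ci_lo`, `ci_hi`, `richness_A`, `richness_B`,
#'   `m_A`, `m_B`, `coverage_level`, `B`.
#' @export
relative_diversity <- function(XA, XB, coverage_level, B = 10L, seed = 1L,
                               max_extrap = 2, conf = 0.95) {
  XA <- abundance_vector(XA); XB <- abundance_vector(XB)
  assert_scalar_int(B, "B", lower = 2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  mA <- invert_coverage(XA, coverage_level, max_extrap * XA$n, "catalogue A")
  mB <- invert_coverage(XB, coverage_level, max_extrap * XB$n, "catalogue B")
  rA <- .richness_one(XA, mA); rB <- .richness_one(XB, mB)
  pA <- bootstrap_community(XA); pB <- bootstrap_community(XB)
  ratios <- with_seed(child_seed(seed, "relative_diversity"), {
    vapply(seq_len(B), function(b) {
      Xa <- bootstrap_replicate(pA, XA$n)
      Xb <- bootstrap_replicate(pB, XB$n)
      ## a replicate may not reach the target coverage within range; evaluate
      ## at the range end in that case so the pair is never dropped
      ma <- tryCatch(invert_coverage(Xa, coverage_level, max_extrap * Xa$n),
                     error = function(e) max_extrap * Xa$n)
      mb <- tryCatch(invert_coverage(Xb, coverage_level, max_extrap * Xb$n),
                     error = function(e) max_extrap * Xb$n)
      .richness_one(Xa, ma) / .richness_one(Xb, mb)
    }, numeric(1))
  })
  ratio <- rA / rB
  list(ratio = ratio,
       ci_lo = ratio - z * sd(ratios), ci_hi = ratio + z * sd(ratios),
       richness_A = rA, richness_B = rB, m_A = mA, m_B = mB,
       coverage_level = coverage_level, B = as.integer(B))
}

#' Asymptotic richness estimate with bootstrap confidence interval
#'
#' The extrapolation asymptote `S_obs + f0_hat` with a normal-approximation
#' CI over B bootstrap replicates.
#'
#' @inheritParams re_curve_with_bootstrap
#' @return list with `estimate`, `ci_lo`, `ci_hi`, `S_obs`, `f0`.
#' @export
asymptotic_richness <- function(X, B = 10L, seed = 1L, conf = 0.95) {
  X <- abundance_vector(X)
  assert_scalar_int(B, "B", lower = 2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est <- X$S_obs + f0_hat(X)
  p <- bootstrap_community(X)
  reps <- with_seed(child_seed(seed, "asymptotic_richness"), {
    vapply(seq_len(B), function(b) {
      Xb <- bootstrap_replicate(p, X$n)
      Xb$S_obs + f0_hat(Xb)
    }, numeric(1))
  })
  list(estimate = est, ci_lo = est - z * sd(reps), ci_hi = est + z * sd(reps),
       S_obs = X$S_obs, f0 = f0_hat(X))
}

#' Hill-number diversity interface (order q)
#'
#' Only clonotype richness (q = 0) is implemented; other orders are rejected
#' with a clear message.
#'
#' @param X abundance vector input.
#' @param m clone count(s).
#' @param q Hill order; must be 0.
#' @return richness estimates, as [richness_hat()].
#' @export
hill_diversity <- function(X, m, q = 0) {
  if (!identical(as.numeric(q), 0)) {
    stopf("only Hill order q = 0 (clonotype richness) is implemented; got q = %s",
          format(q))
  }
  richness_hat(X, m)
}
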