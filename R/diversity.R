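# Hill-number diversity with rarefaction/extrapolation and coverage-
# adjusted bootstrap confidence intervals.
#
# An abundance vector holds the clone-size counts X_i of one sample
# (one count per observed clone, all >= 1, n = sum X_i). Two orders are
# supported: q = 0 (species richness) and q = 1 (exponential of Shannon
# entropy, the "effective number of clones"). Interpolation uses exact
# hypergeometric expectations of without-replacement subsampling;
# extrapolation uses the Chao1 unseen-clone estimate (q = 0) and an
# asymptotic entropy estimator (q = 1). Confidence intervals come from a
# bootstrap over a coverage-adjusted assemblage that reintroduces the
# estimated unseen clones.

as_abundance <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop_tcrgd("abundance vector is empty")
  if (any(counts != floor(counts))) stop_tcrgd("counts must be integers")
  counts
}

# Singleton/doubleton counts and the Chao1 unseen-clone estimate.
frequency_counts <- function(counts) {
  counts <- as_abundance(counts)
  n <- sum(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  f0 <- if (f1 == 0) 0
        else if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
        else ((n - 1) / n) * f1 * (f1 - 1) / 2
  list(n = n, s_obs = length(counts), f1 = f1, f2 = f2, f0_hat = f0)
}

#' Hill number of an abundance vector
#'
#' Plug-in diversity at the observed sample size: order \code{q = 0} is
#' the number of observed clones; \code{q = 1} is \code{exp(H)} with
#' \code{H} the Shannon entropy of the empirical clone frequencies (nats).
#'
#' @param counts positive integer clone sizes.
#' @param q diversity order, 0 or 1.
#' @return the effective number of clones.
#' @examples
#' hill_number(c(1, 1, 1, 1), q = 1)  # 4 equally-sized clones -> 4
#' @export
hill_number <- function(counts, q = c(0, 1)) {
  q <- match.arg(as.character(q[1]), c("0", "1"))
  counts <- as_abundance(counts)
  if (q == "0") return(length(counts))
  p <- counts / sum(counts)
  exp(-sum(p * log(p)))
}

#' Rarefied (interpolated) species richness
#'
#' Expected number of distinct clones in a without-replacement subsample
#' of size \code{m}:
#' \deqn{\hat S(m) = \sum_i \left[1 - \binom{n - X_i}{m} / \binom{n}{m}\right]}
#' Computed in log space; exact, no simulation.
#'
#' @param counts clone sizes.
#' @param m subsample size(s), each between 1 and \code{n}.
#' @return expected richness, one value per \code{m}.
#' @export
rarefied_richness <- function(counts, m) {
  counts <- as_abundance(counts)
  n <- sum(counts)
  if (any(m < 1 | m > n)) {
    stop_tcrgd("m must lie in [1, n]; use extrapolate_richness beyond n")
  }
  vapply(m, function(mm) {
    keep <- (n - counts) >= mm
    absent <- numeric(length(counts))
    absent[keep] <- exp(lchoose(n - counts[keep], mm) - lchoose(n, mm))
    sum(1 - absent)
  }, numeric(1))
}

# Exact expected Shannon entropy of a without-replacement subsample of
# size m: for each clone with count X, the subsample count J is
# hypergeometric(X, n - X, m), and
#   H(m) = sum_i E[ (J/m) log(m/J) ].
# Clones with equal X contribute identically, so work is grouped by
# unique count value.
subsample_entropy_exact <- function(counts, m) {
  n <- sum(counts)
  tab <- table(counts)
  xs <- as.numeric(names(tab))
  mult <- as.numeric(tab)
  H <- 0
  for (i in seq_along(xs)) {
    x <- xs[i]
    j <- seq_len(min(x, m))
    pj <- stats::dhyper(j, x, n - x, m)
    H <- H + mult[i] * sum((j / m) * log(m / j) * pj)
  }
  H
}

subsample_entropy_mc <- function(counts, m, n_draws = 1000L) {
  pool <- rep.int(seq_along(counts), counts)
  mean(vapply(seq_len(n_draws), function(b) {
    sub <- tabulate(sample(pool, m))
    sub <- sub[sub > 0]
    p <- sub / m
    -sum(p * log(p))
  }, numeric(1)))
}

#' Rarefied exponential Shannon diversity
#'
#' Expected Shannon entropy (and its exponential, the order-1 Hill
#' number) of a without-replacement subsample of size \code{m}. The exact
#' mode evaluates the hypergeometric expectation clone-count by
#' clone-count; Monte-Carlo mode averages the entropy of \code{n_draws}
#' seeded subsamples and is used automatically when the exact work
#' (distinct count values times \code{m}) exceeds \code{exact_budget}.
#'
#' @param counts clone sizes.
#' @param m subsample size, between 1 and \code{n}.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"monte_carlo"}.
#' @param n_draws Monte-Carlo subsamples (at least 1000).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param exact_budget work limit above which auto mode switches to
#'   Monte-Carlo (default 5e7 hypergeometric terms).
#' @return list with \code{H} (nats) and \code{D = exp(H)}.
#' @export
rarefied_shannon_hill <- function(counts, m,
                                  mode = c("auto", "exact", "monte_carlo"),
                                  n_draws = 1000L, seed = NULL,
                                  exact_budget = 5e7) {
  mode <- match.arg(mode)
  counts <- as_abundance(counts)
  n <- sum(counts)
  if (m < 1 || m > n) {
    stop_tcrgd("m = %s outside [1, n = %s]", format(m), format(n))
  }
  if (mode == "auto") {
    work <- length(unique(counts)) * m
    mode <- if (work <= exact_budget) "exact" else "monte_carlo"
  }
  H <- if (mode == "exact") {
    subsample_entropy_exact(counts, m)
  } else {
    n_draws <- max(1000L, as.integer(n_draws))
    with_local_seed(seed, subsample_entropy_mc(counts, m, n_draws))
  }
  list(H = H, D = exp(H), m = m, mode = mode)
}

#' Extrapolated species richness
#'
#' Expected richness at sample size \code{n + m_star}, using the Chao1
#' estimate of the number of unseen clones:
#' \deqn{\hat f_0 = \frac{n-1}{n}\frac{f_1^2}{2 f_2}} (or
#' \eqn{\frac{n-1}{n} f_1 (f_1 - 1)/2} when \eqn{f_2 = 0}), and
#' \deqn{\hat S(n + m^*) = S_{obs} + \hat f_0
#'   \left[1 - \left(1 - \frac{f_1}{n \hat f_0 + f_1}\right)^{m^*}\right].}
#' With no singletons the sample is treated as complete.
#'
#' @param counts clone sizes.
#' @param m_star additional sample size(s), each \eqn{\ge 0}.
#' @return expected richness at \code{n + m_star}.
#' @export
extrapolate_richness <- function(counts, m_star) {
  counts <- as_abundance(counts)
  fc <- frequency_counts(counts)
  if (any(m_star < 0)) stop_tcrgd("m_star must be non-negative")
  if (fc$f1 == 0 || fc$f0_hat == 0) {
    return(rep(fc$s_obs, length(m_star)))
  }
  r <- fc$f1 / (fc$n * fc$f0_hat + fc$f1)
  fc$s_obs + fc$f0_hat * (1 - (1 - r)^m_star)
}

# Chao-Wang-Jost asymptotic Shannon entropy estimator; supports q = 1
# extrapolation beyond the observed sample size.
asymptotic_entropy <- function(counts) {
  counts <- as_abundance(counts)
  n <- sum(counts)
  if (n == 1) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  # sum over clones with X_i <= n-1 of (X_i/n) * sum_{k=X_i}^{n-1} 1/k,
  # via reverse-cumulative harmonic tail
  tail_harm <- rev(cumsum(1 / rev(seq_len(n - 1))))  # tail_harm[x] = sum_{k=x}^{n-1} 1/k
  idx <- counts[counts <= n - 1]
  H <- sum((idx / n) * tail_harm[idx])
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  if (f1 > 0 && A < 1) {
    r <- seq_len(n - 1)
    corr <- (f1 / n) * (1 - A)^(1 - n) * (-log(A) - sum((1 - A)^r / r))
    H <- H + corr
  }
  H
}

#' Interpolated/extrapolated diversity at an arbitrary size
#'
#' Dispatches to exact interpolation for sizes up to \code{n} and to the
#' extrapolation estimators beyond. For \code{q = 1} the extrapolated
#' entropy blends the plug-in estimate with the asymptotic estimator:
#' \deqn{\hat H(n + m^*) = \frac{n}{n+m^*}\hat H(n) +
#'   \frac{m^*}{n+m^*}\hat H_\infty.}
#'
#' @param counts clone sizes.
#' @param size target sample size (>= 1; may exceed \code{n}).
#' @param q 0 or 1.
#' @param ... passed to [rarefied_shannon_hill()] for q = 1 interpolation.
#' @return the diversity estimate (effective number of clones).
#' @export
diversity_at_size <- function(counts, size, q = c(0, 1), ...) {
  q <- match.arg(as.character(q[1]), c("0", "1"))
  counts <- as_abundance(counts)
  n <- sum(counts)
  if (q == "0") {
    if (size <= n) rarefied_richness(counts, size)
    else extrapolate_richness(counts, size - n)
  } else {
    if (size <= n) {
      rarefied_shannon_hill(counts, size, ...)$D
    } else {
      Hn <- subsample_entropy_exact(counts, n)  # plug-in entropy
      Hinf <- max(asymptotic_entropy(counts), Hn)
      mstar <- size - n
      exp((n / (n + mstar)) * Hn + (mstar / (n + mstar)) * Hinf)
    }
  }
}

#' Coverage-adjusted bootstrap assemblage
#'
#' Reconstructs a clone-probability distribution to resample from:
#' estimated sample coverage
#' \deqn{\hat C = 1 - \frac{f_1}{n}\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2},}
#' adjusted observed-clone probabilities
#' \eqn{\hat p_i = (X_i/n)(1 - \lambda (1 - X_i/n)^n)} with \eqn{\lambda}
#' chosen so the observed clones carry total probability \eqn{\hat C}, and
#' \eqn{\lceil \hat f_0 \rceil} unseen clones sharing \eqn{1 - \hat C}.
#' Degenerate denominators fall back to the naive \eqn{\hat p_i = X_i/n}
#' with a warning.
#'
#' @param counts clone sizes.
#' @return list: \code{p_hat} (observed clones), \code{p_unseen} (per
#'   unseen clone), \code{n_unseen}, \code{coverage}, \code{lambda};
#'   probabilities sum to 1.
#' @export
build_bootstrap_assemblage <- function(counts) {
  counts <- as_abundance(counts)
  fc <- frequency_counts(counts)
  n <- fc$n
  if (fc$f1 == 0) {
    return(list(p_hat = counts / n, p_unseen = 0, n_unseen = 0L,
                coverage = 1, lambda = 0))
  }
  C_hat <- 1 - (fc$f1 / n) * ((n - 1) * fc$f1 / ((n - 1) * fc$f1 + 2 * fc$f2))
  denom <- sum((counts / n) * (1 - counts / n)^n)
  if (!is.finite(C_hat) || denom <= 0) {
    warning("degenerate assemblage; falling back to naive clone probabilities")
    return(list(p_hat = counts / n, p_unseen = 0, n_unseen = 0L,
                coverage = NA_real_, lambda = NA_real_))
  }
  lambda <- (1 - C_hat) / denom
  p_hat <- (counts / n) * (1 - lambda * (1 - counts / n)^n)
  n_unseen <- max(ceiling(fc$f0_hat), if (C_hat < 1) 1L else 0L)
  p_unseen <- if (n_unseen > 0) (1 - C_hat) / n_unseen else 0
  list(p_hat = p_hat, p_unseen = p_unseen,
       n_unseen = as.integer(n_unseen), coverage = C_hat, lambda = lambda)
}

#' Estimated sample coverage
#'
#' Probability that one more sampled chain belongs to an already-observed
#' clone, estimated from singleton/doubleton counts.
#'
#' @param counts clone sizes.
#' @return coverage in \[0, 1\].
#' @export
sample_coverage <- function(counts) {
  counts <- as_abundance(counts)
  fc <- frequency_counts(counts)
  n <- fc$n
  if (fc$f1 == 0) return(1)
  1 - (fc$f1 / n) * ((n - 1) * fc$f1 / ((n - 1) * fc$f1 + 2 * fc$f2))
}

#' Rarefaction/extrapolation specification
#'
#' Bundles the knobs shared by the bootstrap-based estimators. Defaults
#' follow the package's reference analysis: interpolation point 3500,
#' 50 bootstrap replicates, 95 percent normal-theory intervals.
#'
#' @param q diversity order, 0 or 1.
#' @param m reference sample size.
#' @param B bootstrap replicates (>= 2).
#' @param knots grid size for rarefaction curves.
#' @param seed RNG seed.
#' @param resampling \code{"coverage"} (multinomial resampling of n chains
#'   from the coverage-adjusted assemblage) or \code{"subsample"} (plain
#'   without-replacement subsampling of m chains) for sensitivity checks.
#' @return a list of class \code{"rarefaction_spec"}.
#' @export
rarefaction_spec <- function(q = 1, m = 3500L, B = 50L, knots = 40L,
                             seed = 1L, resampling = c("coverage", "subsample")) {
  resampling <- match.arg(resampling)
  stopifnot(q %in% c(0, 1), m >= 1, knots >= 2)
  if (B < 2) stop_tcrgd("B must be at least 2 (replicate SD is required)")
  structure(list(q = q, m = as.integer(m), B = as.integer(B),
                 knots = as.integer(knots), seed = as.integer(seed),
                 resampling = resampling),
            class = "rarefaction_spec")
}

bootstrap_replicates <- function(counts, spec) {
  counts <- as_abundance(counts)
  n <- sum(counts)
  if (spec$m > n) {
    stop_tcrgd("interpolation point m = %d exceeds sample size n = %d",
               spec$m, n)
  }
  with_local_seed(spec$seed, {
    vapply(seq_len(spec$B), function(b) {
      cb <- if (spec$resampling == "coverage") {
        asm <- build_bootstrap_assemblage(counts)
        p <- c(asm$p_hat, rep(asm$p_unseen, asm$n_unseen))
        as.numeric(stats::rmultinom(1, n, p))
      } else {
        pool <- rep.int(seq_along(counts), counts)
        tabulate(sample(pool, spec$m))
      }
      cb <- cb[cb > 0]
      m_eff <- min(spec$m, sum(cb))
      diversity_at_size(cb, m_eff, q = spec$q)
    }, numeric(1))
  })
}

#' Bootstrap diversity estimate at a reference size
#'
#' Point estimate: the interpolated order-\code{q} diversity of the
#' observed sample at \code{m}. Confidence interval: the point estimate
#' plus/minus 1.96 bootstrap standard deviations, where each replicate
#' redraws \code{n} chains from the coverage-adjusted assemblage and
#' re-evaluates the interpolated estimate at \code{m}.
#'
#' @param counts clone sizes.
#' @param spec a [rarefaction_spec()].
#' @return object of class \code{"diversity_estimate"}: \code{q, m,
#'   estimate, H} (entropy, q = 1 only), \code{ci_low, ci_high, se,
#'   replicate_values, B, seed}.
#' @export
bootstrap_diversity <- function(counts, spec = rarefaction_spec()) {
  counts <- as_abundance(counts)
  reps <- bootstrap_replicates(counts, spec)
  if (spec$q == 1) {
    pt <- rarefied_shannon_hill(counts, spec$m)
    est <- pt$D; H <- pt$H
  } else {
    est <- rarefied_richness(counts, spec$m); H <- NA_real_
  }
  se <- stats::sd(reps)
  structure(list(q = spec$q, m = spec$m, estimate = est, H = H,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 se = se, replicate_values = reps, B = spec$B,
                 seed = spec$seed),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Hill diversity (q = %d) at m = %d: %.2f [%.2f, %.2f] (B = %d)\n",
              x$q, x$m, x$estimate, x$ci_low, x$ci_high, x$B))
  invisible(x)
}

#' Compare two samples' diversity at a common interpolation point
#'
#' Bootstraps both samples at the same reference size \code{m} and runs a
#' two-sample t-test over the two replicate sets (Welch by default).
#'
#' @param counts_a,counts_b clone-size vectors of the two samples.
#' @param spec a [rarefaction_spec()]; \code{m} must not exceed either
#'   sample size. Per-sample bootstrap seeds are derived from
#'   \code{spec$seed}.
#' @param var_equal use Student's pooled-variance test instead of Welch.
#' @return list of class \code{"fixed_point_comparison"}: \code{mean_a,
#'   mean_b, t_statistic, p_value, estimate_a, estimate_b, replicates_a,
#'   replicates_b}.
#' @export
compare_diversity_at_point <- function(counts_a, counts_b,
                                       spec = rarefaction_spec(),
                                       var_equal = FALSE) {
  for (nm in c("a", "b")) {
    x <- if (nm == "a") counts_a else counts_b
    n <- sum(as_abundance(x))
    if (spec$m > n) {
      stop_tcrgd("m = %d exceeds n = %d for sample %s", spec$m, n, nm)
    }
  }
  # both samples share spec$seed so identical inputs give identical
  # replicate sets (and p = 1), the natural determinism contract
  est_a <- bootstrap_diversity(counts_a, spec)
  est_b <- bootstrap_diversity(counts_b, spec)
  ra <- est_a$replicate_values; rb <- est_b$replicate_values
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(ra, rb, var.equal = var_equal)
  }
  structure(list(mean_a = mean(ra), mean_b = mean(rb),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 estimate_a = est_a$estimate, estimate_b = est_b$estimate,
                 replicates_a = ra, replicates_b = rb),
            class = "fixed_point_comparison")
}

#' @export
print.fixed_point_comparison <- function(x, ...) {
  cat(sprintf("mean diversity %.2f vs %.2f; t = %.3f, p = %.4g\n",
              x$mean_a, x$mean_b, x$t_statistic, x$p_value))
  invisible(x)
}

#' D50 clonality index
#'
#' The smallest number \code{k} of top clones whose cumulative chain count
#' reaches half of all chains, and its normalization by the number of
#' unique clones. Low normalized D50 means a repertoire dominated by few
#' large clones.
#'
#' @param counts clone sizes.
#' @return list: \code{k}, \code{normalized = k / S_obs}, \code{s_obs},
#'   \code{n}.
#' @export
d50 <- function(counts) {
  counts <- as_abundance(counts)
  n <- sum(counts)
  sorted <- sort(counts, decreasing = TRUE)
  k <- which(cumsum(sorted) >= n / 2)[1]
  list(k = as.integer(k), normalized = k / length(counts),
       s_obs = length(counts), n = n)
}

#' Rarefaction/extrapolation curve
#'
#' Diversity estimates on a size grid from 1 to twice the observed sample
#' size, with bootstrap confidence bands (each replicate re-evaluated on
#' the whole grid).
#'
#' @param counts clone sizes.
#' @param q 0 or 1.
#' @param knots number of grid points (the observed size is always
#'   included).
#' @param B bootstrap replicates for the band; 0 disables the band.
#' @param seed RNG seed for the bootstrap.
#' @return a \code{data.table}: \code{size, method}
#'   (interpolated/observed/extrapolated), \code{estimate, ci_low,
#'   ci_high}.
#' @export
diversity_curve <- function(counts, q = 1, knots = 40L, B = 50L, seed = 1L) {
  counts <- as_abundance(counts)
  stopifnot(knots >= 2)
  n <- sum(counts)
  sizes <- sort(unique(c(1, round(seq(1, 2 * n, length.out = knots)), n)))
  est <- vapply(sizes, function(s) diversity_at_size(counts, s, q = q),
                numeric(1))
  lo <- hi <- rep(NA_real_, length(sizes))
  if (B >= 2) {
    asm <- build_bootstrap_assemblage(counts)
    p <- c(asm$p_hat, rep(asm$p_unseen, asm$n_unseen))
    repmat <- with_local_seed(seed, {
      vapply(seq_len(B), function(b) {
        cb <- as.numeric(stats::rmultinom(1, n, p))
        cb <- cb[cb > 0]
        vapply(sizes, function(s) diversity_at_size(cb, s, q = q), numeric(1))
      }, numeric(length(sizes)))
    })
    se <- apply(repmat, 1, stats::sd)
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
  }
  data.table::data.table(
    size = sizes,
    method = ifelse(sizes < n, "interpolated",
                    ifelse(sizes == n, "observed", "extrapolated")),
    estimate = est, ci_low = lo, ci_high = hi)
}

#' Abundance vector of a clonotype table
#'
#' @param clonotypes table from [group_clonotypes()] or
#'   [group_paired_clonotypes()].
#' @return named integer vector of clone sizes (names are clonotype keys).
#' @export
clonotype_abundance <- function(clonotypes) {
  key_col <- if ("pair_key" %in% names(clonotypes)) "pair_key" else "key"
  stats::setNames(as.integer(clonotypes$size), clonotypes[[key_col]])
}
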