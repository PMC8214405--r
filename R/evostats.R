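ppi_test <- function(test_name, statistic, p_value, alternative, n,
                     method = NULL, estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), alternative = alternative,
                 n = n, method = method, estimate = estimate),
            class = "ppi_test")
}

#' @export
print.ppi_test <- function(x, ...) {
  cat(sprintf("<%s%s: statistic=%.6g, p=%.4g, alternative=%s, n=%s>\n",
              x$test_name,
              if (is.null(x$method)) "" else paste0(" (", x$method, ")"),
              x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "x")))
  invisible(x)
}

check_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "greater", "less"))
}

#' Ordinary least-squares slope of resilience over generations
#'
#' Rate of change of resilience for one population, fit by OLS on all clone
#' points (e.g. 11 timepoints x 2 clones).
#'
#' @param generation numeric vector of generations.
#' @param resilience numeric vector, same length.
#' @return list with `slope` (change per generation), `intercept`,
#'   `n_points`.
#' @export
ols_slope <- function(generation, resilience) {
  stopifnot(length(generation) == length(resilience))
  ok <- is.finite(generation) & is.finite(resilience)
  x <- generation[ok]; y <- resilience[ok]
  if (length(x) < 2L) stop("need at least 2 points")
  if (length(unique(x)) < 2L)
    stop("all generations identical; slope undefined")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       n_points = length(x))
}

# exact null distribution of the signed-rank statistic W+ over all 2^n sign
# assignments, via the generating function prod_i (1 + x^(2 r_i)) on twice
# the (possibly half-integer, tie-averaged) ranks. Returns counts indexed by
# 2*W = 0 .. 2*sum(r).
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact p-value from the full 2^n sign-assignment null distribution of the
#' signed-rank statistic W+ (sum of ranks of positive differences).
#' Zero differences are dropped before ranking; tied absolute differences
#' receive average ranks, and the exact distribution is computed on those
#' (possibly half-integer) ranks. The two-sided p-value is
#' `P(|W - E W| >= |w_obs - E W|)` under the symmetric null.
#'
#' @param differences numeric vector of paired differences (n <= 25 after
#'   dropping zeros; the enumeration regime).
#' @param alternative `"two_sided"`, `"greater"` (differences tend
#'   positive) or `"less"`.
#' @return a `ppi_test` with statistic W+.
#' @examples
#' wilcoxon_signed_rank_exact(rep(1, 12), "greater")  # p = 1/4096
#' @export
wilcoxon_signed_rank_exact <- function(differences,
                                       alternative = "two_sided") {
  alternative <- check_alternative(alternative)
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; test undefined")
  if (n > 25L) stop("exact enumeration supported for n <= 25 nonzero differences")
  r <- rank(abs(d))                       # average ranks for ties
  r2 <- as.integer(round(2 * r))          # twice-ranks are integers
  w2 <- sum(r2[d > 0])                    # twice the observed W+
  counts <- signed_rank_counts(r2)
  total <- sum(r2)
  denom <- 2^n
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / denom
  p_le <- sum(counts[seq_len(w2 + 1L)]) / denom
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = {
      dev <- abs(seq(0L, total) - total / 2)
      sum(counts[dev >= abs(w2 - total / 2) - 1e-9]) / denom
    })
  ppi_test("wilcoxon_signed_rank_exact", statistic = w2 / 2, p_value = min(p, 1),
           alternative = alternative, n = n, method = "exact")
}

#' Paired comparison of evolved vs null resilience slopes
#'
#' The headline comparison: per population, the difference between the
#' evolved slope and the null-ensemble summary slope, tested with the exact
#' signed-rank test. Populations are the unit of replication. The default
#' alternative `"greater"` asks whether evolved networks lose resilience
#' more slowly than their randomized counterparts.
#'
#' @param evolved_slopes data frame `(population, slope)` for the evolved
#'   series.
#' @param null_slopes data frame `(population, slope)` of per-population
#'   null summary slopes (see [null_summary_slopes()]).
#' @param alternative see [wilcoxon_signed_rank_exact()].
#' @return a `ppi_test`; the per-population differences are attached as
#'   attribute `differences`.
#' @export
paired_resilience_test <- function(evolved_slopes, null_slopes,
                                   alternative = "greater") {
  ev <- as.data.frame(evolved_slopes)
  nu <- as.data.frame(null_slopes)
  if (!setequal(ev$population, nu$population))
    stop("evolved and null slope tables cover different populations")
  m <- merge(ev[, c("population", "slope")], nu[, c("population", "slope")],
             by = "population", suffixes = c("_evolved", "_null"))
  d <- m$slope_evolved - m$slope_null
  out <- wilcoxon_signed_rank_exact(d, alternative)
  out$test_name <- "paired_resilience_test"
  attr(out, "differences") <- stats::setNames(d, m$population)
  out
}

# exact null distribution of the rank-sum of sample x under random
# assignment of the pooled (tie-averaged) ranks: counts[k+1, s+1] = number
# of k-subsets of the ranks with doubled rank-sum s
rank_sum_counts <- function(ranks2, n1) {
  total <- sum(ranks2)
  counts <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (r in ranks2) {
    for (k in rev(seq_len(n1))) {
      shifted <- c(numeric(r), counts[k, seq_len(total + 1L - r)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  counts[n1 + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when both samples have at most 10 observations (ties allowed: the
#' null distribution of the rank-sum statistic is computed over all
#' equally-likely assignments of the tie-averaged pooled ranks, by dynamic
#' programming); otherwise a normal approximation with tie and continuity
#' corrections. The branch used is recorded in `method`.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return a `ppi_test` with the Mann-Whitney U statistic for x.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two_sided") {
  alternative <- check_alternative(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 10L && n2 <= 10L) {
    r2 <- as.integer(round(2 * r))          # doubled ranks are integers
    w2 <- sum(r2[seq_len(n1)])              # doubled observed rank-sum
    counts <- rank_sum_counts(r2, n1)
    denom <- choose(n1 + n2, n1)
    total <- sum(r2)
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / denom
    p_le <- sum(counts[seq_len(w2 + 1L)]) / denom
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two_sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    sigma <- sqrt(sigma2)
    z_g <- (u - mu - 0.5) / sigma
    z_l <- (u - mu + 0.5) / sigma
    p <- switch(alternative,
      greater = stats::pnorm(z_g, lower.tail = FALSE),
      less = stats::pnorm(z_l),
      two_sided = min(1, 2 * min(stats::pnorm(z_l),
                                 stats::pnorm(z_g, lower.tail = FALSE))))
    method <- "normal_approximation"
  }
  ppi_test("wilcoxon_rank_sum", statistic = u, p_value = min(max(p, 0), 1),
           alternative = alternative, n = c(n1, n2), method = method)
}

#' Exact binomial tail test
#'
#' Tail sums of the binomial pmf accumulated in log space.
#'
#' @param x observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param alternative `"less"` (deficit), `"greater"` or `"two_sided"`
#'   (sum of outcomes no more probable than x, as in `binom.test`).
#' @return a `ppi_test`.
#' @export
binomial_tail <- function(x, n, p0, alternative = "two_sided") {
  alternative <- check_alternative(alternative)
  if (x < 0 || x > n || p0 < 0 || p0 > 1) stop("invalid x, n or p0")
  logsum <- function(lp) {
    if (length(lp) == 0L) return(-Inf)
    m <- max(lp)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(lp - m)))
  }
  lp_all <- stats::dbinom(0:n, n, p0, log = TRUE)
  p <- switch(alternative,
    less = exp(logsum(lp_all[seq_len(x + 1L)])),
    greater = exp(logsum(lp_all[(x + 1L):(n + 1L)])),
    two_sided = {
      sel <- lp_all <= lp_all[x + 1L] + 1e-7
      exp(logsum(lp_all[sel]))
    })
  ppi_test("binomial_tail", statistic = x, p_value = min(p, 1),
           alternative = alternative, n = n,
           estimate = x / n, method = sprintf("p0=%.6g", p0))
}

#' Fisher's exact test on a 2x2 table
#'
#' One-sided p-values are hypergeometric tails on the top-left cell
#' (`"greater"` = enrichment); the two-sided p-value sums the probabilities
#' of all tables with the observed margins that are no more probable than
#' the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return a `ppi_test` with the top-left count as statistic.
#' @export
fisher_exact_2x2 <- function(table, alternative = "two_sided") {
  alternative <- check_alternative(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  x <- tab[1L, 1L]
  m <- sum(tab[1L, ])   # row 1 total ("successes" in the urn)
  nn <- sum(tab[2L, ])  # row 2 total
  k <- sum(tab[, 1L])   # column 1 draws
  lo <- max(0L, k - nn); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, nn, k)
  p <- switch(alternative,
    greater = sum(dens[support >= x]),
    less = sum(dens[support <= x]),
    two_sided = sum(dens[dens <= dens[support == x] * (1 + 1e-7)]))
  ppi_test("fisher_exact_2x2", statistic = x, p_value = min(p, 1),
           alternative = alternative, n = dim(tab), method = "exact")
}

#' Pearson product-moment correlation
#'
#' r with a two-sided p-value from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length n >= 3, finite, non-constant.
#' @return a `ppi_test` with statistic r (also in `estimate`).
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  ppi_test("pearson_correlation", statistic = r, p_value = p,
           alternative = "two_sided", n = n, estimate = r)
}

#' Per-population evolved slopes
#'
#' @param resilience data frame `(population, generation, resilience)` with
#'   one row per clone (as returned by [evolved_resilience()]).
#' @return data frame `(population, series, slope, n_points)`.
#' @export
population_slopes <- function(resilience) {
  df <- as.data.frame(resilience)
  pops <- unique(df$population)
  out <- lapply(pops, function(p) {
    sub <- df[df$population == p, ]
    fit <- ols_slope(sub$generation, sub$resilience)
    data.frame(population = p, series = "evolved", slope = fit$slope,
               n_points = fit$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-population null summary slopes
#'
#' Default summary (`"mean_of_slopes"`): each replicate series gets its own
#' OLS slope across (generation, clone) points, and the per-population
#' summary is the mean of replicate slopes. The alternative
#' (`"slope_of_means"`) fits one slope to the per-point replicate means.
#'
#' @param ensemble data frame from [build_null_ensemble()].
#' @param summary summary convention.
#' @return data frame `(population, series, slope, n_points)` where series
#'   is the ensemble's scheme.
#' @export
null_summary_slopes <- function(ensemble,
                                summary = c("mean_of_slopes", "slope_of_means")) {
  summary <- match.arg(summary)
  df <- as.data.frame(ensemble)
  scheme <- unique(df$scheme)
  stopifnot(length(scheme) == 1L)
  pops <- unique(df$population)
  out <- lapply(pops, function(p) {
    sub <- df[df$population == p, ]
    if (summary == "mean_of_slopes") {
      sl <- vapply(split(sub, sub$replicate), function(s)
        ols_slope(s$generation, s$resilience)$slope, numeric(1))
      slope <- mean(sl)
      npt <- nrow(sub) / length(unique(sub$replicate))
    } else {
      agg <- stats::aggregate(resilience ~ generation + clone, sub, mean)
      fit <- ols_slope(agg$generation, agg$resilience)
      slope <- fit$slope; npt <- fit$n_points
    }
    data.frame(population = p, series = scheme, slope = slope,
               n_points = npt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between mean fitness and resilience
#'
#' Joins per-clone resilience with a mean-fitness table on (population,
#' generation), averaging resilience over clones, and reports the Pearson
#' correlation.
#'
#' @param resilience data frame `(population, generation, resilience)`.
#' @param fitness data frame `(population, generation, fitness)`.
#' @return a `ppi_test` from [pearson_correlation()].
#' @export
fitness_resilience_correlation <- function(resilience, fitness) {
  res <- stats::aggregate(resilience ~ population + generation,
                          as.data.frame(resilience), mean)
  m <- merge(res, as.data.frame(fitness), by = c("population", "generation"))
  if (nrow(m) < 3L) stop("fewer than 3 (population, generation) pairs in common")
  pearson_correlation(m$fitness, m$resilience)
}
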