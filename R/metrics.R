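#' Expected richness of a random subsample (individual-based rarefaction)
#'
#' Expected number of species in a uniform random draw of `n` individuals
#' without replacement from a community with abundances `counts`:
#' \deqn{E[S_n] = \sum_i 1 - \binom{N - N_i}{n} / \binom{N}{n}}
#' where \eqn{N = \sum_i N_i}. Binomial coefficients are evaluated on the log
#' scale (`lchoose`), so the result is stable for read totals of 1e7 and
#' beyond.
#'
#' @param counts non-negative integer vector of per-species abundances.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return Expected species count, a real number in `[1, S]` (0 for an empty
#'   community is not allowed: `n >= 1` requires individuals).
#' @examples
#' rarefied_richness(c(4, 2, 1), 3)  # 74/35
#' @export
rarefied_richness <- function(counts, n) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (length(n) != 1L || is.na(n) || n != round(n)) stop("n must be a single integer")
  if (n < 1) stop("n must be >= 1")
  if (n > N) stop("n (", n, ") exceeds the total number of individuals (", N, ")")
  counts <- counts[counts > 0]
  # P(species i absent from the subsample) = C(N - N_i, n) / C(N, n)
  p_absent <- exp(lchoose(N - counts, n) - lchoose(N, n))
  p_absent[N - counts < n] <- 0
  sum(1 - p_absent)
}

#' Hurlbert's probability of interspecific encounter (PIE)
#'
#' Probability that two individuals drawn at random without replacement belong
#' to different species. With \eqn{N = \sum_i N_i} this is the bias-corrected
#' Simpson evenness \eqn{\frac{N}{N-1}(1 - \sum_i (N_i/N)^2)}, computed here
#' in the algebraically identical integer form
#' \eqn{(N^2 - \sum_i N_i^2) / (N (N - 1))}, which is exact in double
#' precision for ordinary count magnitudes.
#'
#' @param counts non-negative integer vector of per-species abundances with
#'   total at least 2.
#' @return PIE in `[0, 1]`, or `NA` (with a warning) when fewer than two
#'   individuals are present.
#' @examples
#' hurlbert_pie(c(9, 1))    # 0.2
#' hurlbert_pie(c(10, 10))  # 10/19
#' @export
hurlbert_pie <- function(counts) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (N < 2) {
    warning("PIE undefined for fewer than 2 individuals; returning NA")
    return(NA_real_)
  }
  (N^2 - sum(counts^2)) / (N * (N - 1))
}

#' Effective number of species behind the PIE
#'
#' Converts PIE to the number of equally abundant species that would give the
#' same encounter probability: \eqn{S_{PIE} = 1 / (1 - PIE)}. A monoculture
#' gives 1. PIE = 1 (only possible degenerately) yields `NA` with a warning.
#'
#' @param counts non-negative integer vector of per-species abundances.
#' @return Effective species number `>= 1`, or `NA` when PIE is undefined.
#' @examples
#' effective_species_pie(c(9, 1))    # 1.25
#' effective_species_pie(c(10, 10))  # 19/9
#' @export
effective_species_pie <- function(counts) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (N < 2) {
    warning("S_PIE undefined for fewer than 2 individuals; returning NA")
    return(NA_real_)
  }
  denom <- sum(counts^2) - N  # = N(N-1)(1 - PIE)
  if (denom <= 0) {
    warning("PIE = 1; S_PIE is infinite, returning NA")
    return(NA_real_)
  }
  N * (N - 1) / denom
}

#' Rarefaction base n for a site
#'
#' The subsample size shared by both management types at a site: the minimum
#' total number of individuals over all subplots of the site, both groups
#' pooled into the candidate set. Subplots with fewer than 2 individuals carry
#' no usable signal for the evenness metrics and are excluded from the
#' minimum with a warning.
#'
#' @param table a counts [community_table()].
#' @param site site label.
#' @return Integer `n >= 2`.
#' @export
rarefaction_base_n <- function(table, site) {
  stopifnot(inherits(table, "community_table"))
  sel <- table$samples$site == site
  if (!any(sel)) stop("no samples for site '", site, "'")
  totals <- rowSums(table$abundance[sel, , drop = FALSE])
  tiny <- totals < 2
  if (any(tiny)) {
    warning(sum(tiny), " subplot(s) with fewer than 2 individuals excluded ",
            "from the rarefaction base at site '", site, "'")
    totals <- totals[!tiny]
  }
  if (length(totals) == 0L) {
    stop("no subplot with at least 2 individuals at site '", site, "'")
  }
  as.integer(min(totals))
}

metric_names <- c("N", "S", "S_n", "PIE", "S_PIE")

subplot_metric_matrix <- function(abundance, n) {
  # per-subplot N, S, S_n(n), PIE, S_PIE; rows = subplots
  t(apply(abundance, 1L, function(x) {
    N <- sum(x)
    S <- sum(x > 0)
    S_n <- if (N >= n && n >= 1) rarefied_richness(x, n) else NA_real_
    if (N >= 2) {
      PIE <- hurlbert_pie(x)
      denom <- sum(x^2) - N
      S_PIE <- if (denom > 0) N * (N - 1) / denom else NA_real_
    } else {
      PIE <- NA_real_
      S_PIE <- NA_real_
    }
    c(N = N, S = S, S_n = S_n, PIE = PIE, S_PIE = S_PIE)
  }))
}

#' Alpha-scale metrics for one site-management group
#'
#' Computes N, S, rarefied richness at the site base `n`, PIE and its
#' effective species number for every subplot of the stratum, and summarises
#' them as arithmetic means. Subplots where a metric is undefined (fewer than
#' 2 individuals, or fewer than `n`) contribute `NA` and are dropped from the
#' corresponding mean.
#'
#' @param table a counts [community_table()].
#' @param site site label.
#' @param management `"pasture"` or `"meadow"`.
#' @param n rarefaction base from [rarefaction_base_n()].
#' @return List with `scale = "alpha"`, the group labels, `n_base`,
#'   `n_subplots`, the five metric means, and `subplot`, a data.frame of the
#'   per-subplot values used by the alpha-scale tests.
#' @export
alpha_metrics <- function(table, site, management, n) {
  stopifnot(inherits(table, "community_table"))
  sel <- table$samples$site == site & table$samples$management == management
  if (!any(sel)) {
    stop("no samples for site '", site, "', management '", management, "'")
  }
  ab <- table$abundance[sel, , drop = FALSE]
  per <- subplot_metric_matrix(ab, n)
  means <- colMeans(per, na.rm = TRUE)
  list(scale = "alpha", site = site, management = management,
       n_base = as.integer(n), n_subplots = nrow(ab),
       N = means[["N"]], S = means[["S"]], S_n = means[["S_n"]],
       PIE = means[["PIE"]], S_PIE = means[["S_PIE"]],
       subplot = data.frame(sample_id = rownames(ab), per,
                            stringsAsFactors = FALSE, row.names = NULL))
}

#' Gamma-scale metrics for one site-management group
#'
#' Pools the stratum's subplots and computes N, S, rarefied richness at
#' `n * n_subplots` (the subplot base scaled by the number of replicates in
#' the group), PIE and its effective species number on the pooled vector.
#'
#' @inheritParams alpha_metrics
#' @return List with `scale = "gamma"`, the group labels, `n_base` (the
#'   gamma-scale target `n * n_subplots`), `n_subplots`, the five metrics, and
#'   `pooled`, the pooled abundance vector.
#' @export
gamma_metrics <- function(table, site, management, n) {
  stopifnot(inherits(table, "community_table"))
  pooled <- pool_group(table, site, management)
  n_subplots <- sum(table$samples$site == site & table$samples$management == management)
  n_gamma <- as.integer(n) * n_subplots
  N <- sum(pooled)
  if (n_gamma > N) {
    stop("gamma-scale rarefaction target ", n_gamma,
         " exceeds the pooled total ", N)
  }
  list(scale = "gamma", site = site, management = management,
       n_base = n_gamma, n_subplots = n_subplots,
       N = N, S = sum(pooled > 0),
       S_n = rarefied_richness(pooled, n_gamma),
       PIE = hurlbert_pie(pooled),
       S_PIE = effective_species_pie(pooled),
       pooled = pooled)
}

#' Multiplicative beta-diversity partition for one group
#'
#' Whittaker's multiplicative partition, beta = gamma / mean(alpha), for
#' richness, rarefied richness and the PIE effective species number. To
#' isolate spatial aggregation from density and abundance-distribution
#' effects, the rarefied component compares the pooled community and the
#' subplots at the *same* subsample size `n`; this gamma-scale rarefaction at
#' `n` is deliberately distinct from the reported gamma-scale `S_n` (which
#' uses `n` times the number of replicates).
#'
#' @param alpha result of [alpha_metrics()] for the group.
#' @param gamma_pooled pooled abundance vector for the same group (e.g.
#'   [pool_group()] or the `pooled` element of [gamma_metrics()]).
#' @param n the shared rarefaction base.
#' @return List with `beta_S`, `beta_S_n`, `beta_S_PIE`. For identical
#'   subplots the rarefied and evenness components sit slightly *below* 1 —
#'   the without-replacement corrections see k times the individuals in the
#'   pool — and converge to 1 as subplot totals grow; spatial aggregation
#'   pushes them above 1.
#' @export
beta_partition <- function(alpha, gamma_pooled, n) {
  mean_S <- alpha$S
  mean_S_n <- alpha$S_n
  mean_S_PIE <- alpha$S_PIE
  if (!is.finite(mean_S) || mean_S <= 0) stop("mean alpha-scale richness is zero")
  gamma_S_PIE <- effective_species_pie(gamma_pooled)
  list(
    group = c(site = alpha$site, management = alpha$management),
    beta_S = sum(gamma_pooled > 0) / mean_S,
    beta_S_n = if (is.finite(mean_S_n) && mean_S_n > 0)
      rarefied_richness(gamma_pooled, n) / mean_S_n else NA_real_,
    beta_S_PIE = if (is.finite(mean_S_PIE) && mean_S_PIE > 0 && is.finite(gamma_S_PIE))
      gamma_S_PIE / mean_S_PIE else NA_real_
  )
}

#' All metrics for one site-management group at both scales
#'
#' Convenience wrapper: alpha means, gamma values, and the beta partition,
#' sharing one rarefaction base.
#'
#' @inheritParams alpha_metrics
#' @return List with elements `alpha`, `gamma`, `beta`.
#' @export
group_metrics <- function(table, site, management, n) {
  a <- alpha_metrics(table, site, management, n)
  g <- gamma_metrics(table, site, management, n)
  b <- beta_partition(a, g$pooled, n)
  list(alpha = a, gamma = g, beta = b)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty abundance vector")
  if (anyNA(counts)) stop("abundance vector contains missing values")
  if (any(counts < 0)) stop("abundance vector contains negative values")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("abundance vector must contain integer counts")
  }
  round(counts)
}
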