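#' Configuration for the hierarchical community simulator
#'
#' Describes a nested grassland sampling design (sites > management types >
#' plots > 1 m^2 subplots) and the three community components the simulator
#' controls independently: density of individuals (Poisson subplot totals),
#' the species-abundance distribution (lognormal, with shape `sad_sigma`),
#' and intraspecific spatial aggregation (Dirichlet overdispersion of subplot
#' composition around the regional relative abundances, with concentration
#' `aggregation_theta`). Treatment multipliers perturb the pasture group
#' only; all multipliers at 1 give an exact null in which the two groups are
#' exchangeable by construction.
#'
#' @param n_sites number of sites.
#' @param plots_per_group named integer vector `c(pasture = ..., meadow = ...)`
#'   or a single integer used for both; may also be a list of per-site vectors
#'   to emulate unbalanced designs.
#' @param subplots_per_plot subplots sampled per plot (default 10).
#' @param species_pool regional species pool size.
#' @param sad_sigma lognormal shape sigma >= 0 of the regional
#'   species-abundance distribution; 0 gives a perfectly even pool, larger
#'   values less even communities.
#' @param density_lambda expected individuals per subplot (Poisson mean).
#' @param aggregation_theta Dirichlet concentration > 0; smaller values give
#'   stronger intraspecific aggregation (more between-subplot composition
#'   variance). Values >= 1e8 are treated as the no-aggregation limit.
#' @param density_mult,sigma_mult,theta_mult multipliers applied to
#'   `density_lambda`, `sad_sigma` and `aggregation_theta` for the pasture
#'   group.
#' @param seed mandatory RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 5,
                              plots_per_group = c(pasture = 3, meadow = 3),
                              subplots_per_plot = 10,
                              species_pool = 50,
                              sad_sigma = 1,
                              density_lambda = 100,
                              aggregation_theta = 5,
                              density_mult = 1,
                              sigma_mult = 1,
                              theta_mult = 1,
                              seed) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  norm_plots <- function(x) {
    if (length(x) == 1L && is.null(names(x))) x <- c(pasture = x, meadow = x)
    if (!all(c("pasture", "meadow") %in% names(x))) {
      stop("plots_per_group needs named entries 'pasture' and 'meadow'")
    }
    x <- as.integer(x[c("pasture", "meadow")])
    names(x) <- c("pasture", "meadow")
    if (any(x < 1L)) stop("plots_per_group must be >= 1")
    x
  }
  if (is.list(plots_per_group)) {
    if (length(plots_per_group) != n_sites) {
      stop("per-site plots_per_group list must have n_sites elements")
    }
    plots_per_group <- lapply(plots_per_group, norm_plots)
  } else {
    plots_per_group <- replicate(n_sites, norm_plots(plots_per_group),
                                 simplify = FALSE)
  }
  stopifnot(n_sites >= 1, subplots_per_plot >= 1, species_pool >= 2,
            sad_sigma >= 0, density_lambda > 0, aggregation_theta > 0,
            density_mult > 0, sigma_mult > 0, theta_mult > 0)
  structure(list(n_sites = as.integer(n_sites),
                 plots_per_group = plots_per_group,
                 subplots_per_plot = as.integer(subplots_per_plot),
                 species_pool = as.integer(species_pool),
                 sad_sigma = sad_sigma, density_lambda = density_lambda,
                 aggregation_theta = aggregation_theta,
                 density_mult = density_mult, sigma_mult = sigma_mult,
                 theta_mult = theta_mult, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw a regional species-abundance distribution
#'
#' Draws `S_pool` lognormal(0, sigma^2) abundances and normalizes them to
#' relative abundances. `sigma = 0` degenerates to the perfectly even pool
#' `1/S_pool`.
#'
#' @param S_pool pool size (>= 2).
#' @param sigma lognormal shape.
#' @param seed optional seed.
#' @return Numeric vector of relative abundances summing to 1.
#' @export
draw_regional_sad <- function(S_pool, sigma, seed = NULL) {
  stopifnot(S_pool >= 2, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(S_pool)
  sad_from_deviates(z, sigma)
}

sad_from_deviates <- function(z, sigma) {
  x <- exp(sigma * z)
  x / sum(x)
}

#' Simulate one management group at one site
#'
#' For each subplot, draws a composition `q ~ Dirichlet(theta' * p_regional)`
#' (with `theta'` and the Poisson density multiplied by the treatment factors
#' for pastures), a subplot total `n ~ Poisson(lambda')`, and counts
#' `Multinomial(n, q)`. Concentrations of 1e8 or more shortcut to
#' `q = p_regional` exactly (the no-aggregation limit).
#'
#' @param p_regional regional relative abundances (sum to 1).
#' @param config a [simulation_config()].
#' @param management `"pasture"` or `"meadow"`.
#' @param n_subplots number of subplots to draw; defaults to the config's
#'   plots x subplots for the group at site 1.
#' @return Integer matrix, subplots x species. Uses the current RNG state;
#'   seed via [simulate_experiment()] or `set.seed()` for reproducibility.
#' @export
simulate_group <- function(p_regional, config, management,
                           n_subplots = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            management %in% c("pasture", "meadow"))
  is_pasture <- management == "pasture"
  lambda <- config$density_lambda * if (is_pasture) config$density_mult else 1
  theta <- config$aggregation_theta * if (is_pasture) config$theta_mult else 1
  if (is.null(n_subplots)) {
    n_subplots <- config$plots_per_group[[1L]][[management]] * config$subplots_per_plot
  }
  S <- length(p_regional)
  out <- matrix(0L, nrow = n_subplots, ncol = S)
  for (j in seq_len(n_subplots)) {
    q <- if (theta >= 1e8) p_regional else rdirichlet_mean(p_regional, theta)
    n_ind <- stats::rpois(1L, lambda)
    if (n_ind > 0L) out[j, ] <- stats::rmultinom(1L, n_ind, q)[, 1L]
  }
  out
}

rdirichlet_mean <- function(p, theta) {
  # Dirichlet with mean p and concentration theta
  g <- stats::rgamma(length(p), shape = theta * p)
  s <- sum(g)
  if (s <= 0) return(p)  # all shapes underflowed; fall back to the mean
  g / s
}

#' Simulate a full two-management grassland study
#'
#' Assembles a hierarchical dataset in the study design: each site gets a
#' shared regional species-abundance distribution (one standard-normal
#' deviate per species, scaled by the group's sigma, so treatment changes
#' evenness without changing the species pool), and each management group's
#' plots and subplots are drawn with [simulate_group()]. Pasture groups see
#' the treatment multipliers; with all multipliers at 1 both groups are draws
#' from the same process.
#'
#' @param config a [simulation_config()].
#' @return List with `table` (a counts [community_table()]) and `truth`
#'   (per-site realized parameters and regional relative abundances, plus the
#'   config echo) for parameter-recovery checks.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  S <- config$species_pool
  taxa <- sprintf("sp%03d", seq_len(S))
  lui_cycle <- c("low", "intermediate", "high")

  mats <- list()
  metas <- list()
  truth_sites <- list()
  for (i in seq_len(config$n_sites)) {
    site <- sprintf("site%02d", i)
    z <- stats::rnorm(S)
    sigma_m <- config$sad_sigma
    sigma_p <- config$sad_sigma * config$sigma_mult
    p_meadow <- sad_from_deviates(z, sigma_m)
    p_pasture <- sad_from_deviates(z, sigma_p)
    plots <- config$plots_per_group[[i]]
    for (mg in c("pasture", "meadow")) {
      n_plots <- plots[[mg]]
      n_sub <- n_plots * config$subplots_per_plot
      p_reg <- if (mg == "pasture") p_pasture else p_meadow
      mat <- simulate_group(p_reg, config, mg, n_subplots = n_sub)
      plot_lab <- rep(sprintf("%s_%s_plot%d", site, mg, seq_len(n_plots)),
                      each = config$subplots_per_plot)
      sub_lab <- rep(sprintf("sub%02d", seq_len(config$subplots_per_plot)),
                     times = n_plots)
      metas[[length(metas) + 1L]] <- data.frame(
        sample_id = paste(plot_lab, sub_lab, sep = "_"),
        site = site, plot = plot_lab, subplot = sub_lab, management = mg,
        lui_category = if (mg == "pasture")
          lui_cycle[((i - 1L) %% length(lui_cycle)) + 1L] else "none",
        stringsAsFactors = FALSE
      )
      mats[[length(mats) + 1L]] <- mat
    }
    truth_sites[[site]] <- list(
      p_regional = list(pasture = p_pasture, meadow = p_meadow),
      sigma = c(pasture = sigma_p, meadow = sigma_m),
      lambda = c(pasture = config$density_lambda * config$density_mult,
                 meadow = config$density_lambda),
      theta = c(pasture = config$aggregation_theta * config$theta_mult,
                meadow = config$aggregation_theta)
    )
  }
  abundance <- do.call(rbind, mats)
  samples <- do.call(rbind, metas)
  table <- community_table(abundance, samples, taxa = taxa,
                           abundance_kind = "counts")
  list(table = table,
       truth = list(config = unclass(config), sites = truth_sites))
}
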