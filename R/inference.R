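#' Log-response ratio of a management effect
#'
#' Effect size `ln(x_pasture / x_meadow)` with meadows as reference: positive
#' values mean the quantity is higher under pasture management.
#'
#' @param x_pasture,x_meadow positive group-level values.
#' @return The log ratio, or `NA` (with a warning) when either value is
#'   missing or non-positive.
#' @export
log_response_ratio <- function(x_pasture, x_meadow) {
  if (is.na(x_pasture) || is.na(x_meadow) || x_pasture <= 0 || x_meadow <= 0) {
    warning("log-response ratio undefined for non-positive or missing values")
    return(NA_real_)
  }
  log(x_pasture) - log(x_meadow)
}

#' Alpha-scale management test (one-way ANOVA on subplot values)
#'
#' Compares per-subplot metric values between the two management types with a
#' one-way analysis of variance (two groups, so F equals the squared
#' pooled-variance t statistic). The effect size is the log-response ratio of
#' the group means. A label-permutation p-value for the same F statistic is
#' available on request.
#'
#' @param values_pasture,values_meadow numeric vectors of per-subplot metric
#'   values; `NA`s are dropped, at least 2 values per group must remain.
#' @param n_perm if not `NULL`, also compute a permutation p-value from this
#'   many label shuffles (add-one rule).
#' @param seed RNG seed for the permutation option.
#' @return List with `lrr`, `statistic` (F), `p_value`, `df`, group sizes,
#'   `method = "anova"`, and `p_permutation` when requested. Degenerate data
#'   (no variance anywhere, equal means) give `statistic = 0`, `p_value = 1`.
#' @export
alpha_scale_test <- function(values_pasture, values_meadow, n_perm = NULL, seed = NULL) {
  vp <- values_pasture[!is.na(values_pasture)]
  vm <- values_meadow[!is.na(values_meadow)]
  if (length(vp) < 2L || length(vm) < 2L) {
    stop("need at least 2 non-missing values per group")
  }
  y <- c(vp, vm)
  g <- factor(rep(c("pasture", "meadow"), c(length(vp), length(vm))))
  lrr <- suppressWarnings(log_response_ratio(mean(vp), mean(vm)))

  res <- anova_f(y, g)
  out <- list(lrr = lrr, statistic = res$F, p_value = res$p,
              df = c(1L, length(y) - 2L),
              n_pasture = length(vp), n_meadow = length(vm),
              method = "anova")
  if (!is.null(n_perm)) {
    if (!is.null(seed)) set.seed(seed)
    f_obs <- res$F
    hits <- 0L
    for (b in seq_len(n_perm)) {
      f_b <- anova_f(y, sample(g))$F
      if (f_b >= f_obs - 1e-12) hits <- hits + 1L
    }
    out$p_permutation <- (1 + hits) / (n_perm + 1)
    out$n_perm <- as.integer(n_perm)
  }
  out
}

anova_f <- function(y, g) {
  # two-group one-way ANOVA with a guard for zero-variance inputs
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12 * max(1, mean(y)^2)) {
    return(list(F = 0, p = 1))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f_val <- unname(fit$statistic)
  p_val <- unname(fit$p.value)
  if (!is.finite(f_val)) {  # zero within-group variance, unequal means
    f_val <- Inf
    p_val <- .Machine$double.xmin
  }
  list(F = f_val, p = p_val)
}

#' Gamma- and beta-scale permutation tests
#'
#' At the pooled scale there is one value per management type, so management
#' effects are tested against a permutation null: subplots (or whole plots)
#' are randomly reassigned to the two management labels preserving group
#' sizes, the group-level metrics are recomputed, and the observed
#' log-response ratio is compared two-sidedly to the permuted ones with the
#' add-one rule `p = (1 + #\{|LRR*| >= |LRR|\}) / (n_perm + 1)`. All requested
#' metrics share the same permutations. The rarefaction base `n` is the
#' site-wide subplot minimum and does not change under permutation.
#'
#' @param table a counts [community_table()].
#' @param site site label; both management types must be present.
#' @param metric character vector from `N`, `S`, `S_n`, `S_PIE` (gamma scale)
#'   and `beta_S`, `beta_S_n`, `beta_S_PIE` (beta scale).
#' @param n_perm number of permutations (default 199, so the smallest
#'   attainable p is 1/200 = 0.005).
#' @param seed RNG seed; required for reproducibility.
#' @param statistic `"lrr"` (log-response ratio, default) or `"diff"` (raw
#'   difference pasture minus meadow).
#' @param permute `"subplot"` (default) or `"plot"`: the exchangeable unit.
#' @return data.frame with one row per metric: `metric`, `scale`, `lrr` (the
#'   observed log-response ratio), `statistic` (the observed test statistic,
#'   equal to `lrr` unless `statistic = "diff"`), `p_value`, `n_perm`,
#'   `method`, `value_pasture`, `value_meadow`.
#' @export
gamma_scale_permutation_test <- function(table, site,
                                         metric = c("N", "S", "S_n", "S_PIE"),
                                         n_perm = 199, seed = NULL,
                                         statistic = c("lrr", "diff"),
                                         permute = c("subplot", "plot")) {
  stopifnot(inherits(table, "community_table"))
  statistic <- match.arg(statistic)
  permute <- match.arg(permute)
  valid <- c("N", "S", "S_n", "S_PIE", "beta_S", "beta_S_n", "beta_S_PIE")
  metric <- match.arg(metric, valid, several.ok = TRUE)

  sel <- table$samples$site == site
  if (!any(sel)) stop("no samples for site '", site, "'")
  ab <- table$abundance[sel, , drop = FALSE]
  meta <- table$samples[sel, , drop = FALSE]
  grp <- meta$management
  if (length(unique(grp)) != 2L) {
    stop("site '", site, "' lacks one of the management types")
  }
  n_base <- rarefaction_base_n(table, site)

  needs_subplot <- any(startsWith(metric, "beta"))
  per <- if (needs_subplot) subplot_metric_matrix(ab, n_base) else NULL

  eval_groups <- function(idx_p, idx_m) {
    vals <- matrix(NA_real_, nrow = length(metric), ncol = 2L,
                   dimnames = list(metric, c("pasture", "meadow")))
    for (k in 1:2) {
      idx <- if (k == 1L) idx_p else idx_m
      pooled <- colSums(ab[idx, , drop = FALSE])
      N <- sum(pooled)
      for (m in metric) {
        vals[m, k] <- switch(
          m,
          N = N,
          S = sum(pooled > 0),
          S_n = rarefied_richness(pooled, n_base * length(idx)),
          S_PIE = suppressWarnings(effective_species_pie(pooled)),
          beta_S = sum(pooled > 0) / mean(per[idx, "S"]),
          beta_S_n = rarefied_richness(pooled, n_base) /
            mean(per[idx, "S_n"], na.rm = TRUE),
          beta_S_PIE = suppressWarnings(effective_species_pie(pooled)) /
            mean(per[idx, "S_PIE"], na.rm = TRUE)
        )
      }
    }
    vals
  }
  stat_of <- function(vals) {
    if (statistic == "lrr") {
      s <- log(vals[, "pasture"] / vals[, "meadow"])
      s[!is.finite(s)] <- NA_real_
      s
    } else {
      vals[, "pasture"] - vals[, "meadow"]
    }
  }

  idx_p <- which(grp == "pasture")
  idx_m <- which(grp == "meadow")
  obs_vals <- eval_groups(idx_p, idx_m)
  obs <- stat_of(obs_vals)
  if (anyNA(obs)) {
    stop("observed statistic undefined for metric(s): ",
         paste(metric[is.na(obs)], collapse = ", "))
  }

  if (!is.null(seed)) set.seed(seed)
  draw_labels <- function() {
    if (permute == "subplot") {
      shuffled <- sample(seq_along(grp))
      list(p = shuffled[seq_along(idx_p)],
           m = shuffled[length(idx_p) + seq_along(idx_m)])
    } else {
      plot_key <- paste(meta$management, meta$plot)
      plots <- unique(plot_key)
      n_plots_p <- length(unique(plot_key[grp == "pasture"]))
      perm_plots <- sample(plots)
      new_p <- plot_key %in% perm_plots[seq_len(n_plots_p)]
      list(p = which(new_p), m = which(!new_p))
    }
  }

  null_stats <- matrix(NA_real_, nrow = n_perm, ncol = length(metric))
  attempts <- 0L
  max_attempts <- 10L * n_perm + 100L
  b <- 1L
  while (b <= n_perm) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("too many degenerate permutation draws at site '", site, "'")
    }
    lab <- draw_labels()
    s <- stat_of(eval_groups(lab$p, lab$m))
    if (anyNA(s)) next  # degenerate draw: resample
    null_stats[b, ] <- s
    b <- b + 1L
  }

  p_vals <- vapply(seq_along(metric), function(j) {
    (1 + sum(abs(null_stats[, j]) >= abs(obs[j]) - 1e-12)) / (n_perm + 1)
  }, numeric(1))

  lrr_obs <- log(obs_vals[, "pasture"] / obs_vals[, "meadow"])
  data.frame(
    metric = metric,
    scale = ifelse(startsWith(metric, "beta"), "beta", "gamma"),
    lrr = unname(lrr_obs),
    statistic = unname(obs),
    p_value = p_vals,
    n_perm = as.integer(n_perm),
    method = "permutation",
    value_pasture = unname(obs_vals[, "pasture"]),
    value_meadow = unname(obs_vals[, "meadow"]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Plan the design-balancing resampling for a site
#'
#' When the two management types have unequal numbers of plots, sampling
#' effort is standardized by repeatedly restricting the larger group to as
#' many whole plots as the smaller group has, enumerating every unique plot
#' combination without replacement. When the combination count exceeds `cap`,
#' `cap` distinct combinations are drawn uniformly. Balanced designs yield a
#' single identity replicate.
#'
#' @param table a [community_table()].
#' @param site site label with both management types.
#' @param cap maximum number of replicates.
#' @param seed RNG seed used only when sampling beyond `cap`.
#' @return List of class `standardization_plan`: `site`, `larger_group`,
#'   `smaller_group`, `plot_combinations` (list of plot-label vectors for the
#'   larger group; a single `NULL` for balanced designs), `n_possible`,
#'   `cap`, `seed`.
#' @export
build_standardization_plan <- function(table, site, cap = 200, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  meta <- table$samples[table$samples$site == site, , drop = FALSE]
  if (nrow(meta) == 0L) stop("no samples for site '", site, "'")
  plots_p <- unique(meta$plot[meta$management == "pasture"])
  plots_m <- unique(meta$plot[meta$management == "meadow"])
  if (length(plots_p) == 0L || length(plots_m) == 0L) {
    stop("site '", site, "' lacks one of the management types")
  }
  if (length(plots_p) == length(plots_m)) {
    return(structure(list(site = site, larger_group = NA_character_,
                          smaller_group = NA_character_,
                          plot_combinations = list(NULL),
                          n_possible = 1L, cap = as.integer(cap), seed = seed),
                     class = "standardization_plan"))
  }
  if (length(plots_p) > length(plots_m)) {
    larger <- "pasture"; smaller <- "meadow"
    pool <- plots_p; k <- length(plots_m)
  } else {
    larger <- "meadow"; smaller <- "pasture"
    pool <- plots_m; k <- length(plots_p)
  }
  n_possible <- choose(length(pool), k)
  if (n_possible <= cap) {
    combos <- utils::combn(pool, k, simplify = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    seen <- character(0)
    combos <- list()
    while (length(combos) < cap) {
      cand <- sort(sample(pool, k))
      key <- paste(cand, collapse = "\r")
      if (!key %in% seen) {
        seen <- c(seen, key)
        combos[[length(combos) + 1L]] <- cand
      }
    }
  }
  structure(list(site = site, larger_group = larger, smaller_group = smaller,
                 plot_combinations = combos,
                 n_possible = n_possible, cap = as.integer(cap), seed = seed),
            class = "standardization_plan")
}

#' @export
print.standardization_plan <- function(x, ...) {
  if (is.null(x$plot_combinations[[1L]])) {
    cat("standardization_plan for site '", x$site,
        "': balanced design, 1 identity replicate\n", sep = "")
  } else {
    cat("standardization_plan for site '", x$site, "': ",
        length(x$plot_combinations), " replicate(s) of ", x$n_possible,
        " possible (larger group: ", x$larger_group, ")\n", sep = "")
  }
  invisible(x)
}

#' Extract one standardized replicate dataset
#'
#' @param table a [community_table()].
#' @param plan a [build_standardization_plan()] result.
#' @param i replicate index.
#' @return A `community_table` holding the site's smaller group in full plus
#'   the subplots of the selected plots of the larger group (the whole site
#'   for balanced designs).
#' @export
standardized_replicate <- function(table, plan, i) {
  stopifnot(inherits(plan, "standardization_plan"))
  meta <- table$samples
  at_site <- meta$site == plan$site
  combo <- plan$plot_combinations[[i]]
  if (is.null(combo)) return(subset_samples(table, at_site))
  keep <- at_site & (meta$management == plan$smaller_group |
                       (meta$management == plan$larger_group & meta$plot %in% combo))
  subset_samples(table, keep)
}

#' Harmonic-mean combination of replicate p-values
#'
#' Unweighted harmonic mean `k / sum(1/p_i)`, used to average the p-values of
#' the standardized replicates of one test. It always lies between the
#' smallest and largest input and never exceeds the arithmetic mean.
#'
#' @param ps p-values in (0, 1].
#' @return The harmonic mean.
#' @export
combine_pvalues_harmonic <- function(ps) {
  ps <- as.numeric(ps)
  if (length(ps) == 0L) stop("no p-values to combine")
  if (anyNA(ps) || any(ps <= 0) || any(ps > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  length(ps) / sum(1 / ps)
}

#' Classify the scale dependence of a management response
#'
#' Compares the alpha-scale and gamma-scale effects of one metric at one site:
#' a significant reversal of sign across scales is a qualitative reversal;
#' significance at a single scale is scale-dependent in degree; significance
#' at both scales with a shared sign is a consistent response.
#'
#' @param effect_alpha,effect_gamma lists (or one-row data.frames) with
#'   elements `lrr` and `p_value` for the same metric at the two scales.
#' @param alpha_level significance threshold (default 0.05).
#' @return List: `category` (one of `qualitative_reversal`, `alpha_only`,
#'   `gamma_only`, `consistent_both`, `none`, `undetermined`), `lrr_alpha`,
#'   `lrr_gamma`, `p_alpha`, `p_gamma`, and `scale_independent` (`TRUE` when
#'   the two effects coincide, i.e. the point lies on the 1:1 line).
#' @export
classify_scale_dependence <- function(effect_alpha, effect_gamma, alpha_level = 0.05) {
  la <- as.numeric(effect_alpha$lrr)[1L]
  lg <- as.numeric(effect_gamma$lrr)[1L]
  pa <- as.numeric(effect_alpha$p_value)[1L]
  pg <- as.numeric(effect_gamma$p_value)[1L]
  if (anyNA(c(la, lg, pa, pg))) {
    category <- "undetermined"
  } else {
    sig_a <- pa < alpha_level
    sig_g <- pg < alpha_level
    category <- if (sig_a && sig_g && la * lg < 0) "qualitative_reversal"
    else if (sig_a && sig_g) "consistent_both"
    else if (sig_a) "alpha_only"
    else if (sig_g) "gamma_only"
    else "none"
  }
  list(category = category, lrr_alpha = la, lrr_gamma = lg,
       p_alpha = pa, p_gamma = pg,
       scale_independent = !anyNA(c(la, lg)) && isTRUE(abs(la - lg) < 1e-12))
}

#' Full management-effect analysis for one site and taxon group
#'
#' Runs the complete per-site analysis: builds the design-balancing plan,
#' and for every standardized replicate computes the rarefaction base, the
#' alpha-scale ANOVA for N, S, rarefied richness and the PIE effective
#' species number, and the gamma- and beta-scale permutation tests. Replicate
#' log-response ratios are combined by their arithmetic mean and replicate
#' p-values by their harmonic mean; each metric's alpha/gamma pair is then
#' classified for scale dependence.
#'
#' @param table a counts [community_table()] (a single taxon group).
#' @param site site label with both management types.
#' @param taxon_group label carried into the result tables.
#' @param n_perm permutations for the pooled-scale tests (default 199).
#' @param alpha_level significance threshold for classification.
#' @param cap maximum standardized replicates.
#' @param seed master seed; all replicate-level permutation seeds derive from
#'   it, so reruns are exactly reproducible.
#' @param statistic,permute passed to [gamma_scale_permutation_test()].
#' @return List with `site`, `taxon_group`, `plan`, `effects` (combined
#'   effect table: one row per metric x scale), `replicates` (per-replicate
#'   effect rows), `classification` (one row per alpha/gamma metric), and
#'   `metrics` (observed group metric values on the full, unstandardized
#'   site data).
#' @export
run_site_taxon_analysis <- function(table, site, taxon_group = "all",
                                    n_perm = 199, alpha_level = 0.05,
                                    cap = 200, seed = 1,
                                    statistic = "lrr", permute = "subplot") {
  stopifnot(inherits(table, "community_table"))
  mgmt_here <- unique(table$samples$management[table$samples$site == site])
  if (!all(c("pasture", "meadow") %in% mgmt_here)) {
    stop("site '", site, "' lacks stratum: ",
         paste(setdiff(c("pasture", "meadow"), mgmt_here), collapse = ", "))
  }
  set.seed(seed)
  plan <- build_standardization_plan(table, site, cap = cap,
                                     seed = sample.int(.Machine$integer.max, 1L))
  n_rep <- length(plan$plot_combinations)
  rep_seeds <- sample.int(.Machine$integer.max, n_rep)

  alpha_metrics_tested <- c("N", "S", "S_n", "S_PIE")
  perm_metrics <- c("N", "S", "S_n", "S_PIE", "beta_S_n", "beta_S_PIE")

  rep_rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    tab_r <- standardized_replicate(table, plan, r)
    n_base <- rarefaction_base_n(tab_r, site)
    ap <- alpha_metrics(tab_r, site, "pasture", n_base)
    am <- alpha_metrics(tab_r, site, "meadow", n_base)

    arow <- lapply(alpha_metrics_tested, function(m) {
      tst <- alpha_scale_test(ap$subplot[[m]], am$subplot[[m]])
      data.frame(replicate = r, metric = m, scale = "alpha",
                 lrr = tst$lrr, statistic = tst$statistic,
                 p_value = tst$p_value, n_perm = NA_integer_,
                 method = "anova", stringsAsFactors = FALSE)
    })
    g <- gamma_scale_permutation_test(tab_r, site, metric = perm_metrics,
                                      n_perm = n_perm, seed = rep_seeds[r],
                                      statistic = statistic, permute = permute)
    grow <- data.frame(replicate = r, metric = g$metric, scale = g$scale,
                       lrr = g$lrr, statistic = g$statistic,
                       p_value = g$p_value, n_perm = g$n_perm,
                       method = g$method, stringsAsFactors = FALSE)
    rep_rows[[r]] <- rbind(do.call(rbind, arow), grow)
  }
  replicates <- do.call(rbind, rep_rows)

  key <- unique(replicates[, c("metric", "scale")])
  effects <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- replicates[replicates$metric == key$metric[i] &
                        replicates$scale == key$scale[i], ]
    ok <- !is.na(sub$lrr) & !is.na(sub$p_value)
    if (sum(!ok) > 0L) {
      message(sum(!ok), " replicate(s) dropped for ", key$metric[i], " (",
              key$scale[i], ") at site '", site, "'")
    }
    data.frame(
      site = site, taxon_group = taxon_group,
      metric = key$metric[i], scale = key$scale[i],
      lrr = if (any(ok)) mean(sub$lrr[ok]) else NA_real_,
      statistic = if (any(ok)) mean(sub$statistic[ok]) else NA_real_,
      p_value = if (any(ok)) combine_pvalues_harmonic(sub$p_value[ok]) else NA_real_,
      n_perm = sub$n_perm[1L],
      n_replicates = sum(ok),
      method = sub$method[1L],
      stringsAsFactors = FALSE
    )
  }))

  classification <- do.call(rbind, lapply(alpha_metrics_tested, function(m) {
    ea <- effects[effects$metric == m & effects$scale == "alpha", ]
    eg <- effects[effects$metric == m & effects$scale == "gamma", ]
    cl <- classify_scale_dependence(ea, eg, alpha_level)
    data.frame(site = site, taxon_group = taxon_group, metric = m,
               category = cl$category, lrr_alpha = cl$lrr_alpha,
               lrr_gamma = cl$lrr_gamma, p_alpha = cl$p_alpha,
               p_gamma = cl$p_gamma, stringsAsFactors = FALSE)
  }))

  n_full <- rarefaction_base_n(table, site)
  metrics <- do.call(rbind, lapply(c("pasture", "meadow"), function(mg) {
    gm <- group_metrics(table, site, mg, n_full)
    rbind(
      metric_rows(site, taxon_group, mg, "alpha", gm$alpha, n_full),
      metric_rows(site, taxon_group, mg, "gamma", gm$gamma, n_full),
      data.frame(site = site, taxon_group = taxon_group, management = mg,
                 scale = "beta",
                 metric = c("beta_S", "beta_S_n", "beta_S_PIE"),
                 value = c(gm$beta$beta_S, gm$beta$beta_S_n, gm$beta$beta_S_PIE),
                 n_base = n_full, n_subplots = gm$alpha$n_subplots,
                 stringsAsFactors = FALSE)
    )
  }))

  list(site = site, taxon_group = taxon_group, plan = plan,
       effects = effects, replicates = replicates,
       classification = classification, metrics = metrics)
}

metric_rows <- function(site, taxon_group, management, scale, ms, n_base) {
  data.frame(site = site, taxon_group = taxon_group, management = management,
             scale = scale, metric = c("N", "S", "S_n", "PIE", "S_PIE"),
             value = c(ms$N, ms$S, ms$S_n, ms$PIE, ms$S_PIE),
             n_base = if (scale == "gamma") ms$n_base else n_base,
             n_subplots = ms$n_subplots, stringsAsFactors = FALSE)
}
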