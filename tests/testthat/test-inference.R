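test_that("log-response ratio follows its defining identities", {
  expect_equal(log_response_ratio(5, 5), 0)
  expect_equal(log_response_ratio(exp(1) * 3.7, 3.7), 1)
  set.seed(5)
  for (i in 1:10) {
    a <- rexp(1); b <- rexp(1)
    expect_equal(log_response_ratio(a, b), -log_response_ratio(b, a))
  }
  expect_warning(v <- log_response_ratio(0, 1), "non-positive")
  expect_true(is.na(v))
})

test_that("alpha-scale ANOVA matches the pooled-variance t-test identity", {
  vp <- c(0, 1, 2); vm <- c(10, 11, 12)
  tt <- t.test(vp, vm, var.equal = TRUE)  # independent route: F = t^2
  res <- alpha_scale_test(vp, vm)
  expect_equal(res$statistic, unname(tt$statistic)^2)
  expect_equal(res$statistic, 150)
  expect_equal(res$p_value, tt$p.value)
  expect_equal(res$p_value, pf(150, 1, 4, lower.tail = FALSE))
  expect_equal(res$lrr, log(1 / 11))

  # identical samples: no effect
  same <- alpha_scale_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$lrr, 0)

  # fully degenerate data: equal constants in both groups
  const <- alpha_scale_test(c(3, 3), c(3, 3))
  expect_equal(const$p_value, 1)
  expect_equal(const$lrr, 0)

  # the optional permutation p agrees in direction with the parametric one;
  # 3-vs-3 admits only choose(6,3) = 20 label splits and the observed one is
  # tied with its mirror, so the permutation p concentrates near 2/20
  perm <- alpha_scale_test(vp, vm, n_perm = 99, seed = 1)
  expect_gte(perm$p_permutation, 1 / 100)
  expect_lt(perm$p_permutation, 0.2)
  expect_error(alpha_scale_test(c(1), c(2, 3)), "at least 2")
})

test_that("gamma permutation test honours the add-one rule and exchangeability", {
  tab <- make_duplicate_group_table()
  res <- gamma_scale_permutation_test(tab, "dup", metric = c("N", "S", "S_n", "S_PIE"),
                                      n_perm = 199, seed = 3)
  # identical multisets of subplots: zero effect, every permutation ties
  expect_equal(res$lrr, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))

  # smallest attainable p with 199 permutations is 1/200
  toy <- make_toy_table()
  r2 <- gamma_scale_permutation_test(toy, "A", metric = "N", n_perm = 199, seed = 9)
  expect_gte(r2$p_value, 1 / 200)

  # seeded runs are exactly reproducible, and subplot order does not matter
  r3 <- gamma_scale_permutation_test(toy, "A", metric = c("S_n", "S_PIE"),
                                     n_perm = 99, seed = 11)
  r4 <- gamma_scale_permutation_test(toy, "A", metric = c("S_n", "S_PIE"),
                                     n_perm = 99, seed = 11)
  expect_identical(r3, r4)
  shuf <- subset_samples(toy, sample(nrow(toy$abundance)))
  r5 <- gamma_scale_permutation_test(shuf, "A", metric = c("S_n", "S_PIE"),
                                     n_perm = 99, seed = 11)
  expect_equal(r5$lrr, r3$lrr)

  expect_error(gamma_scale_permutation_test(toy, "Z", metric = "N"), "no samples")
})

test_that("standardization plans enumerate plot combinations without replacement", {
  make_design <- function(n_pasture, n_meadow) {
    meta <- do.call(rbind, c(
      lapply(seq_len(n_pasture), function(p) data.frame(
        sample_id = paste0("p", p, "_", 1:2), site = "X", plot = paste0("p", p),
        subplot = c("a", "b"), management = "pasture")),
      lapply(seq_len(n_meadow), function(p) data.frame(
        sample_id = paste0("m", p, "_", 1:2), site = "X", plot = paste0("m", p),
        subplot = c("a", "b"), management = "meadow"))))
    community_table(matrix(5, nrow(meta), 3), meta, taxa = c("x", "y", "z"))
  }
  # the study's unbalanced designs: 3-vs-1 plots and 4-vs-2 plots
  p31 <- build_standardization_plan(make_design(3, 1), "X")
  expect_length(p31$plot_combinations, 3L)
  p42 <- build_standardization_plan(make_design(4, 2), "X")
  expect_length(p42$plot_combinations, 6L)
  expect_equal(anyDuplicated(lapply(p42$plot_combinations, paste, collapse = "|")), 0L)
  # balanced: one identity replicate covering the whole site
  p33 <- build_standardization_plan(make_design(3, 3), "X")
  expect_length(p33$plot_combinations, 1L)
  expect_null(p33$plot_combinations[[1L]])
  tab33 <- make_design(3, 3)
  expect_identical(standardized_replicate(tab33, p33, 1)$abundance, tab33$abundance)

  # each 3-vs-1 replicate keeps the meadow in full plus one pasture plot
  tab31 <- make_design(3, 1)
  rep1 <- standardized_replicate(tab31, p31, 1)
  expect_equal(sum(rep1$samples$management == "meadow"), 2L)
  expect_equal(sum(rep1$samples$management == "pasture"), 2L)
  expect_length(unique(rep1$samples$plot[rep1$samples$management == "pasture"]), 1L)

  # a cap below the combination count draws distinct combinations
  capped <- build_standardization_plan(make_design(6, 2), "X", cap = 5, seed = 2)
  expect_length(capped$plot_combinations, 5L)
  expect_equal(capped$n_possible, choose(6, 2))
  expect_equal(anyDuplicated(lapply(capped$plot_combinations, paste, collapse = "|")), 0L)
})

test_that("harmonic-mean combination matches its formula and bounds", {
  expect_equal(combine_pvalues_harmonic(c(0.5, 0.5)), 0.5)
  expect_equal(combine_pvalues_harmonic(0.123), 0.123)
  # independent reciprocal-sum computation
  ps <- c(0.01, 1.0)
  expect_equal(combine_pvalues_harmonic(ps), 2 / (1 / 0.01 + 1 / 1))
  expect_equal(combine_pvalues_harmonic(ps), 2 / 101)
  set.seed(13)
  for (i in 1:20) {
    ps <- runif(sample(2:6, 1), min = 1e-4)
    h <- combine_pvalues_harmonic(ps)
    expect_lte(h, mean(ps))          # harmonic <= arithmetic
    expect_gte(h, min(ps))           # bounded by the inputs
    expect_lte(h, max(ps))
  }
  expect_error(combine_pvalues_harmonic(numeric(0)), "no p-values")
  expect_error(combine_pvalues_harmonic(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("scale-dependence classification covers its quadrants", {
  eff <- function(lrr, p) list(lrr = lrr, p_value = p)
  expect_equal(classify_scale_dependence(eff(0.3, 0.01), eff(-0.2, 0.02))$category,
               "qualitative_reversal")
  expect_equal(classify_scale_dependence(eff(0.3, 0.01), eff(0.1, 0.40))$category,
               "alpha_only")
  expect_equal(classify_scale_dependence(eff(0.3, 0.50), eff(0.1, 0.01))$category,
               "gamma_only")
  expect_equal(classify_scale_dependence(eff(0.3, 0.01), eff(0.1, 0.01))$category,
               "consistent_both")
  expect_equal(classify_scale_dependence(eff(0.3, 0.50), eff(0.1, 0.40))$category,
               "none")
  expect_equal(classify_scale_dependence(eff(NA, NA), eff(0.1, 0.01))$category,
               "undetermined")
  # equal effects at both scales sit on the 1:1 line
  on_line <- classify_scale_dependence(eff(0.25, 0.2), eff(0.25, 0.9))
  expect_true(on_line$scale_independent)
  off_line <- classify_scale_dependence(eff(0.25, 0.2), eff(0.24, 0.9))
  expect_false(off_line$scale_independent)
})

test_that("site analysis returns a null result on duplicate groups and errors on missing strata", {
  tab <- make_duplicate_group_table()
  res <- run_site_taxon_analysis(tab, "dup", n_perm = 49, seed = 17)
  expect_equal(res$effects$lrr, rep(0, nrow(res$effects)))
  gamma_rows <- res$effects$scale %in% c("gamma", "beta")
  expect_equal(res$effects$p_value[gamma_rows], rep(1, sum(gamma_rows)))
  expect_true(all(res$classification$category == "none"))
  expect_equal(nrow(res$effects), 10L)  # 4 metrics x 2 scales + 2 beta metrics

  one_group <- subset_samples(tab, tab$samples$management == "pasture")
  expect_error(run_site_taxon_analysis(one_group, "dup"), "stratum")
})

test_that("balanced designs make the standardized analysis equal the plain one", {
  toy <- make_toy_table()
  res <- run_site_taxon_analysis(toy, "A", n_perm = 49, seed = 23)
  expect_length(res$plan$plot_combinations, 1L)
  expect_equal(res$effects$n_replicates, rep(1L, nrow(res$effects)))
  # with a single replicate the combined values are the replicate values
  expect_equal(res$effects$lrr, res$replicates$lrr)
  expect_equal(res$effects$p_value, res$replicates$p_value)
  # reruns with the same master seed are identical
  res2 <- run_site_taxon_analysis(toy, "A", n_perm = 49, seed = 23)
  expect_identical(res$effects, res2$effects)
})
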