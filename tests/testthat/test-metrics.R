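test_that("rarefied richness matches its worked values and boundaries", {
  # one species: every subsample holds exactly it
  expect_equal(rarefied_richness(5, 3), 1.0)
  # the full sample recovers observed richness exactly
  for (v in list(c(4, 2, 1), c(10, 3), c(2, 2, 2, 2))) {
    expect_equal(rarefied_richness(v, sum(v)), sum(v > 0))
  }
  # subset-enumeration value for [4,2,1] at n = 3 is 74/35
  expect_equal(rarefy_bruteforce(c(4, 2, 1), 3), 74 / 35)
  expect_equal(rarefied_richness(c(4, 2, 1), 3), 74 / 35, tolerance = 1e-12)
  expect_error(rarefied_richness(c(4, 2, 1), 8), "exceeds")
  expect_error(rarefied_richness(c(4, 2, 1), 0), ">= 1")
})

test_that("rarefied richness agrees with vegan and is stable at read-scale totals", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:20) {
    v <- rmultinom(1, 400, prop.table(rexp(15)))[, 1]
    n <- sample(2:sum(v), 1)
    expect_equal(rarefied_richness(v, n),
                 as.numeric(suppressWarnings(vegan::rarefy(v, n))),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # log-gamma arithmetic keeps 1e7-read communities finite and ordered
  big <- c(7.2e6, 2.1e6, 6e5, 9e4, 1e4, 900, 10, 1)
  s1 <- rarefied_richness(big, 1000L)
  s2 <- rarefied_richness(big, 100000L)
  expect_true(is.finite(s1) && is.finite(s2))
  expect_true(s1 < s2 && s2 <= 8)
})

test_that("rarefied richness is nondecreasing in n", {
  set.seed(21)
  for (i in 1:20) {
    v <- rmultinom(1, 60, prop.table(rexp(8)))[, 1]
    curve <- vapply(seq_len(sum(v)), function(n) rarefied_richness(v, n), 0)
    expect_true(all(diff(curve) >= -1e-12))
    expect_equal(curve[sum(v)], sum(v > 0))
  }
})

test_that("PIE and S_PIE match the pair-enumeration oracle and worked values", {
  expect_equal(pie_enumeration(c(9, 1)), 0.2)
  expect_identical(hurlbert_pie(c(9, 1)), 0.2)
  expect_identical(hurlbert_pie(c(7)), 0)
  expect_identical(hurlbert_pie(c(10, 10)), 10 / 19)
  expect_equal(effective_species_pie(c(9, 1)), 1.25)
  expect_equal(effective_species_pie(c(7)), 1.0)
  expect_equal(effective_species_pie(c(10, 10)), 19 / 9)
  expect_warning(p <- hurlbert_pie(c(1)), "undefined")
  expect_true(is.na(p))
})

test_that("S_PIE tends to the order-2 Hill number and is monotone under novelty", {
  # multiplying all counts by k leaves sum(p^2) fixed; as k grows S_PIE
  # approaches 1 / sum(p^2)
  v <- c(5, 3, 2)
  hill2 <- 1 / sum((v / sum(v))^2)
  vals <- vapply(c(1, 10, 1000), function(k) effective_species_pie(v * k), 0)
  expect_true(all(diff(abs(vals - hill2)) < 0))
  expect_equal(vals[3], hill2, tolerance = 1e-3)
  # perfectly even community of S species: S_PIE -> S as N grows
  expect_equal(effective_species_pie(rep(1000L, 7)), 7, tolerance = 1e-2)
  # adding one individual of a brand-new species never decreases S, S_n, Hill-2
  set.seed(31)
  for (i in 1:10) {
    v <- rmultinom(1, 50, prop.table(rexp(6)))[, 1]
    v <- v[v > 0]
    w <- c(v, 1L)
    expect_gte(sum(w > 0), sum(v > 0))
    n <- min(sum(v), 10L)
    expect_gte(rarefied_richness(w, n), rarefied_richness(v, n) - 1e-12)
    expect_gte(1 / sum((w / sum(w))^2), 1 / sum((v / sum(v))^2))
  }
})

test_that("rarefaction base n is the subplot minimum across both groups", {
  meta <- data.frame(sample_id = paste0("s", 1:4), site = "X",
                     plot = rep(c("p1", "m1"), each = 2),
                     subplot = paste0("q", 1:4),
                     management = rep(c("pasture", "meadow"), each = 2))
  ab <- rbind(c(5, 2), c(8, 4), c(6, 3), c(20, 10))  # totals 7, 12, 9, 30
  ct <- community_table(ab, meta)
  expect_equal(rarefaction_base_n(ct, "X"), 7L)

  # subplots below 2 individuals are excluded with a warning
  ab2 <- rbind(c(1, 0), c(5, 3), c(6, 3), c(20, 10))
  ct2 <- community_table(ab2, meta)
  expect_warning(n2 <- rarefaction_base_n(ct2, "X"), "fewer than 2")
  expect_equal(n2, 8L)
})

test_that("alpha and gamma metrics reduce correctly in degenerate designs", {
  # two identical subplots per group: alpha means equal the subplot values
  row <- c(4, 2, 1)
  meta <- data.frame(sample_id = paste0("s", 1:4), site = "X",
                     plot = rep(c("p1", "m1"), each = 2),
                     subplot = paste0("q", 1:4),
                     management = rep(c("pasture", "meadow"), each = 2))
  ct <- community_table(rbind(row, row, row, row), meta)
  n <- rarefaction_base_n(ct, "X")
  expect_equal(n, 7L)
  a <- alpha_metrics(ct, "X", "pasture", 3L)
  expect_equal(a$S_n, 74 / 35, tolerance = 1e-12)
  expect_equal(a$S_n, a$subplot$S_n[1])
  expect_equal(a$N, 7)
  expect_equal(a$S, 3)

  g <- gamma_metrics(ct, "X", "pasture", 3L)
  expect_equal(g$n_base, 6L)
  expect_equal(g$N, 14)
  expect_equal(g$S, 3)
  expect_lte(g$S_n, g$S)  # rarefied never exceeds observed richness

  # a single-subplot group's gamma metrics equal that subplot's at n x 1
  meta1 <- meta[c(1, 3), ]
  ct1 <- community_table(rbind(row, c(9, 1, 0)), meta1)
  g1 <- gamma_metrics(ct1, "X", "meadow", 3L)
  expect_equal(g1$S_n, rarefied_richness(c(9, 1), 3))
  expect_equal(g1$S_PIE, 1.25)
})

test_that("beta partition nears 1 for identical subplots and counts disjoint monocultures", {
  # identical subplots carry no aggregation signal, but the finite-sample
  # corrections (hypergeometric rarefaction, N/(N-1) in PIE) see k times the
  # individuals in the pool, so beta sits just below 1 and converges to 1 as
  # totals grow
  row <- c(6, 3, 1)
  meta <- data.frame(sample_id = paste0("s", 1:3), site = "X", plot = "p1",
                     subplot = paste0("q", 1:3), management = "pasture")
  ct <- community_table(rbind(row, row, row), meta)
  gm <- group_metrics(ct, "X", "pasture", 5L)
  expect_true(gm$beta$beta_S_n <= 1 && gm$beta$beta_S_n > 0.9)
  expect_true(gm$beta$beta_S_PIE <= 1 && gm$beta$beta_S_PIE > 0.9)
  expect_equal(gm$beta$beta_S, 1)

  big <- community_table(rbind(row, row, row) * 200L, meta)
  gm_big <- group_metrics(big, "X", "pasture", 5L)
  expect_equal(gm_big$beta$beta_S_n, 1, tolerance = 1e-3)
  expect_equal(gm_big$beta$beta_S_PIE, 1, tolerance = 1e-3)
  expect_true(abs(gm_big$beta$beta_S_n - 1) < abs(gm$beta$beta_S_n - 1))

  # two disjoint monocultures of equal size: beta_S = 2
  meta2 <- meta[1:2, ]
  ct2 <- community_table(rbind(c(8, 0, 0), c(0, 8, 0)), meta2)
  gm2 <- group_metrics(ct2, "X", "pasture", 4L)
  expect_equal(gm2$beta$beta_S, 2)

  # k disjoint monocultures of m individuals: pooled S_n at k*m equals k
  k <- 3L; m <- 5L
  meta3 <- data.frame(sample_id = paste0("s", 1:k), site = "X", plot = "p1",
                      subplot = paste0("q", 1:k), management = "pasture")
  ab3 <- diag(m, k)
  ct3 <- community_table(ab3, meta3)
  g3 <- gamma_metrics(ct3, "X", "pasture", m)
  expect_equal(g3$S_n, k)
})

test_that("multinomially split common pools have beta_S_n near 1", {
  # individuals assigned to subplots at random from one shared pool: no
  # aggregation, so the rarefied beta should approach 1
  set.seed(41)
  p <- prop.table(rexp(20))
  reps <- 1000L
  vals <- numeric(reps)
  n_sub <- 5L
  for (r in seq_len(reps)) {
    mat <- t(rmultinom(n_sub, 200, p))
    meta <- data.frame(sample_id = paste0("s", 1:n_sub), site = "X", plot = "p1",
                       subplot = paste0("q", 1:n_sub), management = "pasture")
    ct <- community_table(mat, meta)
    n <- min(rowSums(mat))
    gm <- group_metrics(ct, "X", "pasture", n)
    vals[r] <- gm$beta$beta_S_n
  }
  expect_equal(mean(vals), 1, tolerance = 0.02)
})
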