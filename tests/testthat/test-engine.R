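test_that("utility mapping is anchored at 0.05 and saturates at the extremes", {
  expect_equal(utility(0.05), 0)
  expect_equal(utility(1e-6), 1)
  expect_equal(utility(1e-9), 1)   # saturated below 1e-6
  expect_equal(utility(1), -1)
  expect_equal(utility(0.05, "unfavourable"), 0)
  # applicability direction is penalty-only: violated assumptions cost,
  # passed checks earn nothing
  expect_equal(utility(1, "unfavourable"), 0)
  expect_lt(utility(0.001, "unfavourable"), 0)
  expect_equal(utility(1e-6, "unfavourable"), -1)
  # monotone decreasing in alpha (favourable), non-decreasing (unfavourable)
  a <- 10^seq(-9, 0, length.out = 50)
  expect_true(all(diff(utility(a)) <= 1e-12))
  expect_true(all(diff(utility(a, "unfavourable")) >= -1e-12))
  expect_true(all(utility(a) >= -1 & utility(a) <= 1))
  expect_error(utility(0), "alpha")
  expect_error(utility(1.5), "alpha")
})

test_that("the seven subsets follow the half-split rules", {
  set.seed(71)
  x <- rnorm(12); f <- rnorm(12)
  s <- make_subsets(x, f)
  expect_named(s, c("all", "low_f", "high_f", "mid_f", "low_x", "high_x", "mid_x"))
  expect_equal(lengths(s), c(all = 12L, low_f = 6L, high_f = 6L, mid_f = 6L,
                             low_x = 6L, high_x = 6L, mid_x = 6L))
  expect_equal(s$low_f, sort(order(f)[1:6]))
  expect_equal(s$high_x, sort(order(-x)[1:6]))
  expect_equal(s$mid_x, sort(order(abs(x - mean(x)))[1:6]))
  # distinct feature values, even n: low and high halves cover everything
  expect_setequal(c(s$low_f, s$high_f), 1:12)
  # odd n takes ceiling(n/2)
  expect_equal(lengths(make_subsets(rnorm(17), rnorm(17)))[["low_f"]], 9L)
  expect_error(make_subsets(rnorm(5), rnorm(5)), "at least 6")
})

test_that("xi is the exact mean of the 77 utilities, bounded in [-1, 1]", {
  t2 <- load_table2()
  xb <- xi_score(t2, t2$extra$rhhk_f3)
  expect_equal(dim(xb$alphas), c(7L, 11L))
  expect_equal(dim(xb$utilities), c(7L, 11L))
  expect_equal(xb$xi, mean(xb$utilities), tolerance = 1e-12)
  expect_gte(xb$xi, -1); expect_lte(xb$xi, 1)
  # utilities recompute from alphas with the direction split
  for (k in 1:7) {
    expect_equal(unname(xb$utilities[k, 1:5]),
                 unname(utility(xb$alphas[k, 1:5], "favourable")))
    expect_equal(unname(xb$utilities[k, 6:11]),
                 unname(utility(xb$alphas[k, 6:11], "unfavourable")))
  }
  # constant feature convention
  expect_equal(xi_score(t2, rep(2, 12))$xi, -1)
})

test_that("a strong planted linear signal earns a positive xi", {
  sim <- planted_sim(seed = 101, noise_to_signal = 0.1)
  expect_gt(xi_score(sim$dataset, sim$truth$feature)$xi, 0)
})

test_that("staged search equals exhaustive search on small variant spaces", {
  sim <- planted_sim(seed = 55)
  tetras <- restricted_tetras(5, "RHHK", seed = 56)
  lib <- builtin_profiles(22)
  n_var <- length(tetras) * ncol(lib$values)
  expect_lte(n_var, 2000)
  staged <- search_features(sim$dataset, tetras, lib, screen_top_k = 40)
  exhaustive <- search_features(sim$dataset, tetras, lib, screen_top_k = n_var)
  expect_equal(staged$best$tetra, exhaustive$best$tetra)
  expect_equal(staged$best$profile_id, exhaustive$best$profile_id)
  expect_equal(staged$best$xi, exhaustive$best$xi, tolerance = 1e-12)
  expect_equal(exhaustive$n_variants, n_var)
})

test_that("search is deterministic and ranks by xi with the documented tie-break", {
  sim <- planted_sim(seed = 77)
  tetras <- restricted_tetras(10, "RHHK", seed = 78)
  a <- search_features(sim$dataset, tetras, screen_top_k = 30)
  b <- search_features(sim$dataset, tetras, screen_top_k = 30)
  expect_identical(a$ranked, b$ranked)
  expect_true(all(diff(a$ranked$xi) <= 1e-12))
})

test_that("search recovers a planted tetranucleotide signal", {
  seeds <- 1:8
  hits <- vapply(seeds, function(s) {
    sim <- planted_sim(seed = s, noise_to_signal = 0.2)
    tetras <- restricted_tetras(60, "RHHK", seed = 1000 + s)
    res <- search_features(sim$dataset, tetras, screen_top_k = 15)
    if (!res$useful) return(FALSE)
    if (res$best$tetra == "RHHK") return(TRUE)
    abs(cor(res$best$feature, sim$truth$feature)) >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("permutation verification uses the lower binomial tail", {
  sim <- planted_sim(seed = 91, noise_to_signal = 0.1)
  tetras <- restricted_tetras(12, "RHHK", seed = 92)
  res <- search_features(sim$dataset, tetras, screen_top_k = 8)
  expect_true(res$useful)
  pv <- permutation_verify(sim$dataset, res, tetras = tetras,
                           screen_top_k = 8, cycles = 60, seed = 9)
  expect_equal(pv$alpha, pbinom(pv$recurrences, 60, 0.05))
  expect_equal(pv$verified, pv$alpha < 0.05)
  # closed-form anchors for the alpha rule
  expect_equal(pbinom(0, 100, 0.05), 0.95^100)
  expect_lt(pbinom(0, 100, 0.05), 0.05)    # absence in 100 cycles is significant
  expect_equal(pbinom(0, 1, 0.05), 0.95)   # a single cycle proves nothing
  # a strong planted signal should rarely recur under permutation
  expect_lte(pv$recurrences, 2)
})

test_that("null data rarely yields a verified feature", {
  lib <- builtin_profiles(22)
  seeds <- 1:12
  verified <- vapply(seeds, function(s) {
    prof <- u_profile(0.5, 0.2, "peak", 0, 19)
    sim <- synthetic_dataset(16, 22, "RHHK", prof, slope = 0, noise_sd = 1,
                             seed = 3000 + s)
    tetras <- restricted_tetras(12, "RHHK", seed = 4000 + s)
    res <- search_features(sim$dataset, tetras, lib, screen_top_k = 5)
    if (!res$useful) return(FALSE)
    pv <- permutation_verify(sim$dataset, res, tetras = tetras, profiles = lib,
                             screen_top_k = 5, cycles = 60, seed = 5000 + s)
    pv$verified
  }, logical(1))
  # 5% + 3 s.e. at 12 runs allows at most 3 verified nulls
  expect_lte(mean(verified), 0.05 + 3 * sqrt(0.05 * 0.95 / length(seeds)))
})
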