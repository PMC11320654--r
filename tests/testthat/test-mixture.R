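# Boltzmann populations, simplex grids, mixture averaging and the mixture
# DP4+ scan.

test_that("Boltzmann weights obey the closed forms and invariances", {
  expect_equal(unname(boltzmann_weights(c(5, 5, 5))), rep(1 / 3, 3))
  RT <- 8.314462618e-3 * 298.15
  w <- boltzmann_weights(c(0, RT * log(2)))
  expect_equal(unname(w), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # uniform shift invariance, monotone decreasing in own energy
  e <- c(0, 3.7, 9.1, 12.4)
  expect_equal(boltzmann_weights(e + 100), boltzmann_weights(e))
  expect_true(all(diff(boltzmann_weights(e)) < 0))
  expect_error(boltzmann_weights(c(1, NA)), "non-finite")
  expect_error(boltzmann_weights(c(1, 2), temperature = 0), "positive")
})

test_that("simplex grids enumerate exactly the stars-and-bars count", {
  g <- simplex_grid(2, 0.5)
  expect_equal(unname(g), rbind(c(1, 0), c(0.5, 0.5), c(0, 1)))
  for (k in 1:5) for (step in c(0.5, 0.25, 0.2, 0.1)) {
    g <- simplex_grid(k, step)
    n <- round(1 / step)
    expect_equal(nrow(g), choose(n + k - 1, k - 1))
    expect_equal(unname(rowSums(g)), rep(1, nrow(g)))
    expect_true(all(g >= 0 & g <= 1))
    expect_false(any(duplicated(g)))
    # vertices present
    expect_true(all(apply(diag(k), 1L, function(v)
      any(apply(g, 1L, function(row) all(row == v))))))
  }
  expect_equal(nrow(simplex_grid(3, 0.1)), 66L)
  expect_equal(nrow(simplex_grid(4, 0.1)), 286L)
  expect_error(simplex_grid(3, 0.3), "positive integer")
})

test_that("mixture averaging is the population-weighted mean", {
  v <- cbind(a = c(10, 1), b = c(20, 3))
  expect_equal(mixture_shifts(v, c(1, 0)), c(10, 1))
  expect_equal(mixture_shifts(v, c(0.5, 0.5)), c(15, 2))
  same <- cbind(c(7, 8), c(7, 8))
  expect_equal(mixture_shifts(same, c(0.3, 0.7)), c(7, 8))
  expect_error(mixture_shifts(v, c(0.7, 0.7)), "sum to 1")
})

test_that("the mixture scan normalises and reduces to pure conformers at
           step 1", {
  study <- generate_study(seed = 5, n_conformers = 3, n_sites_h = 12,
                          n_sites_c = 12, ground_truth = c(0.6, 0.3, 0.1))
  fit <- mixture_fit(study$ensemble, study$shift_table, study$params,
                     step = 0.1)
  expect_equal(sum(fit$prob[, "combined"]), 1, tolerance = 1e-9)
  expect_equal(nrow(fit$grid), 66L)

  vert <- mixture_fit(study$ensemble, study$shift_table, study$params,
                      step = 1)
  pure <- dp4_fit(study$ensemble, study$shift_table, study$params)
  expect_equal(unname(vert$prob[, "combined"]),
               unname(pure$prob[, "combined"]), tolerance = 1e-12)
})

test_that("a noise-free study generated on a grid point is recovered
           exactly", {
  study <- generate_study(seed = 9, n_conformers = 4,
                          ground_truth = c(0.5, 0.3, 0.1, 0.1),
                          noise = list(H1 = c(sigma = 1e-9, nu = 10),
                                       C13 = c(sigma = 1e-9, nu = 10)))
  fit <- mixture_fit(study$ensemble, study$shift_table, study$params,
                     step = 0.1)
  expect_equal(unname(coef(fit)), study$ground_truth)
})

test_that("permuting the representatives permutes the result coherently", {
  study <- generate_study(seed = 13, n_conformers = 3, n_sites_h = 10,
                          n_sites_c = 10, ground_truth = c(0.5, 0.4, 0.1))
  fit <- mixture_fit(study$ensemble, study$shift_table, study$params)
  perm <- c(3, 1, 2)
  fit_p <- mixture_fit(study$ensemble[perm], study$shift_table,
                       study$params)
  expect_equal(max(fit_p$prob[, "combined"]), max(fit$prob[, "combined"]),
               tolerance = 1e-12)
  expect_equal(sort(unname(coef(fit_p))), sort(unname(coef(fit))))
  # fraction of original representative i sits at position match(i, perm)
  expect_equal(unname(coef(fit_p))[match(seq_along(perm), perm)],
               unname(coef(fit)), tolerance = 1e-12)
})

test_that("the error scan agrees with single-conformer statistics at the
           vertices", {
  study <- generate_study(seed = 21, n_conformers = 3, n_sites_h = 10,
                          n_sites_c = 10, ground_truth = c(0.7, 0.2, 0.1))
  scan <- mixture_error_scan(study$ensemble, study$shift_table,
                             study$params, step = 0.5)
  pure <- dp4_fit(study$ensemble, study$shift_table, study$params)
  es <- error_summary(pure)
  for (k in 1:3) {
    vrow <- which(apply(scan[, 1:3], 1L, function(r)
      all(r == diag(3)[k, ])))
    expect_equal(scan$cmae_H1[vrow],
                 es$cmae[es$candidate == study$ensemble[[k]]$id &
                           es$nucleus == "H1"], tolerance = 1e-12)
    expect_equal(scan$cmaxerr_C13[vrow],
                 es$cmaxerr[es$candidate == study$ensemble[[k]]$id &
                              es$nucleus == "C13"], tolerance = 1e-12)
  }

  # identical representatives give a flat error surface
  twins <- list(study$ensemble[[1]], study$ensemble[[1]])
  twins[[2]]$id <- "twin"
  scan2 <- mixture_error_scan(twins, study$shift_table, study$params,
                              step = 0.25)
  expect_equal(diff(range(scan2$cmae_H1)), 0, tolerance = 1e-12)
  expect_equal(diff(range(scan2$cmae_C13)), 0, tolerance = 1e-12)
})

test_that("ternary aggregation conserves probability and collapses the
           grid", {
  study <- generate_study(seed = 17, n_conformers = 4, n_sites_h = 8,
                          n_sites_c = 8,
                          ground_truth = c(0.4, 0.3, 0.2, 0.1))
  fit <- mixture_fit(study$ensemble, study$shift_table, study$params,
                     step = 0.1)
  tg <- aggregate_ternary(fit, groups = list(1L, 2L, 3:4))
  expect_equal(sum(tg$probability), 1, tolerance = 1e-9)
  expect_equal(nrow(tg), 66L)  # stars-and-bars for k = 3, step 0.1
  expect_equal(rowSums(tg[, c("a", "b", "c")]), rep(1, nrow(tg)),
               tolerance = 1e-9, ignore_attr = TRUE)

  study3 <- generate_study(seed = 18, n_conformers = 3, n_sites_h = 8,
                           n_sites_c = 8, ground_truth = c(0.5, 0.3, 0.2))
  fit3 <- mixture_fit(study3$ensemble, study3$shift_table, study3$params,
                      step = 0.1)
  tg3 <- aggregate_ternary(fit3, groups = list(1L, 2L, 3L))
  expect_equal(nrow(tg3), nrow(fit3$grid))
  ord <- order(-fit3$grid[, 1], -fit3$grid[, 2])
  expect_equal(tg3$probability, unname(fit3$prob[ord, "combined"]),
               tolerance = 1e-12)

  expect_error(aggregate_ternary(fit, groups = list(1L, 2L, 3L)),
               "exactly once")
})

test_that("band probabilities are sums over the selected compositions", {
  study <- generate_study(seed = 25, n_conformers = 3, n_sites_h = 6,
                          n_sites_c = 6, ground_truth = c(0.6, 0.3, 0.1))
  fit <- mixture_fit(study$ensemble, study$shift_table, study$params)
  expect_equal(band_probability(fit, function(x) TRUE), 1,
               tolerance = 1e-9)
  expect_equal(band_probability(fit, function(x) FALSE), 0)
  half <- band_probability(fit, function(x) x[1] >= 0.5)
  other <- band_probability(fit, function(x) x[1] < 0.5)
  expect_equal(half + other, 1, tolerance = 1e-9)
})
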