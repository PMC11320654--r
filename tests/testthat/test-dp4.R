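# Shift referencing, scaling, error statistics and DP4+ probabilities.

test_that("site shifts average equivalent atoms against the reference", {
  p <- toy_params(ref_h = 31.8)
  cf <- toy_conformer("c1", c(31.8, 30, 31, 32), rep("H", 4))
  tab_ref <- toy_table(0, "H1", atom_indices = list(1L))
  expect_equal(candidate_site_shifts(cf, tab_ref, p), 0)
  tab_me <- toy_table(1.0, "H1", atom_indices = list(c(2L, 3L, 4L)))
  expect_equal(candidate_site_shifts(cf, tab_me, p), 0.8)
  tab_bad <- toy_table(1.0, "H1", atom_indices = list(99L))
  expect_error(candidate_site_shifts(cf, tab_bad, p), "s1")
})

test_that("scaling is exact on affine data and matches the closed form", {
  d_exp <- c(1.2, 3.4, 5.1, 6.6, 7.9)
  fit <- fit_scaling(d_exp, d_exp)
  expect_equal(fit$m, 1)
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_equal(fit$scaled, d_exp)

  d_calc <- 1.05 * d_exp + 2.0
  fit2 <- fit_scaling(d_calc, d_exp)
  expect_equal(fit2$scaled, d_exp, tolerance = 1e-12)

  set.seed(101)
  for (r in 1:5) {
    x <- rnorm(5, 100, 30)
    y <- 0.97 * x - 3 + rnorm(5, sd = 2)
    fit3 <- fit_scaling(y, x)
    co <- ols_oracle(x, y)
    expect_equal(fit3$m, co[["m"]], tolerance = 1e-10)
    expect_equal(fit3$b, co[["b"]], tolerance = 1e-10)
  }

  expect_error(fit_scaling(1, 1), "at least 2 sites")
  expect_error(fit_scaling(c(1, 2), c(5, 5)), "unscaled channel")
})

test_that("cmae and cmaxerr are the mean and max absolute deviations", {
  expect_equal(cmae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cmaxerr(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cmae(c(1, -3), c(0, 0)), 2)
  expect_equal(cmaxerr(c(1, -3), c(0, 0)), 3)
  expect_error(cmae(numeric(0), numeric(0)), "empty")
  expect_error(cmaxerr(numeric(0), numeric(0)), "empty")
  set.seed(7)
  for (r in 1:20) {
    a <- rnorm(sample(1:30, 1))
    b <- rnorm(length(a))
    expect_lte(cmae(a, b), cmaxerr(a, b))
  }
})

test_that("the t error density has the right closed forms and limits", {
  expect_equal(t_density(0.7, 0.2, 1.3, 5), t_density(-0.3, 0.2, 1.3, 5))
  expect_equal(t_density(0, 0, 1, 1), 1 / pi)
  for (e in c(0, 1, 2))
    expect_equal(t_density(e, 0, 1, 1e6), dnorm(e), tolerance = 1e-4)
  expect_error(t_density(0, 0, -1, 5), "sigma")
  expect_error(t_density(0, 0, 1, 0), "nu")
})

make_candidates <- function(n_cand, n_sites = 8L, seed = 1) {
  set.seed(seed)
  nucleus <- rep(c("H1", "C13"), length.out = n_sites)
  d_exp <- ifelse(nucleus == "H1", runif(n_sites, 1, 8),
                  runif(n_sites, 20, 150))
  tab <- toy_table(d_exp, nucleus)
  cands <- lapply(seq_len(n_cand), function(k)
    d_exp + rnorm(n_sites, sd = ifelse(nucleus == "H1", 0.15, 1.5)))
  names(cands) <- paste0("cand-", seq_len(n_cand))
  list(tab = tab, cands = cands)
}

test_that("probabilities normalise, and duplicates split mass in half", {
  p <- toy_params()
  mc <- make_candidates(4)
  fit <- dp4_fit(mc$cands, mc$tab, p)
  for (ch in colnames(fit$prob)) {
    expect_equal(sum(fit$prob[, ch]), 1, tolerance = 1e-9)
    expect_true(all(fit$prob[, ch] >= 0))
  }

  dup <- c(mc$cands, list(`cand-1bis` = mc$cands[[1]]))
  fit2 <- dp4_fit(dup, mc$tab, p)
  expect_equal(fit2$prob["cand-1bis", "combined"],
               fit2$prob["cand-1", "combined"], tolerance = 1e-12)
  pair_mass <- fit2$prob["cand-1", "combined"] +
    fit2$prob["cand-1bis", "combined"]
  expect_equal(fit2$prob["cand-1", "combined"], pair_mass / 2)
  # ratios among the other candidates are untouched
  r_before <- fit$prob[2:4, "combined"] / fit$prob[2, "combined"]
  r_after <- fit2$prob[2:4, "combined"] / fit2$prob[2, "combined"]
  expect_equal(r_after, r_before, tolerance = 1e-12)
})

test_that("degenerate candidate sets behave as announced", {
  p <- toy_params()
  mc <- make_candidates(2)
  expect_message(fit1 <- dp4_fit(mc$cands[1], mc$tab, p),
                 "single candidate")
  expect_equal(unname(fit1$prob[1, "combined"]), 1)

  twins <- list(a = mc$cands[[1]], b = mc$cands[[1]])
  fit2 <- dp4_fit(twins, mc$tab, p)
  expect_equal(unname(fit2$prob[, "combined"]), c(0.5, 0.5))
  for (ch in colnames(fit2$prob))
    expect_equal(unname(fit2$prob[, ch]), c(0.5, 0.5))
})

test_that("log-space scoring reproduces direct products on small inputs", {
  p <- toy_params(sigma_h = 0.2, sigma_c = 2, nu = 8)
  set.seed(33)
  d_exp <- runif(5, 1, 8)
  tab <- toy_table(d_exp, rep("H1", 5))
  cands <- lapply(1:3, function(k) d_exp + rnorm(5, sd = 0.2))
  names(cands) <- paste0("c", 1:3)
  fit <- dp4_fit(cands, tab, p, channels = "H1", kinds = "unscaled")
  oracle <- direct_dp4_oracle(cands, d_exp, 0, 0.2, 8)
  expect_equal(unname(fit$prob[, "combined"]), unname(oracle),
               tolerance = 1e-10)
  fit_s <- dp4_fit(cands, tab, p, channels = "H1", kinds = "scaled")
  oracle_s <- direct_dp4_oracle(cands, d_exp, 0, 0.2, 8, scaled = TRUE)
  expect_equal(unname(fit_s$prob[, "combined"]), unname(oracle_s),
               tolerance = 1e-10)
})

test_that("an affine distortion of all candidates leaves scaled channels
           unchanged", {
  p <- toy_params()
  mc <- make_candidates(3, n_sites = 10)
  fit <- dp4_fit(mc$cands, mc$tab, p)
  warped <- lapply(mc$cands, function(d) 1.07 * d - 2.5)
  fit_w <- dp4_fit(warped, mc$tab, p)
  expect_equal(fit_w$prob[, "scaled"], fit$prob[, "scaled"],
               tolerance = 1e-9)
  # error statistics ride on scaled shifts, so they are also invariant
  expect_equal(fit_w$errors$cmae, fit$errors$cmae, tolerance = 1e-9)
  expect_equal(fit_w$errors$cmaxerr, fit$errors$cmaxerr, tolerance = 1e-9)
})

test_that("sites without an experimental shift are dropped symmetrically", {
  p <- toy_params()
  mc <- make_candidates(3, n_sites = 10)
  tab_na <- mc$tab
  tab_na$delta_exp[c(2, 9)] <- NA
  expect_message(fit_na <- dp4_fit(mc$cands, tab_na, p), "dropping 2")
  tab_cut <- mc$tab[-c(2, 9), ]
  class(tab_cut) <- c("shift_table", "data.frame")
  cands_cut <- lapply(mc$cands, function(d) d[-c(2, 9)])
  fit_cut <- dp4_fit(cands_cut, tab_cut, p)
  expect_equal(fit_na$prob, fit_cut$prob)
})

test_that("accessors expose probabilities, errors and residuals", {
  p <- toy_params()
  mc <- make_candidates(3)
  fit <- dp4_fit(mc$cands, mc$tab, p)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  es <- error_summary(fit)
  expect_setequal(es$nucleus, c("H1", "C13"))
  expect_true(all(es$cmae <= es$cmaxerr))
  res <- residuals(fit, candidate = "cand-2", kind = "unscaled")
  expect_equal(unname(res), unname(mc$cands[[2]] - mc$tab$delta_exp))
  s <- summary(fit)
  expect_true(all(s$top %in% fit$ids))
})
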