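# The synthetic-study generator and the recovery experiment.

test_that("studies regenerate bit-identically from the same seed", {
  s1 <- generate_study(seed = 77)
  s2 <- generate_study(seed = 77)
  expect_identical(s1$shift_table$delta_exp, s2$shift_table$delta_exp)
  expect_identical(s1$ensemble[[2]]$shieldings,
                   s2$ensemble[[2]]$shieldings)
  expect_identical(s1$ensemble[[3]]$coords, s2$ensemble[[3]]$coords)
  expect_identical(s1$coupling_table$j_exp, s2$coupling_table$j_exp)
  s3 <- generate_study(seed = 78)
  expect_false(identical(s1$shift_table$delta_exp,
                         s3$shift_table$delta_exp))
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_study(seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("a noise-free vertex-truth study is won by the true conformer", {
  study <- generate_study(seed = 55, n_conformers = 3,
                          ground_truth = c(0, 1, 0),
                          noise = list(H1 = c(sigma = 1e-9, nu = 10),
                                       C13 = c(sigma = 1e-9, nu = 10)))
  fit <- dp4_fit(study$ensemble, study$shift_table, study$params)
  expect_equal(unname(fit$prob["conf-2", "combined"]), 1,
               tolerance = 1e-9)
})

test_that("energies reproduce the intended Boltzmann ordering", {
  study <- generate_study(seed = 61, ground_truth = c(0.5, 0.3, 0.1, 0.1))
  w <- boltzmann_weights(study$ensemble, temperature = study$temperature)
  expect_equal(order(-w)[1:2], 1:2)
  expect_equal(unname(w), (c(0.5, 0.3, 0.1, 0.1) + 0.01) / 1.04,
               tolerance = 1e-9)
})

test_that("written studies read back into an equivalent pipeline input", {
  study <- generate_study(seed = 71, n_conformers = 3, n_sites_h = 6,
                          n_sites_c = 6, ground_truth = c(0.5, 0.3, 0.2))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("ensemble.xyz", "shifts.csv", "shieldings.csv", "couplings.csv",
      "dp4_params.yaml", "ground_truth.json")))))
  ens <- read_xyz_ensemble(file.path(dir, "ensemble.xyz"))
  ens <- attach_shieldings_csv(ens, file.path(dir, "shieldings.csv"))
  tab <- read_shift_table(file.path(dir, "shifts.csv"))
  prm <- read_dp4_params(file.path(dir, "dp4_params.yaml"))
  fit_disk <- mixture_fit(ens, tab, prm, step = 0.1)
  fit_mem <- mixture_fit(study$ensemble, study$shift_table, study$params,
                         step = 0.1)
  expect_equal(coef(fit_disk), coef(fit_mem))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$ground_truth, study$ground_truth)
})

test_that("recovery is perfect without noise and degrades to chance when
           noise swamps the spread", {
  perfect <- recovery_experiment(
    3, seed = 5, noise = list(H1 = c(sigma = 1e-9, nu = 10),
                              C13 = c(sigma = 1e-9, nu = 10)))
  expect_equal(perfect$recovery_rate, 1)
  expect_equal(perfect$mean_abs_error, 0)

  swamped <- recovery_experiment(
    10, seed = 5, noise = list(H1 = c(sigma = 3, nu = 10),
                               C13 = c(sigma = 30, nu = 10)))
  expect_true(swamped$degenerate)
  expect_output(print(swamped), "near chance")
})

test_that("recovery does not improve as noise grows", {
  rates <- vapply(c(0.5, 2, 6), function(mult) {
    recovery_experiment(
      50, seed = 31,
      noise = list(H1 = c(sigma = 0.10 * mult, nu = 10),
                   C13 = c(sigma = 1.5 * mult, nu = 10)))$recovery_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("the mixture argmax matches a brute-force re-scoring oracle", {
  for (r in 1:5) {
    study <- generate_study(seed = 200 + r, n_conformers = 3,
                            n_sites_h = 10, n_sites_c = 10,
                            ground_truth = c(0.5, 0.3, 0.2))
    fit <- mixture_fit(study$ensemble, study$shift_table, study$params,
                       step = 0.1)
    # oracle: per composition, average shieldings, reference, scale via the
    # normal equations, direct product of t densities
    tab <- study$shift_table
    shield <- vapply(study$ensemble, function(cf)
      cf$shieldings[unlist(tab$atom_indices)], numeric(nrow(tab)))
    refs <- ifelse(tab$nucleus == "H1", 31.8, 186.5)
    grid <- simplex_grid(3, 0.1)
    lik <- apply(grid, 1L, function(x) {
      calc <- refs - drop(shield %*% x)
      total <- 1
      for (nuc in c("H1", "C13")) {
        sel <- tab$nucleus == nuc
        pars <- study$params[[nuc]]$scaled
        co <- ols_oracle(tab$delta_exp[sel], calc[sel])
        scaled <- (calc[sel] - co[["b"]]) / co[["m"]]
        for (kind_err in list(scaled - tab$delta_exp[sel],
                              calc[sel] - tab$delta_exp[sel]))
          total <- total * prod(dt(kind_err / pars[["sigma"]],
                                   df = pars[["nu"]]) / pars[["sigma"]])
      }
      total
    })
    expect_equal(unname(grid[which.max(lik), ]), unname(coef(fit)))
    expect_equal(unname(fit$prob[, "combined"]), lik / sum(lik),
                 tolerance = 1e-8)
  }
})

test_that("scaling shields recovery from systematic slope/offset bias", {
  study <- generate_study(seed = 91, n_conformers = 3,
                          ground_truth = c(0.6, 0.3, 0.1),
                          slope_bias = c(m = 1.06, b = -3.5),
                          noise = list(H1 = c(sigma = 1e-9, nu = 10),
                                       C13 = c(sigma = 1e-9, nu = 10)))
  scaled_fit <- mixture_fit(study$ensemble, study$shift_table,
                            study$params, kinds = "scaled")
  expect_equal(unname(coef(scaled_fit)), study$ground_truth)
  unscaled_fit <- mixture_fit(study$ensemble, study$shift_table,
                              study$params, kinds = "unscaled")
  # under the bias the unscaled likelihood at the truth collapses
  truth_row <- which(apply(unscaled_fit$grid, 1L, function(x)
    all(x == study$ground_truth)))
  expect_lt(max(unscaled_fit$loglik[truth_row, ]),
            min(scaled_fit$loglik[truth_row, ]))
})
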