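# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately avoid the code paths they check: least squares via
# raw normal equations, superposition RMSD via a rotation-grid search,
# likelihoods via direct products of densities.

toy_params <- function(sigma_h = 0.2, sigma_c = 2, nu = 10,
                       ref_h = 31.8, ref_c = 186.5, mu = 0) {
  dp4_params(
    H1 = list(scaled = c(mu = mu, sigma = sigma_h, nu = nu),
              unscaled = c(mu = mu, sigma = sigma_h, nu = nu),
              sigma_ref = ref_h),
    C13 = list(scaled = c(mu = mu, sigma = sigma_c, nu = nu),
               unscaled = c(mu = mu, sigma = sigma_c, nu = nu),
               sigma_ref = ref_c))
}

# conformer with one H/C atom per site and prescribed per-site shieldings
toy_conformer <- function(id, shieldings, elements,
                          coords = NULL, energy = NULL) {
  n <- length(elements)
  if (is.null(coords)) coords <- matrix(seq_len(3 * n) / 7, n, 3)
  conformer_record(id, elements, coords, energy = energy,
                   shieldings = shieldings, energy_unit = "kJ/mol")
}

toy_table <- function(delta_exp, nucleus, atom_indices = NULL) {
  n <- length(delta_exp)
  if (is.null(atom_indices)) atom_indices <- as.list(seq_len(n))
  shift_table(site_label = paste0("s", seq_len(n)), nucleus = nucleus,
              delta_exp = delta_exp, atom_indices = atom_indices)
}

# closed-form ordinary least squares (sum-based normal equations)
ols_oracle <- function(x, y) {
  n <- length(x)
  m <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- (sum(y) - m * sum(x)) / n
  c(m = m, b = b)
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0),
                           c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)),
                           c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# superposition RMSD by iteratively refined grid search over z-y-z Euler
# angles; independent of the SVD route
brute_rmsd_oracle <- function(P, Q, rounds = 5L, steps = 13L) {
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  centre <- c(0, pi / 2, 0)
  width <- c(pi, pi / 2, pi)
  best <- Inf
  for (r in seq_len(rounds)) {
    aa <- seq(centre[1] - width[1], centre[1] + width[1], length.out = steps)
    bb <- seq(max(0, centre[2] - width[2]),
              min(pi, centre[2] + width[2]), length.out = steps)
    cc <- seq(centre[3] - width[3], centre[3] + width[3], length.out = steps)
    for (a in aa) for (b in bb) for (ct in cc) {
      Rm <- rot_z(a) %*% rot_y(b) %*% rot_z(ct)
      v <- mean(rowSums((P %*% t(Rm) - Q)^2))
      if (v < best) { best <- v; centre <- c(a, b, ct) }
    }
    width <- width / 4
  }
  sqrt(best)
}

# direct-product DP4+ probabilities on small inputs (no log space)
direct_dp4_oracle <- function(calc_list, delta_exp, mu, sigma, nu,
                              scaled = FALSE) {
  lik <- vapply(calc_list, function(dc) {
    if (scaled) {
      co <- ols_oracle(delta_exp, dc)
      dc <- (dc - co[["b"]]) / co[["m"]]
    }
    prod(stats::dt((dc - delta_exp - mu) / sigma, df = nu) / sigma)
  }, numeric(1))
  lik / sum(lik)
}

# random rigid motion applied to a conformer's coordinates
rigid_move <- function(conformer, axis, angle, shift) {
  conformer$coords <- sweep(conformer$coords %*% t(rot_axis(axis, angle)),
                            2L, -shift)
  conformer
}
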