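test_that("vibronic weights are the Franck-Condon Poisson factors", {
  # no coupling: all weight in the elastic channel
  w0 <- vibronic_weights(0, 5)
  expect_equal(w0, c(1, 0, 0, 0, 0, 0))
  w <- vibronic_weights(0.1, 3)
  expect_equal(w[1], exp(-0.1))
  expect_equal(w[2], 0.1 * exp(-0.1))
  expect_error(vibronic_weights(-0.1), "S must be")
})

test_that("vibronic weights normalize, with tiny truncation error", {
  expect_equal(sum(vibronic_weights(0.3, 20)), 1, tolerance = 1e-12)
  # truncation at n_max = 10 loses < 1e-10 for any S <= 0.3
  for (S in c(0.01, 0.1, 0.3)) {
    expect_lt(1 - sum(vibronic_weights(S, 10)), 1e-10)
  }
})

test_that("tuned-receptor channel times match the published anchors", {
  p <- default_params()
  tau0 <- transfer_rate(p, 0)$characteristic_time
  tau1 <- transfer_rate(p, 1)$characteristic_time
  expect_equal(tau0, 87e-9, tolerance = 0.02)
  expect_equal(signif(tau1 * 1e9, 2), 0.15)
  expect_lt(tau1, tau0 / 100)  # discriminating channel dominates broadly
})

test_that("rate result fields are internally consistent", {
  r <- transfer_rate(default_params(), 1)
  expect_equal(r$characteristic_time, 1 / r$rate)
  expect_equal(r$weight, 0.1 * exp(-0.1))
  expect_identical(r$channel_index, 1L)
  # for the tuned receptor the n=1 channel energy is 0, so the exponent is
  # lambda^2 / (4 kT lambda) = lambda / (4 kT)
  expect_equal(r$activation_exponent, 0.03 / (4 * 0.027))
})

test_that("rates scale as the matrix element squared", {
  p1 <- default_params()
  p2 <- default_params(matrix_element = energy(2, "meV"))
  expect_equal(transfer_rate(p2, 0)$rate, 4 * transfer_rate(p1, 0)$rate)
  expect_equal(transfer_rate(p2, 1)$rate, 4 * transfer_rate(p1, 1)$rate)
})

test_that("channel ratio is independent of |t| and vanishes with S", {
  cmp <- channel_comparison(default_params())
  expect_equal(cmp$ratio, cmp$tau_T0 / cmp$tau_T1)
  expect_equal(cmp$ratio, 87 / 0.15, tolerance = 0.05)
  for (scale in c(0.1, 3, 100)) {
    cmp_s <- channel_comparison(
      default_params(matrix_element = energy(scale, "meV")))
    expect_equal(cmp_s$ratio, cmp$ratio, tolerance = 1e-12)
  }
  # S -> 0: sigma_1 -> 0, so tau_T1 -> Inf and the ratio collapses linearly
  cmp_small <- channel_comparison(default_params(huang_rhys = 1e-8))
  expect_lt(cmp_small$ratio, 1e-3)
  cmp_half <- channel_comparison(default_params(huang_rhys = 0.5e-8))
  expect_equal(cmp_half$ratio / cmp_small$ratio, 0.5, tolerance = 1e-6)
})

test_that("Marcus rate peaks where the channel energy equals lambda", {
  p <- default_params()
  gaps <- seq(0.005, 0.12, by = 0.005)
  rates <- vapply(gaps, function(g) {
    transfer_rate(receptor_params(da_gap = energy(g, "eV")), 0)$rate
  }, numeric(1))
  expect_equal(gaps[which.max(rates)], p$lambda, tolerance = 0.005)
})

test_that("crossover reorganization energy is ~62 meV for the tuned set", {
  lam <- crossover_lambda(default_params())
  expect_equal(as_eV(lam) * 1e3, 62, tolerance = 1 / 62)
  # closed form and bisection agree to better than 1e-9 eV
  lam_bis <- crossover_lambda(default_params(), method = "bisection")
  expect_lt(abs(as_eV(lam) - as_eV(lam_bis)), 1e-9)
  # S = 1 degenerates to hw0 / 2; above 1 there is no crossover
  expect_equal(as_eV(crossover_lambda(default_params(huang_rhys = 1))), 0.1)
  expect_error(crossover_lambda(default_params(huang_rhys = 1.5)),
               "no crossover")
  expect_error(crossover_lambda(default_params(da_gap = energy(0.1, "eV"))),
               "tuned")
})

test_that("crossover is unique in (0, hw0) across the weak-coupling range", {
  for (S in c(0.02, 0.1, 0.3, 0.9)) {
    p <- default_params(huang_rhys = S)
    lam <- as_eV(crossover_lambda(p))
    expect_gt(lam, 0)
    expect_lt(lam, p$hw0)
    lam_b <- as_eV(crossover_lambda(p, method = "bisection"))
    expect_lt(abs(lam - lam_b), 1e-9)
  }
})

test_that("lambda sweep is consistent with the pointwise rates", {
  p <- default_params()
  grid <- c(0.01, 0.03, 0.0617, 0.09)
  tab <- lambda_sweep(p, grid)
  expect_named(tab, c("lambda_meV", "tau0_s", "tau1_s"))
  expect_equal(tab$lambda_meV, grid * 1e3)
  # the lambda = 30 meV row equals the channel comparison
  cmp <- channel_comparison(p)
  expect_equal(tab$tau0_s[2], cmp$tau_T0)
  expect_equal(tab$tau1_s[2], cmp$tau_T1)
  # tuned case: the discriminating time grows monotonically with lambda
  fine <- lambda_sweep(p, seq(0.005, 0.15, by = 0.005))
  expect_true(all(diff(fine$tau1_s) > 0))
  # rows partition around the crossover
  lam_star <- as_eV(crossover_lambda(p))
  below <- fine$lambda_meV / 1e3 < lam_star
  expect_true(all(fine$tau0_s[below] > fine$tau1_s[below]))
  expect_true(all(fine$tau0_s[!below] < fine$tau1_s[!below]))
  expect_error(lambda_sweep(p, c(0.01, -0.02)), "lambda_grid")
})

test_that("inner-shell reorganization sums harmonic mode contributions", {
  expect_equal(as_eV(inner_shell_reorganization()), 0)
  expect_equal(as_eV(inner_shell_reorganization(2, 0.1)), 0.01)
  # additive over mode sets
  a_k <- c(1, 2); a_q <- c(0.05, 0.1)
  b_k <- c(3);    b_q <- c(0.2)
  expect_equal(
    as_eV(inner_shell_reorganization(c(a_k, b_k), c(a_q, b_q))),
    as_eV(inner_shell_reorganization(a_k, a_q)) +
      as_eV(inner_shell_reorganization(b_k, b_q))
  )
})

test_that("outer-shell reorganization vanishes in a non-polar pocket", {
  for (sign in c("as_printed", "standard_marcus")) {
    expect_equal(
      as_eV(outer_shell_reorganization(1, 3, 4, 8, 2.5, 2.5,
                                       separation_sign = sign)), 0)
  }
  expect_equal(as_eV(outer_shell_reorganization(0, 3, 4, 8, 2, 40)), 0)
})

test_that("outer-shell reorganization arithmetic and sign conventions", {
  lam_std <- outer_shell_reorganization(1, 3, 3, 8, 2, 4,
                                        separation_sign = "standard_marcus")
  expect_equal(as_eV(lam_std), 14.39964 * (1 / 3 - 1 / 8) * 0.25,
               tolerance = 1e-12)
  expect_equal(as_eV(lam_std), 0.750, tolerance = 1e-3)
  lam_printed <- outer_shell_reorganization(1, 3, 3, 8, 2, 4)
  expect_equal(as_eV(lam_printed), 14.39964 * (1 / 3 + 1 / 8) * 0.25,
               tolerance = 1e-12)
  expect_gt(as_eV(lam_printed), as_eV(lam_std))
})

test_that("multiphonon and matrix-element suppression factors", {
  expect_equal(multiphonon_suppression(0.1, 0.1, 0.1), 20)
  # within the published factor 100-500 band for weakly coupled pairs
  r <- multiphonon_suppression(0.1, 0.04, 0.04)
  expect_equal(r, 125)
  expect_gt(r, 100); expect_lt(r, 500)
  # linear in the discriminating coupling
  expect_equal(multiphonon_suppression(0.2, 0.04, 0.04), 2 * r)
  expect_error(multiphonon_suppression(0.1, 0, 0.1), "zero")

  expect_equal(matrix_element_suppression(30), 900)
  expect_equal(matrix_element_suppression(1), 1)
  expect_equal(matrix_element_suppression(10), 100)
  expect_error(matrix_element_suppression(0), "> 0")
})
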