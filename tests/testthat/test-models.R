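ds <- ppn_fixture()

test_that("fit diagnostics match their definitions", {
  x <- c(1e-4, 2e-4, 3e-4)
  expect_equal(rmsd_percent(x, x), 0)
  expect_equal(rmsd_percent(1e-3, 1.1e-3), 10)
  expect_error(rmsd_percent(x, x[1:2]), "length")
  expect_error(rmsd_percent(c(-1, 1), c(1, 1)), "positive")
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand-computed sums of squares: SS_res = 0.02, SS_tot = 2
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 2, 3.1)), 1 - 0.02 / 2)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
})

test_that("van't Hoff fitting recovers exact data and matches oracles", {
  s <- vh_series(1, -100)
  f <- fit_vant_hoff(s$T, s$x)
  expect_equal(f$a, 1, tolerance = 1e-10)
  expect_equal(f$b, -100, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmsd_pct, 0, tolerance = 1e-8)

  # noisy toy series against two independent least-squares routes
  set.seed(3)
  x_noisy <- s$x * exp(rnorm(5, 0, 0.02))
  f2 <- fit_vant_hoff(s$T, x_noisy)
  cf <- ols_closed_form(1 / s$T, log(x_noisy))
  expect_equal(c(f2$a, f2$b), unname(cf), tolerance = 1e-8)
  gs <- grid_search_vant_hoff(s$T, x_noisy)
  expect_equal(c(f2$a, f2$b), unname(gs), tolerance = 1e-3)

  expect_error(fit_vant_hoff(rep(300, 4), c(1, 2, 3, 4) * 1e-4), "degenerate")
  expect_error(fit_vant_hoff(c(300, 310), c(1e-4, 2e-4)), "at least 3")
})

test_that("van't Hoff predictions follow the closed form", {
  fit <- structure(list(a = -4.45, b = -2093.60), class = "vant_hoff_fit")
  expect_equal(predict(fit, 308.2), exp(-4.45 - 2093.60 / 308.2))
  expect_equal(predict(fit, 308.2), 1.31e-5, tolerance = 3e-3)
  flat <- structure(list(a = -2, b = 0), class = "vant_hoff_fit")
  expect_equal(predict(flat, c(300, 350)), rep(exp(-2), 2))
})

test_that("Apelblat fitting nests van't Hoff and matches the normal equations", {
  s <- vh_series(1, -100)             # C = 0 data
  f <- fit_apelblat(s$T, s$x)
  expect_equal(f$A, 1, tolerance = 1e-5)
  expect_equal(f$B, -100, tolerance = 1e-3)
  expect_equal(f$C, 0, tolerance = 1e-6)
  expect_gt(f$condition_number, 1e3)  # collinear design over a 20 K window

  set.seed(4)
  x_noisy <- s$x * exp(rnorm(5, 0, 0.02))
  f2 <- fit_apelblat(s$T, x_noisy)
  X <- cbind(1, 1 / s$T, log(s$T))
  ne <- normal_equations_fit(X, log(x_noisy))
  expect_equal(c(f2$A, f2$B, f2$C), ne, tolerance = 1e-8)

  expect_error(fit_apelblat(c(300, 310, 320), c(1, 2, 3) * 1e-4),
               "at least 4")
})

test_that("Apelblat never fits worse than van't Hoff on the same series", {
  vh <- vant_hoff_table(ds)
  ap <- apelblat_table(ds)
  expect_equal(ap$m, vh$m)
  expect_true(all(ap$rmsd_pct <= vh$rmsd_pct))
  expect_true(all(ap$r2 >= vh$r2))
})

test_that("log-linear blending is exact at the endpoints and bounded between them", {
  expect_equal(yalkowsky_roseman(1, 8.44e-2, 1.31e-5), log10(8.44e-2))
  expect_equal(yalkowsky_roseman(0, 8.44e-2, 1.31e-5), log10(1.31e-5))
  m1 <- seq(0, 1, by = 0.05)
  l10 <- yalkowsky_roseman(m1, 8.44e-2, 1.31e-5)
  expect_true(all(l10 >= log10(1.31e-5) & l10 <= log10(8.44e-2)))
  expect_error(yalkowsky_roseman(0.5, -1, 1e-5), "positive")

  yl <- yalkowsky_table(ds)
  expect_equal(nrow(yl$rmsd_by_m), 9L)
  # reproduces the study's per-composition deviations to print rounding
  expect_equal(yl$rmsd_by_m$rmsd_pct[yl$rmsd_by_m$m == 0.2], 0.46,
               tolerance = 0.02)
  expect_equal(yl$rmsd_pct, 1.24, tolerance = 0.03)
})

test_that("Jouyban-Acree fitting recovers generating coefficients exactly", {
  g <- generate_solubility_grid(generator_config(J = c(50, 10, 0),
                                                 noise_sigma = 0))
  f <- fit_jouyban_acree(g)
  expect_equal(sort(names(f$J)), c("J0", "J1"))
  expect_equal(unname(f$J["J0"]), 50, tolerance = 1e-8)
  expect_equal(unname(f$J["J1"]), 10, tolerance = 1e-8)
  expect_equal(f$rmsd_pct, 0, tolerance = 1e-8)

  # all-zero interaction: every term insignificant, log-linear rule remains
  g0 <- generate_solubility_grid(generator_config(J = c(0, 0, 0),
                                                  noise_sigma = 0))
  f0 <- fit_jouyban_acree(g0)
  expect_length(f0$J, 0)
  yal <- yalkowsky_table(g0)
  pred <- predict(f0, yal$table$m, yal$table$T_K)
  expect_equal(pred, yal$table$x_pred, tolerance = 1e-12)
})

test_that("single-term no-intercept estimate equals the projection formula", {
  noisy <- perturb_fixture(ds, 0.01, seed = 5)
  f <- fit_jouyban_acree(noisy, p_drop = 1, order = 0L)
  d <- noisy$data
  mix <- d[d$m > 0 & d$m < 1, ]
  x1 <- d$x_e[d$m == 1][match(mix$T_K, sort(unique(d$T_K)))]
  x2 <- d$x_e[d$m == 0][match(mix$T_K, sort(unique(d$T_K)))]
  y <- log(mix$x_e) - mix$m * log(x1) - (1 - mix$m) * log(x2)
  w <- mix$m * (1 - mix$m) / mix$T_K
  expect_equal(unname(f$J["J0"]), sum(w * y) / sum(w^2), tolerance = 1e-10)
})

test_that("two-stage mixture fit reuses the pure-solvent van't Hoff lines", {
  f <- fit_ja_vant_hoff(ds)
  vh1 <- fit_vant_hoff(ds$data$T_K[ds$data$m == 1], ds$data$x_e[ds$data$m == 1])
  vh2 <- fit_vant_hoff(ds$data$T_K[ds$data$m == 0], ds$data$x_e[ds$data$m == 0])
  expect_equal(c(f$A1, f$B1), c(vh1$a, vh1$b))
  expect_equal(c(f$A2, f$B2), c(vh2$a, vh2$b))
  # stage-1 coefficients sit within 2% of the study's pure-solvent lines
  expect_equal(f$A1, -0.21, tolerance = 0.02)
  expect_equal(f$B1, -696.21, tolerance = 0.02)
  expect_equal(f$A2, -4.45, tolerance = 0.02)
  expect_equal(f$B2, -2093.60, tolerance = 0.02)

  # noiseless surface: all six coefficients recovered
  g <- generate_solubility_grid(generator_config(J = c(-16.42, 4, 0),
                                                 noise_sigma = 0))
  fr <- fit_ja_vant_hoff(g)
  expect_equal(c(fr$A1, fr$B1, fr$A2, fr$B2), c(-0.21, -696.21, -4.45, -2093.60),
               tolerance = 1e-8)
  expect_equal(unname(fr$J["J0"]), -16.42, tolerance = 1e-8)
  expect_equal(unname(fr$J["J1"]), 4, tolerance = 1e-8)

  # zero interaction: predictions equal blending of the fitted lines
  g0 <- generate_solubility_grid(generator_config(J = 0, noise_sigma = 0))
  f0 <- fit_ja_vant_hoff(g0)
  expect_length(f0$J, 0)
  m <- c(0.25, 0.5, 0.75); T <- c(303.2, 313.2)
  for (ti in T) {
    x1 <- predict(structure(list(a = f0$A1, b = f0$B1),
                            class = "vant_hoff_fit"), ti)
    x2 <- predict(structure(list(a = f0$A2, b = f0$B2),
                            class = "vant_hoff_fit"), ti)
    expect_equal(log10(predict(f0, m, rep(ti, 3))),
                 yalkowsky_roseman(m, x1, x2), tolerance = 1e-12)
  }
})

test_that("interaction coefficient recovery is unbiased with noise of the study's scale", {
  cfg0 <- generator_config(noise_sigma = 0)
  truth <- -16.42
  n_rep <- 100
  est <- se <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    g <- generate_solubility_grid(generator_config(noise_sigma = 0.01,
                                                   seed = 1000 + k))
    f <- fit_ja_vant_hoff(g, p_drop = 1)
    est[k] <- f$J[["J0"]]
  }
  # mean estimate within 3 Monte-Carlo standard errors of truth
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(n_rep))
  # spread consistent with the analytic no-intercept OLS standard error
  d <- generate_solubility_grid(cfg0)$data
  mix <- d[d$m > 0 & d$m < 1, ]
  W <- cbind(mix$m * (1 - mix$m) / mix$T_K,
             mix$m * (1 - mix$m) * (2 * mix$m - 1) / mix$T_K,
             mix$m * (1 - mix$m) * (2 * mix$m - 1)^2 / mix$T_K)
  se_theory <- 0.01 * sqrt(solve(crossprod(W))[1, 1])
  # the mixture-only formula understates the spread because stage-1 noise
  # in the pure-solvent lines propagates into the residual response
  expect_gt(sd(est) / se_theory, 0.8)
  expect_lt(sd(est) / se_theory, 2.2)
})
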