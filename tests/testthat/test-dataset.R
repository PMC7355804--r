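test_that("mole-fraction conversion reproduces the pure-solvent worked values", {
  expect_equal(signif(to_mole_fraction(185.29, m = 1), 3), 8.01e-2)
  expect_equal(signif(to_mole_fraction(0.164, m = 0), 3), 1.04e-5)
  expect_identical(to_mole_fraction(0, m = 0.5), 0)
})

test_that("conversion is strictly increasing in raw solubility and inverts exactly", {
  set.seed(42)
  for (rep in 1:20) {
    m <- runif(1)
    raw <- sort(runif(5, 0.01, 500))
    x <- to_mole_fraction(raw, m)
    expect_true(all(diff(x) > 0))
    expect_equal(from_mole_fraction(x, m), raw, tolerance = 1e-12)
  }
  expect_error(to_mole_fraction(-1, 0.5), "non-negative")
  expect_error(to_mole_fraction(1, 1.2), "0, 1")
})

test_that("saturated composition sums to one and matches mole bookkeeping", {
  mm <- molar_masses()
  # binary limits
  expect_equal(unlist(saturated_composition(0.0788, 1, mm)),
               c(x1 = 0.0788, x2 = 0.9212, x3 = 0))
  expect_equal(unlist(saturated_composition(1.03e-5, 0, mm)),
               c(x1 = 1.03e-5, x2 = 0, x3 = 1 - 1.03e-5))
  # mid-grid record: cosolvent/water mole ratio follows the blend
  cmp <- saturated_composition(9.06e-4, 0.5, mm)
  expect_equal(cmp$x2 / cmp$x3, (0.5 / 134.17) / (0.5 / 18.07),
               tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:25) {
    m <- runif(1); x <- runif(1, 1e-6, 0.5)
    got <- unlist(saturated_composition(x, m, mm))
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(got, composition_by_mole_count(x, m, mm), tolerance = 1e-12)
  }
})

test_that("dataset construction validates records and rejects duplicates", {
  d <- data.frame(m = c(0, 0.5, 0.5), T_K = c(298.2, 298.2, 298.2),
                  x_e = c(1e-5, 9e-4, 9.1e-4))
  expect_error(solubility_dataset(d), "duplicate \\(m, T\\)")
  expect_error(solubility_dataset(data.frame(m = 0.5, T_K = 298.2)),
               "solubility column")
  expect_error(solubility_dataset(data.frame(m = 0.5, T_K = 298.2, x_e = 1.2)),
               "\\(0, 1\\)")
  expect_error(solubility_dataset(data.frame(m = 2, T_K = 298.2, x_e = 0.1)),
               "mass fraction")
  expect_error(solubility_dataset(
    data.frame(m = numeric(0), T_K = numeric(0), x_e = numeric(0))), "empty")
})

test_that("CSV round trip and raw-unit CSVs load to the same dataset", {
  ds <- ppn_fixture()
  f1 <- tempfile(fileext = ".csv")
  write_solubility_csv(ds, f1)
  again <- read_solubility_csv(f1, masses = ds$masses, labels = ds$labels)
  expect_equal(again$data, ds$data, tolerance = 1e-12)

  # same grid expressed in mg per g of solvent
  raw <- ds$data
  raw$mg_per_g <- from_mole_fraction(raw$x_e, raw$m, ds$masses)
  raw$x_e <- NULL
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, f2, row.names = FALSE)
  from_raw <- read_solubility_csv(f2, masses = ds$masses)
  expect_equal(from_raw$data$x_e, ds$data$x_e, tolerance = 1e-12)

  writeLines(c("m,T_K,x_e", "0.5,298.2,oops"), f2)
  expect_error(read_solubility_csv(f2), "unparseable|\\(0, 1\\)")
  expect_error(read_solubility_csv(tempfile()), "not found")
  writeLines(c("m,T_K", "0.5,298.2"), f2)
  expect_error(read_solubility_csv(f2), "solubility column")
})

test_that("the packaged piperine grid is complete and matches its anchors", {
  ds <- ppn_fixture()
  d <- ds$data
  expect_equal(nrow(d), 55L)
  lv <- grid_levels(ds)
  expect_equal(lv$m, seq(0, 1, by = 0.1))
  expect_equal(lv$T_K, seq(298.2, 318.2, by = 5))
  expect_silent(assert_complete_grid(ds))
  expect_equal(d$x_e[d$m == 0 & d$T_K == 298.2], 1.03e-5)
  expect_equal(d$x_e[d$m == 1 & d$T_K == 318.2], 9.10e-2)
  expect_equal(unlist(ds$masses),
               c(solute = 285.34, cosolvent = 134.17, water = 18.07))
  # solubility rises with both temperature and cosolvent fraction
  for (mi in lv$m) expect_true(all(diff(d$x_e[d$m == mi]) > 0))
  for (ti in lv$T_K)
    expect_true(all(diff(d$x_e[d$T_K == ti][order(d$m[d$T_K == ti])]) > 0))
})

test_that("grid completeness is enforced only where required", {
  ds <- ppn_fixture()
  holed <- solubility_dataset(ds$data[-3, ], ds$masses, ds$labels)
  expect_error(assert_complete_grid(holed), "missing cell m = 0, T = 308.2")
  no_pure <- solubility_dataset(subset(ds$data, m < 1), ds$masses, ds$labels)
  expect_error(assert_complete_grid(no_pure), "pure solvents")
  # single-solvent analyses accept partial data
  expect_s3_class(solubility_dataset(subset(ds$data, m == 0.5)),
                  "solubility_dataset")
})
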