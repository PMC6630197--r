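test_that("young_laplace_gamma does the arithmetic and validates", {
  expect_equal(young_laplace_gamma(1.0e-3, 7.0), 3.5e-3)
  expect_equal(young_laplace_gamma(2.0e-3, 4.0), 4.0e-3)
  expect_equal(young_laplace_gamma(1.0e-3, 0), 0)
  # linear in both arguments
  expect_equal(young_laplace_gamma(3e-3, 5), 3 * young_laplace_gamma(1e-3, 5))
  expect_equal(young_laplace_gamma(1e-3, 15),
               3 * young_laplace_gamma(1e-3, 5))
  expect_error(young_laplace_gamma(0, 5), "> 0")
  expect_error(young_laplace_gamma(1e-3, -1), ">= 0")
})

test_that("noiseless synthetic curves are recovered to high precision", {
  for (lipid in c("DPPC", "DPPE")) {
    fc <- amphisurf:::.tension_fixture_constants[[lipid]]
    ds <- gen_tension_dataset(tension_fixture(lipid, sigma = 0))
    ft <- fit_tension_curve(ds$curve)
    expect_true(ft$converged)
    expect_lt(abs(ft$params$log10_K_X - fc$log10_K_X), 1e-3)
    expect_lt(abs(ft$params$log10_K_Y - fc$log10_K_Y), 1e-3)
    # regenerated curve matches at every data pH
    back <- gamma_of_pH(as_amphoteric(ft$params), ds$curve$pH)
    expect_equal(back, ds$curve$gamma, tolerance = 1e-6)
    # pI from recovered exponents matches the generating pI
    expect_lt(abs(ft$pI_estimate - fc$pI), 0.05)
  }
})

test_that("flat data yield a flagged baseline-only fit, no exception", {
  curve <- tension_curve(seq(2, 9, length.out = 10), rep(3.1e-3, 10))
  expect_warning(ft <- fit_tension_curve(curve), "flat")
  expect_true(ft$flat)
  expect_true(ft$converged)
  expect_equal(ft$params$baseline_B, 3.1e-3)
  expect_equal(ft$params$amp_AX, 0)
})

test_that("fit is scale-equivariant", {
  ds <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0.01, seed = 3))
  f1 <- fit_tension_curve(ds$curve)
  scaled <- tension_curve(ds$curve$pH, ds$curve$gamma * 7,
                          sigma = ds$curve$sigma * 7)
  f2 <- fit_tension_curve(scaled)
  expect_equal(f2$params$log10_K_X, f1$params$log10_K_X, tolerance = 1e-6)
  expect_equal(f2$params$log10_K_Y, f1$params$log10_K_Y, tolerance = 1e-6)
  expect_equal(f2$params$baseline_B, 7 * f1$params$baseline_B,
               tolerance = 1e-6)
  expect_equal(f2$params$amp_AX, 7 * f1$params$amp_AX, tolerance = 1e-4)
})

test_that("fix_k mode estimates only the linear parameters", {
  ds <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0))
  ft <- fit_tension_curve(ds$curve, fix_k = c(2.58, 5.69))
  expect_equal(ft$params$log10_K_X, 2.58)
  expect_equal(ft$params$baseline_B, ds$params$baseline_B,
               tolerance = 1e-9)
  expect_equal(ft$params$amp_AX, ds$params$amp_AX, tolerance = 1e-6)
})

test_that("locate_maximum agrees with a dense grid oracle", {
  ip <- as_identifiable(dppc_params())
  mx <- locate_maximum(ip, 0, 14)
  grid <- seq(0, 14, by = 1e-4)
  vals <- gamma_of_pH(dppc_params(), grid)
  expect_lt(abs(mx[["gamma_max"]] - max(vals)), 1e-9)
  expect_lt(abs(mx[["pH_at_max"]] - grid[which.max(vals)]), 1e-3)
  expect_lt(abs(mx[["gamma_max"]] - ip$baseline_B), 0.005 * ip$baseline_B)
  # symmetric single peak: maximum at the midpoint of the transitions
  sym <- identifiable_params(3e-3, -1e-3, -1e-3, 4, 4)
  mxs <- locate_maximum(sym, 0, 14)
  expect_equal(mxs[["pH_at_max"]], (4 + (14 - 4)) / 2, tolerance = 1e-3)
  # monotone curve: maximum at an endpoint
  mono <- identifiable_params(3e-3, -1e-3, 0, 4, 5)
  mxm <- locate_maximum(mono, 0, 14)
  expect_equal(mxm[["pH_at_max"]], 14, tolerance = 1e-6)
  expect_error(locate_maximum(sym, 5, 5), "pH_lo < pH_hi")
})

test_that("surface_energy reproduces the calibrated molar energies", {
  expect_equal(surface_energy(0, 85.4), 0)
  expect_equal(surface_energy(3.5e-3, 85.4), 1800, tolerance = 1e-3)
  expect_equal(surface_energy(4.0e-3, 77.0), 1854, tolerance = 1e-3)
  expect_error(surface_energy(1e-3, 0), "> 0")
})

test_that("tension_curve validates its invariants", {
  expect_error(tension_curve(c(1, 1), c(1e-3, 2e-3)), "increasing")
  expect_error(tension_curve(c(1, 2), c(1e-3, -2e-3)), "> 0")
  expect_error(tension_curve(c(1, 2), c(1e-3, 2e-3), sigma = c(1, -1)),
               "sigma")
})
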