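test_that("gamma_of_pH reaches its plateaus and collapses when K -> 0", {
  p <- amphoteric_params(1e-3, 2e-3, 1.5e-3, 0.5e-3,
                         K_X = 1e-12, K_Y = 1e-12)
  # both sigmoid weights vanish: baseline only
  expect_equal(gamma_of_pH(p, c(0, 7, 14)), rep(1e-3 + 1.5e-3, 3),
               tolerance = 1e-9)

  dppc <- dppc_params()
  lim <- limiting_tensions(dppc)
  # low-pH limit: fully protonated phosphate + cationic amine
  expect_equal(gamma_of_pH(dppc, -10), dppc$gamma_XH0 + dppc$gamma_Yplus0,
               tolerance = 1e-9)
  expect_equal(gamma_of_pH(dppc, -6), lim[["gamma_lowpH"]],
               tolerance = 1e-6 * lim[["gamma_lowpH"]])
  expect_equal(gamma_of_pH(dppc, 20), lim[["gamma_highpH"]],
               tolerance = 1e-6 * lim[["gamma_highpH"]])
})

test_that("gamma_of_pH maximum sits between the transitions (grid oracle)", {
  for (lipid in c("DPPC", "DPPE")) {
    p <- fixture_params(lipid)
    ip <- as_identifiable(p)
    grid <- seq(0, 14, by = 1e-3)
    vals <- gamma_of_pH(p, grid)
    i <- which.max(vals)
    expect_lt(abs(vals[i] - ip$baseline_B), 0.005 * ip$baseline_B)
    expect_gt(grid[i], ip$log10_K_X)
    expect_lt(grid[i], 14 - ip$log10_K_Y)
    # bounded by the extreme corner sums of the two-sigmoid model
    corners <- c(ip$baseline_B, ip$baseline_B + ip$amp_AX,
                 ip$baseline_B + ip$amp_AY,
                 ip$baseline_B + ip$amp_AX + ip$amp_AY)
    expect_true(all(vals >= min(corners) - 1e-15))
    expect_true(all(vals <= max(corners) + 1e-15))
  }
})

test_that("gamma_of_pH validates inputs", {
  expect_error(gamma_of_pH(dppc_params(), NaN), "finite")
  expect_error(amphoteric_params(1e-3, 1e-3, 1e-3, 1e-3, -1, 10), "> 0")
  expect_error(amphoteric_params(-1e-3, 1e-3, 1e-3, 1e-3, 10, 10), ">= 0")
})

test_that("speciation fractions are complementary, bounded and correct", {
  p <- dppc_params()
  # half-saturation: K_X * a_H = 1 at pH = log10(K_X)
  f <- speciation_fractions(p, log10(p$K_X))
  expect_equal(f$f_XH, 0.5)
  expect_equal(f$f_Xminus, 0.5)
  # direct arithmetic oracle at pH 4.135
  f2 <- speciation_fractions(p, 4.135)
  expect_equal(f2$f_Xminus, 1 / (1 + 10^(2.58 - 4.135)), tolerance = 1e-12)
  expect_equal(round(f2$f_Xminus, 4), 0.9729)
  # property: sums exact, all within [0, 1], on a wide random grid
  set.seed(42)
  pH <- runif(200, -5, 19)
  fr <- speciation_fractions(p, pH)
  expect_equal(fr$f_XH + fr$f_Xminus, rep(1, 200))
  expect_equal(fr$f_Yplus + fr$f_YOH, rep(1, 200))
  expect_true(all(fr[, -1] >= 0 & fr[, -1] <= 1))
})

test_that("limiting_tensions is symmetric for equal components", {
  p <- amphoteric_params(2e-3, 2e-3, 2e-3, 2e-3, 10, 10)
  expect_equal(unname(limiting_tensions(p)), c(4e-3, 4e-3))
})

test_that("compute_pI reproduces the reference table and symmetric case", {
  expect_equal(round(compute_pI(2.58, 5.69), 2), 4.14)  # DPPC
  expect_equal(round(compute_pI(2.42, 5.98), 2), 4.20)  # DPPE
  expect_equal(compute_pI(6.3, 6.3), 6.3)
  # the charge-balance alternative differs by design
  expect_equal(compute_pI(2.58, 5.69, method = "charge_balance"),
               (14 + 2.58 - 5.69) / 2)
  expect_error(compute_pI(NA, 5), "finite")
})

test_that("identifiable round-trip preserves gamma(pH) for any split", {
  ip <- as_identifiable(dppc_params())
  pH <- seq(-2, 16, length.out = 181)
  ref <- gamma_of_pH(dppc_params(), pH)
  lo <- max(0, -ip$amp_AY)
  hi <- min(ip$baseline_B, ip$baseline_B + ip$amp_AX)
  for (split in c(lo, (lo + hi) / 2, hi)) {
    back <- as_amphoteric(ip, gamma_Yplus0 = split)
    expect_equal(gamma_of_pH(back, pH), ref, tolerance = 1e-12)
  }
})

test_that("monotone flanks: non-decreasing before and after transitions", {
  ip <- as_identifiable(dppc_params())
  lowside <- seq(-4, ip$log10_K_X - 2, length.out = 50)
  highside <- seq(14 - ip$log10_K_Y + 2, 18, length.out = 50)
  expect_true(all(diff(gamma_of_pH(dppc_params(), lowside)) >= 0))
  expect_true(all(diff(gamma_of_pH(dppc_params(), highside)) <= 0))
})

test_that("ion activities satisfy the water ion product", {
  act <- ion_activities(c(1, 4.5, 13), pKw = 14)
  expect_equal(act$a_H * act$a_OH, rep(1e-14, 3))
})
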