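test_that("gen_tension_dataset: noiseless, deterministic, calibrated", {
  fx0 <- tension_fixture("DPPC", sigma = 0)
  ds0 <- gen_tension_dataset(fx0)
  expect_equal(ds0$curve$gamma, gamma_of_pH(dppc_params(), ds0$curve$pH))
  # same seed, bitwise identical; different seed differs
  d1 <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0.02, seed = 4))
  d2 <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0.02, seed = 4))
  d3 <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0.02, seed = 5))
  expect_identical(d1$curve$gamma, d2$curve$gamma)
  expect_false(identical(d1$curve$gamma, d3$curve$gamma))
  # calibration: model maximum equals the tabulated gamma_max
  for (lipid in c("DPPC", "DPPE")) {
    fc <- amphisurf:::.tension_fixture_constants[[lipid]]
    mx <- locate_maximum(fixture_params(lipid), 0, 14)
    expect_lt(abs(mx[["gamma_max"]] - fc$gamma_max), 0.005 * fc$gamma_max)
  }
  expect_error(tension_fixture("DPPC", sigma = -0.1), "sigma")
  expect_error(tension_fixture("DPPC", pH = c(-1, 5)), "0, 14")
})

test_that("noiseless generate -> fit -> pI closure recovers the fixture pI", {
  for (lipid in c("DPPC", "DPPE")) {
    ds <- gen_tension_dataset(tension_fixture(lipid, sigma = 0))
    ft <- fit_tension_curve(ds$curve)
    fc <- amphisurf:::.tension_fixture_constants[[lipid]]
    expect_lt(abs(ft$pI_estimate - fc$pI), 0.05)
  }
})

test_that("planted single bridge yields one 150 ps lifetime end to end", {
  pl <- plant_spec(bridges = data.frame(
    water = 1, lipid_i = 1, label_i = "O2", lipid_j = 2, label_j = "O1",
    first_frame = 1, last_frame = 3))
  toy <- gen_toy_trajectory(4, 6, pl, n_frames = 10, seed = 2)
  bonds <- detect_hbonds_trajectory(toy$trajectory)
  br <- do.call(rbind, lapply(split(bonds, bonds$frame), find_water_bridges))
  dd <- event_durations(br, frame_spacing = 50)
  expect_equal(dd$lifetimes, 150)
  expect_equal(toy$truth$lifetimes$bridges$lifetime_ps, 150)
})

test_that("planted margins hold: bonds clear cutoffs, decoys are far", {
  pl <- random_plant_spec(10, 20, 6, n_bridges = 3, n_contacts = 2,
                          n_hbonds = 1, seed = 31)
  toy <- gen_toy_trajectory(10, 20, pl, n_frames = 6, seed = 31)
  fr <- toy$trajectory[[1]]
  strict <- detect_hbonds(fr, hbond_criteria(d_max = 3.2, angle_min = 145))
  loose <- detect_hbonds(fr, hbond_criteria(d_max = 4.4, angle_min = 135))
  base <- detect_hbonds(fr)
  # planted bonds survive stricter criteria; looser criteria add nothing
  expect_same_events(strict, base)
  expect_same_events(loose, base)
})

test_that("no waters means no bridges", {
  toy <- gen_toy_trajectory(4, 0, plant_spec(), n_frames = 3)
  bonds <- detect_hbonds_trajectory(toy$trajectory)
  br <- find_water_bridges(bonds[bonds$frame == 1, ])
  expect_equal(nrow(br), 0)
})

test_that("infeasible plants are rejected", {
  # two events on the same lipid pair
  expect_error(gen_toy_trajectory(4, 6, plant_spec(
    bridges = data.frame(water = 1:2, lipid_i = 1, label_i = c("O1", "O3"),
                         lipid_j = 2, label_j = c("O2", "O4"),
                         first_frame = 1, last_frame = 2)),
    n_frames = 5), "pair")
  # shared water
  expect_error(gen_toy_trajectory(6, 6, plant_spec(
    bridges = data.frame(water = 1, lipid_i = c(1, 3),
                         label_i = c("O1", "O2"), lipid_j = c(2, 4),
                         label_j = c("O2", "O1"), first_frame = 1,
                         last_frame = 2)),
    n_frames = 5), "water")
  # non-adjacent lipids
  expect_error(gen_toy_trajectory(10, 6, plant_spec(
    bridges = data.frame(water = 1, lipid_i = 1, label_i = "O1",
                         lipid_j = 3, label_j = "O2", first_frame = 1,
                         last_frame = 2)),
    n_frames = 5), "adjacent")
  # interval outside the trajectory
  expect_error(gen_toy_trajectory(4, 6, plant_spec(
    bridges = data.frame(water = 1, lipid_i = 1, label_i = "O1",
                         lipid_j = 2, label_j = "O2", first_frame = 1,
                         last_frame = 9)),
    n_frames = 5), "intervals")
  # unknown water id
  expect_error(gen_toy_trajectory(4, 1, plant_spec(
    hbonds = data.frame(water = 5, lipid_i = 1, label_i = "O1",
                        lipid_j = 2, first_frame = 1, last_frame = 2)),
    n_frames = 5), "water")
})

test_that("trajectory generator is deterministic per seed", {
  pl <- random_plant_spec(8, 16, 5, seed = 13)
  t1 <- gen_toy_trajectory(8, 16, pl, n_frames = 5, seed = 13)
  t2 <- gen_toy_trajectory(8, 16, pl, n_frames = 5, seed = 13)
  expect_identical(t1$trajectory[[3]]$atoms, t2$trajectory[[3]]$atoms)
  t3 <- gen_toy_trajectory(8, 16, pl, n_frames = 5, seed = 14)
  expect_false(identical(t1$trajectory[[3]]$atoms, t3$trajectory[[3]]$atoms))
})

test_that("planted count ratio mirrors the 150% comparison", {
  # two systems whose planted per-frame bridge counts differ 1 : 2.5
  mk <- function(n_bridges, seed) {
    pl <- random_plant_spec(20, 30, 4, n_bridges = n_bridges,
                            n_contacts = 0, n_hbonds = 0, seed = seed)
    pl$bridges$first_frame <- 1
    pl$bridges$last_frame <- 4
    pl$bridges <- pl$bridges[!duplicated(paste(pl$bridges$water)), ]
    toy <- gen_toy_trajectory(20, 30, pl, n_frames = 4, seed = seed)
    bonds <- detect_hbonds_trajectory(toy$trajectory)
    do.call(rbind, lapply(split(bonds, bonds$frame), find_water_bridges))
  }
  a <- mk(4, seed = 41)   # 4 bridges x 4 frames = 16 events
  b <- mk(10, seed = 42)  # 10 bridges x 4 frames = 40 events
  expect_equal(nrow(a), 16)
  expect_equal(nrow(b), 40)
  expect_equal(compare_counts(a, b), 150)
})
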