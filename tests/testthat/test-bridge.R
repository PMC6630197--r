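test_that("canonical two-water geometry gives exactly one bond", {
  fr <- two_water_frame(o_o_dist = 2.8)
  b <- detect_hbonds(fr)
  expect_equal(nrow(b), 1)
  expect_equal(b$donor_res, 1)
  expect_equal(b$acceptor_res, 2)
  # beyond the cutoff: nothing
  expect_equal(nrow(detect_hbonds(two_water_frame(o_o_dist = 5.0))), 0)
  # tighter distance criterion excludes the 2.8 A pair as well
  expect_equal(nrow(detect_hbonds(fr, hbond_criteria(d_max = 2.5))), 0)
  # brute-force oracle agrees
  expect_same_events(detect_hbonds(fr), oracle_hbonds(fr))
})

test_that("missing water hydrogens raise a topology error", {
  atoms <- data.frame(atom = c("OW", "OW"), element = "O", resid = 1:2,
                      kind = "water", x = c(0, 2.8), y = 0, z = 0)
  fr <- trajectory_frame(atoms, c(20, 20, 20))
  expect_error(detect_hbonds(fr), "topology")
})

test_that("detection is invariant under rigid translation and image shifts", {
  pl <- random_plant_spec(10, 24, 8, n_bridges = 3, n_contacts = 2,
                          n_hbonds = 1, seed = 11)
  toy <- gen_toy_trajectory(10, 24, pl, n_frames = 8, seed = 11)
  fr <- toy$trajectory[[2]]
  ref <- detect_hbonds(fr)
  # rigid translation (all atoms) with wrap into the box
  sh <- fr
  sh$atoms$x <- (sh$atoms$x + 31.7) %% sh$box[1]
  sh$atoms$y <- (sh$atoms$y + 12.3) %% sh$box[2]
  sh$atoms$z <- (sh$atoms$z - 44.1) %% sh$box[3]
  expect_same_events(detect_hbonds(sh), ref)
  # shift one whole water by a box period
  w1 <- which(sh$atoms$kind == "water" & sh$atoms$resid == 1)
  sh$atoms$x[w1] <- sh$atoms$x[w1] + sh$box[1]
  expect_same_events(detect_hbonds(sh), ref)
})

test_that("water bridge definition: shared water, two distinct lipids", {
  bonds <- data.frame(
    donor_atom = c("OW", "OW"), donor_res = c(5, 5), donor_kind = "water",
    acceptor_atom = c("O2", "O1"), acceptor_res = c(1, 2),
    acceptor_kind = "lipid", frame = 1L)
  br <- find_water_bridges(bonds)
  expect_equal(nrow(br), 1)
  expect_equal(br$label_i, "O2")  # lipid 1 side
  expect_equal(br$label_j, "O1")
  # twice to the same lipid: no bridge
  bonds2 <- bonds
  bonds2$acceptor_res <- c(1, 1)
  expect_equal(nrow(find_water_bridges(bonds2)), 0)
  # lipid-donated bonds count too (direction-agnostic)
  bonds3 <- rbind(bonds[1, ], data.frame(
    donor_atom = "N", donor_res = 2, donor_kind = "lipid",
    acceptor_atom = "OW", acceptor_res = 5, acceptor_kind = "water",
    frame = 1L))
  br3 <- find_water_bridges(bonds3)
  expect_equal(nrow(br3), 1)
  expect_equal(br3$label_j, "N")
})

test_that("lipid_contacts keeps only inter-lipid bonds", {
  bonds <- data.frame(
    donor_atom = c("N", "OW"), donor_res = c(3, 9),
    donor_kind = c("lipid", "water"),
    acceptor_atom = c("O4", "O1"), acceptor_res = c(1, 2),
    acceptor_kind = c("lipid", "lipid"), frame = 1L)
  ct <- lipid_contacts(bonds)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$lipid_i, 1)  # ordered by residue
  expect_equal(ct$label_i, "O4")
  expect_equal(ct$label_j, "N")
  only_water <- bonds[2, ]
  expect_equal(nrow(lipid_contacts(only_water)), 0)
})

test_that("event_durations handles runs, gaps and tolerance", {
  ev <- function(frames) data.frame(id = rep("a", length(frames)),
                                    frame = frames)
  expect_equal(event_durations(ev(c(1, 2, 3)), 50)$lifetimes, 150)
  d0 <- event_durations(ev(c(1, 2, 4)), 50, gap_tolerance = 0)
  expect_equal(sort(d0$lifetimes), c(50, 100))
  d1 <- event_durations(ev(c(1, 2, 4)), 50, gap_tolerance = 1)
  expect_equal(d1$lifetimes, 200)
  # two keys kept separate
  ev2 <- rbind(data.frame(id = "a", frame = 1:3),
               data.frame(id = "b", frame = c(7, 9)))
  dd <- event_durations(ev2, 10)
  expect_equal(sort(dd$lifetimes), c(10, 10, 30))
  expect_error(event_durations(data.frame(id = "a", frame = 1.5), 50),
               "uniform")
  expect_equal(length(event_durations(ev(integer(0))[0, ], 50)$lifetimes), 0)
})

test_that("bridge_map normalizes counts and flags empties", {
  ev <- data.frame(label_i = c("O1", "O1", "O2", "N"),
                   label_j = c("O2", "O2", "O1", "O1"))
  m <- bridge_map(ev)
  expect_equal(m["O1", "O2"], 0.75)
  expect_equal(m["N", "O1"], 0.25)
  expect_equal(sum(map_matrix(m)), 1)
  expect_equal(attr(m, "n_events"), 4L)
  # all events on one pair: single entry 1.0
  m1 <- bridge_map(data.frame(label_i = "O1", label_j = "O2"))
  expect_equal(sum(map_matrix(m1) != 0), 1)
  expect_equal(m1["O1", "O2"], 1.0)
  # symmetric view double-counts off-diagonal but keeps pair frequencies
  ms <- map_matrix(m, symmetric = TRUE)
  expect_equal(ms["O2", "O1"], 0.75)
  expect_equal(ms, t(ms))
  # empty
  me <- bridge_map(data.frame(label_i = character(0),
                              label_j = character(0)))
  expect_true(attr(me, "empty"))
  expect_equal(nrow(me), 0)
  # counting oracle on random planted labels
  set.seed(5)
  labs <- paste0("O", 1:4)
  rev <- data.frame(label_i = sample(labs, 60, TRUE),
                    label_j = sample(labs, 60, TRUE))
  mr <- bridge_map(rev)
  a <- pmin(rev$label_i, rev$label_j); b <- pmax(rev$label_i, rev$label_j)
  for (pair in unique(paste(a, b))) {
    ab <- strsplit(pair, " ")[[1]]
    expect_equal(mr[ab[1], ab[2]], mean(a == ab[1] & b == ab[2]))
  }
  expect_equal(sum(map_matrix(mr)), 1, tolerance = 1e-12)
})

test_that("compare_counts implements the percent-more definition", {
  expect_equal(compare_counts(1000, 2500), 150)
  expect_equal(compare_counts(1000, 1500), 50)
  expect_equal(compare_counts(123, 123), 0)
  expect_error(compare_counts(0, 10), "> 0")
})

test_that("every bridge implies >= 2 same-frame H-bonds of its water", {
  pl <- random_plant_spec(12, 30, 12, n_bridges = 4, n_contacts = 2,
                          n_hbonds = 2, seed = 21)
  toy <- gen_toy_trajectory(12, 30, pl, n_frames = 12, seed = 21)
  bonds <- detect_hbonds_trajectory(toy$trajectory)
  br <- do.call(rbind, lapply(split(bonds, bonds$frame), find_water_bridges))
  expect_gt(nrow(br), 0)
  for (r in seq_len(nrow(br))) {
    wb <- bonds[bonds$frame == br$frame[r] &
                  ((bonds$donor_kind == "water" &
                      bonds$donor_res == br$water[r]) |
                     (bonds$acceptor_kind == "water" &
                        bonds$acceptor_res == br$water[r])), ]
    expect_gte(nrow(wb), 2)
  }
})
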