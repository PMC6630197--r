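# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (loops, dense grids) rather than calling the
# implementation paths they check.

# sort rows for order-insensitive data frame comparison
sort_df <- function(d) {
  d <- d[do.call(order, d), , drop = FALSE]
  rownames(d) <- NULL
  d
}

expect_same_events <- function(a, b) {
  expect_equal(sort_df(as.data.frame(a)), sort_df(as.data.frame(b)))
}

# All-pairs brute-force hydrogen-bond oracle: explicit donor loop with
# minimum-image geometry recomputed from scratch.
oracle_hbonds <- function(frame, d_max = 3.5, angle_min = 135) {
  a <- frame$atoms
  L <- frame$box
  mi <- function(d, l) d - l * round(d / l)
  heavy <- which(a$element %in% c("O", "N"))
  hs <- which(a$element == "H")
  parent <- vapply(hs, function(h) {
    cand <- which(a$element != "H" & a$resid == a$resid[h] &
                    a$kind == a$kind[h])
    d2 <- mi(a$x[cand] - a$x[h], L[1])^2 +
      mi(a$y[cand] - a$y[h], L[2])^2 + mi(a$z[cand] - a$z[h], L[3])^2
    cand[which.min(d2)]
  }, integer(1))
  rows <- list()
  for (don in heavy) {
    myh <- hs[parent == don]
    if (length(myh) == 0) next
    acc <- heavy[heavy != don &
                   !(a$resid[heavy] == a$resid[don] &
                       a$kind[heavy] == a$kind[don])]
    if (length(acc) == 0) next
    dd <- sqrt(mi(a$x[acc] - a$x[don], L[1])^2 +
                 mi(a$y[acc] - a$y[don], L[2])^2 +
                 mi(a$z[acc] - a$z[don], L[3])^2)
    acc <- acc[dd <= d_max]
    for (ac in acc) {
      bonded <- FALSE
      for (h in myh) {
        v1 <- c(mi(a$x[don] - a$x[h], L[1]), mi(a$y[don] - a$y[h], L[2]),
                mi(a$z[don] - a$z[h], L[3]))
        v2 <- c(mi(a$x[ac] - a$x[h], L[1]), mi(a$y[ac] - a$y[h], L[2]),
                mi(a$z[ac] - a$z[h], L[3]))
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        if (acos(max(-1, min(1, cosang))) * 180 / pi >= angle_min) {
          bonded <- TRUE
          break
        }
      }
      if (bonded)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_atom = a$atom[don], donor_res = a$resid[don],
          donor_kind = a$kind[don], acceptor_atom = a$atom[ac],
          acceptor_res = a$resid[ac], acceptor_kind = a$kind[ac],
          frame = frame$frame_index)
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor_atom = character(0), donor_res = integer(0),
                      donor_kind = character(0),
                      acceptor_atom = character(0),
                      acceptor_res = integer(0),
                      acceptor_kind = character(0), frame = integer(0)))
  do.call(rbind, rows)
}

# brute-force pH solver: scan a dense grid of the ideal charge balance
oracle_pH_gridscan <- function(recipe, pKw = 13.997, step = 1e-5) {
  dil <- recipe$initial_volume /
    (recipe$initial_volume + recipe$titrant_volume)
  na <- recipe$titrant_concentration * recipe$titrant_volume /
    (recipe$initial_volume + recipe$titrant_volume)
  imb <- function(pH) {
    h <- 10^(-pH); oh <- 10^(pH - pKw)
    chg <- 0
    for (a in recipe$acids) {
      Ka <- 10^(-a$pKa)
      terms <- cumprod(c(1, Ka / h))
      fr <- terms / sum(terms)
      chg <- chg + a$conc * dil * sum((seq_along(fr) - 1) * fr)
    }
    na + h - oh - chg
  }
  # coarse bracket, then fine scan (full 1e-5 grid over (0,14) is slow)
  coarse <- seq(0, 14, by = 0.01)
  v <- vapply(coarse, imb, numeric(1))
  i <- which(diff(sign(v)) != 0)[1]
  fine <- seq(coarse[i], coarse[i + 1], by = step)
  vf <- vapply(fine, imb, numeric(1))
  j <- which.min(abs(vf))
  fine[j]
}

# run-length lifetime oracle (gap tolerance 0): explicit frame walk
oracle_lifetimes <- function(frames, spacing) {
  frames <- sort(unique(frames))
  lives <- numeric(0)
  run <- 1
  for (k in seq_along(frames)[-1]) {
    if (frames[k] == frames[k - 1] + 1) {
      run <- run + 1
    } else {
      lives <- c(lives, run * spacing)
      run <- 1
    }
  }
  c(lives, run * spacing)
}

# a small hand-positioned frame: two waters plus naming helpers
two_water_frame <- function(o_o_dist = 2.8, linear = TRUE) {
  # water 1 donates along +x toward water 2
  h1x <- if (linear) 0.96 else -0.96
  atoms <- data.frame(
    atom = c("OW", "HW1", "HW2", "OW", "HW1", "HW2"),
    element = c("O", "H", "H", "O", "H", "H"),
    resid = c(1, 1, 1, 2, 2, 2), kind = "water",
    x = c(10, 10 + h1x, 9.76, 10 + o_o_dist, 10 + o_o_dist + 0.96,
          10 + o_o_dist - 0.24),
    y = c(10, 10, 10.93, 10, 10, 10.93),
    z = 10)
  trajectory_frame(atoms, box = c(50, 50, 50))
}
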