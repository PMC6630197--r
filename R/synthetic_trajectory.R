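# Toy bilayer/water trajectory generator with planted ground truth.
#
# The generator builds a geometrically explicit "stated world": rigid
# pseudo-lipid headgroup scaffolds (sites P, O1..O8, N plus one amine
# hydrogen HN; no acyl chains) on two leaflets of an orthorhombic box, and
# 3-site waters parked on sparse grids in the two aqueous regions. Planted
# events (water bridges, direct lipid-lipid contacts, single lipid-water
# H-bonds) are realized by exact coordinate construction with wide safety
# margins: every planted bond satisfies the default geometric criteria with
# >= 0.3 A distance / >= 10 deg angle to spare, and every non-planted pair
# misses the distance cutoff by >= 1 A, so a correct detector must recover
# exactly the planted set.

LIPID_LABELS <- c("P", paste0("O", 1:8), "N")

# Anchor grid: per-leaflet square lattice, 10 A pitch.
lipid_grid <- function(n_lipids, box = c(100, 90, 90)) {
  nx <- floor((box[1] - 10) / 10)
  ny <- floor((box[2] - 10) / 10)
  per_leaflet <- nx * ny
  if (n_lipids > 2 * per_leaflet)
    stop("gen_toy_trajectory: too many lipids for the box")
  n_lower <- ceiling(n_lipids / 2)
  out <- data.frame(resid = seq_len(n_lipids))
  idx <- function(k) c(x = 10 * ((k - 1) %% nx) + 10,
                       y = 10 * ((k - 1) %/% nx) + 10)
  pos <- t(vapply(seq_len(n_lipids), function(r) {
    k <- if (r <= n_lower) r else r - n_lower
    idx(k)
  }, c(x = 0, y = 0)))
  out$x <- pos[, "x"]; out$y <- pos[, "y"]
  out$leaflet <- ifelse(out$resid <= n_lower, "lower", "upper")
  out$z0 <- ifelse(out$leaflet == "lower", 30, 60)
  out$coldir <- ifelse(out$leaflet == "lower", 1, -1)  # toward interior
  out
}

grid_adjacent <- function(grid, i, j) {
  gi <- grid[grid$resid == i, ]; gj <- grid[grid$resid == j, ]
  gi$leaflet == gj$leaflet &&
    abs(gi$x - gj$x) + abs(gi$y - gj$y) == 10
}

#' Plant specification for the toy trajectory generator
#'
#' Each component is a data frame of planted event intervals. `bridges`:
#' columns `water`, `lipid_i`, `label_i`, `lipid_j`, `label_j`,
#' `first_frame`, `last_frame` (a single water H-bonded to one O-site of
#' each lipid during the interval; several rows with the same key give
#' several lifetimes). `contacts`: columns `lipid_i` (donor via its N-H),
#' `lipid_j`, `label_j` (acceptor O-site), `first_frame`, `last_frame`.
#' `hbonds`: columns `water`, `lipid_i`, `label_i`, `lipid_j` (an adjacent
#' lipid that only fixes the geometric direction; no bond to it),
#' `first_frame`, `last_frame` (a single lipid-water bond, no bridge).
#'
#' Constraints (checked by [gen_toy_trajectory()]): every event's lipid
#' pair (including the `hbond` direction pair) must be lattice-adjacent
#' within one leaflet, each unordered lipid pair hosts at most one planted
#' event, each (lipid, label) target site and each water is used by at most
#' one event, and each lipid donates at most one contact.
#'
#' @param bridges,contacts,hbonds Data frames as described (or NULL).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(bridges = NULL, contacts = NULL, hbonds = NULL) {
  empty_iv <- function(cols) {
    as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
  }
  if (is.null(bridges))
    bridges <- empty_iv(c("water", "lipid_i", "label_i", "lipid_j",
                          "label_j", "first_frame", "last_frame"))
  if (is.null(contacts))
    contacts <- empty_iv(c("lipid_i", "lipid_j", "label_j",
                           "first_frame", "last_frame"))
  if (is.null(hbonds))
    hbonds <- empty_iv(c("water", "lipid_i", "label_i", "lipid_j",
                         "first_frame", "last_frame"))
  structure(list(bridges = bridges, contacts = contacts, hbonds = hbonds),
            class = "plant_spec")
}

#' Random feasible plant specification
#'
#' Samples lattice-adjacent lipid pairs without replacement and assigns
#' each a bridge, contact or single H-bond with one or two active
#' intervals, respecting all [plant_spec()] constraints.
#'
#' @param n_lipids,n_waters,n_frames System dimensions.
#' @param n_bridges,n_contacts,n_hbonds Event counts.
#' @param seed Integer RNG seed.
#' @param box Box edges, Angstrom.
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(n_lipids, n_waters, n_frames,
                              n_bridges = 3, n_contacts = 2, n_hbonds = 1,
                              seed = 1L, box = c(100, 90, 90)) {
  local_rng(seed, {
    grid <- lipid_grid(n_lipids, box)
    pairs <- list()
    for (i in seq_len(n_lipids)) for (j in seq_len(n_lipids)) {
      if (i < j && grid_adjacent(grid, i, j))
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
    n_events <- n_bridges + n_contacts + n_hbonds
    if (length(pairs) < n_events)
      stop("random_plant_spec: not enough adjacent lipid pairs")
    if (n_waters < n_bridges + n_hbonds)
      stop("random_plant_spec: not enough waters")
    pick <- sample(length(pairs), n_events)
    chosen <- pairs[pick]
    waters <- sample(n_waters, n_bridges + n_hbonds)
    used_site <- character(0)
    fresh_site <- function(lipid) {
      free <- setdiff(paste(lipid, paste0("O", 1:8)), used_site)
      s <- if (length(free) == 1) free else sample(free, 1)
      used_site <<- c(used_site, s)
      sub(".* ", "", s)
    }
    intervals <- function() {
      # one or two non-touching intervals inside 1..n_frames
      l1 <- sample(seq_len(max(1, min(4, n_frames - 1))), 1)
      s1 <- sample(seq_len(n_frames - l1 + 1), 1)
      iv <- data.frame(first_frame = s1, last_frame = s1 + l1 - 1)
      room <- n_frames - (s1 + l1 + 1)
      if (room >= 1 && stats::runif(1) < 0.5) {
        l2 <- sample(seq_len(min(3, room)), 1)
        s2 <- s1 + l1 + 2
        iv <- rbind(iv, data.frame(first_frame = s2,
                                   last_frame = s2 + l2 - 1))
      }
      iv
    }
    br <- list(); ct <- list(); hb <- list()
    ev <- 0L; wat <- 0L
    donor_used <- integer(0)
    for (b in seq_len(n_bridges)) {
      ev <- ev + 1L; wat <- wat + 1L
      p <- chosen[[ev]]
      iv <- intervals()
      br[[b]] <- data.frame(water = waters[wat], lipid_i = p[1],
                            label_i = fresh_site(p[1]), lipid_j = p[2],
                            label_j = fresh_site(p[2]), iv)
    }
    for (cc in seq_len(n_contacts)) {
      ev <- ev + 1L
      p <- chosen[[ev]]
      donor <- if (p[1] %in% donor_used) p[2] else p[1]
      if (donor %in% donor_used)
        stop("random_plant_spec: cannot place contact donor")
      donor_used <- c(donor_used, donor)
      accept <- setdiff(p, donor)
      iv <- intervals()
      ct[[cc]] <- data.frame(lipid_i = donor, lipid_j = accept,
                             label_j = fresh_site(accept), iv)
    }
    for (h in seq_len(n_hbonds)) {
      ev <- ev + 1L; wat <- wat + 1L
      p <- chosen[[ev]]
      iv <- intervals()
      hb[[h]] <- data.frame(water = waters[wat], lipid_i = p[1],
                            label_i = fresh_site(p[1]), lipid_j = p[2], iv)
    }
    plant_spec(bridges = if (length(br)) do.call(rbind, br) else NULL,
               contacts = if (length(ct)) do.call(rbind, ct) else NULL,
               hbonds = if (length(hb)) do.call(rbind, hb) else NULL)
  })
}

validate_plant <- function(plant, grid, n_lipids, n_waters, n_frames) {
  b <- plant$bridges; ct <- plant$contacts; hb <- plant$hbonds
  all_iv <- rbind(b[c("first_frame", "last_frame")],
                  ct[c("first_frame", "last_frame")],
                  hb[c("first_frame", "last_frame")])
  if (nrow(all_iv) > 0 &&
      (any(all_iv$first_frame < 1) || any(all_iv$last_frame > n_frames) ||
       any(all_iv$first_frame > all_iv$last_frame)))
    stop("gen_toy_trajectory: planted intervals outside 1..n_frames")
  paste0_safe <- function(...) {
    args <- list(...)
    if (any(lengths(args) == 0)) character(0) else do.call(paste, args)
  }
  pair_of <- c(paste0_safe(pmin(b$lipid_i, b$lipid_j),
                           pmax(b$lipid_i, b$lipid_j)),
               paste0_safe(pmin(ct$lipid_i, ct$lipid_j),
                           pmax(ct$lipid_i, ct$lipid_j)),
               paste0_safe(pmin(hb$lipid_i, hb$lipid_j),
                           pmax(hb$lipid_i, hb$lipid_j)))
  keys <- c(paste0_safe("b", b$water, b$lipid_i, b$label_i, b$lipid_j,
                        b$label_j),
            paste0_safe("c", ct$lipid_i, ct$lipid_j, ct$label_j),
            paste0_safe("h", hb$water, hb$lipid_i, hb$label_i))
  if (length(keys)) {
    per_pair <- tapply(keys, pair_of, function(k) length(unique(k)))
    if (any(per_pair > 1))
      stop("gen_toy_trajectory: a lipid pair hosts more than one event")
  }
  lipids_used <- c(b$lipid_i, b$lipid_j, ct$lipid_i, ct$lipid_j,
                   hb$lipid_i, hb$lipid_j)
  if (length(lipids_used) &&
      (max(lipids_used) > n_lipids || min(lipids_used) < 1))
    stop("gen_toy_trajectory: event references an unknown lipid")
  waters_used <- c(b$water, hb$water)
  if (length(waters_used) &&
      (max(waters_used) > n_waters || min(waters_used) < 1))
    stop("gen_toy_trajectory: event references an unknown water")
  wkey <- unique(data.frame(
    w = c(b$water, hb$water),
    k = c(paste0_safe("b", b$lipid_i, b$lipid_j),
          paste0_safe("h", hb$lipid_i, hb$label_i))))
  if (nrow(wkey) && anyDuplicated(wkey$w))
    stop("gen_toy_trajectory: a water is shared between events")
  sites <- c(paste(b$lipid_i, b$label_i), paste(b$lipid_j, b$label_j),
             paste(ct$lipid_j, ct$label_j), paste(hb$lipid_i, hb$label_i))
  site_event <- c(rep(keys[seq_len(nrow(b))], 2),
                  keys[nrow(b) + seq_len(nrow(ct))],
                  keys[nrow(b) + nrow(ct) + seq_len(nrow(hb))])
  if (length(sites)) {
    tab <- tapply(site_event, sites, function(k) length(unique(k)))
    if (any(tab > 1))
      stop("gen_toy_trajectory: a (lipid, label) site is used by two events")
    bad_lab <- setdiff(unique(sub(".* ", "", sites)), paste0("O", 1:8))
    if (length(bad_lab))
      stop("gen_toy_trajectory: target labels must be O1..O8")
  }
  if (nrow(ct)) {
    donors <- unique(ct[c("lipid_i", "lipid_j", "label_j")])$lipid_i
    if (anyDuplicated(donors))
      stop("gen_toy_trajectory: a lipid donates more than one contact")
  }
  check_adj <- function(i, j) {
    if (!grid_adjacent(grid, i, j))
      stop("gen_toy_trajectory: event lipids are not adjacent in a leaflet")
  }
  for (r in seq_len(nrow(b))) check_adj(b$lipid_i[r], b$lipid_j[r])
  for (r in seq_len(nrow(ct))) check_adj(ct$lipid_i[r], ct$lipid_j[r])
  for (r in seq_len(nrow(hb))) check_adj(hb$lipid_i[r], hb$lipid_j[r])
  invisible(TRUE)
}

# Merge interval rows of one event key and return the sorted intervals.
merge_intervals <- function(first, last) {
  o <- order(first)
  first <- first[o]; last <- last[o]
  out <- list(c(first[1], last[1]))
  for (r in seq_along(first)[-1]) {
    cur <- out[[length(out)]]
    if (first[r] <= cur[2] + 1) {
      out[[length(out)]] <- c(cur[1], max(cur[2], last[r]))
    } else {
      out[[length(out) + 1L]] <- c(first[r], last[r])
    }
  }
  do.call(rbind, out)
}

#' Generate a toy bilayer/water trajectory with planted ground truth
#'
#' Builds `n_frames` frames at `frame_spacing` ps in an orthorhombic box
#' (default 100 x 90 x 90 A) containing rigid pseudo-lipid headgroups on two
#' leaflets and 3-site waters, constructed so that exactly the planted
#' hydrogen bonds, water bridges and lipid-lipid contacts of `plant` are
#' present in their active frames (with >= 0.3 A / >= 10 deg margin) and
#' nothing else comes within 1 A of the default criteria. Waters not
#' involved in an active event are parked on sparse grids in the two
#' aqueous slabs (small seeded jitter, margins preserved).
#'
#' @param n_lipids,n_waters Counts (`n_lipids` >= 1, `n_waters` >= 0).
#' @param plant A [plant_spec()] (default: no planted events).
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed (parked-water jitter only; the planted
#'   geometry is deterministic).
#' @param box Box edges, Angstrom.
#' @param frame_spacing Frame spacing, ps (default 50).
#' @return List with `trajectory` (a [trajectory()]) and `truth`, a list of
#'   data frames mirroring the analyzer outputs exactly: `hbonds`
#'   (donor/acceptor records per active frame), `bridges`, `contacts`, and
#'   `lifetimes` (per-key multisets at gap tolerance 0: `$bridges` and
#'   `$contacts` with columns `key`, `lifetime_ps`).
#' @export
#' @examples
#' pl <- plant_spec(bridges = data.frame(
#'   water = 1, lipid_i = 1, label_i = "O2", lipid_j = 2, label_j = "O1",
#'   first_frame = 1, last_frame = 3))
#' toy <- gen_toy_trajectory(4, 6, pl, n_frames = 10)
#' toy$truth$lifetimes$bridges  # one lifetime of 150 ps
gen_toy_trajectory <- function(n_lipids, n_waters, plant = plant_spec(),
                               n_frames = 10, seed = 1L,
                               box = c(100, 90, 90), frame_spacing = 50) {
  if (n_lipids < 1 || n_waters < 0 || n_frames < 1)
    stop("gen_toy_trajectory: counts must be positive")
  stopifnot(inherits(plant, "plant_spec"))
  grid <- lipid_grid(n_lipids, box)
  validate_plant(plant, grid, n_lipids, n_waters, n_frames)

  # --- static lipid scaffold ------------------------------------------------
  lipid_atoms <- do.call(rbind, lapply(seq_len(n_lipids), function(r) {
    g <- grid[grid$resid == r, ]
    dz <- c(0, 1:8, 9, 10) * g$coldir
    data.frame(atom = c(LIPID_LABELS, "HN"),
               element = c("P", rep("O", 8), "N", "H"),
               resid = r, kind = "lipid", leaflet = g$leaflet,
               x = g$x, y = g$y, z = g$z0 + dz)
  }))
  rownames(lipid_atoms) <- NULL

  # parked water slots on sparse grids in the two aqueous slabs
  slot_grid <- function(zs) {
    expand.grid(x = seq(5, box[1] - 5, by = 6),
                y = seq(5, box[2] - 5, by = 6), z = zs)
  }
  slots <- rbind(slot_grid(c(8, 14, 20)), slot_grid(c(70, 76, 82)))
  if (n_waters > nrow(slots))
    stop("gen_toy_trajectory: too many waters for the box")
  jit <- local_rng(seed, matrix(stats::runif(3 * max(1, n_waters),
                                             -0.1, 0.1), ncol = 3))
  park <- slots[seq_len(n_waters), , drop = FALSE] +
    jit[seq_len(n_waters), , drop = FALSE]

  anchor <- function(r) unname(unlist(grid[grid$resid == r,
                                           c("x", "y", "z0")]))
  uvec <- function(ri, rj) {
    d <- anchor(rj)[1:2] - anchor(ri)[1:2]
    d / sqrt(sum(d^2))
  }
  move_site <- function(atoms, lipid, label, pos) {
    i <- which(atoms$resid == lipid & atoms$kind == "lipid" &
                 atoms$atom == label)
    atoms$x[i] <- pos[1]; atoms$y[i] <- pos[2]; atoms$z[i] <- pos[3]
    atoms
  }

  # --- per-event geometry (one entry per event key) -------------------------
  key_b <- if (nrow(plant$bridges))
    paste(plant$bridges$water, plant$bridges$lipid_i, plant$bridges$label_i,
          plant$bridges$lipid_j, plant$bridges$label_j) else character(0)
  key_h <- if (nrow(plant$hbonds))
    paste(plant$hbonds$water, plant$hbonds$lipid_i,
          plant$hbonds$label_i) else character(0)
  key_c <- if (nrow(plant$contacts))
    paste(plant$contacts$lipid_i, plant$contacts$lipid_j,
          plant$contacts$label_j) else character(0)

  plant_geo <- list()
  for (k in unique(key_b)) {
    rows <- plant$bridges[key_b == k, ]
    pb <- rows[1, ]
    ai <- anchor(pb$lipid_i); aj <- anchor(pb$lipid_j)
    u <- uvec(pb$lipid_i, pb$lipid_j)
    mid <- c((ai[1:2] + aj[1:2]) / 2, ai[3])
    lipid_atoms <- move_site(lipid_atoms, pb$lipid_i, pb$label_i,
                             mid - c(2.75 * u, 0))
    lipid_atoms <- move_site(lipid_atoms, pb$lipid_j, pb$label_j,
                             mid + c(2.75 * u, 0))
    plant_geo[[length(plant_geo) + 1L]] <- list(
      type = "bridge", row = pb, water = pb$water, o = mid,
      h1 = mid - c(0.96 * u, 0), h2 = mid + c(0.96 * u, 0),
      intervals = merge_intervals(rows$first_frame, rows$last_frame))
  }
  for (k in unique(key_h)) {
    rows <- plant$hbonds[key_h == k, ]
    ph <- rows[1, ]
    ai <- anchor(ph$lipid_i)
    u <- uvec(ph$lipid_i, ph$lipid_j)
    mid <- c(ai[1:2] + 5 * u, ai[3])
    lipid_atoms <- move_site(lipid_atoms, ph$lipid_i, ph$label_i,
                             mid - c(2.75 * u, 0))
    plant_geo[[length(plant_geo) + 1L]] <- list(
      type = "hbond", row = ph, water = ph$water, o = mid,
      h1 = mid - c(0.96 * u, 0), h2 = mid + c(0.96 * u, 0),
      intervals = merge_intervals(rows$first_frame, rows$last_frame))
  }
  contact_geo <- list()
  for (k in unique(key_c)) {
    rows <- plant$contacts[key_c == k, ]
    pc <- rows[1, ]
    ai <- anchor(pc$lipid_i); aj <- anchor(pc$lipid_j)
    u <- uvec(pc$lipid_i, pc$lipid_j)
    lipid_atoms <- move_site(lipid_atoms, pc$lipid_j, pc$label_j,
                             c(aj[1:2] - 3.5 * u, aj[3]))
    contact_geo[[length(contact_geo) + 1L]] <- list(
      row = pc,
      n_active = c(ai[1:2] + 3.5 * u, ai[3]),
      h_active = c(ai[1:2] + 4.5 * u, ai[3]),
      intervals = merge_intervals(rows$first_frame, rows$last_frame))
  }

  water_template <- function(w, o, h1, h2) {
    data.frame(atom = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
               resid = w, kind = "water", leaflet = NA_character_,
               x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
               z = c(o[3], h1[3], h2[3]))
  }
  active_in <- function(iv, f) any(f >= iv[, 1] & f <= iv[, 2])

  # --- frames and per-frame truth -------------------------------------------
  frames <- vector("list", n_frames)
  truth_hb <- list(); truth_br <- list(); truth_ct <- list()
  for (f in seq_len(n_frames)) {
    atoms <- lipid_atoms
    for (cg in contact_geo) {
      pc <- cg$row
      if (active_in(cg$intervals, f)) {
        atoms <- move_site(atoms, pc$lipid_i, "N", cg$n_active)
        atoms <- move_site(atoms, pc$lipid_i, "HN", cg$h_active)
        li <- min(pc$lipid_i, pc$lipid_j)
        lj <- max(pc$lipid_i, pc$lipid_j)
        truth_ct[[length(truth_ct) + 1L]] <- data.frame(
          lipid_i = li, lipid_j = lj,
          label_i = if (li == pc$lipid_i) "N" else pc$label_j,
          label_j = if (li == pc$lipid_i) pc$label_j else "N",
          frame = f)
        truth_hb[[length(truth_hb) + 1L]] <- data.frame(
          donor_atom = "N", donor_res = pc$lipid_i, donor_kind = "lipid",
          acceptor_atom = pc$label_j, acceptor_res = pc$lipid_j,
          acceptor_kind = "lipid", frame = f)
      }
    }
    placed <- rep(FALSE, n_waters)
    wrows <- list()
    for (pg in plant_geo) {
      if (active_in(pg$intervals, f)) {
        wrows[[length(wrows) + 1L]] <-
          water_template(pg$water, pg$o, pg$h1, pg$h2)
        placed[pg$water] <- TRUE
        if (pg$type == "bridge") {
          pb <- pg$row
          li <- min(pb$lipid_i, pb$lipid_j)
          lj <- max(pb$lipid_i, pb$lipid_j)
          truth_br[[length(truth_br) + 1L]] <- data.frame(
            water = pb$water, lipid_i = li, lipid_j = lj,
            label_i = if (li == pb$lipid_i) pb$label_i else pb$label_j,
            label_j = if (li == pb$lipid_i) pb$label_j else pb$label_i,
            frame = f)
          truth_hb[[length(truth_hb) + 1L]] <- data.frame(
            donor_atom = "OW", donor_res = pb$water, donor_kind = "water",
            acceptor_atom = c(pb$label_i, pb$label_j),
            acceptor_res = c(pb$lipid_i, pb$lipid_j),
            acceptor_kind = "lipid", frame = f)
        } else {
          ph <- pg$row
          truth_hb[[length(truth_hb) + 1L]] <- data.frame(
            donor_atom = "OW", donor_res = ph$water, donor_kind = "water",
            acceptor_atom = ph$label_i, acceptor_res = ph$lipid_i,
            acceptor_kind = "lipid", frame = f)
        }
      }
    }
    for (w in which(!placed)) {
      o <- unname(unlist(park[w, ]))
      wrows[[length(wrows) + 1L]] <-
        water_template(w, o, o + c(0.96, 0, 0), o + c(-0.24, 0.93, 0))
    }
    all_atoms <- atoms
    if (length(wrows)) {
      wat <- do.call(rbind, wrows)
      wat <- wat[order(wat$resid), , drop = FALSE]
      all_atoms <- rbind(all_atoms, wat)
    }
    rownames(all_atoms) <- NULL
    frames[[f]] <- trajectory_frame(all_atoms, box, frame_index = f,
                                    time_ps = (f - 1) * frame_spacing)
  }

  bind_or_empty <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    } else proto
  }
  truth_hbonds <- bind_or_empty(truth_hb, data.frame(
    donor_atom = character(0), donor_res = integer(0),
    donor_kind = character(0), acceptor_atom = character(0),
    acceptor_res = integer(0), acceptor_kind = character(0),
    frame = integer(0)))
  truth_bridges <- bind_or_empty(truth_br, empty_bridges())
  truth_contacts <- bind_or_empty(truth_ct, empty_contacts())

  # lifetimes straight from the merged planted intervals (gap tolerance 0)
  lt_b <- list()
  for (pg in plant_geo) {
    if (pg$type != "bridge") next
    pb <- pg$row
    li <- min(pb$lipid_i, pb$lipid_j); lj <- max(pb$lipid_i, pb$lipid_j)
    key <- paste(pb$water, li, lj,
                 if (li == pb$lipid_i) pb$label_i else pb$label_j,
                 if (li == pb$lipid_i) pb$label_j else pb$label_i,
                 sep = "|")
    lt_b[[length(lt_b) + 1L]] <- data.frame(
      key = key,
      lifetime_ps = (pg$intervals[, 2] - pg$intervals[, 1] + 1) *
        frame_spacing)
  }
  lt_c <- list()
  for (cg in contact_geo) {
    pc <- cg$row
    li <- min(pc$lipid_i, pc$lipid_j); lj <- max(pc$lipid_i, pc$lipid_j)
    key <- paste(li, lj,
                 if (li == pc$lipid_i) "N" else pc$label_j,
                 if (li == pc$lipid_i) pc$label_j else "N", sep = "|")
    lt_c[[length(lt_c) + 1L]] <- data.frame(
      key = key,
      lifetime_ps = (cg$intervals[, 2] - cg$intervals[, 1] + 1) *
        frame_spacing)
  }
  empty_lt <- data.frame(key = character(0), lifetime_ps = numeric(0))
  truth <- list(hbonds = truth_hbonds, bridges = truth_bridges,
                contacts = truth_contacts,
                lifetimes = list(bridges = bind_or_empty(lt_b, empty_lt),
                                 contacts = bind_or_empty(lt_c, empty_lt)))
  list(trajectory = trajectory(frames, frame_spacing = frame_spacing),
       truth = truth, plant = plant, grid = grid)
}
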