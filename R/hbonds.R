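#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair (heavy atoms O or N) forms a hydrogen bond when the
#' (minimum-image) donor-acceptor distance is at most `d_max` and the
#' D-H...A angle at the hydrogen is at least `angle_min` for at least one
#' hydrogen attached to the donor. The reference analysis used an unstated
#' energy-based criterion; this geometric criterion is the package's
#' documented stand-in and both thresholds are configurable.
#'
#' @param d_max Maximum donor-acceptor distance, Angstrom (default 3.5).
#' @param angle_min Minimum D-H...A angle, degrees (default 135).
#' @param pbc Apply minimum-image convention on the orthorhombic box
#'   (default TRUE).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 135, pbc = TRUE) {
  if (!is.finite(d_max) || d_max <= 0)
    stop("hbond_criteria: d_max must be > 0")
  if (!is.finite(angle_min) || angle_min <= 0 || angle_min > 180)
    stop("hbond_criteria: angle_min must be in (0, 180]")
  structure(list(d_max = d_max, angle_min = angle_min, pbc = isTRUE(pbc)),
            class = "hbond_criteria")
}

# Minimum-image displacement components for an orthorhombic box.
min_image <- function(d, L) d - L * round(d / L)

# Assign each hydrogen to its parent heavy atom: the nearest non-hydrogen
# atom of the same residue (same resid AND kind) within bond_max Angstrom.
assign_hydrogens <- function(frame, bond_max = 1.3) {
  a <- frame$atoms
  hy <- which(a$element == "H")
  if (length(hy) == 0)
    return(data.frame(h = integer(0), parent = integer(0)))
  heavy <- which(a$element != "H")
  parent <- integer(length(hy))
  for (k in seq_along(hy)) {
    i <- hy[k]
    cand <- heavy[a$resid[heavy] == a$resid[i] & a$kind[heavy] == a$kind[i]]
    if (length(cand) == 0) {
      parent[k] <- NA_integer_
      next
    }
    dx <- min_image(a$x[cand] - a$x[i], frame$box[1])
    dy <- min_image(a$y[cand] - a$y[i], frame$box[2])
    dz <- min_image(a$z[cand] - a$z[i], frame$box[3])
    d2 <- dx^2 + dy^2 + dz^2
    j <- which.min(d2)
    parent[k] <- if (d2[j] <= bond_max^2) cand[j] else NA_integer_
  }
  data.frame(h = hy, parent = parent)
}

#' Detect hydrogen bonds in one trajectory frame
#'
#' Donors are O/N heavy atoms with at least one covalently attached hydrogen
#' (hydrogens are assigned to the nearest heavy atom of their residue);
#' acceptors are all O/N heavy atoms of *other* residues. Every (donor,
#' acceptor) pair satisfying the criteria is returned once per direction of
#' donation. Water oxygens without hydrogens raise a topology error.
#'
#' @param frame A [trajectory_frame()].
#' @param criteria An [hbond_criteria()].
#' @return Data frame with one row per bond: `donor_atom`, `donor_res`,
#'   `donor_kind`, `acceptor_atom`, `acceptor_res`, `acceptor_kind`,
#'   `frame`.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  stopifnot(inherits(frame, "trajectory_frame"),
            inherits(criteria, "hbond_criteria"))
  a <- frame$atoms
  box <- frame$box
  if (!criteria$pbc) box <- c(Inf, Inf, Inf)
  hmap <- assign_hydrogens(frame)
  if (any(is.na(hmap$parent)))
    stop("detect_hbonds: hydrogen without a parent heavy atom (topology error)")
  water_o <- which(a$element == "O" & a$kind == "water")
  if (length(water_o) > 0 && !all(water_o %in% hmap$parent))
    stop("detect_hbonds: water oxygen without hydrogens (topology error)")

  donors <- sort(unique(hmap$parent[a$element[hmap$parent] %in% c("O", "N")]))
  acceptors <- which(a$element %in% c("O", "N"))
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(data.frame(donor_atom = character(0), donor_res = integer(0),
                      donor_kind = character(0),
                      acceptor_atom = character(0),
                      acceptor_res = integer(0),
                      acceptor_kind = character(0), frame = integer(0)))
  }
  dx <- min_image(outer(a$x[donors], a$x[acceptors], "-"), box[1])
  dy <- min_image(outer(a$y[donors], a$y[acceptors], "-"), box[2])
  dz <- min_image(outer(a$z[donors], a$z[acceptors], "-"), box[3])
  within <- which(dx^2 + dy^2 + dz^2 <= criteria$d_max^2, arr.ind = TRUE)
  di <- donors[within[, 1]]
  ai <- acceptors[within[, 2]]
  # drop pairs within the same residue (same resid and kind)
  keep <- !(a$resid[di] == a$resid[ai] & a$kind[di] == a$kind[ai])
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) {
    return(data.frame(donor_atom = character(0), donor_res = integer(0),
                      donor_kind = character(0),
                      acceptor_atom = character(0),
                      acceptor_res = integer(0),
                      acceptor_kind = character(0), frame = integer(0)))
  }
  # expand candidate pairs over the hydrogens of each donor
  hs_of <- split(hmap$h, hmap$parent)
  hlist <- hs_of[as.character(di)]
  nh <- lengths(hlist)
  pd <- rep(di, nh); pa <- rep(ai, nh); ph <- unlist(hlist, use.names = FALSE)
  hdx <- min_image(a$x[pd] - a$x[ph], box[1])
  hdy <- min_image(a$y[pd] - a$y[ph], box[2])
  hdz <- min_image(a$z[pd] - a$z[ph], box[3])
  adx <- min_image(a$x[pa] - a$x[ph], box[1])
  ady <- min_image(a$y[pa] - a$y[ph], box[2])
  adz <- min_image(a$z[pa] - a$z[ph], box[3])
  dotp <- hdx * adx + hdy * ady + hdz * adz
  nn <- sqrt((hdx^2 + hdy^2 + hdz^2) * (adx^2 + ady^2 + adz^2))
  ang <- acos(pmin(1, pmax(-1, dotp / nn))) * 180 / pi
  ok <- ang >= criteria$angle_min
  if (!any(ok)) {
    return(data.frame(donor_atom = character(0), donor_res = integer(0),
                      donor_kind = character(0),
                      acceptor_atom = character(0),
                      acceptor_res = integer(0),
                      acceptor_kind = character(0), frame = integer(0)))
  }
  key <- paste(pd[ok], pa[ok])
  first <- !duplicated(key)
  d_idx <- pd[ok][first]; a_idx <- pa[ok][first]
  out <- data.frame(donor_atom = a$atom[d_idx], donor_res = a$resid[d_idx],
                    donor_kind = a$kind[d_idx],
                    acceptor_atom = a$atom[a_idx],
                    acceptor_res = a$resid[a_idx],
                    acceptor_kind = a$kind[a_idx],
                    frame = frame$frame_index)
  out[order(out$donor_kind, out$donor_res, out$donor_atom,
            out$acceptor_kind, out$acceptor_res, out$acceptor_atom), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds across all frames of a trajectory
#'
#' @param traj A [trajectory()].
#' @inheritParams detect_hbonds
#' @return Row-bound data frame of per-frame [detect_hbonds()] results.
#' @export
detect_hbonds_trajectory <- function(traj, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "toy_trajectory"))
  do.call(rbind, lapply(traj, detect_hbonds, criteria = criteria))
}
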