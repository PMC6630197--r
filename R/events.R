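empty_bridges <- function() {
  data.frame(water = integer(0), lipid_i = integer(0), lipid_j = integer(0),
             label_i = character(0), label_j = character(0),
             frame = integer(0))
}

empty_contacts <- function() {
  data.frame(lipid_i = integer(0), lipid_j = integer(0),
             label_i = character(0), label_j = character(0),
             frame = integer(0))
}

apply_label_map <- function(labels, label_map) {
  if (is.null(label_map)) return(labels)
  mapped <- label_map[labels]
  ifelse(is.na(mapped), labels, unname(mapped))
}

#' Default headgroup atom-label map
#'
#' Identity map over the numbered headgroup oxygens `O1`..`O8` and the `N`
#' and `P` sites, mimicking the conventional numbering of PC/PE headgroup
#' oxygens. The assignment of chemical oxygens to numbers is a documented
#' convention of this package, configurable via the `label_map` arguments.
#'
#' @return Named character vector mapping atom names to labels.
#' @export
default_label_map <- function() {
  labs <- c(paste0("O", 1:8), "N", "P")
  stats::setNames(labs, labs)
}

#' Water bridges from a frame's hydrogen bonds
#'
#' A water bridge is a single water molecule hydrogen-bonded (as donor or
#' acceptor) to atoms of two *different* lipid molecules in the same frame.
#' One event is reported per (water, unordered lipid pair); a water bonded
#' twice to the same lipid yields no bridge. When a water is bonded to a
#' lipid through several atoms the lexicographically smallest label
#' represents that side of the bridge.
#'
#' @param bonds Hydrogen-bond table from [detect_hbonds()] (a single frame).
#' @param frame Optional [trajectory_frame()]; only used to sanity-check
#'   that the bonds belong to this frame.
#' @param label_map Optional named vector renaming lipid atom labels
#'   (default [default_label_map()] semantics: names pass through).
#' @return Data frame with columns `water`, `lipid_i`, `lipid_j` (with
#'   `lipid_i < lipid_j`), `label_i`, `label_j`, `frame`.
#' @export
find_water_bridges <- function(bonds, frame = NULL, label_map = NULL) {
  if (!is.null(frame) && nrow(bonds) > 0 &&
      any(bonds$frame != frame$frame_index))
    stop("find_water_bridges: bonds do not belong to the given frame")
  if (nrow(bonds) == 0) return(empty_bridges())
  # normalize every water-lipid bond to (water res, lipid res, lipid label)
  wl <- bonds[bonds$donor_kind == "water" & bonds$acceptor_kind == "lipid", ]
  lw <- bonds[bonds$donor_kind == "lipid" & bonds$acceptor_kind == "water", ]
  links <- rbind(
    data.frame(water = wl$donor_res, lipid = wl$acceptor_res,
               label = wl$acceptor_atom, frame = wl$frame),
    data.frame(water = lw$acceptor_res, lipid = lw$donor_res,
               label = lw$donor_atom, frame = lw$frame))
  if (nrow(links) == 0) return(empty_bridges())
  links$label <- apply_label_map(links$label, label_map)
  out <- list()
  for (sp in split(links, list(links$water, links$frame), drop = TRUE)) {
    lipids <- sort(unique(sp$lipid))
    if (length(lipids) < 2) next
    lab_of <- vapply(lipids, function(l) min(sp$label[sp$lipid == l]),
                     character(1))
    pairs <- utils::combn(seq_along(lipids), 2)
    out[[length(out) + 1L]] <- data.frame(
      water = sp$water[1],
      lipid_i = lipids[pairs[1, ]], lipid_j = lipids[pairs[2, ]],
      label_i = lab_of[pairs[1, ]], label_j = lab_of[pairs[2, ]],
      frame = sp$frame[1])
  }
  if (length(out) == 0) return(empty_bridges())
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$water, res$lipid_i, res$lipid_j), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Direct lipid-lipid hydrogen-bond contacts
#'
#' @param bonds Hydrogen-bond table from [detect_hbonds()] or
#'   [detect_hbonds_trajectory()].
#' @param label_map Optional label renaming (see [find_water_bridges()]).
#' @return Data frame with columns `lipid_i`, `lipid_j` (`lipid_i <
#'   lipid_j`), `label_i`, `label_j`, `frame`. Labels follow the residue
#'   ordering, not the donor/acceptor roles.
#' @export
lipid_contacts <- function(bonds, label_map = NULL) {
  ll <- bonds[bonds$donor_kind == "lipid" & bonds$acceptor_kind == "lipid" &
                bonds$donor_res != bonds$acceptor_res, , drop = FALSE]
  if (nrow(ll) == 0) return(empty_contacts())
  swap <- ll$donor_res > ll$acceptor_res
  li <- ifelse(swap, ll$acceptor_res, ll$donor_res)
  lj <- ifelse(swap, ll$donor_res, ll$acceptor_res)
  lab_i <- ifelse(swap, ll$acceptor_atom, ll$donor_atom)
  lab_j <- ifelse(swap, ll$donor_atom, ll$acceptor_atom)
  out <- data.frame(lipid_i = li, lipid_j = lj,
                    label_i = apply_label_map(lab_i, label_map),
                    label_j = apply_label_map(lab_j, label_map),
                    frame = ll$frame)
  out <- unique(out)
  out <- out[order(out$frame, out$lipid_i, out$lipid_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event lifetimes from per-frame presence
#'
#' Groups an event table by key, finds maximal runs of frames in which the
#' event is present (interruptions of at most `gap_tolerance` frames are
#' bridged), and converts each run to a lifetime
#' `(last - first + 1) * frame_spacing` ps.
#'
#' @param events Data frame with a `frame` column (integer frame indices on
#'   a uniform grid) plus key columns identifying each event.
#' @param frame_spacing Time between consecutive frames, ps (default 50).
#' @param gap_tolerance Maximum number of missing frames bridged inside one
#'   run (default 0: strict lifetimes).
#' @param key_cols Columns forming the event key (default: all columns
#'   except `frame`).
#' @return An object of class `duration_distribution`: list with `lifetimes`
#'   (ps, one per run), `runs` (data frame: key, first/last frame,
#'   lifetime), `frame_spacing`, `gap_tolerance`.
#' @export
event_durations <- function(events, frame_spacing = 50, gap_tolerance = 0,
                            key_cols = NULL) {
  if (!is.finite(frame_spacing) || frame_spacing <= 0)
    stop("event_durations: frame_spacing must be > 0")
  if (!"frame" %in% names(events))
    stop("event_durations: events need a frame column")
  if (nrow(events) > 0 && any(events$frame != round(events$frame)))
    stop("event_durations: frames must lie on a uniform integer grid")
  if (is.null(key_cols)) key_cols <- setdiff(names(events), "frame")
  if (nrow(events) == 0) {
    return(structure(list(lifetimes = numeric(0),
                          runs = data.frame(key = character(0),
                                            first_frame = integer(0),
                                            last_frame = integer(0),
                                            lifetime_ps = numeric(0)),
                          frame_spacing = frame_spacing,
                          gap_tolerance = gap_tolerance),
                     class = "duration_distribution"))
  }
  key <- if (length(key_cols) == 0) rep("all", nrow(events))
         else do.call(paste, c(events[key_cols], sep = "|"))
  runs <- list()
  for (k in unique(key)) {
    fr <- sort(unique(events$frame[key == k]))
    brk <- c(TRUE, diff(fr) > gap_tolerance + 1)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      f <- fr[grp == g]
      runs[[length(runs) + 1L]] <- data.frame(
        key = k, first_frame = f[1], last_frame = f[length(f)],
        lifetime_ps = (f[length(f)] - f[1] + 1) * frame_spacing)
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(lifetimes = runs$lifetime_ps, runs = runs,
                 frame_spacing = frame_spacing,
                 gap_tolerance = gap_tolerance),
            class = "duration_distribution")
}

#' @export
print.duration_distribution <- function(x, ...) {
  cat(sprintf(
    "Duration distribution: %d lifetimes (spacing %g ps, gap tolerance %d)\n",
    length(x$lifetimes), x$frame_spacing, x$gap_tolerance))
  if (length(x$lifetimes)) print(summary(x$lifetimes))
  invisible(x)
}

#' Normalized bridge/contact map
#'
#' Counts events per unordered label pair and divides by the total event
#' count, so the map entries are the relative frequency of each pair among
#' all events. Entries are stored once per unordered pair (at the row/column
#' of the alphabetically first label); the raw matrix therefore sums to 1.
#' Use `symmetrize = TRUE` in [map_matrix()] for a mirrored matrix.
#'
#' @param events Data frame with `label_i` and `label_j` columns (from
#'   [find_water_bridges()] or [lipid_contacts()]).
#' @param labels Optional label ordering for the matrix axes (default: the
#'   sorted labels present).
#' @return An object of class `bridge_map`: the normalized matrix with
#'   attributes `n_events` and `empty`.
#' @export
bridge_map <- function(events, labels = NULL) {
  n <- nrow(events)
  if (n == 0) {
    m <- matrix(numeric(0), 0, 0)
    attr(m, "n_events") <- 0L
    attr(m, "empty") <- TRUE
    class(m) <- c("bridge_map", class(m))
    return(m)
  }
  a <- pmin(events$label_i, events$label_j)
  b <- pmax(events$label_i, events$label_j)
  if (is.null(labels)) labels <- sort(unique(c(a, b)))
  if (!all(c(a, b) %in% labels))
    stop("bridge_map: events contain labels outside the given label set")
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  tab <- table(paste(a, b, sep = "\r"))
  ab <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  m[cbind(ab[, 1], ab[, 2])] <- as.numeric(tab) / n
  attr(m, "n_events") <- as.integer(n)
  attr(m, "empty") <- FALSE
  class(m) <- c("bridge_map", class(m))
  m
}

#' Extract the map matrix
#'
#' @param m A [bridge_map()].
#' @param symmetric Mirror entries across the diagonal (off-diagonal pair
#'   frequencies then appear twice; the sum over unique unordered pairs is
#'   still 1).
#' @return A plain numeric matrix.
#' @export
map_matrix <- function(m, symmetric = FALSE) {
  stopifnot(inherits(m, "bridge_map"))
  out <- unclass(m)
  attr(out, "n_events") <- NULL
  attr(out, "empty") <- NULL
  if (symmetric && nrow(out) > 0) {
    low <- lower.tri(out)
    tout <- t(out)
    out[low] <- out[low] + tout[low]
    out[upper.tri(out)] <- t(out)[upper.tri(out)]
  }
  out
}

#' @export
print.bridge_map <- function(x, ...) {
  if (isTRUE(attr(x, "empty"))) {
    cat("Bridge/contact map: EMPTY (no events)\n")
  } else {
    cat(sprintf("Bridge/contact map over %d events (entries sum to 1)\n",
                attr(x, "n_events")))
    print(round(map_matrix(x), 4))
  }
  invisible(x)
}

#' Percent difference between two event counts
#'
#' `(count_B - count_A) / count_A * 100`, the "percent more events in B
#' than in A" comparison used when contrasting bilayers: counts (1000, 2500)
#' give 150 and (1000, 1500) give 50.
#'
#' @param count_A Reference event count (> 0) or event data frame.
#' @param count_B Comparison event count or event data frame.
#' @return Percent difference (unitless).
#' @export
compare_counts <- function(count_A, count_B) {
  if (is.data.frame(count_A)) count_A <- nrow(count_A)
  if (is.data.frame(count_B)) count_B <- nrow(count_B)
  if (!is.finite(count_A) || count_A <= 0)
    stop("compare_counts: reference count must be > 0")
  (count_B - count_A) / count_A * 100
}
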