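#' Single trajectory frame
#'
#' @param atoms Data frame with one row per atom and columns `atom` (name,
#'   e.g. "O1", "OW"), `element` ("O", "N", "P", "H", ...), `resid`
#'   (integer residue id, unique within `kind`), `kind` (one of `"lipid"`,
#'   `"water"`, `"ion"`), optional `leaflet` (`"lower"`/`"upper"`/NA), and
#'   coordinates `x`, `y`, `z` in Angstrom.
#' @param box Orthorhombic box edges `c(Lx, Ly, Lz)` in Angstrom (> 0).
#' @param frame_index Integer frame number.
#' @param time_ps Frame time, ps.
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(atoms, box, frame_index = 1L, time_ps = 0) {
  need <- c("atom", "element", "resid", "kind", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("trajectory_frame: atoms must have columns ",
         paste(need, collapse = ", "))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("trajectory_frame: coordinates must be finite")
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("trajectory_frame: box must be three positive edge lengths")
  if (!all(atoms$kind %in% c("lipid", "water", "ion")))
    stop("trajectory_frame: kind must be lipid, water or ion")
  if (!"leaflet" %in% names(atoms)) atoms$leaflet <- NA_character_
  structure(list(atoms = atoms, box = as.numeric(box),
                 frame_index = as.integer(frame_index),
                 time_ps = as.numeric(time_ps)),
            class = "trajectory_frame")
}

#' Multi-frame trajectory
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param frame_spacing Time between consecutive frames, ps (default 50,
#'   the conventional save interval of the reference bilayer simulations).
#' @return An object of class `toy_trajectory` (a list of frames with
#'   attributes `frame_spacing` and `box`).
#' @export
trajectory <- function(frames, frame_spacing = 50) {
  stopifnot(length(frames) > 0,
            all(vapply(frames, inherits, logical(1), "trajectory_frame")))
  structure(frames, frame_spacing = frame_spacing,
            box = frames[[1]]$box, class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, box %s A, spacing %g ps\n",
              length(x), nrow(x[[1]]$atoms),
              paste(format(attr(x, "box")), collapse = " x "),
              attr(x, "frame_spacing")))
  invisible(x)
}

resname_of_kind <- function(kind) {
  c(lipid = "LIP", water = "HOH", ion = "ION")[kind]
}
kind_of_resname <- function(resname) {
  resname <- toupper(trimws(resname))
  ifelse(resname %in% c("HOH", "WAT", "TIP", "SOL", "SPC"), "water",
         ifelse(resname %in% c("ION", "NA", "CL", "K", "MG", "CA"), "ion",
                "lipid"))
}

#' Write a trajectory as multi-model PDB
#'
#' Fixed-width PDB 3.3 layout: one `CRYST1` record for the orthorhombic box,
#' then `MODEL`/`ATOM`/`ENDMDL` blocks per frame. Residue names encode the
#' residue kind (`LIP`, `HOH`, `ION`); chain IDs `L`, `W`, `I` likewise.
#'
#' @param traj A [trajectory()] (or single [trajectory_frame()]).
#' @param path Output file path.
#' @param header Optional character vector of REMARK lines (without the
#'   REMARK prefix) written after CRYST1.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path, header = NULL) {
  if (inherits(traj, "trajectory_frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "toy_trajectory"))
  box <- attr(traj, "box")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90), con)
  if (!is.null(header))
    writeLines(sprintf("REMARK   3 %s", header), con)
  chain_of_kind <- c(lipid = "L", water = "W", ion = "I")
  for (fr in traj) {
    writeLines(sprintf("MODEL     %4d", fr$frame_index), con)
    a <- fr$atoms
    name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                    sprintf(" %-3s", a$atom))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(a)) - 1L) %% 99999L + 1L, name4,
      resname_of_kind(a$kind), chain_of_kind[a$kind],
      a$resid %% 10000L, a$x, a$y, a$z, 1, 0,
      formatC(a$element, width = 2, flag = " "))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Bit-exact fixed-column parsing of `ATOM`/`HETATM` records (name columns
#' 13-16, resName 18-20, chain 22, resSeq 23-26, coordinates 31-54, element
#' 77-78) with the box taken from `CRYST1`. Residue kinds are inferred from
#' the residue name (`HOH`/`WAT`/`TIP`/`SOL` water, common ion names ion,
#' anything else lipid).
#'
#' @param path PDB file path.
#' @param frame_spacing Frame spacing in ps assigned to the trajectory.
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path, frame_spacing = 50) {
  if (!file.exists(path))
    stop("read_pdb_trajectory: cannot read ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cry <- lines[which(rec == "CRYST1")[1]]
  if (is.na(cry)) stop("read_pdb_trajectory: no CRYST1 record")
  box <- c(as.numeric(substr(cry, 7, 15)), as.numeric(substr(cry, 16, 24)),
           as.numeric(substr(cry, 25, 33)))
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0) {
    # single implicit model
    model_starts <- 1L
    model_ends <- length(lines)
    model_ids <- 1L
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("read_pdb_trajectory: unbalanced MODEL/ENDMDL records")
    model_ids <- as.integer(substr(lines[model_starts], 11, 14))
  }
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    blk <- lines[model_starts[m]:model_ends[m]]
    at <- blk[substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")]
    name <- trimws(substr(at, 13, 16))
    resname <- substr(at, 18, 20)
    resid <- as.integer(substr(at, 23, 26))
    x <- as.numeric(substr(at, 31, 38))
    y <- as.numeric(substr(at, 39, 46))
    z <- as.numeric(substr(at, 47, 54))
    element <- trimws(substr(at, 77, 78))
    element[element == ""] <- substr(name[element == ""], 1, 1)
    kind <- kind_of_resname(resname)
    frames[[m]] <- trajectory_frame(
      data.frame(atom = name, element = element, resid = resid,
                 kind = kind, x = x, y = y, z = z),
      box = box, frame_index = model_ids[m],
      time_ps = (model_ids[m] - 1) * frame_spacing)
  }
  trajectory(frames, frame_spacing = frame_spacing)
}

#' Write a trajectory as XYZ plus a sidecar topology table
#'
#' The XYZ comment line of every frame carries `frame=<i> time_ps=<t>
#' box=<Lx> <Ly> <Lz>`; the topology CSV (columns `atom`, `element`,
#' `resid`, `kind`, `leaflet`) describes the fixed atom order.
#'
#' @param traj A [trajectory()].
#' @param xyz_path Output XYZ path.
#' @param topology_path Output topology CSV path.
#' @return `xyz_path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, xyz_path, topology_path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  box <- attr(traj, "box")
  a0 <- traj[[1]]$atoms
  utils::write.csv(a0[, c("atom", "element", "resid", "kind", "leaflet")],
                   topology_path, row.names = FALSE, quote = FALSE)
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (fr in traj) {
    writeLines(as.character(nrow(fr$atoms)), con)
    writeLines(sprintf("frame=%d time_ps=%.6g box=%.6g %.6g %.6g",
                       fr$frame_index, fr$time_ps, box[1], box[2], box[3]),
               con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", fr$atoms$element,
                       fr$atoms$x, fr$atoms$y, fr$atoms$z), con)
  }
  invisible(xyz_path)
}

#' Read an XYZ trajectory with its sidecar topology table
#'
#' @param xyz_path XYZ path written by [write_xyz_trajectory()] (or any XYZ
#'   whose comment line carries `frame=`, `time_ps=` and `box=` fields).
#' @param topology_path Topology CSV path.
#' @param frame_spacing Frame spacing, ps.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(xyz_path, topology_path, frame_spacing = 50) {
  topo <- utils::read.csv(topology_path, stringsAsFactors = FALSE)
  lines <- readLines(xyz_path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) break
    meta <- lines[i + 1L]
    get_field <- function(key) {
      m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+( [0-9eE+.-]+)*"),
                                    meta))
      sub(paste0(key, "="), "", m)
    }
    fi <- as.integer(get_field("frame"))
    tp <- as.numeric(get_field("time_ps"))
    box <- as.numeric(strsplit(get_field("box"), " ")[[1]])
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "[[:space:]]+"))
    atoms <- topo
    atoms$x <- as.numeric(parts[, 2])
    atoms$y <- as.numeric(parts[, 3])
    atoms$z <- as.numeric(parts[, 4])
    frames[[length(frames) + 1L]] <-
      trajectory_frame(atoms, box, frame_index = fi, time_ps = tp)
    i <- i + 2L + n
  }
  trajectory(frames, frame_spacing = frame_spacing)
}
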