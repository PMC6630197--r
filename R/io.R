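# Delimited-table and flat-config I/O shared by the command-line interface.
# Tables are comma-separated with a header row; '#' lines are comments and
# carry provenance (package version, seed, config hash). Numbers are
# serialized in scientific notation with 12 significant digits so that
# write/read round-trips are stable.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "e"))
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed = NA, config = list()) {
  c(sprintf("# amphisurf %s",
            as.character(utils::packageVersion("amphisurf"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s", config_hash(config)))
}

write_table_with_header <- function(df, path, seed = NA, config = list()) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(out, sep = ",")), con)
  invisible(path)
}

read_table_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a tension table with columns pH, gamma and optionally sigma
#'
#' Comma-separated with a header row; `#` lines are comments.
#'
#' @param path File path.
#' @return A [tension_curve()].
#' @export
read_tension_table <- function(path) {
  df <- read_table_skip_comments(path)
  if (!all(c("pH", "gamma") %in% names(df)))
    stop("read_tension_table: need columns pH and gamma")
  tension_curve(df$pH, df$gamma,
                sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
                label = attr(df, "label") %||% "")
}

#' Write a tension curve as a delimited table
#'
#' @param curve A [tension_curve()].
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_tension_table <- function(curve, path, seed = NA) {
  write_table_with_header(as.data.frame(curve), path, seed = seed,
                          config = list(label = attr(curve, "label")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a bridge/contact map as a labeled CSV matrix
#'
#' @param m A [bridge_map()].
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_bridge_map <- function(m, path, seed = NA) {
  stopifnot(inherits(m, "bridge_map"))
  mat <- map_matrix(m)
  df <- data.frame(label = rownames(mat), mat, check.names = FALSE)
  write_table_with_header(df, path, seed = seed,
                          config = list(n_events = attr(m, "n_events")))
}

#' Read a bridge/contact map written by [write_bridge_map()]
#'
#' @param path File path.
#' @return A [bridge_map()]-like matrix (class restored; `n_events` is not
#'   recoverable from the normalized file and is set to NA).
#' @export
read_bridge_map <- function(path) {
  df <- read_table_skip_comments(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$label
  colnames(mat) <- df$label
  attr(mat, "n_events") <- NA_integer_
  attr(mat, "empty") <- nrow(mat) == 0
  class(mat) <- c("bridge_map", class(mat))
  mat
}

#' Write lifetimes one-per-line
#'
#' @param dd A [event_durations()] result (`duration_distribution`).
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_lifetimes <- function(dd, path, seed = NA) {
  stopifnot(inherits(dd, "duration_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, list(spacing = dd$frame_spacing,
                                          gap = dd$gap_tolerance)), con)
  writeLines(fmt_num(dd$lifetimes), con)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Minimal flat-YAML dialect: one `key: value` pair per line, `#` comments,
#' comma-separated lists, numeric conversion where possible. Dotted keys
#' (`acid.acetic.pKa`) are kept literal.
#'
#' @param path File path.
#' @return Named list of values (numeric vectors where parseable).
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop("read_flat_config: malformed line: ", ln)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    suppressWarnings(nums <- as.numeric(parts))
    out[[key]] <- if (length(parts) && !anyNA(nums)) nums else parts
  }
  out
}

# Buffer recipe from a flat config: keys acid.<name>.conc, acid.<name>.pKa,
# initial_volume, titrant_concentration, titrant_volume.
recipe_from_config <- function(cfg) {
  acid_keys <- grep("^acid\\.[^.]+\\.conc$", names(cfg), value = TRUE)
  acids <- lapply(acid_keys, function(k) {
    name <- sub("^acid\\.([^.]+)\\.conc$", "\\1", k)
    pka_key <- paste0("acid.", name, ".pKa")
    if (!pka_key %in% names(cfg))
      stop("recipe config: missing ", pka_key)
    buffer_acid(name, cfg[[k]], cfg[[pka_key]])
  })
  buffer_recipe(acids,
                initial_volume = cfg[["initial_volume"]] %||% 100,
                titrant_concentration = cfg[["titrant_concentration"]] %||%
                  0.2,
                titrant_volume = cfg[["titrant_volume"]] %||% 0)
}

criteria_from_config <- function(cfg) {
  hbond_criteria(d_max = cfg[["d_max"]] %||% 3.5,
                 angle_min = cfg[["angle_min"]] %||% 135,
                 pbc = (cfg[["pbc"]] %||% "true") %in%
                   c("true", "TRUE", "yes", "1", 1))
}
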