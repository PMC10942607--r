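#' Write a photon stream as Photon-HDF5
#'
#' Writes the subset of the Photon-HDF5 layout the pipeline uses:
#' `/photon_data/timestamps` (int64 ticks), `detectors`, optional
#' `nanotimes` (TCSPC bins) with their `*_specs` units, and
#' `/acquisition_duration`.
#'
#' @param stream a `photon_stream`.
#' @param path output file path.
#' @param tcspc_unit TCSPC bin width in seconds used to discretize the
#'   microtimes (default 1 ps).
#' @param description free-text description stored in the file.
#' @return `path`, invisibly.
#' @export
write_photon_hdf5 <- function(stream, path, tcspc_unit = 1e-12,
                              description = "simulated nanopore photon stream") {
  stopifnot(inherits(stream, "photon_stream"))
  detectors <- as.integer(stream$channels) - 1L  # 0 = red, 1 = blue
  nanotimes <- if (length(stream$microtimes))
    round(stream$microtimes * 1e-9 / tcspc_unit) else NULL
  .Call("C_phdf5_write", path.expand(path), as.double(stream$ticks),
        detectors, nanotimes, 1 / stream$ticks_per_second, tcspc_unit,
        as.double(stream$duration), description)
  invisible(path)
}

#' Read a photon stream from Photon-HDF5
#'
#' Validates the mandatory groups (`/photon_data`, timestamps and their
#' unit, `/acquisition_duration`) and maps detector indices to channels.
#' Files without nanotimes yield a stream with empty microtimes.
#'
#' @param path Photon-HDF5 file path.
#' @param channel_map channel name per detector index (detector `i` maps to
#'   `channel_map[i + 1]`).
#' @return a `photon_stream`.
#' @export
read_photon_hdf5 <- function(path, channel_map = c("red", "blue")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- .Call("C_phdf5_read", path.expand(path))
  tps <- 1 / raw$timestamps_unit
  channels <- if (!is.null(raw$detectors))
    channel_map[raw$detectors + 1L] else rep(channel_map[1], length(raw$timestamps))
  micro <- if (!is.null(raw$nanotimes))
    raw$nanotimes * raw$tcspc_unit * 1e9 else numeric(0)
  new_photon_stream(raw$timestamps, micro, channels,
                    raw$acquisition_duration, tps)
}

#' Write a bead trajectory as extended XYZ text
#'
#' Per frame: a line with the bead count, a comment line carrying the
#' geometry (`box=... membrane=... pore_diameter=...`), then one line per
#' bead with `x y z radius` at 9 significant digits.
#'
#' @param trajectory a `bead_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bead_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  g <- trajectory$geometry
  con <- file(path, "w")
  on.exit(close(con))
  comment <- sprintf(
    "box=%.9g,%.9g,%.9g membrane=%.9g,%.9g pore_diameter=%.9g scaffold_bead_radius=%.9g",
    g$box_x, g$box_y, g$box_z, g$membrane_z_lo, g$membrane_z_hi,
    g$pore_diameter, g$scaffold_bead_radius)
  for (f in trajectory$frames) {
    writeLines(as.character(nrow(f)), con)
    writeLines(comment, con)
    if (nrow(f) > 0L)
      writeLines(sprintf("%.9g %.9g %.9g %.9g", f$x, f$y, f$z, f$radius),
                 con)
  }
  invisible(path)
}

#' Read a bead trajectory from extended XYZ text
#'
#' @param path file written by [write_bead_trajectory()].
#' @return a `bead_trajectory`.
#' @export
read_bead_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  geom <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("line ", i, ": expected a bead count, got '", lines[i], "'")
    n <- as.integer(lines[i])
    if (i + 1L > length(lines)) stop("line ", i + 1L, ": missing comment line")
    if (is.null(geom)) geom <- parse_xyz_comment(lines[i + 1L], i + 1L)
    if (i + 1L + n > length(lines))
      stop("frame starting at line ", i, ": header announces ", n,
           " beads but the file ends early")
    body <- lines[i + 1L + seq_len(n)]
    vals <- lapply(seq_along(body), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(body[j]),
                                                "\\s+")[[1]]))
      if (length(v) != 4L || any(is.na(v)))
        stop("line ", i + 1L + j, ": malformed bead line '", body[j], "'")
      v
    })
    m <- do.call(rbind, vals)
    frames[[length(frames) + 1L]] <-
      if (n > 0L) data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                             radius = m[, 4])
      else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0))
    i <- i + 2L + n
  }
  bead_radius <- if (length(frames) && nrow(frames[[1]]) > 0L)
    frames[[1]]$radius[1] else NA_real_
  new_bead_trajectory(frames, geom, bead_radius)
}

parse_xyz_comment <- function(line, lineno) {
  get <- function(key) {
    m <- regmatches(line, regexec(paste0(key, "=([-0-9.eE+,]+)"), line))[[1]]
    if (length(m) < 2L)
      stop("line ", lineno, ": comment line lacks '", key, "='")
    as.numeric(strsplit(m[2], ",")[[1]])
  }
  box <- get("box")
  mem <- get("membrane")
  d <- get("pore_diameter")
  sbr <- get("scaffold_bead_radius")
  structure(list(pore_diameter = d,
                 membrane_thickness = mem[2] - mem[1],
                 box_x = box[1], box_y = box[2], box_z = box[3],
                 membrane_z_lo = mem[1], membrane_z_hi = mem[2],
                 scaffold_bead_radius = sbr),
            class = "pore_geometry")
}

#' Write a data frame as a tab-delimited profile table
#'
#' UTF-8, tab-delimited, with a single `#`-prefixed header line naming the
#' columns; floats at 9 significant digits.
#'
#' @param df data frame.
#' @param path output path.
#' @param comment optional extra `#` comment lines written above the header.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(df, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  fmt <- function(col) if (is.numeric(col)) sprintf("%.9g", col)
         else as.character(col)
  cols <- lapply(df, fmt)
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a tab-delimited profile table written by [write_profile_table()]
#'
#' @param path file path.
#' @return data frame with the columns named in the last `#` header line.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- which(startsWith(lines, "#"))
  if (!length(hdr_idx)) stop("no '#' header line in ", path)
  hdr <- sub("^#\\s*", "", lines[max(hdr_idx)])
  cols <- strsplit(hdr, "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body))
    return(setNames(as.data.frame(replicate(length(cols), numeric(0),
                                            simplify = FALSE)), cols))
  parts <- strsplit(body, "\t")
  m <- do.call(rbind, parts)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}
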