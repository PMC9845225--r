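## Format readers and writers shared by all modules. Units in file headers:
## time in ns, wavelength in nm, q in 1/Angstrom, coordinates in Angstrom.

check_columns <- function(df, needed, file) {
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_ox("%s: missing column(s) %s", file,
            paste(missing, collapse = ", "))
}

#' Write / read a decay trace as CSV
#'
#' Columns: `channel_time_ns`, `counts`, `irf_counts`. Column order is
#' irrelevant on read; missing columns raise a named error.
#'
#' @param trace a [decay_trace()].
#' @param path file path.
#' @return `write_decay_csv` returns `path` invisibly; `read_decay_csv`
#'   returns a `decay_trace`.
#' @export
write_decay_csv <- function(trace, path) {
  utils::write.csv(data.frame(channel_time_ns = trace$channel_times,
                              counts = trace$counts,
                              irf_counts = trace$irf_counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("channel_time_ns", "counts", "irf_counts"), path)
  decay_trace(df$channel_time_ns, df$counts, df$irf_counts,
              metadata = list(source = path))
}

#' Write / read an emission spectrum as CSV
#'
#' Columns: `wavelength_nm`, `intensity`.
#'
#' @param spectrum an [emission_spectrum()].
#' @param path file path.
#' @return the path (write) or an `emission_spectrum` (read).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelengths,
                              intensity = spectrum$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("wavelength_nm", "intensity"), path)
  emission_spectrum(df$wavelength_nm, df$intensity,
                    metadata = list(source = path))
}

#' Write / read a scattering profile as CSV
#'
#' Columns: `q_invA`, `intensity`, optional `sigma`.
#'
#' @param profile a [scattering_profile()].
#' @param path file path.
#' @return the path (write) or a `scattering_profile` (read).
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(q_invA = profile$q, intensity = profile$intensity)
  if (!is.null(profile$uncertainty)) df$sigma <- profile$uncertainty
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("q_invA", "intensity"), path)
  scattering_profile(df$q_invA, df$intensity,
                     uncertainty = df$sigma,
                     metadata = list(source = path))
}

#' Write / read a bilayer trajectory as extended XYZ
#'
#' One block per frame: particle count, a comment line
#' `frame=<i> box=<Lx>,<Ly> dt_ns=<dt> thickness_A=<t>`, then rows
#' `species leaflet role site x y z` (Angstrom). Particle order is stable
#' across frames, so molecule identity is positional.
#'
#' @param traj a `bilayer_trajectory`.
#' @param path file path.
#' @return the path (write) or, on read, a list of per-frame data.frames
#'   with the box / dt metadata in attributes.
#' @export
write_xyz_traj <- function(traj, path) {
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in sort(unique(df$frame))) {
    blk <- df[df$frame == f, ]
    writeLines(as.character(nrow(blk)), con)
    writeLines(sprintf("frame=%d box=%.6f,%.6f dt_ns=%g thickness_A=%g",
                       f, traj$box[1], traj$box[2], traj$dt,
                       traj$thickness), con)
    writeLines(sprintf("%s %s %s %d %.6f %.6f %.6f", blk$species,
                       blk$leaflet, blk$role, blk$site, blk$x, blk$y,
                       blk$z), con)
  }
  invisible(path)
}

#' @rdname write_xyz_traj
#' @export
read_xyz_traj <- function(path) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL; dt <- NA_real_; thickness <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop_ox("%s: expected particle count at line %d", path, i)
    hdr <- lines[i + 1L]
    get <- function(key) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
      if (length(m) < 2) stop_ox("%s: header missing '%s' at line %d",
                                 path, key, i + 1L)
      m[2]
    }
    box <- as.numeric(strsplit(get("box"), ",")[[1]])
    dt <- as.numeric(get("dt_ns"))
    thickness <- as.numeric(get("thickness_A"))
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(rows, " +"))
    if (ncol(parts) != 7L)
      stop_ox("%s: malformed particle row near line %d", path, i + 2L)
    frames[[length(frames) + 1L]] <- data.frame(
      species = parts[, 1], leaflet = parts[, 2], role = parts[, 3],
      site = as.integer(parts[, 4]), x = as.numeric(parts[, 5]),
      y = as.numeric(parts[, 6]), z = as.numeric(parts[, 7]),
      stringsAsFactors = FALSE)
    i <- i + 2L + n
  }
  structure(frames, box = box, dt = dt, thickness = thickness)
}

#' Write / read a FLIM stack as multi-frame TIFF plus JSON sidecar
#'
#' The TIFF holds one 32-bit float image per time channel; the JSON sidecar
#' records `channel_width_ns`, the channel times and the IRF.
#'
#' @param stack a `flim_stack`.
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return the path (write) or a `flim_stack` (read; ground truth is not
#'   persisted).
#' @export
write_flim_tiff <- function(stack, path) {
  d <- dim(stack$counts)
  peak <- max(stack$counts)
  imgs <- lapply(seq_len(d[3]), function(k)
    stack$counts[, , k] / max(peak, 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  jsonlite::write_json(list(channel_width_ns = stack$channel_width,
                            channel_times_ns = stack$channel_times,
                            irf = stack$irf, scale = peak),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flim_tiff
#' @export
read_flim_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_ox("missing JSON sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  counts <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (k in seq_along(imgs)) counts[, , k] <- imgs[[k]] * meta$scale
  structure(list(counts = round(counts), irf = meta$irf,
                 channel_times = meta$channel_times_ns,
                 channel_width = meta$channel_width_ns,
                 truth = NULL, metadata = list(source = path)),
            class = "flim_stack")
}

#' Read a minimal GRO coordinate file
#'
#' Fixed-width single-frame GRO reader for bilayer snapshots. Residue names
#' are mapped to species via `species_map`; an unmapped residue raises an
#' error naming it. Coordinates are converted from nm to Angstrom.
#'
#' @param path GRO file.
#' @param species_map named character vector, residue name -> species label.
#' @return data.frame with columns resid, species, atom, x, y, z (Angstrom)
#'   and the box lengths (Angstrom) as attribute `box`.
#' @export
read_gro <- function(path, species_map) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop_ox("%s: truncated GRO file", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop_ox("%s: invalid atom count on line 2", path)
  if (length(lines) < n + 3L) stop_ox("%s: expected %d atom lines", path, n)
  atoms <- lines[3:(2 + n)]
  resname <- trimws(substr(atoms, 6, 10))
  atom <- trimws(substr(atoms, 11, 15))
  x <- as.numeric(substr(atoms, 21, 28)) * 10
  y <- as.numeric(substr(atoms, 29, 36)) * 10
  z <- as.numeric(substr(atoms, 37, 44)) * 10
  unknown <- setdiff(unique(resname), names(species_map))
  if (length(unknown))
    stop_ox("%s: no species mapping for residue(s) %s", path,
            paste(unknown, collapse = ", "))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), " +")[[1]]) * 10
  out <- data.frame(resid = as.integer(substr(atoms, 1, 5)),
                    species = unname(species_map[resname]),
                    atom = atom, x = x, y = y, z = z,
                    stringsAsFactors = FALSE)
  attr(out, "box") <- box
  out
}
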