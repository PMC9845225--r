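## Lateral organization: fractional enrichment, snorkelling, contact maps.

## squared minimum-image distances between two point sets (2-D periodic)
pair_dist2_2d <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], `-`), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], `-`), box[2])
  dx^2 + dy^2
}

#' Fractional enrichment matrix E_ij
#'
#' For every ordered species pair (i, j), the local concentration of j
#' within an in-plane neighbourhood of radius `radius` around each i
#' molecule (the central molecule excluded) is divided by the bulk leaflet
#' concentration `N_j / (Lx * Ly)`; for the same-species pair the central
#' molecule is excluded from the bulk count as well (`(N_i - 1)/(Lx*Ly)`,
#' the standard finite-N pair normalization), so `E_ii = 1` exactly under
#' ideal mixing:
#' `E_ij = C_j,local / C_j,bulk`. Under ideal mixing E -> 1; same-species
#' values above 1 report clustering, cross-species values below 1 report
#' demixing. Leaflets are evaluated separately and averaged; the SE comes
#' from a seeded block bootstrap over frames.
#'
#' @param traj a `bilayer_trajectory`.
#' @param radius neighbourhood radius (Angstrom); must be below half the
#'   smaller box length (minimum-image validity). Default 12.
#' @param frames frame indices to use (default all).
#' @param mode `"in_plane"` (2-D, per leaflet) or `"three_d"` (includes the
#'   phosphate z offset, both leaflets jointly with the neighbourhood still
#'   normalized per area).
#' @param n_boot block-bootstrap replicates over frames.
#' @param block_length bootstrap block length in frames.
#' @param seed bootstrap seed.
#' @return An `enrichment_matrix`: `E` (species x species), `se`,
#'   `C_bulk`, per-frame values, radius and settings.
#' @export
enrichment <- function(traj, radius = 12, frames = NULL,
                       mode = c("in_plane", "three_d"),
                       n_boot = 100L, block_length = NULL, seed = 1L) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  mode <- match.arg(mode)
  box <- traj$box
  if (radius > min(box) / 2)
    stop_ox("radius %.3g violates the minimum-image criterion (box/2 = %.3g)",
            radius, min(box) / 2)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  sp <- sort(unique(traj$molecules$species))
  ns <- length(sp)
  area_nb <- pi * radius^2
  leaflets <- if (mode == "in_plane") c("upper", "lower") else "both"

  per_frame <- array(NA_real_, c(ns, ns, length(frames)),
                     dimnames = list(sp, sp, NULL))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    acc <- array(0, c(ns, ns)); wt <- array(0, c(ns, ns))
    for (leaf in leaflets) {
      sel <- if (leaf == "both") seq_len(nrow(traj$molecules)) else
        which(traj$molecules$leaflet == leaf)
      spl <- traj$molecules$species[sel]
      xy <- cbind(traj$xy[sel, 1, f], traj$xy[sel, 2, f])
      d2 <- pair_dist2_2d(xy, xy, box)
      if (mode == "three_d") {
        dz <- outer(traj$z_phos[sel, f], traj$z_phos[sel, f], `-`)
        d2 <- d2 + dz^2
      }
      diag(d2) <- Inf
      within <- d2 < radius^2
      for (i in seq_len(ns)) {
        rows <- spl == sp[i]
        if (!any(rows)) next
        for (j in seq_len(ns)) {
          cols <- spl == sp[j]
          n_j <- sum(cols)
          if (n_j == 0 || (i == j && n_j < 2)) next
          c_local <- mean(rowSums(within[rows, cols, drop = FALSE])) / area_nb
          ## same-species bulk excludes the central molecule itself, the
          ## standard finite-N pair normalization; E_ii is then exactly 1
          ## under ideal mixing
          c_bulk <- (n_j - (i == j)) / (box[1] * box[2])
          acc[i, j] <- acc[i, j] + c_local / c_bulk
          wt[i, j] <- wt[i, j] + 1
        }
      }
    }
    per_frame[, , fi] <- ifelse(wt > 0, acc / wt, NA_real_)
  }
  E <- apply(per_frame, c(1, 2), mean)

  nf <- length(frames)
  if (is.null(block_length)) block_length <- max(1L, nf %/% 10L)
  set.seed(seed)
  se <- matrix(NA_real_, ns, ns, dimnames = list(sp, sp))
  if (n_boot > 0 && nf > 1) {
    n_blocks <- ceiling(nf / block_length)
    boot <- array(NA_real_, c(ns, ns, n_boot))
    for (b in seq_len(n_boot)) {
      starts <- sample.int(nf, n_blocks, replace = TRUE)
      idx <- unlist(lapply(starts, function(s0)
        ((s0 - 1 + seq_len(block_length) - 1) %% nf) + 1))[seq_len(nf)]
      boot[, , b] <- apply(per_frame[, , idx, drop = FALSE], c(1, 2), mean)
    }
    se <- apply(boot, c(1, 2), stats::sd)
  }
  c_bulk <- vapply(sp, function(s)
    sum(traj$molecules$species == s & traj$molecules$leaflet == "upper") /
      (box[1] * box[2]), numeric(1))
  structure(list(E = E, se = se, radius = radius, mode = mode,
                 C_bulk_upper = c_bulk, per_frame = per_frame,
                 n_frames = nf, leaflet_handling =
                   "separate leaflets averaged"),
            class = "enrichment_matrix")
}

#' Snorkelling fraction of peroxide groups
#'
#' Fraction of peroxide-proxy particles whose |z| exceeds
#' `z_threshold * (thickness / 2)` (strict inequality), i.e. whose -OOH
#' group sits near the water-lipid interface rather than in the bilayer
#' core. Reports the time average, per-molecule up-state occupancies and
#' mean dwell times of the two states.
#'
#' @param traj a `bilayer_trajectory` with peroxide particles.
#' @param species optional species subset.
#' @param z_threshold fraction of the half-thickness defining "up"; in
#'   (0, 1]. Default 0.6.
#' @return list with `fraction`, `se` (over frames), `per_frame`,
#'   `per_molecule`, `dwell_up_ns`, `dwell_down_ns`.
#' @export
snorkelling_fraction <- function(traj, species = NULL, z_threshold = 0.6) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  if (z_threshold <= 0 || z_threshold > 1)
    stop_ox("z_threshold must be in (0, 1]")
  if (is.null(traj$z_perox)) stop_ox("trajectory has no peroxide particles")
  sel <- which(!is.na(traj$z_perox[, 1]))
  if (!is.null(species))
    sel <- sel[traj$molecules$species[sel] %in% species]
  if (!length(sel)) stop_ox("no peroxide particles for the requested species")
  half <- bilayer_thickness(traj)$thickness / 2
  z <- abs(traj$z_perox[sel, , drop = FALSE])
  up <- z > z_threshold * half
  per_frame <- colMeans(up)
  per_mol <- rowMeans(up)
  dwell <- function(state_mat, state) {
    lens <- unlist(apply(state_mat, 1, function(s) {
      r <- rle(s)
      r$lengths[r$values == state]
    }))
    if (!length(lens)) NA_real_ else mean(lens) * traj$dt
  }
  list(fraction = mean(per_frame),
       se = stats::sd(per_frame) / sqrt(length(per_frame)),
       per_frame = per_frame, per_molecule = per_mol,
       dwell_up_ns = dwell(up, TRUE), dwell_down_ns = dwell(up, FALSE),
       z_threshold = z_threshold, half_thickness = half)
}

## per-molecule coordinates of a named site role at one frame
role_coords <- function(traj, role, f) {
  mol <- traj$molecules
  switch(role,
    phosphate = list(ids = mol$id,
                     xyz = cbind(traj$xy[, 1, f], traj$xy[, 2, f],
                                 traj$z_phos[, f])),
    peroxide_O = {
      if (is.null(traj$z_perox)) stop_ox("unknown site role: no peroxide particles")
      keep <- !is.na(traj$z_perox[, f])
      list(ids = mol$id[keep],
           xyz = cbind(traj$xy[keep, 1, f], traj$xy[keep, 2, f],
                       traj$z_perox[keep, f]))
    },
    chain_end = {
      if (is.null(traj$chain)) stop_ox("unknown site role: no chain sites")
      k <- dim(traj$chain)[2]
      list(ids = mol$id, xyz = traj$chain[, k, , f])
    },
    stop_ox("unknown site role '%s'", role))
}

#' Inter-molecular contact frequencies between site roles
#'
#' Fraction of frame x molecule-pair observations in which the minimum-image
#' distance between two named site roles falls below `cutoff` (same-molecule
#' pairs excluded; x, y periodic, z not). Contacts between peroxide oxygens
#' of neighbouring oxidized chains report the hydrogen-bond-like
#' interactions that drive their clustering.
#'
#' @param traj a `bilayer_trajectory`.
#' @param site_pairs character vector of roles to cross (default
#'   `c("phosphate", "peroxide_O")` when peroxides exist, else
#'   `"phosphate"`); allowed roles: phosphate, peroxide_O, chain_end.
#' @param cutoff contact distance (Angstrom).
#' @param frames frame subset (default all).
#' @return symmetric role x role matrix of contact frequencies.
#' @export
contact_map <- function(traj, site_pairs = NULL, cutoff = 3.5,
                        frames = NULL) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  if (is.null(site_pairs)) {
    site_pairs <- if (!is.null(traj$z_perox)) c("phosphate", "peroxide_O")
      else "phosphate"
  }
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  nr <- length(site_pairs)
  acc <- matrix(0, nr, nr, dimnames = list(site_pairs, site_pairs))
  cnt <- matrix(0, nr, nr)
  for (f in frames) {
    coords <- lapply(site_pairs, role_coords, traj = traj, f = f)
    for (a in seq_len(nr)) {
      for (b in a:nr) {
        ca <- coords[[a]]; cb <- coords[[b]]
        d2 <- pair_dist2_2d(ca$xyz[, 1:2, drop = FALSE],
                            cb$xyz[, 1:2, drop = FALSE], traj$box) +
          outer(ca$xyz[, 3], cb$xyz[, 3], `-`)^2
        same <- outer(ca$ids, cb$ids, `==`)
        hits <- (d2 < cutoff^2) & !same
        acc[a, b] <- acc[a, b] + sum(hits)
        cnt[a, b] <- cnt[a, b] + sum(!same)
      }
    }
  }
  freq <- acc / pmax(cnt, 1)
  freq[lower.tri(freq)] <- t(freq)[lower.tri(freq)]
  freq
}
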