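## Structural trajectory metrics: density profiles, thickness, chain order.

#' Electron (number) density profile along the bilayer normal
#'
#' Histogram of particle z positions, midplane-centred, normalized per unit
#' lateral area and bin width and averaged over frames. With unit weights
#' this is a number-density profile; electron-count weights give the
#' electron density profile.
#'
#' @param traj a `bilayer_trajectory`.
#' @param bin_width z bin width (Angstrom).
#' @param groups named list of filters, each a list with optional `species`
#'   and `role` (`"phosphate"`, `"peroxide_O"`, `"chain_site"`); default one
#'   group per species using all roles.
#' @param weights optional named vector of per-role weights (default 1).
#' @return data.frame with columns group, z (bin centre, Angstrom), density
#'   (1/Angstrom^3 for unit weights).
#' @export
electron_density_profile <- function(traj, bin_width = 1, groups = NULL,
                                     weights = NULL) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  assert_scalar_num(bin_width, "bin_width", 0, strict_lower = TRUE)
  df <- as.data.frame(traj)
  ## midplane per frame from phosphates only
  mp <- tapply(df$z[df$role == "phosphate"], df$frame[df$role == "phosphate"],
               mean)
  df$zc <- df$z - mp[as.character(df$frame)]
  if (is.null(groups)) {
    groups <- lapply(unique(df$species), function(s) list(species = s))
    names(groups) <- unique(df$species)
  }
  area <- traj$box[1] * traj$box[2]
  zr <- range(df$zc)
  breaks <- seq(floor(zr[1] / bin_width) * bin_width,
                ceiling(zr[2] / bin_width) * bin_width, by = bin_width)
  out <- list()
  for (g in names(groups)) {
    sel <- rep(TRUE, nrow(df))
    if (!is.null(groups[[g]]$species)) sel <- sel & df$species %in% groups[[g]]$species
    if (!is.null(groups[[g]]$role)) sel <- sel & df$role %in% groups[[g]]$role
    if (!any(sel)) stop_ox("group '%s' selects no particles", g)
    w <- if (is.null(weights)) rep(1, sum(sel)) else {
      wt <- weights[df$role[sel]]
      wt[is.na(wt)] <- 1
      wt
    }
    h <- graphics::hist(df$zc[sel], breaks = breaks, plot = FALSE)
    dens <- as.numeric(tapply(w, cut(df$zc[sel], breaks), sum))
    dens[is.na(dens)] <- 0
    dens <- dens / (area * bin_width * traj$n_frames)
    out[[g]] <- data.frame(group = g, z = h$mids, density = dens,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_width") <- bin_width
  attr(res, "area") <- area
  res
}

#' Bilayer thickness from phosphate positions
#'
#' Mean phosphate z of the upper leaflet minus that of the lower leaflet,
#' per frame, averaged over frames (the phosphate-phosphate distance).
#'
#' @param traj a `bilayer_trajectory`.
#' @return list with `thickness` (Angstrom), `se` (over frames),
#'   `per_frame`.
#' @export
bilayer_thickness <- function(traj) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  up <- traj$molecules$leaflet == "upper"
  lo <- traj$molecules$leaflet == "lower"
  if (!any(up) || !any(lo)) stop_ox("both leaflets must contain phosphates")
  per_frame <- colMeans(traj$z_phos[up, , drop = FALSE]) -
    colMeans(traj$z_phos[lo, , drop = FALSE])
  list(thickness = mean(per_frame),
       se = stats::sd(per_frame) / sqrt(length(per_frame)),
       per_frame = per_frame)
}

#' Order parameter of a set of vectors
#'
#' `S = 1/2 <3 cos^2(theta) - 1>` where theta is the angle to the bilayer
#' normal (z axis). Aligned vectors give 1, in-plane vectors -0.5,
#' isotropic vectors 0.
#'
#' @param v n x 3 matrix of (not necessarily unit) vectors.
#' @return scalar order parameter in [-0.5, 1].
#' @export
order_parameter_vectors <- function(v) {
  v <- matrix(v, ncol = 3)
  nrm2 <- rowSums(v^2)
  if (any(nrm2 == 0)) stop_ox("zero-length vectors")
  cos2 <- v[, 3]^2 / nrm2
  mean(3 * cos2 - 1) / 2
}

#' Per-site chain order parameter profile
#'
#' Computes `S_cd = 1/2 <3 cos^2(theta) - 1>` per chain-site index, where
#' theta is the angle between the bilayer normal and the chain segment
#' vector (the carbon-hydrogen vector proxy: consecutive chain-site pairs),
#' averaged over frames and molecules of each species. The SE is taken over
#' per-frame means.
#'
#' @param traj a `bilayer_trajectory` generated with chain sites.
#' @param species optional species subset.
#' @return data.frame with columns species, site, s_cd, se.
#' @export
order_parameter <- function(traj, species = NULL) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  if (is.null(traj$chain) || dim(traj$chain)[2] < 1L)
    stop_ox("trajectory carries no chain sites")
  sp <- if (is.null(species)) unique(traj$molecules$species) else species
  ns <- dim(traj$chain)[2]
  nf <- traj$n_frames
  out <- list()
  for (s in sp) {
    sel <- which(traj$molecules$species == s)
    if (!length(sel)) stop_ox("species '%s' not present", s)
    for (k in seq_len(ns)) {
      per_frame <- vapply(seq_len(nf), function(f) {
        prev <- if (k == 1L) {
          cbind(traj$xy[sel, 1, f], traj$xy[sel, 2, f], traj$z_phos[sel, f])
        } else {
          traj$chain[sel, k - 1L, , f]
        }
        order_parameter_vectors(traj$chain[sel, k, , f] - prev)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        species = s, site = k, s_cd = mean(per_frame),
        se = stats::sd(per_frame) / sqrt(nf), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
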