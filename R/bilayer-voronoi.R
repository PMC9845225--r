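## Periodic 2-D Voronoi tessellation and area-per-lipid statistics.

## clip a convex polygon (k x 2) with the half-plane {x : (x - m) . nrm <= 0}
clip_halfplane <- function(poly, m, nrm) {
  d <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2]
  k <- nrow(poly)
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  out <- matrix(NA_real_, k + 4L, 2L)
  n_out <- 0L
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) {
      n_out <- n_out + 1L
      out[n_out, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      n_out <- n_out + 1L
      out[n_out, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(n_out), , drop = FALSE]
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Periodic Voronoi cell areas
#'
#' Computes the Voronoi tessellation of points in a periodic rectangular
#' box by half-plane clipping against the eight periodic images of every
#' seed (nearest bisectors first, with a distance-based early exit). The
#' cell areas tile the box exactly, so they sum to `Lx * Ly`.
#'
#' @param xy n x 2 matrix of seed positions (Angstrom).
#' @param box `c(Lx, Ly)`.
#' @return numeric vector of per-seed areas (Angstrom^2).
#' @export
periodic_voronoi_areas <- function(xy, box) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 4L) stop_ox("need >= 4 seeds")
  if (length(box) != 2 || any(box <= 0)) stop_ox("box must be c(Lx, Ly) > 0")
  xy <- cbind(xy[, 1] %% box[1], xy[, 2] %% box[2])
  if (anyDuplicated(round(xy, 6))) {
    warn_ox("duplicate seed positions jittered by 1e-6 Angstrom")
    dup <- duplicated(round(xy, 6))
    xy[dup, ] <- xy[dup, ] + stats::runif(2 * sum(dup), -1e-6, 1e-6)
  }
  shifts <- as.matrix(expand.grid(dx = c(-1, 0, 1), dy = c(-1, 0, 1)))
  all_pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    cbind(xy[, 1] + shifts[k, 1] * box[1], xy[, 2] + shifts[k, 2] * box[2])
  }))
  centre_block <- which(shifts[, 1] == 0 & shifts[, 2] == 0)
  r0 <- max(box)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    s <- xy[i, ]
    self_centre <- (centre_block - 1L) * n + i
    dx <- all_pts[, 1] - s[1]
    dy <- all_pts[, 2] - s[2]
    d2 <- dx^2 + dy^2
    d2[self_centre] <- Inf
    ord <- order(d2)
    poly <- cbind(s[1] + c(-r0, r0, r0, -r0), s[2] + c(-r0, -r0, r0, r0))
    max_d2 <- 2 * r0^2
    for (j in ord) {
      if (d2[j] >= 4 * max_d2) break
      m <- c(s[1] + dx[j] / 2, s[2] + dy[j] / 2)
      poly <- clip_halfplane(poly, m, c(dx[j], dy[j]))
      if (is.null(poly) || nrow(poly) < 3L) { poly <- NULL; break }
      max_d2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
    }
    areas[i] <- if (is.null(poly)) 0 else shoelace_area(poly)
  }
  areas
}

#' Area-per-lipid map from a periodic Voronoi tessellation
#'
#' Tessellates one leaflet of one frame using the phosphate (x, y)
#' positions as seeds; each lipid receives the area of its Voronoi cell.
#'
#' @param traj a `bilayer_trajectory`.
#' @param frame frame index.
#' @param leaflet `"upper"` or `"lower"`.
#' @return An `apl_map` data.frame: id, species, x, y, area (Angstrom^2);
#'   attributes `box`, `frame`, `leaflet`.
#' @export
apl_voronoi <- function(traj, frame = 1L, leaflet = c("upper", "lower")) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  leaflet <- match.arg(leaflet)
  if (frame < 1L || frame > traj$n_frames) stop_ox("frame out of range")
  sel <- which(traj$molecules$leaflet == leaflet)
  if (length(sel) < 4L) stop_ox("need >= 4 lipids in the leaflet")
  xy <- cbind(traj$xy[sel, 1, frame], traj$xy[sel, 2, frame])
  areas <- periodic_voronoi_areas(xy, traj$box)
  out <- data.frame(id = traj$molecules$id[sel],
                    species = traj$molecules$species[sel],
                    x = xy[, 1], y = xy[, 2], area = areas,
                    stringsAsFactors = FALSE)
  attr(out, "box") <- traj$box
  attr(out, "frame") <- frame
  attr(out, "leaflet") <- leaflet
  class(out) <- c("apl_map", "data.frame")
  out
}

#' Area-per-lipid distribution summary
#'
#' Pools per-lipid Voronoi areas (one or several `apl_map`s, or a plain
#' numeric vector) and reports moments plus a two-component Gaussian
#' mixture comparison. A positive `delta_bic` (BIC of one component minus
#' BIC of two, smaller-is-better convention) indicates a bimodal area
#' distribution, the signature of coexisting dense and loose lipid
#' packing.
#'
#' @param areas numeric vector, an `apl_map`, or a list of `apl_map`s.
#' @return An `apl_distribution`: n, mean, sd, delta_bic, mixture means /
#'   sds / proportions.
#' @export
apl_distribution <- function(areas) {
  if (inherits(areas, "apl_map")) areas <- areas$area
  if (is.list(areas) && !is.numeric(areas))
    areas <- unlist(lapply(areas, function(a)
      if (inherits(a, "apl_map")) a$area else a))
  areas <- as.numeric(areas)
  if (length(areas) < 10L) stop_ox("need >= 10 areas")
  mix <- gmm_delta_bic(areas)
  structure(list(n = length(areas), mean = mean(areas),
                 sd = stats::sd(areas), delta_bic = mix$delta_bic,
                 gmm_means = mix$means, gmm_sds = mix$sds,
                 gmm_proportions = mix$proportions),
            class = "apl_distribution")
}
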