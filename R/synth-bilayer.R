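## Two-leaflet lateral bilayer simulator: overdamped 2-D Brownian dynamics
## with Metropolis-accepted same-species attraction, sampled chain vectors
## with a target order parameter, and a slow two-state snorkelling degree of
## freedom for the peroxidized species. This is a ground-truth generator for
## testing trajectory analyses, not an atomistic simulation.

#' Specify a synthetic bilayer trajectory
#'
#' Defaults emulate the simulated systems in scope: 200 lipids per leaflet,
#' an equimolar POPC / POPC-OOH mixture at ~63 A^2 per lipid, a ~20% lower
#' lateral diffusion coefficient for the peroxidized species, and ~40% of
#' the peroxidized chains in the snorkelling (interface-proximal) state with
#' slow interconversion.
#'
#' @param box_lengths `(Lx, Ly)` in Angstrom.
#' @param n_per_leaflet lipids per leaflet.
#' @param species_fractions named fractions summing to 1.
#' @param diffusion_coeffs named lateral D per species (A^2/ns).
#' @param attraction_eps same-species square-well depth (kT); 0 disables
#'   all interactions (free Brownian motion with the planted diffusion
#'   coefficients exact).
#' @param attraction_range attraction distance (Angstrom).
#' @param core_diameter soft-core exclusion diameter (Angstrom), active in
#'   interacting runs: without excluded area a condensing species would not
#'   deplete the other species from its clusters.
#' @param core_eps soft-core overlap penalty (kT).
#' @param order_target named target segment order parameter per species.
#' @param snorkel_fraction stationary fraction of peroxide groups in the
#'   "up" (interfacial) state.
#' @param snorkel_rates `c(up, down)` switching rates (1/ns): `up` is the
#'   down-to-up rate. `NULL` derives slow rates (total 0.01/ns) whose
#'   stationary fraction equals `snorkel_fraction`.
#' @param peroxide_species species carrying a peroxide proxy particle;
#'   default: names containing "OOH".
#' @param thickness phosphate-phosphate bilayer thickness (Angstrom).
#' @param z_jitter thermal SD of phosphate z positions (Angstrom).
#' @param n_chain_sites chain sites per lipid used for order-parameter
#'   sampling (0 disables chain output).
#' @param bond_length chain segment length (Angstrom).
#' @param dt frame interval (ns).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return `bilayer_sim_spec` object.
#' @export
bilayer_sim_spec <- function(box_lengths = c(112, 112),
                             n_per_leaflet = 200L,
                             species_fractions = c(POPC = 0.5,
                                                   `POPC-OOH` = 0.5),
                             diffusion_coeffs = c(POPC = 1.0,
                                                  `POPC-OOH` = 0.8),
                             attraction_eps = 0,
                             attraction_range = 10,
                             core_diameter = 7, core_eps = 2,
                             order_target = c(POPC = 0.2, `POPC-OOH` = 0.15),
                             snorkel_fraction = 0.4,
                             snorkel_rates = NULL,
                             peroxide_species = NULL,
                             thickness = 39.2, z_jitter = 1,
                             n_chain_sites = 4L, bond_length = 1.5,
                             dt = 1, n_frames = 500L, seed = 1L) {
  if (length(box_lengths) != 2 || any(box_lengths <= 0))
    stop_ox("box_lengths must be two positive lengths")
  if (abs(sum(species_fractions) - 1) > 1e-9)
    stop_ox("species_fractions must sum to 1")
  sp <- names(species_fractions)
  if (is.null(sp) || any(!nzchar(sp))) stop_ox("species_fractions must be named")
  if (!all(sp %in% names(diffusion_coeffs)))
    stop_ox("diffusion_coeffs must cover every species")
  if (any(diffusion_coeffs < 0)) stop_ox("diffusion coefficients must be >= 0")
  assert_scalar_num(snorkel_fraction, "snorkel_fraction", 0, 1)
  assert_scalar_num(attraction_eps, "attraction_eps", 0)
  assert_scalar_num(thickness, "thickness", 0, strict_lower = TRUE)
  assert_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  step <- sqrt(4 * max(diffusion_coeffs[sp]) * dt)
  if (step > min(box_lengths) / 4)
    stop_ox("unphysical step: sqrt(4*D*dt) = %.3g exceeds box/4", step)
  if (is.null(peroxide_species)) peroxide_species <- sp[grepl("OOH", sp)]
  if (is.null(snorkel_rates)) {
    snorkel_rates <- c(up = 0.01 * snorkel_fraction,
                       down = 0.01 * (1 - snorkel_fraction))
  }
  structure(list(box_lengths = as.numeric(box_lengths),
                 n_per_leaflet = as.integer(n_per_leaflet),
                 species_fractions = species_fractions,
                 diffusion_coeffs = diffusion_coeffs,
                 attraction_eps = attraction_eps,
                 attraction_range = attraction_range,
                 core_diameter = core_diameter, core_eps = core_eps,
                 order_target = order_target,
                 snorkel_fraction = snorkel_fraction,
                 snorkel_rates = snorkel_rates,
                 peroxide_species = peroxide_species,
                 thickness = thickness, z_jitter = z_jitter,
                 n_chain_sites = as.integer(n_chain_sites),
                 bond_length = bond_length,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "bilayer_sim_spec")
}

## largest-remainder apportionment of n among fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}

## sample n unit vectors whose order parameter 1/2<3cos^2(theta)-1> targets S
## (mixture of aligned / in-plane with isotropic directions)
sample_order_vectors <- function(n, s_target, down = FALSE) {
  u <- matrix(0, n, 3)
  iso <- stats::runif(n) >= abs(if (s_target >= 0) s_target else 2 * s_target)
  n_iso <- sum(iso)
  if (n_iso) {
    cz <- stats::runif(n_iso, -1, 1)
    phi <- stats::runif(n_iso, 0, 2 * pi)
    sz <- sqrt(pmax(0, 1 - cz^2))
    u[iso, ] <- cbind(sz * cos(phi), sz * sin(phi), cz)
  }
  n_al <- n - n_iso
  if (n_al) {
    if (s_target >= 0) {
      u[!iso, 3] <- if (down) -1 else 1
    } else {
      phi <- stats::runif(n_al, 0, 2 * pi)
      u[!iso, ] <- cbind(cos(phi), sin(phi), 0)
    }
  }
  u
}

#' Generate a synthetic bilayer trajectory
#'
#' Runs overdamped lateral Brownian dynamics independently per leaflet. When
#' `attraction_eps > 0`, each proposed displacement is accepted by a
#' Metropolis criterion on a same-species square-well pair energy, producing
#' lateral clustering; with `attraction_eps = 0` every move is accepted and
#' the planted diffusion coefficients are exact. Phosphate proxies sit at
#' +/- thickness/2 with thermal jitter; peroxide proxies of the oxidized
#' species follow a slow two-state (snorkelling) Markov chain in z; chain
#' vectors are drawn i.i.d. per frame from a mixture matching the target
#' order parameter.
#'
#' @param spec a [bilayer_sim_spec()].
#' @return A `bilayer_trajectory` object (see [as.data.frame.bilayer_trajectory()]
#'   for the tidy particle view).
#' @export
gen_bilayer_traj <- function(spec) {
  if (!inherits(spec, "bilayer_sim_spec")) stop_ox("spec must be a bilayer_sim_spec")
  set.seed(spec$seed)
  L <- spec$box_lengths
  sp_names <- names(spec$species_fractions)
  counts <- apportion(spec$n_per_leaflet, spec$species_fractions)
  species_leaflet <- rep(sp_names, counts)
  n_leaf <- spec$n_per_leaflet
  n_mol <- 2L * n_leaf
  molecules <- data.frame(
    id = seq_len(n_mol),
    species = rep(species_leaflet, 2),
    leaflet = rep(c("upper", "lower"), each = n_leaf),
    stringsAsFactors = FALSE)

  nf <- spec$n_frames
  xy_un <- array(NA_real_, c(n_mol, 2, nf))
  d_sd <- sqrt(2 * spec$diffusion_coeffs[molecules$species] * spec$dt)
  eps <- spec$attraction_eps
  rng2 <- spec$attraction_range^2
  core2 <- spec$core_diameter^2
  core_eps <- spec$core_eps

  for (leaf in c(0L, 1L)) {
    idx <- leaf * n_leaf + seq_len(n_leaf)
    pos <- cbind(stats::runif(n_leaf, 0, L[1]), stats::runif(n_leaf, 0, L[2]))
    sp_i <- molecules$species[idx]
    sd_i <- d_sd[idx]
    xy_un[idx, , 1] <- pos
    wrapped <- pos  # wrapped copy used for energies
    for (f in seq_len(nf)[-1]) {
      step <- matrix(stats::rnorm(2 * n_leaf, 0, sd_i), n_leaf, 2)
      if (eps > 0) {
        same <- outer(sp_i, sp_i, `==`)
        for (i in seq_len(n_leaf)) {
          new_w <- (wrapped[i, ] + step[i, ]) %% L
          dx0 <- min_image(wrapped[, 1] - wrapped[i, 1], L[1])
          dy0 <- min_image(wrapped[, 2] - wrapped[i, 2], L[2])
          dx1 <- min_image(wrapped[, 1] - new_w[1], L[1])
          dy1 <- min_image(wrapped[, 2] - new_w[2], L[2])
          d0 <- dx0^2 + dy0^2
          d1 <- dx1^2 + dy1^2
          in0 <- d0 < rng2; in1 <- d1 < rng2
          ov0 <- d0 < core2; ov1 <- d1 < core2
          in0[i] <- in1[i] <- ov0[i] <- ov1[i] <- FALSE
          dE <- -eps * (sum(in1 & same[i, ]) - sum(in0 & same[i, ])) +
            core_eps * (sum(ov1) - sum(ov0))
          if (dE <= 0 || stats::runif(1) < exp(-dE)) {
            wrapped[i, ] <- new_w
            pos[i, ] <- pos[i, ] + step[i, ]
          }
        }
      } else {
        pos <- pos + step
        wrapped <- cbind(pos[, 1] %% L[1], pos[, 2] %% L[2])
      }
      xy_un[idx, , f] <- pos
    }
  }
  xy <- xy_un
  xy[, 1, ] <- xy[, 1, ] %% L[1]
  xy[, 2, ] <- xy[, 2, ] %% L[2]

  leaf_sign <- ifelse(molecules$leaflet == "upper", 1, -1)
  z_phos <- matrix(stats::rnorm(n_mol * nf, 0, spec$z_jitter), n_mol, nf) +
    leaf_sign * spec$thickness / 2

  ## snorkelling two-state chain for peroxide-bearing species
  z_perox <- NULL
  perox_state <- NULL
  is_perox <- molecules$species %in% spec$peroxide_species
  if (any(is_perox)) {
    np <- sum(is_perox)
    p_up <- 1 - exp(-spec$snorkel_rates[["up"]] * spec$dt)
    p_down <- 1 - exp(-spec$snorkel_rates[["down"]] * spec$dt)
    state <- matrix(FALSE, np, nf)
    ## plant the initial up fraction exactly (random assignment)
    n_up <- round(np * spec$snorkel_fraction)
    state[sample.int(np, n_up), 1] <- TRUE
    if (nf > 1) {
      for (f in seq_len(nf)[-1]) {
        r <- stats::runif(np)
        state[, f] <- ifelse(state[, f - 1], r >= p_down, r < p_up)
      }
    }
    half <- spec$thickness / 2
    zmag <- ifelse(state, 0.85 * half, 0.15 * half) +
      matrix(stats::rnorm(np * nf, 0, 0.5), np, nf)
    z_perox <- matrix(NA_real_, n_mol, nf)
    z_perox[is_perox, ] <- zmag * leaf_sign[is_perox]
    perox_state <- matrix(NA, n_mol, nf)
    perox_state[is_perox, ] <- state
  }

  ## chain sites: random walk down from the phosphate with per-segment
  ## directions drawn from the order-target mixture
  chain <- NULL
  ns <- spec$n_chain_sites
  if (ns > 0) {
    chain <- array(NA_real_, c(n_mol, ns, 3, nf))
    for (f in seq_len(nf)) {
      start <- cbind(xy[, 1, f], xy[, 2, f], z_phos[, f])
      posc <- start
      for (k in seq_len(ns)) {
        u <- matrix(0, n_mol, 3)
        for (s in sp_names) {
          m_up <- molecules$species == s & leaf_sign > 0
          m_dn <- molecules$species == s & leaf_sign < 0
          st <- spec$order_target[[s]]
          if (sum(m_up)) u[m_up, ] <- sample_order_vectors(sum(m_up), st, down = TRUE)
          if (sum(m_dn)) u[m_dn, ] <- sample_order_vectors(sum(m_dn), st, down = FALSE)
        }
        posc <- posc + spec$bond_length * u
        chain[, k, , f] <- posc
      }
    }
  }

  structure(list(molecules = molecules, box = L, dt = spec$dt,
                 n_frames = nf, thickness = spec$thickness,
                 xy = xy, xy_unwrapped = xy_un, z_phos = z_phos,
                 z_perox = z_perox, perox_state = perox_state,
                 chain = chain, truth = spec),
            class = "bilayer_trajectory")
}

#' Tidy particle view of a bilayer trajectory
#'
#' Expands the internal arrays into one long data frame with one row per
#' particle per frame (roles: `phosphate`, `peroxide_O`, `chain_site`).
#'
#' @param x a `bilayer_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns frame, id, species, leaflet, role,
#'   site, x, y, z.
#' @export
as.data.frame.bilayer_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  out <- vector("list", x$n_frames)
  mol <- x$molecules
  for (f in seq_len(x$n_frames)) {
    df <- data.frame(frame = f, id = mol$id, species = mol$species,
                     leaflet = mol$leaflet, role = "phosphate", site = 0L,
                     x = x$xy[, 1, f], y = x$xy[, 2, f], z = x$z_phos[, f],
                     stringsAsFactors = FALSE)
    if (!is.null(x$z_perox)) {
      keep <- !is.na(x$z_perox[, f])
      if (any(keep)) {
        df <- rbind(df, data.frame(frame = f, id = mol$id[keep],
                                   species = mol$species[keep],
                                   leaflet = mol$leaflet[keep],
                                   role = "peroxide_O", site = 0L,
                                   x = x$xy[keep, 1, f], y = x$xy[keep, 2, f],
                                   z = x$z_perox[keep, f],
                                   stringsAsFactors = FALSE))
      }
    }
    if (!is.null(x$chain)) {
      for (k in seq_len(dim(x$chain)[2])) {
        df <- rbind(df, data.frame(frame = f, id = mol$id,
                                   species = mol$species,
                                   leaflet = mol$leaflet,
                                   role = "chain_site", site = k,
                                   x = x$chain[, k, 1, f],
                                   y = x$chain[, k, 2, f],
                                   z = x$chain[, k, 3, f],
                                   stringsAsFactors = FALSE))
      }
    }
    out[[f]] <- df
  }
  do.call(rbind, out)
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat(sprintf("bilayer_trajectory: %d molecules (%s), %d frames, dt = %g ns\n",
              nrow(x$molecules),
              paste(names(table(x$molecules$species)), collapse = "/"),
              x$n_frames, x$dt))
  cat(sprintf("  box %g x %g A, thickness %g A\n", x$box[1], x$box[2],
              x$thickness))
  invisible(x)
}
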