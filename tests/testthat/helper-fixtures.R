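## Shared fixtures and independent oracles for the test suite.

three_band_components <- function() {
  list(c(425, 40, 1.3, 1.0), c(460, 45, 1.3, 0.8), c(495, 50, 1.3, 0.5))
}

## brute-force O(n^2) enrichment oracle: explicit double loop over one
## leaflet of one frame, independent of the pipeline implementation
brute_enrichment <- function(xy, species, box, radius) {
  sp <- sort(unique(species))
  n <- nrow(xy)
  area_nb <- pi * radius^2
  counts <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  n_i <- table(factor(species, levels = sp))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- xy[i, 1] - xy[j, 1]; dx <- dx - box[1] * round(dx / box[1])
      dy <- xy[i, 2] - xy[j, 2]; dy <- dy - box[2] * round(dy / box[2])
      if (dx^2 + dy^2 < radius^2)
        counts[species[i], species[j]] <- counts[species[i], species[j]] + 1
    }
  }
  E <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (a in sp) {
    for (b in sp) {
      c_local <- counts[a, b] / n_i[[a]] / area_nb
      ## same-species bulk excludes the central molecule (pair
      ## normalization), matching the documented definition
      c_bulk <- (n_i[[b]] - (a == b)) / (box[1] * box[2])
      E[a, b] <- c_local / c_bulk
    }
  }
  E
}

## hand-built bilayer trajectory with planted coordinates (single frame
## replicated, or supplied per-frame arrays)
make_toy_traj <- function(xy, z_phos, species, leaflet, box,
                          z_perox = NULL, chain = NULL, dt = 1,
                          thickness = NULL) {
  n_mol <- nrow(xy)
  nf <- if (length(dim(xy)) == 3) dim(xy)[3] else 1L
  if (length(dim(xy)) == 2) xy <- array(xy, c(n_mol, 2, 1))
  if (is.null(dim(z_phos))) z_phos <- matrix(z_phos, n_mol, nf)
  if (is.null(thickness))
    thickness <- mean(z_phos[leaflet == "upper", 1]) -
      mean(z_phos[leaflet == "lower", 1])
  structure(list(molecules = data.frame(id = seq_len(n_mol),
                                        species = species,
                                        leaflet = leaflet,
                                        stringsAsFactors = FALSE),
                 box = box, dt = dt, n_frames = nf,
                 thickness = thickness, xy = xy, xy_unwrapped = xy,
                 z_phos = z_phos, z_perox = z_perox, perox_state = NULL,
                 chain = chain, truth = NULL),
            class = "bilayer_trajectory")
}

## noiseless decay_trace from a spec (expected counts instead of a draw)
noiseless_decay <- function(spec) {
  tr <- gen_decay(spec)
  decay_trace(tr$channel_times, tr$metadata$expected, tr$irf_counts,
              metadata = tr$metadata)
}
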