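test_that("density profile conserves particles and resolves leaflet peaks", {
  ## planted phosphate planes at +/- 19.6 A -> twin peaks 39.2 A apart
  set.seed(2)
  n <- 400
  xy <- cbind(runif(n, 0, 80), runif(n, 0, 80))
  leaf <- rep(c("upper", "lower"), each = n / 2)
  z <- ifelse(leaf == "upper", 19.6, -19.6)
  traj <- make_toy_traj(xy, z, species = rep("POPC", n), leaflet = leaf,
                        box = c(80, 80))
  prof <- electron_density_profile(traj, bin_width = 1)
  peaks <- prof$z[order(prof$density, decreasing = TRUE)][1:2]
  expect_equal(abs(diff(sort(peaks))), 39.2, tolerance = 1)
  ## conservation: integral x area = particles per frame
  total <- sum(prof$density) * attr(prof, "bin_width") * attr(prof, "area")
  expect_equal(total, n, tolerance = 1e-9)
  expect_error(electron_density_profile(traj,
                                        groups = list(g = list(species = "X"))),
               "no particles")
})

test_that("thickness equals the planted phosphate separation", {
  n <- 40
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  leaf <- rep(c("upper", "lower"), each = n / 2)
  traj <- make_toy_traj(xy, ifelse(leaf == "upper", 16.2, -16.2),
                        species = rep("POPC-OOH", n), leaflet = leaf,
                        box = c(50, 50))
  expect_equal(bilayer_thickness(traj)$thickness, 32.4, tolerance = 1e-12)
  flat <- make_toy_traj(xy, rep(0, n), rep("A", n), leaf, c(50, 50),
                        thickness = 0)
  expect_equal(bilayer_thickness(flat)$thickness, 0)
  ## symmetric jitter leaves thickness unbiased
  set.seed(7)
  nf <- 250
  zj <- matrix(rnorm(n * nf, 0, 1), n, nf) +
    ifelse(leaf == "upper", 16.2, -16.2)
  traj_j <- make_toy_traj(array(rep(xy, nf), c(n, 2, nf)), zj,
                          rep("A", n), leaf, c(50, 50))
  th <- bilayer_thickness(traj_j)
  expect_lt(abs(th$thickness - 32.4), 3 * th$se)
})

test_that("order parameter hits its analytic limits", {
  aligned <- cbind(0, 0, rep(1, 100))
  expect_equal(order_parameter_vectors(aligned), 1)
  phi <- seq(0, 2 * pi, length.out = 100)
  in_plane <- cbind(cos(phi), sin(phi), 0)
  expect_equal(order_parameter_vectors(in_plane), -0.5)
  set.seed(1)
  cz <- runif(1e5, -1, 1); ph <- runif(1e5, 0, 2 * pi)
  iso <- cbind(sqrt(1 - cz^2) * cos(ph), sqrt(1 - cz^2) * sin(ph), cz)
  expect_lt(abs(order_parameter_vectors(iso)), 0.01)
  expect_error(order_parameter_vectors(matrix(0, 2, 3)), "zero-length")
})

test_that("periodic Voronoi conserves the box area and respects symmetry", {
  ## 4 seeds on a square lattice: each cell is a quarter of the box
  lattice <- rbind(c(25, 25), c(25, 75), c(75, 25), c(75, 75))
  areas <- periodic_voronoi_areas(lattice, c(100, 100))
  expect_equal(areas, rep(2500, 4), tolerance = 1e-9)
  ## random seeds: exact tiling on every frame
  set.seed(3)
  for (i in 1:5) {
    n <- sample(10:60, 1)
    xy <- cbind(runif(n, 0, 90), runif(n, 0, 40))
    expect_equal(sum(periodic_voronoi_areas(xy, c(90, 40))), 90 * 40,
                 tolerance = 1e-6)
  }
  expect_error(periodic_voronoi_areas(lattice[1:3, ], c(100, 100)), ">= 4")
  expect_warning(periodic_voronoi_areas(rbind(lattice, c(25, 25)),
                                        c(100, 100)), "duplicate")
})

test_that("planted dense and sparse regions give a bimodal APL distribution", {
  ## jittered lattices at ~63 and ~81 A^2 per lipid in the two box halves
  set.seed(11)
  mk_lattice <- function(x0, x1, y1, apl) {
    a <- sqrt(apl)
    gx <- seq(x0 + a / 2, x1 - a / 4, by = a)
    gy <- seq(a / 2, y1 - a / 4, by = a)
    g <- expand.grid(x = gx, y = gy)
    g + matrix(rnorm(nrow(g) * 2, 0, a / 12), ncol = 2)
  }
  Ly <- 63
  dense <- mk_lattice(0, 63, Ly, 63)
  sparse <- mk_lattice(63, 63 + 81, Ly, 81)
  xy <- rbind(as.matrix(dense), as.matrix(sparse))
  areas <- periodic_voronoi_areas(xy, c(144, Ly))
  d <- apl_distribution(areas)
  expect_gt(d$delta_bic, 10)
  expect_equal(sort(d$gmm_means), c(63, 81), tolerance = 0.08)
})

test_that("enrichment equals the brute-force oracle exactly", {
  set.seed(5)
  n <- 120
  xy <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  species <- rep(c("A", "B"), each = n / 2)
  traj <- make_toy_traj(xy, rep(15, n), species, rep("upper", n),
                        box = c(60, 60), thickness = 30)
  ## add a lower leaflet so both leaflets exist, same layout
  traj2 <- make_toy_traj(rbind(xy, xy), c(rep(15, n), rep(-15, n)),
                         rep(species, 2),
                         rep(c("upper", "lower"), each = n),
                         box = c(60, 60), thickness = 30)
  E_pipe <- enrichment(traj2, radius = 12, n_boot = 0)$E
  E_oracle <- brute_enrichment(xy, species, c(60, 60), 12)
  expect_equal(E_pipe, E_oracle, tolerance = 1e-12)
  ## fully segregated half-boxes: strong self-enrichment
  seg_xy <- cbind(c(runif(60, 0, 28), runif(60, 32, 60)), runif(120, 0, 60))
  seg <- make_toy_traj(rbind(seg_xy, seg_xy),
                       c(rep(15, n), rep(-15, n)), rep(species, 2),
                       rep(c("upper", "lower"), each = n),
                       box = c(60, 60), thickness = 30)
  E_seg <- enrichment(seg, radius = 12, n_boot = 0)$E
  expect_equal(E_seg, brute_enrichment(seg_xy, species, c(60, 60), 12),
               tolerance = 1e-12)
  expect_gt(E_seg["A", "A"], 1)
  expect_lt(E_seg["A", "B"], 1)
  ## minimum-image violation
  expect_error(enrichment(traj2, radius = 40), "minimum-image")
})

test_that("enrichment converges to 1 under ideal mixing across seeds", {
  e_self <- vapply(1:40, function(s) {
    traj <- gen_bilayer_traj(bilayer_sim_spec(
      box_lengths = c(80, 80), n_per_leaflet = 100, n_frames = 4,
      attraction_eps = 0, n_chain_sites = 0, seed = 1000 + s))
    enrichment(traj, radius = 12, n_boot = 0)$E["POPC", "POPC"]
  }, numeric(1))
  ## z-test against E = 1 at alpha = 0.01
  z <- abs(mean(e_self) - 1) / (sd(e_self) / sqrt(length(e_self)))
  expect_lt(z, qnorm(0.995))
})

test_that("enrichment is invariant under periodic translation", {
  set.seed(6)
  n <- 80
  xy <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  species <- rep(c("A", "B"), n / 2)
  mk <- function(shift) {
    xs <- cbind((xy[, 1] + shift[1]) %% 60, (xy[, 2] + shift[2]) %% 60)
    make_toy_traj(rbind(xs, xs), c(rep(15, n), rep(-15, n)),
                  rep(species, 2), rep(c("upper", "lower"), each = n),
                  box = c(60, 60), thickness = 30)
  }
  E0 <- enrichment(mk(c(0, 0)), radius = 10, n_boot = 0)$E
  E1 <- enrichment(mk(c(23.7, 41.2)), radius = 10, n_boot = 0)$E
  expect_equal(E0, E1, tolerance = 1e-12)
})

test_that("snorkelling fraction respects the threshold convention", {
  n <- 60
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  leaf <- rep(c("upper", "lower"), each = n / 2)
  z_phos <- ifelse(leaf == "upper", 18, -18)
  ## all peroxides at the midplane -> fraction 0
  mid <- make_toy_traj(xy, z_phos, rep("POPC-OOH", n), leaf, c(50, 50),
                       z_perox = matrix(0, n, 1))
  expect_equal(snorkelling_fraction(mid)$fraction, 0)
  ## peroxides exactly at the phosphate plane with threshold 1: strict
  ## inequality -> 0
  at_plane <- make_toy_traj(xy, z_phos, rep("POPC-OOH", n), leaf, c(50, 50),
                            z_perox = matrix(z_phos, n, 1))
  expect_equal(snorkelling_fraction(at_plane, z_threshold = 1)$fraction, 0)
  expect_error(snorkelling_fraction(mid, z_threshold = 0), "threshold")
  expect_error(snorkelling_fraction(mid, z_threshold = 1.2), "threshold")
})

test_that("contact map matches planted geometry and is symmetric", {
  ## molecule pairs share (x, y); their peroxides sit 2.8 A apart in z
  ## (contact at 3.5 A cutoff) while their phosphates sit 4 A apart (no
  ## contact); distinct columns are 10 A apart laterally
  n <- 20
  xy <- cbind(rep(seq(5, 95, 10), 2), rep(10, n))
  z_perox <- matrix(c(rep(5, 10), rep(7.8, 10)), n, 1)
  traj <- make_toy_traj(xy, c(rep(20, 10), rep(24, 10)),
                        rep("POPC-OOH", n), rep("upper", n),
                        box = c(100, 100), z_perox = z_perox,
                        thickness = 40)
  cm <- contact_map(traj, c("phosphate", "peroxide_O"), cutoff = 3.5)
  ## each peroxide touches exactly its planted partner: 20 ordered pairs
  ## out of n*(n-1)
  expect_equal(cm["peroxide_O", "peroxide_O"], 20 / (n * (n - 1)),
               tolerance = 1e-12)
  expect_equal(cm["phosphate", "phosphate"], 0)
  expect_equal(cm["phosphate", "peroxide_O"], 0)
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_error(contact_map(traj, c("phosphate", "headgroup")), "unknown")
})

test_that("ballistic motion is flagged as non-diffusive", {
  n <- 30; nf <- 60
  xy <- array(0, c(2 * n, 2, nf))
  v <- 0.35
  for (f in seq_len(nf)) {
    xy[, 1, f] <- (seq_len(2 * n) * 3 + v * f) %% 200
    xy[, 2, f] <- (seq_len(2 * n) * 5) %% 200
  }
  leaf <- rep(c("upper", "lower"), each = n)
  traj <- make_toy_traj(xy, matrix(ifelse(leaf == "upper", 18, -18),
                                   2 * n, nf),
                        rep("A", 2 * n), leaf, box = c(200, 200),
                        thickness = 36)
  d <- msd_diffusion(traj)
  expect_match(d$flag, "non-diffusive")
})

test_that("Saffman-Delbruck bridge matches a direct evaluation and inverts", {
  ## independent closed-form evaluation at the in-scope parameter set
  kB <- 1.380649e-23; Tk <- 300
  eta_m <- 0.241; h <- 3.24e-9; r <- 0.45e-9; eta_w <- 1e-3
  L_sd <- eta_m * h / (2 * eta_w)
  D_direct <- kB * Tk / (4 * pi * eta_m * h) *
    (log(L_sd / r) - 0.57721566490153286) * 1e12
  got <- saffman_delbruck(241, 3.24, 0.45, 1, 300)
  expect_equal(got$D_um2_s, D_direct, tolerance = 1e-12)
  expect_equal(got$D_A2_ns, D_direct * 0.1, tolerance = 1e-12)
  ## roundtrip identity
  eta_back <- sd_membrane_viscosity(got$D_um2_s, 3.24, 0.45, 1, 300)
  expect_equal(eta_back, 241, tolerance = 1e-8)
  ## monotone: doubling viscosity lowers D
  expect_lt(saffman_delbruck(482, 3.24, 0.45, 1, 300)$D_um2_s, got$D_um2_s)
  ## probe outside the SD regime
  expect_error(saffman_delbruck(1, 3.24, 10, 1, 300), "SD regime")
})
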