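test_that("bilayer spec validation enforces physical limits", {
  expect_error(bilayer_sim_spec(species_fractions = c(A = 0.6, B = 0.6)),
               "sum to 1")
  expect_error(bilayer_sim_spec(species_fractions = c(A = 1),
                                diffusion_coeffs = c(B = 1)), "cover")
  expect_error(bilayer_sim_spec(snorkel_fraction = 1.5), "snorkel_fraction")
  expect_error(bilayer_sim_spec(box_lengths = c(20, 20),
                                species_fractions = c(A = 1),
                                diffusion_coeffs = c(A = 50),
                                order_target = c(A = 0.2),
                                peroxide_species = character(0)),
               "unphysical step")
})

test_that("trajectory generation is seed-deterministic", {
  spec <- bilayer_sim_spec(n_per_leaflet = 30, n_frames = 10,
                           n_chain_sites = 2, seed = 5)
  t1 <- gen_bilayer_traj(spec)
  t2 <- gen_bilayer_traj(spec)
  expect_identical(t1$xy, t2$xy)
  expect_identical(t1$z_perox, t2$z_perox)
  expect_identical(t1$chain, t2$chain)
})

test_that("non-interacting mixture stays uniform (KS on final frame)", {
  traj <- gen_bilayer_traj(bilayer_sim_spec(n_per_leaflet = 200,
                                            n_frames = 80,
                                            attraction_eps = 0,
                                            n_chain_sites = 0, seed = 17))
  f <- traj$n_frames
  x <- traj$xy[, 1, f] / traj$box[1]
  y <- traj$xy[, 2, f] / traj$box[2]
  expect_gt(suppressWarnings(stats::ks.test(x, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(y, "punif"))$p.value, 0.01)
})

test_that("unwrapped displacements obey <dr^2> = 4 D dt", {
  ## > 10^5 displacement samples per species
  traj <- gen_bilayer_traj(bilayer_sim_spec(attraction_eps = 0,
                                            n_chain_sites = 0, seed = 23))
  un <- traj$xy_unwrapped
  nf <- traj$n_frames
  d <- un[, , 2:nf] - un[, , 1:(nf - 1)]
  for (s in names(traj$truth$diffusion_coeffs)) {
    sel <- traj$molecules$species == s
    msd1 <- mean(d[sel, 1, ]^2 + d[sel, 2, ]^2)
    expect_equal(msd1 / (4 * traj$dt),
                 traj$truth$diffusion_coeffs[[s]], tolerance = 0.05)
  }
})

test_that("snorkelling occupancy matches the stationary fraction", {
  traj <- gen_bilayer_traj(bilayer_sim_spec(n_per_leaflet = 150,
                                            n_frames = 300,
                                            attraction_eps = 0,
                                            n_chain_sites = 0, seed = 31))
  state <- traj$perox_state[!is.na(traj$perox_state[, 1]), ]
  expect_equal(mean(state), 0.4, tolerance = 0.12)
  ## slow switching: dwell times far exceed one frame
  r <- rle(state[1, ])
  expect_gt(mean(r$lengths), 5)
})

test_that("chain vectors reproduce the target order parameter", {
  spec <- bilayer_sim_spec(n_per_leaflet = 100, n_frames = 60,
                           attraction_eps = 0, n_chain_sites = 3,
                           order_target = c(POPC = 0.25, `POPC-OOH` = 0.1),
                           seed = 8)
  op <- order_parameter(gen_bilayer_traj(spec))
  mean_s <- tapply(op$s_cd, op$species, mean)
  expect_lt(abs(mean_s[["POPC"]] - 0.25), 0.03)
  expect_lt(abs(mean_s[["POPC-OOH"]] - 0.1), 0.03)
})

test_that("tidy view and XYZ round trip preserve coordinates", {
  traj <- gen_bilayer_traj(bilayer_sim_spec(n_per_leaflet = 10,
                                            n_frames = 3,
                                            n_chain_sites = 2, seed = 3))
  df <- as.data.frame(traj)
  expect_setequal(unique(df$role), c("phosphate", "peroxide_O", "chain_site"))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_traj(traj, path)
  frames <- read_xyz_traj(path)
  expect_length(frames, 3)
  expect_equal(attr(frames, "box"), traj$box, tolerance = 1e-6)
  f1 <- frames[[2]]
  d1 <- df[df$frame == 2, ]
  expect_equal(f1$x, d1$x, tolerance = 1e-6)
  expect_equal(f1$z, d1$z, tolerance = 1e-6)
  expect_identical(f1$species, d1$species)
})
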