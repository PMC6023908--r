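test_that("GRO files round-trip atoms, coordinates, box and times", {
  g <- gen_membrane_traj(n_lipids = 8, n_solutes = 2,
                         hbond_schedule = c(0, 2))
  path <- tempfile(fileext = ".gro")
  on.exit(unlink(path))
  write_gro(g$gro$atoms, g$gro$frames, path)
  rt <- read_gro(path)
  expect_equal(nrow(rt$atoms), nrow(g$gro$atoms))
  expect_equal(rt$atoms$name, g$gro$atoms$name)
  expect_equal(rt$atoms$resname, g$gro$atoms$resname)
  expect_equal(length(rt$frames), 2L)
  expect_equal(rt$frames[[2]]$box, g$gro$frames[[2]]$box, tolerance = 1e-9)
  expect_equal(rt$frames[[2]]$time_ns, 1)
  # coordinates preserved to the 0.001 nm precision of the format
  expect_lt(max(abs(rt$frames[[1]]$coords - g$gro$frames[[1]]$coords)),
            5.1e-4)
  expect_error(read_gro(file.path(tempdir(), "absent.gro")), "not found")
})

test_that("leaflet assignment splits a symmetric bilayer and warns on monolayers", {
  g <- gen_membrane_traj(n_lipids = 128, n_solutes = 32)
  tr <- trajectory_system(g$gro, g$config)
  lab <- assign_leaflets(tr)
  expect_equal(as.vector(table(lab)), c(64L, 64L))
  # generator truth: solutes mirror the leaflet split too
  expect_equal(sum(g$truth$leaflet == "upper"), 16L)

  # collapse the lower leaflet onto the upper: no longer a bilayer
  mono <- g$gro
  z <- mono$frames[[1]]$coords[, 3]
  zc <- mono$frames[[1]]$box[3] / 2
  mono$frames[[1]]$coords[, 3] <- zc + abs(z - zc)
  tr2 <- trajectory_system(mono, g$config)
  expect_warning(assign_leaflets(tr2), "one side")
})

test_that("depth profile reproduces constructed depths and interfacial placement", {
  # solute COM exactly at the bilayer centre
  g0 <- gen_membrane_traj(n_lipids = 32, n_solutes = 8, depth_nm = 0)
  tr0 <- trajectory_system(g0$gro, g0$config)
  expect_equal(depth_profile(tr0)$solute_z, 0, tolerance = 1e-9)

  g <- gen_membrane_traj(n_lipids = 32, n_solutes = 8, depth_nm = 1.2)
  tr <- trajectory_system(g$gro, g$config)
  dp <- depth_profile(tr)
  expect_equal(dp$solute_z, 1.2, tolerance = 1e-6)
  expect_equal(dp$phosphate_z, 2.0, tolerance = 1e-6)
  expect_equal(dp$glycerol_z, 1.5, tolerance = 1e-6)

  # interfacial scenario: solutes at phosphate depth
  gi <- gen_membrane_traj(n_lipids = 32, n_solutes = 8, depth_nm = 2.0)
  dpi <- depth_profile(trajectory_system(gi$gro, gi$config))
  expect_lt(abs(dpi$solute_z[1] - dpi$phosphate_z[1]), 0.05)
})

test_that("depth and angle observables are invariant under rigid translation", {
  g <- gen_membrane_traj(n_lipids = 32, n_solutes = 8,
                         hbond_schedule = c(1, 3))
  tr <- trajectory_system(g$gro, g$config)
  shift <- c(1.3, -0.7, 2.9)
  g2 <- g$gro
  for (f in seq_along(g2$frames))
    g2$frames[[f]]$coords <- sweep(g2$frames[[f]]$coords, 2, shift, "+")
  tr2 <- trajectory_system(g2, g$config)
  expect_equal(depth_profile(tr2)$solute_z, depth_profile(tr)$solute_z,
               tolerance = 1e-9)
  expect_equal(as.data.frame(hbond_timeseries(tr2)),
               as.data.frame(hbond_timeseries(tr)), tolerance = 1e-9)
  expect_equal(bond_vector_angles(tr2)$density,
               bond_vector_angles(tr)$density)
})

test_that("wrapped depths never exceed half the box height", {
  g <- gen_membrane_traj(n_lipids = 32, n_solutes = 8, depth_nm = 1.0)
  # push every solute up by two box lengths: wrapping must restore depths
  g2 <- g$gro
  sol <- which(g2$atoms$resname == "ALK")
  g2$frames[[1]]$coords[sol, 3] <- g2$frames[[1]]$coords[sol, 3] +
    2 * g2$frames[[1]]$box[3]
  dp <- depth_profile(trajectory_system(g2, g$config))
  expect_equal(dp$solute_z[1], 1.0, tolerance = 1e-6)
  expect_lt(max(unlist(dp[, -1])), g2$frames[[1]]$box[3] / 2)
})

test_that("hydrogen-bond counting honours distance and angle cutoffs", {
  box <- c(5, 5, 5)
  donors <- data.frame(donor = 1L, hydrogen = 2L, side = "solute")
  acceptors <- data.frame(index = 3L, class = "phosphate", side = "lipid")
  place <- function(a_pos) rbind(c(1, 1, 1), c(1.1, 1, 1), a_pos)

  # too far: 0.50 nm > 0.35 nm
  expect_equal(count_hbonds(place(c(1.5, 1, 1)), box, donors, acceptors)[["total"]], 0)
  # ideal collinear geometry at 0.28 nm
  expect_equal(count_hbonds(place(c(1.28, 1, 1)), box, donors, acceptors)[["total"]], 1)
  # close but misaligned: H-D-A angle of 90 degrees
  expect_equal(count_hbonds(place(c(1, 1.28, 1)), box, donors, acceptors)[["total"]], 0)
  # minimal image: acceptor across the periodic boundary
  expect_equal(count_hbonds(place(c(1 - 5 + 0.28, 1, 1)), box, donors,
                            acceptors)[["total"]], 1)
})

test_that("a constructed frame with seven qualifying pairs counts exactly seven", {
  box <- c(6, 6, 6)
  # seven donors in bonding geometry plus decoys, on a grid coarse enough
  # that no cross-molecule pair can qualify by accident
  n_bond <- 7; n_decoy <- 13
  coords <- matrix(0, (n_bond + n_decoy) * 3, 3)
  donors <- data.frame(donor = integer(0), hydrogen = integer(0),
                       side = character(0))
  acceptors <- data.frame(index = integer(0), class = character(0),
                          side = character(0))
  row <- 0
  for (i in seq_len(n_bond + n_decoy)) {
    base <- c(((i - 1) %% 5) * 1.1 + 0.5, ((i - 1) %/% 5) * 1.1 + 0.5, 3)
    d <- row + 1; h <- row + 2; a <- row + 3; row <- row + 3
    coords[d, ] <- base
    coords[h, ] <- base + c(0.1, 0, 0)
    coords[a, ] <- base + if (i <= n_bond) c(0.30, 0, 0) else c(0, 0, 0.6)
    donors <- rbind(donors, data.frame(donor = d, hydrogen = h,
                                       side = "solute"))
    acceptors <- rbind(acceptors,
                       data.frame(index = a, class = "ester",
                                  side = "lipid"))
  }
  got <- count_hbonds(coords, box, donors, acceptors)
  expect_equal(got[["total"]], 7)
  expect_equal(got, oracle_hbonds(coords, box, donors, acceptors))
})

test_that("hydrogen-bond counts equal the brute-force oracle on random frames", {
  set.seed(32)
  for (i in 1:12) {
    fr <- random_hbond_frame()
    got <- count_hbonds(fr$coords, fr$box, fr$donors, fr$acceptors)
    expect_equal(got, oracle_hbonds(fr$coords, fr$box, fr$donors,
                                    fr$acceptors))
  }
})

test_that("hbond time series reproduces schedules and trailing-window means", {
  g <- gen_membrane_traj(n_lipids = 16, n_solutes = 4,
                         hbond_schedule = c(2, 2, 2, 2))
  hb <- hbond_timeseries(trajectory_system(g$gro, g$config))
  expect_equal(hb$total, rep(2, 4))
  expect_equal(attr(hb, "window_means")[["total"]], 2)

  g2 <- gen_membrane_traj(n_lipids = 16, n_solutes = 4,
                          hbond_schedule = c(0, 0, 4, 4))
  tr2 <- trajectory_system(g2$gro, g2$config)
  hb2 <- hbond_timeseries(tr2, window_ns = 1.0)
  expect_equal(attr(hb2, "window_means")[["total"]], 4)
  expect_equal(attr(hbond_timeseries(tr2), "window_means")[["total"]], 2)
  expect_error(hbond_timeseries(tr2, window_ns = -1), "positive")
  expect_error(hbond_timeseries(tr2, window_ns = 100), "span")
})

test_that("tilt angles hit trivial geometries exactly", {
  atoms <- data.frame(resid = c(1, 1, 2, 2, 2), resname = "ALK",
                      name = c("CV", "NV", "CR1", "CR2", "CR3"))
  # one solute per geometry would complicate the selection; use one molecule
  atoms$resid <- 1
  config <- list(lipid_resnames = character(0), solute_resnames = "ALK",
                 roles = list(), donors = list(), acceptors = list(),
                 orient_vector = list(resname = "ALK", from = "CV",
                                      to = "NV"),
                 ring_triplet = list(resname = "ALK",
                                     atoms = c("CR1", "CR2", "CR3")))
  frame_for <- function(nv, ring) {
    list(coords = rbind(c(1, 1, 1), nv, ring[[1]], ring[[2]], ring[[3]]),
         box = c(5, 5, 5), time_ns = 0)
  }
  mk <- function(nv, ring)
    trajectory_system(list(atoms = atoms, frames = list(frame_for(nv, ring))),
                      config)
  ring_xy <- list(c(1, 1, 2), c(1.2, 1, 2), c(1, 1.2, 2))
  ring_xz <- list(c(1, 1, 2), c(1.2, 1, 2), c(1, 1, 2.2))

  # vector along +z
  tr <- mk(c(1, 1, 1.5), ring_xy)
  d <- bond_vector_angles(tr, bin_deg = 1)
  expect_equal(angle_modes(d, 1), 0.5)
  # ring in the xy-plane: normal along z
  r <- ring_normal_angles(tr, bin_deg = 1, fold = TRUE)
  expect_equal(angle_modes(r, 1), 0.5)

  # vector in the xy-plane: exactly 90 degrees, on the bin edge
  tr2 <- mk(c(1.5, 1, 1), ring_xz)
  d2 <- bond_vector_angles(tr2, bin_deg = 1)
  expect_equal(angle_modes(d2, 1), 90.5)
  # ring plane containing z: normal perpendicular to z
  r2 <- ring_normal_angles(tr2, bin_deg = 1)
  expect_equal(angle_modes(r2, 1), 90.5)
})

test_that("mirrored leaflets give supplementary tilt modes that folding merges", {
  g <- gen_membrane_traj(n_lipids = 32, n_solutes = 8, tilt_deg = 35,
                         ring_tilt_deg = 30)
  tr <- trajectory_system(g$gro, g$config)
  unfolded <- bond_vector_angles(tr)
  modes <- sort(angle_modes(unfolded, 2))
  expect_equal(modes, c(35, 145), tolerance = 0.03)
  folded <- bond_vector_angles(tr, fold = TRUE)
  expect_equal(angle_modes(folded, 1), 35, tolerance = 0.03)
  # folding preserves total probability mass
  expect_equal(sum(unfolded$density) * 2, 1, tolerance = 1e-9)
  expect_equal(sum(folded$density) * 2, 1, tolerance = 1e-9)
  expect_equal(folded$n_samples, unfolded$n_samples)

  rn <- ring_normal_angles(tr, fold = TRUE, bin_deg = 0.5)
  expect_equal(angle_modes(rn, 1), 30.25, tolerance = 0.3)
})

test_that("degenerate vectors and collinear rings are skipped with a count", {
  atoms <- data.frame(resid = 1, resname = "ALK",
                      name = c("CV", "NV", "CR1", "CR2", "CR3"))
  config <- list(lipid_resnames = character(0), solute_resnames = "ALK",
                 roles = list(), donors = list(), acceptors = list(),
                 orient_vector = list(resname = "ALK", from = "CV",
                                      to = "NV"),
                 ring_triplet = list(resname = "ALK",
                                     atoms = c("CR1", "CR2", "CR3")))
  co <- rbind(c(1, 1, 1), c(1, 1, 1),            # zero-length vector
              c(1, 1, 2), c(1.1, 1, 2), c(1.2, 1, 2))  # collinear ring
  gro <- list(atoms = atoms,
              frames = list(list(coords = co, box = c(5, 5, 5),
                                 time_ns = 0),
                            list(coords = co + 0.0, box = c(5, 5, 5),
                                 time_ns = 1)))
  # add a valid second frame so the histogram has samples
  gro$frames[[2]]$coords[2, ] <- c(1, 1, 1.4)
  gro$frames[[2]]$coords[4, ] <- c(1.1, 1.1, 2)
  tr <- trajectory_system(gro, config)
  d <- bond_vector_angles(tr)
  expect_equal(d$n_skipped, 1L)
  expect_equal(d$n_samples, 1L)
  r <- ring_normal_angles(tr)
  expect_equal(r$n_skipped, 1L)
})

test_that("selection resolution validates roles and donor hydrogens", {
  g <- gen_membrane_traj(n_lipids = 8, n_solutes = 2)
  bad <- g$config
  bad$donors <- list(list(resname = "ALK", atom = "ND", hydrogen = "HX"))
  expect_error(trajectory_system(g$gro, bad), "hydrogen")
  empty <- g$config
  empty$lipid_resnames <- "NOPE"
  tr_nolip <- trajectory_system(g$gro, empty)
  expect_error(depth_profile(tr_nolip), "lipid")
  expect_error(assign_leaflets(tr_nolip), "lipid")
})
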