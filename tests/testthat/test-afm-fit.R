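test_that("cross-correlation matches the hand-computed form", {
  # 4-pixel grid: exp = [1,2;3,4], sim = [4,3;2,1] -> 20/30
  a <- afm_image(matrix(c(1, 3, 2, 4), 2), 5)
  b <- afm_image(matrix(c(4, 2, 3, 1), 2), 5)
  expect_equal(cross_correlation(a, b), 20 / 30)
  # scale invariance to 1e-12
  for (c0 in c(0.01, 1, 250)) {
    expect_equal(cross_correlation(a, afm_image(c0 * a$heights, 5)), 1,
                 tolerance = 1e-12)
  }
  # orthogonal supports
  o1 <- afm_image(matrix(c(1, 0, 0, 0), 2), 5)
  o2 <- afm_image(matrix(c(0, 0, 1, 0), 2), 5)
  expect_equal(cross_correlation(o1, o2), 0)
  # degenerate / mismatched input
  z <- afm_image(matrix(0, 2, 2), 5)
  expect_error(cross_correlation(z, z), "all zero")
  expect_error(cross_correlation(a, afm_image(matrix(0, 3, 3), 5)),
               "grid mismatch")
})

test_that("pseudopotential is linear in (1 - CC) and zero at CC = 1", {
  w <- fit_weights(theta_afm = 1, kBT = 1)
  expect_equal(afm_pseudopotential(1, w, 100), 0)
  expect_equal(afm_pseudopotential(0, w, 100), 100)
  expect_equal(afm_pseudopotential(0.87, w, 100), 13)
  # strictly decreasing in cc
  v <- vapply(seq(0, 1, 0.1), afm_pseudopotential, 1, weights = w,
              n_beads_total = 50)
  expect_true(all(diff(v) < 0))
})

test_that("energies vanish at the reference state and grow off it", {
  cg <- phantom_Y()
  r <- cg_restraints(cg)
  cov <- covalent_energy(cg, r)
  expect_equal(unname(cov), c(0, 0, 0), tolerance = 1e-9)
  nc <- noncovalent_energy(cg, r)
  expect_lt(nc[["e_pairing"]], 1e-6)
  expect_lt(nc[["e_stacking"]], 1e-6)

  # one stretched bond contributes k * delta^2
  cg2 <- cg
  bond <- r$bonds[1, ]
  dir <- cg2$xyz[bond$b, ] - cg2$xyz[bond$a, ]
  dir <- dir / sqrt(sum(dir^2))
  # move a terminal bead so only that bond stretches appreciably
  tip_bead <- 2L  # base bead of nt 1: only bonded to its backbone
  bvec <- cg2$xyz[tip_bead, ] - cg2$xyz[1L, ]
  bvec <- bvec / sqrt(sum(bvec^2))
  delta <- 0.8
  cg2$xyz[tip_bead, ] <- cg2$xyz[tip_bead, ] + delta * bvec
  cov2 <- covalent_energy(cg2, r)
  expect_equal(cov2[["e_length"]], cg$config$k_length * delta^2,
               tolerance = 1e-6)

  # paired beads pulled apart raise the pairing energy
  perturbed <- perturb_arms(cg, angles = c("2" = 60))
  nc2 <- noncovalent_energy(perturbed, r)
  expect_gte(nc2[["e_pairing"]], nc[["e_pairing"]])

  # randomized coordinates always cost energy (20 seeds)
  etot0 <- sum(covalent_energy(cg, r)) + sum(noncovalent_energy(cg, r))
  for (s in 1:20) {
    cgr <- cg
    cgr$xyz <- cg$xyz + rnatopo:::with_seed(s, matrix(
      rnorm(length(cg$xyz), 0, 1.5), nrow(cg$xyz)))
    etot <- sum(covalent_energy(cgr, r)) + sum(noncovalent_energy(cgr, r))
    expect_gt(etot, etot0)
  }
})

test_that("a near-contact pair costs a large but finite soft-core energy", {
  cfg <- cg_config()
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  cg <- rnatopo:::new_cg_structure(xyz, c(1L, 5L), c(1L, 1L),
                                   c("BS", "BS"), rep(NA_integer_, 2),
                                   matrix(integer(0), ncol = 2),
                                   config = cfg)
  r <- list(bonds = data.frame(a = integer(0), b = integer(0),
                               d0 = numeric(0), k = numeric(0)),
            angles = data.frame(), dihedrals = data.frame(),
            pairing = data.frame(a = integer(0), b = integer(0),
                                 d0 = numeric(0)),
            stacking = data.frame(a = integer(0), b = integer(0),
                                  d0 = numeric(0)),
            excl_keys = numeric(0))
  e <- noncovalent_energy(cg, r, cfg)
  expect_gt(e[["e_contact"]], 1e3)
  expect_true(is.finite(e[["e_contact"]]))
})

test_that("total energy bookkeeping is exact and weight semantics hold", {
  cg <- phantom_Y()
  r <- cg_restraints(cg)
  img <- render_surface(cg)
  w <- fit_weights()
  e <- total_energy(cg, img, r, w)
  expect_equal(e$cc, 1, tolerance = 1e-12)
  expect_lt(e$v_afm, 1e-9)
  recomposed <- e$v_afm + w$theta_c * (e$e_angle + e$e_length + e$e_dih) +
    w$theta_stacking * e$e_stacking + w$theta_pairing * e$e_pairing +
    w$theta_contact * e$e_contact
  expect_equal(e$e_total, recomposed, tolerance = 1e-9)

  # theta_afm = 0 makes the total independent of the image
  w0 <- fit_weights(theta_afm = 0)
  e_img <- total_energy(cg, img, r, w0)
  e_noimg <- total_energy(cg, NULL, r, w0)
  expect_equal(e_img$e_total, e_noimg$e_total, tolerance = 1e-12)
})

test_that("RMSD obeys translation and Kabsch identities", {
  cg <- phantom_hairpin()
  b <- transform_cg(cg, translation = c(3, 4, 0))
  expect_equal(rmsd_cg(cg, b, superpose = FALSE), 5, tolerance = 1e-12)
  rig <- transform_cg(cg, rnatopo:::rot_axis(c(1, 2, 3), 1.1),
                      pivot = c(5, -2, 7), translation = c(10, -4, 2))
  expect_lt(rmsd_cg(cg, rig, superpose = TRUE), 1e-6)
  expect_equal(rmsd_cg(cg, cg), 0)
  expect_error(rmsd_cg(cg, phantom_Y()), "mismatch")
  # cross-check the superposition against the field-standard implementation
  inds <- seq_len(3 * n_beads(cg))
  sup <- bio3d::fit.xyz(fixed = as.numeric(t(cg$xyz)),
                        mobile = as.numeric(t(rig$xyz)),
                        fixed.inds = inds, mobile.inds = inds)
  ours <- rnatopo:::kabsch_superpose(rig$xyz, cg$xyz)
  expect_equal(max(abs(matrix(sup, ncol = 3, byrow = TRUE) - ours)), 0,
               tolerance = 1e-6)
})

test_that("pose registration recovers a known pose and rejects flat images", {
  cg <- phantom_Y()
  posed <- transform_cg(cg, rnatopo:::rotz(45 * pi / 180),
                        pivot = colMeans(cg$xyz), translation = c(12, -8, 0))
  img <- render_surface(posed)
  reg <- register_pose(cg, img, n_rot = 24)
  expect_equal(reg$rotation %% 360, 45)
  expect_gt(reg$cc, 0.99)
  # recovered pose beats every other grid pose by construction of the search
  expect_error(register_pose(cg, afm_image(matrix(0, 8, 8), 5)), "empty")
})

test_that("dynamic fitting is seeded, stable at the truth and improves CC", {
  truth <- phantom_Y()
  img <- render_surface(truth)
  restr <- cg_restraints(truth)
  sch <- fit_schedule(n_steps = 1200, t_start = 1, t_end = 0.2)
  fits <- lapply(1:3, function(s) {
    dynamic_fit(truth, img, seed = s, schedule = sch, restraints = restr)
  })
  for (f in fits) {
    expect_gte(f$cc, 0.99)
    expect_lte(rmsd_cg(truth, f$structure), 2)
  }
  # bit-reproducible given the seed
  again <- dynamic_fit(truth, img, seed = 1, schedule = sch,
                       restraints = restr)
  expect_identical(again$structure$xyz, fits[[1]]$structure$xyz)

  # Metropolis with a dominant image term never ends below the start CC
  start <- perturb_arms(truth, angles = c("2" = 35, "3" = -30))
  cc0 <- cross_correlation(img, render_surface(start, grid = img))
  f <- dynamic_fit(start, img, seed = 2,
                   schedule = fit_schedule(n_steps = 2500),
                   restraints = restr)
  expect_gt(f$cc, cc0)

  # zero-step schedule returns the scored start
  f0 <- dynamic_fit(start, img, seed = 1,
                    schedule = fit_schedule(n_steps = 0), restraints = restr)
  expect_equal(f0$structure$xyz, start$xyz)
  expect_equal(f0$cc, cc0, tolerance = 1e-12)
})

test_that("for a free rigid body the fit matches exhaustive pose search", {
  # 1-nt "molecule": pose moves are the only degrees of freedom
  cfg <- cg_config()
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0))
  tiny <- rnatopo:::new_cg_structure(xyz, c(1L, 1L), c(1L, 1L),
                                     c("BB", "BS"), rep(NA_integer_, 2),
                                     matrix(c(1L, 2L), 1), config = cfg)
  target <- transform_cg(tiny, rnatopo:::rotz(1.1), translation = c(8, 5, 0))
  img <- render_surface(target, pixel_size = 5, pad = 25)
  grid_best <- register_pose(tiny, img, n_rot = 72, refine_px = 3)
  f <- dynamic_fit(tiny, img, ss = NULL,
                   schedule = fit_schedule(n_steps = 4000,
                                           pose_rot_sd_deg = 15,
                                           pose_trans_sd = 4),
                   seed = 1, restraints = cg_restraints(tiny))
  expect_gte(f$cc + 0.005, grid_best$cc)
})

test_that("corrugation of a flat duplex reads near one helical pitch", {
  hx <- build_aform_helix(44, axis = c(1, 0, 0))
  img <- render_surface(hx, tip_model(1), pixel_size = 5)
  per <- corrugation_period(img)
  expect_lt(abs(per - 2.8), 0.4)
})
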