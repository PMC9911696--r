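#' AFM cross-correlation score
#'
#' Uncentered normalized cross-correlation
#' `C = sum(I_exp * I_sim) / (sqrt(sum(I_exp^2)) * sqrt(sum(I_sim^2)))`
#' between two images on the same grid, summed over the evaluation
#' footprint: the union of pixels where either image exceeds a small height
#' floor (whole-frame sums would be dominated by background zeros).  The
#' score is scale-invariant and lies in [0, 1] for non-negative images.
#'
#' @param exp_img,sim_img `afm_image`s on identical grids (experimental and
#'   simulated intensities).
#' @param floor_nm Footprint height floor in nm.
#' @return `C_AFM` in [0, 1].
#' @examples
#' a <- afm_image(matrix(c(1, 3, 2, 4), 2), 5)
#' b <- afm_image(matrix(c(4, 2, 3, 1), 2), 5)
#' cross_correlation(a, b)  # 20/30
#' @export
cross_correlation <- function(exp_img, sim_img, floor_nm = 0.1) {
  stopifnot(inherits(exp_img, "afm_image"), inherits(sim_img, "afm_image"))
  if (!all(dim(exp_img$heights) == dim(sim_img$heights))) {
    stop("grid mismatch between images")
  }
  cc <- cc_footprint_cpp(exp_img$heights, sim_img$heights, floor_nm)
  if (is.na(cc)) stop("undefined cross-correlation: an image is all zero ",
                      "on the evaluation footprint")
  cc
}

#' AFM pseudopotential
#'
#' `V_AFM = theta_afm * N * kBT * (1 - C_AFM)`: the energy that couples
#' image agreement into the dynamic fitting; zero exactly at perfect
#' correlation and strictly decreasing in `cc`.
#'
#' @param cc Cross-correlation score in [0, 1].
#' @param weights A [fit_weights()] (uses `theta_afm` and `kBT`).
#' @param n_beads_total Total number of beads `N` of the molecule.
#' @return Energy in kBT units.
#' @export
afm_pseudopotential <- function(cc, weights = fit_weights(), n_beads_total) {
  stopifnot(is.numeric(cc), length(cc) == 1)
  if (is.na(cc) || cc < -1e-9 || cc > 1 + 1e-9) {
    stop("cc must lie in [0, 1]")
  }
  weights$theta_afm * n_beads_total * weights$kBT * (1 - cc)
}

#' Root-mean-square deviation between two bead models
#'
#' @param a,b `cg_structure`s with identical bead count and ordering.
#' @param superpose Optimally superpose `b` onto `a` first (Kabsch).
#' @param backbone_only Use backbone beads only (the convention for
#'   structure-recovery statistics).
#' @return RMSD in Angstrom.
#' @export
rmsd_cg <- function(a, b, superpose = TRUE, backbone_only = TRUE) {
  if (n_beads(a) != n_beads(b)) stop("bead count mismatch")
  sel <- if (backbone_only) which(a$role == "BB") else seq_len(n_beads(a))
  P <- a$xyz[sel, , drop = FALSE]
  Q <- b$xyz[sel, , drop = FALSE]
  if (superpose) Q <- kabsch_superpose(Q, P)
  sqrt(mean(rowSums((P - Q)^2)))
}

# Rotate+translate P to optimally fit Q (least-squares, proper rotation).
kabsch_superpose <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
}

#' Register a structure's pose against an AFM image
#'
#' Deterministic exhaustive search over in-plane rotations (about the
#' vertical axis through the structure centroid) and pixel-level in-plane
#' translations around the image's height-weighted centroid, maximizing the
#' cross-correlation.  Ties keep the earliest pose in enumeration order.
#'
#' @param cg A `cg_structure`.
#' @param img Target `afm_image`.
#' @param tip A [tip_model()].
#' @param n_rot Number of rotation samples over 360 degrees.
#' @param refine_px Half-width of the translation search (pixels).
#' @param config A [cg_config()].
#' @return List with `structure` (posed `cg_structure`), `rotation`
#'   (degrees), `translation` (Angstrom) and `cc`.
#' @export
register_pose <- function(cg, img, tip = tip_model(), n_rot = 24,
                          refine_px = 2, config = cg$config) {
  if (max(img$heights) <= 0) {
    stop("undefined cross-correlation: image is empty")
  }
  px <- img$pixel_size
  w <- img$heights / sum(img$heights)
  xs <- img$origin[1] + (seq_len(ncol(img$heights)) - 1) * px
  ys <- img$origin[2] + (seq_len(nrow(img$heights)) - 1) * px
  img_ctr <- c(sum(colSums(w) * xs), sum(rowSums(w) * ys))
  ctr <- colMeans(cg$xyz)
  best <- list(cc = -Inf)
  shifts <- (-refine_px):refine_px * px
  for (ang in seq(0, 360 - 360 / n_rot, by = 360 / n_rot)) {
    rot <- transform_cg(cg, rotz(ang * pi / 180), pivot = ctr)
    fctr <- colMeans(rot$xyz)
    base_shift <- img_ctr - fctr[1:2]
    for (dy in shifts) for (dx in shifts) {
      tr <- c(base_shift[1] + dx, base_shift[2] + dy, 0)
      cand <- transform_cg(rot, translation = tr)
      sim <- render_surface(cand, tip = tip, grid = img, config = config)
      cc <- cc_footprint_cpp(img$heights, sim$heights, 0.1)
      if (!is.na(cc) && cc > best$cc + 1e-12) {
        best <- list(structure = cand, rotation = ang,
                     translation = tr[1:2], cc = cc)
      }
    }
  }
  if (!is.finite(best$cc)) stop("pose registration failed: no overlap")
  best
}

#' Annealing schedule for dynamic fitting
#'
#' @param n_steps Monte-Carlo steps.
#' @param t_start,t_end Start and end temperatures (in kBT units) of the
#'   geometric cooling.
#' @param p_helix,p_bead,p_pose Move-type probabilities (helix-subtree
#'   rotation about its junction pivot, single linker/loop nucleotide
#'   displacement, global pose move); normalized internally.
#' @param helix_sd_deg In-plane spread of helix rotations (degrees).
#' @param helix_tilt_sd_deg Out-of-plane spread (degrees).
#' @param bead_sd Spread of bead displacements (Angstrom).
#' @param pose_rot_sd_deg,pose_trans_sd Spread of global pose moves.
#' @return A list of class `fit_schedule`.
#' @export
fit_schedule <- function(n_steps = 20000, t_start = 3, t_end = 0.3,
                         p_helix = 0.45, p_bead = 0.3, p_pose = 0.25,
                         helix_sd_deg = 8, helix_tilt_sd_deg = 2.5,
                         bead_sd = 1.0, pose_rot_sd_deg = 4,
                         pose_trans_sd = 2) {
  s <- as.list(environment())
  class(s) <- "fit_schedule"
  s
}

#' Dynamic fitting of a structure to an AFM molecular surface
#'
#' Simulated-annealing Metropolis Monte-Carlo over junction arm rotations,
#' single-stranded bead moves and global pose moves, scoring each proposal
#' by the total energy (AFM pseudopotential + covalent + noncovalent
#' terms); the simulated image is re-rendered for every proposal.  The
#' reported structure follows the selection rule: among trajectory frames
#' whose cross-correlation is within `cc_tol` of the maximum, the one of
#' lowest total energy ("lowest total energy and highest CC").
#'
#' @param start A `cg_structure` with the correct bonded topology for `ss`.
#' @param img The target `afm_image`.
#' @param ss The secondary structure; defaults to `start$ss`.
#' @param weights A [fit_weights()].
#' @param schedule A [fit_schedule()].
#' @param seed RNG seed; runs are fully reproducible given the seed.
#' @param tip A [tip_model()].
#' @param restraints Optional [cg_restraints()]; by default rebuilt from a
#'   fresh deterministic reference assembly of `ss`, so that restraint
#'   references are ideal rather than inherited from a perturbed start.
#' @param kl_pairs Optional kissing-loop nucleotide pairs (see
#'   [cg_restraints()]).
#' @param cc_floor Fits ending below this CC are flagged `converged = FALSE`.
#' @param cc_tol CC band of the best-structure selection rule.
#' @param config A [cg_config()].
#' @return A list of class `fit_result`: `structure`, `cc`, `energy`
#'   (an `energy_breakdown`), `trajectory` (data frame of iteration, cc,
#'   e_total), `accept_rate`, `converged`, `seed`.
#' @export
dynamic_fit <- function(start, img, ss = start$ss, weights = fit_weights(),
                        schedule = fit_schedule(), seed = NULL,
                        tip = tip_model(), restraints = NULL,
                        kl_pairs = NULL, cc_floor = 0.8, cc_tol = 0.002,
                        config = start$config) {
  stopifnot(inherits(start, "cg_structure"), inherits(img, "afm_image"))
  if (is.null(config)) config <- cg_config()
  if (is.null(restraints)) {
    ref <- if (!is.null(ss)) {
      tryCatch(assemble_topology(ss, config = config),
               error = function(e) start)
    } else start
    restraints <- cg_restraints(ref, ss = ss, config = config,
                                kl_pairs = kl_pairs)
  }
  ht <- if (!is.null(ss)) helix_table(ss) else
    data.frame(helix = integer(0))
  arm_ids <- ht$helix
  arm_beads <- lapply(arm_ids, function(h) helix_subtree_beads(start, h))
  arm_pivot_beads <- lapply(seq_len(nrow(ht)), function(t) {
    c(2L * ht$oi[t] - 1L, 2L * ht$oj[t] - 1L)
  })
  loop_nts <- if (!is.null(ss)) which(is.na(ss$paired)) else unique(start$nt)

  score <- function(cg) {
    sim <- render_surface(cg, tip = tip, grid = img, config = config)
    cc <- cc_footprint_cpp(img$heights, sim$heights, 0.1)
    if (is.na(cc)) return(list(cc = NA_real_, e = Inf))
    cov <- covalent_energy(cg, restraints, config)
    nc <- noncovalent_energy(cg, restraints, config)
    e <- afm_pseudopotential(cc, weights, n_beads(cg)) +
      weights$theta_c * sum(cov) +
      weights$theta_stacking * nc[["e_stacking"]] +
      weights$theta_pairing * nc[["e_pairing"]] +
      weights$theta_contact * nc[["e_contact"]]
    list(cc = cc, e = unname(e))
  }

  with_seed(seed, {
    cur <- start
    sc <- score(cur)
    if (!is.finite(sc$e)) stop("start structure does not overlap the image")
    best <- list(list(cg = cur, cc = sc$cc, e = sc$e))
    max_cc <- sc$cc
    n <- schedule$n_steps
    traj <- list(data.frame(iteration = 0L, cc = sc$cc, e_total = sc$e))
    if (n < 1) {
      en <- total_energy(cur, img, restraints, weights, tip, config)
      return(structure(list(structure = cur, cc = sc$cc, energy = en,
                            pose = NULL, trajectory = traj[[1]],
                            accept_rate = NA_real_,
                            converged = sc$cc >= cc_floor, seed = seed),
                       class = "fit_result"))
    }
    pm <- c(schedule$p_helix, schedule$p_bead, schedule$p_pose)
    if (length(arm_ids) == 0) pm[1] <- 0
    if (length(loop_nts) == 0) pm[2] <- 0
    pm <- pm / sum(pm)
    temps <- schedule$t_start *
      (schedule$t_end / schedule$t_start)^((seq_len(n) - 1) / max(n - 1, 1))
    n_acc <- 0L
    log_every <- max(1L, n %/% 200L)
    for (it in seq_len(n)) {
      mv <- sample.int(3L, 1L, prob = pm)
      cand <- cur
      if (mv == 1L) {
        a <- sample.int(length(arm_ids), 1L)
        pivot <- colMeans(cur$xyz[arm_pivot_beads[[a]], , drop = FALSE])
        R <- rotz(rnorm(1, 0, schedule$helix_sd_deg) * pi / 180)
        if (runif(1) < 0.25) {
          ax <- c(cos(th <- runif(1, 0, 2 * pi)), sin(th), 0)
          R <- rot_axis(ax, rnorm(1, 0, schedule$helix_tilt_sd_deg) *
                          pi / 180) %*% R
        }
        cand <- transform_cg(cur, R, pivot = pivot, rows = arm_beads[[a]])
      } else if (mv == 2L) {
        k <- loop_nts[sample.int(length(loop_nts), 1L)]
        rows <- which(cand$nt == k)
        cand$xyz[rows, ] <- sweep(cand$xyz[rows, , drop = FALSE], 2,
                                  rnorm(3, 0, schedule$bead_sd), "+")
      } else {
        ctr <- colMeans(cur$xyz)
        if (runif(1) < 0.5) {
          cand <- transform_cg(cur, rotz(rnorm(1, 0,
                                               schedule$pose_rot_sd_deg) *
                                           pi / 180), pivot = ctr)
        } else {
          cand <- transform_cg(cur, translation =
                                 c(rnorm(2, 0, schedule$pose_trans_sd), 0))
        }
      }
      sc2 <- score(cand)
      if (is.finite(sc2$e) &&
          (sc2$e <= sc$e || runif(1) < exp((sc$e - sc2$e) / temps[it]))) {
        cur <- cand
        sc <- sc2
        n_acc <- n_acc + 1L
        if (sc$cc > max_cc) {
          max_cc <- sc$cc
          best <- Filter(function(f) f$cc >= max_cc - cc_tol, best)
        }
        if (sc$cc >= max_cc - cc_tol) {
          best[[length(best) + 1]] <- list(cg = cur, cc = sc$cc, e = sc$e)
          if (length(best) > 400) {
            ord <- order(vapply(best, function(f) f$e, 1))
            best <- best[ord[seq_len(200)]]
          }
        }
      }
      if (it %% log_every == 0L) {
        traj[[length(traj) + 1]] <- data.frame(iteration = it, cc = sc$cc,
                                               e_total = sc$e)
      }
    }
    es <- vapply(best, function(f) f$e, 1)
    pick <- best[[which.min(es)]]
    en <- total_energy(pick$cg, img, restraints, weights, tip, config)
    structure(list(structure = pick$cg, cc = pick$cc, energy = en,
                   trajectory = do.call(rbind, traj),
                   accept_rate = n_acc / n,
                   converged = pick$cc >= cc_floor, seed = seed),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Dynamic fit: CC = %.4f, E_total = %.2f kBT, %s\n",
              x$cc, x$energy$e_total,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Noise-ladder validation of the dynamic fitting
#'
#' Renders the ground-truth structure once, adds each configured noise
#' level, perturbs the start mildly and refits; reports per-level mean and
#' SD of the final CC (against the noisy image) and of the backbone RMSD to
#' the ground truth.
#'
#' @param truth Ground-truth `cg_structure` (with `ss`).
#' @param levels Noise levels in percent (default: the twelve-level ladder).
#' @param seeds One fit per seed per level.
#' @param schedule A [fit_schedule()] (use reduced steps for surveys).
#' @param perturb_sd_deg Arm-rotation spread of the starting perturbation.
#' @param tip A [tip_model()].
#' @param weights A [fit_weights()].
#' @return Data frame: `level`, `mean_cc`, `sd_cc`, `mean_rmsd`, `sd_rmsd`.
#' @export
validate_noise_ladder <- function(truth, levels = noise_ladder_levels(),
                                  seeds = 1:3,
                                  schedule = fit_schedule(n_steps = 3000),
                                  perturb_sd_deg = 25, tip = tip_model(),
                                  weights = fit_weights()) {
  clean <- render_surface(truth, tip = tip)
  restr <- cg_restraints(assemble_topology(truth$ss, config = truth$config),
                         config = truth$config)
  rows <- lapply(levels, function(lv) {
    ccs <- numeric(0)
    rmsds <- numeric(0)
    for (sd in seeds) {
      noisy <- if (lv == 0) clean else add_noise(clean, lv, seed = 10000L + sd)
      st <- perturb_arms(truth, seed = 77L + sd, sd_deg = perturb_sd_deg)
      fit <- dynamic_fit(st, noisy, ss = truth$ss, weights = weights,
                         schedule = schedule, seed = sd, tip = tip,
                         restraints = restr, config = truth$config)
      ccs <- c(ccs, fit$cc)
      rmsds <- c(rmsds, rmsd_cg(truth, fit$structure))
    }
    data.frame(level = lv, mean_cc = mean(ccs), sd_cc = sd(ccs),
               mean_rmsd = mean(rmsds), sd_rmsd = sd(rmsds))
  })
  do.call(rbind, rows)
}

#' Dominant corrugation period of a height profile
#'
#' Extracts the centre scan line along an image's longest axis and returns
#' the dominant spatial period of its detrended height profile from the FFT
#' power spectrum (parabolic interpolation around the peak frequency).
#'
#' @param img An `afm_image` of an elongated particle lying along x or y.
#' @param min_height_nm Only pixels above this height count as molecule.
#' @return Dominant period in nm.
#' @export
corrugation_period <- function(img, min_height_nm = 0.5) {
  h <- img$heights
  if (ncol(h) < nrow(h)) h <- t(h)
  ridge <- which(rowSums(h > min_height_nm) > 0)
  if (length(ridge) == 0) stop("no molecule above the height floor")
  row <- round(mean(range(ridge)))
  prof <- h[row, ]
  # keep the high interior plateau; the rounded end caps would otherwise
  # dominate the spectrum with the particle-length envelope
  on_mol <- which(prof >= 0.8 * max(prof))
  prof <- prof[min(on_mol):max(on_mol)]
  n <- length(prof)
  if (n < 8) stop("profile too short for period analysis")
  y <- prof - mean(prof)
  # first local maximum of the normalized autocorrelation: robust against
  # the partially resolved double ridge within one turn
  r <- vapply(0:(n - 4), function(lag) {
    sum(head(y, n - lag) * tail(y, n - lag)) / sum(y^2)
  }, 1)
  lag0 <- NA_real_
  for (k in 3:(length(r) - 1)) {
    if (r[k] > 0.2 && r[k] >= r[k - 1] && r[k] >= r[k + 1]) {
      lag0 <- k - 1  # r[k] corresponds to lag k-1
      den <- r[k - 1] - 2 * r[k] + r[k + 1]
      if (abs(den) > 1e-12) lag0 <- lag0 + 0.5 * (r[k - 1] - r[k + 1]) / den
      break
    }
  }
  if (is.na(lag0)) stop("no periodic corrugation detected")
  lag0 * img$pixel_size / 10  # nm
}
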