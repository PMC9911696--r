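#' Build the restraint set for a topology
#'
#' Reference values for the coarse-grained energy terms are taken from an
#' assembled reference geometry of the same secondary structure: bond
#' lengths for every covalent bond; backbone angle and dihedral references
#' within helices (keeping duplexes near ideal A-form); weak angle
#' references along single-stranded linkers; and flat-bottom distance wells
#' for base pairing (backbone-backbone and base-base distances of every
#' pair) and intra-helix stacking (consecutive base beads along each
#' strand).  Triples and quads that straddle a junction are unrestrained --
#' junction geometry is what the fitting determines.
#'
#' @param cg A `cg_structure` at reference geometry (e.g. a fresh
#'   [assemble_topology()] build).
#' @param ss Its secondary structure; defaults to `cg$ss`.
#' @param config A [cg_config()].
#' @param kl_pairs Optional two-column matrix of extra (kissing-loop)
#'   nucleotide pairs restrained like regular base pairs, with canonical
#'   A-form reference distances.
#' @return A list of class `cg_restraints` with components `bonds`,
#'   `angles`, `dihedrals`, `pairing`, `stacking` and `excl_keys`.
#' @export
cg_restraints <- function(cg, ss = cg$ss, config = cg$config,
                          kl_pairs = NULL) {
  if (is.null(config)) config <- cg_config()
  X <- cg$xyz
  nb <- n_beads(cg)
  bb <- function(k) 2L * k - 1L
  bs <- function(k) 2L * k
  pair_dist <- function(a, b) sqrt(rowSums((X[a, , drop = FALSE] -
                                              X[b, , drop = FALSE])^2))
  bonds <- data.frame(a = cg$bonds[, 1], b = cg$bonds[, 2])
  bonds$d0 <- pair_dist(bonds$a, bonds$b)
  bonds$k <- config$k_length

  helix_of_nt <- cg$helix[seq(1, nb, by = 2)]
  names(helix_of_nt) <- cg$nt[seq(1, nb, by = 2)]
  nt_helix <- function(k) helix_of_nt[as.character(k)]

  angles <- data.frame(a = integer(0), b = integer(0), c = integer(0),
                       th0 = numeric(0), k = numeric(0))
  dihedrals <- data.frame(a = integer(0), b = integer(0), c = integer(0),
                          d = integer(0), phi0 = numeric(0), k = numeric(0))
  if (!is.null(ss)) {
    strand_runs <- strand_nt_runs(cg)
    for (run in strand_runs) {
      if (length(run) >= 3) {
        k1 <- run[seq_len(length(run) - 2)]
        trip_h <- cbind(nt_helix(k1), nt_helix(k1 + 1L), nt_helix(k1 + 2L))
        same_helix <- !is.na(trip_h[, 1]) & !is.na(trip_h[, 2]) &
          !is.na(trip_h[, 3]) & trip_h[, 1] == trip_h[, 2] &
          trip_h[, 2] == trip_h[, 3]
        all_loop <- is.na(trip_h[, 1]) & is.na(trip_h[, 2]) & is.na(trip_h[, 3])
        keep <- same_helix | all_loop
        if (any(keep)) {
          a <- bb(k1[keep]); b <- bb(k1[keep] + 1L); cc <- bb(k1[keep] + 2L)
          angles <- rbind(angles, data.frame(
            a = a, b = b, c = cc,
            th0 = angle_of(X, a, b, cc),
            k = ifelse(same_helix[keep], config$k_angle,
                       config$k_angle_linker)))
        }
      }
      if (length(run) >= 4) {
        k1 <- run[seq_len(length(run) - 3)]
        quad_h <- cbind(nt_helix(k1), nt_helix(k1 + 1L),
                        nt_helix(k1 + 2L), nt_helix(k1 + 3L))
        keep <- !is.na(quad_h[, 1]) & !is.na(quad_h[, 2]) &
          !is.na(quad_h[, 3]) & !is.na(quad_h[, 4]) &
          quad_h[, 1] == quad_h[, 2] & quad_h[, 2] == quad_h[, 3] &
          quad_h[, 3] == quad_h[, 4]
        if (any(keep)) {
          a <- bb(k1[keep]); b <- bb(k1[keep] + 1L)
          cc <- bb(k1[keep] + 2L); d <- bb(k1[keep] + 3L)
          dihedrals <- rbind(dihedrals, data.frame(
            a = a, b = b, c = cc, d = d,
            phi0 = dihedral_of(X, a, b, cc, d),
            k = config$k_dihedral))
        }
      }
    }
  }

  pairing <- data.frame(a = integer(0), b = integer(0), d0 = numeric(0))
  stacking <- pairing
  pr <- if (!is.null(ss)) ss$pairs else attr(cg, "pairs")
  if (!is.null(pr) && nrow(pr) > 0) {
    pairing <- rbind(
      data.frame(a = bb(pr[, 1]), b = bb(pr[, 2]),
                 d0 = pair_dist(bb(pr[, 1]), bb(pr[, 2]))),
      data.frame(a = bs(pr[, 1]), b = bs(pr[, 2]),
                 d0 = pair_dist(bs(pr[, 1]), bs(pr[, 2]))))
    # stacking: consecutive pairs of the same helix, both strands
    hh <- if (!is.null(ss)) ss$helices else
      data.frame(helix = 1L, i = pr[, 1], j = pr[, 2])
    for (h in unique(hh$helix)) {
      d <- hh[hh$helix == h, ]
      if (nrow(d) < 2) next
      i1 <- d$i[-nrow(d)]; i2 <- d$i[-1]
      j1 <- d$j[-nrow(d)]; j2 <- d$j[-1]
      stacking <- rbind(stacking,
                        data.frame(a = bs(i1), b = bs(i2),
                                   d0 = pair_dist(bs(i1), bs(i2))),
                        data.frame(a = bs(j1), b = bs(j2),
                                   d0 = pair_dist(bs(j1), bs(j2))))
    }
  }
  if (!is.null(kl_pairs)) {
    kl_pairs <- matrix(as.integer(kl_pairs), ncol = 2)
    ref_bb <- 2 * config$backbone_radius *
      abs(sin(config$strand_phase * pi / 360))
    ref_bs <- 2 * config$base_radius *
      abs(sin(config$strand_phase * pi / 360))
    pairing <- rbind(pairing,
                     data.frame(a = bb(kl_pairs[, 1]), b = bb(kl_pairs[, 2]),
                                d0 = ref_bb),
                     data.frame(a = bs(kl_pairs[, 1]), b = bs(kl_pairs[, 2]),
                                d0 = ref_bs))
  }

  # contact exclusions: restrained pairs plus 1-3 backbone neighbours
  ex <- rbind(as.matrix(pairing[, c("a", "b")]),
              as.matrix(stacking[, c("a", "b")]))
  for (run in strand_nt_runs(cg)) {
    if (length(run) >= 3) {
      k1 <- run[seq_len(length(run) - 2)]
      ex <- rbind(ex, cbind(bb(k1), bb(k1 + 2L)))
    }
  }
  keys <- sort(unique(pmin(ex[, 1], ex[, 2]) * as.numeric(nb) - nb +
                        pmax(ex[, 1], ex[, 2]) - 1))
  res <- list(bonds = bonds, angles = angles, dihedrals = dihedrals,
              pairing = pairing, stacking = stacking, excl_keys = keys,
              n_beads = nb)
  class(res) <- "cg_restraints"
  res
}

# Contiguous nucleotide runs per chain (strands for bonded terms).
strand_nt_runs <- function(cg) {
  nts <- cg$nt[seq(1, n_beads(cg), by = 2)]
  chains <- cg$chain[seq(1, n_beads(cg), by = 2)]
  out <- list()
  for (ch in unique(chains)) {
    v <- sort(nts[chains == ch])
    out <- c(out, split(v, cumsum(c(1, diff(v) != 1))))
  }
  out
}

angle_of <- function(X, a, b, c) {
  u <- X[a, , drop = FALSE] - X[b, , drop = FALSE]
  v <- X[c, , drop = FALSE] - X[b, , drop = FALSE]
  cs <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(pmax(cs, -1), 1))
}

dihedral_of <- function(X, a, b, c, d) {
  b1 <- X[b, , drop = FALSE] - X[a, , drop = FALSE]
  b2 <- X[c, , drop = FALSE] - X[b, , drop = FALSE]
  b3 <- X[d, , drop = FALSE] - X[c, , drop = FALSE]
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  m1 <- rowcross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

rowcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Covalent energy of a structure
#'
#' Harmonic penalties about the restraint references: bond lengths
#' (kBT/A^2), angles and dihedrals (kBT/rad^2, angle differences wrapped).
#' All terms are >= 0 and vanish at the reference geometry.
#'
#' @param cg A `cg_structure`.
#' @param restraints A [cg_restraints()] set; defaults to one derived from
#'   `cg` itself (then the covalent energy is 0 by construction).
#' @param config A [cg_config()].
#' @return Named numeric vector `c(e_angle, e_length, e_dih)` in kBT.
#' @export
covalent_energy <- function(cg, restraints = NULL, config = cg$config) {
  if (is.null(restraints)) restraints <- cg_restraints(cg, config = config)
  X <- cg$xyz
  b <- restraints$bonds
  d <- sqrt(rowSums((X[b$a, , drop = FALSE] - X[b$b, , drop = FALSE])^2))
  e_length <- sum(b$k * (d - b$d0)^2)
  e_angle <- 0
  if (nrow(restraints$angles)) {
    a <- restraints$angles
    th <- angle_of(X, a$a, a$b, a$c)
    e_angle <- sum(a$k * (th - a$th0)^2)
  }
  e_dih <- 0
  if (nrow(restraints$dihedrals)) {
    dd <- restraints$dihedrals
    phi <- dihedral_of(X, dd$a, dd$b, dd$c, dd$d)
    dphi <- (phi - dd$phi0 + pi) %% (2 * pi) - pi
    e_dih <- sum(dd$k * dphi^2)
  }
  c(e_angle = e_angle, e_length = e_length, e_dih = e_dih)
}

#' Noncovalent energy of a structure
#'
#' Flat-bottom distance wells for base pairing and intra-helix stacking
#' (zero within `pair_halfwidth` / `stack_halfwidth` of the reference
#' separation, harmonic outside) plus a contact term: finite soft-core
#' repulsion below the clash distance and a screened-charge
#' (Debye-Hueckel) repulsion between backbone beads.
#'
#' @inheritParams covalent_energy
#' @return Named numeric vector `c(e_stacking, e_pairing, e_contact)` in kBT.
#' @export
noncovalent_energy <- function(cg, restraints = NULL, config = cg$config) {
  if (is.null(restraints)) restraints <- cg_restraints(cg, config = config)
  if (is.null(config)) config <- cg_config()
  X <- cg$xyz
  well <- function(df, halfwidth, k) {
    if (!nrow(df)) return(0)
    d <- sqrt(rowSums((X[df$a, , drop = FALSE] - X[df$b, , drop = FALSE])^2))
    ex <- pmax(abs(d - df$d0) - halfwidth, 0)
    sum(k * ex^2)
  }
  e_pairing <- well(restraints$pairing, config$pair_halfwidth, config$k_pair)
  e_stacking <- well(restraints$stacking, config$stack_halfwidth,
                     config$k_stack)
  e_contact <- contact_energy_cpp(X, bead_codes(cg), cg$role == "BB",
                                  as.numeric(restraints$excl_keys),
                                  config$clash_dist, config$softcore_k,
                                  config$dh_amp, config$dh_lambda,
                                  config$dh_cut)
  c(e_stacking = e_stacking, e_pairing = e_pairing, e_contact = e_contact)
}

#' Total dynamic-fitting energy
#'
#' Assembles `E_total = V_AFM + theta_c * (E_angle + E_length + E_dih) +
#' theta_stacking * E_stacking + theta_pairing * E_pairing +
#' theta_contact * E_contact`.  With `img = NULL` the pseudopotential term
#' is omitted (pure energy evaluation).
#'
#' @param cg A `cg_structure`.
#' @param img Optional experimental `afm_image` the structure is scored
#'   against.
#' @param restraints A [cg_restraints()] set (defaults to one derived from
#'   `cg`).
#' @param weights A [fit_weights()].
#' @param tip A [tip_model()] used to render the simulated surface.
#' @param config A [cg_config()].
#' @param sim Optional pre-rendered simulated image on `img`'s grid (saves a
#'   render when the caller already has it).
#' @return A list of class `energy_breakdown` with the six energy
#'   components, `v_afm`, `cc` and `e_total` (kBT).
#' @export
total_energy <- function(cg, img = NULL, restraints = NULL,
                         weights = fit_weights(), tip = tip_model(),
                         config = cg$config, sim = NULL) {
  if (is.null(restraints)) restraints <- cg_restraints(cg, config = config)
  cov <- covalent_energy(cg, restraints, config)
  nc <- noncovalent_energy(cg, restraints, config)
  cc <- NA_real_
  v_afm <- 0
  if (!is.null(img)) {
    if (is.null(sim)) {
      sim <- render_surface(cg, tip = tip, grid = img, config = config)
    }
    cc <- cross_correlation(img, sim)
    v_afm <- afm_pseudopotential(cc, weights, n_beads(cg))
  }
  e_total <- v_afm +
    weights$theta_c * sum(cov) +
    weights$theta_stacking * nc[["e_stacking"]] +
    weights$theta_pairing * nc[["e_pairing"]] +
    weights$theta_contact * nc[["e_contact"]]
  out <- list(e_angle = cov[["e_angle"]], e_length = cov[["e_length"]],
              e_dih = cov[["e_dih"]], e_stacking = nc[["e_stacking"]],
              e_pairing = nc[["e_pairing"]], e_contact = nc[["e_contact"]],
              v_afm = v_afm, cc = cc, e_total = unname(e_total))
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("E_total = %.3f kBT (V_AFM %.3f, covalent %.3f, ",
                     "pairing %.3f, stacking %.3f, contact %.3f)\n"),
              x$e_total, x$v_afm, x$e_angle + x$e_length + x$e_dih,
              x$e_pairing, x$e_stacking, x$e_contact))
  if (!is.na(x$cc)) cat(sprintf("C_AFM = %.4f\n", x$cc))
  invisible(x)
}
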