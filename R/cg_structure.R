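# Internal constructor for the coarse-grained structure container.
# Beads are ordered two per nucleotide: backbone (BB) then base (BS), so
# nucleotide k owns beads 2k-1 and 2k.  Coordinates are Angstrom.
new_cg_structure <- function(xyz, nt, chain, role, helix, bonds,
                             ss = NULL, config = cg_config()) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3,
            length(nt) == nrow(xyz), length(role) == nrow(xyz))
  if (any(!is.finite(xyz))) stop("non-finite bead coordinates")
  cg <- list(xyz = xyz, nt = as.integer(nt), chain = as.integer(chain),
             role = role, helix = as.integer(helix),
             bonds = matrix(as.integer(bonds), ncol = 2),
             ss = ss, config = config)
  class(cg) <- "cg_structure"
  cg
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("Coarse-grained RNA:", n_beads(x), "beads,",
      length(unique(x$nt)), "nt,", length(unique(x$chain)), "chain(s),",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Number of beads in a coarse-grained structure
#'
#' This is the `N` entering the AFM pseudopotential
#' `V_AFM = theta_afm * N * kBT * (1 - C_AFM)`.
#'
#' @param cg A `cg_structure`.
#' @return Integer bead count (2 beads per nucleotide per chain).
#' @export
n_beads <- function(cg) nrow(cg$xyz)

#' Bead table of a coarse-grained structure
#'
#' @param cg A `cg_structure`.
#' @return Data frame with one row per bead: `nt`, `chain`, `role`
#'   (`"BB"` backbone / `"BS"` base), `helix` and `x`, `y`, `z` (Angstrom).
#' @export
cg_beads <- function(cg) {
  data.frame(nt = cg$nt, chain = cg$chain, role = cg$role, helix = cg$helix,
             x = cg$xyz[, 1], y = cg$xyz[, 2], z = cg$xyz[, 3])
}

# Rendering radii per bead (Angstrom).
bead_radii <- function(cg, config = cg$config) {
  ifelse(cg$role == "BB", config$bead_radius_backbone,
         config$bead_radius_base)
}

# Integer code per bead used by the contact kernel: beads of the same or of
# sequence-adjacent nucleotides are never "contacts".  Chains are offset so
# inter-chain pairs always count.
bead_codes <- function(cg) {
  span <- max(cg$nt) + 100L
  as.integer(cg$nt + (cg$chain - 1L) * span)
}

#' Build an ideal coarse-grained A-form duplex
#'
#' Generates a canonical A-form double helix (two antiparallel strands,
#' `bp_per_turn` base pairs per turn, `rise` Angstrom per base pair) at two
#' beads per nucleotide.  Strand 1 occupies nucleotides `1..n_bp` (chain 1),
#' strand 2 nucleotides `n_bp+1..2*n_bp` (chain 2), with nucleotide `i`
#' paired to `2*n_bp + 1 - i`.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param origin Axis start point (Angstrom).
#' @param axis Axis direction (need not be normalized).
#' @param phase0 Azimuthal phase of the first base pair (radians).
#' @param config A [cg_config()].
#'
#' @return A `cg_structure` with `4 * n_bp` beads, all assigned to helix 1.
#' @examples
#' hx <- build_aform_helix(11)
#' measure_helix(hx, 1)
#' @export
build_aform_helix <- function(n_bp, origin = c(0, 0, 0), axis = c(0, 0, 1),
                              phase0 = 0, config = cg_config()) {
  if (!is.numeric(n_bp) || length(n_bp) != 1 || n_bp < 1) {
    stop("n_bp must be a single count >= 1")
  }
  n_bp <- as.integer(n_bp)
  fr <- axis_frame(axis)
  twist <- 2 * pi / config$bp_per_turn
  phase <- config$strand_phase * pi / 180
  n <- 2L * n_bp
  xyz <- matrix(NA_real_, 2L * n, 3)
  for (p in seq_len(n_bp)) {
    nt1 <- p
    nt2 <- 2L * n_bp + 1L - p
    ax <- origin + (p - 1) * config$rise * fr$e1
    ph1 <- phase0 + (p - 1) * twist
    ph2 <- ph1 + phase
    xyz[2 * nt1 - 1, ] <- ax + config$backbone_radius *
      (cos(ph1) * fr$e2 + sin(ph1) * fr$e3)
    xyz[2 * nt1, ] <- ax + config$base_radius *
      (cos(ph1) * fr$e2 + sin(ph1) * fr$e3)
    xyz[2 * nt2 - 1, ] <- ax + config$backbone_radius *
      (cos(ph2) * fr$e2 + sin(ph2) * fr$e3)
    xyz[2 * nt2, ] <- ax + config$base_radius *
      (cos(ph2) * fr$e2 + sin(ph2) * fr$e3)
  }
  nt <- rep(seq_len(n), each = 2)
  chain <- ifelse(nt <= n_bp, 1L, 2L)
  role <- rep(c("BB", "BS"), n)
  bonds <- strand_bonds(nt_runs = list(seq_len(n_bp), (n_bp + 1L):n))
  pairs <- cbind(seq_len(n_bp), n + 1L - seq_len(n_bp))
  ss <- NULL
  cg <- new_cg_structure(xyz, nt, chain, role, helix = rep(1L, 2L * n),
                         bonds = bonds, ss = ss, config = config)
  attr(cg, "pairs") <- pairs
  cg
}

# Orthonormal frame with e1 along `axis`.
axis_frame <- function(axis) {
  e1 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- cross3(ref, e1)
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(e1, e2)
  list(e1 = e1, e2 = e2, e3 = e3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Covalent bond list (bead indices) for given per-strand nucleotide runs:
# consecutive backbone beads within each run plus backbone-base bonds.
strand_bonds <- function(nt_runs) {
  bb <- function(k) 2L * k - 1L
  bs <- function(k) 2L * k
  out <- list()
  all_nt <- unlist(nt_runs)
  for (run in nt_runs) {
    if (length(run) > 1) {
      out[[length(out) + 1]] <- cbind(bb(run[-length(run)]), bb(run[-1]))
    }
  }
  out[[length(out) + 1]] <- cbind(bb(all_nt), bs(all_nt))
  do.call(rbind, out)
}

#' Measure pitch and width of a helix
#'
#' Fits the helix axis by principal components of the backbone beads, then
#' measures the pitch as the axial rise accumulated over 2*pi of unwrapped
#' azimuthal twist (linear fit of axial position against unwrapped angle on
#' one strand) and the width as twice the maximal radial backbone-bead
#' distance from the axis.
#'
#' @param cg A `cg_structure`.
#' @param helix_id Helix identifier (as stored in the bead table).
#' @param config A [cg_config()]; used only to decide whether a full turn is
#'   present.
#'
#' @return List with `pitch` (Angstrom, `NA` with `pitch_defined = FALSE`
#'   when the helix is shorter than one full turn), `width` (Angstrom) and
#'   `n_bp`.
#' @export
measure_helix <- function(cg, helix_id = 1, config = cg$config) {
  if (is.null(config)) config <- cg_config()
  sel <- which(cg$role == "BB" & !is.na(cg$helix) & cg$helix == helix_id)
  if (length(sel) < 4) stop("helix ", helix_id, " not found or too short")
  X <- cg$xyz[sel, , drop = FALSE]
  ax <- fit_cylinder_axis(X)
  v <- ax$v
  e2 <- ax$e2
  e3 <- ax$e3
  Xc <- sweep(X, 2, ax$ctr)
  tax <- drop(Xc %*% v)
  rad <- sqrt(drop(Xc %*% e2)^2 + drop(Xc %*% e3)^2)
  width <- 2 * max(rad)
  # one strand = first contiguous nucleotide run within one chain
  nts <- cg$nt[sel]
  chains <- cg$chain[sel]
  ord <- order(chains, nts)
  runs <- split(ord, cumsum(c(1, diff(nts[ord]) != 1 |
                                diff(chains[ord]) != 0)))
  s1 <- runs[[1]]
  n_bp <- length(s1)
  if (n_bp < config$bp_per_turn + 1) {
    return(list(pitch = NA_real_, width = width, n_bp = n_bp,
                pitch_defined = FALSE))
  }
  th <- atan2(drop(Xc[s1, , drop = FALSE] %*% e3),
              drop(Xc[s1, , drop = FALSE] %*% e2))
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi  # unwrap
  thu <- cumsum(c(th[1], dth))
  fit <- lm(tax[s1] ~ thu)
  pitch <- abs(coef(fit)[2]) * 2 * pi
  list(pitch = unname(pitch), width = width, n_bp = n_bp,
       pitch_defined = TRUE)
}

# Cylinder-fit axis: start from the principal component, then refine axis
# direction and base point so the spread of radial distances is minimal.
# Exact for ideal helices regardless of partial turns.
fit_cylinder_axis <- function(X) {
  ctr <- colMeans(X)
  pc <- prcomp(X, center = TRUE)
  v0 <- pc$rotation[, 1]
  frame_of <- function(v) {
    v <- v / sqrt(sum(v^2))
    ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e2 <- cross3(ref, v)
    e2 <- e2 / sqrt(sum(e2^2))
    list(v = v, e2 = e2, e3 = cross3(v, e2))
  }
  obj <- function(p) {
    fr <- frame_of(v0 + p[1] * pc$rotation[, 2] + p[2] * pc$rotation[, 3])
    c0 <- ctr + p[3] * fr$e2 + p[4] * fr$e3
    Xc <- sweep(X, 2, c0)
    r <- sqrt(drop(Xc %*% fr$e2)^2 + drop(Xc %*% fr$e3)^2)
    # tiny radius penalty breaks the tie among coaxial centres when the
    # beads are (near-)collinear
    var(r) + 1e-8 * mean(r)^2
  }
  op <- optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  if (obj(c(0, 0, 0, 0)) <= op$value) op$par <- c(0, 0, 0, 0)
  fr <- frame_of(v0 + op$par[1] * pc$rotation[, 2] +
                   op$par[2] * pc$rotation[, 3])
  list(v = fr$v, e2 = fr$e2, e3 = fr$e3,
       ctr = ctr + op$par[3] * fr$e2 + op$par[4] * fr$e3)
}

#' Apply a rigid transform to (part of) a structure
#'
#' Rotates the selected beads by `R` about `pivot`, then translates.
#'
#' @param cg A `cg_structure`.
#' @param R 3x3 rotation matrix.
#' @param pivot Rotation centre (Angstrom).
#' @param translation Translation vector (Angstrom).
#' @param rows Bead indices to move (default all).
#' @return The transformed `cg_structure`.
#' @export
transform_cg <- function(cg, R = diag(3), pivot = c(0, 0, 0),
                         translation = c(0, 0, 0), rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cg$xyz))
  Xc <- sweep(cg$xyz[rows, , drop = FALSE], 2, pivot)
  cg$xyz[rows, ] <- sweep(Xc %*% t(R), 2, pivot + translation, "+")
  cg
}

rotz <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rot_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}
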