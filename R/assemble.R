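# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Assemble a coarse-grained 3D topology from secondary structure
#'
#' Realizes every helix as an ideal A-form duplex, lays helix axes flat in
#' the xy-plane (the mica plane is the rendering support), and threads
#' unpaired nucleotides as extensible bead chains along smooth arcs between
#' their anchoring paired nucleotides.  At each junction the emanating child
#' helices leave along per-junction fan angles, either supplied through
#' `junction_geometry` or defaulted (with seeded jitter when `seed` is
#' given).  Builds that violate bonded-distance limits or the non-bonded
#' clash distance are retried with fresh jitter and finally rejected.
#'
#' @param ss A [parse_dotbracket()] result.
#' @param junction_geometry Optional named list: for junction at helix `h`
#'   (name `as.character(h)`, or `"root"` for the exterior), a numeric vector
#'   of departure angles in degrees (relative to the incoming helix axis),
#'   one per child helix in sequence order.
#' @param seed Optional integer; seeds the angle jitter so that rebuilding
#'   with the same seed is bit-reproducible.
#' @param config A [cg_config()].
#' @param max_tries Clash-repair attempts before giving up.
#'
#' @return A `cg_structure` carrying `ss` and `config`.
#' @examples
#' ss <- parse_dotbracket("(((((....)))))", "GGGGGAAAACCCCC")
#' cg <- assemble_topology(ss)
#' @export
assemble_topology <- function(ss, junction_geometry = NULL, seed = NULL,
                              config = cg_config(), max_tries = 20) {
  stopifnot(inherits(ss, "secondary_structure"))
  msg <- "unknown"
  for (tr in seq_len(max_tries)) {
    try_seed <- if (is.null(seed)) NULL else seed + 1000L * (tr - 1L)
    cg <- tryCatch(assemble_once(ss, junction_geometry, try_seed, config),
                   error = function(e) e)
    if (!inherits(cg, "error")) {
      audit <- geometry_audit(cg, config)
      if (audit$ok) return(cg)
      msg <- audit$msg
    } else {
      msg <- conditionMessage(cg)
    }
    if (is.null(seed)) break  # deterministic layout; retries cannot differ
  }
  stop("geometry error: could not realize topology (", msg, ")")
}

assemble_once <- function(ss, jg, seed, cfg) {
  with_seed(seed, {
    n <- ss$n
    ht <- helix_table(ss)
    coords <- matrix(NA_real_, 2L * n, 3)
    helix_of_nt <- rep(NA_integer_, n)
    twist <- 2 * pi / cfg$bp_per_turn
    phase <- cfg$strand_phase * pi / 180
    bb <- function(k) 2L * k - 1L
    bs <- function(k) 2L * k

    jangles <- function(key, m) {
      if (!is.null(jg) && !is.null(jg[[key]])) {
        a <- jg[[key]]
        if (length(a) != m) {
          stop("junction_geometry['", key, "'] must list ", m, " angles")
        }
        return(a)
      }
      a <- if (m == 1) 0
      else if (m == 2) c(60, -60)
      else if (m == 3) c(90, 0, -90)
      else seq(110, -110, length.out = m)
      if (!is.null(seed)) a <- a + runif(m, -12, 12)
      a
    }

    # circular-arc chain of unpaired nucleotides from anchor A to anchor B,
    # bulging away from centre Cc; base beads point radially outward from
    # the arc, keeping them clear of the junction interior
    place_run <- function(from, to, A, B, Cc) {
      k <- to - from + 1L
      if (k <= 0L) return(invisible())
      chord <- sqrt(sum((B - A)^2))
      need <- (k + 1) * cfg$link_len
      if (chord > need) {
        stop("linker of ", k, " nt cannot span ", round(chord, 1), " A")
      }
      mid <- (A + B) / 2
      out <- mid - Cc
      nrm <- sqrt(sum(out^2))
      out <- if (nrm < 1e-6) c(0, 0, 1) else out / nrm
      if (chord > 1e-6) {
        ex <- (B - A) / chord
        ey <- out - sum(out * ex) * ex
        if (sqrt(sum(ey^2)) < 1e-6) {
          ey <- cross3(ex, c(0, 0, 1))
          if (sqrt(sum(ey^2)) < 1e-6) ey <- cross3(ex, c(0, 1, 0))
        }
      } else {
        ey <- out
        ex <- cross3(ey, c(0, 0, 1))
        if (sqrt(sum(ex^2)) < 1e-6) ex <- cross3(ey, c(0, 1, 0))
      }
      ex <- ex / sqrt(sum(ex^2))
      ey <- ey / sqrt(sum(ey^2))
      target <- (k + 1) * 0.85 * cfg$link_len
      if (target <= chord) {
        # nearly taut: straight interpolation
        for (t in seq_len(k)) {
          s <- t / (k + 1)
          pos <- (1 - s) * A + s * B
          coords[bb(from + t - 1L), ] <<- pos
          coords[bs(from + t - 1L), ] <<- pos + cfg$base_radius * ey
        }
      } else {
        # arc through A and B with length `target`, sagitta along +ey
        half <- uniroot(function(a) sin(a) / a - chord / target,
                        c(1e-9, pi - 1e-9), tol = 1e-12)$root
        R <- target / (2 * half)
        O <- mid - ey * (R * cos(half))
        for (t in seq_len(k)) {
          phi <- -half + 2 * half * t / (k + 1)
          dirv <- sin(phi) * ex + cos(phi) * ey
          coords[bb(from + t - 1L), ] <<- O + R * dirv
          coords[bs(from + t - 1L), ] <<- O + (R + cfg$base_radius) * dirv
        }
      }
    }

    hrow <- function(h) ht[ht$helix == h, ]
    parent <- helix_parents(ht)
    kids_of <- function(h) ht$helix[parent == h]

    place_helix <- function(h, P, theta) {
      row <- hrow(h)
      u <- c(cos(theta), sin(theta), 0)
      e2 <- c(-sin(theta), cos(theta), 0)
      e3 <- c(0, 0, 1)
      for (p in seq_len(row$len)) {
        nt1 <- row$oi + p - 1L
        nt2 <- row$oj - p + 1L
        ax <- P + (p - 1) * cfg$rise * u
        ph1 <- (p - 1) * twist
        ph2 <- ph1 + phase
        coords[bb(nt1), ] <<- ax + cfg$backbone_radius *
          (cos(ph1) * e2 + sin(ph1) * e3)
        coords[bs(nt1), ] <<- ax + cfg$base_radius *
          (cos(ph1) * e2 + sin(ph1) * e3)
        coords[bb(nt2), ] <<- ax + cfg$backbone_radius *
          (cos(ph2) * e2 + sin(ph2) * e3)
        coords[bs(nt2), ] <<- ax + cfg$base_radius *
          (cos(ph2) * e2 + sin(ph2) * e3)
        helix_of_nt[c(nt1, nt2)] <<- h
      }
      Q <- P + (row$len - 1) * cfg$rise * u
      kids <- kids_of(h)
      if (length(kids) == 0L) {
        place_run(row$ii + 1L, row$ij - 1L,
                  coords[bb(row$ii), ], coords[bb(row$ij), ],
                  Q - cfg$loop_gap * u)
      } else {
        C <- Q + cfg$junction_gap * u
        rel <- jangles(as.character(h), length(kids))
        for (t in seq_along(kids)) {
          th <- theta + rel[t] * pi / 180
          place_helix(kids[t], C + cfg$junction_gap *
                        c(cos(th), sin(th), 0), th)
        }
        prev_nt <- row$ii
        prev_anchor <- coords[bb(row$ii), ]
        for (t in seq_along(kids)) {
          kr <- hrow(kids[t])
          place_run(prev_nt + 1L, kr$oi - 1L, prev_anchor,
                    coords[bb(kr$oi), ], C)
          prev_nt <- kr$oj
          prev_anchor <- coords[bb(kr$oj), ]
        }
        place_run(prev_nt + 1L, row$ij - 1L, prev_anchor,
                  coords[bb(row$ij), ], C)
      }
    }

    root_kids <- if (nrow(ht)) ht$helix[parent == 0L] else integer(0)
    if (length(root_kids) == 0L) {
      for (k in seq_len(n)) {
        coords[bb(k), ] <- c((k - 1) * 0.8 * cfg$link_len, 0, 0)
        coords[bs(k), ] <- coords[bb(k), ] + c(0, -4, 0)
      }
    } else {
      rel <- jangles("root", length(root_kids))
      x <- 0
      starts <- numeric(length(root_kids))
      for (t in seq_along(root_kids)) {
        kr <- hrow(root_kids[t])
        gap_nts <- if (t == 1) 0L else kr$oi - hrow(root_kids[t - 1])$oj - 1L
        if (t > 1) x <- x + max(28, (gap_nts + 1) * cfg$link_len * 0.8)
        starts[t] <- x
        place_helix(root_kids[t], c(x, 0, 0), rel[t] * pi / 180)
        x <- x + (kr$len - 1) * cfg$rise
      }
      # exterior runs: 5' tail, inter-helix linkers, 3' tail
      first <- hrow(root_kids[1])
      if (first$oi > 1L) {
        A <- coords[bb(first$oi), ]
        for (k in seq_len(first$oi - 1L)) {
          coords[bb(k), ] <- A + c(-(first$oi - k) * 0.8 * cfg$link_len,
                                   -6, 0)
          coords[bs(k), ] <- coords[bb(k), ] + c(0, -4, 0)
        }
      }
      if (length(root_kids) > 1L) {
        for (t in seq_len(length(root_kids) - 1L)) {
          a <- hrow(root_kids[t])
          b <- hrow(root_kids[t + 1])
          A <- coords[bb(a$oj), ]
          B <- coords[bb(b$oi), ]
          place_run(a$oj + 1L, b$oi - 1L, A, B, (A + B) / 2 + c(0, 40, 0))
        }
      }
      last <- hrow(root_kids[length(root_kids)])
      if (last$oj < n) {
        A <- coords[bb(last$oj), ]
        for (k in (last$oj + 1L):n) {
          coords[bb(k), ] <- A + c((k - last$oj) * 0.8 * cfg$link_len, -6, 0)
          coords[bs(k), ] <- coords[bb(k), ] + c(0, -4, 0)
        }
      }
    }

    if (any(is.na(coords))) stop("internal layout error: unplaced beads")
    nt <- rep(seq_len(n), each = 2L)
    role <- rep(c("BB", "BS"), n)
    helix <- rep(helix_of_nt, each = 2L)
    bonds <- strand_bonds(list(seq_len(n)))
    new_cg_structure(coords, nt, chain = rep(1L, 2L * n), role = role,
                     helix = helix, bonds = bonds, ss = ss, config = cfg)
  })
}

# Direct parent helix of each helix (0 = exterior).
helix_parents <- function(ht) {
  m <- nrow(ht)
  parent <- integer(m)
  if (m == 0) return(parent)
  for (t in seq_len(m)) {
    enc <- which(ht$oi < ht$oi[t] & ht$oj > ht$oj[t])
    parent[t] <- if (length(enc)) ht$helix[enc[which.max(ht$oi[enc])]] else 0L
  }
  parent
}

# Bond lengths within [2, 12] A and non-bonded separations >= clash_dist.
geometry_audit <- function(cg, config = cg$config) {
  d <- bond_lengths(cg)
  if (any(d < 2 | d > 12)) {
    return(list(ok = FALSE,
                msg = sprintf("bond length out of [2, 12] A (range %.2f-%.2f)",
                              min(d), max(d))))
  }
  dmin <- min_nonbonded_dist_cpp(cg$xyz, bead_codes(cg), numeric(0))
  if (is.finite(dmin) && dmin < config$clash_dist) {
    return(list(ok = FALSE,
                msg = sprintf("non-bonded clash at %.2f A", dmin)))
  }
  list(ok = TRUE, msg = "")
}

bond_lengths <- function(cg) {
  d <- cg$xyz[cg$bonds[, 1], , drop = FALSE] -
    cg$xyz[cg$bonds[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# Beads (both strands, backbone and base) belonging to helix h and everything
# nested inside it: the subtree moved by a junction rigid-body move.
helix_subtree_beads <- function(cg, h) {
  ht <- helix_table(cg$ss)
  row <- ht[ht$helix == h, ]
  nts <- row$oi:row$oj
  which(cg$nt %in% nts)
}

#' Perturb junction arms by rigid rotations
#'
#' Rotates the subtree of each named helix about the vertical axis through
#' the midpoint of its outer base pair.  Used to manufacture misfolded
#' starting structures of known severity for fitting tests.
#'
#' @param cg A `cg_structure` with its `ss` attached.
#' @param angles Named numeric vector: helix id -> rotation angle (degrees),
#'   or `NULL` to draw one angle per top-level junction arm.
#' @param seed RNG seed used when `angles` is `NULL`.
#' @param sd_deg Spread of drawn angles (degrees).
#' @return The perturbed `cg_structure`.
#' @export
perturb_arms <- function(cg, angles = NULL, seed = NULL, sd_deg = 45) {
  stopifnot(!is.null(cg$ss))
  ht <- helix_table(cg$ss)
  if (is.null(angles)) {
    parent <- helix_parents(ht)
    arms <- ht$helix[parent != 0L]
    if (length(arms) == 0) arms <- ht$helix
    angles <- with_seed(seed, setNames(rnorm(length(arms), 0, sd_deg), arms))
  }
  for (h in names(angles)) {
    rows <- helix_subtree_beads(cg, as.integer(h))
    row <- ht[ht$helix == as.integer(h), ]
    pivot <- colMeans(cg$xyz[c(2L * row$oi - 1L, 2L * row$oj - 1L), ,
                             drop = FALSE])
    cg <- transform_cg(cg, rotz(angles[[h]] * pi / 180), pivot = pivot,
                       rows = rows)
  }
  cg
}
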