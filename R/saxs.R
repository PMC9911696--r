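#' 1-D SAXS profile
#'
#' @param q Scattering-vector magnitudes (1/Angstrom), strictly increasing,
#'   >= 0.
#' @param I Intensities (arbitrary units).
#' @param sigma Optional per-point errors (> 0); absent for calculated
#'   curves.
#' @return A data frame of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  stopifnot(is.numeric(q), is.numeric(I), length(q) == length(I))
  if (any(q < 0) || any(diff(q) <= 0)) {
    stop("q must be non-negative and strictly increasing")
  }
  if (!is.null(sigma)) {
    if (length(sigma) != length(q) || any(sigma <= 0)) {
      stop("sigma must be positive and match q in length")
    }
  }
  p <- data.frame(q = q, I = I)
  if (!is.null(sigma)) p$sigma <- sigma
  class(p) <- c("saxs_profile", "data.frame")
  p
}

#' Read / write 3-column SAXS text data
#'
#' `q I sigma` columns (sigma optional), `#` comment lines ignored --
#' the layout used by beamline `.dat` exports.
#'
#' @param path File path.
#' @return A `saxs_profile`.
#' @export
read_saxs <- function(path) {
  d <- read.table(path, comment.char = "#", header = FALSE, fill = TRUE)
  if (ncol(d) < 2) stop("format error: expected q and I columns")
  saxs_profile(d[[1]], d[[2]],
               if (ncol(d) >= 3 && all(is.finite(d[[3]]))) d[[3]] else NULL)
}

#' @rdname read_saxs
#' @param profile A `saxs_profile`.
#' @export
write_saxs <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q(1/A) I(a.u.) sigma", con)
  cols <- c("q", "I", if ("sigma" %in% names(profile)) "sigma")
  write.table(format(as.data.frame(profile)[, cols], digits = 8,
                     scientific = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coarse-grained Debye scattering profile
#'
#' `I(q) = sum_u sum_v f_u f_v sinc(q d_uv)` over all bead pairs with
#' uniform, q-independent form factors, so `I(0) = (sum f)^2`.  No hydration
#' layer or excluded-volume terms: adequate for comparing coarse-grained
#' topological models.
#'
#' @param cg A `cg_structure` (or a plain n x 3 coordinate matrix).
#' @param q_grid Scattering vector grid (1/Angstrom).
#' @param f Bead form factor(s); scalar or one per bead.
#' @return A `saxs_profile` without sigma.
#' @export
debye_profile <- function(cg, q_grid = default_q_grid(), f = 1) {
  X <- if (inherits(cg, "cg_structure")) cg$xyz else as.matrix(cg)
  if (nrow(X) < 1) stop("empty structure")
  fv <- rep_len(f, nrow(X))
  I <- debye_cpp(X, as.numeric(q_grid), as.numeric(fv))
  saxs_profile(q_grid, I)
}

#' Default scattering grid: 200 points in 0 < q < 0.5 1/Angstrom
#' @export
default_q_grid <- function() seq(0.0025, 0.5, length.out = 200)

#' Synthesize an ensemble scattering curve
#'
#' `I_syn(q_i) = sum_k I_calc^k(q_i) * nu_k`: the pointwise volume-fraction
#' weighted sum of per-conformer curves.  All curves must share one q grid;
#' resampling is never implicit.
#'
#' @param curves List of `saxs_profile`s on a common grid.
#' @param fractions Volume fractions `nu_k` (>= 0; enforced to sum to 1 only
#'   when `normalized = TRUE`, which is the ensemble convention).
#' @param normalized Require the simplex constraint.
#' @return A `saxs_profile`.
#' @export
synthesize_ensemble <- function(curves, fractions, normalized = TRUE) {
  stopifnot(length(curves) >= 1, length(fractions) == length(curves))
  q <- curves[[1]]$q
  for (cv in curves[-1]) {
    if (length(cv$q) != length(q) || any(abs(cv$q - q) > 1e-12)) {
      stop("q-grid mismatch between ensemble curves; resample explicitly")
    }
  }
  if (any(fractions < -1e-12)) stop("fractions must be >= 0")
  if (normalized && abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1")
  }
  I <- Reduce(`+`, Map(function(cv, v) v * cv$I, curves, fractions))
  saxs_profile(q, I)
}

#' Ensemble goodness-of-fit chi-square
#'
#' `chi^2 = 1/(N_q - 1) * sum(((I_saxs - a * I_syn - b) / sigma)^2)` with
#' the scale `a` taken from the printed closed form
#' `a = sum(I_saxs * I_syn) / sum(I_saxs * I_saxs)` (convention
#' `"printed"`, the default) or from a joint weighted least-squares solve of
#' `(a, b)` (convention `"lsq"`); the offset `b` is in either case the
#' background offset minimizing chi-square given `a`.
#'
#' @param expt Experimental `saxs_profile` with `sigma`.
#' @param syn Synthesized/calculated `saxs_profile` on the same grid.
#' @param convention `"printed"` or `"lsq"`.
#' @return List with `chi2`, `a`, `b`.
#' @export
chi_square <- function(expt, syn, convention = c("printed", "lsq")) {
  convention <- match.arg(convention)
  if (is.null(expt$sigma)) stop("experimental profile must carry sigma")
  if (any(expt$sigma <= 0)) stop("sigma must be positive")
  if (length(expt$q) != length(syn$q) ||
      any(abs(expt$q - syn$q) > 1e-12)) {
    stop("q-grid mismatch")
  }
  Is <- expt$I
  Iy <- syn$I
  w <- 1 / expt$sigma^2
  if (convention == "printed") {
    a <- sum(Is * Iy) / sum(Is * Is)
    b <- sum(w * (Is - a * Iy)) / sum(w)
  } else {
    # weighted least squares on I_saxs ~ a * I_syn + b
    sw <- sum(w)
    sx <- sum(w * Iy)
    sy <- sum(w * Is)
    sxx <- sum(w * Iy^2)
    sxy <- sum(w * Iy * Is)
    den <- sw * sxx - sx^2
    if (abs(den) < 1e-300) stop("degenerate synthesized curve")
    a <- (sw * sxy - sx * sy) / den
    b <- (sy - a * sx) / sw
  }
  chi2 <- sum(((Is - a * Iy - b) / expt$sigma)^2) / (length(Is) - 1)
  list(chi2 = chi2, a = a, b = b)
}

#' Optimize ensemble volume fractions
#'
#' Minimizes the ensemble chi-square over the volume-fraction simplex
#' (`nu_k >= 0`, `sum nu_k = 1`) by quasi-Newton descent in softmax
#' coordinates, starting from the supplied initial fractions (e.g. AFM
#' particle tallies).  Deterministic given the initialization; an optional
#' seeded multistart adds robustness against local minima.
#'
#' @param expt Experimental `saxs_profile` with `sigma`.
#' @param curves List of per-conformer `saxs_profile`s on `expt`'s grid.
#' @param init_fractions Initial point on the simplex (default uniform).
#' @param convention Chi-square convention, see [chi_square()].
#' @param multistart Number of extra seeded random starts (0 = none).
#' @param seed Seed for the multistart draws.
#' @return A list of class `ensemble_fit`: `fractions`, `chi2`, `a`, `b`,
#'   `curves`, `convention`, `degenerate` (TRUE when curves are numerically
#'   collinear, with a warning attached).
#' @export
optimize_fractions <- function(expt, curves, init_fractions = NULL,
                               convention = "printed", multistart = 0,
                               seed = NULL) {
  K <- length(curves)
  stopifnot(K >= 1)
  if (is.null(init_fractions)) init_fractions <- rep(1 / K, K)
  stopifnot(length(init_fractions) == K)
  if (any(init_fractions < 0) || abs(sum(init_fractions) - 1) > 1e-6) {
    stop("init_fractions must lie on the simplex")
  }
  M <- vapply(curves, function(cv) cv$I, numeric(length(expt$q)))
  degenerate <- FALSE
  if (K >= 2) {
    sv <- svd(scale(M, center = FALSE))$d
    if (sv[1] / max(sv[K], 1e-300) > 1e7) {
      degenerate <- TRUE
      warning("conformer curves are numerically collinear; ",
              "fractions are weakly determined")
    }
  }
  obj_frac <- function(v) {
    syn <- saxs_profile(expt$q, drop(M %*% v))
    chi_square(expt, syn, convention)$chi2
  }
  solve_from <- function(v0) {
    if (K == 1) return(list(v = 1, chi2 = obj_frac(1)))
    z0 <- log(pmax(v0, 1e-8))
    z0 <- z0 - z0[1]
    obj <- function(z) obj_frac(exp(c(0, z)) / sum(exp(c(0, z))))
    op <- optim(z0[-1], obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    if (K > 2) {
      op <- optim(op$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-14))
    } else {
      br <- optimize(function(z) obj(z), c(op$par - 2, op$par + 2),
                     tol = 1e-12)
      if (br$objective < op$value) op <- list(par = br$minimum,
                                              value = br$objective)
    }
    v <- exp(c(0, op$par)) / sum(exp(c(0, op$par)))
    list(v = v, chi2 = op$value)
  }
  sols <- list(solve_from(init_fractions))
  if (multistart > 0) {
    starts <- with_seed(seed, replicate(multistart, {
      x <- rexp(K)
      x / sum(x)
    }, simplify = FALSE))
    sols <- c(sols, lapply(starts, solve_from))
  }
  bestidx <- which.min(vapply(sols, function(s) s$chi2, 1))
  v <- sols[[bestidx]]$v
  syn <- saxs_profile(expt$q, drop(M %*% v))
  cs <- chi_square(expt, syn, convention)
  out <- list(fractions = v, chi2 = cs$chi2, a = cs$a, b = cs$b,
              curves = curves, convention = convention,
              init_fractions = init_fractions, init_chi2 = obj_frac(
                init_fractions), degenerate = degenerate)
  class(out) <- "ensemble_fit"
  out
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Ensemble fit: chi2 =", format(x$chi2, digits = 4), "fractions =",
      paste(format(x$fractions, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Guinier analysis
#'
#' Iterative linear fit of `ln I` against `q^2` restricted so that
#' `q * Rg < qrg_max` (1.3, the RNA-appropriate limit) at convergence;
#' returns `Rg`, `I(0)` and the q range used.
#'
#' @param expt A `saxs_profile`.
#' @param qrg_max Range rule limit on `q * Rg`.
#' @param min_points Minimum points in the fit window.
#' @return List with `rg`, `i0`, `q_range`, `n_points`.
#' @export
guinier_fit <- function(expt, qrg_max = 1.3, min_points = 5) {
  q <- expt$q
  I <- expt$I
  ok <- I > 0 & q > 0
  if (sum(ok) < min_points) stop("not enough positive low-q points")
  q <- q[ok]
  I <- I[ok]
  sel <- seq_len(max(min_points, min(length(q), 15)))
  rg <- NA_real_
  for (iter in 1:60) {
    fit <- lm(log(I[sel]) ~ I(q[sel]^2))
    slope <- coef(fit)[2]
    if (slope >= 0) {
      # flat or rising curve: widen and retry once, else fail
      if (length(sel) < length(q)) {
        sel <- seq_len(min(length(q), length(sel) + 5))
        next
      }
      stop("Guinier fit failed: non-decreasing low-q intensity")
    }
    rg_new <- sqrt(-3 * slope)
    sel_new <- which(q * rg_new < qrg_max)
    if (length(sel_new) < min_points) {
      sel_new <- seq_len(min_points)
    }
    if (identical(sel_new, sel)) {
      rg <- rg_new
      break
    }
    sel <- sel_new
    rg <- rg_new
  }
  fit <- lm(log(I[sel]) ~ I(q[sel]^2))
  rg <- sqrt(-3 * coef(fit)[2])
  list(rg = unname(rg), i0 = unname(exp(coef(fit)[1])),
       q_range = range(q[sel]), n_points = length(sel))
}

#' Pair-distance distribution by regularized indirect Fourier transform
#'
#' Solves `I(q) = integral_0^Dmax P(r) sinc(q r) dr` for `P(r)` on a grid
#' with zero endpoints, under a second-derivative (smoothness) penalty whose
#' weight is picked at the corner of the L-curve.  `Dmax` is scanned over
#' `dmax_search` and chosen as the smallest value whose regularized misfit
#' is within 10% (plus a small absolute slack) of the best across the scan:
#' misfit drops sharply while `Dmax` is too small and plateaus beyond the
#' true dimension.
#'
#' @param expt A `saxs_profile` (ideally extending to q ~ 0.3 1/Angstrom).
#' @param dmax_search Candidate maximal dimensions (Angstrom); default spans
#'   2 to 5 times the Guinier Rg.
#' @param n_r Grid points of P(r).
#' @return List of class `pr_result`: `r`, `pr`, `dmax`, `rg` (real-space),
#'   `i0`, `chi2`, `lambda`.
#' @export
pr_distribution <- function(expt, dmax_search = NULL, n_r = 81) {
  q <- expt$q
  I <- expt$I
  sg <- if ("sigma" %in% names(expt)) expt$sigma else
    rep(max(abs(I)) * 1e-3, length(I))
  if (is.null(dmax_search)) {
    g <- guinier_fit(expt)
    dmax_search <- seq(1.6 * g$rg, 5 * g$rg, length.out = 24)
  }
  solve_dmax <- function(dmax) {
    r <- seq(0, dmax, length.out = n_r)
    dr <- r[2] - r[1]
    wtrap <- rep(dr, n_r)
    wtrap[c(1, n_r)] <- dr / 2
    A <- outer(q, r, function(qq, rr) {
      x <- qq * rr
      ifelse(x < 1e-9, 1, sin(x) / x)
    })
    A <- sweep(A, 2, wtrap, "*")
    # endpoints fixed at zero
    Ai <- A[, 2:(n_r - 1), drop = FALSE]
    Aw <- Ai / sg
    yw <- I / sg
    ni <- ncol(Ai)
    L <- diff(diag(ni), differences = 2)
    AtA <- crossprod(Aw)
    Aty <- crossprod(Aw, yw)
    LtL <- crossprod(L)
    sc <- sum(diag(AtA)) / max(sum(diag(LtL)), 1e-300)
    lams <- sc * 10^seq(-8, 2, length.out = 25)
    rho <- eta <- numeric(length(lams))
    sols <- vector("list", length(lams))
    for (t in seq_along(lams)) {
      # active-set near-positivity: nodes driven negative are pinned to 0
      act <- rep(TRUE, ni)
      p <- numeric(ni)
      for (pass in 1:6) {
        pa <- solve(AtA[act, act, drop = FALSE] +
                      lams[t] * LtL[act, act, drop = FALSE], Aty[act])
        p <- numeric(ni)
        p[act] <- pa
        neg <- p < -1e-6 * max(abs(p), 1e-300)
        if (!any(neg & act)) break
        act <- act & !neg
        if (sum(act) < 3) break
      }
      sols[[t]] <- p
      rho[t] <- sum((Aw %*% p - yw)^2)
      eta[t] <- sum((L %*% p)^2)
    }
    # L-curve corner: farthest point from the line joining the curve ends
    lx <- log(rho + 1e-300)
    ly <- log(eta + 1e-300)
    v <- c(lx[length(lx)] - lx[1], ly[length(ly)] - ly[1])
    v <- v / sqrt(sum(v^2))
    dist <- abs((lx - lx[1]) * v[2] - (ly - ly[1]) * v[1])
    t0 <- which.max(dist)
    p <- sols[[t0]]
    pr <- c(0, p, 0)
    chi2 <- rho[t0] / (length(q) - 1)
    list(r = r, pr = pr, chi2 = chi2, lambda = lams[t0])
  }
  cands <- lapply(dmax_search, solve_dmax)
  chis <- vapply(cands, function(cc) cc$chi2, 1)
  best <- min(chis)
  pick <- which(chis <= best * 1.10 + 0.02)[1]
  sol <- cands[[pick]]
  mom0 <- sum(sol$pr) * (sol$r[2] - sol$r[1])
  rg <- sqrt(sum(sol$r^2 * sol$pr) / (2 * sum(sol$pr)))
  out <- list(r = sol$r, pr = sol$pr, dmax = dmax_search[pick], rg = rg,
              i0 = mom0, chi2 = sol$chi2, lambda = sol$lambda)
  class(out) <- "pr_result"
  out
}

#' Molecular weight from the SAXS correlation volume
#'
#' `Vc = I(0) / integral q I(q) dq` (trapezoid over the measured range),
#' then the RNA power-law calibration `MW = (Vc^2 / Rg / 0.00934)^0.808`
#' (Daltons, lengths in Angstrom).  `Vc` is invariant to uniform intensity
#' scaling.  A warning notes possibly truncated integrals when the
#' integrand has not decayed by the end of the range.
#'
#' @param expt A `saxs_profile`.
#' @param rg,i0 Optional Guinier values (computed if missing).
#' @param mw_coef,mw_exp RNA calibration constants.
#' @return List with `vc` (A^2), `qr`, `mw_da`, `rg`, `i0`.
#' @export
vc_molecular_weight <- function(expt, rg = NULL, i0 = NULL,
                                mw_coef = 0.00934, mw_exp = 0.808) {
  if (is.null(rg) || is.null(i0)) {
    g <- guinier_fit(expt)
    if (is.null(rg)) rg <- g$rg
    if (is.null(i0)) i0 <- g$i0
  }
  q <- expt$q
  integrand <- q * expt$I
  itot <- sum(diff(q) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  if (itot <= 0) stop("divergent or empty q*I integral")
  tail_frac <- mean(tail(integrand, 3)) * (q[length(q)] - q[1]) / itot
  if (tail_frac > 0.2) {
    warning("q*I(q) has not decayed at the end of the range; ",
            "Vc may be truncated")
  }
  vc <- i0 / itot
  qr <- vc^2 / rg
  list(vc = vc, qr = qr, mw_da = (qr / mw_coef)^mw_exp, rg = rg, i0 = i0)
}
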