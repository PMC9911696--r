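test_that("Debye profiles reproduce point-scatterer closed forms", {
  q <- default_q_grid()
  one <- debye_profile(matrix(0, 1, 3), q)
  expect_equal(one$I, rep(1, length(q)))

  d <- 10
  two <- debye_profile(rbind(c(0, 0, 0), c(d, 0, 0)), q)
  expect_equal(two$I, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  expect_equal(debye_profile(rbind(c(0, 0, 0), c(d, 0, 0)),
                             c(1e-12, q))$I[1], 4, tolerance = 1e-6)

  # positivity and forward-peak on the phantom suite
  for (cg in phantom_set()) {
    p <- debye_profile(cg, q)
    expect_true(all(p$I > 0))
    expect_equal(max(p$I), p$I[1])
  }
  expect_error(debye_profile(matrix(0, 0, 3)), "empty")
})

test_that("a uniform sphere phantom scatters with the textbook Rg", {
  pts <- sphere_beads(50, 8)
  p <- debye_profile(pts)
  g <- guinier_fit(p)
  expect_lt(abs(g$rg - sqrt(3 / 5) * 50) / (sqrt(3 / 5) * 50), 0.03)
  expect_lt(g$q_range[2] * g$rg, 1.3)  # the range rule held at convergence
})

test_that("ensemble synthesis is the exact fraction-weighted sum", {
  q <- default_q_grid()
  a <- debye_profile(phantom_Y(), q)
  b <- debye_profile(phantom_candy(), q)
  expect_equal(synthesize_ensemble(list(a), 1)$I, a$I)
  expect_equal(synthesize_ensemble(list(a, a), c(0.5, 0.5))$I, a$I)
  mix <- synthesize_ensemble(list(a, b), c(0.3, 0.7))
  expect_equal(mix$I, 0.3 * a$I + 0.7 * b$I)
  # linearity in the weights (un-normalized arithmetic)
  s1 <- synthesize_ensemble(list(a, b), c(0.2, 0.3), normalized = FALSE)
  s2 <- synthesize_ensemble(list(a, b), c(0.1, 0.4), normalized = FALSE)
  s12 <- synthesize_ensemble(list(a, b), c(0.3, 0.7))
  expect_equal(s1$I + s2$I, s12$I, tolerance = 1e-9)
  bad <- saxs_profile(q + 1e-3, b$I)
  expect_error(synthesize_ensemble(list(a, bad), c(0.5, 0.5)), "grid")
})

test_that("chi-square closed forms and calibration hold", {
  q <- default_q_grid()
  base <- debye_profile(phantom_Y(), q)
  sg <- 0.01 * base$I + 1
  expt <- saxs_profile(q, base$I, sg)

  # identical curves: chi2 = 0, a = 1, b = 0 under the printed convention
  cs <- chi_square(expt, base)
  expect_equal(cs$chi2, 0, tolerance = 1e-12)
  expect_equal(cs$a, 1, tolerance = 1e-12)
  expect_equal(cs$b, 0, tolerance = 1e-9)

  # the printed scale estimate is the literal published expression, which
  # normalizes by sum(I_saxs^2); it is not the least-squares scale
  cs2 <- chi_square(expt, saxs_profile(q, base$I / 3))
  expect_equal(cs2$a, sum(base$I * base$I / 3) / sum(base$I^2),
               tolerance = 1e-12)

  # scale + offset closure holds under the joint least-squares convention
  syn <- saxs_profile(q, (base$I - 50) / 2)
  cs3 <- chi_square(expt, syn, convention = "lsq")
  expect_equal(cs3$chi2, 0, tolerance = 1e-10)
  expect_equal(cs3$a, 2, tolerance = 1e-9)
  expect_equal(cs3$b, 50, tolerance = 1e-6)
  cs4 <- chi_square(expt, saxs_profile(q, base$I / 3), convention = "lsq")
  expect_equal(cs4$chi2, 0, tolerance = 1e-10)

  # unit-sigma noise calibration: chi2 ~ 1 within 3/sqrt(Nq)
  n <- length(q)
  chis <- vapply(1:10, function(s) {
    noisy <- saxs_profile(q, base$I + rnatopo:::with_seed(s, rnorm(n, 0, sg)),
                          sg)
    chi_square(noisy, base)$chi2
  }, 1)
  expect_lt(abs(mean(chis) - 1), 3 / sqrt(n))
  expect_error(chi_square(saxs_profile(q, base$I), base), "sigma")
})

test_that("volume fractions are recovered on and off the simplex vertices", {
  structures <- phantom_set()
  truth <- c(0.2, 0.3, 0.5)
  mx <- make_saxs_mixture(structures, truth, noiseless = TRUE)
  ef <- optimize_fractions(mx$mixture, mx$curves,
                           init_fractions = rep(1 / 3, 3))
  expect_lt(max(abs(ef$fractions - truth)), 0.01)
  expect_equal(sum(ef$fractions), 1, tolerance = 1e-9)
  expect_true(all(ef$fractions >= 0))
  expect_lte(ef$chi2, ef$init_chi2)  # objective never got worse

  # an exact single-conformer curve wins its vertex
  vx <- saxs_profile(mx$mixture$q, mx$curves[[2]]$I, mx$mixture$sigma)
  ef2 <- optimize_fractions(vx, mx$curves)
  expect_gte(ef2$fractions[2], 0.99)

  # collinear curves earn a degeneracy warning but still return
  expect_warning(
    ef3 <- optimize_fractions(vx, list(mx$curves[[1]], mx$curves[[1]])),
    "collinear")
  expect_true(ef3$degenerate)
})

test_that("P(r) inversion recovers sphere geometry and real-space Rg", {
  pts <- sphere_beads(50, 8)
  p <- debye_profile(pts)
  pr <- pr_distribution(p)
  expect_lt(abs(pr$dmax - 100) / 100, 0.10)
  expect_gte(min(pr$pr), -0.01 * max(pr$pr))
  g <- guinier_fit(p)
  expect_lt(abs(pr$rg - g$rg) / g$rg, 0.05)
})

test_that("Guinier fit is exact on an ideal curve and respects the range", {
  q <- seq(5e-4, 0.3, length.out = 400)
  rg <- 20
  p <- saxs_profile(q, 100 * exp(-q^2 * rg^2 / 3))
  g <- guinier_fit(p)
  expect_equal(g$rg, rg, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  expect_lt(g$q_range[2] * g$rg, 1.3)
})

test_that("correlation volume matches its closed form and is scale-free", {
  q <- seq(1e-4, 0.5, length.out = 2000)
  rg <- 20
  p <- saxs_profile(q, 100 * exp(-q^2 * rg^2 / 3))
  v <- vc_molecular_weight(p)
  expect_equal(v$vc, 2 * rg^2 / 3, tolerance = 1e-3)
  v2 <- vc_molecular_weight(saxs_profile(q, 7 * p$I))
  expect_equal(v2$vc, v$vc, tolerance = 1e-9)

  # 20-bp duplex (40 nt, ~26 kDa): the power-law estimate lands within 2x
  dup <- debye_profile(build_aform_helix(20), seq(1e-3, 0.5,
                                                  length.out = 500))
  mw <- suppressWarnings(vc_molecular_weight(dup))$mw_da
  expect_gt(mw, 26000 / 2)
  expect_lt(mw, 26000 * 2)
})
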