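test_that("peak integration recovers pulse areas above any linear baseline", {
  m <- 100
  tt <- 0:(m - 1)
  pulse <- exp(-(tt - 30)^2 / 50)
  pulse <- pulse / sum(pulse)  # unit area at dt = 1
  areas <- c(-20, -10, -5, -2, -1) # microcal
  M <- outer(pulse, areas)
  th <- thermogram(M, dt = 1, inj_vol = 2, cell_conc = 70e-6,
                   syringe_conc = 700e-6)
  iso <- integrate_peaks(th)
  moles <- 700e-6 * 2e-6
  expect_equal(iso$ndh, areas * 1e-9 / moles, tolerance = 1e-3)
  expect_true(all(diff(iso$ratio) > 0))

  # adding a sloped baseline changes nothing
  M2 <- M + outer(0.01 * tt + 3, rep(1, length(areas)))
  iso2 <- integrate_peaks(thermogram(M2, dt = 1, inj_vol = 2,
                                     cell_conc = 70e-6,
                                     syringe_conc = 700e-6))
  expect_equal(iso2$ndh, iso$ndh, tolerance = 1e-3)
})

test_that("SVD selection separates smooth components from noise", {
  # rank-1 noiseless: exactly one kept component with autocorr ~ 1
  m1 <- outer(exp(-((1:100) - 30)^2 / 200), sin((1:20) / 3) + 2)
  s1 <- svd_select(thermogram(m1))
  expect_identical(s1$kept, 1L)
  expect_gt(s1$autocorr[1], 0.95)
  expect_equal(sum(s1$fractions), 1, tolerance = 1e-12)
  expect_true(all(diff(s1$d) <= 1e-9))

  # iid Gaussian matrices keep nothing in >= 95/100 seeded trials
  kept <- vapply(1:100, function(s) {
    M <- rnatopo:::with_seed(s, matrix(rnorm(2000), 100, 20))
    length(svd_select(thermogram(M))$kept)
  }, 1L)
  expect_gte(mean(kept == 0), 0.95)

  expect_error(svd_select(thermogram(matrix(0, 10, 5))), "all-zero")
  expect_error(thermogram(matrix(1, 1, 5)), "m >= 2")
})

test_that("the two-component synthetic keeps exactly two components", {
  th <- make_itc_two_component(seed = 1)
  sel <- svd_select(th)
  expect_identical(sel$kept, 1:2)
  isos <- reconstruct_isotherms(th, sel)
  truth <- attr(th, "truth")
  expect_gt(cor(isos[[1]]$ndh, truth$ndh1), 0.95)
  expect_gt(cor(isos[[2]]$ndh, truth$ndh2), 0.95)

  # kept reconstructions sum to the truncated-SVD approximation
  mats <- attr(isos, "matrices")
  trunc2 <- sel$d[1] * sel$u[, 1] %*% t(sel$v[, 1]) +
    sel$d[2] * sel$u[, 2] %*% t(sel$v[, 2])
  expect_equal(mats[[1]] + mats[[2]], trunc2, tolerance = 1e-10)

  # full-rank reconstruction reproduces M to machine precision
  full <- Reduce(`+`, lapply(seq_along(sel$d), function(k) {
    sel$d[k] * sel$u[, k] %*% t(sel$v[, k])
  }))
  expect_equal(full, th$M, tolerance = 1e-10)

  # rank-1 reconstruction identity
  th1 <- thermogram(outer(exp(-((1:60) - 20)^2 / 40), -(1:15)))
  sel1 <- svd_select(th1)
  rec <- attr(reconstruct_isotherms(th1, sel1), "matrices")[[1]]
  expect_equal(rec, th1$M, tolerance = 1e-10)
})

test_that("the noiseless generator isotherm matches the binding model", {
  th <- make_itc_two_component(seed = 1, snr = Inf)
  truth <- attr(th, "truth")
  iso <- integrate_peaks(th)
  expect_lt(max(abs(iso$ndh - truth$ndh_total)) /
              max(abs(truth$ndh_total)), 0.01)
})

test_that("one-site Wiseman fit recovers parameters to high precision", {
  sch <- itc_default_schedule
  nd <- rnatopo:::model_isotherm(list(list(N = 1, kd = 1e-6, dh = -10)),
                                 25, sch$inj_vol, sch$cell_vol, sch$cell,
                                 sch$syringe)
  iso <- make_isotherm(nd$ndh, nd$ratio)
  f <- fit_one_site(iso, sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol)
  expect_lt(abs(f$N - 1), 1e-3)
  expect_lt(abs(f$kd / 1e-6 - 1), 1e-3)
  expect_lt(abs(f$dh / -10 - 1), 1e-3)
  # thermodynamic bookkeeping: dG = RT ln Kd and dG = dH - T dS
  expect_equal(f$dg, 1.9872041e-3 * 298.15 * log(f$kd), tolerance = 1e-9)
  expect_equal(f$dg, f$dh - 298.15 * f$ds, tolerance = 1e-9)

  # the ODE path agrees with the closed form
  fo <- fit_one_site(iso, sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol,
                     method = "ode")
  expect_lt(abs(fo$kd / f$kd - 1), 0.01)

  # all-zero heats: flat flag
  fz <- fit_one_site(make_isotherm(rep(0, 25), nd$ratio), sch$cell,
                     sch$syringe, sch$inj_vol, sch$cell_vol)
  expect_true("flat" %in% fz$flags)
  expect_equal(fz$dh, 0)

  # units invariance: scaling concentrations and volume together
  nd2 <- rnatopo:::model_isotherm(list(list(N = 1, kd = 1e-6, dh = -10)),
                                  25, 2 * sch$inj_vol, 2 * sch$cell_vol,
                                  sch$cell, sch$syringe)
  f2 <- fit_one_site(make_isotherm(nd2$ndh, nd2$ratio), sch$cell,
                     sch$syringe, 2 * sch$inj_vol, 2 * sch$cell_vol)
  expect_lt(abs(f2$kd / 1e-6 - 1), 1e-3)

  # low-titration c-value earns an information warning flag
  fl <- fit_one_site(make_isotherm(
    rnatopo:::model_isotherm(list(list(N = 1, kd = 2e-3, dh = -10)), 25,
                             sch$inj_vol, sch$cell_vol, sch$cell,
                             sch$syringe)$ndh, nd$ratio),
    sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol)
  expect_true(any(grepl("c-value", fl$flags)))
})

test_that("two-site fit recovers well-separated sites and nests correctly", {
  sch <- itc_default_schedule
  sites <- list(list(N = 0.6, kd = 1e-7, dh = -8),
                list(N = 0.7, kd = 1e-5, dh = 6))
  nd <- rnatopo:::model_isotherm(sites, 30, sch$inj_vol, sch$cell_vol,
                                 sch$cell, sch$syringe)
  iso <- make_isotherm(nd$ndh, nd$ratio)
  g <- fit_two_site(iso, sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol)
  for (k in 1:2) {
    expect_lt(abs(g$sites[[k]]$N / sites[[k]]$N - 1), 0.01)
    expect_lt(abs(g$sites[[k]]$kd / sites[[k]]$kd - 1), 0.01)
    expect_lt(abs(g$sites[[k]]$dh / sites[[k]]$dh - 1), 0.01)
  }
  expect_equal(g$n_app, g$sites[[1]]$N + g$sites[[2]]$N)

  # site 2 emptied: collapses onto the one-site solution
  nd1 <- rnatopo:::model_isotherm(list(list(N = 1, kd = 1e-6, dh = -10)),
                                  30, sch$inj_vol, sch$cell_vol, sch$cell,
                                  sch$syringe)
  iso1 <- make_isotherm(nd1$ndh, nd1$ratio)
  g1 <- suppressWarnings(fit_two_site(iso1, sch$cell, sch$syringe,
                                      sch$inj_vol, sch$cell_vol))
  f1 <- fit_one_site(iso1, sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol)
  expect_lte(g1$rss, f1$rss + 1e-12)
})

test_that("the F-test selects parsimony and detects genuine two-site data", {
  sch <- itc_default_schedule
  one <- rnatopo:::model_isotherm(list(list(N = 1, kd = 1e-6, dh = -10)),
                                  25, sch$inj_vol, sch$cell_vol, sch$cell,
                                  sch$syringe)
  iso <- make_isotherm(one$ndh, one$ratio)
  f1 <- fit_one_site(iso, sch$cell, sch$syringe, sch$inj_vol, sch$cell_vol)
  # identical RSS -> F = 0 -> one-site
  f2 <- f1
  f2$n_par <- 6
  f2$model <- "two_site_independent"
  ch <- select_model_ftest(f1, f2, 25)
  expect_equal(ch$F, 0)
  expect_identical(ch$model, "one_site")
  # optimizer-failure guard: worse big model -> one-site directly
  f2$rss <- f1$rss + 1
  expect_identical(select_model_ftest(f1, f2, 25)$model, "one_site")
})
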