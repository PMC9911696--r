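test_that("ideal A-form duplex has canonical pitch and width", {
  hx <- build_aform_helix(22)
  m <- measure_helix(hx, 1)
  expect_true(m$pitch_defined)
  expect_lt(abs(m$pitch - 30), 1)
  expect_lt(abs(m$width - 25), 3)
  expect_equal(n_beads(build_aform_helix(11)), 44)  # 2 beads/nt, 2 strands

  # one full turn spans one pitch axially (n-1 rise steps)
  one_turn <- build_aform_helix(11)
  expect_equal(diff(range(one_turn$xyz[, 3])), 10 * cg_config()$rise,
               tolerance = 1e-9)

  # single base pair: 4 beads, zero accumulated rise
  bp <- build_aform_helix(1)
  expect_equal(n_beads(bp), 4)
  expect_equal(diff(range(bp$xyz[, 3])), 0, tolerance = 1e-9)
  expect_error(build_aform_helix(0), "n_bp")
})

test_that("pitch and width hold across helix lengths above one turn", {
  for (n in c(12, 16, 22, 33, 44)) {
    m <- measure_helix(build_aform_helix(n), 1)
    expect_lt(abs(m$pitch - 30), 1)
    expect_lt(abs(m$width - 25), 3)
  }
  # below one turn the pitch is flagged undefined
  short <- measure_helix(build_aform_helix(8), 1)
  expect_false(short$pitch_defined)
  expect_true(is.na(short$pitch))
})

test_that("degenerate beads collapsed onto the axis give zero width", {
  hx <- build_aform_helix(12)
  hx$xyz[, 1:2] <- 0
  m <- measure_helix(hx, 1)
  expect_lt(m$width, 1e-6)
})

test_that("assembled topologies respect connectivity and geometry limits", {
  cg <- phantom_Y()
  ss <- cg$ss
  expect_equal(n_beads(cg), 2 * ss$n)
  d <- rnatopo:::bond_lengths(cg)
  expect_true(all(d >= 2 & d <= 12))

  # hairpin loop end-to-end bound: <= 4 max link lengths via 4 loop beads
  hp <- phantom_hairpin()
  loop <- which(is.na(hp$ss$paired))
  ends <- hp$xyz[c(2 * min(loop) - 1, 2 * max(loop) - 1), ]
  expect_lt(sqrt(sum(diff(ends)^2)), 4 * cg_config()$link_len)

  # unsatisfiable linker span fails loudly
  ss2 <- parse_dotbracket("((((....)))).((((....))))",
                          complementary_seq_test("((((....)))).((((....))))"))
  expect_error(
    assemble_topology(ss2, config = cg_config(link_len = 1.0)),
    "geometry error")
})

test_that("same seed rebuilds bit-identically, different seeds move arms", {
  ss <- parse_dotbracket(phantom_spec("Y")$db, phantom_spec("Y")$seq)
  a <- assemble_topology(ss, seed = 11)
  b <- assemble_topology(ss, seed = 11)
  c <- assemble_topology(ss, seed = 12)
  expect_identical(a$xyz, b$xyz)
  expect_identical(a$bonds, c$bonds)  # bonded topology is seed-independent
  expect_gt(max(abs(a$xyz - c$xyz)), 0.5)
  expect_equal(rmsd_cg(a, a), 0)
})

test_that("no seeded build violates the clash distance", {
  ss <- parse_dotbracket(phantom_spec("Y")$db, phantom_spec("Y")$seq)
  cfg <- cg_config()
  for (seed in 1:100) {
    cg <- assemble_topology(ss, seed = seed, config = cfg)
    dmin <- rnatopo:::min_nonbonded_dist_cpp(cg$xyz, rnatopo:::bead_codes(cg),
                                             numeric(0))
    expect_gte(dmin, cfg$clash_dist)
  }
})

test_that("three-way junction presets emanate three arms and stay distinct", {
  y <- phantom_Y()
  ht <- rnatopo:::helix_table(y$ss)
  expect_equal(nrow(ht), 3)
  expect_equal(sum(rnatopo:::helix_parents(ht) == 1), 2)  # two arms + closer
  expect_identical(make_phantom("Y")$xyz, y$xyz)  # deterministic rebuild
  expect_gt(rmsd_cg(phantom_compact(), y), 10)
  expect_gt(rmsd_cg(phantom_candy(), y), 10)
})
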