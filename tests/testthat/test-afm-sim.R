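test_that("tip contact geometry is exact for a single bead", {
  one <- single_bead_cg()
  r <- cg_config()$bead_radius_backbone  # 4 A
  img <- render_surface(one, tip_model(0), pixel_size = 1)
  expect_equal(max(img$heights), 2 * r / 10)  # bead resting on mica: 2r
  # apex above the bead's lateral position
  pk <- which(img$heights == max(img$heights), arr.ind = TRUE)[1, ]
  xs <- img$origin[1] + (pk[2] - 1) * img$pixel_size
  ys <- img$origin[2] + (pk[1] - 1) * img$pixel_size
  expect_lt(abs(xs), img$pixel_size)
  expect_lt(abs(ys), img$pixel_size)
})

test_that("rendering is a dilation: tip radius only widens the footprint", {
  cg <- phantom_hairpin()
  px <- 5
  prev <- -Inf
  base <- render_surface(cg, tip_model(0), pixel_size = px)
  for (tr in c(0, 0.5, 1, 2)) {
    img <- render_surface(cg, tip_model(tr), pixel_size = px,
                          grid = render_surface(cg, tip_model(2),
                                                pixel_size = px))
    fp <- sum(img$heights > 0.1)
    expect_gte(fp, prev)
    prev <- fp
  }
  # zero-radius tip equals the plain bead-top projection oracle
  img0 <- render_surface(cg, tip_model(0), pixel_size = px)
  rad <- rnatopo:::bead_radii(cg)
  z <- cg$xyz[, 3] - min(cg$xyz[, 3] - rad)
  oracle <- matrix(0, nrow(img0$heights), ncol(img0$heights))
  for (b in seq_len(n_beads(cg))) {
    for (j in seq_len(nrow(oracle))) {
      for (i in seq_len(ncol(oracle))) {
        dx <- img0$origin[1] + (i - 1) * px - cg$xyz[b, 1]
        dy <- img0$origin[2] + (j - 1) * px - cg$xyz[b, 2]
        d2 <- dx^2 + dy^2
        if (d2 <= rad[b]^2) {
          oracle[j, i] <- max(oracle[j, i], z[b] + sqrt(rad[b]^2 - d2))
        }
      }
    }
  }
  expect_equal(img0$heights, pmax(oracle, 0) / 10, tolerance = 1e-12)
})

test_that("rendering is translation-equivariant on interior pixels", {
  cg <- phantom_hairpin()
  img <- render_surface(cg, pixel_size = 5, pad = 40)
  shifted <- transform_cg(cg, translation = c(10, 15, 0))  # 2 and 3 pixels
  img2 <- render_surface(shifted, pixel_size = 5, grid = img)
  h1 <- img$heights
  h2 <- img2$heights
  inner1 <- h1[4:(nrow(h1) - 6), 4:(ncol(h1) - 5)]
  inner2 <- h2[(4 + 3):(nrow(h1) - 3), (4 + 2):(ncol(h1) - 3)]
  expect_equal(inner1, inner2, tolerance = 1e-12)
})

test_that("noise percentage is a clipped 2-sigma amplitude of max height", {
  flat <- afm_image(matrix(10, 100, 100), 5)
  for (lv in c(20, 40, 90)) {
    nz <- add_noise(flat, lv, seed = lv)
    eps <- nz$heights - flat$heights
    sigma <- lv / 100 * 10 / 2
    expect_lte(max(abs(eps)), 2 * sigma + 1e-12)   # truncation respected
    expect_lt(abs(2 * sd(eps) - 2 * sigma), 0.05 * 2 * sigma)
  }
  expect_identical(add_noise(flat, 0)$heights, flat$heights)
  expect_error(add_noise(afm_image(matrix(0, 4, 4), 5), 10), "invalid image")
  # same seed reproduces, and heights never go below the mica plane
  a <- add_noise(flat, 100, seed = 7)
  b <- add_noise(flat, 100, seed = 7)
  expect_identical(a$heights, b$heights)
  expect_gte(min(a$heights), 0)
})

test_that("the twelve-level ladder yields twelve images from one render", {
  lv <- noise_ladder_levels()
  expect_length(lv, 12)
  ladder <- make_afm_ladder(phantom_hairpin(), levels = lv, seed = 1)
  expect_length(ladder, 12)
  clean <- attr(ladder, "clean")
  expect_false(identical(ladder[[1]]$heights, clean$heights))
})

test_that("pseudoAFM text round-trips and validates", {
  img <- afm_image(matrix(abs(rnatopo:::with_seed(3, rnorm(64 * 64))),
                          64, 64), 5)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_pseudoafm(img, tf)
  img2 <- read_pseudoafm(tf)
  expect_lt(max(abs(img$heights - img2$heights)), 1e-5)
  expect_equal(img2$pixel_size, 5)

  # headerless file: default 5 A/pixel with a warning
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.1 0", "0.2 0.5 0.1", "0 0.1 0"), tf2)
  expect_warning(img3 <- read_pseudoafm(tf2), "5 A/pixel")
  expect_equal(img3$pixel_size, 5)

  # ragged rows are a format error (header warning is incidental here)
  tf3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pixel_size_A: 5", "0 1 0", "1 2", "0 1 0"), tf3)
  expect_error(read_pseudoafm(tf3), "ragged")
})
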