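test_that("luminance conversion uses the 0.299/0.587/0.114 weights", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(200, 200, 200)   # gray is idempotent
  px[1, 2, ] <- c(255, 0, 0)       # red -> 76
  px[1, 3, ] <- c(0, 0, 255)       # blue -> 29
  g <- to_grayscale(px)
  expect_identical(as.vector(g$pixels), c(200L, 76L, 29L))
  expect_true(all(g$mask))
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "3")
})

test_that("blue-background segmentation extracts the sample and fills holes", {
  px <- array(0, c(12, 12, 3)); px[, , 3] <- 255
  px[3:9, 3:9, 1] <- 120; px[3:9, 3:9, 2] <- 120; px[3:9, 3:9, 3] <- 120
  mask <- segment_sample(px)
  want <- matrix(FALSE, 12, 12); want[3:9, 3:9] <- TRUE
  expect_identical(mask, want)

  # one interior blue pixel is a hole: retained by fill
  px[5, 5, ] <- c(0, 0, 255)
  expect_identical(segment_sample(px), want)

  # all-blue image has no sample
  blue <- array(0, c(6, 6, 3)); blue[, , 3] <- 255
  expect_error(segment_sample(blue), "segmentation failure")
})

test_that("V - E + F reproduces components minus holes on known shapes", {
  expect_identical(euler_characteristic(matrix(TRUE, 5, 5)), 1L)

  ring <- matrix(TRUE, 5, 5); ring[2:4, 2:4] <- FALSE
  expect_identical(euler_characteristic(ring), 0L)

  two <- matrix(FALSE, 5, 8); two[1:2, 1:2] <- TRUE; two[4:5, 6:7] <- TRUE
  expect_identical(euler_characteristic(two), 2L)

  expect_identical(euler_characteristic(matrix(FALSE, 4, 4)), 0L)

  # diagonal pair: 8-connected foreground, so one component
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(euler_characteristic(diag2), 1L)
})

test_that("V - E + F equals the flood-fill oracle on random grids", {
  set.seed(101)
  for (rep in 1:250) {
    B <- random_grid(16, p = stats::runif(1, 0.2, 0.8))
    expect_identical(euler_characteristic(B), as.integer(oracle_euler(B)))
  }
})

test_that("Euler characteristic is additive over disjoint halves", {
  set.seed(202)
  for (rep in 1:20) {
    A <- random_grid(8, 8); B <- random_grid(8, 8)
    G <- matrix(FALSE, 8, 18)
    G[, 1:8] <- A; G[, 11:18] <- B
    expect_identical(euler_characteristic(G),
                     as.integer(euler_characteristic(A) +
                                  euler_characteristic(B)))
  }
})

test_that("the ECC of a constant image is a unit step", {
  img <- gray_image(matrix(100L, 9, 9))
  ec <- euler_curve(img)
  expect_identical(ec$chi, ifelse(0:255 <= 100, 1L, 0L))
  expect_equal(ec$chi_norm, ec$chi / 81)
  expect_identical(ec$n_pixels, 81L)
  # superlevel at level 0 with a simply connected mask is 1
  expect_identical(ec$chi[1], 1L)
})

test_that("sublevel filtration mirrors the step the other way", {
  img <- gray_image(matrix(100L, 9, 9))
  ec <- euler_curve(img, direction = "sublevel")
  expect_identical(ec$chi, ifelse(0:255 >= 100, 1L, 0L))
})

test_that("masked-out pixels never enter the complex", {
  px <- matrix(255L, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  ec <- euler_curve(gray_image(px, mask), levels = c(0, 255))
  expect_identical(ec$chi, c(1L, 1L))
  expect_identical(ec$n_pixels, 16L)
})

test_that("max-min metric is nonnegative, 1/N for constants, reversal-safe", {
  img <- gray_image(matrix(55L, 7, 7))
  expect_equal(max_min_difference(euler_curve(img)), 1 / 49)

  cfg <- simulation_config(grid_n = 48, t_samples = c(600, 3600), seed = 3)
  for (im in generate_impregnation_images(cfg)) {
    ec <- euler_curve(im)
    expect_gte(max_min_difference(ec), 0)
    rev_ec <- ec
    rev_ec$chi_norm <- rev(ec$chi_norm)
    expect_equal(max_min_difference(rev_ec), max_min_difference(ec))
  }
})

test_that("double-peak detection separates diffusion texture from flat images", {
  # constant and all-zero curves: no double peak
  expect_false(detect_double_peak(
    euler_curve(gray_image(matrix(100L, 12, 12))))$double_peak)
  flat <- euler_curve(gray_image(matrix(100L, 12, 12)))
  flat$chi_norm <- rep(0, length(flat$chi_norm))
  expect_false(detect_double_peak(flat)$double_peak)

  # early-time diffusion images with tissue texture: double peak, with the
  # bright-domain maximum at a higher level than the dark-domain minimum
  for (seed in c(1, 7)) {
    cfg <- simulation_config(grid_n = 96, t_samples = c(300, 900),
                             seed = seed)
    imgs <- generate_impregnation_images(cfg)
    ec <- euler_curve(imgs[[1]])
    dp <- detect_double_peak(ec, window = 11)
    expect_true(dp$double_peak)
    expect_gt(dp$max_level, dp$min_level)
  }
})

test_that("ECC round-trips through its CSV representation", {
  ec <- euler_curve(gray_image(matrix(sample(0:255, 64, TRUE), 8, 8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_euler_curve_csv(ec, path)
  d <- read.csv(path)
  expect_identical(names(d), c("level", "chi", "chi_norm"))
  expect_equal(d$chi, ec$chi)
})
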