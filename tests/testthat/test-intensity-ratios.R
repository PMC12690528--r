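mk_mask <- function(nr, nc, rows = NULL, cols = NULL) {
  m <- matrix(FALSE, nr, nc)
  m[if (is.null(rows)) seq_len(nr) else rows,
    if (is.null(cols)) seq_len(nc) else cols] <- TRUE
  m
}

test_that("integrated density and mean intensity follow their definitions", {
  img <- matrix(2, 5, 4)
  m10 <- mk_mask(5, 4, rows = 1:5, cols = 1:2)  # 10 pixels
  expect_equal(integrated_density(img, m10), 20)
  expect_equal(integrated_density(img, matrix(FALSE, 5, 4)), 0)
  # additive over disjoint masks, linear in intensity
  m2 <- mk_mask(5, 4, cols = 3:4)
  expect_equal(integrated_density(img, m10) + integrated_density(img, m2),
               integrated_density(img, m10 | m2))
  expect_equal(integrated_density(3 * img, m10),
               3 * integrated_density(img, m10))
  expect_error(integrated_density(img, matrix(TRUE, 2, 2)), "shapes")

  expect_equal(mean_intensity(matrix(3, 4, 4), mk_mask(4, 4)), 3)
  two <- matrix(0, 2, 2); two[1, 1] <- 1; two[2, 1] <- 3
  expect_equal(mean_intensity(two, mk_mask(2, 2, cols = 1)), 2)
  # invariant to pixels outside the mask
  two[1, 2] <- 999
  expect_equal(mean_intensity(two, mk_mask(2, 2, cols = 1)), 2)
  expect_error(mean_intensity(two, matrix(FALSE, 2, 2)), "empty")
})

test_that("surface/expression ratio is scale invariant with guarded zeros", {
  cell <- mk_mask(6, 6, rows = 2:5, cols = 2:5)
  alfa <- matrix(4, 6, 6); gfp <- matrix(2, 6, 6)
  expect_equal(alfa_gfp_ratio(alfa, gfp, cell)$value, 2)
  expect_equal(alfa_gfp_ratio(gfp, gfp, cell)$value, 1)
  expect_equal(alfa_gfp_ratio(2 * alfa, 2 * gfp, cell)$value, 2)
  expect_error(alfa_gfp_ratio(alfa, matrix(0, 6, 6), cell), "zero")
})

test_that("the myoid split halves a rectangular IS band along the declared axis", {
  is_mask <- mk_mask(30, 20, rows = 11:20)
  my <- split_is_mask(is_mask, axis = "row", proximal = "high")
  expect_true(all(my[16:20, ]))
  expect_false(any(my[1:15, ]))
  expect_true(all(!my | is_mask))        # subset always
  expect_equal(sum(my), sum(is_mask) / 2)
  lo <- split_is_mask(is_mask, axis = "row", proximal = "low")
  expect_true(all(lo[11:15, ]))
  expect_error(split_is_mask(matrix(FALSE, 3, 3)), "empty")

  # odd-depth rectangle: halves differ only by the midline row
  odd <- mk_mask(30, 20, rows = 11:19)
  ho <- split_is_mask(odd, "row", "high")
  expect_lte(abs(sum(ho) - sum(odd) / 2), 20)  # one row-width

  # convex elliptical masks: geometric counting oracle — symmetry about
  # the extent midpoint bounds the count imbalance by one row-width
  set.seed(12)
  for (rep in 1:10) {
    nr <- sample(25:40, 1); nc <- sample(15:30, 1)
    cy <- runif(1, 10, nr - 10); cx <- runif(1, 5, nc - 5)
    ry <- runif(1, 4, 9); rx <- runif(1, 3, min(cx, nc - cx))
    ell <- (row(matrix(0, nr, nc)) - cy)^2 / ry^2 +
           (col(matrix(0, nr, nc)) - cx)^2 / rx^2 <= 1
    if (!any(ell)) next
    half <- split_is_mask(ell, "row", "high")
    expect_true(all(!half | ell))
    expect_lte(abs(sum(half) - sum(ell) / 2), max(rowSums(ell)))
  }
})

test_that("layer ratio operations recover exact analytic values", {
  img <- matrix(1, 20, 10)
  is_mask <- mk_mask(20, 10, rows = 6:15)
  my <- split_is_mask(is_mask, "row", "high")
  expect_equal(myoid_fraction(img, is_mask, my)$value, 0.5)
  conc <- matrix(0, 20, 10); conc[11:15, ] <- 7
  expect_equal(myoid_fraction(conc, is_mask, my)$value, 1)
  conc2 <- matrix(0, 20, 10); conc2[6:10, ] <- 7
  expect_equal(myoid_fraction(conc2, is_mask, my)$value, 0)
  expect_error(myoid_fraction(img, is_mask, mk_mask(20, 10)), "subset")
  expect_error(myoid_fraction(conc, mk_mask(20, 10, rows = 1:5),
                              matrix(FALSE, 20, 10)), "zero")

  masks <- list(OS = mk_mask(30, 10, rows = 1:10),
                IS = mk_mask(30, 10, rows = 11:20),
                ONL = mk_mask(30, 10, rows = 21:30))
  expect_equal(is_photoreceptor_fraction(matrix(1, 30, 10), masks)$value,
               1 / 3)
  only_is <- matrix(0, 30, 10); only_is[11:20, ] <- 4
  expect_equal(is_photoreceptor_fraction(only_is, masks)$value, 1)
  only_os <- matrix(0, 30, 10); only_os[1:10, ] <- 4
  expect_equal(is_photoreceptor_fraction(only_os, masks)$value, 0)
  masks$OS[12, 1] <- TRUE
  expect_error(is_photoreceptor_fraction(only_is, masks), "disjoint")
})

test_that("z-slice averaging matches per-slice integrated densities", {
  m <- mk_mask(5, 2)
  mk_slice <- function(total) matrix(total / 10, 5, 2)
  expect_equal(zslice_average_density(lapply(c(10, 20, 30), mk_slice), m),
               20)
  one <- mk_slice(14)
  expect_equal(zslice_average_density(list(one), m),
               integrated_density(one, m))
  same <- zslice_average_density(rep(list(one), 3), m)
  expect_equal(same, integrated_density(one, m))
})

test_that("synthetic layered images match their analytic ground truth", {
  # noise free: configured fractions recovered exactly
  s <- synth_layer_image(layer_means = c(OS = 5, IS = 10, ONL = 5),
                         noise_sd = 0)
  img <- s$image$intensity[[1L]]; m <- s$image$masks
  expect_equal(is_photoreceptor_fraction(img, m[c("OS", "IS", "ONL")])$value,
               0.5)
  expect_equal(s$truth$is_fraction, 0.5)
  expect_equal(myoid_fraction(img, m$IS, m$myoid)$value,
               s$truth$myoid_fraction)
  # enrichment shifts the analytic fraction
  e <- synth_layer_image(myoid_mean = 15, noise_sd = 0)
  expect_equal(myoid_fraction(e$image$intensity[[1L]], e$image$masks$IS,
                              e$image$masks$myoid)$value,
               15 / 25)
  # determinism under a fixed seed
  a <- synth_layer_image(noise_sd = 1, seed = 33)
  b <- synth_layer_image(noise_sd = 1, seed = 33)
  expect_identical(a$image$intensity, b$image$intensity)

  # noisy recovery: mean over 50 seeds within 3 Monte-Carlo sds of truth
  vals <- vapply(1:50, function(s) {
    im <- synth_layer_image(myoid_mean = 15, noise_sd = 1, seed = s)
    myoid_fraction(im$image$intensity[[1L]], im$image$masks$IS,
                   im$image$masks$myoid)$value
  }, numeric(1L))
  truth <- 15 / 25
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - truth), 3 * mc_se + 1e-4)
})

test_that("group comparisons detect a myoid-enrichment shift with high power", {
  # two groups of layered regions, enrichment effect >= 1 sd of the
  # per-region sampling noise; unpaired t at alpha .05 over 200 reps
  set.seed(99)
  reps <- 200L
  hits <- 0L
  for (r in seq_len(reps)) {
    n_a <- sample(9:15, 1); n_b <- sample(9:15, 1)
    frac <- function(myoid_mean, seed) {
      im <- synth_layer_image(myoid_mean = myoid_mean, noise_sd = 1,
                              seed = seed)$image
      myoid_fraction(im$intensity[[1L]], im$masks$IS,
                     im$masks$myoid)$value
    }
    seeds_a <- sample.int(1e6, n_a); seeds_b <- sample.int(1e6, n_b)
    a <- vapply(seeds_a, function(s) frac(10.6, s), numeric(1L))
    b <- vapply(seeds_b, function(s) frac(10.0, s), numeric(1L))
    if (student_t_unpaired(a, b)$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.8)
})

test_that("TIFF round-trip feeds the reader when the tiff package is present", {
  skip_if_not_installed("tiff")
  d <- withr::local_tempdir()
  img <- matrix(runif(50), 10, 5)
  mask <- mk_mask(10, 5, rows = 3:7)
  tiff::writeTIFF(img, file.path(d, "chan.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(mask * 1, file.path(d, "mask.tif"),
                  bits.per.sample = 32L)
  li <- read_layer_image(c(green = file.path(d, "chan.tif")),
                         c(IS = file.path(d, "mask.tif")))
  expect_equal(dim(li$intensity$green), c(10L, 5L))
  expect_equal(li$masks$IS, mask)
  expect_equal(mean_intensity(li$intensity$green, li$masks$IS),
               mean(img[mask]), tolerance = 1e-6)
  expect_equal(li$intensity$green, img, tolerance = 1e-7)
})
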