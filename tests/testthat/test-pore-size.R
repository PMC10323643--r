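# Collagen-network topology: segmentation, disk-opening pore ladder, the 50%
# rule, and fibril content.

test_that("two-level images segment exactly, with polarity handling", {
  img <- matrix(10, 32, 32)
  img[9:24, 9:24] <- 200
  mask <- binarize(img)
  expect_identical(mask$pixels, img > 100)
  inv <- binarize(max(img) - img + 5, invert = TRUE)
  expect_identical(inv$pixels, mask$pixels)
  expect_error(binarize(matrix(7, 8, 8)), "constant")
})

test_that("segmentation of noisy synthetic networks matches the generating mask", {
  net <- simulate_network_image(seed = 3)   # fibril 200 vs background 10, SNR ~ 10
  mask <- binarize(net$image)
  expect_gte(mean(mask$pixels == net$mask$pixels), 0.95)
})

test_that("opening by a single-pixel disk is the identity and larger disks shrink coverage", {
  net <- simulate_network_image(seed = 5)
  fr <- eroded_pore_area(net$mask, c(1, 5, 10, 15))
  expect_identical(unname(fr[1]), 1)
  expect_true(all(diff(fr) <= 1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("opening agrees with the exhaustive placement oracle on small masks", {
  # a disk pore opened by a smaller disk is unchanged
  m <- matrix(TRUE, 41, 41)
  d2 <- outer(((1:41) - 21)^2, ((1:41) - 21)^2, "+")
  m[d2 <= (21 / 2)^2] <- FALSE
  expect_equal(unname(eroded_pore_area(network_mask(m), c(1, 11))[2]), 1)
  # a 4-px-wide rectangular pore cannot host a 5-px disk
  m2 <- matrix(TRUE, 20, 30)
  m2[5:8, 3:28] <- FALSE
  expect_equal(unname(eroded_pore_area(network_mask(m2), c(1, 5))[2]), 0)
  expect_equal(oracle_open_fraction(!m2, 5), 0)
  # random small masks against the brute-force oracle
  set.seed(12)
  for (rep in 1:5) {
    mk <- matrix(runif(24 * 24) < 0.35, 24, 24)   # fibril ~35%
    if (!any(mk) || all(mk)) next
    for (d in c(3, 5)) {
      pkg <- unname(eroded_pore_area(network_mask(mk), c(1, d))[2])
      expect_equal(pkg, oracle_open_fraction(!mk, d), tolerance = 1e-12)
    }
  }
})

test_that("opening is anti-extensive: the opened set stays inside the pore phase", {
  net <- simulate_network_image(seed = 8)
  pore <- !net$mask$pixels
  dist_to_fibril <- as.matrix(EBImage::distmap(
    matrix(as.numeric(pore), nrow(pore), ncol(pore))))
  for (d in c(5, 11, 17)) {
    r <- d / 2
    centres <- dist_to_fibril > r
    dist_to_centres <- as.matrix(EBImage::distmap(
      matrix(as.numeric(!centres), nrow(pore), ncol(pore))))
    opened <- dist_to_centres <= r
    expect_true(all(pore[opened]))
  }
})

test_that("the 50% rule interpolates the instrument ladder to ~7.85 px", {
  # fractions as printed for the reference ladder {1, 5, 10, 15} px
  mpd <- mean_pore_diameter(c(1, 5, 10, 15),
                            c(0.9339, 0.6745, 0.3684, 0.2051))
  expect_equal(mpd, 5 + (0.6745 - 0.5) / (0.6745 - 0.3684) * 5,
               tolerance = 1e-12)
  expect_equal(mpd, 7.85, tolerance = 0.01)
  # endpoint hit is exact
  expect_identical(mean_pore_diameter(c(1, 5), c(1, 0.5)), 5)
  # unbracketed ladders are rejected with advice
  expect_error(mean_pore_diameter(c(1, 5), c(1, 0.8)), "widen")
  expect_error(mean_pore_diameter(c(1, 5, 10), c(1, 0.4, 0.6)),
               "non-increasing")
})

test_that("disk-pore phantoms are sized to within 2 px by the full ladder", {
  for (D in c(9, 15, 21)) {
    lad <- pore_size_ladder(network_mask(disk_pore_phantom(D)))
    expect_gte(lad$mean_pore_diameter_px, D - 2)
    expect_lte(lad$mean_pore_diameter_px, D + 2)
  }
})

test_that("physical pore size is stable under pixel-size rescaling", {
  # the same physical object (15 um pores) sampled at 1 um and 0.5 um pitch
  lad1 <- pore_size_ladder(network_mask(disk_pore_phantom(15),
                                        pixel_size_um = 1))
  lad2 <- pore_size_ladder(network_mask(disk_pore_phantom(30),
                                        pixel_size_um = 0.5),
                           disk_diameters_px = seq(1, 61, 2))
  expect_equal(lad2$mean_pore_diameter_px / lad1$mean_pore_diameter_px, 2,
               tolerance = 0.1)
  expect_equal(lad2$mean_pore_diameter_um, lad1$mean_pore_diameter_um,
               tolerance = 0.1)
})

test_that("fibril content averages slice fractions and matches programmed density", {
  expect_equal(fibril_content(network_mask(matrix(TRUE, 8, 8))), 1)
  checker <- matrix(c(TRUE, FALSE), 8, 8)
  expect_equal(fibril_content(network_mask(checker)), 0.5)
  dens <- vapply(1:20, function(s)
    simulate_network_image(seed = s)$fibril_density, numeric(1))
  expect_lt(abs(mean(dens) - 0.12), 0.01)
  # list input averages over slices
  two <- list(network_mask(matrix(TRUE, 4, 4)),
              network_mask(matrix(FALSE, 4, 4)))
  expect_equal(fibril_content(two), 0.5)
})
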