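test_that("Otsu foreground separates two-level and bimodal images", {
  img <- matrix(c(rep(0, 32), rep(10, 32)), 8, 8)
  mask <- otsu_foreground(img)
  expect_identical(c(unclass(mask)), c(img == 10))
  expect_false(attr(mask, "degenerate"))

  # constant image: empty mask plus degenerate warning
  expect_warning(m0 <- otsu_foreground(matrix(3, 4, 4)), "constant")
  expect_false(any(m0))
  expect_true(attr(m0, "degenerate"))

  # two Gaussian modes: at least 99% of the high mode lands in the mask
  set.seed(12)
  low <- rnorm(2000, 5, 1); high <- rnorm(2000, 50, 1)
  img2 <- matrix(c(low, high), 40, 100)
  m2 <- otsu_foreground(img2)
  expect_gte(mean(m2[img2 > 40]), 0.99)
  expect_lte(mean(m2[img2 < 15]), 0.01)
})

test_that("Otsu foreground agrees with the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  img <- matrix(c(rpois(500, 3), rpois(500, 40)), 20, 50)
  mask <- otsu_foreground(img)
  ref_thr <- EBImage::otsu(img / max(img), range = c(0, 1), levels = 256) *
    max(img)
  # both implementations must pick the same foreground pixels (the exact
  # threshold placement within the inter-mode gap may differ)
  expect_gte(mean(c(mask) == c(img > ref_thr)), 0.99)
})

test_that("SNR follows the 75th-percentile foreground formula", {
  # foreground values 10,14,18,22 over zero background: p75 = 19, mean 16;
  # confocal foreground all 2: p75 = 2 -> SNR = (19-16)/2 = 1.5
  sted <- matrix(0, 4, 4); sted[1, ] <- c(10, 14, 18, 22)
  conf <- matrix(0, 4, 4); conf[1, ] <- 2
  tr <- acquisition_triplet(conf, sted, conf, 20)
  expect_equal(snr(tr), 1.5)

  # doubling the STED image doubles the SNR (confocal unchanged)
  tr2 <- acquisition_triplet(conf, 2 * sted, conf, 20)
  expect_equal(snr(tr2), 3.0)

  # constant STED foreground: numerator 0
  sted3 <- matrix(0, 4, 4); sted3[1, ] <- 8
  expect_equal(snr(acquisition_triplet(conf, sted3, conf, 20)), 0)
})

test_that("photobleaching is the relative confocal foreground drop", {
  conf1 <- matrix(0, 4, 4); conf1[1:2, ] <- 10
  tr_same <- acquisition_triplet(conf1, conf1, conf1, 20)
  expect_equal(photobleaching(tr_same), 0)
  conf2 <- conf1; conf2[1:2, ] <- 5
  expect_equal(photobleaching(acquisition_triplet(conf1, conf1, conf2, 20)),
               0.5)
  conf3 <- conf1; conf3[1:2, ] <- 0
  expect_equal(photobleaching(acquisition_triplet(conf1, conf1, conf3, 20)),
               1.0)
  # intensity increase reported unclipped (negative)
  conf4 <- conf1; conf4[1:2, ] <- 15
  expect_equal(photobleaching(acquisition_triplet(conf1, conf1, conf4, 20)),
               -0.5)
})

test_that("background added below the Otsu threshold leaves SNR and
           bleaching unchanged when the mask is unchanged", {
  set.seed(8)
  sp <- small_space(4)
  tr <- generate_image(grid_matrix(sp)[3, ], ground_truth(sp, noise_sd = 0))
  # raise only the sub-threshold pixels: foreground statistics and masks
  # stay identical by construction
  bump <- function(m) {
    fg <- otsu_foreground(m)
    m[!fg] <- m[!fg] + 0.2
    m
  }
  tr2 <- acquisition_triplet(bump(tr$confocal_before), bump(tr$sted),
                             bump(tr$confocal_after), tr$pixel_size)
  expect_equal(as.numeric(snr(tr2)), as.numeric(snr(tr)))
  expect_equal(as.numeric(photobleaching(tr2)),
               as.numeric(photobleaching(tr)))
})

test_that("autocorrelation amplitude reads the lattice signature", {
  # pure cosine, 180 nm period sampled at 20 nm: amplitude about 2
  x <- seq_len(72)
  prof <- cos(2 * pi * x / 9)
  expect_equal(autocorrelation_amplitude(prof, 20), 2, tolerance = 0.1)
  # constant profile: degenerate 0
  a0 <- autocorrelation_amplitude(rep(5, 32), 20)
  expect_equal(as.numeric(a0), 0)
  expect_true(attr(a0, "degenerate"))
  # white noise: low amplitude
  set.seed(2)
  expect_lt(autocorrelation_amplitude(rnorm(128), 20), 0.5)
  expect_error(autocorrelation_amplitude(1:8, 20), "length")
})

test_that("2x2 subsampling partitions the image and doubles pixel size", {
  m <- matrix(1:4, 2, 2, byrow = TRUE)  # [[1,2],[3,4]]
  subs <- frc_subsample(m)
  expect_equal(length(subs), 4)
  expect_equal(as.numeric(unlist(subs)), c(1, 2, 3, 4))
  # conservation and exact reassembly on a larger image
  set.seed(6)
  img <- matrix(rpois(112 * 112, 10), 112, 112)
  s4 <- frc_subsample(img)
  expect_true(all(vapply(s4, function(s) all(dim(s) == c(56, 56)),
                         logical(1))))
  expect_equal(sum(unlist(s4)), sum(img))
  re <- matrix(0, 112, 112)
  re[seq(1, 112, 2), seq(1, 112, 2)] <- s4[[1]]
  re[seq(1, 112, 2), seq(2, 112, 2)] <- s4[[2]]
  re[seq(2, 112, 2), seq(1, 112, 2)] <- s4[[3]]
  re[seq(2, 112, 2), seq(2, 112, 2)] <- s4[[4]]
  expect_equal(re, img, ignore_attr = TRUE)
  # odd trailing column dropped with a flag
  expect_true(attr(frc_subsample(matrix(1:6, 2, 3)), "cropped"))
})

test_that("ring correlation is 1 for identical inputs and the averaged
           curve stays in [-1, 1]", {
  set.seed(14)
  img <- matrix(rpois(64 * 64, 20), 64, 64)
  sub <- frc_subsample(img)[[1]]
  Fc <- stats::fft(sub)
  ring <- stedopt:::.ring_index(nrow(sub), ncol(sub))
  rc <- stedopt:::.ring_correlation(Fc, Fc, ring, nrow(sub) %/% 2)
  expect_true(all(abs(rc - 1) < 1e-9 | rc == 0))
  res <- frc_resolution(img, 20)
  expect_s3_class(res, "frc_result")
  expect_equal(res$n_pairs, 6)
  expect_true(all(res$raw_curve >= -1 - 1e-9 & res$raw_curve <= 1 + 1e-9))
  expect_true(all(diff(res$frequencies) > 0))
})

test_that("independent noise stays below the 3-sigma threshold on most
           rings and an all-zero image is undefined", {
  set.seed(21)
  img <- matrix(rpois(64 * 64, 50), 64, 64)  # pure noise, no structure
  res <- frc_resolution(img, 20)
  frac_below <- mean(abs(res$raw_curve) < res$threshold_curve)
  expect_gte(frac_below, 0.9)
  z <- frc_resolution(matrix(0, 8, 8), 20)
  expect_true(inherits(z, "undefined_value"))
})

test_that("calcium response measures dF/F on foreground tiles", {
  # identical stacks: all dF/F zero, ratio 0
  rec0 <- uncaging_stacks(0)
  out0 <- calcium_response(rec0)
  expect_equal(sum(out0$foreground), 4)
  expect_equal(out0$response_size_ratio, 0)
  expect_equal(out0$peak_dff, 0)

  # half the foreground tiles double intensity: dF/F = 1, ratio 0.5
  out2 <- calcium_response(uncaging_stacks(2))
  expect_equal(out2$response_size_ratio, 0.5)
  expect_equal(out2$peak_dff, 1)

  # ratio is monotone in the number of responding tiles
  ratios <- vapply(0:4, function(k)
    calcium_response(uncaging_stacks(k))$response_size_ratio, numeric(1))
  expect_true(all(diff(ratios) >= 0))
  expect_true(all(ratios >= 0 & ratios <= 1))

  # background-only recording: undefined ratio sentinel
  dark <- calcium_recording(array(1, c(16, 16, 5)), array(1, c(16, 16, 5)))
  expect_true(inherits(calcium_response(dark)$response_size_ratio,
                       "undefined_value"))
})

test_that("response classification at the 0.6 threshold", {
  expect_equal(classify_response(0), "no_response")
  expect_equal(classify_response(0.5), "local")
  expect_equal(classify_response(0.6), "local")
  expect_equal(classify_response(0.61), "widespread")
  expect_true(is.na(classify_response(NA)))
})

test_that("triplets survive a TIFF round trip", {
  set.seed(33)
  sp <- small_space(4)
  tr <- generate_image(grid_matrix(sp)[2, ], ground_truth(sp))
  paths <- file.path(tempdir(), c("b.tif", "s.tif", "a.tif"))
  write_triplet(tr, paths[1], paths[2], paths[3])
  tr2 <- read_triplet(paths[1], paths[2], paths[3], pixel_size = 20)
  expect_equal(tr2$sted, tr$sted)
  expect_equal(tr2$confocal_before, tr$confocal_before)
  expect_equal(compute_objectives(tr2)$photobleaching,
               compute_objectives(tr)$photobleaching)
})
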