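#' Confocal/STED/confocal acquisition triplet
#'
#' Container for the three images acquired per STED acquisition: a confocal
#' image before the STED scan, the STED image itself, and a confocal image
#' after, from which photobleaching is estimated. Images are numeric
#' matrices of non-negative, photon-count-like values; row/column indexing
#' with origin at the top-left.
#'
#' @param confocal_before,sted,confocal_after Numeric matrices of equal
#'   dimensions.
#' @param pixel_size Pixel size in nm (> 0).
#' @return An object of class \code{acquisition_triplet}.
#' @export
acquisition_triplet <- function(confocal_before, sted, confocal_after,
                                pixel_size) {
  imgs <- list(confocal_before = confocal_before, sted = sted,
               confocal_after = confocal_after)
  for (nm in names(imgs)) {
    if (!is.matrix(imgs[[nm]]) || !is.numeric(imgs[[nm]]))
      stop("'", nm, "' must be a numeric matrix")
    if (any(imgs[[nm]] < 0, na.rm = TRUE))
      stop("'", nm, "' contains negative values")
  }
  d <- dim(confocal_before)
  if (!identical(d, dim(sted)) || !identical(d, dim(confocal_after)))
    stop("the three images must share dimensions")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(c(imgs, list(pixel_size = pixel_size)),
            class = "acquisition_triplet")
}

#' Foreground extraction by Otsu's method
#'
#' Finds the threshold minimizing the within-class intensity variance over
#' a 256-bin histogram spanning the image range, and returns the mask of
#' pixels strictly above it. A constant image has no separable modes: the
#' mask is empty and carries attribute \code{degenerate = TRUE} along with
#' a warning.
#'
#' @param image Numeric matrix.
#' @return Logical matrix; attributes \code{threshold} and
#'   \code{degenerate}.
#' @export
otsu_foreground <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant image: Otsu foreground is empty")
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  nbins <- 256L
  ## bin i covers [lo + (i-1)w, lo + iw); top value lands in the last bin
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / length(v)
  mids <- lo + ((seq_len(nbins) - 0.5) / nbins) * (hi - lo)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[nbins]
  w1 <- 1 - w0
  ## between-class variance; maximizing it minimizes within-class variance
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_tot * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(bcv)
  thr <- lo + (k / nbins) * (hi - lo)   # upper edge of the chosen bin
  mask <- image > thr
  attr(mask, "threshold") <- thr
  attr(mask, "degenerate") <- FALSE
  mask
}

## sentinel for undefined objective values, with a reason for the audit log
undefined_value <- function(reason) {
  structure(NA_real_, reason = reason, class = c("undefined_value", "numeric"))
}

#' @export
print.undefined_value <- function(x, ...) {
  cat("undefined objective value:", attr(x, "reason"), "\n")
  invisible(x)
}

#' Signal-to-noise ratio of a STED acquisition
#'
#' \deqn{SNR = (STED_{fg}^{75} - \overline{STED_{fg}}) / Confocal1_{fg}^{75}}
#' where the 75th percentile and mean are taken over each image's own Otsu
#' foreground (STED mask for the STED terms, before-confocal mask for the
#' confocal term) and the percentile uses linear interpolation between
#' order statistics.
#'
#' @param triplet An \code{acquisition_triplet}.
#' @return Dimensionless ratio, or an undefined-value sentinel when a
#'   foreground is empty or the denominator is zero.
#' @export
snr <- function(triplet) {
  stopifnot(inherits(triplet, "acquisition_triplet"))
  fg_sted <- otsu_foreground(triplet$sted)
  fg_conf <- otsu_foreground(triplet$confocal_before)
  if (!any(fg_sted)) return(undefined_value("empty STED foreground"))
  if (!any(fg_conf)) return(undefined_value("empty confocal foreground"))
  s <- triplet$sted[fg_sted]
  c1 <- triplet$confocal_before[fg_conf]
  denom <- stats::quantile(c1, 0.75, names = FALSE, type = 7)
  if (denom == 0) return(undefined_value("zero confocal 75th percentile"))
  (stats::quantile(s, 0.75, names = FALSE, type = 7) - mean(s)) / denom
}

#' Photobleaching fraction across a STED acquisition
#'
#' \deqn{(\overline{Confocal1_{fg}} - \overline{Confocal2_{fg}}) /
#'       \overline{Confocal1_{fg}}}
#' with the Otsu foreground mask computed on the before image and applied
#' to both confocal images. Values can be negative (intensity increase)
#' and are reported unclipped; complete bleaching gives 1.
#'
#' @param triplet An \code{acquisition_triplet}.
#' @return Fraction (at most 1), or an undefined-value sentinel.
#' @export
photobleaching <- function(triplet) {
  stopifnot(inherits(triplet, "acquisition_triplet"))
  fg <- otsu_foreground(triplet$confocal_before)
  if (!any(fg)) return(undefined_value("empty confocal foreground"))
  m1 <- mean(triplet$confocal_before[fg])
  if (m1 == 0) return(undefined_value("zero foreground mean before"))
  m2 <- mean(triplet$confocal_after[fg])
  (m1 - m2) / m1
}

#' Autocorrelation amplitude of a periodic line profile
#'
#' The profile is mean-subtracted and variance-normalized, and its
#' (unbiased, lag-normalized) autocorrelation is computed over lags
#' 0..length/2. The amplitude is the difference between the first local
#' maximum following the first local minimum at positive lag and that
#' minimum — the signature of a periodic lattice (e.g. the ~180 nm axonal
#' actin rings). Returns 0 with attribute \code{degenerate = TRUE} for a
#' constant profile and 0 when no interior extremum exists.
#'
#' @param profile Numeric vector, length >= 16.
#' @param pixel_size Pixel size in nm (recorded; lags are in pixels).
#' @return Amplitude (first max minus first min of the autocorrelation).
#' @export
autocorrelation_amplitude <- function(profile, pixel_size = NA_real_) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 16) stop("profile must have length >= 16")
  s <- stats::sd(profile)
  if (!is.finite(s) || s == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  x <- (profile - mean(profile)) / s
  L <- n %/% 2
  ## unbiased normalized autocorrelation: divide lag-k sum by (n - k)
  ac <- vapply(0:L, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k)
  }, numeric(1))
  if (length(ac) < 3) return(0)
  interior <- 2:(length(ac) - 1)
  is_min <- ac[interior] < ac[interior - 1] & ac[interior] < ac[interior + 1]
  if (!any(is_min)) return(0)
  i_min <- interior[which(is_min)[1]]
  after <- interior[interior > i_min]
  if (length(after) == 0) return(0)
  is_max <- ac[after] > ac[after - 1] & ac[after] > ac[after + 1]
  if (!any(is_max)) return(0)
  i_max <- after[which(is_max)[1]]
  ac[i_max] - ac[i_min]
}

#' Split an image into four independent sub-images (2 x 2 binning)
#'
#' Every 2 x 2 pixel bin contributes one pixel to each of four sub-images:
#' pixel (2r+a, 2c+b), a,b in {0,1}, goes to sub-image (a,b) at position
#' (r,c). The four sub-images partition the input and the effective pixel
#' size doubles. Odd trailing rows/columns are dropped with attribute
#' \code{cropped = TRUE}.
#'
#' @param image Numeric matrix.
#' @return List of four matrices, in order (0,0), (0,1), (1,0), (1,1) of
#'   (row offset, column offset).
#' @export
frc_subsample <- function(image) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  cropped <- (nr %% 2L != 0L) || (nc %% 2L != 0L)
  nr <- nr - nr %% 2L; nc <- nc - nc %% 2L
  if (nr < 2 || nc < 2) stop("image too small to subsample")
  img <- image[seq_len(nr), seq_len(nc), drop = FALSE]
  subs <- list(
    img[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE],
    img[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE],
    img[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE],
    img[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE])
  attr(subs, "cropped") <- cropped
  subs
}

## 2-D Hann window (alpha = beta = 0.5) applied in both directions
.hann2d <- function(nr, nc) {
  hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(hr, hc)
}

## integer ring index (rounded radius on the centered Fourier grid) per
## element of an nr x nc spectrum, plus per-ring pixel counts
.ring_index <- function(nr, nc) {
  fr <- ifelse(seq_len(nr) - 1 <= nr %/% 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr)
  fc <- ifelse(seq_len(nc) - 1 <= nc %/% 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc)
  r <- round(sqrt(outer(fr^2, fc^2, "+")))
  r
}

## ring correlation between two spectra for rings 1..rmax
.ring_correlation <- function(F1, F2, ring, rmax) {
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  keep <- ring >= 1 & ring <= rmax
  idx <- factor(ring[keep], levels = seq_len(rmax))
  sn <- tapply(num[keep], idx, sum, default = 0)
  s1 <- tapply(p1[keep], idx, sum, default = 0)
  s2 <- tapply(p2[keep], idx, sum, default = 0)
  corr <- as.numeric(sn) / sqrt(as.numeric(s1) * as.numeric(s2))
  corr[!is.finite(corr)] <- 0
  corr
}

## centered moving average with half-width hw (shrinking window at edges)
.moving_average <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Fourier ring correlation resolution estimate
#'
#' The image is split into four independent sub-images
#' (\code{\link{frc_subsample}}), each is Hann-windowed in x and y and
#' Fourier transformed, and the ring correlation per integer-radius
#' frequency ring (DC excluded) is averaged over the six unordered
#' sub-image pairs. A moving-average filter of half-width 3 smooths the
#' curve. The resolution is the reciprocal of the first spatial frequency
#' at which the smoothed curve falls below the 3-sigma threshold curve
#' \eqn{3/\sqrt{n_{ring}/2}}; absent (NA) if no crossing occurs.
#'
#' @param image Numeric matrix, even dimensions.
#' @param pixel_size Pixel size of the input image in nm; the sub-images
#'   have twice this pixel size.
#' @return An object of class \code{frc_result} with \code{frequencies}
#'   (1/nm), \code{curve}, \code{raw_curve}, \code{threshold_curve},
#'   \code{resolution} (nm or NA) and \code{n_pairs}.
#' @export
frc_resolution <- function(image, pixel_size) {
  stopifnot(is.matrix(image), is.finite(pixel_size), pixel_size > 0)
  if (all(image == 0)) return(undefined_value("all-zero image"))
  subs <- frc_subsample(image)
  nr <- nrow(subs[[1]]); nc <- ncol(subs[[1]])
  win <- .hann2d(nr, nc)
  spectra <- lapply(subs, function(s) stats::fft(s * win))
  ring <- .ring_index(nr, nc)
  rmax <- min(nr, nc) %/% 2
  nring <- tabulate(ring[ring >= 1 & ring <= rmax], rmax)
  pairs <- utils::combn(4, 2)
  curves <- apply(pairs, 2, function(p)
    .ring_correlation(spectra[[p[1]]], spectra[[p[2]]], ring, rmax))
  raw <- rowMeans(curves)
  smooth <- .moving_average(raw, 3L)
  threshold <- 3 / sqrt(nring / 2)
  sub_px <- 2 * pixel_size
  ## ring r corresponds to spatial frequency r / (n * pixel) per axis;
  ## use the geometric size of the (possibly non-square) field
  freq <- seq_len(rmax) / (min(nr, nc) * sub_px)
  below <- which(smooth < threshold)
  resolution <- if (length(below) == 0) NA_real_ else 1 / freq[below[1]]
  structure(list(frequencies = freq, curve = smooth, raw_curve = raw,
                 threshold_curve = threshold, resolution = resolution,
                 n_pairs = ncol(pairs)),
            class = "frc_result")
}

#' Calcium uncaging recording
#'
#' A baseline time-lapse stack acquired before the uncaging pulse and a
#' response stack acquired after it, as 3-D arrays (rows x cols x frames).
#'
#' @param baseline_stack,response_stack Numeric 3-D arrays sharing frame
#'   dimensions; defaults in acquisition were 25 baseline and 75 response
#'   frames.
#' @param photon_threshold Foreground photon-count threshold per tile
#'   (default 5).
#' @param tile Tile edge in pixels (default 8).
#' @param dff_response_level Minimum transient amplitude, in dF/F, defining
#'   the responding area (default 0.75).
#' @return An object of class \code{calcium_recording}.
#' @export
calcium_recording <- function(baseline_stack, response_stack,
                              photon_threshold = 5, tile = 8L,
                              dff_response_level = 0.75) {
  if (length(dim(baseline_stack)) != 3L || length(dim(response_stack)) != 3L)
    stop("stacks must be 3-D arrays (rows x cols x frames)")
  if (!identical(dim(baseline_stack)[1:2], dim(response_stack)[1:2]))
    stop("stacks must share frame dimensions")
  if (photon_threshold <= 0 || tile < 1 || dff_response_level <= 0)
    stop("thresholds must be positive")
  structure(list(baseline_stack = baseline_stack,
                 response_stack = response_stack,
                 photon_threshold = photon_threshold, tile = as.integer(tile),
                 dff_response_level = dff_response_level),
            class = "calcium_recording")
}

## mean of each t x t tile of a matrix; trailing partial tiles dropped
.tile_means <- function(m, t) {
  nr <- nrow(m) %/% t; nc <- ncol(m) %/% t
  m <- m[seq_len(nr * t), seq_len(nc * t), drop = FALSE]
  ## average over tile rows then tile columns
  rowgrp <- rep(seq_len(nr), each = t)
  colgrp <- rep(seq_len(nc), each = t)
  tm <- rowsum(m, rowgrp) / t
  t(rowsum(t(tm), colgrp) / t)
}

#' Calcium-uncaging response statistics
#'
#' The field is split into square tiles (default 8 x 8 pixels). A tile is
#' foreground when its mean signal across all baseline frames and the
#' first ten response frames exceeds the photon threshold. Per foreground
#' tile, F0 is the tile mean of the time-averaged baseline stack and F the
#' tile mean of the average of the first two response frames;
#' dF/F = (F - F0)/F0. The response size ratio is the fraction of
#' foreground tiles whose dF/F reaches the response level (default 0.75).
#'
#' @param rec A \code{calcium_recording}.
#' @return List with \code{foreground} (logical tile matrix), \code{dff}
#'   (tile matrix, NA outside foreground or where F0 = 0), \code{peak_dff},
#'   \code{response_size_ratio} (undefined sentinel when no foreground),
#'   and \code{n_excluded} (foreground tiles dropped for F0 = 0).
#' @export
calcium_response <- function(rec) {
  stopifnot(inherits(rec, "calcium_recording"))
  t <- rec$tile
  nb <- dim(rec$baseline_stack)[3]
  nresp <- dim(rec$response_stack)[3]
  base_mean <- apply(rec$baseline_stack, c(1, 2), mean)
  n10 <- min(10L, nresp)
  resp10_mean <- apply(rec$response_stack[, , seq_len(n10), drop = FALSE],
                       c(1, 2), mean)
  ## detection signal: mean over all baseline frames and first 10 response
  detect <- (base_mean * nb + resp10_mean * n10) / (nb + n10)
  fg <- .tile_means(detect, t) > rec$photon_threshold
  n2 <- min(2L, nresp)
  resp2_mean <- apply(rec$response_stack[, , seq_len(n2), drop = FALSE],
                      c(1, 2), mean)
  F0 <- .tile_means(base_mean, t)
  Fv <- .tile_means(resp2_mean, t)
  dff <- matrix(NA_real_, nrow(F0), ncol(F0))
  usable <- fg & F0 > 0
  dff[usable] <- (Fv[usable] - F0[usable]) / F0[usable]
  n_excluded <- sum(fg & F0 <= 0)
  n_fg <- sum(fg)
  if (n_fg == 0L) {
    return(list(foreground = fg, dff = dff, peak_dff = NA_real_,
                response_size_ratio = undefined_value("no foreground tiles"),
                n_excluded = n_excluded))
  }
  responding <- sum(dff[usable] >= rec$dff_response_level)
  list(foreground = fg, dff = dff,
       peak_dff = if (any(usable)) max(dff[usable]) else NA_real_,
       response_size_ratio = responding / n_fg,
       n_excluded = n_excluded)
}

#' Classify a response-size ratio as no / local / widespread response
#'
#' A response is "no response" at ratio 0, "local" when the ratio is
#' positive but does not exceed the threshold, and "widespread" above it.
#'
#' @param ratio Response-size ratio in [0, 1] (NA allowed).
#' @param threshold Response-size ratio threshold (default 0.6).
#' @return Character: "no_response", "local", "widespread" or NA.
#' @export
classify_response <- function(ratio, threshold = 0.6) {
  if (is.na(ratio)) return(NA_character_)
  if (ratio == 0) "no_response"
  else if (ratio <= threshold) "local"
  else "widespread"
}

#' Compute all STED objectives on a triplet
#'
#' @param triplet An \code{acquisition_triplet}.
#' @param profile_row Row of the STED image used as the lattice line
#'   profile (default: middle row).
#' @return Named list: \code{snr}, \code{photobleaching},
#'   \code{autocorrelation}, \code{frc_resolution}.
#' @export
compute_objectives <- function(triplet, profile_row = NULL) {
  stopifnot(inherits(triplet, "acquisition_triplet"))
  if (is.null(profile_row)) profile_row <- (nrow(triplet$sted) + 1L) %/% 2L
  frc <- tryCatch(frc_resolution(triplet$sted, triplet$pixel_size),
                  error = function(e) NULL)
  list(
    snr = as.numeric(snr(triplet)),
    photobleaching = as.numeric(photobleaching(triplet)),
    autocorrelation = as.numeric(
      autocorrelation_amplitude(triplet$sted[profile_row, ],
                                triplet$pixel_size)),
    frc_resolution = if (inherits(frc, "frc_result")) frc$resolution
                     else NA_real_)
}

#' Read/write an acquisition triplet as TIFF files
#'
#' Images are stored as single-channel TIFFs; intensities are divided by
#' \code{scale} on write (16-bit range) and multiplied back on read. The
#' pixel size is not parsed from TIFF tags — it travels in configs.
#'
#' @param triplet An \code{acquisition_triplet}.
#' @param before,sted,after File paths.
#' @param pixel_size Pixel size in nm (read).
#' @param scale Maximum representable photon count (default 65535).
#' @return \code{write_triplet} returns the paths invisibly;
#'   \code{read_triplet} returns an \code{acquisition_triplet}.
#' @export
write_triplet <- function(triplet, before, sted, after, scale = 65535) {
  stopifnot(inherits(triplet, "acquisition_triplet"))
  wr <- function(img, path)
    tiff::writeTIFF(pmin(pmax(img / scale, 0), 1), path,
                    bits.per.sample = 16L)
  wr(triplet$confocal_before, before)
  wr(triplet$sted, sted)
  wr(triplet$confocal_after, after)
  invisible(c(before, sted, after))
}

#' @rdname write_triplet
#' @export
read_triplet <- function(before, sted, after, pixel_size, scale = 65535) {
  rd <- function(path) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * scale)
  }
  acquisition_triplet(rd(before), rd(sted), rd(after), pixel_size)
}
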