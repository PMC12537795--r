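# Stimulus generation and preprocessing.
#
# Coordinate convention (fixed package-wide): pixel (row, col) is 0-based in
# continuous coordinates, x = col increasing rightward, y = row increasing
# downward; orientation is measured in degrees from the positive x-axis,
# counter-clockwise in (x, y). A grating of orientation theta modulates along
# the direction (cos theta, sin theta); its bars run perpendicular to theta.

#' Construct a stimulus image
#'
#' Wraps a numeric matrix of intensities in \[0, 1\] together with provenance
#' metadata. All generators in this module return this class.
#'
#' @param pixels numeric matrix, intensities in \[0, 1\] (rows = y, cols = x).
#' @param provenance one of "loaded", "pink_noise", "oriented_texture",
#'   "grating".
#' @param seed integer seed used for generation, or NULL for loaded images.
#' @param params list of generator parameters recorded for reproducibility.
#' @return an object of class `stim_image`.
#' @export
stim_image <- function(pixels, provenance = "loaded", seed = NULL,
                       params = list()) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0) stop("empty image")
  if (anyNA(pixels)) stop("NA pixels")
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12) {
    stop("pixel intensities must lie in [0, 1]")
  }
  provenance <- match.arg(provenance,
    c("loaded", "pink_noise", "oriented_texture", "grating"))
  if (provenance != "loaded" && is.null(seed) &&
      provenance != "grating") {
    stop("synthetic images must record their seed")
  }
  structure(
    list(pixels = pmin(pmax(pixels, 0), 1),
         height = nrow(pixels), width = ncol(pixels),
         provenance = provenance, seed = seed, params = params),
    class = "stim_image")
}

#' @export
print.stim_image <- function(x, ...) {
  cat(sprintf("<stim_image %dx%d, %s%s>\n", x$height, x$width, x$provenance,
              if (!is.null(x$seed)) paste0(", seed=", x$seed) else ""))
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "stim_image")) image$pixels else as.matrix(image)
}

#' Preprocess a raw image
#'
#' Converts to grayscale (luminance average over channels), applies 256-bin
#' histogram equalization, and rescales to \[0, 1\]. This is the only
#' preprocessing applied to photographs before LGN encoding.
#'
#' @param raw_pixels numeric matrix or 3-d array (h x w x channels) of
#'   nonnegative intensities, any scale.
#' @return a `stim_image` with provenance "loaded".
#' @export
preprocess_image <- function(raw_pixels) {
  if (length(raw_pixels) == 0) stop("empty image")
  if (is.array(raw_pixels) && length(dim(raw_pixels)) == 3) {
    raw_pixels <- apply(raw_pixels, c(1, 2), mean)
  }
  v <- as.matrix(raw_pixels)
  if (anyNA(v) || min(v) < 0) stop("raw intensities must be nonnegative")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: histogram equalization degenerate, returning 0.5")
    return(stim_image(matrix(0.5, nrow(v), ncol(v)), "loaded"))
  }
  u <- (v - rng[1]) / (rng[2] - rng[1])
  # 256-bin equalization regardless of source bit depth
  bin <- pmin(floor(u * 256), 255) + 1L
  cdf <- cumsum(tabulate(bin, 256L)) / length(bin)
  cdf_min <- min(cdf[cdf > 0])
  eq <- (cdf[bin] - cdf_min) / (1 - cdf_min)
  out <- matrix(pmin(pmax(eq, 0), 1), nrow(v), ncol(v))
  stim_image(out, "loaded")
}

# Signed fft frequencies in cycles/pixel for n samples.
fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

rescale01 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0.5, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# Filter white noise in the Fourier domain by a real, conjugate-symmetric
# amplitude weight, returning a real image rescaled to [0, 1].
fourier_synth <- function(height, width, weight_fn, seed, provenance, params) {
  if (height <= 0 || width <= 0) stop("non-positive image dimensions")
  with_seed(seed, {
    noise <- matrix(stats::rnorm(height * width), height, width)
    fy <- fft_freq(height)
    fx <- fft_freq(width)
    f2 <- outer(fy^2, fx^2, "+")
    w <- weight_fn(sqrt(f2), outer(fy, rep(1, width)), outer(rep(1, height), fx))
    w[1, 1] <- 0  # zero DC: mean carries no structure
    spec <- stats::fft(noise) * w
    img <- Re(stats::fft(spec, inverse = TRUE)) / (height * width)
    stim_image(rescale01(img), provenance, seed = seed, params = params)
  })
}

#' Generate 1/f^alpha pink noise
#'
#' Random-phase Fourier synthesis with amplitude spectrum proportional to
#' `f^(-spectral_exponent)`; stands in for texture-rich natural images, whose
#' power spectra fall off approximately as 1/f^2 (amplitude 1/f).
#'
#' @param height,width image size in pixels.
#' @param spectral_exponent nonnegative amplitude-spectrum exponent
#'   (default 1: natural-image-like; 0: white noise).
#' @param seed integer seed; same seed reproduces the image bit-identically.
#' @return a `stim_image` with provenance "pink_noise".
#' @export
make_pink_noise <- function(height, width, spectral_exponent = 1, seed = 1L) {
  if (spectral_exponent < 0) stop("spectral_exponent must be >= 0")
  fourier_synth(height, width,
    function(f, fy, fx) {
      w <- ifelse(f > 0, f^(-spectral_exponent), 0)
      w
    },
    seed, "pink_noise",
    list(spectral_exponent = spectral_exponent))
}

#' Generate an oriented band-pass texture
#'
#' White noise filtered by an oriented band-pass filter: a Gaussian angular
#' window of width `bandwidth_deg` about the requested modulation direction,
#' combined with a 1/f radial amplitude falloff. Because a single global
#' filter shapes the whole image, non-overlapping windows share orientation
#' statistics — the long-range contextual structure the column model exploits.
#'
#' @param height,width image size in pixels.
#' @param orientation_deg modulation (wave-vector) direction in \[0, 180).
#' @param bandwidth_deg angular SD of the orientation band (> 0).
#' @param seed integer seed.
#' @return a `stim_image` with provenance "oriented_texture".
#' @export
make_oriented_texture <- function(height, width, orientation_deg,
                                  bandwidth_deg = 15, seed = 1L) {
  if (bandwidth_deg <= 0) stop("bandwidth must be positive")
  theta <- orientation_deg * pi / 180
  bw <- bandwidth_deg * pi / 180
  fourier_synth(height, width,
    function(f, fy, fx) {
      ang <- atan2(fy, fx)                 # wave-vector angle
      d <- ang - theta
      d <- atan2(sin(d), cos(d))           # wrap to (-pi, pi]
      d <- ifelse(abs(d) > pi / 2, d - sign(d) * pi, d)  # axial (mod 180)
      radial <- ifelse(f > 0, 1 / f, 0)
      radial * exp(-d^2 / (2 * bw^2))
    },
    seed, "oriented_texture",
    list(orientation_deg = orientation_deg, bandwidth_deg = bandwidth_deg))
}

#' Specify a sinewave grating
#'
#' @param orientation_deg modulation direction in degrees, \[0, 180).
#' @param spatial_frequency cycles per pixel, in (0, 0.5\].
#' @param phase_deg phase in degrees, \[0, 360).
#' @param contrast Michelson contrast in (0, 1\].
#' @return an object of class `grating_spec`.
#' @export
grating_spec <- function(orientation_deg, spatial_frequency,
                         phase_deg = 0, contrast = 1) {
  if (spatial_frequency <= 0) stop("spatial frequency must be positive")
  if (spatial_frequency > 0.5) {
    stop("spatial frequency above Nyquist limit (0.5 cycles/pixel)")
  }
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  structure(
    list(orientation_deg = orientation_deg %% 180,
         spatial_frequency = spatial_frequency,
         phase_deg = phase_deg %% 360, contrast = contrast),
    class = "grating_spec")
}

#' Render a sinewave grating
#'
#' `I(x, y) = 0.5 + 0.5 * contrast * sin(2 pi sf (x cos t + y sin t) + phase)`
#' with x = column and y = row in 0-based pixel coordinates.
#'
#' @param spec a [grating_spec()].
#' @param height,width canvas size in pixels.
#' @return a `stim_image` with provenance "grating".
#' @export
make_grating <- function(spec, height, width) {
  stopifnot(inherits(spec, "grating_spec"))
  theta <- spec$orientation_deg * pi / 180
  phase <- spec$phase_deg * pi / 180
  x <- outer(rep(1, height), 0:(width - 1))
  y <- outer(0:(height - 1), rep(1, width))
  arg <- 2 * pi * spec$spatial_frequency * (x * cos(theta) + y * sin(theta)) +
    phase
  px <- 0.5 + 0.5 * spec$contrast * sin(arg)
  stim_image(px, "grating", seed = NULL, params = unclass(spec))
}

#' Render a drifting grating as discrete phase steps
#'
#' "Moving" gratings are realized as `phase_steps` phase offsets evenly
#' spanning one full 360-degree drift cycle.
#'
#' @param spec a [grating_spec()]; its phase is the cycle origin.
#' @param height,width canvas size.
#' @param phase_steps number of frames per cycle (default 16).
#' @return list of `stim_image` frames.
#' @export
make_drifting_grating <- function(spec, height, width, phase_steps = 16) {
  phases <- spec$phase_deg + 360 * (0:(phase_steps - 1)) / phase_steps
  lapply(phases, function(p) {
    make_grating(grating_spec(spec$orientation_deg, spec$spatial_frequency,
                              p, spec$contrast), height, width)
  })
}

#' Radially averaged amplitude spectrum
#'
#' Diagnostic used to verify generator spectra: the 2-d FFT amplitude is
#' binned by radial frequency and averaged.
#'
#' @param image `stim_image` or matrix.
#' @param n_bins number of radial bins.
#' @return data.frame with columns `freq` and `amplitude`.
#' @export
radial_spectrum <- function(image, n_bins = 20) {
  px <- as_pixels(image)
  px <- px - mean(px)
  amp <- Mod(stats::fft(px))
  f <- sqrt(outer(fft_freq(nrow(px))^2, fft_freq(ncol(px))^2, "+"))
  keep <- f > 0 & f <= 0.5
  bins <- cut(f[keep], breaks = seq(0, 0.5, length.out = n_bins + 1))
  data.frame(
    freq = tapply(f[keep], bins, mean),
    amplitude = tapply(amp[keep], bins, mean))
}

#' Dominant orientation of an image power spectrum
#'
#' Energy-weighted axial (doubled-angle) circular mean of wave-vector angles,
#' in degrees in \[0, 180). Used to verify oriented-texture generation and to
#' characterize learned receptive fields.
#'
#' @param image `stim_image` or matrix.
#' @return list with `orientation_deg` (dominant modulation direction) and
#'   `selectivity` (resultant length in \[0, 1\], 0 = isotropic).
#' @export
spectral_orientation <- function(image) {
  px <- as_pixels(image)
  px <- px - mean(px)
  p <- Mod(stats::fft(px))^2
  fy <- fft_freq(nrow(px)); fx <- fft_freq(ncol(px))
  fyg <- outer(fy, rep(1, ncol(px)))
  fxg <- outer(rep(1, nrow(px)), fx)
  f <- sqrt(fyg^2 + fxg^2)
  keep <- f > 0
  ang2 <- 2 * atan2(fyg[keep], fxg[keep])
  wt <- p[keep]
  z <- sum(wt * exp(1i * ang2)) / sum(wt)
  list(orientation_deg = (Arg(z) / 2 * 180 / pi) %% 180,
       selectivity = Mod(z))
}

#' Read a grayscale image from disk
#'
#' Supports plain/raw PGM (P2/P5), PNG (if the `png` package is installed),
#' and CSV matrices. Values are rescaled to \[0, 1\] and histogram-equalized
#' when `equalize = TRUE`.
#'
#' @param path file path.
#' @param equalize apply [preprocess_image()] (default TRUE).
#' @return a `stim_image`.
#' @export
read_image <- function(path, equalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    pgm = read_pgm(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG requires the 'png' package")
      }
      img <- png::readPNG(path)
      if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                              c(1, 2), mean)
      img
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: ", ext))
  if (equalize) preprocess_image(raw) else {
    stim_image(rescale01(as.matrix(raw)), "loaded")
  }
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  tokens <- integer(0)
  # header: width, height, maxval with comment lines allowed
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0 || nchar(ch) == 0) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (ch == "\n" || nchar(ch) == 0) break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  vals <- if (magic == "P2") {
    as.integer(scan(con, what = integer(), n = w * h, quiet = TRUE))
  } else {
    if (maxval > 255) stop("16-bit raw PGM not supported")
    as.integer(readBin(con, "integer", n = w * h, size = 1, signed = FALSE))
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a stimulus image to disk
#'
#' Writes plain PGM (P2, 8-bit) plus a JSON sidecar recording provenance,
#' generator parameters, and seed; or PNG when the `png` package is available
#' and the path ends in .png.
#'
#' @param image a `stim_image`.
#' @param path output path (.pgm or .png).
#' @return invisibly, the path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "stim_image"))
  ext <- tolower(tools::file_ext(path))
  q <- round(image$pixels * 255)
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package")
    }
    png::writePNG(image$pixels, path)
  } else {
    lines <- c("P2", paste(image$width, image$height), "255",
               apply(q, 1, paste, collapse = " "))
    writeLines(lines, path)
  }
  sidecar <- list(provenance = image$provenance, seed = image$seed,
                  height = image$height, width = image$width,
                  params = image$params)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Generate a battery of synthetic training images
#'
#' Desk-scale stand-in for the natural-image training sets: a mixture of
#' oriented textures (planted long-range orientation structure) and pink
#' noise, all histogram-equalized like loaded photographs.
#'
#' @param n_images number of images.
#' @param height,width image size (default 160).
#' @param seed master seed; each image derives its own seed.
#' @param p_oriented fraction of oriented-texture images (default 0.75).
#' @param bandwidth_deg orientation bandwidth for textures.
#' @return list of `stim_image`s.
#' @export
make_stimulus_battery <- function(n_images = 20, height = 160, width = 160,
                                  seed = 1L, p_oriented = 0.75,
                                  bandwidth_deg = 20) {
  oris <- with_seed(derive_seed(seed, "battery-ori"),
                    stats::runif(n_images, 0, 180))
  kinds <- with_seed(derive_seed(seed, "battery-kind"),
                     stats::runif(n_images) < p_oriented)
  lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, 1000L + i)
    img <- if (kinds[i]) {
      make_oriented_texture(height, width, oris[i], bandwidth_deg, seed = s)
    } else {
      make_pink_noise(height, width, 1, seed = s)
    }
    out <- preprocess_image(img$pixels)
    out$provenance <- img$provenance
    out$seed <- s
    out$params <- img$params
    out
  })
}
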