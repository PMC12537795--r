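# LGN front end: ON/OFF difference-of-Gaussians cells on a hexagonal
# receptive-field lattice. A mesocolumn's afferent input is the 182-vector of
# 91 ON followed by 91 OFF rectified responses.

#' LGN encoding parameters
#'
#' Center-surround difference-of-Gaussians receptive fields with a hard
#' support cutoff. Defaults reproduce the standard retina/LGN model used for
#' V1 simulations: sigma_center = 0.8833 px, sigma_surround = 2.6499 px,
#' support radius 8 px (16 px RF diameter), spontaneous baseline 0.1.
#'
#' @param sigma_center center Gaussian SD in pixels.
#' @param sigma_surr surround Gaussian SD in pixels (> sigma_center).
#' @param cutoff_radius kernel support radius in pixels; the kernel is 0 at
#'   distances greater than this.
#' @param baseline spontaneous activity added before rectification.
#' @param rings hexagonal lattice ring count (5 gives 91 sites).
#' @param spacing lattice nearest-neighbor spacing in pixels.
#' @return an object of class `lgn_params`.
#' @export
lgn_params <- function(sigma_center = 0.8833, sigma_surr = 2.6499,
                       cutoff_radius = 8, baseline = 0.1,
                       rings = 5, spacing = 1) {
  if (sigma_center >= sigma_surr) stop("sigma_center must be < sigma_surr")
  if (cutoff_radius <= 0) stop("cutoff_radius must be positive")
  structure(list(sigma_center = sigma_center, sigma_surr = sigma_surr,
                 cutoff_radius = cutoff_radius, baseline = baseline,
                 rings = rings, spacing = spacing),
            class = "lgn_params")
}

#' Centered hexagonal lattice of RF centers
#'
#' Sites lie on a hex grid with rows parallel to the x-axis, alternate rows
#' offset by spacing/2, and row pitch spacing * sqrt(3)/2. Site count is the
#' centered hexagonal number 1 + 3 r (r + 1); rings = 5 gives the 91 ON-cell
#' arrangement of a mesocolumn's LGN window. Ordering is deterministic: by
#' ring index, then by angle from the positive x-axis.
#'
#' @param rings number of hexagonal rings around the center (>= 0).
#' @param spacing nearest-neighbor distance in pixels.
#' @param center 2-vector (x, y) of the lattice center in image coordinates.
#' @param rotation_deg optional rigid rotation of the lattice.
#' @return data.frame (x, y, ring) of class `hex_lattice` with attributes
#'   `rings` and `spacing`.
#' @export
hex_lattice <- function(rings, spacing = 1, center = c(0, 0),
                        rotation_deg = 0) {
  if (rings < 0) stop("rings must be >= 0")
  if (spacing <= 0) stop("spacing must be positive")
  qr <- expand.grid(q = -rings:rings, r = -rings:rings)
  qr <- qr[abs(qr$q + qr$r) <= rings, , drop = FALSE]
  x <- spacing * (qr$q + qr$r / 2)
  y <- spacing * (qr$r * sqrt(3) / 2)
  ring <- pmax(abs(qr$q), abs(qr$r), abs(qr$q + qr$r))
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    xr <- x * cos(th) - y * sin(th)
    y <- x * sin(th) + y * cos(th)
    x <- xr
  }
  ang <- atan2(y, x) %% (2 * pi)
  ord <- order(ring, ang, method = "radix")
  out <- data.frame(x = x[ord] + center[1], y = y[ord] + center[2],
                    ring = ring[ord])
  structure(out, class = c("hex_lattice", "data.frame"),
            rings = rings, spacing = spacing)
}

#' Difference-of-Gaussians kernel weights
#'
#' Evaluates the DoG profile at every integer pixel whose Euclidean distance
#' from the (possibly fractional) center is at most the cutoff radius:
#' `R = exp(-D^2 / 2 sc^2) / (2 pi sc^2) - exp(-D^2 / 2 ss^2) / (2 pi ss^2)`,
#' zero outside the support. No renormalization is applied after truncation.
#'
#' @param params an [lgn_params()].
#' @param center 2-vector (x, y) of the RF center in pixel coordinates.
#' @return data.frame (x, y, w) of integer pixel coordinates and weights.
#' @export
dog_kernel <- function(params, center = c(0, 0)) {
  rad <- params$cutoff_radius
  xs <- seq(floor(center[1] - rad), ceiling(center[1] + rad))
  ys <- seq(floor(center[2] - rad), ceiling(center[2] + rad))
  g <- expand.grid(x = xs, y = ys)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2
  # tolerance: hex geometry places pixels at exactly D = cutoff (included)
  keep <- d2 <= rad^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  sc2 <- params$sigma_center^2
  ss2 <- params$sigma_surr^2
  g$w <- exp(-d2 / (2 * sc2)) / (2 * pi * sc2) -
    exp(-d2 / (2 * ss2)) / (2 * pi * ss2)
  rownames(g) <- NULL
  g
}

# Sum of the truncated kernel over its support (net DC gain); truncation
# removes more surround than center mass, so this is a small positive number.
dog_kernel_sum <- function(params) sum(dog_kernel(params)$w)

#' Encode an image patch into a mesocolumn's afferent vector
#'
#' For each lattice site the ON response is `[baseline + sum(R * I)]+` and the
#' OFF response `[baseline - sum(R * I)]+`; ON and OFF cells share the same
#' centers. The returned vector stacks the ON block then the OFF block
#' (length 182 at default parameters).
#'
#' @param image `stim_image` or intensity matrix in \[0, 1\].
#' @param window_center 2-vector (x, y), 0-based pixel coordinates of the
#'   lattice center within the image.
#' @param params an [lgn_params()].
#' @param lattice optional precomputed [hex_lattice()] centered at origin.
#' @return numeric vector of length 2 * sites with attribute `n_on`.
#' @export
encode_patch <- function(image, window_center, params = lgn_params(),
                         lattice = NULL) {
  px <- as_pixels(image)
  if (is.null(lattice)) lattice <- hex_lattice(params$rings, params$spacing)
  extent <- max(sqrt(lattice$x^2 + lattice$y^2)) + params$cutoff_radius
  h <- nrow(px); w <- ncol(px)
  if (window_center[1] - extent < 0 || window_center[1] + extent > w - 1 ||
      window_center[2] - extent < 0 || window_center[2] + extent > h - 1) {
    stop("encoding window out of image bounds (no padding is applied)")
  }
  drive <- vapply(seq_len(nrow(lattice)), function(i) {
    k <- dog_kernel(params,
                    c(window_center[1] + lattice$x[i],
                      window_center[2] + lattice$y[i]))
    # pixel (x, y) -> matrix [y + 1, x + 1]
    sum(k$w * px[cbind(k$y + 1L, k$x + 1L)])
  }, numeric(1))
  a <- c(pmax(params$baseline + drive, 0), pmax(params$baseline - drive, 0))
  attr(a, "n_on") <- nrow(lattice)
  a
}

#' Export a lattice as CSV
#'
#' @param lattice a [hex_lattice()].
#' @param path output CSV path (columns x, y, ring).
#' @return invisibly, the path.
#' @export
write_lattice_csv <- function(lattice, path) {
  utils::write.csv(as.data.frame(lattice), path, row.names = FALSE)
  invisible(path)
}
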