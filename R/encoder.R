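# Batched LGN encoding of an entire columnar field.
#
# Encoding ~200 mesocolumn windows patch-by-patch dominates training cost,
# so windows are grouped by the fractional part of their pixel offset: all
# windows in a group share one dense stencil matrix (91 DoG kernels evaluated
# on a common integer grid), and a group is encoded with a single dense
# matrix product over the gathered patches of all its windows. This is
# arithmetically identical to evaluating the DoG at every integer pixel
# around each (fractional) site center.

dog_value <- function(d2, params) {
  sc2 <- params$sigma_center^2
  ss2 <- params$sigma_surr^2
  v <- exp(-d2 / (2 * sc2)) / (2 * pi * sc2) -
    exp(-d2 / (2 * ss2)) / (2 * pi * ss2)
  v[d2 > params$cutoff_radius^2 + 1e-9] <- 0
  v
}

#' Build a batched LGN encoder for a field layout
#'
#' Precomputes dense DoG stencils for every distinct fractional window
#' offset in the layout, so that [encode_field()] reduces to gathers plus
#' dense matrix products.
#'
#' @param layout a [build_field()] layout, or NULL for a single window at
#'   the anchor.
#' @param params an [lgn_params()].
#' @return an object of class `field_encoder`.
#' @export
build_encoder <- function(layout = NULL, params = lgn_params()) {
  lattice <- hex_lattice(params$rings, params$spacing)
  if (is.null(layout)) {
    wx <- 0; wy <- 0
  } else {
    wx <- layout$units$x; wy <- layout$units$y
  }
  n_windows <- length(wx)
  n_on <- nrow(lattice)
  iux <- floor(wx); iuy <- floor(wy)
  fux <- wx - iux;  fuy <- wy - iuy
  key <- paste(round(fux, 9), round(fuy, 9))
  groups <- split(seq_len(n_windows), key)
  rad <- params$cutoff_radius
  group_data <- lapply(groups, function(wins) {
    fx <- fux[wins[1]]; fy <- fuy[wins[1]]
    cx <- lattice$x + fx  # site centers relative to anchor + int offset
    cy <- lattice$y + fy
    gx <- floor(min(cx) - rad):ceiling(max(cx) + rad)
    gy <- floor(min(cy) - rad):ceiling(max(cy) + rad)
    grid <- expand.grid(dy = gy, dx = gx)  # dy fastest: column-major per dx
    d2 <- outer(grid$dx, cx, "-")^2 + outer(grid$dy, cy, "-")^2
    stencil <- dog_value(d2, params)        # grid points x sites
    list(windows = wins, gx = gx, gy = gy, stencil = t(stencil))
  })
  ext_x <- max(vapply(seq_along(group_data), function(g) {
    max(abs(c(outer(iux[group_data[[g]]$windows], range(group_data[[g]]$gx), "+"))))
  }, numeric(1)))
  ext_y <- max(vapply(seq_along(group_data), function(g) {
    max(abs(c(outer(iuy[group_data[[g]]$windows], range(group_data[[g]]$gy), "+"))))
  }, numeric(1)))
  half <- as.integer(max(ext_x, ext_y))
  side <- 2L * half + 1L
  # per-window gather indices into the flattened bbox patch (x-major)
  gather <- vector("list", n_windows)
  for (g in group_data) {
    for (w in g$windows) {
      px <- iux[w] + g$gx  # absolute x offsets from anchor
      py <- iuy[w] + g$gy
      # flatten: idx = (x + half) * side + (y + half) + 1
      gather[[w]] <- as.integer(outer(py + half + 1L, (px + half) * side, "+"))
    }
  }
  structure(list(groups = group_data, gather = gather,
                 half = half, side = side, n_on = n_on,
                 n_windows = n_windows, params = params, lattice = lattice),
            class = "field_encoder")
}

# Extract flattened bounding-box patches (x-major order) for anchors.
extract_patches <- function(encoder, images, anchors) {
  half <- encoder$half; side <- encoder$side
  n <- nrow(anchors)
  out <- matrix(0, side^2, n)
  for (i in seq_len(n)) {
    px <- as_pixels(images[[anchors[i, "img"]]])
    rows <- (anchors[i, "y"] - half):(anchors[i, "y"] + half) + 1L
    cols <- (anchors[i, "x"] - half):(anchors[i, "x"] + half) + 1L
    if (rows[1] < 1 || cols[1] < 1 || rows[side] > nrow(px) ||
        cols[side] > ncol(px)) {
      stop("anchor out of bounds for encoder bounding box")
    }
    out[, i] <- as.vector(px[rows, cols])  # y fastest within each x block?
  }
  out
}

#' Encode a batch of anchors through the field
#'
#' @param encoder a [build_encoder()].
#' @param images list of `stim_image`s.
#' @param anchors matrix/data.frame with columns img, x, y (0-based integer
#'   pixel coordinates of the field center).
#' @param windows integer indices of windows to encode (default all).
#' @return array of afferent vectors, dim (2 * n_on) x length(windows) x
#'   n_anchors; ON block then OFF block per window, windows in the order
#'   given.
#' @export
encode_field <- function(encoder, images, anchors, windows = NULL) {
  anchors <- as.matrix(anchors)
  windows <- windows %||% seq_len(encoder$n_windows)
  patches <- extract_patches(encoder, images, anchors)
  n <- ncol(patches)
  n_on <- encoder$n_on
  pos <- match(seq_len(encoder$n_windows), windows)  # window -> output slot
  b <- encoder$params$baseline
  out <- array(0, dim = c(2L * n_on, length(windows), n))
  on_rows <- seq_len(n_on)
  for (g in encoder$groups) {
    wins <- g$windows[!is.na(pos[g$windows])]
    if (length(wins) == 0) next
    gathered <- matrix(0, ncol(g$stencil), length(wins) * n)
    for (k in seq_along(wins)) {
      gathered[, (k - 1L) * n + seq_len(n)] <-
        patches[encoder$gather[[wins[k]]], , drop = FALSE]
    }
    res <- g$stencil %*% gathered  # n_on x (len(wins)*n)
    a_on <- b + res
    a_on[a_on < 0] <- 0
    a_off <- b - res
    a_off[a_off < 0] <- 0
    for (k in seq_along(wins)) {
      cols <- (k - 1L) * n + seq_len(n)
      out[on_rows, pos[wins[k]], ] <- a_on[, cols]
      out[n_on + on_rows, pos[wins[k]], ] <- a_off[, cols]
    }
  }
  out
}

#' Sample valid anchors uniformly over a set of images
#'
#' Anchors are drawn so the encoder bounding box always fits inside the
#' image (out-of-bounds placements are impossible by construction).
#'
#' @param encoder a [build_encoder()].
#' @param images list of `stim_image`s.
#' @param n number of anchors.
#' @param seed integer seed.
#' @return matrix with columns img, x, y.
#' @export
sample_anchors <- function(encoder, images, n, seed = NULL) {
  half <- encoder$half
  with_seed(seed, {
    img <- sample.int(length(images), n, replace = TRUE)
    x <- integer(n); y <- integer(n)
    for (i in seq_len(n)) {
      h <- images[[img[i]]]$height %||% nrow(as_pixels(images[[img[i]]]))
      w <- images[[img[i]]]$width %||% ncol(as_pixels(images[[img[i]]]))
      if (w - 1 - half < half || h - 1 - half < half) {
        stop("image smaller than encoder bounding box")
      }
      x[i] <- sample(half:(w - 1 - half), 1)
      y[i] <- sample(half:(h - 1 - half), 1)
    }
    cbind(img = img, x = x, y = y)
  })
}
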