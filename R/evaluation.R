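# Evaluation battery: grating response characterization (F1/F0, orientation
# tuning, HWHH), population discrimination angles, signed-r^2 similarity,
# texture clustering, and contextual-correlation histograms.

#' F1/F0 ratio of a response timecourse
#'
#' F0 is the mean response over one drift cycle; F1 is the amplitude of the
#' fundamental, `2/P * |DFT bin 1|`. Cells with F1/F0 > 1 are phase-sensitive
#' (simple), < 1 phase-invariant (complex). A zero mean response gives ratio
#' 0 with attribute `flat = TRUE`.
#'
#' @param response numeric vector of >= 8 responses uniformly sampling
#'   exactly one drift cycle.
#' @return the F1/F0 ratio (nonnegative scalar).
#' @export
f1f0_score <- function(response) {
  P <- length(response)
  if (P < 8) stop("need >= 8 uniform phase samples spanning one cycle")
  f0 <- mean(response)
  if (f0 == 0) {
    out <- 0
    attr(out, "flat") <- TRUE
    return(out)
  }
  f1 <- 2 / P * Mod(stats::fft(response)[2])
  f1 / abs(f0)
}

#' Orientation tuning curve and simple/complex classification
#'
#' Finds the optimal spatial frequency (maximal cycle-mean F0 over `sf_grid`
#' at a coarse orientation scan), then samples orientations at `ori_step`
#' over \[0, 180) at that frequency. The per-orientation statistic is the F0
#' (cycle mean) of the drift-cycle response. HWHH is measured from the peak
#' to the half-height crossing (half-height = min + (max - min)/2) by linear
#' interpolation, averaging the two sides when both exist. F1/F0 is scored
#' at the optimal orientation and frequency.
#'
#' @param respond_fn function mapping a `stim_image` to a scalar response.
#' @param height,width grating canvas size.
#' @param sf_grid spatial frequencies to scan (cycles/pixel).
#' @param ori_step orientation sampling step in degrees (default 5).
#' @param phase_steps phase frames per drift cycle (default 16).
#' @param coarse_step orientation step for the sf scan (default 30).
#' @return list of class `tuning_curve`: `orientations`, `responses`,
#'   `optimal_orientation`, `optimal_sf`, `hwhh` (NA with `flat = TRUE` for
#'   an isotropic responder), `f1f0`, `cell_class` ("simple"/"complex").
#' @export
orientation_tuning <- function(respond_fn, height = 64, width = 64,
                               sf_grid = c(0.03, 0.05, 0.08, 0.12, 0.18, 0.25),
                               ori_step = 5, phase_steps = 16,
                               coarse_step = 30) {
  cycle_f0 <- function(ori, sf) {
    frames <- make_drifting_grating(grating_spec(ori, sf), height, width,
                                    phase_steps)
    mean(vapply(frames, respond_fn, numeric(1)))
  }
  coarse_ori <- seq(0, 179, by = coarse_step)
  sf_resp <- vapply(sf_grid, function(sf) {
    max(vapply(coarse_ori, cycle_f0, numeric(1), sf = sf))
  }, numeric(1))
  optimal_sf <- sf_grid[which.max(sf_resp)]
  orientations <- seq(0, 180 - ori_step, by = ori_step)
  responses <- vapply(orientations, cycle_f0, numeric(1), sf = optimal_sf)
  peak_i <- which.max(responses)
  optimal_orientation <- orientations[peak_i]
  hwhh <- hwhh_from_curve(orientations, responses)
  frames <- make_drifting_grating(
    grating_spec(optimal_orientation, optimal_sf), height, width, phase_steps)
  tc <- vapply(frames, respond_fn, numeric(1))
  f1f0 <- f1f0_score(tc)
  structure(list(orientations = orientations, responses = responses,
                 optimal_orientation = optimal_orientation,
                 optimal_sf = optimal_sf, hwhh = hwhh,
                 f1f0 = as.numeric(f1f0),
                 cell_class = if (f1f0 > 1) "simple" else "complex"),
            class = "tuning_curve")
}

# Half-width at half-height of a circular (180-degree periodic) tuning curve
# by linear interpolation from the peak outward on both sides.
hwhh_from_curve <- function(orientations, responses) {
  rng <- range(responses)
  if (rng[1] == rng[2]) {
    out <- NA_real_
    attr(out, "flat") <- TRUE
    return(out)
  }
  half <- rng[1] + (rng[2] - rng[1]) / 2
  n <- length(responses)
  peak_i <- which.max(responses)
  side_width <- function(dir) {
    prev <- responses[peak_i]
    for (step in seq_len(n - 1)) {
      i <- ((peak_i - 1 + dir * step) %% n) + 1
      cur <- responses[i]
      if (cur <= half) {
        # interpolate between previous sample and this one
        frac <- if (prev == cur) 0 else (prev - half) / (prev - cur)
        return((step - 1 + frac) * abs(orientations[2] - orientations[1]))
      }
      prev <- cur
    }
    NA_real_  # never crosses half-height on this side
  }
  w <- c(side_width(1L), side_width(-1L))
  if (all(is.na(w))) {
    out <- NA_real_
    attr(out, "flat") <- TRUE
    return(out)
  }
  mean(w, na.rm = TRUE)
}

#' Angle between two population response vectors
#'
#' @param vec_a,vec_b equal-length nonzero numeric vectors.
#' @return angle in degrees (arccos of cosine similarity).
#' @export
population_angle <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) stop("length mismatch")
  na <- sqrt(sum(vec_a^2)); nb <- sqrt(sum(vec_b^2))
  if (na == 0 || nb == 0) stop("zero vector")
  cosv <- sum(vec_a * vec_b) / (na * nb)
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Signed squared correlation
#'
#' `sign(r) * r^2`; zero-variance input gives 0 with attribute `flat`.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return signed r^2 scalar.
#' @export
signed_sq_corr <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- 0
    attr(out, "flat") <- TRUE
    return(out)
  }
  r <- stats::cor(x, y)
  sign(r) * r^2
}

#' Within-texture response similarity
#'
#' For each texture, all pairwise signed r^2 between location-response
#' vectors are averaged; high values mean different views of one texture
#' evoke similar population responses.
#'
#' @param responses_by_texture named list; each element a cells x locations
#'   matrix of population responses for one texture (>= 2 locations).
#' @return named numeric vector of per-texture mean signed r^2.
#' @export
texture_similarity <- function(responses_by_texture) {
  vapply(responses_by_texture, function(m) {
    L <- ncol(m)
    if (L < 2) stop("need >= 2 locations per texture")
    pairs <- utils::combn(L, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      signed_sq_corr(m[, pairs[1, p]], m[, pairs[2, p]])
    }, numeric(1)))
  }, numeric(1))
}

#' Texture clustering in the L3 output space
#'
#' Each location's feature vector is the across-mesocolumn average per cell
#' index; PCA scores of the first three components are returned together
#' with a silhouette score over the texture labels.
#'
#' @param field_responses locations x (cells) matrix of across-mesocolumn
#'   averaged responses (rows = locations, in label order), or a 3-d array
#'   cells x mesocolumns x locations to be averaged here.
#' @param labels factor of texture classes, one per location (>= 2 classes,
#'   >= 10 locations each).
#' @return list with `scores` (locations x 3 PC scores), `silhouette`
#'   (mean silhouette over locations), `explained` (variance fractions).
#' @export
texture_clustering <- function(field_responses, labels) {
  if (length(dim(field_responses)) == 3) {
    field_responses <- t(apply(field_responses, 3, function(m) rowMeans(m)))
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("separation undefined for a single class")
  if (min(table(labels)) < 10) stop("need >= 10 locations per class")
  # per-cell autoscaling makes the statistic invariant to per-cell affine
  # rescaling; constant cells carry no information and are dropped
  keep <- apply(field_responses, 2, stats::sd) > 0
  field_responses <- field_responses[, keep, drop = FALSE]
  pca <- stats::prcomp(field_responses, center = TRUE, scale. = TRUE)
  k <- min(3, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  list(scores = scores,
       silhouette = mean_silhouette(scores, labels),
       explained = (pca$sdev^2 / sum(pca$sdev^2))[seq_len(k)])
}

# Mean silhouette width on Euclidean distances; small-n implementation kept
# local to avoid a hard dependency.
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  labels <- factor(labels)
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(levels(labels)[levels(labels) != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Contextual correlation histograms
#'
#' Two statistics over common patterns: for each central cell, the maximum
#' correlation over all ring cells (selection-biased "best partner"
#' statistic), and the correlation with its same-index ("functionally
#' identical", shared weights) ring cell, pooled over ring columns.
#'
#' @param central cells x patterns response matrix of the central column.
#' @param ring list of cells x patterns matrices for ring columns.
#' @return list with `max_corr` (per central cell) and `matched_corr`
#'   (central cells x ring columns).
#' @export
contextual_histograms <- function(central, ring) {
  rall <- lapply(ring, function(m) cor0(t(central), t(m)))
  max_corr <- apply(do.call(cbind, lapply(rall, function(r) {
    apply(r, 1, max)
  })), 1, max)
  matched <- vapply(rall, function(r) diag(r), numeric(nrow(central)))
  list(max_corr = max_corr,
       matched_corr = matrix(matched, nrow = nrow(central)))
}

#' Discrimination angles between population responses to transformed gratings
#'
#' Draws random base gratings, applies a rotation (mode "orientation") or a
#' phase shift (mode "phase") of size `delta`, and measures the mean angle
#' between the population response vectors to the base and transformed
#' gratings.
#'
#' @param respond_fn function mapping a `stim_image` to a response vector.
#' @param delta transformation magnitude: degrees of rotation, or degrees of
#'   phase shift.
#' @param mode "orientation" or "phase".
#' @param n_gratings random base gratings to average over (default 100).
#' @param height,width canvas size.
#' @param sf_grid spatial frequencies sampled for base gratings.
#' @param seed integer seed.
#' @return mean angle in degrees, with attribute `sd`.
#' @export
discrimination_angle <- function(respond_fn, delta,
                                 mode = c("orientation", "phase"),
                                 n_gratings = 100, height = 64, width = 64,
                                 sf_grid = c(0.03, 0.05, 0.08, 0.12, 0.18, 0.25),
                                 seed = 1L) {
  mode <- match.arg(mode)
  angles <- with_seed(seed, {
    oris <- stats::runif(n_gratings, 0, 180)
    phases <- stats::runif(n_gratings, 0, 360)
    sfs <- sample(sf_grid, n_gratings, replace = TRUE)
    vapply(seq_len(n_gratings), function(i) {
      base <- grating_spec(oris[i], sfs[i], phases[i])
      shifted <- if (mode == "orientation") {
        grating_spec(oris[i] + delta, sfs[i], phases[i])
      } else {
        grating_spec(oris[i], sfs[i], phases[i] + delta)
      }
      va <- respond_fn(make_grating(base, height, width))
      vb <- respond_fn(make_grating(shifted, height, width))
      if (sum(va^2) == 0 || sum(vb^2) == 0) return(NA_real_)
      population_angle(va, vb)
    }, numeric(1))
  })
  out <- mean(angles, na.rm = TRUE)
  attr(out, "sd") <- stats::sd(angles, na.rm = TRUE)
  out
}
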