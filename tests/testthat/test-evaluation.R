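test_that("F1/F0 matches closed forms", {
  ph <- 2 * pi * (0:63) / 64
  expect_equal(f1f0_score(rep(3, 16)), 0)                 # constant
  expect_equal(f1f0_score(1 + cos(ph)), 1, tolerance = 1e-10)
  # half-wave rectified sinusoid: F0 = 1/pi, F1 = 1/2, ratio = pi/2
  expect_equal(f1f0_score(pmax(sin(ph), 0)), pi / 2, tolerance = 1e-3)
  expect_error(f1f0_score(1:4), ">= 8")
  z <- f1f0_score(rep(0, 16))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flat"))
  # invariant to a phase offset of the drift cycle
  expect_equal(f1f0_score(1 + cos(ph + 1.2)), 1, tolerance = 1e-10)
})

test_that("HWHH matches analytic tuning widths", {
  oris <- seq(0, 175, by = 5)
  # Gaussian tuning of SD sigma: HWHH = sigma * sqrt(2 ln 2)
  for (sigma in c(12, 20, 30)) {
    resp <- exp(-(oris - 90)^2 / (2 * sigma^2))
    h <- mesocol:::hwhh_from_curve(oris, resp)
    expect_lt(abs(h - sigma * sqrt(2 * log(2))), 2.5)
  }
  # von Mises (axial) kappa = 2: exact inversion of the half-height crossing
  kappa <- 2
  vm <- exp(kappa * cos(2 * (oris - 90) * pi / 180))
  half_arg <- log((exp(kappa) + exp(-kappa)) / 2) / kappa
  analytic <- acos(half_arg) / 2 * 180 / pi
  h <- mesocol:::hwhh_from_curve(oris, vm)
  expect_lt(abs(h - analytic), 2.5)
  # flat curve is flagged
  flat <- mesocol:::hwhh_from_curve(oris, rep(1, length(oris)))
  expect_true(is.na(flat) && attr(flat, "flat"))
})

test_that("orientation_tuning recovers a planted preferred orientation", {
  # synthetic responder tuned to 60 degrees with Gaussian width 15
  respond <- function(img) {
    o <- img$params$orientation_deg
    d <- abs(o - 60); d <- min(d, 180 - d)
    exp(-d^2 / (2 * 15^2))
  }
  tc <- orientation_tuning(respond, height = 32, width = 32,
                           sf_grid = c(0.1), ori_step = 5)
  expect_equal(tc$optimal_orientation, 60)
  expect_lt(abs(tc$hwhh - 15 * sqrt(2 * log(2))), 2.5)
  expect_equal(tc$cell_class, "complex")  # phase-invariant responder
  # a half-wave-rectified phase-locked responder classifies as simple
  respond_s <- function(img) {
    o <- img$params$orientation_deg
    d <- abs(o - 60); d <- min(d, 180 - d)
    exp(-d^2 / (2 * 15^2)) * max(sin(img$params$phase_deg * pi / 180), 0)
  }
  tcs <- orientation_tuning(respond_s, height = 32, width = 32,
                            sf_grid = c(0.1), ori_step = 15)
  expect_equal(tcs$cell_class, "simple")
  expect_gt(tcs$f1f0, 1)
})

test_that("population angles match geometry and concentration of measure", {
  expect_equal(population_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(population_angle(c(1, 0), c(0, 2)), 90)
  expect_error(population_angle(c(0, 0), c(1, 1)), "zero")
  expect_error(population_angle(1:3, 1:4), "mismatch")
  set.seed(8)
  angs <- replicate(30, population_angle(rnorm(150), rnorm(150)))
  expect_lt(abs(mean(angs) - 90), 5)
})

test_that("signed squared correlation keeps the sign", {
  set.seed(9)
  x <- rnorm(100)
  y <- -x + rnorm(100) * 1.5
  r <- cor(x, y)
  expect_equal(signed_sq_corr(x, y), sign(r) * r^2, tolerance = 1e-12)
  expect_equal(signed_sq_corr(x, x), 1)
  expect_lt(abs(signed_sq_corr(rnorm(1000), rnorm(1000))), 0.02)
  flat <- signed_sq_corr(rep(1, 10), rnorm(10))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "flat"))
})

test_that("texture similarity separates shared-statistics families from noise", {
  set.seed(10)
  identical_locs <- matrix(rep(rnorm(40), 5), 40, 5)
  noise_locs <- matrix(rnorm(40 * 12), 40, 12)
  template <- rnorm(40)
  family <- template %*% t(runif(8, 0.8, 1.2)) + matrix(rnorm(40 * 8), 40, 8) * 0.4
  sim <- texture_similarity(list(same = identical_locs, noise = noise_locs,
                                 family = family))
  expect_equal(unname(sim["same"]), 1, tolerance = 1e-12)
  expect_lt(abs(sim["noise"]), 0.1)
  expect_gt(sim["family"], sim["noise"])
})

test_that("texture clustering separates planted classes and centers scores", {
  set.seed(11)
  mk_class <- function(mu) t(mu + matrix(rnorm(20 * 15), 20, 15) * 0.3)
  feats <- rbind(mk_class(rnorm(20) * 2), mk_class(rnorm(20) * 2),
                 mk_class(rnorm(20) * 2))
  labels <- rep(c("a", "b", "c"), each = 15)
  out <- texture_clustering(feats, labels)
  expect_gt(out$silhouette, 0.5)
  expect_lt(max(abs(colMeans(out$scores))), 1e-10)
  # shuffled labels destroy separation
  shuf <- texture_clustering(feats, sample(labels))
  expect_lt(shuf$silhouette, 0.15)
  # invariant to per-cell affine rescaling applied uniformly across locations
  rescaled <- sweep(sweep(feats, 2, runif(20, 0.5, 3), "*"),
                    2, rnorm(20), "+")
  out2 <- texture_clustering(rescaled, labels)
  expect_equal(out$silhouette, out2$silhouette, tolerance = 1e-8)
  expect_error(texture_clustering(feats, rep("a", 45)), "single class")
})

test_that("contextual histograms: copies, reduction, and permutation null", {
  set.seed(12)
  central <- matrix(rnorm(10 * 150), 10, 150)
  # ring of copies: all correlations 1
  hc <- contextual_histograms(central, list(central, central))
  expect_equal(hc$max_corr, rep(1, 10), tolerance = 1e-12)
  expect_true(all(abs(hc$matched_corr - 1) < 1e-12))
  # a single ring cell population: max equals matched
  ring1 <- list(matrix(rnorm(10 * 150), 10, 150))
  h1 <- contextual_histograms(central[1, , drop = FALSE],
                              list(ring1[[1]][1, , drop = FALSE]))
  expect_equal(h1$max_corr, drop(h1$matched_corr))
  # independent responses: max-correlation distribution matches a
  # permutation oracle (selection bias of the max over 20 ring cells)
  ring <- list(matrix(rnorm(20 * 150), 20, 150))
  h <- contextual_histograms(central, ring)
  perm <- replicate(40, {
    shuffled <- central[, sample(150)]
    mean(contextual_histograms(shuffled, ring)$max_corr)
  })
  expect_lt(abs(mean(h$max_corr) - mean(perm)), 3 * sd(perm))
  expect_gt(mean(h$max_corr), 0)  # selection bias keeps the max positive
})

test_that("discrimination angle responds to transformation size", {
  # population of 30 idealized orientation-tuned units
  prefs <- seq(0, 174, by = 6)
  respond <- function(img) {
    o <- img$params$orientation_deg
    d <- abs(o - prefs); d <- pmin(d, 180 - d)
    exp(-d^2 / (2 * 20^2))
  }
  small <- discrimination_angle(respond, 10, "orientation", n_gratings = 20,
                                height = 16, width = 16, seed = 3)
  large <- discrimination_angle(respond, 80, "orientation", n_gratings = 20,
                                height = 16, width = 16, seed = 3)
  expect_lt(small, large)
  expect_gt(large, 30)
})
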