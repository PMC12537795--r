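test_that("collect_afferents assembles flattened 7-block vectors", {
  asm <- collect_afferents(fx_l4(), fx_layout(), fx_images(), 40, seed = 3,
                           encoder = fx_encoder())
  expect_s3_class(asm, "afferent_assembly")
  expect_equal(nrow(asm$central), 7 * 20)
  expect_length(asm$context, 18)
  # shared weights: the central block of the central mesocolumn equals the
  # direct response of window 1
  aff <- encode_field(fx_encoder(), fx_images(),
                      asm$anchors[1, , drop = FALSE], windows = 1)
  expect_equal(asm$central[1:20, 1], l4_respond(fx_l4(), aff[, 1, 1]),
               tolerance = 1e-12)
})

test_that("a planted shared latent is recovered as the leading variate", {
  pl <- make_planted_views(4000, 12, 1, n_views = 19, seed = 21)
  basis <- fit_variates(pl$views[[1]], pl$views[-1], n_variates = 5,
                        ridge = 0)
  # leading variate aligns with the optimal detector K_auto^-1 K_xs
  detector <- solve(basis$K_auto, cov(t(pl$views[[1]]), pl$S[, 1]))
  cosang <- abs(sum(basis$b[, 1] * detector)) /
    sqrt(sum(basis$b[, 1]^2) * sum(detector^2))
  expect_gt(cosang, 0.95)
  expect_gt(basis$r[1], 0.5)
  # K_auto-conjugacy of the basis (ridge 0: exact to 1e-8)
  btkb <- t(basis$b) %*% basis$K_auto %*% basis$b
  expect_lt(max(abs(btkb - diag(5))), 1e-8)
  expect_true(all(diff(basis$eigenvalues) <= 1e-10))
})

test_that("independent views yield null contextual correlations", {
  nv <- make_null_views(3000, 10, n_views = 19, seed = 5)
  basis <- fit_variates(nv[[1]], nv[-1], n_variates = 8)
  # held-out evaluation: project fresh independent data
  fresh <- make_null_views(3000, 10, n_views = 19, seed = 6)
  phi0 <- project(basis, fresh[[1]])
  phim <- lapply(fresh[-1], function(x) project(basis, x))
  r <- ring_correlation(phi0, phim)$r
  expect_lt(max(abs(r)), 3 / sqrt(3000))
})

test_that("the generalized eigensolver matches brute-force Rayleigh maximization", {
  pl <- make_planted_views(800, 10, 2, n_views = 6, seed = 33)
  X0 <- pl$views[[1]]; ctx <- pl$views[-1]
  mu <- rowMeans(X0); Xc <- X0 - mu
  Ka <- tcrossprod(Xc) / (ncol(X0) - 1)
  Kc <- tcrossprod(Xc, Reduce(`+`, lapply(ctx, function(x) x - mu))) /
    (ncol(X0) - 1)
  Kc <- (Kc + t(Kc)) / 2
  basis <- fit_variates(X0, ctx, n_variates = 3, ridge = 0)
  oracle <- oracle_rayleigh_max(Kc, Ka, n_dirs = 1e5, seed = 2)
  expect_lt(abs(basis$eigenvalues[1] - oracle), 1e-3)
})

test_that("projection is centered, linear, and dimension-checked", {
  pl <- make_planted_views(500, 8, 1, n_views = 3, seed = 9)
  basis <- fit_variates(pl$views[[1]], pl$views[-1], n_variates = 4)
  expect_equal(project(basis, basis$mu), rep(0, 4), tolerance = 1e-12)
  phi <- project(basis, pl$views[[1]])
  expect_lt(max(abs(rowMeans(phi))), 1e-10)
  v <- pl$views[[1]][, 1]
  expect_equal(project(basis, basis$mu + 3 * (v - basis$mu)),
               3 * project(basis, v), tolerance = 1e-10)
  expect_error(project(basis, rep(1, 5)), "mismatch")
})

test_that("extra pure-noise dimensions leave leading correlations unchanged", {
  n <- 4000
  pl <- make_planted_views(n, 8, 1, n_views = 7, seed = 41)
  b1 <- fit_variates(pl$views[[1]], pl$views[-1], n_variates = 3)
  aug <- with_seed(42, lapply(pl$views, function(x) {
    rbind(x, matrix(rnorm(8 * n), 8, n))
  }))
  b2 <- fit_variates(aug[[1]], aug[-1], n_variates = 3)
  expect_lt(abs(b1$r[1] - b2$r[1]), 2 / sqrt(n))
})

test_that("ring_correlation handles degenerate and null harnesses", {
  set.seed(7)
  phi <- matrix(rnorm(3 * 200), 3, 200)
  dup <- ring_correlation(phi, list(phi, phi))
  expect_equal(dup$r, rep(1, 3), tolerance = 1e-12)
  # constant ring responses are guarded to r = 0
  expect_equal(ring_correlation(matrix(1:3, 1), list(matrix(1, 1, 3)))$r, 0)
  indep <- ring_correlation(phi, lapply(1:12, function(i) {
    matrix(rnorm(3 * 200), 3, 200)
  }))
  expect_lt(max(abs(indep$r)), 3 / sqrt(200))
  # r = (1, 0, 0) gives total contextual correlation 1
  central <- rbind(seq_len(50), matrix(rnorm(100), 2))
  ring1 <- rbind(seq_len(50), matrix(rnorm(100), 2))
  rc <- ring_correlation(central, list(ring1))
  expect_equal(rc$signed_r2[1], 1, tolerance = 1e-12)
  expect_equal(rc$total, sum(rc$signed_r2))
})

test_that("count_significant applies the Bonferroni-corrected Pearson test", {
  expect_equal(count_significant(rep(0, 20), 1000)$total, 0)
  cs <- count_significant(c(0.99, 0.5, 0.001), 1000)
  expect_true(cs$significant[1] && cs$significant[2] && !cs$significant[3])
  expect_equal(cs$leading, 2L)
  # family-wise error under the null stays near alpha (Bonferroni)
  set.seed(15)
  fw <- vapply(1:50, function(rep) {
    r <- vapply(1:20, function(i) cor(rnorm(200), rnorm(200)), numeric(1))
    count_significant(r, 200)$total > 0
  }, logical(1))
  expect_lte(mean(fw), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
  expect_error(count_significant(0.5, 3), "n_eval")
})

test_that("cca_overlap scores subspace identity, rotation, and disjointness", {
  pl <- make_planted_views(2000, 10, 3, n_views = 5, noise = 0.3, seed = 55)
  fitp <- pl$views[[1]]
  evalp <- make_planted_views(800, 10, 3, n_views = 5, noise = 0.3,
                              seed = 56)$views[[1]]
  basis <- fit_variates(fitp, pl$views[-1], n_variates = 3)
  # identical bases
  ov <- cca_overlap(basis, basis, fitp, evalp)
  expect_true(all(ov$correlations > 0.999))
  # rotated basis spans the same subspace
  rot <- with_seed(1, qr.Q(qr(matrix(rnorm(9), 3, 3))))
  basis_r <- basis
  basis_r$b <- basis$b %*% rot
  ovr <- cca_overlap(basis, basis_r, fitp, evalp)
  expect_true(all(ovr$correlations > 0.99))
  # orthogonal independent subspaces of a white signal
  white_fit <- matrix(rnorm(10 * 2000), 10, 2000)
  white_eval <- matrix(rnorm(10 * 800), 10, 800)
  ba <- basis; bb <- basis
  ba$b <- diag(10)[, 1:3]; ba$mu <- rep(0, 10)
  bb$b <- diag(10)[, 4:6]; bb$mu <- rep(0, 10)
  ovo <- cca_overlap(ba, bb, white_fit, white_eval)
  expect_lt(max(ovo$correlations), 0.12)
})

test_that("fit_variates validates inputs", {
  pl <- make_planted_views(100, 6, 1, n_views = 3, seed = 3)
  expect_error(fit_variates(pl$views[[1]], pl$views[2]), ">= 2")
  wide <- make_planted_views(9, 50, 1, n_views = 3, seed = 4)
  expect_warning(
    fit_variates(wide$views[[1]], wide$views[-1], n_variates = 2),
    "unstable")
  bad <- pl$views[[1]]; bad[1, 1] <- NA
  expect_error(fit_variates(bad, pl$views[-1]), "NA")
})
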