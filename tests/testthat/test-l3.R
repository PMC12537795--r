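test_that("initialization satisfies both row normalizations", {
  p <- l3_params(n_cells = 9, context_variates_per_meso = 5)
  pop <- l3_init(p, basal_dim = 70, seed = 3)
  expect_equal(sqrt(rowSums(pop$u^2)), rep(1, 9), tolerance = 1e-12)
  expect_equal(rowSums(abs(pop$v)), rep(1, 9), tolerance = 1e-12)
  expect_equal(dim(pop$v), c(9, 18 * 5))
  expect_error(l3_params(theta_L3 = -1), "scales")
  expect_error(l3_params(eta_L3 = 0), "eta")
})

test_that("basal output is linear pre-scaling and autoscaled post-scaling", {
  p <- l3_params(n_cells = 5, context_variates_per_meso = 4)
  pop <- l3_init(p, basal_dim = 30, seed = 1)
  set.seed(2)
  Fb <- matrix(runif(30 * 100), 30, 100)
  raw <- basal_output(pop, Fb, autoscale = FALSE)
  Fc <- Fb - rowMeans(Fb)
  expect_equal(basal_output(pop, 2 * Fc, autoscale = FALSE),
               2 * basal_output(pop, Fc, autoscale = FALSE),
               tolerance = 1e-12)
  phi <- basal_output(pop, Fb)
  expect_lt(max(abs(rowMeans(phi))), 1e-10)
  expect_equal(apply(phi, 1, function(x) sqrt(mean(x^2))), rep(1, 5),
               tolerance = 1e-10)
  # zero-variance cell triggers the variance floor warning
  pop0 <- pop; pop0$u[1, ] <- 0
  expect_warning(basal_output(pop0, Fb), "zero-variance")
})

test_that("apical output reduces correctly in the limiting cases", {
  set.seed(4)
  p0 <- l3_params(n_cells = 6, theta_L3 = 0, lam_L3 = 0,
                  context_variates_per_meso = 3)
  pop <- l3_init(p0, basal_dim = 42, seed = 5)
  Fb <- matrix(runif(42 * 80), 42, 80)
  vr <- matrix(rnorm(18 * 3 * 80), 18 * 3, 80)
  phi <- basal_output(pop, Fb)
  # theta = lambda = 0: A equals the autoscaled contextual drive I
  A <- apical_output(pop, vr, phi, F_aff_central = Fb)
  I <- mesocol:::autoscale_rows(pop$v %*% vr, warn = FALSE)
  expect_equal(A, I, tolerance = 1e-12)
  # no-context mode with zero scales: A = phi
  pn <- l3_params(n_cells = 6, theta_L3 = 0, lam_L3 = 0, mode = "no_context",
                  context_variates_per_meso = 3)
  popn <- pop; popn$params <- pn
  expect_equal(apical_output(popn, NULL, phi, F_aff_central = Fb), phi,
               tolerance = 1e-12)
  # a cell perfectly correlated with F_FF loses theta_L3 * F_FF
  pth <- l3_params(n_cells = 6, theta_L3 = 0.2, lam_L3 = 0,
                   context_variates_per_meso = 3)
  popt <- pop; popt$params <- pth
  # craft phi whose first row is exactly the autoscaled macrocolumn sum
  div <- mesocol:::diversification_state(phi, Fb)
  phi2 <- phi; phi2[1, ] <- div$F_FF
  div2 <- mesocol:::diversification_state(phi2, Fb)
  A2 <- apical_output(popt, vr, phi2, div = div2)
  I2 <- mesocol:::autoscale_rows(popt$v %*% vr, warn = FALSE)
  expect_equal(A2[1, ], I2[1, ] - 0.2 * div$F_FF, tolerance = 1e-10)
})

test_that("the update step follows the signed square-root Hebbian rule", {
  # no-context mode with zero diversification makes A = phi, so the expected
  # update is recomputable independently from the batch correlations
  p <- l3_params(n_cells = 4, theta_L3 = 0, lam_L3 = 0, mode = "no_context",
                 eta_L3 = 0.01, context_variates_per_meso = 3)
  pop <- l3_init(p, basal_dim = 25, seed = 6)
  set.seed(7)
  Fb <- matrix(runif(25 * 120), 25, 120)
  phi_exp <- pop$u %*% Fb
  phi_exp <- (phi_exp - rowMeans(phi_exp)) /
    apply(phi_exp, 1, function(x) sqrt(mean((x - mean(x))^2)))
  rho <- suppressWarnings(cor(t(phi_exp), t(Fb)))
  u_t <- (1 - 0.01) * pop$u + 0.01 * sign(rho) * sqrt(abs(rho))
  u_exp <- u_t / sqrt(rowSums(u_t^2))
  out <- l3_update_step(pop, Fb)
  expect_equal(out$pop$u, u_exp, tolerance = 1e-10)
  expect_equal(sqrt(rowSums(out$pop$u^2)), rep(1, 4), tolerance = 1e-12)
  # contextual mode also renormalizes the apical rows to unit L1
  pc <- l3_params(n_cells = 4, context_variates_per_meso = 3)
  popc <- l3_init(pc, basal_dim = 25, seed = 8)
  vr <- matrix(rnorm(18 * 3 * 120), 54, 120)
  outc <- l3_update_step(popc, Fb, vr)
  expect_equal(rowSums(abs(outc$pop$v)), rep(1, 4), tolerance = 1e-12)
  # increment magnitude is eta * sqrt(|rho|), sign preserved
  rho_v <- suppressWarnings(cor(t(mesocol:::autoscale_rows(popc$u %*% Fb)),
                                t(vr)))
  v_t <- (1 - 0.01) * popc$v + 0.01 * sign(rho_v) * sqrt(abs(rho_v))
  expect_equal(outc$pop$v, v_t / rowSums(abs(v_t)), tolerance = 1e-10)
  expect_error(l3_update_step(popc, Fb[, 1:2], vr[, 1:2]), "batch")
})

test_that("training is seeded-deterministic and traces end at 1", {
  m <- fx_l4(); basis <- fx_basis()
  p <- l3_params(n_cells = 8, n_updates = 4, step_patterns = 80,
                 context_variates_per_meso = 10)
  pop1 <- train_l3(m, basis, fx_layout(), fx_images(), p, seed = 31,
                   n_test = 40, encoder = fx_encoder())
  pop2 <- train_l3(m, basis, fx_layout(), fx_images(), p, seed = 31,
                   n_test = 40, encoder = fx_encoder())
  expect_identical(pop1$u, pop2$u)
  expect_identical(pop1$v, pop2$v)
  tr <- attr(pop1, "trace")
  expect_equal(dim(tr), c(4, 8))
  expect_equal(tr[4, ], rep(1, 8), tolerance = 1e-12)
})

test_that("diversification pressure lowers pairwise basal correlations", {
  m <- fx_l4()
  imgs <- fx_images()
  run <- function(theta, lam) {
    p <- l3_params(n_cells = 10, theta_L3 = theta, lam_L3 = lam,
                   n_updates = 12, step_patterns = 150,
                   mode = "no_context", context_variates_per_meso = 5)
    pop <- train_l3(m, NULL, fx_layout(), imgs, p, seed = 17, n_test = 30,
                    encoder = fx_encoder())
    asm <- collect_afferents(m, fx_layout(), imgs, 200, seed = 91,
                             include = "central", encoder = fx_encoder())
    pc <- suppressWarnings(cor(t(basal_output(pop, asm$central))))
    mean(abs(pc[upper.tri(pc)]))
  }
  with_div <- run(0.01, 0.03)
  without_div <- run(0, 0)
  expect_lt(with_div, without_div)
})
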