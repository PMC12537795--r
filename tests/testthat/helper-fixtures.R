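# Shared fixtures (built once per run) and independent oracles.

with_seed <- mesocol:::with_seed  # also usable when helpers are sourced bare

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_images <- function() {
  fx("images", function() make_stimulus_battery(6, 160, 160, seed = 101))
}

fx_layout <- function() fx("layout", build_field)

fx_encoder <- function() {
  fx("encoder", function() build_encoder(fx_layout(), lgn_params()))
}

# Small trained L4 model shared by variate/L3 tests.
fx_l4 <- function() {
  fx("l4", function() {
    train_l4(fx_images(), l4_params(n_cells = 20), n_updates = 5,
             step_patterns = 200, seed = 42)
  })
}

fx_basis <- function() {
  fx("basis", function() {
    asm <- collect_afferents(fx_l4(), fx_layout(), fx_images(), 600,
                             seed = 7, encoder = fx_encoder())
    fit_variates(asm, n_variates = 15)
  })
}

# Planted-latent multi-view world: k latent scalars loaded onto fixed random
# orthonormal directions D, shared by every view; latent strengths decline
# geometrically. sample_planted() draws fresh samples from the same world.
make_planted_world <- function(d, k, strength = 1, noise = 0.5, seed = 1) {
  with_seed(seed, {
    D <- matrix(stats::rnorm(d * k), d, k)
    D <- qr.Q(qr(D))[, seq_len(k), drop = FALSE]
    list(D = D, sc = strength * 0.8^(seq_len(k) - 1), d = d, k = k,
         noise = noise)
  })
}

sample_planted <- function(world, n, n_views = 19, seed = 1) {
  with_seed(seed, {
    S <- matrix(stats::rnorm(n * world$k), n, world$k)
    views <- lapply(seq_len(n_views), function(v) {
      t(S %*% diag(world$sc, world$k) %*% t(world$D) +
          matrix(stats::rnorm(n * world$d), n, world$d) * world$noise)
    })
    list(views = views, S = S)
  })
}

make_planted_views <- function(n, d, k, n_views = 19, strength = 1,
                               noise = 0.5, seed = 1) {
  world <- make_planted_world(d, k, strength, noise, seed)
  out <- sample_planted(world, n, n_views, seed = seed + 31L)
  list(views = out$views, D = world$D, S = out$S, world = world)
}

# Independent-views null generator.
make_null_views <- function(n, d, n_views = 19, seed = 1) {
  with_seed(seed, lapply(seq_len(n_views), function(v) {
    matrix(stats::rnorm(d * n), d, n)
  }))
}

# Brute-force Rayleigh-quotient maximizer for sum_m b' Kc b / b' Ka b:
# 1e5 random unit directions, then derivative-free polish of the best few
# (never calls the generalized eigensolver).
oracle_rayleigh_max <- function(Kc, Ka, n_dirs = 1e5, n_polish = 5,
                                seed = 1) {
  d <- nrow(Ka)
  rq <- function(b) {
    drop(crossprod(b, Kc %*% b) / crossprod(b, Ka %*% b))
  }
  with_seed(seed, {
    B <- matrix(stats::rnorm(d * n_dirs), d, n_dirs)
    vals <- colSums(B * (Kc %*% B)) / colSums(B * (Ka %*% B))
    best <- order(vals, decreasing = TRUE)[seq_len(n_polish)]
    max(vapply(best, function(i) {
      o <- stats::optim(B[, i], function(b) -rq(b),
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
      -o$value
    }, numeric(1)))
  })
}

# Principal angles (degrees) between the column spans of A and B.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# Radially-averaged-spectrum slope oracle (log-log periodogram fit).
fit_spectral_slope <- function(image) {
  rs <- radial_spectrum(image, n_bins = 15)
  rs <- rs[is.finite(rs$amplitude) & rs$amplitude > 0, ]
  unname(stats::coef(stats::lm(log(amplitude) ~ log(freq), rs))[2])
}
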