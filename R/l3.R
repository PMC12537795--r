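# Layer 3: two-compartment pyramidal cells. Basal dendrites read the
# 7-mesocolumn L4 afferent vector; apical dendrites read context-variate
# responses from the 18 surrounding mesocolumns. Hebbian co-tuning of the
# two compartments, with feed-forward and lateral diversification pressure,
# drives cells into the contextually predictable subspace.

#' L3 training parameters
#'
#' @param n_cells number of L3 cells (default: same as N_L4mc at paper scale).
#' @param theta_L3 feed-forward diversification scale (default 0.01).
#' @param lam_L3 lateral diversification scale (default 0.03).
#' @param eta_L3 learning rate (default 0.01).
#' @param n_updates update steps (paper scale 1000).
#' @param step_patterns patterns per step (paper scale 5000).
#' @param context_variates_per_meso variates fed per context mesocolumn
#'   (default 20).
#' @param mode "contextual" (apical input from surrounding columns' variate
#'   responses) or "no_context" (apical input is the cell's own basal
#'   output, the self-organizing control).
#' @return object of class `l3_params`.
#' @export
l3_params <- function(n_cells = 150, theta_L3 = 0.01, lam_L3 = 0.03,
                      eta_L3 = 0.01, n_updates = 1000, step_patterns = 5000,
                      context_variates_per_meso = 20,
                      mode = c("contextual", "no_context")) {
  if (theta_L3 < 0 || lam_L3 < 0) stop("diversification scales must be >= 0")
  if (eta_L3 <= 0 || eta_L3 > 1) stop("eta_L3 must be in (0, 1]")
  structure(list(n_cells = n_cells, theta_L3 = theta_L3, lam_L3 = lam_L3,
                 eta_L3 = eta_L3, n_updates = n_updates,
                 step_patterns = step_patterns,
                 context_variates_per_meso = context_variates_per_meso,
                 mode = match.arg(mode)),
            class = "l3_params")
}

#' Initialize an L3 population
#'
#' Basal rows start as i.i.d. standard normal, L2-normalized; apical rows as
#' i.i.d. uniform(0, 1), L1-normalized.
#'
#' @param params an [l3_params()].
#' @param basal_dim afferent dimensionality (7 * N_L4mc).
#' @param n_context number of context mesocolumns (default 18).
#' @param seed integer seed.
#' @return object of class `l3_population` with basal weights `u`
#'   (n_cells x basal_dim, unit L2 rows) and apical weights `v`
#'   (n_cells x n_context * variates, unit L1 rows).
#' @export
l3_init <- function(params, basal_dim, n_context = 18, seed = 1L) {
  apical_dim <- n_context * params$context_variates_per_meso
  with_seed(seed, {
    u <- matrix(stats::rnorm(params$n_cells * basal_dim),
                params$n_cells, basal_dim)
    v <- matrix(stats::runif(params$n_cells * apical_dim),
                params$n_cells, apical_dim)
  })
  structure(list(u = u / sqrt(rowSums(u^2)),
                 v = v / rowSums(abs(v)),
                 params = params, n_context = n_context),
            class = "l3_population")
}

#' Basal (feature) output of L3 cells
#'
#' Linear readout `phi = u F_aff`, then batch autoscaling of each cell to
#' zero mean and unit variance over the batch.
#'
#' @param pop an [l3_population][l3_init()].
#' @param F_aff basal afferent matrix, (7 N_L4mc) x n_patterns.
#' @param autoscale apply the batch autoscaling (default TRUE).
#' @return n_cells x n_patterns matrix of basal outputs.
#' @export
basal_output <- function(pop, F_aff, autoscale = TRUE) {
  if (nrow(F_aff) != ncol(pop$u)) stop("basal dimension mismatch")
  phi <- pop$u %*% F_aff
  if (autoscale) autoscale_rows(phi) else phi
}

# Batch statistics used by the apical pathway; computed over the current
# step's batch. F_FF is the summed L4 output of the central macrocolumn,
# autoscaled over the batch.
diversification_state <- function(phi, F_aff_central) {
  ff_raw <- colSums(F_aff_central)
  sd_ff <- stats::sd(ff_raw)
  F_FF <- if (sd_ff > 0) (ff_raw - mean(ff_raw)) / sd_ff else ff_raw * 0
  rho_FF <- drop(cor0(t(phi), matrix(F_FF, ncol = 1)))
  rho_BB <- cor0(t(phi))
  diag(rho_BB) <- 0
  list(F_FF = F_FF, rho_FF = rho_FF, rho_BB = rho_BB)
}

#' Apical (contextual) output of L3 cells
#'
#' In contextual mode the net apical drive is `I = v Phi_context` (with
#' variate responses autoscaled upstream), itself autoscaled over the batch;
#' in no-context mode `I = phi`. The diversified output is
#' `A_i = I_i - theta_L3 rho_FF_i F_FF - lam_L3 sum_{k != i} rho_BB_ik phi_k`.
#'
#' @param pop an `l3_population`.
#' @param variate_responses (n_context * variates) x n_patterns matrix of
#'   autoscaled context variate responses (ignored in no-context mode).
#' @param phi autoscaled basal outputs from [basal_output()].
#' @param div batch statistics from the internal diversification state; if
#'   NULL they are computed from `phi` and `F_aff_central`.
#' @param F_aff_central central-macrocolumn afferent matrix (needed when
#'   `div` is NULL).
#' @return n_cells x n_patterns matrix of apical outputs A.
#' @export
apical_output <- function(pop, variate_responses = NULL, phi, div = NULL,
                          F_aff_central = NULL) {
  p <- pop$params
  if (is.null(div)) {
    if (is.null(F_aff_central)) {
      stop("must supply diversification state or F_aff_central")
    }
    div <- diversification_state(phi, F_aff_central)
  }
  I <- if (p$mode == "no_context") {
    phi
  } else {
    if (is.null(variate_responses)) stop("contextual mode needs variate responses")
    autoscale_rows(pop$v %*% variate_responses, warn = FALSE)
  }
  I - p$theta_L3 * outer(div$rho_FF, div$F_FF) -
    p$lam_L3 * (div$rho_BB %*% phi)
}

#' One Hebbian update of the L3 population
#'
#' Over the batch: basal weights move toward
#' `sgn(rho) |rho|^0.5` with `rho = corr(F_L4j, A_i)`, mixed into the
#' previous normalized weights at rate eta, then L2-normalized per cell;
#' apical weights likewise with `rho = corr(Phi_j, phi_i)`, then
#' L1-normalized per cell.
#'
#' @param pop an `l3_population`.
#' @param F_aff_central (7 N_L4mc) x n_patterns basal afferent batch.
#' @param variate_responses context variate batch (autoscaled), or NULL in
#'   no-context mode.
#' @return list with the updated `pop`, plus the batch's `phi`, `A`.
#' @export
l3_update_step <- function(pop, F_aff_central, variate_responses = NULL) {
  p <- pop$params
  if (ncol(F_aff_central) < 3) stop("batch too small for correlations")
  phi <- basal_output(pop, F_aff_central)
  div <- diversification_state(phi, F_aff_central)
  A <- apical_output(pop, variate_responses, phi, div = div)
  eta <- p$eta_L3
  rho_u <- cor0(t(A), t(F_aff_central))  # cells x basal_dim
  u_t <- (1 - eta) * pop$u + eta * sign(rho_u) * sqrt(abs(rho_u))
  pop$u <- u_t / sqrt(rowSums(u_t^2))
  if (p$mode == "contextual") {
    rho_v <- cor0(t(phi), t(variate_responses))  # cells x apical_dim
    v_t <- (1 - eta) * pop$v + eta * sign(rho_v) * sqrt(abs(rho_v))
    pop$v <- v_t / rowSums(abs(v_t))
  }
  list(pop = pop, phi = phi, A = A)
}

#' Train the L3 population on images
#'
#' Full training loop: each update step samples `step_patterns` anchors,
#' computes L4 responses across the field, projects context variates,
#' autoscales, and applies [l3_update_step()]. A fixed test set of anchors is
#' used to record the convergence trace: after each step, each cell's test
#' responses are correlated with its final responses.
#'
#' @param l4_model trained shared [l4_model][l4_init()].
#' @param basis [canonical_basis][fit_variates()] (NULL allowed in
#'   no-context mode).
#' @param layout a [build_field()] layout.
#' @param images list of `stim_image`s.
#' @param params an [l3_params()].
#' @param seed integer seed.
#' @param lgn an [lgn_params()].
#' @param n_test anchors in the convergence-trace test set (default 200).
#' @param encoder optional precomputed encoder for `layout`.
#' @return the trained `l3_population`, with attribute `trace`
#'   (n_updates x n_cells matrix of final-state correlations).
#' @export
train_l3 <- function(l4_model, basis, layout, images, params = l3_params(),
                     seed = 1L, lgn = lgn_params(), n_test = 200,
                     encoder = NULL) {
  contextual <- params$mode == "contextual"
  if (contextual && is.null(basis)) stop("contextual mode needs a basis")
  if (contextual && params$context_variates_per_meso > basis$n_variates) {
    stop("basis has fewer variates than context_variates_per_meso")
  }
  if (is.null(encoder)) encoder <- build_encoder(layout, lgn)
  n_cells <- l4_model$params$n_cells
  pop <- l3_init(params, 7L * n_cells, n_context = 18,
                 seed = derive_seed(seed, "l3-init"))
  include <- if (contextual) c("central", "context") else "central"
  test_asm <- collect_afferents(l4_model, layout, images, n_test,
                                derive_seed(seed, "l3-test"), lgn,
                                include = "central", encoder = encoder)
  test_hist <- vector("list", params$n_updates)
  for (s in seq_len(params$n_updates)) {
    asm <- collect_afferents(l4_model, layout, images, params$step_patterns,
                             derive_seed(seed, 10000L + s), lgn,
                             include = include, encoder = encoder)
    vr <- NULL
    if (contextual) {
      kv <- params$context_variates_per_meso
      vr <- do.call(rbind, lapply(asm$context, function(Fm) {
        autoscale_rows(project(basis, Fm)[seq_len(kv), , drop = FALSE],
                       warn = FALSE)
      }))
    }
    pop <- l3_update_step(pop, asm$central, vr)$pop
    test_hist[[s]] <- pop$u %*% test_asm$central
  }
  final <- test_hist[[params$n_updates]]
  trace <- t(vapply(test_hist, function(h) {
    vapply(seq_len(params$n_cells), function(i) {
      cor0_vec(h[i, ], final[i, ])
    }, numeric(1))
  }, numeric(params$n_cells)))
  attr(pop, "trace") <- trace
  pop
}

#' Held-out apical-basal and basal-variate statistics
#'
#' Evaluates a trained population on fresh patterns: per-cell correlation of
#' apical and basal outputs, pairwise basal correlations, and the mean
#' squared basal-variate correlation (the contextual-guidance yardstick).
#'
#' @param pop trained `l3_population`.
#' @param l4_model shared `l4_model`.
#' @param basis `canonical_basis` (used for variate correlations and, in
#'   contextual mode, apical input).
#' @param layout,images,lgn as in [train_l3()].
#' @param n_patterns held-out patterns (default 1000).
#' @param seed integer seed.
#' @param encoder optional precomputed encoder.
#' @return list with `apical_basal_r` (per cell), `pairwise_basal`
#'   (cell x cell, signed r^2), `basal_variate_r2` (cells x variates,
#'   squared), `mean_sq_basal_variate`.
#' @export
evaluate_l3 <- function(pop, l4_model, basis, layout, images,
                        n_patterns = 1000, seed = 99L, lgn = lgn_params(),
                        encoder = NULL) {
  contextual <- pop$params$mode == "contextual"
  include <- if (contextual) c("central", "context") else "central"
  asm <- collect_afferents(l4_model, layout, images, n_patterns, seed, lgn,
                           include = include, encoder = encoder)
  phi <- basal_output(pop, asm$central)
  vr <- NULL
  if (contextual) {
    kv <- pop$params$context_variates_per_meso
    vr <- do.call(rbind, lapply(asm$context, function(Fm) {
      autoscale_rows(project(basis, Fm)[seq_len(kv), , drop = FALSE],
                     warn = FALSE)
    }))
  }
  div <- diversification_state(phi, asm$central)
  A <- apical_output(pop, vr, phi, div = div)
  apical_basal_r <- vapply(seq_len(nrow(phi)), function(i) {
    cor0_vec(phi[i, ], A[i, ])
  }, numeric(1))
  pb <- cor0(t(phi))
  phi_var <- project(basis, asm$central)
  rv <- cor0(t(phi), t(phi_var))  # cells x variates
  list(apical_basal_r = apical_basal_r,
       pairwise_basal = sign(pb) * pb^2,
       basal_variate_r2 = rv^2,
       mean_sq_basal_variate = mean(rv^2))
}
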