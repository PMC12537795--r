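# Layer 4: leaky-integrator dynamics with untuned feed-forward inhibition and
# learned lateral connections; Hebbian afferent / anti-Hebbian lateral
# plasticity. One trained mesocolumn model is replicated across the field
# (shared-weights convention).

#' L4 dynamics parameters
#'
#' The membrane equation per cell i is
#' `tau dF_i/dt = -F_i + [sum_j w_ij a_j - theta nu(a) + lambda sum_k z_ik F_k]+ / (1 - theta)`
#' integrated by Euler steps of size `dt` for `n_steps` steps from F = 0.
#' `nu(a)` is the untuned feed-forward inhibition statistic; the default is
#' the Euclidean norm of the afferent vector (the reading under which
#' inhibition scales linearly with input magnitude, as the conic-RBF
#' interpretation requires), with the literal sum and sum-of-squares
#' readings available.
#'
#' @param n_cells number of L4 cells per mesocolumn (paper scale 150).
#' @param theta feed-forward inhibition scale, in (0, 1) (default 0.65).
#' @param lam lateral connection scale (default 3).
#' @param tau membrane time constant, ms (default 4).
#' @param dt Euler step, ms (default 1; must be <= tau).
#' @param n_steps Euler steps per response (default 20).
#' @param inhibition_norm one of "l2", "sum", "sum_sq".
#' @return object of class `l4_params`.
#' @export
l4_params <- function(n_cells = 150, theta = 0.65, lam = 3, tau = 4,
                      dt = 1, n_steps = 20, inhibition_norm = "l2") {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (dt > tau) stop("dt must be <= tau")
  inhibition_norm <- match.arg(inhibition_norm, c("l2", "sum", "sum_sq"))
  structure(list(n_cells = n_cells, theta = theta, lam = lam, tau = tau,
                 dt = dt, n_steps = n_steps,
                 inhibition_norm = inhibition_norm),
            class = "l4_params")
}

inhibition_stat <- function(a, norm) {
  switch(norm,
    l2 = if (is.matrix(a)) sqrt(colSums(a^2)) else sqrt(sum(a^2)),
    sum = if (is.matrix(a)) colSums(a) else sum(a),
    sum_sq = if (is.matrix(a)) colSums(a^2) else sum(a^2))
}

#' Initialize an L4 model
#'
#' Afferent weights start as i.i.d. uniform(0, 1) rows rectified and
#' L1-normalized (each row sums to 1); lateral weights start at zero with a
#' zero diagonal.
#'
#' @param params an [l4_params()].
#' @param n_afferents afferent dimensionality (182 at LGN defaults).
#' @param seed integer seed.
#' @return object of class `l4_model` with elements `w` (n_cells x
#'   n_afferents), `z` (n_cells x n_cells), `w_tilde` (unnormalized afferent
#'   memory), and `params`.
#' @export
l4_init <- function(params = l4_params(), n_afferents = 182, seed = 1L) {
  w_tilde <- with_seed(seed,
    matrix(stats::runif(params$n_cells * n_afferents),
           params$n_cells, n_afferents))
  w <- normalize_w(w_tilde)
  z <- matrix(0, params$n_cells, params$n_cells)
  structure(list(w = w, z = z, w_tilde = w_tilde, params = params),
            class = "l4_model")
}

# Rectified L1 row normalization of the afferent memory.
normalize_w <- function(w_tilde) {
  wp <- pmax(w_tilde, 0)
  s <- rowSums(wp)
  s[s == 0] <- 1
  wp / s
}

#' L4 response to afferent input
#'
#' Runs the Euler integration for `n_steps` steps from F = 0 and returns the
#' final state (the model's operating definition of "the response"; no
#' fixed-point solving).
#'
#' @param model an [l4_model][l4_init()].
#' @param a afferent vector (length n_afferents) or matrix (n_afferents x
#'   n_patterns) for a batch.
#' @return activity vector (n_cells) or matrix (n_cells x n_patterns); all
#'   entries nonnegative.
#' @export
l4_respond <- function(model, a) {
  p <- model$params
  single <- !is.matrix(a)
  A <- if (single) matrix(a, ncol = 1) else a
  if (nrow(A) != ncol(model$w)) stop("afferent length mismatch")
  # Response-time drive uses L2-renormalized rows so that excitation is the
  # cosine similarity times |a| and theta acts as a cone half-angle; the L1
  # (sum-to-1) normalization of the learning rule leaves the drive an order
  # of magnitude below theta * nu(a), silencing the network (see vignette).
  wn <- model$w / pmax(sqrt(rowSums(model$w^2)), .Machine$double.eps)
  ff <- wn %*% A  # constant across Euler steps
  inh <- inhibition_stat(A, p$inhibition_norm)
  drive0 <- sweep(ff, 2, p$theta * inh, "-")
  f <- matrix(0, p$n_cells, ncol(A))
  k <- p$dt / p$tau
  gain <- 1 / (1 - p$theta)
  lam <- p$lam
  for (s in seq_len(p$n_steps)) {
    g <- if (lam == 0 && s > 1) g else drive0 + lam * (model$z %*% f)
    if (lam > 0 || s == 1) g[g < 0] <- 0
    f <- (1 - k) * f + (k * gain) * g
  }
  if (single) drop(f) else f
}

#' One Hebbian/anti-Hebbian L4 update
#'
#' Pairwise Pearson correlations between afferent channels and L4 responses
#' over the batch drive the afferent memory update
#' `w~ <- (1 - eta_aff) w~ + eta_aff rho`, followed by rectified L1 row
#' normalization; lateral weights follow the anti-Hebbian rule
#' `z <- (1 - eta_lat) z - eta_lat rho` with the diagonal forced to zero.
#' Zero-variance channels contribute rho = 0.
#'
#' @param model an `l4_model`.
#' @param afferent_batch n_afferents x n_patterns matrix.
#' @param response_batch n_cells x n_patterns matrix.
#' @param eta_aff afferent rate (default 0.01).
#' @param eta_lat lateral rate (default 0.1).
#' @return the updated `l4_model`.
#' @export
hebbian_update_l4 <- function(model, afferent_batch, response_batch,
                              eta_aff = 0.01, eta_lat = 0.1) {
  if (ncol(afferent_batch) < 3) stop("batch too small for correlations")
  if (ncol(afferent_batch) != ncol(response_batch)) {
    stop("afferent/response batch size mismatch")
  }
  rho_aff <- cor0(t(response_batch), t(afferent_batch))  # cells x afferents
  rho_lat <- cor0(t(response_batch))                     # cells x cells
  model$w_tilde <- (1 - eta_aff) * model$w_tilde + eta_aff * rho_aff
  model$w <- normalize_w(model$w_tilde)
  z <- (1 - eta_lat) * model$z - eta_lat * rho_lat
  diag(z) <- 0
  model$z <- z
  model
}

#' Train the L4 mesocolumn network
#'
#' Runs `n_updates` update steps; each step samples `step_patterns` random
#' window placements in the image set, computes the 20-step responses, and
#' applies one Hebbian/anti-Hebbian update. Fully reproducible from the seed.
#'
#' @param images list of `stim_image`s.
#' @param params an [l4_params()].
#' @param lgn an [lgn_params()].
#' @param n_updates number of update steps (paper scale 20).
#' @param step_patterns patterns per step (paper scale 1000).
#' @param eta_aff,eta_lat learning rates (paper values 0.01, 0.1).
#' @param seed integer seed.
#' @param init_seed seed for weight initialization (defaults to `seed`).
#' @param trace if TRUE, record mean |delta w| per step in attribute
#'   `delta_w`.
#' @return the trained `l4_model`.
#' @export
train_l4 <- function(images, params = l4_params(), lgn = lgn_params(),
                     n_updates = 20, step_patterns = 1000,
                     eta_aff = 0.01, eta_lat = 0.1, seed = 1L,
                     init_seed = NULL, trace = FALSE) {
  if (length(images) == 0) stop("empty image set")
  enc <- build_encoder(NULL, lgn)  # single-window encoder
  model <- l4_init(params, 2L * enc$n_on, init_seed %||% derive_seed(seed, "l4-init"))
  dw <- numeric(n_updates)
  for (s in seq_len(n_updates)) {
    anchors <- sample_anchors(enc, images, step_patterns,
                              derive_seed(seed, 100L + s))
    aff <- encode_field(enc, images, anchors)
    A <- matrix(aff, dim(aff)[1], dim(aff)[3])  # single window
    f <- l4_respond(model, A)
    w_old <- model$w
    model <- hebbian_update_l4(model, A, f, eta_aff, eta_lat)
    dw[s] <- mean(abs(model$w - w_old))
  }
  if (trace) attr(model, "delta_w") <- dw
  model
}

#' Responses of every mesocolumn window in a field
#'
#' Applies the shared L4 model to every window's afferent block.
#'
#' @param model an `l4_model`.
#' @param aff array from [encode_field()], (2 n_on) x n_windows x n_patterns.
#' @return array n_cells x n_windows x n_patterns.
#' @export
l4_respond_field <- function(model, aff) {
  d <- dim(aff)
  A <- matrix(aff, d[1], d[2] * d[3])
  f <- l4_respond(model, A)
  array(f, dim = c(model$params$n_cells, d[2], d[3]))
}
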