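# Canonical variates: the contextually predictable subspace of a
# mesocolumn's L3 state space. A variate is a direction b maximizing the
# pooled cross-covariance with the surrounding mesocolumns relative to the
# central auto-covariance; the stack of variates solves the generalized
# symmetric eigenproblem K_cross b = lambda K_auto b.

#' Collect flattened L3 afferent vectors across the field
#'
#' For each sampled anchor, computes L4 responses of every mesocolumn window
#' in the layout (shared weights) and flattens them per macrocolumn: own
#' mesocolumn block first, then the 6 neighbors in fixed angular order, giving
#' a vector of length 7 * n_cells per mesocolumn.
#'
#' @param l4_model a trained [l4_model][l4_init()].
#' @param layout a [build_field()] layout.
#' @param images list of `stim_image`s.
#' @param n_patterns number of random anchors.
#' @param seed integer seed.
#' @param lgn an [lgn_params()].
#' @param include which groups to assemble: subset of
#'   c("central", "context", "eval").
#' @param chunk anchors per encoding chunk (memory control).
#' @param encoder optional precomputed [build_encoder()] for `layout`.
#' @return object of class `afferent_assembly`: list with `central`
#'   (7 n_cells x n_patterns matrix), `context` (list of 18 such matrices),
#'   optionally `eval` (list of 12), plus `anchors` and `n_patterns`.
#' @export
collect_afferents <- function(l4_model, layout, images, n_patterns,
                              seed = 1L, lgn = lgn_params(),
                              include = c("central", "context"),
                              chunk = 500L, encoder = NULL) {
  if (is.null(encoder)) encoder <- build_encoder(layout, lgn)
  anchors <- sample_anchors(encoder, images, n_patterns, seed)
  n_cells <- l4_model$params$n_cells
  groups <- list(central = 1L)
  if ("context" %in% include) groups$context <- 2:19
  if ("eval" %in% include) groups$eval <- 19L + 1:12
  needed <- sort(unique(unlist(lapply(unlist(groups), function(m) {
    macro_unit_ids(layout, m)
  }))))
  out <- lapply(groups, function(macros) {
    lapply(macros, function(m) matrix(0, 7L * n_cells, n_patterns))
  })
  starts <- seq(1L, n_patterns, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n_patterns)
    aff <- encode_field(encoder, images, anchors[idx, , drop = FALSE],
                        windows = needed)
    f <- l4_respond_field(l4_model, aff)
    for (g in names(groups)) {
      for (k in seq_along(groups[[g]])) {
        mids <- match(macro_unit_ids(layout, groups[[g]][k]), needed)
        block <- f[, mids, , drop = FALSE]  # n_cells x 7 x chunk
        out[[g]][[k]][, idx] <- matrix(block, 7L * n_cells, length(idx))
      }
    }
  }
  structure(list(central = out$central[[1]],
                 context = out$context %||% NULL,
                 eval = out$eval %||% NULL,
                 anchors = anchors, n_patterns = n_patterns),
            class = "afferent_assembly")
}

#' Fit canonical variates by the generalized eigenproblem
#'
#' Moments are estimated from the central mesocolumn only (the model assumes
#' identical statistics across mesocolumns): `mu = E[F0]`,
#' `K_auto = cov(F0)`, and the pooled cross-covariance
#' `K_cross = E[(F0 - mu) sum_m (Fm - mu)^T]`, symmetrized as
#' `(K + K^T) / 2` before solving `K_cross b = lambda (K_auto + ridge I) b`.
#' Basis vectors are K_auto-conjugate (`b_i^T K_auto b_j = delta_ij`); signs
#' are fixed by making each vector's largest-magnitude coefficient positive.
#'
#' @param assembly_central dim x n matrix of central F_aff vectors, or an
#'   `afferent_assembly` (in which case `assemblies_context` defaults to its
#'   context list).
#' @param assemblies_context list of >= 2 dim x n context matrices.
#' @param n_variates number of leading variates to keep (default 20).
#' @param ridge ridge added to K_auto; default 1e-6 * trace(K_auto) / dim.
#' @return object of class `canonical_basis`: `mu`, `b` (dim x n_variates),
#'   `eigenvalues`, `r` (per-variate contextual correlation on the fitting
#'   set, mean of pairwise correlations with each context mesocolumn),
#'   `ridge`, `n_context`.
#' @export
fit_variates <- function(assembly_central, assemblies_context = NULL,
                         n_variates = 20, ridge = NULL) {
  if (inherits(assembly_central, "afferent_assembly")) {
    assemblies_context <- assemblies_context %||% assembly_central$context
    assembly_central <- assembly_central$central
  }
  X0 <- as.matrix(assembly_central)
  if (anyNA(X0)) stop("NA values in afferent assembly")
  if (length(assemblies_context) < 2) stop("need >= 2 context assemblies")
  n <- ncol(X0); d <- nrow(X0)
  if (any(vapply(assemblies_context, ncol, 1L) != n)) {
    stop("pattern counts differ between central and context assemblies")
  }
  if (n <= d / 5) {
    warning("pattern count <= dimension/5; covariance estimates unstable")
  }
  mu <- rowMeans(X0)
  Xc <- X0 - mu
  K_auto <- tcrossprod(Xc) / (n - 1)
  Csum <- Reduce(`+`, lapply(assemblies_context, function(Xm) Xm - mu))
  K_cross <- tcrossprod(Xc, Csum) / (n - 1)
  K_cross <- (K_cross + t(K_cross)) / 2
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(K_auto)) / d
  sol <- gen_eigen(K_cross, K_auto, ridge)
  k <- min(n_variates, d)
  b <- sol$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude coefficient positive
  flip <- vapply(seq_len(k), function(i) {
    sign(b[which.max(abs(b[, i])), i])
  }, numeric(1))
  b <- sweep(b, 2, flip, "*")
  phi0 <- crossprod(b, Xc)  # k x n
  r <- rowMeans(vapply(assemblies_context, function(Xm) {
    phim <- crossprod(b, Xm - mu)
    vapply(seq_len(k), function(i) cor0_vec(phi0[i, ], phim[i, ]), numeric(1))
  }, numeric(k)))
  structure(list(mu = mu, b = b, eigenvalues = sol$values[seq_len(k)],
                 r = r, K_auto = K_auto, ridge = ridge,
                 n_variates = k, n_context = length(assemblies_context)),
            class = "canonical_basis")
}

# Generalized symmetric eigenproblem A v = lambda (B + ridge I) v via
# Cholesky whitening; vectors satisfy v^T (B + ridge I) v = I.
gen_eigen <- function(A, B, ridge = 0) {
  d <- nrow(B)
  Br <- B + diag(ridge, d)
  U <- tryCatch(chol(Br), error = function(e) {
    stop("K_auto is singular; supply a positive ridge")
  })
  # M = U^-T A U^-1, symmetric
  S <- backsolve(U, A, transpose = TRUE)      # U^T S = A
  M <- backsolve(U, t(S), transpose = TRUE)   # U^T M^T = S^T
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vectors <- backsolve(U, e$vectors)          # U v = y
  list(values = e$values, vectors = vectors)
}

#' @export
print.canonical_basis <- function(x, ...) {
  cat(sprintf("<canonical_basis: %d variates, dim %d, ridge %.3g>\n",
              x$n_variates, length(x$mu), x$ridge))
  cat("  leading r:", paste(sprintf("%.3f", utils::head(x$r, 5)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Project afferent vectors onto the canonical basis
#'
#' `Phi_i = b_i^T (F_aff - mu)`; the batch mean of Phi over the fitting set
#' is zero by construction.
#'
#' @param basis a [canonical_basis][fit_variates()].
#' @param F_aff dim-vector or dim x n matrix.
#' @return n_variates-vector or n_variates x n matrix of variate responses.
#' @export
project <- function(basis, F_aff) {
  single <- !is.matrix(F_aff)
  X <- if (single) matrix(F_aff, ncol = 1) else F_aff
  if (nrow(X) != length(basis$mu)) stop("dimension mismatch")
  out <- crossprod(basis$b, X - basis$mu)
  if (single) drop(out) else out
}

#' Ring-based contextual correlation of variate responses
#'
#' The evaluation statistic: for each variate, the Pearson correlation
#' between its response in the central mesocolumn and the across-ring mean of
#' its responses in the ring mesocolumns. Also returns the signed squared
#' correlations and their sum (the "total contextual correlation").
#'
#' @param phi_central k x n matrix of central variate responses.
#' @param phi_ring list of k x n matrices, one per ring mesocolumn.
#' @return list with `r`, `signed_r2`, `total`.
#' @export
ring_correlation <- function(phi_central, phi_ring) {
  ring_mean <- Reduce(`+`, phi_ring) / length(phi_ring)
  k <- nrow(phi_central)
  r <- vapply(seq_len(k), function(i) {
    cor0_vec(phi_central[i, ], ring_mean[i, ])
  }, numeric(1))
  signed_r2 <- sign(r) * r^2
  list(r = r, signed_r2 = signed_r2, total = sum(signed_r2))
}

#' Contextual correlation of a basis over the evaluation ring
#'
#' Samples `n_eval` fresh anchors, computes variate responses in the central
#' mesocolumn and the 12 evaluation-ring mesocolumns (non-overlapping RFs),
#' and applies [ring_correlation()].
#'
#' @param basis a [canonical_basis][fit_variates()].
#' @param layout a [build_field()] layout.
#' @param l4_model the shared `l4_model`.
#' @param images list of `stim_image`s.
#' @param n_eval number of evaluation anchors (>= 30).
#' @param seed integer seed.
#' @param lgn an [lgn_params()].
#' @param encoder optional precomputed encoder for `layout`.
#' @return list with `r`, `signed_r2`, `total`, `n_eval`.
#' @export
contextual_correlation <- function(basis, layout, l4_model, images,
                                   n_eval = 1000, seed = 1L,
                                   lgn = lgn_params(), encoder = NULL) {
  if (n_eval < 30) stop("n_eval must be >= 30")
  asm <- collect_afferents(l4_model, layout, images, n_eval, seed, lgn,
                           include = c("central", "eval"), encoder = encoder)
  phi0 <- project(basis, asm$central)
  phir <- lapply(asm$eval, function(Fm) project(basis, Fm))
  out <- ring_correlation(phi0, phir)
  out$n_eval <- n_eval
  out
}

#' Count statistically significant variates
#'
#' Two-sided Pearson tests per variate at Bonferroni-corrected level
#' `alpha / n_tests`; reports the length of the leading run of significant
#' variates and the total count.
#'
#' @param r_values per-variate contextual correlations.
#' @param n_eval number of evaluation patterns behind each correlation (> 3).
#' @param alpha family-wise level (default 0.05).
#' @param n_tests Bonferroni divisor (default `length(r_values)`).
#' @return list with `leading`, `total`, `significant` (logical), `p`.
#' @export
count_significant <- function(r_values, n_eval, alpha = 0.05,
                              n_tests = length(r_values)) {
  if (n_eval <= 3) stop("n_eval must be > 3")
  r <- pmin(pmax(r_values, -1), 1)
  tt <- r * sqrt((n_eval - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n_eval - 2)
  sig <- p < alpha / n_tests
  leading <- if (all(sig)) length(sig) else which(!sig)[1] - 1L
  list(leading = as.integer(leading), total = sum(sig),
       significant = sig, p = p)
}

#' Subspace overlap between two bases by canonical correlation analysis
#'
#' Projects both bases onto a common fitting set of afferent vectors, fits
#' two-set CCA loadings (with a small ridge for rank deficiency), and
#' evaluates the canonical correlations on a held-out set. Correlations near
#' 1 indicate matching subspaces regardless of basis rotation.
#'
#' @param basis_A,basis_B [canonical_basis][fit_variates()] objects on the
#'   same afferent space.
#' @param fit_patterns dim x n matrix for fitting CCA loadings.
#' @param eval_patterns dim x m matrix for held-out evaluation.
#' @param k number of leading variates per basis (default: all shared).
#' @param ridge regularization for the within-set covariances (default
#'   1e-8 * mean diagonal, recorded in the result).
#' @return list with `correlations` (decreasing), `ridge`.
#' @export
cca_overlap <- function(basis_A, basis_B, fit_patterns, eval_patterns,
                        k = NULL, ridge = NULL) {
  k <- k %||% min(basis_A$n_variates, basis_B$n_variates)
  X <- t(project(basis_A, fit_patterns))[, seq_len(k), drop = FALSE]
  Y <- t(project(basis_B, fit_patterns))[, seq_len(k), drop = FALSE]
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  if (is.null(ridge)) {
    ridge <- 1e-8 * mean(c(diag(Sxx), diag(Syy)))
  }
  Ux <- chol(Sxx + diag(ridge, k))
  Uy <- chol(Syy + diag(ridge, k))
  W <- backsolve(Ux, t(backsolve(Uy, t(Sxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(W)
  A <- backsolve(Ux, sv$u)  # loadings for X
  B <- backsolve(Uy, sv$v)
  Xe <- sweep(t(project(basis_A, eval_patterns))[, seq_len(k), drop = FALSE],
              2, mx)
  Ye <- sweep(t(project(basis_B, eval_patterns))[, seq_len(k), drop = FALSE],
              2, my)
  corrs <- vapply(seq_len(k), function(i) {
    cor0_vec(Xe %*% A[, i], Ye %*% B[, i])
  }, numeric(1))
  list(correlations = sort(abs(corrs), decreasing = TRUE), ridge = ridge)
}

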