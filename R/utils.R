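# Internal helpers shared across modules.

#' Correlation matrix with zero-variance guard
#'
#' Column-wise Pearson correlations between two matrices. Columns with zero
#' variance contribute 0 rather than NA, matching the learning rules' guard
#' that constant channels carry no Hebbian signal.
#'
#' @param x n x p matrix (rows = observations).
#' @param y n x q matrix; defaults to `x`.
#' @return p x q correlation matrix with zero-variance entries set to 0.
#' @keywords internal
cor0 <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (is.null(y)) y <- x else y <- as.matrix(y)
  if (anyNA(x) || anyNA(y)) stop("NA values in correlation input")
  r <- suppressWarnings(stats::cor(x, y))
  r[!is.finite(r)] <- 0
  r
}

# Pearson r between two vectors, 0 when either is constant.
cor0_vec <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Evaluate an expression under a temporary RNG seed, restoring state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic seed splitting used throughout the pipeline: each stage (or
#' step) gets `(master * 48271 + idx * 16807) mod (2^31 - 1)`, where `idx` is
#' the integer stage index or a character-derived index for named stages.
#' Editing a later stage's configuration therefore never perturbs the seeds
#' of earlier stages.
#'
#' @param master master seed (integer).
#' @param stage integer index or character stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else as.integer(stage)
  as.integer((as.numeric(master) * 48271 + idx * 16807) %% 2147483647)
}

# Row-wise autoscale of a cells x patterns matrix to mean 0, sd 1 per row.
# Zero-variance rows are floored at `floor_sd` with a warning.
autoscale_rows <- function(m, floor_sd = 1e-12, warn = TRUE) {
  mu <- rowMeans(m)
  centred <- m - mu
  sd <- sqrt(rowMeans(centred^2))
  bad <- sd < floor_sd
  if (any(bad) && warn) {
    warning(sum(bad), " zero-variance row(s) floored during autoscaling")
  }
  sd[bad] <- 1
  centred / sd
}

`%||%` <- function(a, b) if (is.null(a)) b else a
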