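# Staged experiment pipeline: simulate-stimuli -> train-l4 ->
# extract-variates -> train-l3 -> evaluate. Every stage serializes its
# artifacts with checksums and can be resumed; one master seed derives all
# per-stage seeds.
#
# Config format is JSON (an in-image TOML parser is not available); the CLI
# in inst/cli/mesocol mirrors the config keys as flags.

# Numeric CSV helpers guaranteeing exact decimal round-trip (%.17g).
write_num_csv <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_num_csv <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Assemble a pipeline run configuration
#'
#' @param scale "desk" (runs end-to-end in minutes on one CPU) or "paper"
#'   (the full published schedule: 150 L4 cells, 20 x 1000 L4 training,
#'   5000-pattern variate fit, 1000 x 5000 L3 training).
#' @param image_dir directory of images to load, or NULL to generate the
#'   synthetic battery.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir artifact directory.
#' @param ... overrides for any config entry (n_l4_cells, l4_updates,
#'   l4_step_patterns, variate_patterns, n_variates, l3_updates,
#'   l3_step_patterns, n_images, image_size, theta, lam, theta_L3, lam_L3,
#'   eval_patterns, l3_mode).
#' @return list of class `run_config`.
#' @export
run_config <- function(scale = c("desk", "paper"), image_dir = NULL,
                       seed = 1L, out_dir = "mesocol_run", ...) {
  scale <- match.arg(scale)
  base <- if (scale == "paper") {
    list(n_l4_cells = 150, l4_updates = 20, l4_step_patterns = 1000,
         variate_patterns = 5000, n_variates = 20,
         l3_updates = 1000, l3_step_patterns = 5000,
         n_images = 100, image_size = 320, eval_patterns = 1000)
  } else {
    list(n_l4_cells = 40, l4_updates = 20, l4_step_patterns = 500,
         variate_patterns = 1500, n_variates = 20,
         l3_updates = 100, l3_step_patterns = 500,
         n_images = 12, image_size = 160, eval_patterns = 500)
  }
  cfg <- utils::modifyList(
    c(base, list(scale = scale, image_dir = image_dir, seed = as.integer(seed),
                 out_dir = out_dir, theta = 0.65, lam = 3,
                 theta_L3 = 0.01, lam_L3 = 0.03, l3_mode = "contextual")),
    list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Structural dimensions implied by a configuration
#'
#' @param config a [run_config()].
#' @return list with `afferent` (LGN channels per mesocolumn), `f_aff`
#'   (flattened L3 afferent length), `context` (apical input length).
#' @export
config_dims <- function(config) {
  lat <- hex_lattice(5)
  list(afferent = 2L * nrow(lat),
       f_aff = 7L * config$n_l4_cells,
       context = 18L * config$n_variates)
}

stage_manifest <- function(dir, files, extra = list()) {
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  manifest <- c(list(checksums = sums), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

stage_complete <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  manifest <- jsonlite::read_json(mf)
  for (f in names(manifest$checksums)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(FALSE)
    if (unname(tools::md5sum(p)) != manifest$checksums[[f]]) {
      stop("artifact checksum mismatch in ", dir, ": ", f)
    }
  }
  TRUE
}

#' Save / load an L4 model
#'
#' Directory layout: w.csv, z.csv, w_tilde.csv (all %.17g, bit-exact
#' round-trip), params.json, manifest.json with md5 checksums.
#'
#' @param model an `l4_model`.
#' @param dir target directory.
#' @return invisibly `dir`; `load_l4` returns the model.
#' @export
save_l4 <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_csv(model$w, file.path(dir, "w.csv"))
  write_num_csv(model$z, file.path(dir, "z.csv"))
  write_num_csv(model$w_tilde, file.path(dir, "w_tilde.csv"))
  jsonlite::write_json(unclass(model$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_manifest(dir, c("w.csv", "z.csv", "w_tilde.csv", "params.json"),
                 list(kind = "l4_model", version = 1L))
  invisible(dir)
}

#' @rdname save_l4
#' @export
load_l4 <- function(dir) {
  if (!stage_complete(dir)) stop("incomplete or corrupt l4 artifact: ", dir)
  params <- do.call(l4_params, jsonlite::read_json(file.path(dir, "params.json")))
  structure(list(w = read_num_csv(file.path(dir, "w.csv")),
                 z = read_num_csv(file.path(dir, "z.csv")),
                 w_tilde = read_num_csv(file.path(dir, "w_tilde.csv")),
                 params = params),
            class = "l4_model")
}

#' Save / load a canonical basis
#'
#' @param basis a `canonical_basis`.
#' @param dir target directory.
#' @return invisibly `dir`; `load_canonical_basis` returns the basis
#'   (without the fitting covariance, which is not needed for projection).
#' @export
save_canonical_basis <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_csv(matrix(basis$mu, ncol = 1), file.path(dir, "mu.csv"))
  write_num_csv(basis$b, file.path(dir, "b.csv"))
  write_num_csv(matrix(basis$eigenvalues, ncol = 1),
                file.path(dir, "eigenvalues.csv"))
  write_num_csv(matrix(basis$r, ncol = 1), file.path(dir, "r.csv"))
  jsonlite::write_json(
    list(kind = "canonical_basis", version = 1L,
         n_variates = basis$n_variates, ridge = basis$ridge,
         n_context = basis$n_context, symmetrized_cross = TRUE),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  stage_manifest(dir, c("mu.csv", "b.csv", "eigenvalues.csv", "r.csv",
                        "meta.json"),
                 list(kind = "canonical_basis", version = 1L))
  invisible(dir)
}

#' @rdname save_canonical_basis
#' @export
load_canonical_basis <- function(dir) {
  if (!stage_complete(dir)) stop("incomplete or corrupt basis artifact: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(list(mu = drop(read_num_csv(file.path(dir, "mu.csv"))),
                 b = read_num_csv(file.path(dir, "b.csv")),
                 eigenvalues = drop(read_num_csv(file.path(dir, "eigenvalues.csv"))),
                 r = drop(read_num_csv(file.path(dir, "r.csv"))),
                 K_auto = NULL, ridge = meta$ridge,
                 n_variates = meta$n_variates, n_context = meta$n_context),
            class = "canonical_basis")
}

#' Save / load an L3 population
#'
#' @param pop an `l3_population`.
#' @param dir target directory.
#' @return invisibly `dir`; `load_l3` returns the population.
#' @export
save_l3 <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_csv(pop$u, file.path(dir, "u.csv"))
  write_num_csv(pop$v, file.path(dir, "v.csv"))
  jsonlite::write_json(unclass(pop$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_manifest(dir, c("u.csv", "v.csv", "params.json"),
                 list(kind = "l3_population", version = 1L))
  invisible(dir)
}

#' @rdname save_l3
#' @export
load_l3 <- function(dir) {
  if (!stage_complete(dir)) stop("incomplete or corrupt l3 artifact: ", dir)
  params <- do.call(l3_params, jsonlite::read_json(file.path(dir, "params.json")))
  structure(list(u = read_num_csv(file.path(dir, "u.csv")),
                 v = read_num_csv(file.path(dir, "v.csv")),
                 params = params, n_context = 18L),
            class = "l3_population")
}

load_config_images <- function(config) {
  if (!is.null(config$image_dir)) {
    paths <- list.files(config$image_dir,
                        pattern = "\\.(png|pgm|csv)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(paths) == 0) stop("no images found in ", config$image_dir)
    lapply(paths, read_image)
  } else {
    make_stimulus_battery(config$n_images, config$image_size,
                          config$image_size,
                          seed = derive_seed(config$seed, "stimuli"))
  }
}

#' Run the full pipeline
#'
#' Executes the stages in order, serializing each stage's artifacts under
#' `config$out_dir` with checksums; completed stages are skipped on re-run,
#' so an interrupted run resumes where it stopped and reproduces the same
#' final artifacts (everything derives from the master seed).
#'
#' @param config a [run_config()].
#' @param stages subset of c("stimuli", "l4", "variates", "l3", "evaluate")
#'   to run (dependencies must already exist).
#' @param quiet suppress progress messages.
#' @return invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config,
                         stages = c("stimuli", "l4", "variates", "l3",
                                    "evaluate"),
                         quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say <- function(...) if (!quiet) message("[mesocol] ", ...)
  lgn <- lgn_params()
  layout <- build_field()
  dims <- config_dims(config)

  # stimuli ----
  stim_dir <- file.path(out, "stimuli")
  images <- NULL
  if ("stimuli" %in% stages) {
    if (!stage_complete(stim_dir)) {
      say("stage stimuli")
      dir.create(stim_dir, showWarnings = FALSE)
      images <- load_config_images(config)
      files <- sprintf("img_%03d.pgm", seq_along(images))
      for (i in seq_along(images)) {
        write_image(images[[i]], file.path(stim_dir, files[i]))
      }
      stage_manifest(stim_dir, c(files, paste0(files, ".json")),
                     list(kind = "stimuli", n_images = length(images)))
      # later stages always read the serialized (8-bit quantized) stimuli so
      # that resumed and uninterrupted runs see identical inputs
      images <- NULL
    } else say("stage stimuli: cached")
  }
  get_images <- function() {
    if (is.null(images)) {
      paths <- sort(list.files(stim_dir, pattern = "\\.pgm$",
                               full.names = TRUE))
      images <<- lapply(paths, function(p) read_image(p, equalize = FALSE))
    }
    images
  }

  # l4 ----
  l4_dir <- file.path(out, "l4")
  if ("l4" %in% stages) {
    if (!stage_complete(l4_dir)) {
      say("stage l4 (", config$l4_updates, " x ", config$l4_step_patterns, ")")
      model <- train_l4(get_images(),
                        l4_params(n_cells = config$n_l4_cells,
                                  theta = config$theta, lam = config$lam),
                        lgn,
                        n_updates = config$l4_updates,
                        step_patterns = config$l4_step_patterns,
                        seed = derive_seed(config$seed, "l4"))
      save_l4(model, l4_dir)
    } else say("stage l4: cached")
  }

  # variates ----
  var_dir <- file.path(out, "variates")
  if ("variates" %in% stages) {
    if (!stage_complete(var_dir)) {
      say("stage variates (", config$variate_patterns, " patterns)")
      model <- load_l4(l4_dir)
      asm <- collect_afferents(model, layout, get_images(),
                               config$variate_patterns,
                               seed = derive_seed(config$seed, "variates"),
                               lgn = lgn)
      basis <- fit_variates(asm, n_variates = config$n_variates)
      save_canonical_basis(basis, var_dir)
    } else say("stage variates: cached")
  }

  # l3 ----
  l3_dir <- file.path(out, "l3")
  if ("l3" %in% stages) {
    if (!stage_complete(l3_dir)) {
      say("stage l3 (", config$l3_updates, " x ", config$l3_step_patterns,
          ", ", config$l3_mode, ")")
      model <- load_l4(l4_dir)
      basis <- load_canonical_basis(var_dir)
      pop <- train_l3(model, basis, layout, get_images(),
                      l3_params(n_cells = config$n_l4_cells,
                                theta_L3 = config$theta_L3,
                                lam_L3 = config$lam_L3,
                                n_updates = config$l3_updates,
                                step_patterns = config$l3_step_patterns,
                                context_variates_per_meso = config$n_variates,
                                mode = config$l3_mode),
                      seed = derive_seed(config$seed, "l3"), lgn = lgn)
      save_l3(pop, l3_dir)
      write_num_csv(attr(pop, "trace"), file.path(l3_dir, "trace.csv"))
    } else say("stage l3: cached")
  }

  # evaluate ----
  eval_dir <- file.path(out, "evaluate")
  if ("evaluate" %in% stages) {
    if (!stage_complete(eval_dir)) {
      say("stage evaluate")
      dir.create(eval_dir, showWarnings = FALSE)
      model <- load_l4(l4_dir)
      basis <- load_canonical_basis(var_dir)
      pop <- load_l3(l3_dir)
      cc <- contextual_correlation(basis, layout, model, get_images(),
                                   n_eval = config$eval_patterns,
                                   seed = derive_seed(config$seed, "eval"),
                                   lgn = lgn)
      sig <- count_significant(cc$r, config$eval_patterns)
      l3_stats <- evaluate_l3(pop, model, basis, layout, get_images(),
                              n_patterns = config$eval_patterns,
                              seed = derive_seed(config$seed, "eval-l3"),
                              lgn = lgn)
      utils::write.csv(
        data.frame(variate = seq_along(cc$r), r = cc$r,
                   signed_r2 = cc$signed_r2, significant = sig$significant),
        file.path(eval_dir, "contextual_correlation.csv"), row.names = FALSE)
      summary <- list(
        dims = dims,
        total_contextual_correlation = cc$total,
        significant_leading = sig$leading, significant_total = sig$total,
        frac_positive_apical_basal = mean(l3_stats$apical_basal_r > 0),
        mean_sq_basal_variate = l3_stats$mean_sq_basal_variate,
        parameters = list(
          theta = config$theta, lam = config$lam, tau = 4, dt = 1,
          n_steps = 20, eta_aff = 0.01, eta_lat = 0.1,
          theta_L3 = config$theta_L3, lam_L3 = config$lam_L3, eta_L3 = 0.01,
          sigma_center = 0.8833, sigma_surr = 2.6499, cutoff_radius = 8,
          baseline = 0.1, meso_shift = 3, inner_ring_shift = 9,
          outer_ring_shift = 18, eval_ring_shift = 21))
      jsonlite::write_json(summary, file.path(eval_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_manifest(eval_dir,
                     c("contextual_correlation.csv", "summary.json"),
                     list(kind = "evaluate"))
    } else say("stage evaluate: cached")
  }
  invisible(out)
}
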