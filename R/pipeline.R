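#' Assemble a pipeline run configuration
#'
#' One configuration object drives the whole generate -> label -> train ->
#' evaluate chain. Unknown keys are rejected. A single global seed fans
#' out to fixed per-stage offsets, so each stage is individually
#' reproducible.
#'
#' @param n_geometries dataset size.
#' @param n_train,n_test split sizes.
#' @param seed global seed.
#' @param out_dir output directory for artifacts.
#' @param generator named list of overrides for [generator_config()]
#'   (other than \code{n_geometries} and \code{seed}).
#' @param oracle named list of overrides for [oracle_spec()].
#' @param training named list of overrides for [train_config()]
#'   (other than \code{seed}).
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_geometries = 200L, n_train = 120L,
                            n_test = 60L, seed = 1L,
                            out_dir = tempfile("dimergpr_run_"),
                            generator = list(), oracle = list(),
                            training = list()) {
  chk <- function(lst, fn, excl) {
    bad <- setdiff(names(lst), setdiff(names(formals(fn)), excl))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    lst
  }
  structure(list(
    n_geometries = as.integer(n_geometries),
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    seed = as.integer(seed), out_dir = out_dir,
    generator = chk(generator, generator_config, c("n_geometries", "seed")),
    oracle = chk(oracle, oracle_spec, character(0)),
    training = chk(training, train_config, "seed")),
    class = "pipeline_config")
}

## content hash of an R object, via serialization to a temp file
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

.stage_cached <- function(dir, stage, key, outputs) {
  hf <- file.path(dir, paste0(stage, ".hash"))
  file.exists(hf) && identical(readLines(hf)[1], key) &&
    all(file.exists(file.path(dir, outputs)))
}

.stage_done <- function(dir, stage, key) {
  writeLines(key, file.path(dir, paste0(stage, ".hash")))
}

#' Run the full pipeline: generate, label, train, evaluate
#'
#' Executes the stages in order with content-hash caching: a stage is
#' re-run only when its configuration or an upstream stage's output hash
#' changed. Every run writes a resolved-configuration snapshot. The
#' summary reports per-atom MAEs, the total-energy S-curve summary and
#' the fraction of test geometries within chemical accuracy.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return an object of class \code{pipeline_result}: the
#'   [evaluate_potential()] report, the fitted potential, and artifact
#'   paths.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) cat(sprintf(...), "\n")

  ## resolved-config snapshot
  writeLines(deparse(unclass(config)),
             file.path(config$out_dir, "config_resolved.txt"))

  run_stage <- function(stage, key, outputs, run) {
    if (.stage_cached(config$out_dir, stage, key, outputs)) {
      say("stage %s: cached", stage)
      return(FALSE)
    }
    say("stage %s: running", stage)
    tryCatch(run(),
             error = function(e)
               stop(sprintf("stage '%s' failed: %s (outputs under %s)",
                            stage, conditionMessage(e),
                            config$out_dir), call. = FALSE))
    .stage_done(config$out_dir, stage, key)
    TRUE
  }

  ## stage: generate
  gcfg <- do.call(generator_config,
                  c(list(n_geometries = config$n_geometries,
                         seed = config$seed + 101L), config$generator))
  gen_key <- .hash_obj(list("generate", gcfg))
  env <- new.env()
  run_stage("generate", gen_key, "dataset.xyz", function() {
    env$dataset <- generate_dataset(gcfg)
    write_xyz(env$dataset$geometries, file.path(config$out_dir, "dataset.xyz"))
    writeLines(c(sprintf("seed: %d", gcfg$seed),
                 sprintf("n_geometries: %d", gcfg$n_geometries),
                 sprintf("separation_range: %g %g", gcfg$separation_range[1],
                         gcfg$separation_range[2]),
                 sprintf("separation_mode: %s", gcfg$separation_mode),
                 sprintf("bond_range: %g %g", gcfg$bond_range[1],
                         gcfg$bond_range[2]),
                 sprintf("angle_range: %g %g", gcfg$angle_range[1],
                         gcfg$angle_range[2]),
                 sprintf("min_contact: %g", gcfg$min_contact)),
               file.path(config$out_dir, "dataset_provenance.txt"))
  })
  if (is.null(env$dataset)) {
    geoms <- read_xyz(file.path(config$out_dir, "dataset.xyz"))
    env$dataset <- structure(list(geometries = geoms, config = gcfg),
                             class = "dimer_dataset")
  }

  ## stage: label
  ospec <- do.call(oracle_spec, config$oracle)
  lab_key <- .hash_obj(list("label", gen_key, ospec))
  run_stage("label", lab_key, "labels.csv", function() {
    env$labeled <- label_dataset(env$dataset, ospec, forces = FALSE)
    write_labeled(env$labeled, file.path(config$out_dir, "labels.csv"))
  })
  if (is.null(env$labeled))
    env$labeled <- read_labeled(file.path(config$out_dir, "labels.csv"), ospec)

  ## stage: train + evaluate (model kept in memory; report on disk)
  tcfg <- do.call(train_config,
                  c(list(seed = config$seed + 303L), config$training))
  fit_key <- .hash_obj(list("fit", lab_key, tcfg,
                            config$n_train, config$n_test, config$seed))
  report_path <- file.path(config$out_dir, "evaluation.txt")
  model_path <- file.path(config$out_dir, "model.rds")
  run_stage("fit", fit_key, c("evaluation.txt", "model.rds"), function() {
    sp <- split_dataset(env$labeled, config$n_train, config$n_test,
                        seed = config$seed + 202L)
    env$potential <- fit_dimer_gpr(sp$train, tcfg)
    env$report <- evaluate_potential(env$potential, sp$test)
    saveRDS(list(potential = env$potential, report = env$report), model_path)
    writeLines(utils::capture.output(print(env$report)), report_path)
  })
  if (is.null(env$potential)) {
    cached <- readRDS(model_path)
    env$potential <- cached$potential
    env$report <- cached$report
  }

  structure(list(report = env$report, potential = env$potential,
                 paths = list(dataset = file.path(config$out_dir, "dataset.xyz"),
                              labels = file.path(config$out_dir, "labels.csv"),
                              evaluation = report_path),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$config$out_dir, "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
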