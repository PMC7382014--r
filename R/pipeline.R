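# End-to-end pipeline: synth -> normalize -> features -> screen -> select ->
# classify -> seqtrain, driven by one config (R list or YAML file).  Every
# stage is also callable on its own; the pipeline only sequences them,
# writes artifacts and records a machine-readable run summary (seed, input
# hashes, per-stage outputs) so a rerun with the same config reproduces the
# deterministic outputs bit for bit.

PIPELINE_STAGES <- c("synth", "features", "screen", "select", "classify",
                     "seqtrain")

#' Default pipeline configuration
#'
#' @param out_dir Run directory.
#' @param seed Master seed; propagated to every stochastic stage.
#' @param stages Stages to run, in order (subset of
#'   synth/features/screen/select/classify/seqtrain).
#' @return Config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(out_dir = tempfile("facetremor_run_"),
                               seed = 1L, stages = PIPELINE_STAGES) {
  list(out_dir = out_dir, seed = seed, stages = stages,
       synth = list(), input_dir = NULL,
       screen = list(alphas = c(0.05, 0.005)),
       select = list(alpha_grid = NULL, folds = 5),
       classify = list(algorithms = ALGORITHMS, folds = 5),
       seqtrain = list(arch = "lstm", folds = 3, hidden = 64, epochs = 60))
}

#' Run the analysis pipeline
#'
#' @param config Config list (see [default_run_config()]) or path to a YAML
#'   file with the same structure.  Either the `synth` stage generates the
#'   cohort or `input_dir` must point at a directory with a `manifest.csv`
#'   readable by [load_dataset()].
#' @return Invisibly, the run summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(PIPELINE_STAGES, collapse = ", "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  summary <- list(seed = seed, stages = config$stages,
                  package_version = as.character(
                    utils::packageVersion("facetremor")),
                  artifacts = list())
  add_artifact <- function(name, path) {
    summary$artifacts[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fn) {
    message("[facetremor] stage ", name)
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  seqs <- NULL
  if ("synth" %in% config$stages) {
    run_stage("synth", function() {
      cfg <- do.call(synthetic_config,
                     utils::modifyList(list(seed = seed), config$synth))
      cohort <- generate_cohort(cfg)
      seqs <<- cohort$sequences
      lm_dir <- file.path(out, "landmarks")
      write_dataset(seqs, lm_dir)
      add_artifact("manifest", file.path(lm_dir, "manifest.csv"))
    })
  } else {
    if (is.null(config$input_dir)) stop("no synth stage and no input_dir")
    run_stage("load", function() {
      seqs <<- load_dataset(file.path(config$input_dir, "manifest.csv"))
    })
  }

  rels <- lapply(seqs, to_relative_sequence)
  table <- NULL
  if ("features" %in% config$stages) {
    run_stage("features", function() {
      table <<- feature_table(seqs, rels)
      fp <- file.path(out, "features.csv")
      data.table::fwrite(table, fp)
      add_artifact("features", fp)
    })
  }
  if ("screen" %in% config$stages) {
    run_stage("screen", function() {
      rep <- count_significant(table, alphas = config$screen$alphas)
      fp <- file.path(out, "screen_counts.csv")
      data.table::fwrite(rep$counts, fp)
      data.table::fwrite(rep$pvalues, file.path(out, "screen_pvalues.csv"))
      add_artifact("screen", fp)
    })
  }
  if ("select" %in% config$stages) {
    run_stage("select", function() {
      grid <- config$select$alpha_grid
      if (is.null(grid)) grid <- default_alpha_grid()
      sw <- lasso_sweep(table, grid, folds = config$select$folds, seed = seed)
      fp <- file.path(out, "lasso_sweep.csv")
      data.table::fwrite(sw$sweep, fp)
      add_artifact("select", fp)
    })
  }
  if ("classify" %in% config$stages) {
    run_stage("classify", function() {
      rep <- evaluate_classifiers(table,
                                  algorithms = config$classify$algorithms,
                                  folds = config$classify$folds, seed = seed)
      fp <- file.path(out, "classify.json")
      jsonlite::write_json(list(metrics = rep$metrics,
                                confusion = rep$confusion),
                           fp, auto_unbox = TRUE, digits = NA)
      add_artifact("classify", fp)
    })
  }
  if ("seqtrain" %in% config$stages) {
    run_stage("seqtrain", function() {
      diffs <- lapply(rels, difference)
      res <- train_sequence_classifier(
        diffs, arch = config$seqtrain$arch, folds = config$seqtrain$folds,
        hidden = config$seqtrain$hidden, epochs = config$seqtrain$epochs,
        seed = seed)
      fp <- file.path(out, "seqtrain.json")
      jsonlite::write_json(list(metrics = res$report$metrics,
                                confusion = res$report$confusion),
                           fp, auto_unbox = TRUE, digits = NA)
      add_artifact("seqtrain", fp)
    })
  }
  sp <- file.path(out, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
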