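# End-to-end orchestration: simulate/ingest -> label -> featurize -> split
# -> train -> evaluate -> explain -> motifs/regions, with one config and a
# master seed from which every stage seed is derived.

#' Pipeline configuration
#'
#' @param out_dir Artifact directory.
#' @param synth A [synth_config()] used when no input data are given.
#' @param input Optional list `list(com_paths = <character vector of
#'   canonical COM CSVs>, annotations = <annotation CSV path>)`; when
#'   supplied the generator is skipped.
#' @param labeling A [labeling_config()].
#' @param train_fraction Stratified split fraction.
#' @param spec A [network_spec()], or `NULL` to build one matching the
#'   data (default blocks, input length 3M).
#' @param train A [train_config()].
#' @param lrp An [lrp_config()].
#' @param n_traj,per_state Explanation sampling (see
#'   [select_explanation_frames()]).
#' @param fence_factor IQR fence multiplier for motif extraction.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synth = synth_config(), input = NULL,
                            labeling = synth$labeling, train_fraction = 0.7,
                            spec = NULL, train = train_config(),
                            lrp = lrp_config(), n_traj = 100L,
                            per_state = NULL, fence_factor = 1.5,
                            seed = 1L) {
  if (!is.null(input)) {
    if (is.null(input$annotations) || !file.exists(input$annotations)) {
      abort("pre-flight: input$annotations file not found")
    }
    missing_files <- input$com_paths[!file.exists(input$com_paths)]
    if (length(missing_files) > 0) {
      abort(paste0("pre-flight: missing COM table(s): ",
                   paste(utils::head(missing_files, 3), collapse = ", ")))
    }
  }
  structure(list(out_dir = out_dir, synth = synth, input = input,
                 labeling = labeling, train_fraction = train_fraction,
                 spec = spec, train = train, lrp = lrp,
                 n_traj = as.integer(n_traj), per_state = per_state,
                 fence_factor = fence_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage and persists the artifacts: model checkpoint
#' (`model.rds`), evaluation report and confusion matrix, per-class
#' relevance maps, motif tables and region summaries (each as CSV + plot),
#' and a provenance manifest (`manifest.json`: config echo, stage seeds,
#' package version). A stage failure aborts with the stage name; artifacts
#' already written are kept.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory results (`model`,
#'   `evaluation`, `maps`, `motifs`, `summaries`, `paths`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  data <- stage("data", {
    if (is.null(cfg$input)) {
      cfg$synth$seed <- derive_seed(cfg$seed, 10L)
      generate_ensemble(cfg$synth)
    } else {
      ann <- read_annotations(cfg$input$annotations)
      trajs <- lapply(cfg$input$com_paths, function(p) {
        label_trajectory(read_com_table(p, annotations = ann), cfg$labeling)
      })
      list(trajectories = trajs, annotations = ann, planted = NULL,
           config = NULL)
    }
  })

  ds <- stage("featurize+split", {
    ef <- ensemble_features(data$trajectories)
    keep <- undersample(ef$frame_info$label, seed = derive_seed(cfg$seed, 20L))
    split <- stratified_split(keep, ef$frame_info$label[keep],
                              train_fraction = cfg$train_fraction,
                              seed = derive_seed(cfg$seed, 30L))
    scaler <- fit_minmax(ef$features[split$train, , drop = FALSE])
    write_minmax(scaler, file.path(cfg$out_dir, "scaler.json"))
    write_split(split, cfg$out_dir)
    list(ef = ef, split = split, scaler = scaler,
         x = apply_minmax(scaler, ef$features))
  })

  model <- stage("train", {
    spec <- cfg$spec %||% network_spec(input_length = ncol(ds$x))
    m <- build_network(spec, seed = derive_seed(cfg$seed, 40L))
    cfg$train$seed <- derive_seed(cfg$seed, 50L)
    m <- train_cnn(m, ds$x[ds$split$train, , drop = FALSE],
                   ds$ef$frame_info$label[ds$split$train], cfg$train)
    saveRDS(m, file.path(cfg$out_dir, "model.rds"))
    m
  })

  evaluation <- stage("evaluate", {
    ev <- evaluate_model(model, ds$x[ds$split$validation, , drop = FALSE],
                         ds$ef$frame_info$label[ds$split$validation])
    write_eval_report(ev, file.path(cfg$out_dir, "confusion_matrix.csv"))
    ev
  })

  analysis <- stage("explain", {
    sel <- select_explanation_frames(model, ds$x, ds$ef$frame_info,
                                     n_traj = cfg$n_traj,
                                     per_state = cfg$per_state,
                                     seed = derive_seed(cfg$seed, 60L))
    maps <- relevance_maps(model, ds$x, sel, cfg = cfg$lrp)
    fm <- attr(maps, "frame_maps")
    classes <- unique(maps$class)
    motifs <- lapply(stats::setNames(classes, classes), function(cl) {
      iqr_motifs(filter(maps, .data$class == cl), data$annotations,
                 fence_factor = cfg$fence_factor)
    })
    summaries <- lapply(stats::setNames(classes, classes), function(cl) {
      region_summary(filter(fm, .data$class == cl), data$annotations)
    })
    list(maps = maps, motifs = motifs, summaries = summaries)
  })

  paths <- stage("render", {
    render_outputs(analysis$maps, analysis$motifs, analysis$summaries,
                   evaluation, data$annotations, cfg$out_dir)
  })

  stage("manifest", {
    manifest <- list(
      package_version = as.character(utils::packageVersion("conformotif")),
      master_seed = cfg$seed,
      stage_seeds = list(data = derive_seed(cfg$seed, 10L),
                         undersample = derive_seed(cfg$seed, 20L),
                         split = derive_seed(cfg$seed, 30L),
                         init = derive_seed(cfg$seed, 40L),
                         train = derive_seed(cfg$seed, 50L),
                         explain = derive_seed(cfg$seed, 60L)),
      accuracy = evaluation$accuracy,
      macro_f1 = evaluation$macro_f1,
      files = basename(unname(paths)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })

  invisible(list(model = model, evaluation = evaluation,
                 maps = analysis$maps, motifs = analysis$motifs,
                 summaries = analysis$summaries, paths = paths))
}
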