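#' Pipeline configuration
#'
#' Aggregates the parameters of the full pipeline: manifest, extractor
#' backend, patch/resize geometry, NCA weighting, INCA loop range, CV folds
#' and seeds.
#'
#' @param manifest Path to a manifest CSV (`id,path,label`) or `NULL` when
#'   records are passed to [run_pipeline()] directly.
#' @param extractor `"fallback"` (seeded random projection; no downloaded
#'   weights, fully reproducible) or `"alexnet"` (AlexNet-architecture
#'   backbone).
#' @param extractor_seed Seed for the extractor weights.
#' @param output_dim Fallback extractor width (default 8192; ignored by the
#'   AlexNet backend, which is fixed at 4096 + 4096).
#' @param patch_side Patch side in pixels (default 16).
#' @param resize_side Image grid side before tiling (default 224).
#' @param nca An [nca_config()]. The pipeline default caps the ascent at 30
#'   accepted iterations: at the fused width (~1.6M columns) the weight
#'   RANKING — all the selection stage consumes — stabilizes within tens of
#'   iterations, long before the objective itself converges.
#' @param k_min,k_max INCA loop range (defaults 1, 500).
#' @param folds CV folds for both the INCA loss and the final evaluation
#'   (default 10).
#' @param seed Seed for fold assignment.
#' @param selection_scope `"full"` ranks and selects on the complete dataset
#'   and then cross-validates the selected subset (the protocol of the
#'   original pipeline); `"nested"` repeats weighting and selection inside
#'   every training fold, so the test fold never influences selection.
#' @param run_benchmark Also run the nine-classifier benchmark on the
#'   selected features (default TRUE; `"full"` scope only).
#' @param output_dir Directory for run artifacts, or `NULL` to skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL,
                            extractor = c("fallback", "alexnet"),
                            extractor_seed = 1L, output_dim = 8192L,
                            patch_side = 16L, resize_side = 224L,
                            nca = nca_config(max_iters = 30L),
                            k_min = 1L, k_max = 500L,
                            folds = 10L, seed = 1L,
                            selection_scope = c("full", "nested"),
                            run_benchmark = TRUE, output_dir = NULL) {
  extractor <- match.arg(extractor)
  selection_scope <- match.arg(selection_scope)
  if (!inherits(nca, "nca_config")) stop_validation("nca must be an nca_config")
  if (!is_count(folds, 2L)) stop_validation("folds must be a count >= 2")
  if (as.integer(resize_side) %% as.integer(patch_side) != 0L)
    stop_validation("resize_side %s is not divisible by patch_side %s",
                    resize_side, patch_side)
  structure(list(manifest = manifest, extractor = extractor,
                 extractor_seed = as.integer(extractor_seed),
                 output_dim = as.integer(output_dim),
                 patch_side = as.integer(patch_side),
                 resize_side = as.integer(resize_side), nca = nca,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 folds = as.integer(folds), seed = as.integer(seed),
                 selection_scope = selection_scope,
                 run_benchmark = isTRUE(run_benchmark),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Load labeled records from a manifest CSV
#'
#' Reads a manifest with columns `id,path,label` (paths relative to the
#' manifest location, labels 0/1) and loads every referenced image.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return List of labeled `image_record`s in manifest order.
#' @export
load_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_io("manifest '%s' does not exist", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  if (!all(need %in% names(man)))
    stop_validation("manifest must have columns id,path,label (got: %s)",
                    paste(names(man), collapse = ","))
  if (!all(man$label %in% c(0L, 1L)))
    stop_validation("manifest labels must be 0 or 1")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    rec <- load_image(file.path(base, man$path[i]), id = man$id[i])
    rec$label <- as.integer(man$label[i])
    rec
  })
}

#' Run the full patch-feature pipeline
#'
#' Executes the eight pipeline steps in order: load, resize, tile, extract
#' raw-image and per-patch deep features, fuse, NCA weighting, INCA top-k
#' selection, and 1-NN evaluation under stratified tenfold cross-validation,
#' optionally followed by the nine-classifier benchmark. With the fallback
#' extractor the run is end-to-end deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of labeled `image_record`s; when `NULL`, the
#'   manifest in `config` is loaded.
#' @return List with `features` (`feature_matrix`), `nca` (`nca_weights`;
#'   `NULL` under nested scope), `selection` (`selection_result` or per-fold
#'   list), `report` (kNN `evaluation_report`), `benchmark` (list of reports
#'   or `NULL`) and `run_info` (config echo, versions, timings).
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      if (inherits(e, "pdfe_error")) {
        e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
        stop(e)
      }
      stop_validation("[stage %s] %s", name, conditionMessage(e))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  records <- records %||% stage("load", {
    if (is.null(config$manifest))
      stop_validation("no records given and no manifest configured")
    load_manifest(config$manifest)
  })
  labels <- vapply(records, function(r) as.integer(r$label %||% NA_integer_),
                   integer(1))
  if (anyNA(labels)) stop_validation("[stage validate] unlabeled record present")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L))
    stop_validation("[stage validate] both classes must be present (counts %s)",
                    paste(counts, collapse = "/"))
  if (any(counts < config$folds))
    stop_validation("[stage validate] each class needs >= %d samples for %d-fold CV",
                    config$folds, config$folds)

  ex <- stage("extractor", switch(config$extractor,
    fallback = fallback_extractor(seed = config$extractor_seed,
                                  output_dim = config$output_dim),
    alexnet = alexnet_extractor(seed = config$extractor_seed)))
  fm <- stage("features",
              build_feature_matrix(ex, records, patch_side = config$patch_side,
                                   resize_side = config$resize_side))

  if (config$selection_scope == "full") {
    w <- stage("nca", nca_weights(fm, config = config$nca))
    sel <- stage("inca",
                 inca_select(fm, weights = w, k_min = config$k_min,
                             k_max = config$k_max,
                             loss_folds = config$folds, seed = config$seed))
    Xsel <- fm$values[, sel$selected_indices, drop = FALSE]
    report <- stage("classify",
                    cross_validate("kNN", Xsel, fm$labels,
                                   folds = config$folds, seed = config$seed))
    bench <- if (config$run_benchmark)
      stage("benchmark", benchmark_classifiers(Xsel, fm$labels,
                                               folds = config$folds,
                                               seed = config$seed))
    else NULL
  } else {
    nested <- stage("nested_selection",
                    nested_selection_cv(fm, config))
    w <- NULL
    sel <- nested$per_fold
    report <- nested$report
    bench <- NULL
  }

  run_info <- list(config = unclass(config),
                   extractor = ex$name,
                   n_samples = length(records),
                   class_counts = as.integer(counts),
                   n_features = ncol(fm$values),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("pdfe")),
                   timings = as.list(timings),
                   total_elapsed = proc.time()[["elapsed"]] - t_all)

  if (!is.null(config$output_dir)) {
    od <- config$output_dir
    if (!dir.exists(od) && !dir.create(od, recursive = TRUE, showWarnings = FALSE))
      stop_io("cannot create output directory '%s'", od)
    write_feature_matrix(fm, file.path(od, "features.rds"))
    if (inherits(sel, "selection_result"))
      write_selection_result(sel, file.path(od, "selection.json"))
    write_reports(c(list(kNN = report), bench[setdiff(names(bench), "kNN")]),
                  json_path = file.path(od, "reports.json"),
                  csv_path = file.path(od, "reports.csv"))
    jsonlite::write_json(run_info, file.path(od, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  list(features = fm, nca = w, selection = sel, report = report,
       benchmark = bench, run_info = run_info)
}

# Nested-selection cross-validation: NCA weighting and the INCA loop are
# re-run inside every training fold, and the held-out fold is classified with
# that fold's own selected subset. This removes the selection leakage of the
# "full" protocol (where the selected subset has seen every sample), at
# `folds` times the selection cost.
nested_selection_cv <- function(fm, config) {
  y <- fm$labels
  fold_id <- stratified_folds(y, config$folds, config$seed)
  pred_all <- integer(length(y))
  per_fold <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    Xtr <- fm$values[tr, , drop = FALSE]
    inner_folds <- min(config$folds, min(table(y[tr])))
    w_f <- nca_weights(Xtr, y[tr], config = config$nca)
    sel_f <- inca_select(Xtr, y[tr], weights = w_f, k_min = config$k_min,
                         k_max = config$k_max, loss_folds = inner_folds,
                         seed = config$seed + f)
    cols <- sel_f$selected_indices
    sfit <- standardize_fit(fm$values[, cols, drop = FALSE], tr)
    Str <- standardize_apply(Xtr[, cols, drop = FALSE], sfit)
    Ste <- standardize_apply(fm$values[te, cols, drop = FALSE], sfit)
    pred_all[te] <- knn_predict(Str, y[tr], Ste, k = 1L)
    per_fold[[f]] <- list(fold = f, chosen_k = sel_f$chosen_k,
                          selected_indices = cols)
  }
  conf <- pool_confusion(pred_all, y, 0L)
  metrics <- compute_metrics(conf)
  report <- structure(
    list(classifier_name = "kNN", folds = config$folds, seed = config$seed,
         confusion = conf, accuracy = metrics$accuracy,
         recall = metrics$recall, precision = metrics$precision,
         f1 = metrics$f1,
         per_fold_accuracy = vapply(seq_len(config$folds), function(f)
           mean(pred_all[fold_id == f] == y[fold_id == f]), numeric(1)),
         per_fold_confusion = NULL,
         settings = list(k = 1, distance = "Euclidean", voting = "none",
                         selection_scope = "nested",
                         chosen_k_per_fold = vapply(per_fold, `[[`,
                                                    integer(1), "chosen_k"))),
    class = "evaluation_report")
  list(report = report, per_fold = per_fold)
}
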