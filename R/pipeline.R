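#' Default pipeline configuration
#'
#' A complete demo configuration for [run_pipeline()]: simulates the default
#' synthetic cohort with measurements, trains the treatment-recommendation
#' tree (none vs hearing device, then hearing aid vs cochlear implant), runs
#' the exhaustive binary weight search for the expert CAFPAs and each
#' requested prediction model, derives the configured weights and writes all
#' reports.
#'
#' @param seed Integer master seed.
#' @param output_dir Output directory for run artifacts.
#' @param weight_mode One of `"uniform"`, `"binary-search"`, `"rel-model"`,
#'   `"rel-all"`, `"explicit"`.
#' @param predict_families Character vector of prediction families to run
#'   (empty for expert CAFPAs only).
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = "cafpa_run",
                                    weight_mode = "rel-model",
                                    predict_families = "lasso") {
  list(
    seed = seed,
    output_dir = output_dir,
    cohort = list(simulate = list(n_per_category = 80L)),
    measurements = list(generate = length(predict_families) > 0L),
    predict = list(families = predict_families, nfolds = 5L),
    comparison_sets = list(
      list(id = "CS_root", categories = c("none", "hearing-device"),
           members = list("hearing-device" = c("hearing-aid",
                                               "cochlear-implant"))),
      list(id = "CS_leaf", categories = c("hearing-aid",
                                          "cochlear-implant"))),
    tree_sets = list(list(id = "tree_device", root = "CS_root",
                          leaf = "CS_leaf")),
    weights = list(mode = weight_mode, explicit = NULL),
    loo = NULL
  )
}

# Validate a pipeline configuration before any computation.
validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stop("config: 'seed' is required", call. = FALSE)
  modes <- c("uniform", "binary-search", "rel-model", "rel-all", "explicit")
  mode <- config$weights$mode
  if (is.null(mode) || length(mode) != 1L || !mode %in% modes)
    stop("config: weights$mode must be exactly one of ",
         paste(modes, collapse = ", "), call. = FALSE)
  if (mode == "explicit" && is.null(config$weights$explicit))
    stop("config: weight mode 'explicit' needs weights$explicit",
         call. = FALSE)
  cs_ids <- vapply(config$comparison_sets, `[[`, character(1), "id")
  if (anyDuplicated(cs_ids))
    stop("config: duplicated comparison-set ids", call. = FALSE)
  for (ts in config$tree_sets) {
    for (ref in c("root", "leaf"))
      if (!ts[[ref]] %in% cs_ids)
        stop("config: tree set '", ts$id, "' references unknown ",
             "comparison set '", ts[[ref]], "'", call. = FALSE)
    root <- config$comparison_sets[[match(ts$root, cs_ids)]]
    leaf <- config$comparison_sets[[match(ts$leaf, cs_ids)]]
    terminals <- c(root$categories[1], leaf$categories)
    if (anyDuplicated(terminals))
      stop("config: tree set '", ts$id, "' has duplicated terminal ",
           "categories", call. = FALSE)
  }
  fams <- config$predict$families
  if (length(fams) > 0L &&
      !all(fams %in% c("lasso", "elastic-net", "random-forest")))
    stop("config: unknown prediction family", call. = FALSE)
  invisible(config)
}

# Resolve the CAFPA weight vector for one comparison set and source.
resolve_weights <- function(mode, explicit, searches, source) {
  if (mode == "uniform") {
    list(w = uniform_weights() / length(CAFPA_NAMES), note = "uniform")
  } else if (mode == "explicit") {
    list(w = check_weights(unlist(explicit)), note = "explicit")
  } else if (mode == "binary-search") {
    s <- searches[[source]]
    best <- which.max(s$youden)
    list(w = setNames(s$weights[best, ], CAFPA_NAMES),
         note = sprintf("best combination (Y = %.3f)", s$youden[best]))
  } else {
    # rel-model: expert + this source; rel-all: expert + every model source
    sel <- lapply(searches, select_y90)
    pick <- if (mode == "rel-model") {
      if (source == "expert") sel else sel[c("expert", source)]
    } else sel
    w <- derive_rel_weights(pick)
    note <- if (attr(w, "fallback"))
      "fallback: no common Y90 combination, best own combination used"
    else sprintf("%d common Y90 combination(s)", attr(w, "n_common"))
    list(w = w, note = note)
  }
}

#' Run the full decision-support pipeline
#'
#' Executes, in order: cohort simulation or loading, optional measurement
#' generation, optional cross-validated CAFPA prediction, comparison-set
#' training, exhaustive binary weight search with Y90 selection, weight
#' derivation according to the configured mode, tree-set classification for
#' the expert CAFPAs and every prediction model, and report writing
#' (cohort, Youden tables, selected weights, per-patient terminals and
#' certainties, confusion matrices of model vs expert classifications,
#' accuracies, and a machine-readable JSON manifest).  Reruns with an
#' identical configuration produce byte-identical numeric outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a YAML/JSON file with the same structure.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, weight_mode = config$weights$mode,
                   files = character(0), notes = list())
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table_csv(df, path)
    manifest$files <<- c(manifest$files, name)
  }

  ## 1. cohort -------------------------------------------------------------
  cohort <- if (!is.null(config$cohort$file)) {
    read_cohort(config$cohort$file)
  } else {
    sim <- config$cohort$simulate
    spec <- default_cohort_spec(seed = config$seed,
                                n_per_category = sim$n_per_category %||% 80L)
    simulate_cohort(spec)
  }
  if (isTRUE(config$measurements$generate))
    cohort <- generate_measurements(cohort, default_forward_spec(),
                                    seed = config$seed)
  emit(cohort, "cohort.csv")

  ## 2. CAFPA prediction ----------------------------------------------------
  feature_cols <- setdiff(names(cohort),
                          c("patient_id", CAFPA_NAMES, "labels"))
  sources <- list(expert = cohort_cafpas(cohort))
  for (fam in config$predict$families %||% character(0)) {
    if (length(feature_cols) == 0L)
      stop("prediction requested but the cohort has no measurement columns",
           call. = FALSE)
    fit <- predict_cafpas_cv(cohort[, feature_cols, drop = FALSE], cohort,
                             family = fam,
                             nfolds = config$predict$nfolds %||% 5L,
                             seed = config$seed)
    sources[[fam]] <- fit$predictions
    emit(data.frame(patient_id = cohort$patient_id, fit$predictions),
         paste0("predicted_cafpas_", fam, ".csv"))
    emit(fit$diagnostics, paste0("prediction_diagnostics_", fam, ".csv"))
    emit(feature_importance(fit), paste0("feature_importance_", fam, ".csv"))
  }

  ## 3. training ------------------------------------------------------------
  cs_ids <- vapply(config$comparison_sets, `[[`, character(1), "id")
  cs_fits <- list()
  for (cs in config$comparison_sets) {
    fit <- cafpa_cs(cohort, cs$categories, members = cs$members)
    cs_fits[[cs$id]] <- fit
    s <- summary(fit)$table
    emit(s, paste0("training_", cs$id, ".csv"))
  }

  ## 4. weight search + weight derivation ------------------------------------
  W <- enumerate_binary_weights()
  chosen <- list()
  youden_rows <- list()
  for (cs_id in cs_ids) {
    fit <- cs_fits[[cs_id]]
    searches <- list()
    for (src in names(sources)) {
      searches[[src]] <- search_weights(
        fit, cohort, weights = W, loo = config$loo,
        cafpas = if (src == "expert") NULL else sources[[src]],
        source = src)
      df <- as.data.frame(searches[[src]])
      emit(df, paste0("youden_", cs_id, "_", src, ".csv"))
      youden_rows[[paste(cs_id, src)]] <- data.frame(
        comparison_set = cs_id, source = src,
        max_youden = max(searches[[src]]$youden, na.rm = TRUE),
        n_y90 = nrow(select_y90(searches[[src]])$weights))
    }
    chosen[[cs_id]] <- list()
    for (src in names(sources)) {
      rw <- resolve_weights(config$weights$mode, config$weights$explicit,
                            searches, src)
      chosen[[cs_id]][[src]] <- rw$w
      manifest$notes[[paste0(cs_id, "/", src)]] <- rw$note
    }
  }
  emit(do.call(rbind, c(youden_rows, list(make.row.names = FALSE))),
       "youden_summary.csv")
  wtab <- do.call(rbind, lapply(cs_ids, function(cs_id)
    do.call(rbind, lapply(names(sources), function(src)
      data.frame(comparison_set = cs_id, source = src,
                 t(chosen[[cs_id]][[src]]), check.names = FALSE)))))
  emit(wtab, "selected_weights.csv")

  ## 5. tree classification ---------------------------------------------------
  acc_rows <- list()
  for (ts in config$tree_sets) {
    expert_res <- NULL
    for (src in names(sources)) {
      tree <- cafpa_tree(cs_fits[[ts$root]], cs_fits[[ts$leaf]],
                         root_weights = chosen[[ts$root]][[src]],
                         leaf_weights = chosen[[ts$leaf]][[src]])
      res <- predict(tree, sources[[src]])
      emit(data.frame(patient_id = cohort$patient_id, res),
           paste0("tree_", ts$id, "_", src, ".csv"))
      if (src == "expert") {
        expert_res <- res
      } else {
        cm <- cafpa_confusion(expert_res$terminal, res$terminal,
                              terminals = tree$terminals)
        emit(data.frame(test = rownames(cm$counts), cm$counts,
                        check.names = FALSE),
             paste0("confusion_", ts$id, "_", src, ".csv"))
        acc_rows[[paste(ts$id, src)]] <- data.frame(
          tree_set = ts$id, source = src, accuracy = accuracy(cm))
      }
    }
  }
  if (length(acc_rows) > 0L)
    emit(do.call(rbind, c(acc_rows, list(make.row.names = FALSE))),
         "accuracies.csv")

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
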