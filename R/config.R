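# Run configuration and pipeline orchestration. One YAML config drives the
# subcommands; every output directory receives a copy of the configuration,
# the seed and the layout, enough to reproduce itself.

run_config_defaults <- function() {
  list(
    paths = list(ontology = NULL, annotations = NULL, mutation = NULL,
                 amplification = NULL, deletion = NULL, expression = NULL,
                 fingerprints = NULL, descriptors = NULL, triplets = NULL,
                 targets = NULL, synergy = NULL, checkpoint = NULL,
                 predictions = NULL, out_dir = "movida_out"),
    model = unclass(movida_config()),
    evaluation = list(n_per_class = 100L, runs = 1000L),
    simulate = list(preset = "default"),
    seed = 1L
  )
}

merge_with_defaults <- function(user, defaults, where = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s)", if (nzchar(where)) paste0(" in ", where),
         ": ", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_with_defaults(user[[nm]], defaults[[nm]], nm)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) file, fills defaults (k = 6, learning rate 1e-5,
#' 300 epochs, smoothing penalty 80, 12 bins over `[0, 1.2]`, ...) and
#' rejects unknown keys. An empty file yields the all-defaults configuration.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A `run_config` list with blocks `paths`, `model`, `evaluation`,
#'   `simulate` and a `seed`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_with_defaults(user, run_config_defaults())
  cfg$model <- do.call(movida_config, cfg$model)
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && nm != "out_dir" && !file.exists(p)) {
      stop("configured path does not exist: ", nm, " = ", p)
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (inherits(x, "movida_config")) unclass(x) else x), path)
  invisible(path)
}

require_paths <- function(config, keys, subcommand) {
  missing <- keys[vapply(keys, function(k) is.null(config$paths[[k]]),
                         logical(1))]
  if (length(missing)) {
    stop("`", subcommand, "` needs config path(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

load_inputs <- function(config) {
  graph <- parse_obo(config$paths$ontology)
  channels <- c("mutation", "amplification", "deletion", "expression")
  ann <- load_annotations(config$paths$annotations, channels, graph = graph)
  layout <- build_layout(graph, ann)
  cohort <- load_cohort(config$paths$mutation, config$paths$amplification,
                        config$paths$deletion, config$paths$expression,
                        layout)
  drugs <- load_drug_features(config$paths$fingerprints,
                              config$paths$descriptors)
  list(graph = graph, layout = layout, cohort = cohort, drugs = drugs)
}

write_run_metadata <- function(dir, config, seed, layout = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_config(config, file.path(dir, "config.yaml"))
  writeLines(as.character(seed), file.path(dir, "seed.txt"))
  if (!is.null(layout)) layout_to_json(layout, file.path(dir, "layout.json"))
  invisible(dir)
}

#' Run a pipeline subcommand
#'
#' Orchestrates `simulate`, `train`, `predict`, `evaluate`, `explain`,
#' `combine` and `train-synergy` over a [load_config()] configuration.
#' Outputs, a config copy, the seed and the layout are written to the output
#' directory.
#'
#' @param subcommand One of the pipeline stages above.
#' @param config A `run_config` (or path to one).
#' @param seed Optional override of the configured seed.
#' @param out Optional override of `paths$out_dir`.
#' @return The subcommand's main result, invisibly.
#' @export
movida_run <- function(subcommand = c("simulate", "train", "predict",
                                      "evaluate", "explain", "combine",
                                      "train-synergy"),
                       config, seed = NULL, out = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out)) config$paths$out_dir <- out
  out_dir <- config$paths$out_dir
  config$model$seed <- config$seed

  result <- switch(subcommand,
    simulate = {
      res <- simulate_preset(config$simulate$preset, dir = out_dir,
                             seed = config$seed)
      write_run_metadata(out_dir, config, config$seed, res$layout)
      res
    },
    train = {
      require_paths(config, c("ontology", "annotations", "mutation",
                              "amplification", "deletion", "expression",
                              "fingerprints", "descriptors", "triplets"),
                    "train")
      inp <- load_inputs(config)
      triplets <- read_triplets(config$paths$triplets)
      drugs <- scale_descriptors(inp$drugs)
      model <- build_model(inp$layout, config$model,
                           ncol(drugs), seed = config$seed)
      fit <- train_model(model, inp$cohort, drugs, triplets)
      write_run_metadata(out_dir, config, config$seed, inp$layout)
      save_model(fit$model, file.path(out_dir, "checkpoint.json"))
      data.table::fwrite(fit$history, file.path(out_dir, "history.tsv"),
                         sep = "\t")
      fit
    },
    predict = {
      require_paths(config, c("checkpoint", "mutation", "amplification",
                              "deletion", "expression", "fingerprints",
                              "descriptors", "triplets"), "predict")
      model <- load_model(config$paths$checkpoint)
      cohort <- load_cohort(config$paths$mutation,
                            config$paths$amplification,
                            config$paths$deletion, config$paths$expression,
                            model$layout)
      drugs <- scale_descriptors(load_drug_features(
        config$paths$fingerprints, config$paths$descriptors))
      pairs <- read_triplets(config$paths$triplets)
      preds <- predict_batch(model, cohort, drugs, pairs)
      write_run_metadata(out_dir, config, config$seed, model$layout)
      data.table::fwrite(preds, file.path(out_dir, "predictions.tsv"),
                         sep = "\t")
      preds
    },
    evaluate = {
      require_paths(config, c("predictions", "triplets"), "evaluate")
      preds <- data.table::fread(config$paths$predictions,
                                 data.table = FALSE)
      truths <- read_triplets(config$paths$triplets)
      key <- function(d) paste(d$cell_id, d$drug_id)
      m <- match(key(truths), key(preds))
      if (anyNA(m)) stop("predictions missing for some triplets")
      p <- preds$predicted_auc[m]
      rep_ <- macro_mse(p, truths$auc, config$model$n_bins,
                        config$model$bin_range)
      bc <- balanced_correlation(p, truths$auc,
                                 config$evaluation$n_per_class,
                                 config$evaluation$runs, seed = config$seed,
                                 n_bins = config$model$n_bins,
                                 bin_range = config$model$bin_range)
      report <- list(mmse = rep_$mmse, per_bin_mse = rep_$per_bin_mse,
                     counts = rep_$counts,
                     balanced_pearson = bc$pearson,
                     balanced_pearson_sd = bc$pearson_sd,
                     balanced_spearman = bc$spearman,
                     balanced_spearman_sd = bc$spearman_sd)
      write_run_metadata(out_dir, config, config$seed)
      jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      data.table::fwrite(
        data.frame(bin = seq_len(config$model$n_bins) - 1L,
                   count = rep_$counts, mse = rep_$per_bin_mse),
        file.path(out_dir, "per_bin.tsv"), sep = "\t")
      report
    },
    explain = {
      require_paths(config, c("checkpoint", "mutation", "amplification",
                              "deletion", "expression", "fingerprints",
                              "descriptors", "triplets"), "explain")
      model <- load_model(config$paths$checkpoint)
      cohort <- load_cohort(config$paths$mutation,
                            config$paths$amplification,
                            config$paths$deletion, config$paths$expression,
                            model$layout)
      drugs <- scale_descriptors(load_drug_features(
        config$paths$fingerprints, config$paths$descriptors))
      pairs <- read_triplets(config$paths$triplets)
      ris <- ris_scores(model, cohort, drugs, pairs)
      write_run_metadata(out_dir, config, config$seed, model$layout)
      data.table::fwrite(ris, file.path(out_dir, "ris.tsv"), sep = "\t")
      ris
    },
    combine = {
      require_paths(config, c("checkpoint", "targets", "synergy"), "combine")
      model <- load_model(config$paths$checkpoint)
      ris_path <- file.path(out_dir, "ris.tsv")
      if (!file.exists(ris_path)) {
        stop("`combine` expects ris.tsv in the output directory; run ",
             "`explain` first")
      }
      ris <- data.table::fread(ris_path, data.table = FALSE)
      targets <- read_target_table(config$paths$targets)
      syn <- read_synergy_table(config$paths$synergy)
      pairs <- unique(ris[, c("cell_id", "drug_id")])
      rows <- lapply(seq_len(nrow(pairs)), function(i) {
        sub <- ris[ris$cell_id == pairs$cell_id[i] &
                     ris$drug_id == pairs$drug_id[i], ]
        cand <- candidate_combinations(sub, model$layout, targets)
        val <- validated_partners(syn, pairs$cell_id[i], pairs$drug_id[i])
        if (!nrow(val)) return(NULL)
        enr <- synergy_enrichment(cand, val)
        data.frame(cell_id = pairs$cell_id[i], drug_id = pairs$drug_id[i],
                   TP = enr$TP, FP = enr$FP, S = enr$S, NS = enr$NS,
                   precision = enr$precision, baseline = enr$baseline,
                   enrichment = enr$enrichment, p_value = enr$p_value)
      })
      res <- do.call(rbind, rows)
      write_run_metadata(out_dir, config, config$seed)
      data.table::fwrite(res, file.path(out_dir, "combinations.tsv"),
                         sep = "\t")
      res
    },
    `train-synergy` = {
      require_paths(config, c("ontology", "annotations", "mutation",
                              "amplification", "deletion", "expression",
                              "fingerprints", "descriptors", "synergy"),
                    "train-synergy")
      inp <- load_inputs(config)
      pairs <- read_synergy_table(config$paths$synergy)
      drugs <- scale_descriptors(inp$drugs)
      model <- build_synergy_model(inp$layout, config$model, ncol(drugs),
                                   seed = config$seed)
      fit <- train_synergy(model, inp$cohort, drugs, pairs)
      write_run_metadata(out_dir, config, config$seed, inp$layout)
      save_model(fit$model, file.path(out_dir, "checkpoint.json"))
      data.table::fwrite(fit$history, file.path(out_dir, "history.tsv"),
                         sep = "\t")
      fit
    })
  invisible(result)
}

#' Partners tested with a given (cell, drug) pair in a synergy table
#'
#' Collects every combination involving the query drug on the query cell and
#' returns the partner drug with its synergy label.
#' @param synergy data.frame from [read_synergy_table()].
#' @param cell_id,drug_id The query pair.
#' @return data.frame `drug_id`, `label`.
#' @export
validated_partners <- function(synergy, cell_id, drug_id) {
  sub <- synergy[synergy$cell_id == cell_id &
                   (synergy$drug_a == drug_id | synergy$drug_b == drug_id), ,
                 drop = FALSE]
  partner <- ifelse(sub$drug_a == drug_id, sub$drug_b, sub$drug_a)
  out <- data.frame(drug_id = partner, label = sub$label,
                    stringsAsFactors = FALSE)
  # a pair tested more than once counts once, synergistic if ever labelled so
  if (nrow(out)) {
    agg <- tapply(out$label, out$drug_id, max)
    out <- data.frame(drug_id = names(agg), label = as.integer(agg),
                      stringsAsFactors = FALSE)
  }
  out
}
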