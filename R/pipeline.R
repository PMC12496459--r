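# Pipeline orchestration: simulate -> preprocess -> train -> explain ->
# evaluate -> report, with per-stage manifests (parameters, seed, content
# hashes) so identical configurations reproduce identical artifacts.

log_msg <- function(level, stage, msg) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  threshold <- getOption("serveload.log_level", "info")
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("%-5s [%s] %s", toupper(level), stage, msg))
  }
}

#' Pipeline run configuration
#'
#' Assembles the full configuration of [run_pipeline()] with per-module
#' parameter blocks mirroring each module's defaults. Any block can be
#' overridden by passing a partial list.
#'
#' @param out_dir Artifact directory.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "preprocess", "train", "explain", "evaluate", "report")`.
#' @param seed Global seed; module seeds are derived from it.
#' @param simulate Overrides for [sim_config()] arguments.
#' @param preprocess Overrides: `cutoff`, `order`, `interp`, `fold_id`,
#'   `group_by_participant`.
#' @param model Overrides for [model_config()] arguments.
#' @param explain Overrides: `epsilon`, `norm_method`.
#' @param evaluate Overrides: `alpha`, `spm_method`, `n_perm`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "preprocess", "train",
                                       "explain", "evaluate", "report"),
                            seed = 1L,
                            simulate = list(),
                            preprocess = list(),
                            model = list(),
                            explain = list(),
                            evaluate = list()) {
  all_stages <- c("simulate", "preprocess", "train", "explain", "evaluate", "report")
  if (!all(stages %in% all_stages)) {
    abort_config(sprintf(
      "unknown stage(s): %s", paste(setdiff(stages, all_stages), collapse = ", ")
    ))
  }
  merge_block <- function(defaults, overrides) {
    defaults[names(overrides)] <- overrides
    defaults
  }
  structure(
    list(
      out_dir = out_dir,
      stages = stages,
      seed = as.integer(seed),
      simulate = simulate,
      preprocess = merge_block(
        list(cutoff = 10, order = 4, interp = "monotone_cubic",
             fold_id = 0L, group_by_participant = TRUE),
        preprocess
      ),
      model = model,
      explain = merge_block(list(epsilon = 1e-6, norm_method = "global"), explain),
      evaluate = merge_block(list(alpha = 0.05, spm_method = "rft", n_perm = 1000),
                             evaluate)
    ),
    class = "run_config"
  )
}

write_manifest <- function(out_dir, stage, params, inputs, outputs) {
  hashes <- tools::md5sum(outputs)
  manifest <- list(
    stage = stage,
    params = params,
    inputs = as.list(basename(inputs)),
    outputs = as.list(setNames(unname(hashes), basename(outputs)))
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

load_normalized_set <- function(norm_dir) {
  idx <- read.csv(file.path(norm_dir, "index.csv"))
  ntrials <- lapply(seq_len(nrow(idx)), function(i) {
    nt <- read_normalized_csv(file.path(norm_dir, idx$file[i]))
    nt$participant_id <- idx$participant_id[i]
    nt$trial_id <- idx$trial_id[i]
    nt
  })
  list(index = idx, ntrials = ntrials)
}

read_split_json <- function(path) {
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(train = as.integer(sp$train), validation = as.integer(sp$validation),
         test = as.integer(sp$test), fold_id = as.integer(sp$fold_id),
         seed = as.integer(sp$seed)),
    class = "split_indices"
  )
}

# Single-feature ablation diagnostic: metrics of the moment prediction when
# all input features except one are frozen at the training mean (zero after
# standardization). Labels the per-feature rows of the evaluation table;
# see the methods vignette for why per-feature metrics are defined this way.
ablation_metrics <- function(model, graphs, targets) {
  out <- list()
  for (j in seq_along(JOINT_NAMES)) {
    masked <- lapply(graphs, function(g) {
      nf <- g$node_features
      keep <- nf[, j]
      nf[] <- rep(model$scaler$mean, each = nrow(nf))
      nf[, j] <- keep
      g$node_features <- nf
      g
    })
    Y <- predict(model, masked)
    per_trial <- lapply(seq_len(nrow(Y)), function(i) {
      regression_metrics(targets[i, ], Y[i, ])
    })
    out[[JOINT_NAMES[j]]] <- data.frame(
      feature = JOINT_NAMES[j],
      mae_mean = mean(vapply(per_trial, `[[`, numeric(1), "mae")),
      mae_sd = sd(vapply(per_trial, `[[`, numeric(1), "mae")),
      mse_mean = mean(vapply(per_trial, `[[`, numeric(1), "mse")),
      mse_sd = sd(vapply(per_trial, `[[`, numeric(1), "mse")),
      r2_mean = mean(vapply(per_trial, `[[`, numeric(1), "r2")),
      r2_sd = sd(vapply(per_trial, `[[`, numeric(1), "r2"))
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order against `config$out_dir`. Each
#' stage writes its artifacts plus a JSON manifest recording parameters,
#' seed, inputs and MD5 content hashes of its outputs; manifests carry no
#' timestamps, so identical configurations reproduce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of per-stage artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  for (stage in config$stages) {
    log_msg("info", stage, "starting")
    artifacts[[stage]] <- switch(stage,
      simulate = stage_simulate(config),
      preprocess = stage_preprocess(config),
      train = stage_train(config),
      explain = stage_explain(config),
      evaluate = stage_evaluate(config),
      report = list(report = utils::capture.output(pipeline_report(out)))
    )
    log_msg("info", stage, "done")
  }
  invisible(artifacts)
}

stage_simulate <- function(config) {
  out <- config$out_dir
  sim_args <- config$simulate
  sim_args$seed <- sim_args$seed %||% config$seed
  scfg <- do.call(sim_config, sim_args)
  trials <- simulate_dataset(scfg)
  tdir <- file.path(out, "trials")
  manifest <- write_dataset_csv(trials, tdir)
  files <- file.path(tdir, c(manifest$file, "manifest.csv"))
  write_manifest(out, "simulate",
                 params = unclass(scfg)[c("n_participants", "trials_per_participant",
                                          "sampling_rate_hz", "n_samples", "noise_sd",
                                          "seed")],
                 inputs = character(), outputs = files)
  list(dir = tdir, n_trials = length(trials))
}

stage_preprocess <- function(config) {
  out <- config$out_dir
  pp <- config$preprocess
  tdir <- file.path(out, "trials")
  if (!file.exists(file.path(tdir, "manifest.csv"))) {
    abort_state("preprocess: no simulated trials found; run the simulate stage first")
  }
  trials <- read_dataset_csv(tdir)
  ndir <- file.path(out, "normalized")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    nt <- assemble_matrices(trials[[i]], cutoff = pp$cutoff, order = pp$order,
                            interp = pp$interp)
    file <- sprintf("normalized_%04d.csv", i)
    write_normalized_csv(nt, file.path(ndir, file))
    data.frame(
      trial_index = i, participant_id = trials[[i]]$participant_id,
      trial_id = trials[[i]]$trial_id, file = file,
      phase_end_pp = nt$phase_nodes[1], phase_end_fp = nt$phase_nodes[2]
    )
  })
  idx <- do.call(rbind, rows)
  write.csv(idx, file.path(ndir, "index.csv"), row.names = FALSE, quote = FALSE)
  # modal phase label per node across trials, for downstream phase summaries
  pb <- round(colMeans(idx[c("phase_end_pp", "phase_end_fp")]))
  phases <- data.frame(
    node_index = 0:(N_NODES - 1),
    phase = rep(PHASE_NAMES, c(pb[1] + 1, pb[2] - pb[1], N_NODES - 1 - pb[2]))
  )
  write.csv(phases, file.path(ndir, "phases.csv"), row.names = FALSE, quote = FALSE)
  groups <- if (isTRUE(pp$group_by_participant)) idx$participant_id else NULL
  split <- split_dataset(nrow(idx), fold_id = pp$fold_id, seed = config$seed,
                         groups = groups)
  split_path <- file.path(ndir, "split.json")
  jsonlite::write_json(unclass(split), split_path, auto_unbox = TRUE, digits = NA)
  files <- c(file.path(ndir, idx$file),
             file.path(ndir, c("index.csv", "phases.csv", "split.json")))
  write_manifest(out, "preprocess", params = pp, inputs = file.path(tdir, "manifest.csv"),
                 outputs = files)
  list(dir = ndir, n_trials = nrow(idx))
}

stage_train <- function(config) {
  out <- config$out_dir
  ndir <- file.path(out, "normalized")
  if (!file.exists(file.path(ndir, "index.csv"))) {
    abort_state("train: no normalized trials found; run the preprocess stage first")
  }
  ds <- load_normalized_set(ndir)
  graphs <- lapply(ds$ntrials, build_graph)
  split <- read_split_json(file.path(ndir, "split.json"))
  margs <- config$model
  margs$seed <- margs$seed %||% config$seed
  mcfg <- do.call(model_config, margs)
  bcfg_args <- margs
  bcfg_args$baseline_mode <- TRUE
  bcfg <- do.call(model_config, bcfg_args)
  mdir <- file.path(out, "models")
  dir.create(mdir, showWarnings = FALSE)

  st_main <- train_model(graphs, mcfg, split)
  st_base <- train_model(graphs, bcfg, split)
  save_model(st_main$model, file.path(mdir, "gnn_gru.json"))
  save_model(st_base$model, file.path(mdir, "gru_baseline.json"))
  hist <- rbind(
    cbind(model = "gnn_gru", st_main$loss_history),
    cbind(model = "gru_baseline", st_base$loss_history)
  )
  hist[c("train", "validation")] <- lapply(hist[c("train", "validation")], format_sig)
  write.csv(hist, file.path(mdir, "loss_history.csv"), row.names = FALSE, quote = FALSE)
  files <- file.path(mdir, c("gnn_gru.json", "gru_baseline.json", "loss_history.csv"))
  write_manifest(out, "train", params = unclass(mcfg),
                 inputs = file.path(ndir, c("index.csv", "split.json")),
                 outputs = files)
  list(dir = mdir)
}

stage_explain <- function(config) {
  out <- config$out_dir
  ndir <- file.path(out, "normalized")
  mpath <- file.path(out, "models", "gnn_gru.json")
  if (!file.exists(mpath)) {
    abort_state("explain: no trained model found; run the train stage first")
  }
  model <- load_model(mpath)
  ds <- load_normalized_set(ndir)
  split <- read_split_json(file.path(ndir, "split.json"))
  ex <- config$explain
  maps <- lapply(split$test, function(i) {
    explain(model, build_graph(ds$ntrials[[i]]), epsilon = ex$epsilon)
  })
  contrib <- aggregate_and_normalize(maps, method = ex$norm_method)
  edir <- file.path(out, "explain")
  dir.create(edir, showWarnings = FALSE)
  cpath <- file.path(edir, "contributions.csv")
  write_contributions_csv(contrib, cpath, epsilon = ex$epsilon,
                          seeding = "predicted", method = ex$norm_method)
  phases <- read.csv(file.path(ndir, "phases.csv"))
  summ <- phase_contribution_summary(contrib, factor(phases$phase, PHASE_NAMES))
  spath <- file.path(edir, "phase_summary.csv")
  sdf <- data.frame(phase = rownames(summ), summ, row.names = NULL)
  sdf[JOINT_NAMES] <- lapply(sdf[JOINT_NAMES], format_sig)
  write.csv(sdf, spath, row.names = FALSE, quote = FALSE)
  files <- c(cpath, paste0(cpath, ".meta.json"), spath)
  write_manifest(out, "explain", params = ex,
                 inputs = c(mpath, file.path(ndir, "split.json")),
                 outputs = files)
  list(dir = edir)
}

stage_evaluate <- function(config) {
  out <- config$out_dir
  ndir <- file.path(out, "normalized")
  mdir <- file.path(out, "models")
  if (!file.exists(file.path(mdir, "gnn_gru.json"))) {
    abort_state("evaluate: no trained models found; run the train stage first")
  }
  ev <- config$evaluate
  ds <- load_normalized_set(ndir)
  split <- read_split_json(file.path(ndir, "split.json"))
  graphs <- lapply(ds$ntrials[split$test], build_graph)
  targets <- do.call(rbind, lapply(ds$ntrials[split$test],
                                   function(nt) nt$resultant_moment))
  models <- list(
    gnn_gru = load_model(file.path(mdir, "gnn_gru.json")),
    gru_baseline = load_model(file.path(mdir, "gru_baseline.json"))
  )
  edir <- file.path(out, "evaluate")
  dir.create(edir, showWarnings = FALSE)

  per_trial <- lapply(models, function(m) {
    Y <- predict(m, graphs)
    data.frame(
      mae = vapply(seq_len(nrow(Y)), function(i)
        regression_metrics(targets[i, ], Y[i, ])$mae, numeric(1)),
      mse = vapply(seq_len(nrow(Y)), function(i)
        regression_metrics(targets[i, ], Y[i, ])$mse, numeric(1)),
      r2 = vapply(seq_len(nrow(Y)), function(i)
        regression_metrics(targets[i, ], Y[i, ])$r2, numeric(1))
    )
  })
  comparison <- lapply(c(mae = "mae", mse = "mse", r2 = "r2"), function(metric) {
    a <- per_trial$gnn_gru[[metric]]
    b <- per_trial$gru_baseline[[metric]]
    tt <- paired_t(a, b, alpha = ev$alpha)
    list(
      gnn_gru_mean = mean(a), gnn_gru_sd = sd(a),
      gru_mean = mean(b), gru_sd = sd(b),
      t = tt$t, p = tt$p, normality_ok = tt$normality_ok,
      d = cohens_d_pooled(mean(a), sd(a), mean(b), sd(b))
    )
  })
  jsonlite::write_json(comparison, file.path(edir, "model_comparison.json"),
                       auto_unbox = TRUE, digits = NA)

  # Table-1-layout per-feature diagnostic (single-feature ablation)
  feat <- do.call(rbind, lapply(names(models), function(nm) {
    cbind(model = nm, ablation_metrics(models[[nm]], graphs, targets))
  }))
  num <- vapply(feat, is.double, logical(1))
  feat[num] <- lapply(feat[num], format_sig)
  write.csv(feat, file.path(edir, "metrics_per_feature.csv"),
            row.names = FALSE, quote = FALSE)

  spm <- spm_paired_t(predict(models$gnn_gru, graphs), targets,
                      alpha = ev$alpha, method = ev$spm_method,
                      n_perm = ev$n_perm, seed = derive_seed(config$seed, 55L))
  write_spm_json(spm, file.path(edir, "spm.json"))
  files <- file.path(edir, c("model_comparison.json", "metrics_per_feature.csv",
                             "spm.json"))
  write_manifest(out, "evaluate", params = ev,
                 inputs = file.path(ndir, "split.json"), outputs = files)
  list(dir = edir)
}

#' Summarize a completed pipeline run
#'
#' Renders the per-feature metrics table, the GNN-GRU vs GRU comparison
#' (p values and pooled effect sizes), the SPM cluster summary and the
#' per-phase contribution summary from the artifacts in `dir`. Raises an
#' error listing the absent files if the required stages have not run.
#'
#' @param dir Pipeline artifact directory.
#' @return Invisibly, a list with the parsed artifacts.
#' @export
pipeline_report <- function(dir) {
  need <- c(
    file.path(dir, "evaluate", "model_comparison.json"),
    file.path(dir, "evaluate", "metrics_per_feature.csv"),
    file.path(dir, "evaluate", "spm.json"),
    file.path(dir, "explain", "phase_summary.csv")
  )
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort_state(paste0(
      "pipeline_report: missing artifacts:\n  ",
      paste(missing, collapse = "\n  ")
    ))
  }
  comparison <- jsonlite::read_json(need[1], simplifyVector = TRUE)
  feat <- read.csv(need[2])
  spm <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  phase_summary <- read.csv(need[4])

  cat("== Per-feature single-feature-ablation metrics (test split) ==\n")
  print(feat, digits = 3)
  cat("\n== GNN-GRU vs GRU baseline (paired, test split) ==\n")
  for (metric in names(comparison)) {
    cm <- comparison[[metric]]
    cat(sprintf(
      "  %-4s GNN-GRU %.4f (%.4f) vs GRU %.4f (%.4f): t = %.3f, p = %.4g, d = %.3f\n",
      metric, cm$gnn_gru_mean, cm$gnn_gru_sd, cm$gru_mean, cm$gru_sd,
      cm$t, cm$p, cm$d
    ))
  }
  cat(sprintf(
    "\n== SPM paired t (predicted vs actual moment): critical |t| = %.3f, %s ==\n",
    spm$critical_t,
    if (isTRUE(spm$significant)) "significant clusters found" else "no significant difference"
  ))
  cat("\n== Phase-averaged normalized contributions ==\n")
  print(phase_summary, digits = 3)
  invisible(list(
    comparison = comparison, per_feature = feat, spm = spm,
    phase_summary = phase_summary
  ))
}
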