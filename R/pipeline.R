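# Orchestration: descriptive summaries and a seed-controlled
# simulate -> fit -> compare -> (rope) pipeline that writes versioned,
# provenance-stamped artifacts.

#' Descriptive choice summaries
#'
#' The model-free quantities: proportion of equal-accuracy trials on which
#' the more positive psychic was chosen, and proportion of unequal-accuracy
#' trials on which the more accurate psychic was chosen — the latter split by
#' whether the more accurate psychic was also the more positive one.  No
#' inferential statistics are computed.
#'
#' @param data Experiment-1 dataset with `chose_a`.
#' @return list with `pooled` (one row) and `per_participant` data.frames;
#'   categories with no trials are reported as `NA`.
#' @export
descriptive_summaries <- function(data) {
  stopifnot(all(c("chose_a", "n_acc_a", "n_acc_b") %in% names(data)))
  eq <- data$n_acc_a == data$n_acc_b
  more_pos_a <- data$n_pos_a > data$n_pos_b
  more_acc_a <- data$n_acc_a > data$n_acc_b
  chose_pos <- ifelse(more_pos_a, data$chose_a, 1 - data$chose_a)
  chose_acc <- ifelse(more_acc_a, data$chose_a, 1 - data$chose_a)
  # is the more accurate psychic also the more positive one?
  acc_is_pos <- ifelse(more_acc_a, data$n_pos_a > data$n_pos_b,
                       data$n_pos_b > data$n_pos_a)
  summarize <- function(rows) {
    prop <- function(x, sel) if (any(sel)) mean(x[sel]) else NA_real_
    data.frame(
      p_pos_equal_acc = prop(chose_pos, rows & eq),
      p_acc_unequal = prop(chose_acc, rows & !eq),
      p_acc_unequal_acc_more_pos = prop(chose_acc, rows & !eq & acc_is_pos),
      p_acc_unequal_acc_less_pos = prop(chose_acc, rows & !eq & !acc_is_pos))
  }
  per <- do.call(rbind, lapply(unique(data$participant_id), function(id) {
    cbind(participant_id = id, summarize(data$participant_id == id))
  }))
  list(pooled = summarize(rep(TRUE, nrow(data))), per_participant = per)
}

#' Pipeline configuration
#'
#' @param out_dir artifact directory (created if absent; its parent must
#'   exist).
#' @param experiment 1 or 2.
#' @param models model ids to fit and compare (defaults to all models of the
#'   experiment).
#' @param n_participants synthetic cohort size.
#' @param generating_model data-generating model id (first of `models` by
#'   default).
#' @param sampler an [sampler_config()].
#' @param method elpd method.
#' @param inner_draws marginalization draws.
#' @param seed master seed, stamped into every artifact.
#' @return list of class `hs_run_config`.
#' @export
pipeline_config <- function(out_dir, experiment = 1L, models = NULL,
                            n_participants = 12L, generating_model = NULL,
                            sampler = sampler_config(chains = 2, warmup = 300,
                                                     draws = 300),
                            method = "tis", inner_draws = 50L, seed = 1L) {
  models <- models %||% (if (experiment == 1L) CHOICE_MODELS else BELIEF_MODELS)
  if (!all(vapply(models, model_experiment, integer(1)) == experiment)) {
    stop("all models must belong to experiment ", experiment)
  }
  structure(list(out_dir = out_dir, experiment = as.integer(experiment),
                 models = models,
                 generating_model = generating_model %||% models[[1L]],
                 n_participants = as.integer(n_participants),
                 sampler = sampler, method = method,
                 inner_draws = as.integer(inner_draws), seed = seed),
            class = "hs_run_config")
}

write_json_artifact <- function(x, path, config) {
  payload <- list(seed = config$seed, config_hash = fingerprint(unclass(config)),
                  content = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full pipeline
#'
#' simulate -> fit every model -> compare -> (Experiment 2) ROPE assessment,
#' writing a dataset CSV, per-model diagnostics and point estimates, a
#' comparison report and a manifest.  Every artifact embeds the master seed
#' and a hash of the configuration; reruns with an identical config are
#' byte-identical for the dataset and numerically identical elsewhere.
#'
#' @param config an [pipeline_config()].
#' @return (invisibly) list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hs_run_config"))
  if (!dir.exists(dirname(config$out_dir))) {
    stop("configuration error: parent of out_dir does not exist: ",
         dirname(config$out_dir))
  }
  dir.create(config$out_dir, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    message(sprintf("[%s] started", name))
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  spec <- cohort_spec(config$n_participants, model = config$generating_model,
                      seed = config$seed)
  data <- stage("simulate", {
    d <- if (config$experiment == 1L) generate_exp1(spec) else generate_exp2(spec)
    paths$data <- file.path(config$out_dir, "dataset.csv")
    write.csv(cbind(d, seed = config$seed), paths$data, row.names = FALSE)
    d
  })

  if (config$experiment == 1L) {
    stage("descriptives", {
      ds <- descriptive_summaries(data)
      paths$descriptives <- write_json_artifact(
        ds, file.path(config$out_dir, "descriptives.json"), config)
    })
  }

  fits <- stage("fit", {
    fl <- setNames(lapply(config$models, function(m) {
      suppressWarnings(fit_hierarchical(m, data, config$sampler))
    }), config$models)
    for (m in config$models) {
      dg <- fl[[m]]$diagnostics
      est <- point_estimates(fl[[m]])
      paths[[paste0("fit_", m)]] <- write_json_artifact(
        list(model = m,
             divergent = sum(fl[[m]]$n_divergent),
             max_rhat = if (!is.null(dg)) max(dg$rhat, na.rm = TRUE) else NA,
             hyper = est$hyper, individual = est$individual),
        file.path(config$out_dir, paste0("fit_", m, ".json")), config)
    }
    fl
  })

  cmp <- stage("compare", {
    cm <- compare_models(data, config$models, method = config$method,
                         inner_draws = config$inner_draws, fits = fits,
                         seed = child_seed(config$seed, 99L))
    paths$comparison <- write_json_artifact(
      list(models = cm$models, elpd_total = cm$elpd_total,
           elpd_se = cm$elpd_se, delta_elpd = cm$delta_elpd,
           waic = cm$waic, waic_se = cm$waic_se,
           stacking = as.list(cm$stacking), prop_best = as.list(cm$prop_best),
           elpd_matrix = cm$elpd),
      file.path(config$out_dir, "comparison.json"), config)
    tab <- utils::capture.output(print(cm))
    writeLines(tab, file.path(config$out_dir, "comparison.txt"))
    paths$comparison_txt <- file.path(config$out_dir, "comparison.txt")
    cm
  })

  rope <- NULL
  if (config$experiment == 2L && "full" %in% config$models) {
    rope <- stage("rope", {
      ra <- rope_assessment(fits[["full"]], data)
      paths$rope <- write_json_artifact(
        ra, file.path(config$out_dir, "rope.json"), config)
      ra
    })
  }

  stage("manifest", {
    paths$manifest <- write_json_artifact(
      list(experiment = config$experiment, models = config$models,
           n_participants = config$n_participants,
           generating_model = config$generating_model,
           method = config$method,
           sampler = unclass(config$sampler),
           artifacts = lapply(paths, as.character),
           package_version = as.character(utils::packageVersion("hedoseek"))),
      file.path(config$out_dir, "manifest.json"), config)
  })

  invisible(list(data = data, fits = fits, comparison = cmp, rope = rope,
                 paths = paths, config = config))
}
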