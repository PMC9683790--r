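#' Run the full analysis pipeline on one configuration
#'
#' Orchestrates the standard stages in dependency order on a generated
#' session: `generate` (synthetic session), `align` (per-trial dF/F and
#' event alignment), `respond` (responsiveness classification and
#' population statistics), `cluster` (profile normalisation, PCA, k-means),
#' `tca` (trial tensor and non-negative CP decomposition), `arousal`
#' (pupil/speed splits), `glm` (behavioural design matrix and lasso fit).
#' Every stage writes its tables under `out_dir` and contributes to a
#' machine-readable `summary.json` stamped with the configuration hash;
#' the same configuration and seed reproduce the summary byte for byte.
#'
#' @param config Named list (or path to a JSON file) with optional fields
#'   `stages` (character subset, default all), `seed`, `out_dir`, and
#'   `session` (arguments passed to [session_config()]).
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  all_stages <- c("generate", "align", "respond", "cluster", "tca",
                  "arousal", "glm")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; valid stages: ", paste(all_stages, collapse = ", "))
  }
  stages <- all_stages[all_stages %in% stages]
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("vipmode-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  summary <- list(config_hash = fnv1a(as.character(cfg_json)), seed = seed,
                  stages = stages)

  ses_args <- config$session %||% list()
  ses_args$seed <- seed
  scfg <- do.call(session_config, ses_args)
  session <- NULL
  aligned <- NULL
  need <- function(x, stage, from) {
    if (is.null(x)) stop("stage '", stage, "' requires output of stage '",
                         from, "'", call. = FALSE)
    x
  }

  for (st in stages) {
    if (st == "generate") {
      session <- generate_session(scfg)
      write_session(session, file.path(out_dir, "session"))
      summary$generate <- list(n_neurons = scfg$n_neurons,
                               n_trials = nrow(session$trials),
                               trial_counts = as.list(table(
                                 session$trials$type)))
    } else if (st == "align") {
      need(session, st, "generate")
      aligned <- align_trials(session, mode = "expected_reinforcement",
                              window = c(-2, 4))
      summary$align <- list(n_trials_aligned = dim(aligned$data)[3],
                            window = aligned$window)
    } else if (st == "respond") {
      need(aligned, st, "align")
      res <- classify_all(aligned)
      utils::write.csv(res, file.path(out_dir, "responsiveness.csv"),
                       row.names = FALSE)
      act <- trial_activity(aligned)
      cat_tab <- category_table(res)
      sync <- synchronicity(act)
      summary$respond <- list(
        fraction_both = unname(cat_tab$fractions["both"]),
        fraction_reward = unname(cat_tab$fractions["both"] +
                                   cat_tab$fractions["reward_only"]),
        fraction_punishment = unname(cat_tab$fractions["both"] +
                                       cat_tab$fractions["punishment_only"]),
        mean_synchronicity_hit = mean(
          sync[attr(act, "trial_types") == "Hit"]),
        mean_reliability_hit = mean(reliability(act, "Hit")))
    } else if (st == "cluster") {
      need(aligned, st, "align")
      # cluster reward-activated cells only, as the analysis assumes
      hit_cl <- classify_all(aligned, trial_types = "Hit")
      keep <- hit_cl$neuron[hit_cl$direction == "activated"]
      sub <- aligned
      sub$data <- aligned$data[keep, , , drop = FALSE]
      prof <- preprocess_profiles(sub)
      attr(prof, "kept") <- keep[attr(prof, "kept")]
      pcs <- pca_reduce(prof)
      cl <- kmeans_cluster(pcs$scores, k = 5, seed = seed)
      utils::write.csv(data.frame(neuron = attr(prof, "kept"),
                                  label = cl$labels),
                       file.path(out_dir, "clusters.csv"),
                       row.names = FALSE)
      summary$cluster <- list(n_retained_pcs = pcs$n_retained,
                              cluster_sizes = as.list(table(cl$labels)))
    } else if (st == "tca") {
      need(session, st, "generate")
      summary$tca <- tryCatch({
        tens <- build_tensor(session)
        fac <- nncp_decompose(tens, rank = 3, n_init = 5, seed = seed)
        sep <- trial_factor_separation(fac, tens$trial_types)
        utils::write.csv(as.data.frame(fac$trial),
                         file.path(out_dir, "tca_trial_factors.csv"),
                         row.names = FALSE)
        list(reconstruction_error = fac$error,
             reinforcement_component = sep$reinforcement_component,
             separation_p = min(sep$p_values))
      }, error = function(e) list(skipped = TRUE,
                                  reason = conditionMessage(e)))
    } else if (st == "arousal") {
      need(aligned, st, "align")
      beh <- session$behavior
      pup <- normalize_pupil(beh$pupil, beh$time, session$trials)
      rows <- session$trials[aligned$trial_index, ]
      ev <- ifelse(is.na(rows$reinforcement_onset),
                   rows$tone_onset + aligned$mean_reaction_time,
                   rows$reinforcement_onset)
      dpp <- trial_dpp(pup, rows, ev)
      split <- auc_split(dpp, types = rows$type)
      cmp <- compare_split_responses(aligned, split)
      summary$arousal <- list(mean_high = cmp$mean_high,
                              mean_low = cmp$mean_low,
                              p_value = cmp$p_value)
    } else if (st == "glm") {
      need(session, st, "generate")
      sim <- simulate_population_signal(session, seed = seed)
      fit <- fit_lasso(sim$design, sim$y, seed = seed)
      jsonlite::write_json(list(weights = as.list(fit$weights),
                                variance_explained =
                                  fit$variance_explained),
                           file.path(out_dir, "glm.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$glm <- list(variance_explained = fit$variance_explained,
                          weights = as.list(fit$weights))
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
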