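# End-to-end pipeline: simulate -> preprocess -> encoding CV -> delay
# decoding -> replay statistics -> behavior -> ERF contrast.

#' Pipeline configuration
#'
#' Collects every setting of an end-to-end run in one serializable list.
#' Two runs with equal configuration (including seed) produce byte-identical
#' result tables.
#'
#' @param n_subjects Number of simulated subjects.
#' @param params A [sim_params] object (per-subject seeds are derived from
#'   the config seed).
#' @param n_trials Optional cap on trials per subject (`NULL` = full 162
#'   design); smaller values give fast smoke runs.
#' @param cv_window Encoding CV window `c(start, end)` ms.
#' @param folds CV folds.
#' @param reliability Override for the rejection-rule reliability; `NULL`
#'   uses each subject's mean-over-pairs CV accuracy at the selected bin.
#' @param predominance_rule `"bins"` or `"longest"`.
#' @param artifact_threshold Epoch rejection threshold, tesla.
#' @param n_perm_accuracy,n_perm_erf Permutation counts for the two
#'   cluster tests.
#' @param seed Master integer seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 14L, params = sim_params(),
                            n_trials = NULL, cv_window = c(-20, 500),
                            folds = 10L, reliability = NULL,
                            predominance_rule = "bins",
                            artifact_threshold = 1.5e-11,
                            n_perm_accuracy = 1000L, n_perm_erf = 1000L,
                            seed = 1L, out_dir = NULL) {
  structure(list(n_subjects = as.integer(n_subjects), params = params,
                 n_trials = n_trials, cv_window = cv_window,
                 folds = as.integer(folds), reliability = reliability,
                 predominance_rule = predominance_rule,
                 artifact_threshold = artifact_threshold,
                 n_perm_accuracy = as.integer(n_perm_accuracy),
                 n_perm_erf = as.integer(n_perm_erf),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  c2 <- config
  c2$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(c2, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# One subject: simulate, preprocess, decode, summarize.
analyze_subject <- function(config, subject) {
  p <- config$params
  p$seed <- as.integer(derive_seed(config$seed, 1000L + subject))
  # the cohort shares one sensor topography; everything else is per-subject
  p$pattern_seed <- p$pattern_seed %||% as.integer(derive_seed(config$seed, 2000L))
  design <- enumerate_design(p$seed)
  if (!is.null(config$n_trials)) design <- design[seq_len(config$n_trials), ]
  design <- assign_predominant(design, p)

  enc <- simulate_encoding_epochs(design, p)
  enc <- notch_filter(enc)
  rej <- reject_artifact_epochs(enc, config$artifact_threshold)
  enc <- baseline_correct(rej$epochs)

  grid <- make_time_bins(config$cv_window[1], config$cv_window[2], 20, p$fs)
  curve <- crossvalidate_bins(enc, grid, config$folds,
                              seed = derive_seed(p$seed, 20L))
  best <- select_best_bin(curve)
  classifiers <- train_bin_classifiers(enc, best$bin_center_ms, grid,
                                       seed = derive_seed(p$seed, 21L))
  reliability <- config$reliability %||% best$mean_accuracy

  states_ret <- simulate_hidden_state_sequence(design, p, "retention")
  states_iti <- simulate_hidden_state_sequence(design, p, "iti")
  windows <- define_analysis_windows(fs = p$fs)
  dec_ret <- decode_period(classifiers,
                           simulate_delay_epochs(design, states_ret, p, "retention"),
                           windows$retention, "retention")
  dec_iti <- decode_period(classifiers,
                           simulate_delay_epochs(design, states_iti, p, "iti"),
                           windows$iti, "iti")
  thr <- compute_rejection_threshold(as.vector(dec_ret$d), reliability)
  dec_ret <- apply_threshold(dec_ret, thr)
  dec_iti <- apply_threshold(dec_iti, thr)

  pred <- summarize_predominance(dec_ret, design, config$predominance_rule)
  pred$subject <- subject
  ep_ret <- extract_replay_epochs(dec_ret)
  ep_iti <- extract_replay_epochs(dec_iti)
  tm_ret <- estimate_transition_matrix(dec_ret)
  tm_remap <- estimate_transition_matrix(dec_ret, design, remap = TRUE)

  design <- simulate_behavior(design, states_ret, p)
  behavior <- data.frame(subject = subject, trial_id = design$trial_id,
                         replay_ms = pred$probe_longest_ms,
                         probe_longest_ms = pred$probe_longest_ms,
                         detail_response = design$detail_response,
                         detail_rt = design$detail_rt,
                         order_correct = design$order_response == design$probe_position,
                         order_rt = design$order_rt)

  erf_epochs <- baseline_correct(lowpass_filter(rej$epochs))
  pm_flags <- erf_epochs$trial_meta$category ==
    pred$pm_category[match(erf_epochs$trial_meta$trial_id, pred$trial_id)]
  pm_flags[is.na(pm_flags)] <- FALSE

  list(subject = subject, design = design, curve = curve, best = best,
       reliability = reliability, d_star = thr$d_star,
       rejected_retention = dec_ret$rejected_fraction,
       rejected_iti = dec_iti$rejected_fraction,
       preprocessing = rej$report,
       predominance = pred, epochs_retention = ep_ret, epochs_iti = ep_iti,
       hist_retention = histogram_epoch_lengths(ep_ret),
       hist_iti = histogram_epoch_lengths(ep_iti),
       n_replay_retention = sum(dec_ret$labels != "N"),
       n_replay_iti = sum(dec_iti$labels != "N"),
       transition_retention = tm_ret, transition_remapped = tm_remap,
       behavior = behavior, erf_epochs = erf_epochs, pm_flags = pm_flags)
}

#' Run the full analysis pipeline
#'
#' Executes, per simulated subject, the whole chain — synthetic data
#' generation, notch filtering, artifact rejection, baseline correction,
#' time-binned encoding cross-validation, best-bin selection, delay-period
#' decoding with the d* rejection rule, replay-epoch and Markov-transition
#' statistics — then the group-level analyses: cluster-permutation accuracy
#' significance, retention-vs-ITI comparisons, directionality tests,
#' predominance ANOVA, the replay-length mixed model with replay-group ANOVA,
#' and the PM vs non-PM ERF cluster contrast. When `config$out_dir` is set,
#' result tables, the configuration, and a checksum manifest are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @return A list with per-subject results (`subjects`) and all group-level
#'   results; invisibly also the written `manifest` when an output directory
#'   is configured.
#' @export
run_pipeline <- function(config) {
  stage <- "setup"
  result <- tryCatch({
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      stage <<- sprintf("subject %d", s)
      analyze_subject(config, s)
    })
    stage <- "group: encoding accuracy"
    acc_sig <- group_accuracy_significance(lapply(subjects, `[[`, "curve"),
                                           n_perm = config$n_perm_accuracy,
                                           seed = derive_seed(config$seed, 30L))
    stage <- "group: retention vs ITI"
    period_tests <- list(
      n_replay = compare_periods(
        vapply(subjects, `[[`, numeric(1), "n_replay_retention"),
        vapply(subjects, `[[`, numeric(1), "n_replay_iti")),
      epoch_hist = lapply(seq_along(EPOCH_RANGES_MS), function(j)
        compare_periods(
          vapply(subjects, function(s) s$hist_retention[[j]], numeric(1)),
          vapply(subjects, function(s) s$hist_iti[[j]], numeric(1))))
    )
    stage <- "group: directionality"
    directionality <- directionality_test(lapply(subjects, `[[`, "transition_remapped"))
    stage <- "group: predominance ANOVA"
    pred_all <- do.call(rbind, lapply(subjects, `[[`, "predominance"))
    pred_anova <- predominance_anova(pred_all)
    stage <- "group: behavior"
    beh_all <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
    lmm <- list(
      detail_accuracy = fit_replay_behavior_lmm(beh_all, "detail_response"),
      detail_rt = fit_replay_behavior_lmm(beh_all, "detail_rt"),
      order_accuracy = fit_replay_behavior_lmm(beh_all, "order_correct"),
      order_rt = fit_replay_behavior_lmm(beh_all, "order_rt"))
    grouped <- group_by_replay_duration(beh_all)
    beh_anova <- tryCatch(behavior_anova_posthoc(grouped),
                          error = function(e) list(error = conditionMessage(e)))
    stage <- "group: ERF contrast"
    erf <- compute_erf_contrast(lapply(subjects, `[[`, "erf_epochs"),
                                lapply(subjects, `[[`, "pm_flags"),
                                n_perm = config$n_perm_erf,
                                seed = derive_seed(config$seed, 31L))
    list(config = config, subjects = subjects, accuracy_significance = acc_sig,
         period_tests = period_tests, directionality = directionality,
         predominance = pred_all, predominance_anova = pred_anova,
         behavior = beh_all, behavior_lmm = lmm, behavior_grouped = grouped,
         behavior_anova = beh_anova, erf = erf,
         methods = list(
           fwe = "sign-flip max-cluster-mass permutation",
           predominance_rule = config$predominance_rule,
           reliability = if (is.null(config$reliability))
             "mean-over-pairs CV accuracy at selected bin" else config$reliability))
  }, error = function(e) {
    stopf("pipeline failed at stage [%s]: %s", stage, conditionMessage(e))
  })
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  invisible(result)
}

num_fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(result$config)
  wcsv <- function(df, name) {
    df <- cbind(df, config_hash = cfg_hash)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    name
  }
  wjson <- function(x, name) {
    x$config_hash <- cfg_hash
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    name
  }
  curves <- do.call(rbind, lapply(result$subjects, function(s) {
    data.frame(subject = s$subject,
               pair = rep(rownames(s$curve$acc), ncol(s$curve$acc)),
               bin_center_ms = rep(s$curve$centers_ms, each = nrow(s$curve$acc)),
               accuracy = as.vector(s$curve$acc))
  }))
  files <- c(
    wcsv(curves, "accuracy_curves.csv"),
    wcsv(result$predominance, "predominance.csv"),
    wcsv(result$behavior, "behavior.csv"),
    wcsv(do.call(rbind, lapply(result$subjects, function(s) {
      data.frame(subject = s$subject, state_from = rep(s$transition_retention$states, 4),
                 state_to = rep(s$transition_retention$states, each = 4),
                 prob = as.vector(s$transition_retention$probs))
    })), "transition_matrices.csv"),
    wjson(list(
      per_subject = data.frame(
        subject = vapply(result$subjects, `[[`, integer(1), "subject"),
        selected_bin_ms = vapply(result$subjects, function(s) s$best$bin_center_ms, numeric(1)),
        reliability = vapply(result$subjects, `[[`, numeric(1), "reliability"),
        d_star = vapply(result$subjects, `[[`, numeric(1), "d_star"),
        rejected_retention = vapply(result$subjects, `[[`, numeric(1), "rejected_retention"),
        rejected_iti = vapply(result$subjects, `[[`, numeric(1), "rejected_iti"))),
      "decoding_summary.json"),
    wjson(list(p_forward = result$directionality$p_forward,
               p_backward = result$directionality$p_backward,
               comparisons = lapply(result$directionality$comparisons,
                                    function(x) x["p"])),
          "directionality.json"),
    wjson(list(anova = result$predominance_anova[c("category", "position", "interaction")]),
          "predominance_anova.json"),
    wjson(list(lmm = lapply(result$behavior_lmm, function(m)
      m[c("outcome", "estimate", "se", "t", "p", "n_observations")]),
      anova = result$behavior_anova[setdiff(names(result$behavior_anova), "by_subject")]),
      "behavior_stats.json"),
    wjson(list(clusters = result$erf$clusters, f_threshold = result$erf$f_threshold,
               method = result$erf$method), "erf_clusters.json"),
    # out_dir is a run location, not part of the scientific configuration
    wjson(unclass(result$config)[setdiff(names(result$config), "out_dir")],
          "config.json")
  )
  checks <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config_hash = cfg_hash,
                   files = data.frame(file = files, md5 = unname(checks)),
                   methods = result$methods)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' Refuse to mix artifacts from different configurations
#'
#' @param dir1,dir2 Output directories holding pipeline manifests.
#' @return `TRUE` invisibly if compatible, otherwise an error.
#' @export
check_same_config <- function(dir1, dir2) {
  h <- vapply(c(dir1, dir2), function(d)
    jsonlite::read_json(file.path(d, "manifest.json"))$config_hash, character(1))
  if (h[1] != h[2]) stopf("artifacts come from different configurations (%s vs %s)",
                          h[1], h[2])
  invisible(TRUE)
}
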