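#' Run the full cfMeth diagnostic pipeline on a simulated study
#'
#' Chains every stage of the framework: DMR calling on the tissue
#' methylomes, hypo-DMR reference panel construction, size-selected
#' per-fragment origin inference and marker profiling of the discovery
#' cohort, top-k marker selection, the cross-validated random-forest
#' cfMeth score, the ridge-combined model with imaging, cutoff selection
#' at the FNR bound, and evaluation. If the study carries a validation
#' cohort it is scored with the discovery-trained models and the
#' discovery threshold; validation labels are only ever touched by the
#' final evaluation step.
#'
#' @param study output of [simulate_study()] (or a list with the same
#'   shape built from real data).
#' @param k number of markers (default 10).
#' @param n_folds cfMeth cross-validation folds (default 10).
#' @param max_fnr FNR bound for the operating cutoff (default 0.02).
#' @param config an [infer_config()].
#' @param min_delta,alpha DMR-calling thresholds.
#' @param seed integer seed for fold assignment, forests and bootstrap.
#' @param n_boot bootstrap replicates in evaluation.
#' @return list with `dmrs`, `panel`, `profiles`, `markers`, `cfmeth`,
#'   `combined`, `threshold`, `discovery` (scores + `model_result`s) and,
#'   when present, `validation`.
#' @export
run_cfmeth_pipeline <- function(study, k = 10L, n_folds = 10L,
                                max_fnr = 0.02, config = infer_config(),
                                min_delta = 0.2, alpha = 0.05, seed = 1L,
                                n_boot = 2000L) {
  map <- study$map
  regions <- segment_candidate_regions(map)
  dmrs <- call_dmrs(regions, study$tissues, min_delta = min_delta,
                    alpha = alpha)
  panel <- build_reference_panel(dmrs, study$tissues)

  tab_d <- study$discovery$table
  prof_d <- build_marker_profiles(study$discovery$samples, panel,
                                  labels = tab_d$label, config = config)
  markers <- select_markers(prof_d, tab_d$label, k = k)
  cfmeth <- train_cfmeth(prof_d$ratios[, markers, drop = FALSE],
                         tab_d$label, n_folds = n_folds, seed = seed)
  combined <- train_combined(cfmeth$oof_scores, tab_d, tab_d$label,
                             seed = seed)
  threshold <- select_cutoff(combined$scores, tab_d$label, max_fnr = max_fnr)

  disc <- list(
    cfmeth_scores = cfmeth$oof_scores,
    combined_scores = combined$scores,
    cfmeth_eval = evaluate_model(cfmeth$oof_scores, tab_d$label,
                                 threshold = 0.5, stages = tab_d$stage,
                                 n_boot = n_boot, seed = seed),
    combined_eval = evaluate_model(combined$scores, tab_d$label,
                                   threshold = threshold,
                                   stages = tab_d$stage,
                                   n_boot = n_boot, seed = seed))

  out <- list(dmrs = dmrs, panel = panel, profiles = prof_d,
              markers = markers, cfmeth = cfmeth, combined = combined,
              threshold = threshold, discovery = disc)

  if (!is.null(study$validation)) {
    tab_v <- study$validation$table
    # leakage guard: impute with discovery benign medians, never drop
    # markers, and never look at validation labels before evaluation
    prof_v <- build_marker_profiles(study$validation$samples, panel,
                                    config = config,
                                    impute_values = prof_d$benign_medians,
                                    drop_frac = 1)
    cf_v <- predict(cfmeth, prof_v$ratios)
    cb_v <- predict(combined,
                    data.frame(cfmeth = cf_v,
                               mammography = tab_v$mammography_score,
                               ultrasound = tab_v$ultrasound_score))
    out$validation <- list(
      profiles = prof_v, cfmeth_scores = cf_v, combined_scores = cb_v,
      cfmeth_eval = evaluate_model(cf_v, tab_v$label, threshold = 0.5,
                                   stages = tab_v$stage, n_boot = n_boot,
                                   seed = seed),
      combined_eval = evaluate_model(cb_v, tab_v$label,
                                     threshold = threshold,
                                     stages = tab_v$stage, n_boot = n_boot,
                                     seed = seed))
  }
  out
}
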