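# Cohort-level drivers and the end-to-end pipeline runner: gamma recovery,
# model-selection replicates, decoding and tuning identification, report.

#' Per-subject decoding analysis
#'
#' Preprocesses the localizer and main-task hippocampal series, trains the
#' location decoder on localizer trial samples (window 3-13.5 s), and
#' applies it to the partial trials of the main task (window 3-6 s),
#' returning the successor/predecessor evidence contrast and optionally the
#' time-resolved difference course.
#'
#' @param sim Main-task `subject_data`.
#' @param loc Localizer `localizer_data` for the same subject.
#' @param time_resolved Also compute the per-offset difference course.
#' @return List: `contrast` (successor, predecessor, by_lag), `model`,
#'   `timecourse` (if requested).
#' @export
analyze_subject_decoding <- function(sim, loc, time_resolved = FALSE) {
  blocks <- loc$schedule$blocks[!loc$schedule$blocks$rest, ]
  ts_loc <- preprocess(loc$hippocampus)
  samples <- extract_trial_samples(
    ts_loc, blocks$onset_s, rep(1L, nrow(blocks)), blocks$location,
    window = c(3, 13.5)
  )
  model <- train_decoder(samples)
  ev_main <- sim$design$events
  part <- ev_main[grepl("^partial_", ev_main$trial_type), ]
  shown <- match(sub("^partial_", "", part$trial_type), SEQ_LABELS)
  ts_main <- preprocess(sim$hippocampus)
  main_samples <- extract_trial_samples(ts_main, part$onset_s, part$run,
                                        shown, window = c(3, 6))
  ev <- evidence(model, main_samples)
  out <- list(contrast = evidence_contrast(ev, shown, sim$design$spec),
              model = model)
  if (time_resolved)
    out$timecourse <- time_resolved_evidence(model, ts_main, part$onset_s,
                                             part$run, shown,
                                             sim$design$spec)
  out
}

#' Per-subject localizer tuning analysis
#'
#' Cross-validated localizer evidence (leave-one-cycle-out by default)
#' aggregated into the 4x4 coactivation matrix over sequence locations.
#'
#' @param loc A `localizer_data`.
#' @param roi "hippocampus" or "v1".
#' @param folds Cross-validation folds for [cross_validated_evidence()].
#' @return 4x4 coactivation matrix.
#' @export
analyze_subject_tuning <- function(loc, roi = c("hippocampus", "v1"),
                                   folds = "cycle") {
  roi <- match.arg(roi)
  blocks <- loc$schedule$blocks[!loc$schedule$blocks$rest, ]
  ts <- preprocess(loc[[roi]])
  samples <- extract_trial_samples(
    ts, blocks$onset_s, rep(1L, nrow(blocks)), blocks$location,
    window = c(3, 13.5)
  )
  # leave-one-cycle-out by default: each fold is one full cycle, so every
  # training split stays class-balanced (7 blocks per location)
  fold_id <- if (identical(folds, "cycle")) blocks$cycle else folds
  ev <- cross_validated_evidence(samples, folds = fold_id)
  build_coactivation(ev, blocks$location, loc$spec, baseline = "control")
}

#' Gamma parameter recovery on a synthetic cohort
#'
#' Simulates an SR cohort at each requested true gamma, runs the V1 pathway
#' and the SR fit per subject, and summarizes recovery.
#'
#' @param gammas True discount factors to probe.
#' @param n_subjects Cohort size per gamma.
#' @param seed Base seed (one derived seed per gamma).
#' @param truth Ground-truth template (its `gamma` is overridden).
#' @return Data frame: gamma_true, subject, gamma_hat.
#' @export
gamma_recovery <- function(gammas = c(0.1, 0.3, 0.5, 0.7), n_subjects = 35,
                           seed = 1, truth = ground_truth()) {
  rows <- list()
  for (gi in seq_along(gammas)) {
    truth$generative_model <- "SR"
    truth$gamma <- gammas[gi]
    cohort <- make_cohort(n_subjects, truth, seed = derive_seed(seed, gi))
    profiles <- cohort_v1_profiles(cohort)
    ghat <- vapply(profiles,
                   function(p) fit_model(p, "SR")$params$gamma, numeric(1))
    rows[[gi]] <- data.frame(gamma_true = gammas[gi],
                             subject = seq_len(n_subjects),
                             gamma_hat = ghat)
  }
  do.call(rbind, rows)
}

#' Model-selection consistency over replicate cohorts
#'
#' For each generating model, simulates `n_replicates` seeded cohorts and
#' records which model wins the group-mean-BIC comparison.
#'
#' @param models Generating models to probe.
#' @param n_replicates Replicate cohorts per model.
#' @param n_subjects Cohort size.
#' @param seed Base seed.
#' @param truth Ground-truth template.
#' @return Data frame: generating, replicate, winner.
#' @export
model_selection_replicates <- function(models = c("SR", "CO", "H0"),
                                       n_replicates = 20, n_subjects = 35,
                                       seed = 1, truth = ground_truth()) {
  rows <- list()
  for (m in models) {
    for (r in seq_len(n_replicates)) {
      tr_ <- truth
      tr_$generative_model <- m
      cohort <- make_cohort(n_subjects, tr_,
                            seed = derive_seed(seed, 100 * match(m, models) + r))
      comp <- model_comparison(cohort_v1_profiles(cohort))
      rows[[length(rows) + 1]] <- data.frame(generating = m, replicate = r,
                                             winner = comp$winner)
    }
  }
  do.call(rbind, rows)
}

#' Tuning-identification consistency over replicate cohorts
#'
#' Simulates cohorts with temporal, spatial, or no hippocampal coactivation
#' and records the tuning-comparison winner per replicate. The "none"
#' generating condition is identified when H0 wins.
#'
#' @param tunings Generating tuning types.
#' @param n_replicates Replicates per type.
#' @param n_subjects Cohort size.
#' @param seed Base seed.
#' @param truth Ground-truth template.
#' @return Data frame: generating, replicate, winner.
#' @export
tuning_identification_replicates <- function(tunings = c("temporal",
                                                         "spatial", "none"),
                                             n_replicates = 20,
                                             n_subjects = 35, seed = 1,
                                             truth = ground_truth()) {
  rows <- list()
  for (tn in tunings) {
    for (r in seq_len(n_replicates)) {
      tr_ <- truth
      tr_$hippocampus_tuning <- ground_truth(
        hippocampus_tuning = list(type = tn, intercept = NULL, slope = NULL)
      )$hippocampus_tuning
      cohort <- make_cohort(n_subjects, tr_,
                            seed = derive_seed(seed, 1000 * match(tn, tunings) + r))
      coacts <- list(); specs <- list()
      for (i in seq_len(n_subjects)) {
        loc <- realize_localizer(cohort, i)
        coacts[[i]] <- analyze_subject_tuning(loc, "hippocampus")
        specs[[i]] <- loc$spec
      }
      comp <- compare_tuning(coacts, specs, cohort$layout)
      rows[[length(rows) + 1]] <- data.frame(generating = tn, replicate = r,
                                             winner = comp$winner)
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic pipeline and write a report
#'
#' Executes simulate -> V1 GLM and model comparison -> hippocampal decoding
#' -> tuning comparison on one seeded cohort and writes a JSON report with
#' the fitted gamma distribution, model-comparison winner,
#' successor/predecessor contrasts, tuning winner and a provenance block.
#'
#' @param config Named list: `seed` (mandatory), `n_subjects`, `truth` (a
#'   [ground_truth()]), `out_dir` (optional; report and tables written
#'   there), `n_runs`, and toggles `do_decoding`, `do_tuning`.
#' @return The report list, invisibly written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is given.
#' @export
run_pipeline <- function(config) {
  defaults <- list(n_subjects = 35, truth = ground_truth(), out_dir = NULL,
                   n_runs = 3, do_decoding = TRUE, do_tuning = TRUE)
  unknown <- setdiff(names(config), c("seed", names(defaults)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("`seed` is mandatory")
  config <- utils::modifyList(defaults, config)

  cohort <- make_cohort(config$n_subjects, config$truth, seed = config$seed,
                        n_runs = config$n_runs)
  profiles <- list(); contrasts <- list(); coacts <- list(); specs <- list()
  sp_v1 <- matrix(NA_real_, config$n_subjects, 2,
                  dimnames = list(NULL, c("successor", "predecessor")))
  for (i in seq_len(config$n_subjects)) {
    sim <- realize_subject(cohort, i)
    profiles[[i]] <- analyze_subject_v1(sim)
    sp <- successor_predecessor_average(profiles[[i]])
    sp_v1[i, ] <- c(sp$successor, sp$predecessor)
    if (config$do_decoding || config$do_tuning) {
      loc <- realize_localizer(cohort, i)
      if (config$do_decoding)
        contrasts[[i]] <- analyze_subject_decoding(sim, loc)$contrast
      if (config$do_tuning) {
        coacts[[i]] <- analyze_subject_tuning(loc, "hippocampus")
        specs[[i]] <- loc$spec
      }
    }
  }
  comp <- model_comparison(profiles)
  gammas <- comp$fits$gamma[comp$fits$model == "SR"]
  report <- list(
    provenance = list(seed = config$seed, n_subjects = config$n_subjects,
                      n_runs = config$n_runs,
                      generative_model = config$truth$generative_model,
                      package_version =
                        as.character(utils::packageVersion("srmap"))),
    v1 = list(
      gamma_mean = mean(gammas), gamma_sd = stats::sd(gammas),
      successor_mean = mean(sp_v1[, "successor"]),
      predecessor_mean = mean(sp_v1[, "predecessor"]),
      successor_vs_predecessor = paired_t(sp_v1[, "successor"],
                                          sp_v1[, "predecessor"]),
      model_winner = comp$winner,
      mean_bic = as.list(comp$mean_bic)
    )
  )
  if (config$do_decoding) {
    succ <- vapply(contrasts, function(x) x$successor, numeric(1))
    pred <- vapply(contrasts, function(x) x$predecessor, numeric(1))
    report$hippocampus <- list(
      successor_evidence = mean(succ), predecessor_evidence = mean(pred),
      successor_vs_predecessor = paired_t(succ, pred)
    )
  }
  if (config$do_tuning) {
    tun <- compare_tuning(coacts, specs, cohort$layout)
    report$tuning <- list(winner = tun$winner,
                          mean_bic = as.list(tun$mean_bic))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
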