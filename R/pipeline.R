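# End-to-end orchestration: synthetic session -> ensembles -> statistics ->
# report, and the shuffle-control multiple-comparison experiment.

#' Pipeline run configuration
#'
#' Bundles every stage's parameters so a run is reproducible from the config
#' and its seed alone. Desk-scale defaults: 60 neurons, 20 adaptation + 60
#' training + 20 open-loop trials at 3 Hz.
#'
#' @param seed run seed
#' @param session a [session_config()]
#' @param specs list of [ensemble_spec()]s embedded in the synthetic data
#' @param n_neurons total neurons in the synthetic recording
#' @param noise_sd dF/F0 noise level
#' @param policy behavior policy for the scripted fish
#' @param k_range NMF orders scanned by AIC
#' @param nmf_restarts,nmf_max_iter,nmf_tol order-scan optimizer settings
#' @param candidate_threshold correlation threshold for candidate screening
#' @param act_threshold,rule_factor classifier activity thresholds
#' @param top_n,bin_width_um,shuffle_repeats spatial-analysis settings
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L,
                            session = session_config(seed = seed),
                            specs = default_ensemble_specs(),
                            n_neurons = 60L, noise_sd = 0.1,
                            policy = "learner_with_halts",
                            k_range = 2:6, nmf_restarts = 2L,
                            nmf_max_iter = 400L, nmf_tol = 1e-5,
                            candidate_threshold = 0.25,
                            act_threshold = 0.3, rule_factor = 3,
                            top_n = 10L, bin_width_um = 37.6,
                            shuffle_repeats = 10L) {
  structure(list(seed = seed, session = session, specs = specs,
                 n_neurons = n_neurons, noise_sd = noise_sd, policy = policy,
                 k_range = k_range, nmf_restarts = nmf_restarts,
                 nmf_max_iter = nmf_max_iter, nmf_tol = nmf_tol,
                 candidate_threshold = candidate_threshold,
                 act_threshold = act_threshold, rule_factor = rule_factor,
                 top_n = top_n, bin_width_um = bin_width_um,
                 shuffle_repeats = shuffle_repeats),
            class = "pipeline_config")
}

#' Run the full synthetic-session analysis pipeline
#'
#' Generates a session with the configured embedded ensembles, classifies
#' every trial, detects the behavioral learning criterion, builds GO/NOGO
#' templates and their similarity traces, factorizes the (zero-clipped)
#' dF/F0 matrix by NMF at the AIC-selected order, screens activations
#' against B(t)/R(t), classifies every candidate ensemble, runs the
#' correlation-versus-distance analysis on each classified ensemble, and
#' compares the found labels with the generator's ground truth.
#'
#' @param config a [pipeline_config()]
#' @param output_dir optional directory; when given, the schedule, behavior,
#'   fluorescence matrix, ground truth and the report are written there
#' @return a `pipeline_report` list (see elements in the description)
#' @export
run_full_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  cfg <- config
  schedule <- generate_experiment(cfg$session)
  behavior <- simulate_agent_behavior(schedule, policy = cfg$policy,
                                      seed = cfg$seed)
  outcomes <- classify_trials(behavior, schedule)
  train <- outcomes[outcomes$phase == "training", ]
  learn_trial <- learning_criterion(train)

  act <- generate_activity(schedule, behavior, cfg$specs,
                           n_neurons = cfg$n_neurons,
                           noise_sd = cfg$noise_sd, seed = cfg$seed)
  dff <- act$fluor$dff

  templates <- list()
  similarity <- list()
  if (!is.na(learn_trial)) {
    for (ty in c("GO", "NOGO")) {
      tm <- tryCatch(build_template(dff, behavior$time, schedule, outcomes,
                                    learn_trial, type = ty),
                     error = function(e) NULL)
      if (is.null(tm)) next
      templates[[ty]] <- tm
      si <- similarity_trace(dff, tm)
      similarity[[ty]] <- list(max = max(si), mean = mean(si),
                               n_trials = attr(tm, "n_trials"))
    }
  }

  D <- pmax(dff, 0)
  sel <- select_order_aic(D, k_range = cfg$k_range, seed = cfg$seed,
                          restarts = cfg$nmf_restarts,
                          max_iter = cfg$nmf_max_iter, tol = cfg$nmf_tol)
  fit <- sel$fit
  regs <- environment_regressors(behavior)
  cand <- candidate_ensembles(fit$T, regs$B, regs$R,
                              threshold = cfg$candidate_threshold)
  labels <- lapply(which(cand$candidate), function(i) {
    cl <- classify_ensemble(fit$T[i, ], behavior, schedule, outcomes,
                            learn_trial, cor_b = cand$cor_b[i],
                            cor_r = cand$cor_r[i],
                            act_threshold = cfg$act_threshold,
                            rule_factor = cfg$rule_factor)
    cl$ensemble <- i
    cl
  })
  found <- vapply(labels, `[[`, character(1), "label")

  spatial <- lapply(labels[found != "unclassified"], function(cl) {
    i <- cl$ensemble
    if (sum(fit$P[, i] > 0) < cfg$top_n) return(NULL)
    pairs <- pairwise_corr_distance(fit$P[, i], dff, act$fluor$centroids,
                                    top_n = cfg$top_n)
    list(label = cl$label, ensemble = i,
         curve = bin_curve(pairs, cfg$bin_width_um),
         shuffle = position_shuffle_curve(dff, act$fluor$centroids,
                                          n_neurons = cfg$top_n,
                                          repeats = cfg$shuffle_repeats,
                                          bin_width = cfg$bin_width_um,
                                          seed = cfg$seed))
  })

  truth_labels <- act$truth$labels
  report <- structure(list(
    seed = cfg$seed,
    n_neurons = nrow(dff), n_frames = ncol(dff),
    n_trials = nrow(schedule),
    learn_trial = learn_trial,
    outcomes = outcomes,
    similarity = similarity,
    aic = sel$aic, k = sel$k,
    candidates = cand,
    labels = labels,
    found_labels = found,
    truth_labels = truth_labels,
    labels_recovered = sort(intersect(found, truth_labels)),
    all_labels_recovered = all(truth_labels %in% found),
    spatial = spatial
  ), class = "pipeline_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_session_csv(schedule, file.path(output_dir, "schedule.csv"))
    write_session_csv(behavior, file.path(output_dir, "behavior.csv"))
    write_session_csv(outcomes, file.path(output_dir, "outcomes.csv"))
    write_fluor_csv(act$fluor, file.path(output_dir, "dff.csv"))
    jsonlite::write_json(
      list(labels = truth_labels,
           membership = act$truth$membership),
      file.path(output_dir, "ground_truth.json"), digits = NA)
    jsonlite::write_json(report_summary(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-friendly digest of a pipeline report.
report_summary <- function(report) {
  list(seed = report$seed,
       n_neurons = report$n_neurons, n_frames = report$n_frames,
       learn_trial = report$learn_trial,
       k = report$k, aic = report$aic,
       n_candidates = sum(report$candidates$candidate),
       found_labels = report$found_labels,
       labels_recovered = report$labels_recovered,
       all_labels_recovered = report$all_labels_recovered)
}

#' Shuffle-control experiment for the multiple-comparison problem
#'
#' Generates `n_sets` pairwise-swap shuffled copies of the activity matrix;
#' each set is factorized at its own AIC-selected order, screened against
#' B(t)/R(t) at the 0.25 threshold, and its candidates classified. On
#' shuffled data no ensemble should pass the selection.
#'
#' @param dff dF/F0 matrix neurons x frames (the unshuffled data)
#' @param behavior `behavior_trace` of the same session
#' @param schedule `trial_schedule`
#' @param config a [pipeline_config()] (NMF/classifier settings)
#' @param n_sets shuffled sets (default 3)
#' @param k_range NMF orders scanned per set
#' @param seed seed
#' @return data frame with one row per set: `set`, `k`, `n_candidates`,
#'   `n_classified`
#' @export
run_shuffle_control <- function(dff, behavior, schedule,
                                config = pipeline_config(), n_sets = 3L,
                                k_range = 2:4, seed = config$seed) {
  outcomes <- classify_trials(behavior, schedule)
  learn_trial <- learning_criterion(outcomes[outcomes$phase == "training", ])
  regs <- environment_regressors(behavior)
  rows <- lapply(seq_len(n_sets), function(s) {
    Ds <- pmax(shuffle_activity(dff, seed = seed + 17L * s), 0)
    sel <- select_order_aic(Ds, k_range = k_range, seed = seed + 1000L * s,
                            restarts = config$nmf_restarts,
                            max_iter = config$nmf_max_iter,
                            tol = config$nmf_tol)
    cand <- candidate_ensembles(sel$fit$T, regs$B, regs$R,
                                threshold = config$candidate_threshold)
    labs <- vapply(which(cand$candidate), function(i) {
      classify_ensemble(sel$fit$T[i, ], behavior, schedule, outcomes,
                        learn_trial, cor_b = cand$cor_b[i],
                        cor_r = cand$cor_r[i],
                        act_threshold = config$act_threshold,
                        rule_factor = config$rule_factor)$label
    }, character(1))
    data.frame(set = s, k = sel$k,
               n_candidates = sum(cand$candidate),
               n_classified = sum(labs != "unclassified"))
  })
  do.call(rbind, rows)
}
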