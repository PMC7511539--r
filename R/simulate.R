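# Synthetic learner cohorts. The generator emulates the structure of the
# study: 13 HIIT / 12 LIIT participants, a 12-note 75-bpm target melody,
# criterion-terminated acquisition (blocks 1-3: 5 listen + 5 train + 5 test;
# blocks 4-6: 5 listen + 5 test), three 10-trial retention tests (R1, R24,
# R7) and a six-block transfer melody practiced without early stopping.
# Only test trials carry dependent measures, so only test trials are
# simulated and scored.

local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(base::on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible()
}

#' Synthetic learner parameters
#'
#' One participant's latent learning curve. Per-note pitch correctness on
#' test trial t follows the exponential law
#' `p(t) = asymptote - (asymptote - p0) * exp(-rate * t)`; incorrect notes
#' are realized as deletions (with probability `deletion_rate`, given
#' incorrect) or substitutions (uniform over the other four study pitches),
#' and `insertion_rate` extra notes per trial (Poisson) are inserted at
#' uniformly random positions. Inter-onset timing noise is multiplicative
#' lognormal with unit mean and coefficient of variation
#' `CV(t) = timing_cv_floor + (timing_cv0 - timing_cv_floor) * exp(-timing_rate * t)`.
#'
#' @param p0 Initial per-note correctness probability.
#' @param asymptote Ceiling probability (>= `p0`).
#' @param rate Per-trial exponential learning rate (>= 0).
#' @param insertion_rate Expected inserted notes per trial (>= 0).
#' @param deletion_rate Probability that an incorrect note is omitted rather
#'   than substituted.
#' @param timing_cv0,timing_cv_floor Initial and asymptotic IOI coefficient
#'   of variation.
#' @param timing_rate Per-trial decay rate of the CV (>= 0).
#' @return A list of class `"learner_params"`.
#' @export
learner_params <- function(p0 = 0.3, asymptote = 0.95, rate = 0.1,
                           insertion_rate = 0.3, deletion_rate = 0.3,
                           timing_cv0 = 0.12, timing_cv_floor = 0.04,
                           timing_rate = 0.08) {
  stopifnot(p0 >= 0, p0 <= 1, asymptote >= p0, asymptote <= 1,
            rate >= 0, insertion_rate >= 0,
            deletion_rate >= 0, deletion_rate <= 1,
            timing_cv0 >= 0, timing_cv_floor >= 0, timing_rate >= 0)
  structure(as.list(environment()), class = "learner_params")
}

#' Draw one participant's learner parameters from the default population
#'
#' Heterogeneous population emulating the wide inter-individual variability
#' seen in novice melody learners: some reach ceiling quickly, some never
#' master the sequence. Consumes the current RNG stream.
#'
#' @return A [learner_params()] object.
#' @export
sample_learner_params <- function() {
  asym <- 1 - 0.4 * stats::rbeta(1, 1, 3)
  learner_params(
    p0 = stats::runif(1, 0.10, min(0.5, asym)),
    asymptote = asym,
    rate = stats::rlnorm(1, log(0.10), 0.5),
    insertion_rate = 0.3,
    deletion_rate = 0.3,
    timing_cv0 = stats::runif(1, 0.08, 0.16),
    timing_cv_floor = stats::runif(1, 0.03, 0.06),
    timing_rate = 0.08
  )
}

#' Simulate a single test-trial performance
#'
#' Realizes one trial from a learner's current state (see [learner_params()]
#' for the generative model). Deterministic for a fixed RNG state.
#'
#' @param params A [learner_params()] object.
#' @param trial_number Cumulative test-trial index t (1, 2, ...).
#' @param melody Target melody.
#' @param ... Metadata fields passed to [performance()].
#' @return A [performance()] object.
#' @examples
#' set.seed(1)
#' p <- simulate_trial(learner_params(p0 = 1, asymptote = 1, timing_cv0 = 0,
#'                                    timing_cv_floor = 0, insertion_rate = 0),
#'                     1, study_melody(1))
#' score_trial(p, study_melody(1)) # noiseless limit: 100 / 100
#' @export
simulate_trial <- function(params, trial_number, melody, ...) {
  ev <- generate_trial_events(params, trial_number, melody)
  performance(pitch = ev$pitch, onset = ev$onset, ...)
}

# generative core shared by simulate_trial and the batch simulator; returns
# bare pitch/onset vectors already in performance order
generate_trial_events <- function(params, trial_number, melody) {
  n <- length(melody$pitches)
  p <- params$asymptote -
    (params$asymptote - params$p0) * exp(-params$rate * trial_number)
  correct <- stats::runif(n) < p
  del <- !correct & (stats::runif(n) < params$deletion_rate)
  sub <- !correct & !del
  alphabet <- sort(unique(melody$pitches))
  pitches <- melody$pitches
  if (any(sub)) {
    k <- length(alphabet)
    shift <- sample.int(k - 1L, sum(sub), replace = TRUE)
    pitches[sub] <- alphabet[(match(pitches[sub], alphabet) - 1L + shift) %% k + 1L]
  }
  nominal <- melody_onsets(melody)
  keep_pitch <- pitches[!del]
  keep_nominal <- nominal[!del]
  n_ins <- stats::rpois(1, params$insertion_rate)
  if (n_ins > 0) {
    span <- max(nominal)
    keep_pitch <- c(keep_pitch, sample(alphabet, n_ins, replace = TRUE))
    keep_nominal <- c(keep_nominal, stats::runif(n_ins, 0, span))
  }
  if (!length(keep_pitch)) return(list(pitch = integer(0), onset = numeric(0)))
  ord <- order(keep_nominal, keep_pitch)
  keep_pitch <- keep_pitch[ord]
  keep_nominal <- keep_nominal[ord]
  cv <- params$timing_cv_floor +
    (params$timing_cv0 - params$timing_cv_floor) * exp(-params$timing_rate * trial_number)
  iois <- diff(c(0, keep_nominal))
  if (cv > 0) {
    s2 <- log(1 + cv^2)
    iois <- iois * stats::rlnorm(length(iois), -s2 / 2, sqrt(s2))
  }
  list(pitch = keep_pitch, onset = cumsum(iois))
}

# lean scoring used inside the batch simulator: same C++ primitives as
# score_trial, no object construction. Returns c(pitch, rhythm, n_performed,
# n_matched).
score_events_fast <- function(pitch, onset, melody, tol_frac, first_mode) {
  pairs <- lcs_match_cpp(as.integer(pitch), melody$pitches)
  counts <- rhythm_count_cpp(pairs, onset, cumsum(c(0, melody$expected_iois)),
                             tol_frac, first_mode)
  n_t <- length(melody$pitches)
  n_p <- length(pitch)
  denom <- max(n_t - 1L, n_p - 1L)
  c(100 * nrow(pairs) / max(n_t, n_p),
    if (denom >= 1L) 100 * counts[2] / denom else 0,
    n_p, nrow(pairs))
}

#' Criterion-training stop rule
#'
#' Practice stops once the participant has produced three consecutive correct
#' test trials, a correct trial being the exact target pitch sequence with no
#' extra or missing notes (rhythm is not considered).
#'
#' @param flags Logical vector of per-test-trial pitch-sequence-correct
#'   flags, in trial order.
#' @return `TRUE` if the last three flags are all `TRUE`.
#' @export
criterion_check <- function(flags) {
  length(flags) >= 3L && all(utils::tail(flags, 3L))
}

trial_is_correct <- function(score) {
  score$pitch_accuracy == 100 && score$n_performed == score$n_target
}

#' Simulate one participant's acquisition phase
#'
#' Generates test trials through blocks 1-6 (5 test trials per block).
#' Participants complete blocks 1-3 as a minimum; from the end of block 3
#' onward the criterion rule applies — practice stops as soon as the last
#' three test trials are all pitch-perfect (a qualifying run inside blocks
#' 1-3 only stops practice once block 3 finishes, and only if it is still the
#' most recent run). Without the criterion the phase ends after block 6.
#'
#' @param params Learner parameters.
#' @param melody Target melody.
#' @param tol,first_note Scoring settings (see [rhythm_accuracy()]).
#' @param apply_criterion If `FALSE` (transfer phase), all six blocks are
#'   always completed.
#' @param trials_per_block Test trials per block (default 5).
#' @param t_offset Added to the cumulative trial number (0 for a fresh
#'   melody).
#' @return A list with `scores` (tibble: block, trial_index, pitch_accuracy,
#'   rhythm_accuracy, n_performed, correct), `stopped_early`, and `t_final`
#'   (cumulative test-trial count).
#' @export
simulate_acquisition <- function(params, melody, tol = rhythm_tolerance(),
                                 first_note = "grid", apply_criterion = TRUE,
                                 trials_per_block = 5L, t_offset = 0L) {
  first_note <- match.arg(first_note, c("grid", "always"))
  tol_frac <- as_tol_fraction(tol)
  first_mode <- if (first_note == "always") 1L else 0L
  n_t <- length(melody$pitches)
  rows <- matrix(NA_real_, 6L * trials_per_block, 5L,
                 dimnames = list(NULL, c("block", "trial_index",
                                         "pitch_accuracy", "rhythm_accuracy",
                                         "n_performed")))
  flags <- logical(0)
  t <- 0L
  stopped <- FALSE
  for (block in 1:6) {
    for (j in seq_len(trials_per_block)) {
      t <- t + 1L
      ev <- generate_trial_events(params, t + t_offset, melody)
      s <- score_events_fast(ev$pitch, ev$onset, melody, tol_frac, first_mode)
      flags[t] <- s[1] == 100 && s[3] == n_t
      rows[t, ] <- c(block, t, s[1], s[2], s[3])
      if (apply_criterion && block >= 4L && criterion_check(flags)) {
        stopped <- TRUE
        break
      }
    }
    if (stopped) break
    if (apply_criterion && block == 3L && criterion_check(flags)) {
      stopped <- TRUE
      break
    }
  }
  scores <- tibble::as_tibble(rows[seq_len(t), , drop = FALSE])
  scores$correct <- flags
  list(scores = scores, stopped_early = stopped, t_final = t)
}

#' Cohort configuration
#'
#' Bundles the study conditions for [simulate_study()]: group sizes, melodies,
#' scoring tolerance, trial plan, group effects and the master seed. The
#' defaults are the study's conditions (13 HIIT / 12 LIIT; 12-note 75-bpm
#' melodies; tolerance 0.10; 5 test trials per block; 10 test trials per
#' retention session) with null group effects and a rhythm consolidation gain
#' of 5 percentage points at the delayed retention sessions.
#'
#' @param n_hiit,n_liit Participants per group.
#' @param melody,transfer_melody Target melodies for acquisition/retention
#'   and for transfer.
#' @param tol Rhythm tolerance fraction or [rhythm_tolerance()].
#' @param first_note First-matched-note rule, `"grid"` or `"always"`.
#' @param retention_offset Percentage points added to HIIT scores (both
#'   measures) at R24 and R7 — the group consolidation effect under study.
#' @param transfer_slope_boost Percentage points per (block - 1) added to
#'   HIIT transfer scores — the group transfer-rate effect.
#' @param consolidation_gain Percentage points added to *both* groups' rhythm
#'   accuracy at R24 and R7 (sleep-dependent consolidation common to all
#'   participants).
#' @param retention_trials Test trials per retention session (default 10).
#' @param trials_per_block Test trials per block (default 5).
#' @param phases Which phases to simulate (subset of
#'   `c("acquisition", "retention", "transfer")`).
#' @param learner_sampler Function returning a [learner_params()] for each
#'   participant (default [sample_learner_params()]); pass a fixed-parameter
#'   function for homogeneous cohorts.
#' @param training_sampler Function returning one musical-training value in
#'   months (default lognormal, median about 8 months, capped at 60,
#'   range-matched to the packaged participant table).
#' @param seed Integer master seed; a fixed config (including seed) yields an
#'   identical trial table.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_hiit = 13L, n_liit = 12L,
                          melody = study_melody(1),
                          transfer_melody = study_melody(2),
                          tol = rhythm_tolerance(), first_note = "grid",
                          retention_offset = 0, transfer_slope_boost = 0,
                          consolidation_gain = 5,
                          retention_trials = 10L, trials_per_block = 5L,
                          phases = c("acquisition", "retention", "transfer"),
                          learner_sampler = sample_learner_params,
                          training_sampler = function()
                            round(min(stats::rlnorm(1, log(8), 1.1), 60), 1),
                          seed = 1L) {
  stopifnot(n_hiit >= 2L, n_liit >= 2L)
  phases <- match.arg(phases, c("acquisition", "retention", "transfer"),
                      several.ok = TRUE)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a full study cohort
#'
#' Generates every participant's test trials (acquisition with criterion
#' stopping, the three retention sessions with the learner state frozen at
#' the end of acquisition, and six transfer blocks on the second melody with
#' no early stop), scores them, and applies the configured additive group
#' effects on the accuracy scale (truncated to `[0, 100]`).
#'
#' @param config A [cohort_config()].
#' @return A long-format tibble (one row per test trial) with columns
#'   `participant_id`, `group`, `phase`, `session` (Acq/R1/R24/R7/Tran),
#'   `block`, `trial_index`, `pitch_accuracy`, `rhythm_accuracy`,
#'   `musical_training`. The config is attached as attribute `"config"`.
#' @examples
#' trials <- simulate_study(cohort_config(n_hiit = 2, n_liit = 2, seed = 7,
#'                                        phases = "acquisition"))
#' head(trials)
#' @export
simulate_study <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$seed)
  n <- config$n_hiit + config$n_liit
  ids <- sprintf("P%02d", seq_len(n))
  groups <- c(rep("HIIT", config$n_hiit), rep("LIIT", config$n_liit))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    params <- config$learner_sampler()
    mt <- config$training_sampler()
    rows <- list()
    t_final <- 0L
    if ("acquisition" %in% config$phases) {
      acq <- simulate_acquisition(params, config$melody, config$tol,
                                  config$first_note, apply_criterion = TRUE,
                                  trials_per_block = config$trials_per_block)
      t_final <- acq$t_final
      rows$acq <- tibble::tibble(
        phase = "acquisition", session = "Acq",
        block = as.integer(acq$scores$block),
        trial_index = as.integer(acq$scores$trial_index),
        pitch_accuracy = acq$scores$pitch_accuracy,
        rhythm_accuracy = acq$scores$rhythm_accuracy
      )
    }
    if ("retention" %in% config$phases) {
      tol_frac <- as_tol_fraction(config$tol)
      first_mode <- if (config$first_note == "always") 1L else 0L
      for (sess in c("R1", "R24", "R7")) {
        sc <- vapply(seq_len(config$retention_trials), function(j) {
          ev <- generate_trial_events(params, t_final, config$melody)
          score_events_fast(ev$pitch, ev$onset, config$melody,
                            tol_frac, first_mode)[1:2]
        }, numeric(2))
        rows[[sess]] <- tibble::tibble(
          phase = "retention", session = sess, block = NA_integer_,
          trial_index = seq_len(config$retention_trials),
          pitch_accuracy = sc[1, ], rhythm_accuracy = sc[2, ]
        )
      }
    }
    if ("transfer" %in% config$phases) {
      tran <- simulate_acquisition(params, config$transfer_melody, config$tol,
                                   config$first_note, apply_criterion = FALSE,
                                   trials_per_block = config$trials_per_block)
      rows$tran <- tibble::tibble(
        phase = "transfer", session = "Tran",
        block = as.integer(tran$scores$block),
        trial_index = as.integer(tran$scores$trial_index),
        pitch_accuracy = tran$scores$pitch_accuracy,
        rhythm_accuracy = tran$scores$rhythm_accuracy
      )
    }
    tab <- dplyr::bind_rows(rows)
    tab$participant_id <- ids[i]
    tab$group <- groups[i]
    tab$musical_training <- mt
    out[[i]] <- tab
  }
  trials <- dplyr::bind_rows(out)
  trials <- trials[, c("participant_id", "group", "phase", "session", "block",
                       "trial_index", "pitch_accuracy", "rhythm_accuracy",
                       "musical_training")]
  trials <- apply_group_effects(trials, config)
  attr(trials, "config") <- config
  trials
}

clip01 <- function(x) pmin(pmax(x, 0), 100)

apply_group_effects <- function(trials, config) {
  late <- trials$session %in% c("R24", "R7")
  if (config$consolidation_gain != 0) {
    trials$rhythm_accuracy[late] <-
      clip01(trials$rhythm_accuracy[late] + config$consolidation_gain)
  }
  if (config$retention_offset != 0) {
    idx <- late & trials$group == "HIIT"
    trials$pitch_accuracy[idx] <- clip01(trials$pitch_accuracy[idx] + config$retention_offset)
    trials$rhythm_accuracy[idx] <- clip01(trials$rhythm_accuracy[idx] + config$retention_offset)
  }
  if (config$transfer_slope_boost != 0) {
    idx <- trials$phase == "transfer" & trials$group == "HIIT"
    boost <- config$transfer_slope_boost * (trials$block[idx] - 1L)
    trials$pitch_accuracy[idx] <- clip01(trials$pitch_accuracy[idx] + boost)
    trials$rhythm_accuracy[idx] <- clip01(trials$rhythm_accuracy[idx] + boost)
  }
  trials
}

#' End-of-acquisition summary: mean of the last 10 trials
#'
#' Because trials-to-criterion varies, each participant's end-of-acquisition
#' performance (Acq) is the arithmetic mean of their final 10 test trials;
#' participants with fewer than 10 trials contribute the mean of all their
#' trials (with a message).
#'
#' @param scores Numeric vector of one participant's per-trial accuracies, in
#'   trial order.
#' @return The summary mean.
#' @export
last10_average <- function(scores) {
  if (!length(scores)) stop("no trials to summarize", call. = FALSE)
  if (length(scores) < 10L) {
    message("fewer than 10 trials; averaging all ", length(scores))
    return(mean(scores))
  }
  mean(utils::tail(scores, 10L))
}

#' Session-level summaries for the retention analysis
#'
#' Collapses the trial table to one value per participant and session:
#' Acq is the last-10-trials mean of acquisition; R1, R24 and R7 are the
#' means of their 10 test trials.
#'
#' @param trials A [simulate_study()] table (or any TrialScore table).
#' @return A tibble with columns `participant_id`, `group`,
#'   `musical_training`, `session` (factor Acq/R1/R24/R7), `pitch_accuracy`,
#'   `rhythm_accuracy`.
#' @export
summarize_sessions <- function(trials) {
  acq <- trials[trials$session == "Acq", ]
  acq <- dplyr::summarise(
    dplyr::group_by(acq, participant_id, group, musical_training),
    session = "Acq",
    pitch_accuracy = last10_average(pitch_accuracy[order(trial_index)]),
    rhythm_accuracy = last10_average(rhythm_accuracy[order(trial_index)]),
    .groups = "drop")
  ret <- trials[trials$session %in% c("R1", "R24", "R7"), ]
  ret <- dplyr::summarise(
    dplyr::group_by(ret, participant_id, group, musical_training, session),
    pitch_accuracy = mean(pitch_accuracy),
    rhythm_accuracy = mean(rhythm_accuracy),
    .groups = "drop")
  out <- dplyr::bind_rows(acq, ret)
  out$session <- factor(out$session, levels = c("Acq", "R1", "R24", "R7"))
  out[order(out$participant_id, out$session), ]
}

#' Block-level summaries for the transfer / acquisition-vs-transfer analyses
#'
#' One value per participant, phase and block (mean over that block's test
#' trials).
#'
#' @param trials A TrialScore table.
#' @param phases Phases to keep (default acquisition and transfer).
#' @return A tibble with `participant_id`, `group`, `musical_training`,
#'   `phase`, `session`, `block`, `pitch_accuracy`, `rhythm_accuracy`.
#' @export
summarize_blocks <- function(trials, phases = c("acquisition", "transfer")) {
  d <- trials[trials$phase %in% phases & !is.na(trials$block), ]
  dplyr::summarise(
    dplyr::group_by(d, participant_id, group, musical_training, phase,
                    session, block),
    pitch_accuracy = mean(pitch_accuracy),
    rhythm_accuracy = mean(rhythm_accuracy),
    .groups = "drop")
}
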