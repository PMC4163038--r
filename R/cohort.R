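#' Specify a synthetic cohort
#'
#' Describes the groups of a simulated lesion-study cohort. Each group is a
#' list with elements:
#'
#' * `label`: group name.
#' * `n_subjects`: number of subjects (>= 1).
#' * `perception`, `memory`: per-domain generative metacognitive efficiency,
#'   either `list(efficiency_mean =, efficiency_sd =)` (subject-level targets
#'   drawn from a normal distribution, truncated to \[0.05, 1.5\], and mapped
#'   to noise levels through a simulated calibration curve) or direct noise
#'   parameters `list(confidence_noise_sd =, decision_extra_noise_sd =)`.
#'
#' Every subject completes one perception session (8 blocks x 25 staircased
#' trials) and one memory session (4 blocks x 50 trials; study times 0.5, 1,
#' 1, 1.5 minutes), 200 trials per task.
#'
#' @param groups List of group descriptions (see above).
#' @param seed Integer master seed; everything downstream derives from it.
#' @param observer Template [observer_model()] shared by all subjects.
#' @param calibration_trials Trials per point of the efficiency-noise
#'   calibration curve (default 4e4).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L, observer = observer_model(),
                        calibration_trials = 4e4) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n_subjects) || g$n_subjects < 1) {
      stop("each group needs a `label` and `n_subjects` >= 1")
    }
    for (dom in c("perception", "memory")) {
      spec <- g[[dom]]
      if (is.null(spec) ||
          !(("efficiency_mean" %in% names(spec)) ||
            any(c("confidence_noise_sd", "decision_extra_noise_sd") %in% names(spec)))) {
        stop(sprintf(
          "group '%s' needs a `%s` spec with either efficiency_mean/efficiency_sd or direct noise parameters",
          g$label, dom
        ))
      }
    }
  }
  structure(
    list(groups = groups, seed = as.integer(seed), observer = observer,
         calibration_trials = calibration_trials,
         design = list(perception = c(blocks = 8L, trials = 25L),
                       memory = c(blocks = 4L, trials = 50L))),
    class = "cohort_spec"
  )
}

#' Cohort specification mirroring a three-group lesion study
#'
#' A convenience [cohort_spec()] with an anterior-prefrontal-lesion-like
#' group (n = 7; perceptual efficiency well below optimal, memory efficiency
#' near optimal), a temporal-lobe-lesion-like group (n = 11) and a healthy
#' control group (n = 19), using group-mean generative efficiencies of
#' 0.46/1.04, 0.84/0.92 and 0.88/1.09 (perception/memory) with
#' between-subject SD `efficiency_sd`.
#'
#' @param seed Integer master seed.
#' @param efficiency_sd Between-subject SD of generative efficiency
#'   (default 0.15).
#' @param ... Passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
example_cohort_spec <- function(seed = 1L, efficiency_sd = 0.15, ...) {
  grp <- function(label, n, mp, mm) {
    list(label = label, n_subjects = n,
         perception = list(efficiency_mean = mp, efficiency_sd = efficiency_sd),
         memory = list(efficiency_mean = mm, efficiency_sd = efficiency_sd))
  }
  cohort_spec(
    groups = list(
      grp("anterior_pfc", 7L, 0.46, 1.04),
      grp("temporal_lobe", 11L, 0.84, 0.92),
      grp("healthy_control", 19L, 0.88, 1.09)
    ),
    seed = seed, ...
  )
}

#' Generate a synthetic cohort
#'
#' Simulates every subject of a [cohort_spec()]: per-subject generative
#' efficiencies are drawn (or direct noise parameters taken) per group and
#' domain, mapped to confidence/decision noise via a calibration curve
#' simulated once per domain, and each subject completes one staircased
#' perception session and one memory session of 200 trials each. The output
#' is fully reproducible from the spec's seed.
#'
#' @param spec A `cohort_spec`.
#' @return A list with `trials` (trial table for all subjects, see
#'   [trial-table]) and `ground_truth` (one row per subject x domain:
#'   generative target efficiency and noise parameters, plus the evidence
#'   scale).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  needs_curve <- vapply(spec$groups, function(g) {
    any(vapply(c("perception", "memory"),
               function(d) "efficiency_mean" %in% names(g[[d]]), logical(1)))
  }, logical(1))
  curves <- list()
  if (any(needs_curve)) {
    curves <- list(
      perception = efficiency_noise_curve("perception", spec$observer,
                                          n_trials = spec$calibration_trials,
                                          seed = derive_seed(spec$seed, 11L)),
      memory = efficiency_noise_curve("memory", spec$observer,
                                      n_trials = spec$calibration_trials,
                                      seed = derive_seed(spec$seed, 12L))
    )
  }

  trials <- list()
  truth <- list()
  subj_counter <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    for (si in seq_len(g$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("%s_%02d", g$label, si)
      for (di in 1:2) {
        dom <- c("perception", "memory")[di]
        dspec <- g[[dom]]
        if ("efficiency_mean" %in% names(dspec)) {
          sd_ <- dspec$efficiency_sd %||% 0
          target <- with_seed(derive_seed(spec$seed, gi, si, di, 1L), {
            min(max(rnorm(1, dspec$efficiency_mean, sd_), 0.05), 1.5)
          })
          noise <- noise_for_efficiency(curves[[dom]], target)
        } else {
          noise <- list(
            confidence_noise_sd = dspec$confidence_noise_sd %||% 0,
            decision_extra_noise_sd = dspec$decision_extra_noise_sd %||% 0
          )
          target <- NA_real_
        }
        obs <- spec$observer
        obs$confidence_noise_sd <- noise$confidence_noise_sd
        obs$decision_extra_noise_sd <- noise$decision_extra_noise_sd
        sess_seed <- derive_seed(spec$seed, gi, si, di, 2L)
        sess <- if (dom == "perception") {
          simulate_perception_session(obs, seed = sess_seed,
                                      subject_id = sid, group = g$label)
        } else {
          simulate_memory_session(obs, seed = sess_seed,
                                  subject_id = sid, group = g$label)
        }
        trials[[length(trials) + 1L]] <- sess
        truth[[length(truth) + 1L]] <- tibble::tibble(
          subject_id = sid, group = g$label, domain = dom,
          target_efficiency = target,
          confidence_noise_sd = noise$confidence_noise_sd,
          decision_extra_noise_sd = noise$decision_extra_noise_sd,
          evidence_per_dot = spec$observer$evidence_per_dot
        )
      }
    }
  }
  list(
    trials = dplyr::bind_rows(trials),
    ground_truth = dplyr::bind_rows(truth)
  )
}
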