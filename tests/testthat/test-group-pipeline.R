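test_that("the domain-general index is the absolute log-ratio of efficiencies", {
  expect_equal(dgi(0.7, 0.7), 0)
  expect_equal(dgi(0.5, 1.0), log(2), tolerance = 1e-12)
  set.seed(51)
  for (i in 1:20) {
    a <- runif(1, 0.05, 1.5)
    b <- runif(1, 0.05, 1.5)
    expect_equal(dgi(a, b), dgi(b, a))
    expect_gte(dgi(a, b), 0)
  }
  expect_equal(dgi(0.5, 1, base = 10), log10(2))
  expect_error(dgi(-0.1, 1), "non-positive")
  expect_error(dgi(0.5, 0), "non-positive")
})

test_that("bootstrap percentile CIs behave on constant and random input", {
  ci <- bootstrap_percentile_ci(rep(3.5, 10), n_resamples = 500, seed = 1)
  expect_equal(unname(ci), c(3.5, 3.5), ignore_attr = TRUE)

  x <- rnorm(30)
  ci1 <- bootstrap_percentile_ci(x, n_resamples = 2000, seed = 7)
  ci2 <- bootstrap_percentile_ci(x, n_resamples = 2000, seed = 7)
  expect_identical(ci1, ci2)
  expect_gte(ci1[["lower"]], min(x))
  expect_lte(ci1[["upper"]], max(x))
  expect_lte(ci1[["lower"]], mean(x))
  expect_gte(ci1[["upper"]], mean(x))

  ci99 <- bootstrap_percentile_ci(x, level = 0.99, n_resamples = 2000, seed = 7)
  expect_lte(ci99[["lower"]], ci1[["lower"]])
  expect_gte(ci99[["upper"]], ci1[["upper"]])

  expect_error(bootstrap_percentile_ci(3), "at least 2")
})

make_fits <- function(...) {
  # ... = subject entries list(id, group, mp, mm)
  entries <- list(...)
  dplyr::bind_rows(lapply(entries, function(e) {
    tibble::tibble(subject_id = e[[1]], group = e[[2]],
                   domain = c("perception", "memory"),
                   efficiency = c(e[[3]], e[[4]]))
  }))
}

test_that("the exclusion rule covers all four sign patterns and is idempotent", {
  fits <- make_fits(
    list("s1", "g", 0.8, 1.1),    # both positive
    list("s2", "g", -0.2, 1.0),   # negative perception
    list("s3", "g", 0.5, -0.1),   # negative memory
    list("s4", "g", -0.3, -0.4)   # negative both
  )
  res <- apply_exclusions(fits)
  s <- res$subjects
  expect_equal(s$excluded_domains, c("", "perception", "memory", "perception,memory"))
  expect_equal(is.na(s$log_Mp), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(is.na(s$log_Mm), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(is.na(s$dgi), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(s$dgi[1], abs(log(0.8) - log(1.1)))
  # raw efficiencies retained even when excluded from log analyses
  expect_equal(s$Mp, c(0.8, -0.2, 0.5, -0.3))
  expect_equal(nrow(res$exclusions), 4)
  expect_identical(apply_exclusions(fits)$subjects, s)

  one_neg <- apply_exclusions(make_fits(
    list("a", "g", -0.05, 1.0), list("b", "g", 0.9, 1.0)
  ))
  expect_equal(nrow(one_neg$exclusions), 1)
  expect_equal(one_neg$exclusions$domain, "perception")

  all_pos <- apply_exclusions(make_fits(list("a", "g", 0.9, 1.0)))
  expect_equal(nrow(all_pos$exclusions), 0)
})

test_that("group tests match hand-computed closed forms", {
  # identical groups: t ~ 0, p ~ 1
  fits <- make_fits(
    list("a1", "g1", 0.8, 0.9), list("a2", "g1", 0.6, 0.7),
    list("a3", "g1", 0.7, 0.8),
    list("b1", "g2", 0.8, 0.9), list("b2", "g2", 0.6, 0.7),
    list("b3", "g2", 0.7, 0.8)
  )
  subj <- apply_exclusions(fits)$subjects
  res <- group_tests(subj, config = run_config(n_resamples = 200, permutations = 200))
  t_row <- res$tests[res$tests$measure == "log_Mp" &
                       res$tests$method == "t (pooled)", ]
  expect_equal(t_row$statistic, 0, tolerance = 1e-10)
  expect_equal(t_row$p_value, 1, tolerance = 1e-10)

  # textbook fixture {1..5} vs {3..7}: pooled t = -2, F = 4, df = (1, 8)
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 4, 5, 6, 7)
  tt <- mratio:::pooled_t(x, y)
  expect_equal(unname(tt["t"]), -2)
  expect_equal(unname(tt["df"]), 8)
  expect_equal(unname(tt["p"]), 2 * pt(-2, 8))
  f <- mratio:::oneway_f(c(x, y), rep(c("A", "B"), each = 5))
  expect_equal(unname(f["F"]), 4)
  expect_equal(unname(f["p"]), 2 * pt(-2, 8), tolerance = 1e-10)
})

test_that("the interaction permutation test detects a true group x domain dissociation", {
  # one group with lowered perceptual but intact memory efficiency, the other
  # intact in both; dispersion matches fitted-efficiency noise at 200 trials
  set.seed(52)
  n <- 50
  reps <- 60
  rejected <- 0
  for (r in seq_len(reps)) {
    subjects <- tibble::tibble(
      subject_id = sprintf("s%03d", 1:(2 * n)),
      group = rep(c("lesion", "control"), each = n),
      log_Mp = c(rnorm(n, log(0.46), 0.5), rnorm(n, log(0.88), 0.5)),
      log_Mm = c(rnorm(n, log(1.04), 0.4), rnorm(n, log(1.09), 0.4))
    )
    res <- interaction_permutation_test(subjects, permutations = 500,
                                        seed = 5000 + r)
    if (res$p_value < 0.05) rejected <- rejected + 1
  }
  expect_gt(rejected / reps, 0.8)
})

test_that("insufficient group sizes yield not-computable markers, not errors", {
  fits <- make_fits(list("a", "g1", 0.8, 0.9))
  subj <- apply_exclusions(fits)$subjects
  res <- group_tests(subj, config = run_config(n_resamples = 100, permutations = 100))
  expect_true(all(is.na(res$tests$p_value)))
  expect_true(is.na(res$interaction$p_value))
  expect_match(res$interaction$note, "not computable")
})

test_that("run_full_analysis composes fits, exclusions, tests and report", {
  spec <- cohort_spec(
    groups = list(
      list(label = "g1", n_subjects = 3,
           perception = list(confidence_noise_sd = 1.2),
           memory = list(confidence_noise_sd = 0.2)),
      list(label = "g2", n_subjects = 3,
           perception = list(confidence_noise_sd = 0.3),
           memory = list(confidence_noise_sd = 0.3))
    ),
    seed = 11
  )
  cohort <- generate_cohort(spec)
  cfg <- run_config(n_resamples = 500, permutations = 500, seed = 9)
  out_dir <- withr::local_tempdir()
  res <- run_full_analysis(cohort$trials, config = cfg, out_dir = out_dir)

  expect_equal(nrow(res$fits), 12)
  expect_equal(nrow(res$subjects), 6)
  expect_true(all(c("fits.csv", "subjects.csv", "exclusions.csv",
                    "group_tests.csv", "report.md", "config.yaml")
                  %in% list.files(out_dir)))
  report <- res$report
  expect_true(any(grepl("meta-d'/d'", report)))
  expect_true(any(grepl("Domain-general index", report)))
  expect_true(any(grepl("% correct", report)))
  expect_true(any(grepl("Confidence|confidence", report)))

  # groups generated at clearly distinct efficiencies keep their rank order
  expect_lt(mean(res$subjects$Mp[res$subjects$group == "g1"]),
            mean(res$subjects$Mp[res$subjects$group == "g2"]))

  # determinism: identical config and trials give identical objects
  res2 <- run_full_analysis(cohort$trials, config = cfg)
  expect_identical(res$subjects, res2$subjects)
  expect_identical(res$groups$bootstrap_cis, res2$groups$bootstrap_cis)
  expect_identical(res$report, res2$report)
})

test_that("a single-subject table yields per-subject output with test gaps", {
  obs <- observer_model(confidence_noise_sd = 0.5)
  trials <- dplyr::bind_rows(
    simulate_perception_session(obs, seed = 21, subject_id = "solo", group = "g"),
    simulate_memory_session(obs, seed = 22, subject_id = "solo", group = "g")
  )
  res <- run_full_analysis(trials, config = run_config(n_resamples = 100,
                                                       permutations = 100))
  expect_equal(nrow(res$fits), 2)
  expect_equal(nrow(res$subjects), 1)
  expect_true(all(is.na(res$groups$tests$p_value)))
  expect_true(any(grepl("not computable", res$report)))
})
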