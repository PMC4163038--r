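#' Build subject summaries and apply the exclusion rule
#'
#' Combines per-subject per-domain meta-d' fits into one row per subject
#' with perceptual (`Mp`) and memory (`Mm`) efficiency. Subjects whose
#' fitted efficiency in a domain is missing or non-positive are excluded
#' from log-based analyses in that domain (their `log_Mp`/`log_Mm` is `NA`)
#' and from the domain-general index, which requires both log terms; their
#' raw efficiencies remain available for raw-scale summaries. Exclusions are
#' data, not failures: the rule is total and idempotent, and every exclusion
#' is logged with subject, domain and reason.
#'
#' @param fits A data frame with one row per subject x domain and columns
#'   `subject_id`, `group`, `domain` (`"perception"`/`"memory"`),
#'   `efficiency` (and optionally `quality` from [fit_meta_d()]).
#' @param log_base Base for the log transform (default natural log).
#' @return A list with `subjects` (tibble: `subject_id`, `group`, `Mp`,
#'   `Mm`, `log_Mp`, `log_Mm`, `dgi`, `excluded_domains`) and `exclusions`
#'   (tibble: `subject_id`, `domain`, `reason`).
#' @export
apply_exclusions <- function(fits, log_base = exp(1)) {
  stopifnot(all(c("subject_id", "group", "domain", "efficiency") %in% names(fits)))
  fits <- tibble::as_tibble(fits)
  get_eff <- function(df, dom) {
    v <- df$efficiency[df$domain == dom]
    if (length(v) == 0) NA_real_ else v[1]
  }
  subj_keys <- unique(fits[, c("subject_id", "group")])
  rows <- lapply(seq_len(nrow(subj_keys)), function(i) {
    df <- fits[fits$subject_id == subj_keys$subject_id[i] &
                 fits$group == subj_keys$group[i], ]
    mp <- get_eff(df, "perception")
    mm <- get_eff(df, "memory")
    excl_p <- is.na(mp) || mp <= 0
    excl_m <- is.na(mm) || mm <= 0
    tibble::tibble(
      subject_id = subj_keys$subject_id[i],
      group = subj_keys$group[i],
      Mp = mp, Mm = mm,
      log_Mp = if (excl_p) NA_real_ else log(mp, base = log_base),
      log_Mm = if (excl_m) NA_real_ else log(mm, base = log_base),
      dgi = if (excl_p || excl_m) NA_real_ else dgi(mp, mm, base = log_base),
      excluded_domains = paste(c(if (excl_p) "perception", if (excl_m) "memory"),
                               collapse = ",")
    )
  })
  subjects <- dplyr::bind_rows(rows)
  exclusions <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    doms <- strsplit(subjects$excluded_domains[i], ",")[[1]]
    if (length(doms) == 0) return(NULL)
    eff <- ifelse(doms == "perception", subjects$Mp[i], subjects$Mm[i])
    tibble::tibble(
      subject_id = subjects$subject_id[i],
      domain = doms,
      reason = ifelse(is.na(eff),
                      "efficiency not estimable",
                      sprintf("non-positive efficiency (%.3f) precludes log(meta-d'/d')", eff))
    )
  }))
  if (nrow(exclusions) == 0) {
    exclusions <- tibble::tibble(subject_id = character(), domain = character(),
                                 reason = character())
  }
  list(subjects = subjects, exclusions = exclusions)
}

# Pooled-variance two-sample t statistic; returns c(t, df, p).
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(c(t = NA_real_, df = NA_real_, p = NA_real_))
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F from values and group labels; returns c(F, df1, df2, p).
oneway_f <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    return(c(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
  }
  fit <- anova(aov(values ~ groups))
  c(F = fit[["F value"]][1], df1 = fit[["Df"]][1], df2 = fit[["Df"]][2],
    p = fit[["Pr(>F)"]][1])
}

# F statistic only, from scratch, for permutation loops (no model objects).
fstat_fast <- function(values, gindex, ng) {
  n <- length(values)
  gm <- rowsum(values, gindex, reorder = TRUE)
  cnt <- tabulate(gindex, ng)
  means <- gm / cnt
  grand <- sum(gm) / n
  ssb <- sum(cnt * (means - grand)^2)
  ssw <- sum((values - means[gindex])^2)
  (ssb / (ng - 1)) / (ssw / (n - ng))
}

#' Permutation test of the group x domain interaction
#'
#' Each subject contributes one value per domain, so the group x domain
#' interaction reduces to a between-group contrast on the within-subject
#' domain difference `log(Mp) - log(Mm)`. The observed one-way F statistic
#' on these differences is compared with its distribution under random
#' permutation of group labels across subjects, which is the exact
#' exchangeability null for the interaction at this design's granularity.
#'
#' @param subjects Subject summary table from [apply_exclusions()]; subjects
#'   missing either log term are dropped.
#' @param groups Optional character vector restricting the test to a subset
#'   of groups (e.g. healthy controls versus one lesion group); default all.
#' @param permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return A list with `statistic` (observed F), `p_value`
#'   (`(1 + #{F* >= F}) / (permutations + 1)`), `permutations`, `n_subjects`
#'   and `groups`.
#' @export
interaction_permutation_test <- function(subjects, groups = NULL,
                                         permutations = 10000L, seed = 1L) {
  df <- subjects[!is.na(subjects$log_Mp) & !is.na(subjects$log_Mm), ]
  if (!is.null(groups)) df <- df[df$group %in% groups, ]
  g <- factor(df$group)
  diffs <- df$log_Mp - df$log_Mm
  ng <- nlevels(g)
  if (ng < 2 || any(table(g) < 2)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                permutations = permutations, n_subjects = nrow(df),
                groups = levels(g),
                note = "not computable: need >= 2 groups with >= 2 subjects each"))
  }
  gindex <- as.integer(g)
  f_obs <- fstat_fast(diffs, gindex, ng)
  n_ge <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(permutations)) {
      f_b <- fstat_fast(diffs, sample(gindex), ng)
      if (f_b >= f_obs - 1e-12) count <- count + 1L
    }
    count
  })
  list(statistic = f_obs, p_value = (1 + n_ge) / (permutations + 1),
       permutations = permutations, n_subjects = nrow(df), groups = levels(g))
}

#' Group-level descriptives, bootstrap CIs and tests
#'
#' Computes, per group: means and SDs of raw efficiency (`Mp`, `Mm`) and of
#' the domain-general index, with subject-resampled percentile bootstrap
#' CIs on the means; and between-group tests on log-efficiency and DGI:
#' one-way ANOVA and Kruskal-Wallis across all groups, pooled-variance
#' two-sample t and Wilcoxon rank-sum tests for every group pair, plus the
#' permutation group x domain interaction test
#' ([interaction_permutation_test()]). All tests are two-tailed and no
#' multiple-comparison adjustment is applied. Comparisons that are not
#' computable at the available group sizes are reported as `NA` rather than
#' failing.
#'
#' @param subjects Subject summary table from [apply_exclusions()].
#' @param config A [run_config()]; governs bootstrap resamples, CI level,
#'   permutations and seed.
#' @param interaction_groups Optional subset of groups for the interaction
#'   test.
#' @return An object of class `group_result`: list with `descriptives`,
#'   `bootstrap_cis`, `tests` (tibbles) and `interaction`.
#' @export
group_tests <- function(subjects, config = run_config(),
                        interaction_groups = NULL) {
  measures <- c(Mp = "Mp", Mm = "Mm", dgi = "dgi")
  glabs <- unique(subjects$group)

  descriptives <- dplyr::bind_rows(lapply(glabs, function(gl) {
    df <- subjects[subjects$group == gl, ]
    tibble::tibble(
      group = gl, n = nrow(df),
      measure = names(measures),
      mean = vapply(measures, function(m) mean(df[[m]], na.rm = TRUE), numeric(1)),
      sd = vapply(measures, function(m) sd(df[[m]], na.rm = TRUE), numeric(1)),
      n_used = vapply(measures, function(m) sum(!is.na(df[[m]])), integer(1))
    )
  }))

  cis <- dplyr::bind_rows(lapply(glabs, function(gl) {
    df <- subjects[subjects$group == gl, ]
    dplyr::bind_rows(lapply(names(measures), function(m) {
      v <- df[[measures[[m]]]]
      v <- v[!is.na(v)]
      if (length(v) < 2) {
        ci <- c(NA_real_, NA_real_)
      } else {
        ci <- bootstrap_percentile_ci(
          v, level = config$ci_level, n_resamples = config$n_resamples,
          seed = derive_seed(config$seed, match(gl, glabs), match(m, names(measures)))
        )
      }
      tibble::tibble(group = gl, measure = m, ci_lower = ci[[1]], ci_upper = ci[[2]],
                     level = config$ci_level, n_resamples = config$n_resamples)
    }))
  }))

  test_measures <- c(log_Mp = "log_Mp", log_Mm = "log_Mm", dgi = "dgi")
  tests <- dplyr::bind_rows(lapply(names(test_measures), function(m) {
    v_all <- subjects[[test_measures[[m]]]]
    keep <- !is.na(v_all)
    v <- v_all[keep]; g <- factor(subjects$group[keep])
    rows <- list()
    f <- oneway_f(v, g)
    rows[[1]] <- tibble::tibble(measure = m, comparison = "all groups",
                                method = "one-way ANOVA", statistic = f[["F"]],
                                df = paste0(f[["df1"]], ",", f[["df2"]]),
                                p_value = f[["p"]])
    kw <- if (nlevels(g) >= 2 && all(table(g) >= 1) && length(v) > nlevels(g)) {
      k <- kruskal.test(v, g)
      unname(c(k$statistic, k$parameter, k$p.value))
    } else c(NA_real_, NA_real_, NA_real_)
    rows[[2]] <- tibble::tibble(measure = m, comparison = "all groups",
                                method = "Kruskal-Wallis", statistic = kw[1],
                                df = as.character(kw[2]), p_value = kw[3])
    pairs <- if (length(levels(g)) >= 2) utils::combn(levels(g), 2, simplify = FALSE) else list()
    for (pr in pairs) {
      x <- v[g == pr[1]]; y <- v[g == pr[2]]
      tt <- pooled_t(x, y)
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m, comparison = paste(pr, collapse = " vs "),
        method = "t (pooled)", statistic = tt[["t"]],
        df = as.character(tt[["df"]]), p_value = tt[["p"]]
      )
      wp <- if (length(x) >= 2 && length(y) >= 2) {
        suppressWarnings(wilcox.test(x, y)$p.value)
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m, comparison = paste(pr, collapse = " vs "),
        method = "rank-sum", statistic = NA_real_, df = NA_character_,
        p_value = wp
      )
    }
    dplyr::bind_rows(rows)
  }))

  interaction <- interaction_permutation_test(
    subjects, groups = interaction_groups,
    permutations = config$permutations,
    seed = derive_seed(config$seed, 999L)
  )

  structure(
    list(descriptives = descriptives, bootstrap_cis = cis, tests = tests,
         interaction = interaction, config = config),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat("Group-level metacognition results\n\n")
  print(x$descriptives, n = Inf)
  cat("\nInteraction (group x domain), permutation test: F =",
      format(x$interaction$statistic, digits = 3),
      ", p =", format(x$interaction$p_value, digits = 3), "\n")
  invisible(x)
}
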