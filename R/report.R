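# Plain-text/markdown report of group means in the conventional
# means-and-(SD) table layout, with bootstrap CIs and test results.

fmt_ms <- function(m, s, digits = 3) {
  if (is.na(m)) return("n/a")
  paste0(signif(m, digits), " (", if (is.na(s)) "n/a" else signif(s, digits), ")")
}

#' Format an analysis report
#'
#' Renders group descriptives (percent correct and confidence per domain and
#' study time, staircase difficulty, meta-d'/d', domain-general index),
#' bootstrap CIs, exclusions and tests as markdown lines. Numbers are
#' rounded to 2-3 significant figures with SDs in parentheses; missing or
#' not-computable entries are reported explicitly as gaps.
#'
#' @param analysis An `mratio_analysis` from [run_full_analysis()].
#' @return Character vector of report lines.
#' @export
format_report <- function(analysis) {
  subjects <- analysis$subjects
  glabs <- unique(subjects$group)
  perf <- analysis$performance
  lines <- c("# Metacognition analysis report", "")

  header <- paste0("| Measure | ", paste(glabs, collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---|", length(glabs) + 1), collapse = ""))
  by_group <- function(df, value_col, filter = NULL) {
    vapply(glabs, function(gl) {
      d <- df[df$group == gl, ]
      if (!is.null(filter)) d <- d[filter(d), ]
      if (nrow(d) == 0) return("n/a")
      fmt_ms(mean(d[[value_col]], na.rm = TRUE), sd(d[[value_col]], na.rm = TRUE))
    }, character(1))
  }
  row <- function(label, vals) paste0("| ", label, " | ", paste(vals, collapse = " | "), " |")

  lines <- c(lines, "## Group means (SD)", "", header, rule)

  mem <- perf$memory_by_time
  if (!is.null(mem) && nrow(mem)) {
    for (st in sort(unique(as.numeric(mem$condition_tag)))) {
      flt <- function(d) as.numeric(d$condition_tag) == st
      lines <- c(lines,
                 row(sprintf("Memory %% correct, %g min study", st),
                     by_group(mem, "pct_correct", flt)))
    }
    for (st in sort(unique(as.numeric(mem$condition_tag)))) {
      flt <- function(d) as.numeric(d$condition_tag) == st
      lines <- c(lines,
                 row(sprintf("Memory confidence, %g min study", st),
                     by_group(mem, "confidence", flt)))
    }
  } else {
    lines <- c(lines, row("Memory task", rep("no data", length(glabs))))
  }
  lines <- c(lines, row("Memory meta-d'/d'",
                        by_group(subjects, "Mm")))

  if (!is.null(perf$perception) && nrow(perf$perception)) {
    lines <- c(lines,
               row("Perception % correct", by_group(perf$perception, "pct_correct")),
               row("Perception delta-d (dots)", by_group(perf$perception, "delta_d")),
               row("Perception confidence", by_group(perf$perception, "confidence")))
  } else {
    lines <- c(lines, row("Perception task", rep("no data", length(glabs))))
  }
  lines <- c(lines,
             row("Perception meta-d'/d'", by_group(subjects, "Mp")),
             row("Domain-general index", by_group(subjects, "dgi")),
             "")

  groups <- analysis$groups
  if (!is.null(groups)) {
    lines <- c(lines, "## Bootstrap CIs on group means", "")
    cis <- groups$bootstrap_cis
    for (i in seq_len(nrow(cis))) {
      lines <- c(lines, sprintf(
        "- %s, %s: %s", cis$group[i], cis$measure[i],
        if (is.na(cis$ci_lower[i])) "not computable (fewer than 2 usable subjects)"
        else sprintf("%.2f-%.2f (%d%% CI, %d resamples)",
                     cis$ci_lower[i], cis$ci_upper[i],
                     round(100 * cis$level[i]), cis$n_resamples[i])
      ))
    }
    lines <- c(lines, "", "## Group tests (two-tailed, unadjusted)", "")
    tst <- groups$tests
    for (i in seq_len(nrow(tst))) {
      lines <- c(lines, sprintf(
        "- %s, %s, %s: %s", tst$measure[i], tst$comparison[i], tst$method[i],
        if (is.na(tst$p_value[i])) "not computable at these group sizes"
        else sprintf("statistic = %s, p = %.3g",
                     ifelse(is.na(tst$statistic[i]), "n/a",
                            format(signif(tst$statistic[i], 3))),
                     tst$p_value[i])
      ))
    }
    it <- groups$interaction
    lines <- c(lines, "", sprintf(
      "Group x domain interaction (permutation, %s subjects): %s",
      it$n_subjects,
      if (is.na(it$p_value)) "not computable at these group sizes"
      else sprintf("F = %.3g, p = %.4g (%d permutations)",
                   it$statistic, it$p_value, it$permutations)
    ))
  }

  lines <- c(lines, "", "## Exclusions", "")
  if (nrow(analysis$exclusions) == 0) {
    lines <- c(lines, "- none")
  } else {
    lines <- c(lines, sprintf("- %s, %s: %s", analysis$exclusions$subject_id,
                              analysis$exclusions$domain, analysis$exclusions$reason))
  }
  lines <- c(lines, "",
             paste("Note: no covariate adjustment (e.g. IQ, gender, lesion",
                   "volume) is applied; such ANCOVA analyses are outside the",
                   "scope of this pipeline."))
  lines
}

#' Write the analysis report
#'
#' @param analysis An `mratio_analysis` from [run_full_analysis()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(analysis, path) {
  writeLines(format_report(analysis), path)
  invisible(path)
}
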