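#' Per-subject, per-chromosome SNV counts
#'
#' Tabulates the cardinality of every subject's SNV set on every chromosome
#' of the collection's universe (zero counts included), optionally joined
#' with manifest labels. Per-subject totals are the sums over chromosomes.
#'
#' @param sets An [as_snv_sets()] collection.
#' @param manifest Optional `cohort_manifest`; its `group` and `population`
#'   columns are joined onto the counts.
#' @return A tibble with columns `subject`, `chrom`, `n_snvs` (one row per
#'   subject x chromosome) plus any joined labels.
#' @export
count_snvs <- function(sets, manifest = NULL) {
  stopifnot(inherits(sets, "snv_sets"))
  if (nrow(sets) == 0 && length(snv_subjects(sets)) == 0) {
    abort("collection has no subjects")
  }
  grid <- tidyr::expand_grid(subject = snv_subjects(sets),
                             chrom = snv_chroms(sets))
  counts <- dplyr::count(tibble::as_tibble(sets)[c("subject", "chrom")],
                         .data$subject, .data$chrom, name = "n_snvs")
  out <- dplyr::left_join(grid, counts, by = c("subject", "chrom"))
  out$n_snvs <- tidyr::replace_na(out$n_snvs, 0L)
  if (!is.null(manifest)) {
    out <- dplyr::left_join(
      out, manifest[c("id", "group", "population")],
      by = c(subject = "id"))
  }
  out
}

#' Per-subject total SNV counts
#'
#' @param counts Output of [count_snvs()].
#' @return One row per subject with `total_snvs` plus any label columns.
#' @export
snv_count_totals <- function(counts) {
  labels <- intersect(c("group", "population"), names(counts))
  dplyr::summarise(dplyr::group_by(counts,
                                   dplyr::across(dplyr::all_of(c("subject", labels)))),
                   total_snvs = sum(.data$n_snvs), .groups = "drop")
}

#' Two-sample t test (Welch by default)
#'
#' Compares two groups of measurements (e.g. total SNV counts of two
#' populations). The default is Welch's unequal-variance statistic
#' \deqn{t = (m_A - m_B) / \sqrt{s_A^2/n_A + s_B^2/n_B}}
#' with Welch–Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution; `var_equal = TRUE` gives the pooled-variance variant.
#' Welch is the sensible default for cohorts whose group variances differ by
#' orders of magnitude, as whole-genome variant burdens across populations
#' do. `log10_p` is reported alongside, so vanishing p-values remain
#' comparable.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param labels Length-2 character vector naming the groups.
#' @param var_equal Use the pooled-variance statistic instead of Welch.
#' @return An object of class `group_comparison` with `tidy()`, `glance()`
#'   and `print()` methods; fields include means, SDs, `t`, `df`, `p_value`
#'   and `log10_p`.
#' @examples
#' welch_t_test(rnorm(10), rnorm(10, 1))
#' @export
welch_t_test <- function(values_a, values_b, labels = c("A", "B"),
                         var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (any(!is.finite(c(values_a, values_b)))) {
    abort("values must be finite")
  }
  na <- length(values_a); nb <- length(values_b)
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  diff <- ma - mb
  if (se == 0) {
    # degenerate zero-variance groups
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    log10_p <- if (diff == 0) 0 else -Inf
    df <- NA_real_
  } else {
    t_stat <- diff / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    log10_p <- (log(2) + stats::pt(-abs(t_stat), df, log.p = TRUE)) / log(10)
  }
  out <- list(group_a = labels[1], group_b = labels[2], n_a = na, n_b = nb,
              mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb),
              estimate = diff, statistic = t_stat, df = df, p_value = p,
              log10_p = log10_p,
              method = if (var_equal) "pooled" else "Welch")
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s variant)\n", x$method))
  cat(sprintf("  %s: n = %d, mean = %.6g, sd = %.6g\n",
              x$group_a, x$n_a, x$mean_a, x$sd_a))
  cat(sprintf("  %s: n = %d, mean = %.6g, sd = %.6g\n",
              x$group_b, x$n_b, x$mean_b, x$sd_b))
  cat(sprintf("  t = %.4f, df = %.4g, two-sided p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @describeIn welch_t_test One-row tibble of the comparison.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x[c("group_a", "group_b", "n_a", "n_b", "mean_a",
                        "mean_b", "sd_a", "sd_b", "estimate", "statistic",
                        "df", "p_value", "log10_p", "method")])
}

#' @describeIn welch_t_test Same as `tidy()`; the fit has no extra
#'   per-term structure.
#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' Group means and standard deviations
#'
#' Summarizes a numeric column within groups, reporting both the population
#' standard deviation (divisor n) and the sample standard deviation
#' (divisor n - 1). Cohort descriptive tables commonly print the
#' population form for small demographic summaries (it reproduces, e.g.,
#' printed age SDs), so both are always emitted.
#'
#' @param data A data frame.
#' @param value Unquoted numeric column to summarize.
#' @param by Character vector of grouping columns.
#' @return A tibble with the grouping columns, `n`, `mean`, `sd_pop`
#'   (divisor n) and `sd_sample` (divisor n - 1).
#' @examples
#' manifest <- read_manifest(snvclust_example("cohort25.tsv"))
#' group_summary(manifest, age, by = c("population", "group"))
#' @export
group_summary <- function(data, value, by) {
  missing_by <- setdiff(by, names(data))
  if (length(missing_by) > 0) {
    abort(paste0("grouping column(s) not in data: ",
                 paste(missing_by, collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    mean = mean({{ value }}),
    sd_pop = sqrt(mean(({{ value }} - mean({{ value }}))^2)),
    sd_sample = stats::sd({{ value }}),
    .groups = "drop")
  if (any(!is.finite(out$mean))) {
    bad <- do.call(paste, c(out[by][!is.finite(out$mean), , drop = FALSE],
                            sep = "/"))
    abort(paste0("group(s) with missing values: ", paste(bad, collapse = ", ")))
  }
  out
}

#' Five-number summaries for boxplots
#'
#' Tukey five-number summaries (minimum, lower hinge, median, upper hinge,
#' maximum — the statistics a default boxplot draws) of a numeric column
#' within groups, e.g. per-chromosome SNV counts by group.
#'
#' @inheritParams group_summary
#' @return A tibble with the grouping columns, `n`, and `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
boxplot_stats <- function(data, value, by) {
  missing_by <- setdiff(by, names(data))
  if (length(missing_by) > 0) {
    abort(paste0("grouping column(s) not in data: ",
                 paste(missing_by, collapse = ", ")))
  }
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    min = stats::fivenum({{ value }})[1],
    q1 = stats::fivenum({{ value }})[2],
    median = stats::fivenum({{ value }})[3],
    q3 = stats::fivenum({{ value }})[4],
    max = stats::fivenum({{ value }})[5],
    .groups = "drop")
}

#' Boxplots of per-chromosome SNV counts
#'
#' @param counts Output of [count_snvs()] (with a manifest joined if the
#'   fill grouping is wanted).
#' @param fill Optional column name to color boxes by (e.g. `"group"`).
#' @return A ggplot object.
#' @export
plot_snv_boxplots <- function(counts, fill = NULL) {
  counts$chrom <- factor(counts$chrom, levels = chrom_order(unique(counts$chrom)))
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$chrom, y = .data$n_snvs))
  p <- if (is.null(fill)) p + ggplot2::geom_boxplot() else
    p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data[[fill]]))
  p + ggplot2::labs(x = "chromosome", y = "SNV count") +
    ggplot2::theme_minimal()
}
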