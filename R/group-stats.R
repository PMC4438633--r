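#' Per-group summary statistics (mean, SD)
#'
#' @param data Data frame with columns `group_label` and `value`.
#' @return Tibble with `group_label`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator; 0 when n = 1).
#' @examples
#' summarize_groups(data.frame(group_label = c("A", "A"), value = c(1, 3)))
#' @export
summarize_groups <- function(data) {
  data <- check_group_data(data, min_per_group = 1)
  dplyr::summarise(
    dplyr::group_by(data, .data$group_label),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
    .groups = "drop")
}

check_group_data <- function(data, min_per_group = 2) {
  data <- as_tibble(data)
  if (!all(c("group_label", "value") %in% names(data)) || nrow(data) == 0) {
    abort("`data` must have columns group_label and value (>= 1 row).",
          class = "ecmquant_invalid_input")
  }
  if (anyNA(data$value)) {
    abort("`value` contains missing values.", class = "ecmquant_invalid_input")
  }
  sizes <- table(data$group_label)
  small <- names(sizes)[sizes < min_per_group]
  if (length(small)) {
    abort(sprintf("Group(s) with fewer than %d values: %s.",
                  min_per_group, paste(small, collapse = ", ")),
          class = "ecmquant_insufficient_data")
  }
  data
}

#' Compare measurement groups (t-test or one-way ANOVA with post hoc)
#'
#' Two groups: two-sided unpaired Student's t-test (equal variances by
#' default; `welch = TRUE` for the unequal-variance form). Three or more
#' groups: one-way ANOVA followed by all-pairs Tukey HSD (or Dunnett-style
#' contrasts against a named control via `dunnett_control`).
#'
#' Degenerate separations whose p-value underflows are reported as the
#' smallest positive double rather than 0.
#'
#' @param data Data frame with columns `group_label` and `value`; every group
#'   needs at least two values.
#' @param welch Use the Welch t-test for two groups.
#' @param dunnett_control Optional control-group label; pairwise comparisons
#'   are then restricted to each group vs control (Bonferroni-adjusted two-sample
#'   contrasts within the ANOVA framework via multcomp-free Tukey subset).
#' @return A `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `pairwise` (tibble `group_a`, `group_b`, `adjusted_p`; NULL for two
#'   groups), and the group summaries. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- data.frame(group_label = rep(c("ctrl", "tgfb1"), each = 5),
#'                 value = c(rnorm(5), rnorm(5, 2)))
#' compare_groups(d)
#' @export
compare_groups <- function(data, welch = FALSE, dunnett_control = NULL) {
  data <- check_group_data(data, min_per_group = 2)
  groups <- unique(data$group_label)
  if (length(groups) < 2) {
    abort("Need at least two groups to compare.", class = "ecmquant_invalid_input")
  }
  summaries <- summarize_groups(data)
  floor_p <- function(p) max(p, .Machine$double.xmin)
  if (length(groups) == 2) {
    v1 <- data$value[data$group_label == groups[1]]
    v2 <- data$value[data$group_label == groups[2]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      # zero within-group variance: t statistic is infinite when means differ
      same <- isTRUE(all.equal(mean(v1), mean(v2)))
      res <- list(statistic = if (same) 0 else Inf,
                  p.value = if (same) 1 else 0)
    } else {
      res <- t.test(v1, v2, var.equal = !welch)
    }
    out <- list(test_name = if (welch) "Welch t-test" else "Student t-test",
                statistic = unname(res$statistic),
                p_value = floor_p(res$p.value),
                pairwise = NULL, summaries = summaries)
  } else {
    data$group_label <- factor(data$group_label)
    fit <- aov(value ~ group_label, data = data)
    an <- summary(fit)[[1]]
    pw_raw <- TukeyHSD(fit)$group_label
    labs <- strsplit(rownames(pw_raw), "-", fixed = TRUE)
    pw <- tibble(
      group_a = vapply(labs, `[`, character(1), 1),
      group_b = vapply(labs, `[`, character(1), 2),
      difference = pw_raw[, "diff"],
      adjusted_p = vapply(pw_raw[, "p adj"], floor_p, numeric(1)))
    if (!is.null(dunnett_control)) {
      pw <- dplyr::filter(pw, .data$group_a == dunnett_control |
                            .data$group_b == dunnett_control)
    }
    out <- list(test_name = "one-way ANOVA + Tukey HSD",
                statistic = an$`F value`[1],
                p_value = floor_p(an$`Pr(>F)`[1]),
                pairwise = pw, summaries = summaries)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.3g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble(group_a = x$summaries$group_label[1],
           group_b = x$summaries$group_label[2],
           adjusted_p = x$p_value)
  } else {
    x$pairwise
  }
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test_name = x$test_name, statistic = x$statistic, p_value = x$p_value)
}

#' Plot group values with mean +/- SD overlay
#'
#' @param data Data frame with columns `group_label` and `value`.
#' @return A ggplot.
#' @export
plot_groups <- function(data) {
  data <- check_group_data(data, min_per_group = 1)
  s <- summarize_groups(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group_label, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = s,
      ggplot2::aes(x = .data$group_label, y = .data$mean,
                   ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      color = "red3") +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
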