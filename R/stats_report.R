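#' Remaining mitochondrial area at the end of a movie
#'
#' Mean `area_fraction` over the terminal window, per ROI — the
#' condition-level readout separating permeabilizing (wild-type + ferutinin,
#' area collapses toward 0) from depolarization-only conditions (area stays
#' near 1).  Invalid ROIs (zero baseline area) are excluded.
#'
#' @param traces an [area_trace()] / [mito_traces()] table.
#' @param terminal_window 0-based frame indices (default: last 3 frames).
#' @return tibble `roi_id, remaining_area`.
#' @export
remaining_area <- function(traces, terminal_window = NULL) {
  stopifnot(all(c("roi_id", "frame", "area_fraction") %in% names(traces)))
  nT <- max(traces$frame) + 1L
  terminal_window <- terminal_window %||% ((nT - 3L):(nT - 1L))
  if (any(terminal_window < 0L | terminal_window >= nT)) {
    abort("`terminal_window` exceeds the trace.")
  }
  traces |>
    filter(if ("valid" %in% names(traces)) .data$valid else TRUE,
           .data$frame %in% terminal_window) |>
    group_by(.data$roi_id) |>
    summarise(remaining_area = mean(.data$area_fraction), .groups = "drop")
}

#' Group means with standard errors
#'
#' Mean +/- SEM per group, the summary convention used throughout the
#' assay's reporting.  `sem = sd / sqrt(n)`; for `n = 1` the sd (hence sem)
#' is reported as 0 and the group is flagged `degenerate`.
#'
#' @param data a data frame.
#' @param value column with the measurement (tidy-eval).
#' @param group grouping column (tidy-eval).
#' @return tibble `group, n, mean, sd, sem, degenerate`.
#' @export
group_summary <- function(data, value, group) {
  out <- data |>
    filter(!is.na({{ value }})) |>
    group_by(group = {{ group }}) |>
    summarise(n = n(),
              mean = mean({{ value }}),
              sd = ifelse(n > 1, sd({{ value }}), 0),
              .groups = "drop") |>
    mutate(sem = .data$sd / sqrt(.data$n), degenerate = .data$n < 2)
  if (any(out$n < 1)) abort("Empty group.")
  out
}

#' Significance star code
#'
#' The standard convention: `p < 0.05` = `*`, `p < 0.01` = `**`,
#' `p < 0.001` = `***`, else `ns`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare groups with ANOVA or a t-test
#'
#' One-way ANOVA (>= 2 groups) or a two-sided two-sample t-test (exactly 2
#' groups; equal-variance pooling by default, Welch via `var_equal =
#' FALSE`), with the star code attached.  With two groups the ANOVA F
#' statistic equals the squared pooled t statistic.
#'
#' @param data a data frame.
#' @param value measurement column (tidy-eval).
#' @param group grouping column (tidy-eval).
#' @param test `"anova"` or `"t_test"` (default: t-test for 2 groups,
#'   ANOVA otherwise).
#' @param var_equal pool variances in the t-test (default TRUE).
#' @return object of class `mito_test`; see [tidy.mito_test()] and
#'   [glance.mito_test()].
#' @export
compare_groups <- function(data, value, group, test = NULL,
                           var_equal = TRUE) {
  df <- data |>
    select(value = {{ value }}, group = {{ group }}) |>
    filter(!is.na(.data$value))
  groups <- unique(df$group)
  ng <- length(groups)
  if (ng < 2) abort("At least 2 groups are required.")
  if (all(tapply(df$value, df$group, sd, default = 0) == 0) &&
      length(unique(df$value)) == 1) {
    abort("Zero variance in all groups; no test is possible.")
  }
  test <- test %||% if (ng == 2) "t_test" else "one_way_anova"
  test <- match.arg(test, c("one_way_anova", "t_test", "anova"))
  if (test == "anova") test <- "one_way_anova"
  if (test == "t_test") {
    if (ng != 2) abort("A t-test needs exactly 2 groups.")
    ht <- t.test(value ~ group, data = df, var.equal = var_equal)
    res <- list(test = "t_test", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value,
                groups = as.character(groups), var_equal = var_equal)
  } else {
    fit <- aov(value ~ factor(group), data = df)
    tab <- summary(fit)[[1]]
    res <- list(test = "one_way_anova", statistic = tab[["F value"]][1],
                df = c(tab[["Df"]][1], tab[["Df"]][2]),
                p_value = tab[["Pr(>F)"]][1],
                groups = as.character(groups), var_equal = TRUE)
  }
  res$stars <- star_code(res$p_value)
  structure(res, class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  lab <- if (x$test == "t_test") {
    sprintf("t(%.1f) = %.3f", x$df, x$statistic)
  } else {
    sprintf("F(%d, %d) = %.3f", x$df[1], x$df[2], x$statistic)
  }
  cat(sprintf("<mito_test> %s [%s]: %s, p = %.3g %s\n", x$test,
              paste(x$groups, collapse = " vs "), lab, x$p_value, x$stars))
  invisible(x)
}

#' Tidy a group-comparison result
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return one-row tibble: `test, statistic, df1, df2, p_value, stars`.
#' @exportS3Method generics::tidy
#' @export
tidy.mito_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value, stars = x$stars)
}

#' @rdname tidy.mito_test
#' @exportS3Method generics::glance
#' @export
glance.mito_test <- function(x, ...) tidy(x, ...)
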