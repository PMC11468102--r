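#' Collapse triplicate, two-rater measurement records
#'
#' The measurement protocol records every distance/angle three times by each
#' of two raters. Per subject x measure x side, the three replicates are
#' averaged within rater, then the two rater means are averaged. The pooled
#' within-cell replicate SD is kept as a measurement-noise diagnostic.
#'
#' @param records Tibble with columns `subject`, `measure`, `side`, `rater`,
#'   `replicate`, `value` (and optionally `group`, `affected_side`, `unit`).
#' @return Tibble with one row per subject x measure x side: `value` (grand
#'   mean of rater means) and `replicate_sd`.
#' @export
collapse_replicates <- function(records) {
  need <- c("subject", "measure", "side", "rater", "replicate", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  counts <- records |>
    dplyr::count(.data$subject, .data$measure, .data$side, .data$rater)
  bad <- dplyr::filter(counts, .data$n != 3)
  if (nrow(bad) > 0) {
    stop("missing-replicate error: expected 3 replicates per rater for ",
         paste(utils::head(paste(bad$subject, bad$measure, bad$side, "rater", bad$rater), 5),
               collapse = "; "),
         if (nrow(bad) > 5) " ..." else "", call. = FALSE)
  }
  n_raters <- records |>
    dplyr::distinct(.data$subject, .data$measure, .data$side, .data$rater) |>
    dplyr::count(.data$subject, .data$measure, .data$side)
  if (any(n_raters$n != 2)) {
    stop("missing-replicate error: expected exactly 2 raters per record", call. = FALSE)
  }
  keep <- intersect(c("group", "affected_side", "unit"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", "measure", "side", keep, "rater")))) |>
    dplyr::summarise(rater_mean = mean(.data$value), rater_sd = stats::sd(.data$value),
                     .groups = "drop_last") |>
    dplyr::summarise(value = mean(.data$rater_mean),
                     replicate_sd = sqrt(mean(.data$rater_sd^2)),
                     .groups = "drop")
}

#' Two-sample unpaired Student t-test
#'
#' Pooled-variance (classic Student) test, matching the study protocol;
#' Welch's correction is available behind a flag.
#'
#' @param xs,ys Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance test instead.
#' @return A `cranio_ttest`: list with `t`, `df`, `p`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`, `n_x`, `n_y`, `significant` (p < 0.05).
#' @export
ttest_two_sample <- function(xs, ys, welch = FALSE) {
  stopifnot(length(xs) >= 2, length(ys) >= 2)
  if (stats::sd(xs) == 0 && stats::sd(ys) == 0) {
    # zero pooled variance edge contract: p = 1 on equal means, else p = 0
    eq <- isTRUE(all.equal(mean(xs), mean(ys)))
    return(new_cranio_ttest(t = if (eq) 0 else Inf, df = length(xs) + length(ys) - 2,
                            p = if (eq) 1 else 0, xs, ys))
  }
  ht <- stats::t.test(xs, ys, var.equal = !welch)
  new_cranio_ttest(t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value, xs, ys)
}

new_cranio_ttest <- function(t, df, p, xs, ys) {
  structure(list(
    t = t, df = df, p = p,
    mean_x = mean(xs), mean_y = mean(ys),
    sd_x = stats::sd(xs), sd_y = stats::sd(ys),
    n_x = length(xs), n_y = length(ys),
    significant = p < 0.05
  ), class = "cranio_ttest")
}

#' @export
print.cranio_ttest <- function(x, ...) {
  cat(sprintf("Two-sample Student t-test: t = %.4f, df = %g, p = %.4g%s\n",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Tidy a two-sample t-test result
#' @param x A `cranio_ttest`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.cranio_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_x - x$mean_y, mean_x = x$mean_x, mean_y = x$mean_y,
    statistic = x$t, df = x$df, p.value = x$p, significant = x$significant
  )
}

#' Pooled-variance t-test from summary statistics
#'
#' Classic Student t computed from printed group means, SDs and sizes. Exactly
#' equals [ttest_two_sample()] on raw data with those moments.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return A `cranio_ttest`.
#' @export
#' @examples
#' ttest_from_summary(77.76, 3.82, 30, 73.19, 2.86, 30)
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    eq <- isTRUE(all.equal(m1, m2))
    t <- if (eq) 0 else Inf
    p <- if (eq) 1 else 0
  } else {
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, mean_x = m1, mean_y = m2,
                 sd_x = s1, sd_y = s2, n_x = n1, n_y = n2,
                 significant = p < 0.05), class = "cranio_ttest")
}

#' Group comparison table in the study layout
#'
#' From per-subject measurement tables (one value per subject x measure x side
#' label), builds the three comparisons per bilateral measure — ipsilateral vs
#' contralateral, ipsilateral vs control, contralateral vs control — plus
#' mean +/- SD summaries of the two midline deviations. Controls contribute
#' one value per subject per measure, by default the average of their two
#' sides (`control_sides = "pooled"` keeps both sides as separate values).
#'
#' @param measurements A tibble of per-subject values with columns `subject`,
#'   `group`, `measure`, `side`, `value` (e.g. several [measure_all()] results
#'   bound together, or [collapse_replicates()] output joined to metadata).
#' @param control_sides `"averaged"` (default) or `"pooled"`.
#' @param welch Use Welch's test instead of pooled-variance Student.
#' @return A `comparison_table` tibble: `measure`, `comparison`, per-group
#'   mean/SD/n, `t`, `df`, `p`, `significant`. Deviation rows carry the group
#'   summary with `comparison = "deviation"`.
#' @export
build_comparison_table <- function(measurements, control_sides = c("averaged", "pooled"),
                                   welch = FALSE) {
  control_sides <- match.arg(control_sides)
  m <- tibble::as_tibble(measurements)
  uls <- dplyr::filter(m, .data$group == "ULS", .data$side %in% c("ipsilateral", "contralateral"))
  ctl <- dplyr::filter(m, .data$group == "control", .data$side %in% c("left", "right"))
  if (control_sides == "averaged") {
    ctl <- ctl |>
      dplyr::group_by(.data$subject, .data$measure) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  groups <- list(
    ipsilateral = function(ms) uls$value[uls$measure == ms & uls$side == "ipsilateral"],
    contralateral = function(ms) uls$value[uls$measure == ms & uls$side == "contralateral"],
    control = function(ms) ctl$value[ctl$measure == ms]
  )
  combos <- tibble::tribble(
    ~comparison, ~g1, ~g2,
    "ipsilateral_vs_contralateral", "ipsilateral", "contralateral",
    "ipsilateral_vs_control", "ipsilateral", "control",
    "contralateral_vs_control", "contralateral", "control"
  )
  measures <- intersect(c(bilateral_measures(), volume_measures()), unique(m$measure))
  rows <- purrr::map_dfr(measures, function(ms) {
    purrr::pmap_dfr(combos, function(comparison, g1, g2) {
      x <- groups[[g1]](ms); y <- groups[[g2]](ms)
      if (length(x) < 2 || length(y) < 2) {
        stop(sprintf("group-size error for %s (%s): need >= 2 subjects per group",
                     ms, comparison), call. = FALSE)
      }
      tt <- ttest_two_sample(x, y, welch = welch)
      tibble::tibble(
        measure = ms, comparison = comparison,
        group1 = g1, group2 = g2,
        mean1 = tt$mean_x, sd1 = tt$sd_x, n1 = tt$n_x,
        mean2 = tt$mean_y, sd2 = tt$sd_y, n2 = tt$n_y,
        t = tt$t, df = tt$df, p = tt$p, significant = tt$significant
      )
    })
  })
  devs <- dplyr::filter(m, .data$group == "ULS",
                        .data$measure %in% c("nasal_deviation", "chin_deviation"))
  if (nrow(devs) > 0) {
    dev_rows <- devs |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(mean1 = mean(.data$value), sd1 = stats::sd(.data$value),
                       n1 = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(comparison = "deviation", group1 = "ULS contralateral-signed",
                    group2 = NA_character_, mean2 = NA_real_, sd2 = NA_real_,
                    n2 = NA_integer_, t = NA_real_, df = NA_real_, p = NA_real_,
                    significant = NA)
    rows <- dplyr::bind_rows(rows, dev_rows[, names(rows)])
  }
  out <- dplyr::mutate(rows, facial_third = facial_third(.data$measure), .before = 1)
  class(out) <- c("comparison_table", class(tibble::tibble()))
  out
}

facial_third <- function(measure) {
  upper <- c("fossa_angle", "fossa_volume")
  middle <- c("orbital_volume", "orbital_height", "orbital_width", "orbital_depth",
              "horizontal_orbital_angle", "vertical_orbital_angle",
              "zygomatic_volume", "zygomatic_length", "zygomatic_height",
              "zygomatic_angle", "nasal_deviation")
  dplyr::case_when(
    measure %in% upper ~ "upper",
    measure %in% middle ~ "middle",
    TRUE ~ "lower"
  )
}

#' Glance at a comparison table
#' @param x A `comparison_table`.
#' @param ... Unused.
#' @return One-row tibble with counts of measures, comparisons, and
#'   significant results.
#' @export
glance.comparison_table <- function(x, ...) {
  tests <- dplyr::filter(x, .data$comparison != "deviation")
  tibble::tibble(
    n_measures = dplyr::n_distinct(x$measure),
    n_comparisons = nrow(tests),
    n_significant = sum(tests$significant, na.rm = TRUE)
  )
}

#' Plot a comparison table as mean +/- SD by group
#'
#' @param object A `comparison_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_table <- function(object, ...) {
  long <- object |>
    dplyr::filter(.data$comparison == "ipsilateral_vs_control") |>
    dplyr::select("measure", ipsilateral_mean = "mean1", ipsilateral_sd = "sd1",
                  control_mean = "mean2", control_sd = "sd2") |>
    dplyr::left_join(
      object |>
        dplyr::filter(.data$comparison == "contralateral_vs_control") |>
        dplyr::select("measure", contralateral_mean = "mean1", contralateral_sd = "sd1"),
      by = "measure"
    ) |>
    tidyr::pivot_longer(-"measure", names_to = c("grp", ".value"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(.data$measure, .data$mean, colour = .data$grp)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean ± SD", colour = NULL) +
    ggplot2::theme_minimal()
}
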