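# ggplot2 views of the main result types. Tables are the contract; these
# are conveniences for interactive work and reports.

#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  st <- object$steps
  df <- tibble::tibble(
    time = c(0, rep(st$time, each = 2), object$max_time),
    surv = c(1, 1, rep(head(st$surv, -1), each = 2), rep(tail(st$surv, 1), 2))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves by stratum from an outcome report
#'
#' @param report An [stratify_and_report()] result.
#' @return A ggplot object.
#' @export
plot_km_strata <- function(report) {
  stopifnot(inherits(report, "outcome_report"), !is.null(report$km))
  df <- purrr::imap_dfr(report$km, function(f, nm) {
    st <- f$steps
    tibble::tibble(
      stratum = nm,
      time = c(0, rep(st$time, each = 2), f$max_time),
      surv = c(1, 1, rep(head(st$surv, -1), each = 2), rep(tail(st$surv, 1), 2))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$stratum)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Progression-free survival",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g",
                                     report$logrank$p_value)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lod_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = factor(.data$fraction),
                               y = .data$detected / .data$n_sites)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = "Mix fraction", y = "Fraction of sites detected") +
    ggplot2::theme_minimal()
}

#' Genome-wide log2 copy-number profile plot
#'
#' @param profile A [compute_log2_ratios()] result.
#' @param calls Optional [segment_and_call()] table used to colour called
#'   arms.
#' @return A ggplot object.
#' @export
plot_log2_profile <- function(profile, calls = NULL) {
  stopifnot("log2_ratio" %in% names(profile))
  df <- profile |>
    dplyr::filter(!is.na(.data$log2_ratio)) |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "log2 depth ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  if (!is.null(calls)) {
    called <- calls |> dplyr::filter(.data$call %in% c("gain", "loss"))
    if (nrow(called)) {
      gg <- gg + ggplot2::geom_segment(
        data = called |> dplyr::mutate(
          chrom = factor(.data$chrom, levels = levels(df$chrom))),
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$median_log2, yend = .data$median_log2,
                     colour = .data$call),
        linewidth = 1.2, inherit.aes = FALSE
      )
    }
  }
  gg
}

#' Longitudinal reporter-VAF ("ribbon") plot for one patient
#'
#' @param ribbon The per-variant longitudinal table emitted by
#'   [run_pipeline()] (columns `patient`, `timepoint`, `day`, `chrom`,
#'   `pos`, `vaf`).
#' @param patient Patient id to plot.
#' @return A ggplot object.
#' @export
plot_ribbon <- function(ribbon, patient) {
  df <- ribbon |>
    dplyr::filter(.data$patient == !!patient) |>
    dplyr::mutate(variant = paste0(.data$chrom, ":", .data$pos))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$vaf,
                                   colour = .data$variant,
                                   group = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(trans = "sqrt") +
    ggplot2::labs(x = "Study day", y = "VAF", colour = NULL,
                  title = patient) +
    ggplot2::theme_minimal()
}
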