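#' Mean and SEM over trial means
#'
#' Population summaries are computed over independent trial means, not
#' pooled cells, so the SEM reflects trial-to-trial variability.
#'
#' @param trial_means numeric vector of per-trial means (>= 2 values;
#'   a warning is issued below 3).
#' @return list: `mean`, `sem`, `n`.
#' @export
sem_over_trials <- function(trial_means) {
  trial_means <- trial_means[!is.na(trial_means)]
  n <- length(trial_means)
  if (n < 2) stop("need at least 2 trial means to compute an SEM")
  if (n < 3) warning("fewer than 3 trials: SEM is poorly determined")
  list(mean = mean(trial_means), sem = sd(trial_means) / sqrt(n), n = n)
}

#' Star annotation for a p-value
#'
#' The conventional four-threshold annotation: `****` p < 0.0001,
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p p-value in \[0, 1\].
#' @return one of `"****"`, `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Two-group comparison of trial means
#'
#' Two-sample two-tailed Student's t-test (equal variances by default;
#' set `var.equal = FALSE` for Welch's variant) with the star annotation
#' of [significance_stars()]. Two identical constant groups — zero pooled
#' variance with equal means — are reported as p = 1, `ns`.
#'
#' @param a,b numeric vectors of trial means (each >= 2 values).
#' @param var.equal use the pooled-variance Student's test (default).
#' @return a `group_comparison` list: `mean_a`, `mean_b`, `t`, `p_value`,
#'   `annotation`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, var.equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    res <- list(mean_a = mean(a), mean_b = mean(b), t = 0, p_value = 1,
                annotation = "ns", n_a = length(a), n_b = length(b))
    class(res) <- "group_comparison"
    return(res)
  }
  tt <- t.test(a, b, var.equal = var.equal)
  res <- list(mean_a = mean(a), mean_b = mean(b), t = unname(tt$statistic),
              p_value = tt$p.value, annotation = significance_stars(tt$p.value),
              n_a = length(a), n_b = length(b))
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %.4g vs %.4g: t = %.3f, p = %.3g (%s)\n",
              x$mean_a, x$mean_b, x$t, x$p_value, x$annotation))
  invisible(x)
}

#' Build a figure-style summary report
#'
#' Writes per-condition summary tables and standard figures from the
#' outputs of the upstream modules: a per-cell rho scatter with mean
#' lines, trial-averaged recovery curves with SEM bars, and puncta
#' overlap-fraction histograms. Inputs that are `NULL` are skipped;
#' entirely empty inputs produce empty report files.
#'
#' @param coloc_records optional data.frame of per-cell records carrying a
#'   `condition` column plus [per_cell_coloc()] columns.
#' @param frap_summary optional output of [aggregate_trials()].
#' @param frap_curves optional long curve data.frame (see
#'   [curves_from_traces()]) used for the recovery-curve figure.
#' @param overlap_tables optional named list (by condition) of
#'   [overlap_fractions()] outputs.
#' @param comparisons optional list of `group_comparison` objects, named
#'   `"a_vs_b"`.
#' @param out_dir output directory (created if needed).
#' @param rho_col which rho column to plot from `coloc_records`.
#' @return (invisibly) character vector of files written.
#' @export
build_report <- function(coloc_records = NULL, frap_summary = NULL,
                         frap_curves = NULL, overlap_tables = NULL,
                         comparisons = NULL, out_dir = ".",
                         rho_col = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(path) { written <<- c(written, path); path }

  if (!is.null(coloc_records)) {
    if (nrow(coloc_records) > 0 && !"condition" %in% names(coloc_records)) {
      stop("coloc_records must carry a `condition` column")
    }
    write.csv(coloc_records, w(file.path(out_dir, "coloc_records.csv")),
              row.names = FALSE)
    if (nrow(coloc_records) > 0) {
      if (is.null(rho_col)) {
        rho_col <- grep("^rho_", names(coloc_records), value = TRUE)[1]
      }
      summ <- do.call(rbind, lapply(
        split(coloc_records, coloc_records$condition), function(d) {
          rho <- d[[rho_col]][!is.na(d[[rho_col]])]
          data.frame(condition = d$condition[1], n_cells = length(rho),
                     rho_mean = mean(rho),
                     rho_sem = if (length(rho) > 1) sd(rho) / sqrt(length(rho)) else NA)
        }))
      write.csv(summ, w(file.path(out_dir, "coloc_summary.csv")), row.names = FALSE)
      p <- ggplot2::ggplot(coloc_records,
                           ggplot2::aes(x = .data$condition, y = .data[[rho_col]])) +
        ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 1) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                              color = "blue", linewidth = 0.3) +
        ggplot2::labs(x = NULL, y = expression(rho)) +
        ggplot2::theme_classic()
      ggplot2::ggsave(w(file.path(out_dir, "coloc_scatter.png")), p,
                      width = 5, height = 4)
    }
  }

  if (!is.null(frap_summary)) {
    write.csv(frap_summary, w(file.path(out_dir, "frap_summary.csv")),
              row.names = FALSE)
  }

  if (!is.null(frap_curves) && nrow(frap_curves) > 0) {
    ag <- aggregate(R ~ condition + time_s, data = frap_curves, FUN = mean)
    se <- aggregate(R ~ condition + time_s, data = frap_curves,
                    FUN = function(x) sd(x) / sqrt(length(x)))
    names(se)[names(se) == "R"] <- "sem"
    ag <- merge(ag, se, by = c("condition", "time_s"))
    p <- ggplot2::ggplot(ag, ggplot2::aes(x = .data$time_s, y = .data$R,
                                          color = .data$condition)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$R - .data$sem,
                                          ymax = .data$R + .data$sem),
                             width = 0, alpha = 0.5) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time after bleach (s)", y = "normalized recovery R") +
      ggplot2::theme_classic()
    ggplot2::ggsave(w(file.path(out_dir, "frap_recovery.png")), p,
                    width = 6, height = 4)
  }

  if (!is.null(overlap_tables)) {
    if (is.null(names(overlap_tables)) || any(!nzchar(names(overlap_tables)))) {
      stop("overlap_tables must be a named list (names = condition labels)")
    }
    hist_rows <- do.call(rbind, lapply(names(overlap_tables), function(cond) {
      h <- overlap_tables[[cond]]$histogram
      h$condition <- cond
      h
    }))
    write.csv(hist_rows, w(file.path(out_dir, "overlap_histograms.csv")),
              row.names = FALSE)
    if (sum(hist_rows$count) > 0) {
      p <- ggplot2::ggplot(hist_rows,
                           ggplot2::aes(x = .data$bin_low + 0.05, y = .data$count)) +
        ggplot2::geom_col(width = 0.09) +
        ggplot2::facet_wrap(~condition, ncol = 1) +
        ggplot2::labs(x = "fraction of punctum pixels with GFP", y = "puncta") +
        ggplot2::theme_classic()
      ggplot2::ggsave(w(file.path(out_dir, "overlap_histograms.png")), p,
                      width = 4, height = 2.5 * length(overlap_tables))
    }
  }

  if (!is.null(comparisons)) {
    rows <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cmp <- comparisons[[nm]]
      data.frame(comparison = nm, mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                 t = cmp$t, p_value = cmp$p_value, annotation = cmp$annotation)
    }))
    write.csv(rows, w(file.path(out_dir, "comparisons.csv")), row.names = FALSE)
  }

  invisible(written)
}
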