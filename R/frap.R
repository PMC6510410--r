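#' Measure a FRAP trace from a movie
#'
#' Extracts the bleach-spot mean intensity (`I`) and the whole-nucleus
#' total intensity (`A`) from every frame of an image stack, storing the
#' prebleach frame's values as the `I_o` / `A_o` references and the
#' remaining frames as the post-bleach series with `t = 0` at the first
#' post-bleach frame.
#'
#' @param movie numeric array `h x w x n_frames`.
#' @param nucleus_mask logical matrix selecting the nucleus.
#' @param bleach_roi list with `center` (row, col) and `radius` (px); the
#'   circle must lie inside the nucleus mask.
#' @param prebleach_index index of the prebleach frame (must precede all
#'   post-bleach frames; frames before it are ignored).
#' @param frame_interval_s time between frames, seconds.
#' @return a [frap_trace].
#' @export
measure_trace <- function(movie, nucleus_mask, bleach_roi,
                          prebleach_index = 1L, frame_interval_s = 0.1) {
  d <- dim(movie)
  if (length(d) != 3) stop("`movie` must be a 3D array (h x w x frames)")
  if (!identical(d[1:2], dim(nucleus_mask))) {
    stop("nucleus_mask must match the movie's frame dimensions")
  }
  if (prebleach_index < 1 || prebleach_index >= d[3]) {
    stop("prebleach frame must exist and precede at least one post-bleach frame")
  }
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  spot <- (rr - bleach_roi$center[1])^2 + (cc - bleach_roi$center[2])^2 <=
    bleach_roi$radius^2
  if (!any(spot)) stop("bleach ROI contains no pixels")
  if (any(spot & !nucleus_mask)) stop("bleach ROI extends outside the nucleus mask")
  frame_I <- function(j) mean(movie[, , j][spot])
  frame_A <- function(j) sum(movie[, , j][nucleus_mask])
  post <- (prebleach_index + 1):d[3]
  frap_trace(
    time_s = (seq_along(post) - 1) * frame_interval_s,
    I_t = vapply(post, frame_I, numeric(1)),
    A_t = vapply(post, frame_A, numeric(1)),
    I_o = frame_I(prebleach_index),
    A_o = frame_A(prebleach_index)
  )
}

#' Normalize a FRAP trace by the whole-nucleus ratio
#'
#' Computes the double-normalized recovery
#' \deqn{R(t) = \frac{A_o \, I_t}{A_t \, I_o}}
#' where `I` is the bleach-spot intensity, `A` the whole-nucleus
#' intensity, and the `o` subscript denotes the prebleach frame. Any
#' multiplicative signal loss applied equally to spot and nucleus (e.g.
#' acquisition photobleaching, or a detector gain change) cancels exactly,
#' so `R` is the prebleach-normalized spot recovery corrected for
#' acquisition decay.
#'
#' @param trace a [frap_trace].
#' @return a `normalized_recovery`: data.frame with `time_s` and `R`.
#' @export
normalize_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$A_t <= 0)) {
    stop("non-positive whole-nucleus intensity: segmentation failure")
  }
  structure(
    data.frame(time_s = trace$time_s,
               R = (trace$A_o * trace$I_t) / (trace$A_t * trace$I_o)),
    class = c("normalized_recovery", "data.frame")
  )
}

#' Fit the one-component exponential recovery
#'
#' Nonlinear least-squares fit of
#' \deqn{R(t) = P - (P - R_0) e^{-k t}}
#' to a normalized recovery curve, with a free post-bleach intercept
#' `R0`, plateau `P` and rate constant `k` bounded to `k` in (0, 100\],
#' `0 <= R0 <= P <= 1.5`. Initial guesses: `R0` = first point, `P` = mean
#' of the last five points, `k` = ln(2) / time-to-half-rise. Percent
#' recovery is `100 * P` (plateau of the prebleach-normalized curve); the
#' classical mobile fraction `(P - R0) / (1 - R0)` is reported as a
#' secondary quantity.
#'
#' @param norm a `normalized_recovery` (or data.frame with `time_s`, `R`).
#' @param min_points minimum number of post-bleach points required.
#' @return a `frap_fit` list: `k`, `percent_recovery`, `R0_fit`,
#'   `plateau`, `mobile_fraction_pct`, `rmse`, `n_points`, `converged`.
#' @export
fit_recovery <- function(norm, min_points = 10) {
  t <- norm$time_s
  R <- norm$R
  keep <- is.finite(t) & is.finite(R)
  t <- t[keep]; R <- R[keep]
  failed <- function() {
    structure(list(k = NA_real_, percent_recovery = NA_real_,
                   R0_fit = NA_real_, plateau = NA_real_,
                   mobile_fraction_pct = NA_real_, rmse = NA_real_,
                   n_points = length(t), converged = FALSE),
              class = "frap_fit")
  }
  if (length(t) < min_points) {
    stop(sprintf("need at least %d post-bleach points", min_points))
  }
  if (sd(R) == 0) return(failed())

  R0_0 <- R[1]
  P_0 <- mean(tail(R, 5))
  half <- R0_0 + (P_0 - R0_0) / 2
  i_half <- which(R >= half)[1]
  t_half <- if (!is.na(i_half) && t[i_half] > 0) t[i_half] else max(t[2], 1e-3)
  k_0 <- min(max(log(2) / t_half, 1e-3), 100)
  P_0 <- min(max(P_0, 1e-3), 1.5)
  R0_0 <- min(max(R0_0, 0), P_0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      R ~ P - (P - R0) * exp(-k * t),
      data = data.frame(t = t, R = R),
      start = list(P = P_0, R0 = R0_0, k = k_0),
      lower = c(P = 0, R0 = 0, k = 1e-6),
      upper = c(P = 1.5, R0 = 1.5, k = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  cf <- coef(fit)
  if (cf[["R0"]] > cf[["P"]] + 1e-8 || cf[["k"]] <= 1e-6) return(failed())
  resid <- R - predict(fit)
  structure(list(
    k = unname(cf[["k"]]),
    percent_recovery = 100 * unname(cf[["P"]]),
    R0_fit = unname(cf[["R0"]]),
    plateau = unname(cf[["P"]]),
    mobile_fraction_pct = 100 * (cf[["P"]] - cf[["R0"]]) / (1 - cf[["R0"]]),
    rmse = sqrt(mean(resid^2)),
    n_points = length(t),
    converged = TRUE
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<frap_fit> k = %.4g /s, recovery = %.1f%% (R0 = %.3f, rmse = %.2g, n = %d)\n",
                x$k, x$percent_recovery, x$R0_fit, x$rmse, x$n_points))
  } else {
    cat("<frap_fit> not converged\n")
  }
  invisible(x)
}

#' Aggregate normalized recovery curves over trials
#'
#' Implements the two complementary summaries used for multi-trial FRAP
#' designs: (a) per-trial curves are averaged pointwise and fitted once
#' per trial, giving a mean and SEM of `k` and percent recovery over
#' trials; and (b) the trial-mean curves are averaged again into one
#' condition-level curve that receives a single fit. Both are reported.
#'
#' @param curves data.frame with columns `condition`, `trial`, `cell`,
#'   `time_s`, `R` (one row per trace per time point); build it with
#'   [curves_from_traces()].
#' @return data.frame, one row per condition: `condition`, `n_trials`,
#'   `k_mean`, `k_sem`, `pct_recovery_mean`, `pct_recovery_sem` (over
#'   per-trial fits), and `k_avg_curve`, `pct_recovery_avg_curve` (single
#'   fit of the trial-averaged curve). SEM columns are `NA` (with a
#'   warning) below 3 trials.
#' @export
aggregate_trials <- function(curves) {
  need <- c("condition", "trial", "cell", "time_s", "R")
  if (!all(need %in% names(curves))) {
    stop("curves must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(curves, curves$condition), function(d) {
    trial_curves <- lapply(split(d, d$trial), function(td) {
      ag <- aggregate(R ~ time_s, data = td, FUN = mean)
      ag[order(ag$time_s), ]
    })
    tg <- lapply(trial_curves, `[[`, "time_s")
    for (g in tg) {
      if (!isTRUE(all.equal(g, tg[[1]]))) {
        stop("trials must share a common time grid for pointwise averaging")
      }
    }
    trial_fits <- lapply(trial_curves, fit_recovery)
    ok <- vapply(trial_fits, `[[`, logical(1), "converged")
    if (!any(ok)) stop("no trial-level fit converged for condition ", d$condition[1])
    ks <- vapply(trial_fits[ok], `[[`, numeric(1), "k")
    ps <- vapply(trial_fits[ok], `[[`, numeric(1), "percent_recovery")
    n_tr <- sum(ok)
    if (n_tr < 3) {
      warning("fewer than 3 trials for condition ", d$condition[1],
              ": SEM suppressed")
      sem_k <- sem_p <- NA_real_
    } else {
      sem_k <- sd(ks) / sqrt(n_tr)
      sem_p <- sd(ps) / sqrt(n_tr)
    }
    Rmat <- vapply(trial_curves, `[[`, numeric(nrow(trial_curves[[1]])), "R")
    avg_curve <- data.frame(time_s = tg[[1]], R = rowMeans(as.matrix(Rmat)))
    avg_fit <- fit_recovery(avg_curve)
    data.frame(condition = d$condition[1], n_trials = n_tr,
               k_mean = mean(ks), k_sem = sem_k,
               pct_recovery_mean = mean(ps), pct_recovery_sem = sem_p,
               k_avg_curve = avg_fit$k,
               pct_recovery_avg_curve = avg_fit$percent_recovery,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Long-format normalized curves from traces
#'
#' Normalizes each trace ([normalize_recovery()]) and stacks the results
#' into the long data.frame expected by [aggregate_trials()].
#'
#' @param traces list of [frap_trace] objects.
#' @param index data.frame with columns `condition`, `trial`, `cell` and
#'   `trace` (list index into `traces`), as produced by
#'   [simulate_frap_experiment()].
#' @return data.frame: `condition`, `trial`, `cell`, `time_s`, `R`.
#' @export
curves_from_traces <- function(traces, index) {
  rows <- lapply(seq_len(nrow(index)), function(i) {
    nr <- normalize_recovery(traces[[index$trace[i]]])
    data.frame(condition = index$condition[i], trial = index$trial[i],
               cell = index$cell[i], time_s = nr$time_s, R = nr$R,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bleach-depth quality control
#'
#' The bleach-depth fraction of a trace is the first post-bleach spot
#' intensity divided by the prebleach spot intensity. When two conditions
#' are compared, equal bleach depths support attributing differences in
#' recovery kinetics to the protein rather than to the bleach itself.
#'
#' @param traces list of [frap_trace] objects.
#' @param groups optional factor/character vector (one per trace) with
#'   exactly two levels; if given, a two-sample t-test compares the groups.
#' @param var.equal passed to [stats::t.test()] (Student's test when TRUE).
#' @return list: `fractions` (data.frame: group, fraction), and when two
#'   groups are given, `p_value`, `t`, `annotation` (star string from
#'   [significance_stars()]).
#' @export
bleach_depth_qc <- function(traces, groups = NULL, var.equal = TRUE) {
  if (length(traces) < 1) stop("need at least one trace")
  frac <- vapply(traces, function(tr) {
    if (tr$I_o == 0) stop("prebleach spot intensity is zero")
    tr$I_t[1] / tr$I_o
  }, numeric(1))
  out <- list(fractions = data.frame(
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    fraction = frac, stringsAsFactors = FALSE))
  if (!is.null(groups)) {
    lev <- unique(as.character(groups))
    if (length(lev) != 2) stop("`groups` must define exactly two groups")
    a <- frac[groups == lev[1]]
    b <- frac[groups == lev[2]]
    tt <- t.test(a, b, var.equal = var.equal)
    out$t <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out$annotation <- significance_stars(tt$p.value)
  }
  out
}
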