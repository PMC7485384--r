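#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward (zero phase lag),
#' with a 16 Hz cut-off by default, as used to condition experimental
#' kinematics and kinetics before comparison.  DC gain is 1.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz); must exceed `2 * fc`.
#' @param order filter order.
#' @param fc cut-off frequency (Hz).
#' @return the filtered series.
#' @export
butterworth_lowpass <- function(x, fs, order = 2, fc = 16) {
  if (fs <= 2 * fc)
    rlang::abort(sprintf("sampling rate %g Hz must exceed twice the cut-off %g Hz", fs, fc))
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses start/end transients of the
  # forward-backward pass (so a constant input passes through unchanged)
  n <- length(x)
  np <- min(n - 1, max(24, round(6 * fs / fc)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

#' Resample a trajectory table onto target times
#'
#' Linear interpolation of every non-time column at the requested time
#' points; extrapolation is an error.
#'
#' @param table data frame with a `time_s` column.
#' @param target_times times (s) to interpolate at; must lie within the
#'   table's time span.
#' @return tibble at the target times.
#' @export
resample_to <- function(table, target_times) {
  if (!"time_s" %in% names(table)) rlang::abort("table must have a time_s column")
  if (min(target_times) < min(table$time_s) - 1e-9 ||
      max(target_times) > max(table$time_s) + 1e-9)
    rlang::abort("target times extend beyond the source time span (extrapolation)")
  cols <- setdiff(names(table), "time_s")
  out <- tibble::tibble(time_s = target_times)
  for (cn in cols)
    out[[cn]] <- stats::approx(table$time_s, table[[cn]], xout = target_times,
                               rule = 2)$y
  out
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; the p-value comes from the t-transform with
#' n - 2 degrees of freedom (two-sided).  A zero-variance input is
#' undefined and reported as `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return tibble with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3) rlang::abort("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

trajectory_signals <- function() {
  tibble::tibble(
    column = c("hip_deg", "knee_deg", "ankle_deg", "hip_Nm", "knee_Nm", "ankle_Nm"),
    kind = rep(c("angle", "moment"), each = 3),
    joint = rep(c("hip", "knee", "ankle"), 2)
  )
}

#' Compare simulated and experimental trajectories
#'
#' Correlates the six signals (hip/knee/ankle angles and moments) of a
#' simulated trajectory table against an experimental one.  The experimental
#' series are low-pass filtered at their native rate (zero-phase, 2nd-order
#' Butterworth, 16 Hz) and then resampled onto the simulation time points;
#' the simulated series, being noise-free model output, are not filtered.
#'
#' @param sim,exp trajectory tables in the evaluation dialect
#'   (`time_s, hip_deg, knee_deg, ankle_deg, hip_Nm, knee_Nm, ankle_Nm`).
#' @param filter_exp apply the Butterworth filter to the experimental table.
#' @param fc filter cut-off (Hz).
#' @param start_offset drop this much time (s) from the start of both tables
#'   before comparison (used for second-sample analyses).
#' @return an `sr_comparison` tibble: one row per signal with `column`,
#'   `kind`, `joint`, `r`, `p`, `n`, `mean_offset` (experimental minus
#'   simulated mean, deg or N m).
#' @export
compare_trajectories <- function(sim, exp, filter_exp = TRUE, fc = 16,
                                 start_offset = 0) {
  sigs <- trajectory_signals()
  for (tb in list(sim = sim, exp = exp)) {
    miss <- setdiff(c("time_s", sigs$column), names(tb))
    if (length(miss) > 0)
      rlang::abort(paste("trajectory table missing column(s):", paste(miss, collapse = ", ")))
  }
  if (start_offset > 0) {
    sim <- sim[sim$time_s >= start_offset, ]
    exp <- exp[exp$time_s >= start_offset, ]
  }
  if (filter_exp) {
    fs <- 1 / stats::median(diff(exp$time_s))
    for (cn in sigs$column) exp[[cn]] <- butterworth_lowpass(exp[[cn]], fs, fc = fc)
  }
  keep <- sim$time_s >= min(exp$time_s) - 1e-9 & sim$time_s <= max(exp$time_s) + 1e-9
  sim <- sim[keep, ]
  exp_rs <- resample_to(exp, sim$time_s)
  rows <- lapply(seq_len(nrow(sigs)), function(i) {
    cn <- sigs$column[i]
    pr <- pearson(sim[[cn]], exp_rs[[cn]])
    tibble::tibble(column = cn, kind = sigs$kind[i], joint = sigs$joint[i],
                   r = pr$r, p = pr$p, n = pr$n,
                   mean_offset = mean(exp_rs[[cn]]) - mean(sim[[cn]]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sr_comparison", class(out))
  out
}

#' Write / read an evaluation trajectory table CSV
#'
#' @param table tibble in the evaluation dialect.
#' @param path file path.
#' @export
write_trajectory_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  d <- utils::read.csv(path)
  miss <- setdiff(c("time_s", trajectory_signals()$column), names(d))
  if (length(miss) > 0)
    rlang::abort(paste("trajectory table missing column(s):", paste(miss, collapse = ", ")))
  tibble::as_tibble(d)
}
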