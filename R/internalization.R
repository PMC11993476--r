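# Antibody internalization kinetics from flow-cytometry MFI time series.

#' Antibody-bound MFI time series
#'
#' Mean fluorescence intensity of surface-bound antibody at increasing
#' incubation times. Times must start at 0 (the baseline before
#' internalization) and be strictly increasing; all MFI values positive at
#' baseline.
#'
#' @param cell_line Label.
#' @param times Minutes, strictly increasing from 0.
#' @param mfi MFI per time, same length as `times`.
#' @param replicate_id Optional replicate label.
#' @return An object of class `mfi_series`.
#' @export
mfi_series <- function(cell_line, times, mfi, replicate_id = NULL) {
  if (length(times) != length(mfi))
    stop("times and mfi must have equal length", call. = FALSE)
  if (times[1L] != 0)
    stop("times must include 0 as the first measurement", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (mfi[1L] <= 0)
    stop("mfi at t = 0 must be positive", call. = FALSE)
  if (any(mfi < 0))
    stop("mfi values must be non-negative", call. = FALSE)
  structure(list(cell_line = cell_line, times = as.numeric(times),
                 mfi = as.numeric(mfi), replicate_id = replicate_id),
            class = "mfi_series")
}

#' @export
print.mfi_series <- function(x, ...) {
  cat("mfi_series [", x$cell_line, "]: ", length(x$times),
      " time points, t = ", paste(x$times, collapse = ", "), " min\n",
      sep = "")
  invisible(x)
}

#' Read an MFI time-series CSV
#'
#' Columns: `cell_line`, `time_min`, `mfi`, optional `replicate`. Replicates
#' are averaged per time point before curve construction.
#'
#' @param path CSV path.
#' @param cell_line Optional filter when the file holds several lines.
#' @return An [mfi_series].
#' @export
read_mfi_series <- function(path, cell_line = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "time_min", "mfi")
  if (!all(need %in% names(df)))
    stop("MFI CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(cell_line)) df <- df[df$cell_line == cell_line, ]
  if (nrow(df) == 0) stop("no MFI rows for requested cell line",
                          call. = FALSE)
  agg <- stats::aggregate(mfi ~ time_min, df, mean)
  agg <- agg[order(agg$time_min), ]
  mfi_series(cell_line = df$cell_line[1L], times = agg$time_min,
             mfi = agg$mfi)
}

#' Internalization efficiency at a time point
#'
#' `(1 - MFI(t) / MFI(0)) * 100`: the percentage of initially surface-bound
#' antibody no longer detectable at the surface, i.e. endocytosed by time t.
#' Values may be negative under assay noise and are not clipped; a value
#' below -5% triggers a warning since it usually signals a staining or
#' gating problem.
#'
#' @param mfi_t MFI at incubation time t (>= 0); vectorised.
#' @param mfi_0 MFI at t = 0 (> 0).
#' @return Efficiency in percent.
#' @examples
#' internalization_efficiency(533, 1000)  # 46.7
#' @export
internalization_efficiency <- function(mfi_t, mfi_0) {
  if (!is.numeric(mfi_0) || any(mfi_0 <= 0))
    stop("mfi_0 must be positive", call. = FALSE)
  if (any(mfi_t < 0)) stop("mfi_t must be non-negative", call. = FALSE)
  eff <- (1 - mfi_t / mfi_0) * 100
  if (any(eff < -5))
    warning("internalization efficiency below -5%: check assay baseline",
            call. = FALSE)
  eff
}

#' Build an internalization curve from an MFI series
#'
#' Converts the series to efficiencies, takes the final-time efficiency as
#' the empirical plateau, and (optionally) fits the monoexponential model
#' `E(t) = 100 * p * (1 - exp(-k t))` by bounded least squares, where `p` is
#' the internalizable fraction and `k` the rate constant (1/min).
#'
#' @param series An [mfi_series] with at least 3 time points.
#' @param fit Fit the monoexponential model (default TRUE).
#' @return A list of class `internalization_curve`: `times`, `efficiency`
#'   (percent), `plateau_empirical`, and when fitted `fit = list(p, k, rss)`.
#' @export
build_curve <- function(series, fit = TRUE) {
  stopifnot(inherits(series, "mfi_series"))
  if (length(series$times) < 3L)
    stop("at least 3 time points are required", call. = FALSE)
  eff <- internalization_efficiency(series$mfi, series$mfi[1L])
  curve <- list(
    cell_line = series$cell_line,
    times = series$times,
    efficiency = eff,
    plateau_empirical = eff[length(eff)],
    fit = NULL
  )
  if (fit) curve$fit <- fit_internalization(series$times, eff)
  structure(curve, class = "internalization_curve")
}

# Bounded Levenberg-Marquardt fit of E(t) = 100 p (1 - exp(-k t)).
fit_internalization <- function(times, eff) {
  p0 <- min(max(eff[length(eff)] / 100, 0.01), 0.99)
  k0 <- 0.01
  df <- data.frame(t = times, e = eff)
  fit <- tryCatch(
    minpack.lm::nlsLM(e ~ 100 * p * (1 - exp(-k * t)), data = df,
                      start = list(p = p0, k = k0),
                      lower = c(p = 0, k = 0), upper = c(p = 1, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  list(p = unname(co["p"]), k = unname(co["k"]),
       rss = sum(stats::residuals(fit)^2))
}

#' @export
print.internalization_curve <- function(x, ...) {
  cat("internalization_curve [", x$cell_line, "]: plateau ",
      sprintf("%.1f%%", x$plateau_empirical), sep = "")
  if (!is.null(x$fit))
    cat(sprintf(" (fit: p = %.3f, k = %.4f/min)", x$fit$p, x$fit$k))
  cat("\n")
  invisible(x)
}
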