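#' Construct a FRAP trace
#'
#' One worm's raw fluorescence time series: a bleached region of interest and
#' a non-bleached reference region recorded on the same uniform frame grid
#' (12-bit intensity scale, arbitrary units).
#'
#' @param worm_id Identifier.
#' @param group Group label (genotype / condition / temperature).
#' @param times Frame times in seconds; strictly increasing, uniform grid.
#' @param bleach_roi,reference_roi Intensity series, same length as `times`.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(worm_id, group, times, bleach_roi, reference_roi) {
  times <- as.numeric(times)
  bleach_roi <- as.numeric(bleach_roi)
  reference_roi <- as.numeric(reference_roi)
  n <- length(times)
  if (n < 10L) stop("a FRAP trace needs at least 10 frames")
  if (length(bleach_roi) != n || length(reference_roi) != n) {
    stop("times, bleach_roi and reference_roi must have equal length")
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("times must lie on a uniform frame grid")
  }
  structure(
    list(worm_id = worm_id, group = group, times = times,
         bleach_roi = bleach_roi, reference_roi = reference_roi),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace %s [%s]: %d frames, dt = %g s\n",
              x$worm_id, x$group, length(x$times), x$times[2] - x$times[1]))
  invisible(x)
}

frame_interval <- function(trace) mean(diff(trace$times))

#' Locate the bleach frame
#'
#' The bleach frame is the frame with the lowest bleached-ROI intensity
#' (immediately after the bleach pulse); ties are broken by the earliest
#' frame. At least five frames must precede it, since they form the
#' pre-bleach baseline window.
#'
#' @param trace A [frap_trace()].
#' @return Integer frame index (1-based).
#' @export
detect_bleach_index <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  idx <- which.min(trace$bleach_roi)
  if (idx <= 5L) {
    stop(sprintf(
      "bleach minimum at frame %d: no room for the 5-frame pre-bleach window", idx))
  }
  idx
}

#' Correct for acquisition photobleaching
#'
#' Repeated scanning slowly bleaches the whole field. The trend is estimated
#' by a least-squares line fitted to the non-bleached reference region over
#' all frames, and both series are divided by that trend normalized to the
#' first frame. A zero fitted slope leaves the trace unchanged; the corrected
#' reference region has (numerically) zero slope.
#'
#' @param trace A [frap_trace()] (reference series of length >= 3).
#' @return A corrected `frap_trace`.
#' @export
correct_acquisition_bleaching <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (length(trace$reference_roi) < 3L) stop("reference series needs >= 3 frames")
  fit <- stats::lm(reference_roi ~ times,
                   data = data.frame(times = trace$times,
                                     reference_roi = trace$reference_roi))
  trend <- unname(stats::fitted(fit))
  if (any(trend <= 0)) {
    stop("fitted reference trend is not positive over the observation window")
  }
  factor <- trend / trend[1]
  frap_trace(trace$worm_id, trace$group, trace$times,
             trace$bleach_roi / factor, trace$reference_roi / factor)
}

#' Normalize a FRAP trace
#'
#' The post-bleach minimum is subtracted from all intensities (setting the
#' post-bleach fluorescence to zero), the mean of the five frames preceding
#' the bleach frame defines the pre-bleach value, and all intensities are
#' divided by that (min-subtracted) value:
#' \deqn{f(t) = \frac{F(t) - F_{min}}{\bar F_{pre} - F_{min}}.}
#' The normalized curve is therefore 0 at the bleach frame and averages 1
#' over the pre-bleach window, and the recovery plateau reads directly as the
#' mobile fraction of the bleached-away signal.
#'
#' @param trace A [frap_trace()] (acquisition-bleaching corrected).
#' @param bleach_index Bleach frame index; defaults to [detect_bleach_index()].
#' @return An object of class `frap_norm`: `times`, `f_norm`, `bleach_index`,
#'   `prebleach_window` (the 5 frame indices before the bleach frame),
#'   `qc_flags`, and the originating ids.
#' @export
normalize_trace <- function(trace, bleach_index = detect_bleach_index(trace)) {
  stopifnot(inherits(trace, "frap_trace"))
  if (bleach_index <= 5L) stop("bleach_index must leave 5 pre-bleach frames")
  f <- trace$bleach_roi
  fmin <- f[bleach_index]
  window <- (bleach_index - 5L):(bleach_index - 1L)
  fpre <- mean(f[window])
  if (fpre - fmin <= 0) {
    stop("zero dynamic range: pre-bleach mean does not exceed the post-bleach minimum")
  }
  structure(
    list(worm_id = trace$worm_id, group = trace$group, times = trace$times,
         f_norm = (f - fmin) / (fpre - fmin),
         bleach_index = as.integer(bleach_index),
         prebleach_window = window, qc_flags = character(0)),
    class = "frap_norm"
  )
}

#' @export
print.frap_norm <- function(x, ...) {
  cat(sprintf("normalized FRAP trace %s [%s]: bleach at frame %d of %d\n",
              x$worm_id, x$group, x$bleach_index, length(x$times)))
  invisible(x)
}

#' @export
plot.frap_norm <- function(x, ...) {
  rel <- x$times - x$times[x$bleach_index]
  graphics::plot(rel, x$f_norm, type = "l", xlab = "time after bleach (s)",
                 ylab = "normalized fluorescence",
                 main = sprintf("%s [%s]", x$worm_id, x$group), ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey50")
  invisible(x)
}

#' Model-free recovery estimates
#'
#' The mean of the final five normalized measurements approximates the
#' recovery plateau and is reported as both the maximum recovery and the
#' mobile fraction. The half-time of recovery is the time (relative to the
#' bleach frame) at which the curve first crosses half of the maximum
#' recovery from below, located by linear interpolation between the
#' bracketing frames. If the curve never reaches half of the plateau the
#' half-time is `NA` and a QC flag is set; a mobile fraction above 1.2
#' (possible with noise) also sets a flag.
#'
#' @param norm A [normalize_trace()] result with at least 5 frames after the
#'   bleach frame.
#' @return An object of class `frap_estimate` with `t_half` (s),
#'   `mobile_fraction`, `max_recovery`, `qc_flags`, plus worm/group ids.
#' @export
estimate_recovery <- function(norm) {
  stopifnot(inherits(norm, "frap_norm"))
  bi <- norm$bleach_index
  n <- length(norm$f_norm)
  if (n - bi < 5L) stop("need at least 5 post-bleach frames")
  f <- norm$f_norm
  plateau <- mean(f[(n - 4L):n])
  flags <- character(0)
  if (plateau > 1.2) flags <- c(flags, "mobile_fraction_gt_1.2")
  half <- plateau / 2
  t_half <- NA_real_
  if (plateau > 0) {
    post <- bi:n
    rel <- norm$times[post] - norm$times[bi]
    fp <- f[post]
    cross <- which(fp[-1] >= half & fp[-length(fp)] < half)
    if (length(cross) > 0) {
      j <- cross[1]
      t_half <- rel[j] + (half - fp[j]) / (fp[j + 1] - fp[j]) * (rel[j + 1] - rel[j])
    }
  }
  if (is.na(t_half)) flags <- c(flags, "never_reaches_half_recovery")
  structure(
    list(worm_id = norm$worm_id, group = norm$group,
         t_half = t_half, mobile_fraction = plateau, max_recovery = plateau,
         qc_flags = flags),
    class = "frap_estimate"
  )
}

#' @export
print.frap_estimate <- function(x, ...) {
  cat(sprintf("FRAP estimate %s [%s]: mobile fraction %.3f, t_half %s s%s\n",
              x$worm_id, x$group, x$mobile_fraction,
              ifelse(is.na(x$t_half), "NA", sprintf("%.3f", x$t_half)),
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @export
coef.frap_estimate <- function(object, ...) {
  c(t_half = object$t_half, mobile_fraction = object$mobile_fraction)
}

#' Exponential-recovery cross-check fit
#'
#' Least-squares fit of the single-exponential recovery
#' \eqn{M (1 - 2^{-t/\tau})} (half-time parameterization, so `tau` is directly
#' comparable to the model-free half-time) to the post-bleach segment of a
#' normalized trace. This is a consistency cross-check for the model-free
#' estimates, not the primary estimator. Non-convergence or an unidentifiable
#' time constant (e.g. a flat-zero curve) is flagged rather than raised.
#'
#' @param norm A [normalize_trace()] result with >= 8 post-bleach frames.
#' @return An object of class `frap_expfit`: `m_fit`, `tau_fit`, `rss`,
#'   `converged`, `qc_flags`, `fitted`, `residuals`, `times_rel`.
#' @export
fit_exponential <- function(norm) {
  stopifnot(inherits(norm, "frap_norm"))
  bi <- norm$bleach_index
  n <- length(norm$f_norm)
  if (n - bi < 8L) stop("need at least 8 post-bleach frames")
  post <- bi:n
  t <- norm$times[post] - norm$times[bi]
  y <- norm$f_norm[post]
  flags <- character(0)
  plateau <- mean(y[(length(y) - 4L):length(y)])
  # start values from the model-free estimates
  m0 <- max(plateau, 1e-3)
  est <- tryCatch(estimate_recovery(norm)$t_half, error = function(e) NA_real_)
  tau0 <- if (is.finite(est) && est > 0) est else max(t) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ m * (1 - 2^(-t / tau)),
                      start = list(m = m0, tau = tau0),
                      lower = c(0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    flags <- c(flags, "fit_not_converged")
    return(structure(list(m_fit = NA_real_, tau_fit = NA_real_, rss = NA_real_,
                          converged = FALSE, qc_flags = flags,
                          fitted = rep(NA_real_, length(t)),
                          residuals = rep(NA_real_, length(t)), times_rel = t),
                     class = "frap_expfit"))
  }
  cf <- stats::coef(fit)
  if (cf[["m"]] < 1e-3) flags <- c(flags, "tau_unidentifiable")
  fv <- as.numeric(stats::fitted(fit))
  structure(
    list(m_fit = unname(cf[["m"]]), tau_fit = unname(cf[["tau"]]),
         rss = sum((y - fv)^2), converged = TRUE, qc_flags = flags,
         fitted = fv, residuals = y - fv, times_rel = t),
    class = "frap_expfit"
  )
}

#' @export
print.frap_expfit <- function(x, ...) {
  cat(sprintf("exponential recovery fit: M = %.4f, tau = %.4f s, rss = %.3g%s\n",
              x$m_fit, x$tau_fit, x$rss,
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @export
coef.frap_expfit <- function(object, ...) {
  c(m = object$m_fit, tau = object$tau_fit)
}

#' @export
fitted.frap_expfit <- function(object, ...) object$fitted

#' @export
residuals.frap_expfit <- function(object, ...) object$residuals

process_trace <- function(trace) {
  corrected <- correct_acquisition_bleaching(trace)
  normalize_trace(corrected)
}

#' Group-level FRAP summary
#'
#' Runs the full pipeline (acquisition-bleaching correction, normalization,
#' model-free estimation) on every trace, aligns normalized curves on the
#' bleach frame, and summarizes each group as mean +/- sem per time point.
#' Pairwise group differences in half-time and mobile fraction are tested
#' with Welch t-tests ([welch_t()]).
#'
#' @param traces List of [frap_trace()] objects sharing one frame interval.
#' @param groups Group labels; defaults to each trace's `group` field.
#' @return An object of class `frap_group_summary` with components
#'   `estimates` (data frame of per-worm estimates), `curves` (per-group data
#'   frames with `time_rel`, `mean`, `sem`, `n`), and `tests` (data frame of
#'   pairwise Welch tests on `t_half` and `mobile_fraction`).
#' @export
summarize_group <- function(traces, groups = NULL) {
  stopifnot(is.list(traces), length(traces) >= 2L)
  if (is.null(groups)) groups <- vapply(traces, function(tr) as.character(tr$group), "")
  stopifnot(length(groups) == length(traces))
  dts <- vapply(traces, frame_interval, 0)
  if (max(dts) - min(dts) > 1e-6 * mean(dts)) {
    stop("traces have mixed frame intervals; no resampling is performed")
  }
  dt <- mean(dts)
  norms <- lapply(traces, process_trace)
  ests <- lapply(norms, estimate_recovery)
  estimates <- data.frame(
    worm_id = vapply(norms, function(x) as.character(x$worm_id), ""),
    group = groups,
    t_half = vapply(ests, function(x) x$t_half, 0),
    mobile_fraction = vapply(ests, function(x) x$mobile_fraction, 0),
    qc = vapply(ests, function(x) paste(x$qc_flags, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  # align on the bleach frame: frame offset k = index - bleach_index
  curves <- list()
  for (g in unique(groups)) {
    members <- norms[groups == g]
    if (length(members) < 2L) stop(sprintf("group '%s' has fewer than 2 traces", g))
    lo <- max(vapply(members, function(x) 1L - x$bleach_index, 0L))
    hi <- min(vapply(members, function(x) length(x$f_norm) - x$bleach_index, 0L))
    ks <- lo:hi
    mat <- vapply(members, function(x) x$f_norm[x$bleach_index + ks],
                  numeric(length(ks)))
    mn <- rowMeans(mat)
    sem <- apply(mat, 1, stats::sd) / sqrt(ncol(mat))
    curves[[g]] <- data.frame(time_rel = ks * dt, mean = mn, sem = sem,
                              n = ncol(mat))
  }
  gl <- unique(groups)
  tests <- NULL
  if (length(gl) >= 2L) {
    pairs <- utils::combn(gl, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      rows <- lapply(c("t_half", "mobile_fraction"), function(metric) {
        a <- estimates[[metric]][estimates$group == pr[1]]
        b <- estimates[[metric]][estimates$group == pr[2]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) {
          return(data.frame(group_a = pr[1], group_b = pr[2], metric = metric,
                            mean_a = NA, mean_b = NA, t = NA, df = NA, p = NA))
        }
        w <- welch_t(a, b)
        data.frame(group_a = pr[1], group_b = pr[2], metric = metric,
                   mean_a = w$mean_a, mean_b = w$mean_b,
                   t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }
  structure(list(estimates = estimates, curves = curves, tests = tests,
                 frame_interval = dt),
            class = "frap_group_summary")
}

#' @export
print.frap_group_summary <- function(x, ...) {
  cat("FRAP group summary\n")
  for (g in names(x$curves)) {
    e <- x$estimates[x$estimates$group == g, ]
    cat(sprintf("  %s: n = %d, t_half = %.2f s, mobile fraction = %.3f\n",
                g, nrow(e), mean(e$t_half, na.rm = TRUE),
                mean(e$mobile_fraction)))
  }
  if (!is.null(x$tests)) {
    cat("pairwise Welch tests:\n")
    print(x$tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.frap_group_summary <- function(x, ...) {
  cols <- seq_along(x$curves)
  xr <- range(unlist(lapply(x$curves, `[[`, "time_rel")))
  yr <- range(unlist(lapply(x$curves, function(d) c(d$mean - d$sem, d$mean + d$sem))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time after bleach (s)",
                 ylab = "normalized fluorescence (mean +/- sem)", ...)
  for (i in seq_along(x$curves)) {
    d <- x$curves[[i]]
    graphics::lines(d$time_rel, d$mean, col = cols[i])
    graphics::arrows(d$time_rel, d$mean - d$sem, d$time_rel, d$mean + d$sem,
                     length = 0.02, angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("bottomright", legend = names(x$curves), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
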