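# FRAP recovery kinetics: trace normalisation, one-site specific-binding
# fits, and nested-model half-time comparison by the extra-sum-of-squares
# F-test.
#
# Recovery model: Y(t) = Ymax * t / (t_half + t), with t = 0 at the first
# post-bleach frame. For a fixed t_half the least-squares Ymax has the
# closed form sum(y*x)/sum(x^2) with x = t/(t_half + t), so all fits reduce
# to a deterministic one-dimensional profile optimisation over t_half.

#' Construct a FRAP trace
#'
#' @param times post-bleach acquisition times in seconds, strictly
#'   increasing, with `t = 0` at the first post-bleach frame.
#' @param intensities spot intensities (arbitrary units), one per time point.
#' @param prebleach_value spot intensity immediately before bleaching.
#' @param postbleach_value spot intensity immediately after bleaching; must
#'   be below `prebleach_value`.
#' @param id optional trace identifier.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, prebleach_value, postbleach_value,
                       id = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    validation_error("times and intensities must have equal length")
  if (any(diff(times) <= 0))
    validation_error("times must be strictly increasing")
  if (!(prebleach_value > postbleach_value))
    validation_error("prebleach_value must exceed postbleach_value")
  structure(list(times = times, intensities = intensities,
                 prebleach_value = as.numeric(prebleach_value),
                 postbleach_value = as.numeric(postbleach_value),
                 id = id %||% "trace"),
            class = "frap_trace")
}

is_normalized <- function(trace) {
  isTRUE(all.equal(trace$prebleach_value, 1)) &&
    isTRUE(all.equal(trace$postbleach_value, 0))
}

#' Normalise a FRAP trace to the pre/post-bleach anchors
#'
#' Maps intensity `i` to `(i - post) / (pre - post)`, so the intensity
#' immediately before bleaching becomes 1 and the intensity immediately
#' after bleaching becomes 0. Idempotent on already-normalised traces.
#'
#' @param trace a `frap_trace`.
#' @return The normalised `frap_trace` (`prebleach_value = 1`,
#'   `postbleach_value = 0`).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  span <- trace$prebleach_value - trace$postbleach_value
  if (abs(span) < .Machine$double.eps)
    validation_error(sprintf(
      "degenerate trace '%s': pre- and post-bleach intensities are equal",
      trace$id))
  frap_trace((trace$times),
             (trace$intensities - trace$postbleach_value) / span,
             prebleach_value = 1, postbleach_value = 0, id = trace$id)
}

#' One-site specific-binding recovery model
#'
#' `Y(t) = ymax * t / (t_half + t)`; satisfies `Y(t_half) = ymax / 2`.
#'
#' @param t time in seconds.
#' @param ymax recovery plateau (normalised units).
#' @param t_half half-time of recovery in seconds, > 0.
#' @return Model intensities.
#' @export
one_site_model <- function(t, ymax, t_half) ymax * t / (t_half + t)

# Profile SSR over t_half with the closed-form conditional ymax.
profile_fit <- function(times, ys, t_half, ymax_fixed = NULL) {
  x <- times / (t_half + times)
  ymax <- if (is.null(ymax_fixed)) {
    sxx <- sum(x^2)
    if (sxx == 0) 0 else sum(ys * x) / sxx
  } else {
    ymax_fixed
  }
  list(ymax = ymax, ssr = sum((ys - ymax * x)^2))
}

T_HALF_STARTS <- c(1, 2, 5, 10, 20, 50)
T_HALF_LO <- 1e-4
T_HALF_HI <- 1e4
YMAX_MAX <- 1.5

optimize_t_half <- function(ssr_fun) {
  grid <- vapply(T_HALF_STARTS, ssr_fun, 0)
  best <- T_HALF_STARTS[which.min(grid)]
  opt <- stats::optimize(ssr_fun,
                         interval = c(max(T_HALF_LO, best / 50),
                                      min(T_HALF_HI, best * 50)),
                         tol = 1e-10)
  # guard against the bracket missing the optimum near its edge
  if (min(grid) < opt$objective) {
    opt <- stats::optimize(ssr_fun, interval = c(T_HALF_LO, T_HALF_HI),
                           tol = 1e-10)
  }
  opt
}

#' Fit the one-site binding recovery model to a trace
#'
#' Least-squares estimation of `(ymax, t_half)` on the normalised recovery
#' curve. The fit is deterministic: candidate half-times from a fixed start
#' grid seed a bounded one-dimensional profile optimisation (the plateau has
#' a closed form given `t_half`). The plateau is constrained to
#' `(0, 1.5]`; if the unconstrained optimum exceeds 1.5 the model is refit
#' with `ymax` pinned at 1.5.
#'
#' @param trace a `frap_trace`; normalised automatically if its anchors are
#'   not already (1, 0). At least 6 post-bleach points are required.
#' @return Object of class `frap_fit`: `ymax`, `t_half`, `ssr`, `n_points`.
#' @export
fit_one_site <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!is_normalized(trace)) trace <- normalize_trace(trace)
  if (length(trace$times) < 6L)
    validation_error(sprintf(
      "trace '%s' has %d post-bleach points; at least 6 are required",
      trace$id, length(trace$times)))
  ts <- trace$times
  ys <- trace$intensities
  opt <- optimize_t_half(function(th) profile_fit(ts, ys, th)$ssr)
  fit <- profile_fit(ts, ys, opt$minimum)
  if (fit$ymax > YMAX_MAX) {
    opt <- optimize_t_half(function(th)
      profile_fit(ts, ys, th, ymax_fixed = YMAX_MAX)$ssr)
    fit <- profile_fit(ts, ys, opt$minimum, ymax_fixed = YMAX_MAX)
  }
  result <- structure(list(ymax = fit$ymax, t_half = opt$minimum,
                           ssr = fit$ssr, n_points = length(ts),
                           id = trace$id),
                      class = "frap_fit")
  if (!is.finite(fit$ssr) || fit$ymax <= 0) {
    cond <- errorCondition(
      sprintf("one-site fit failed for trace '%s' (ymax = %.3g)",
              trace$id, fit$ymax),
      class = c("trapint_fit_failure", "trapint_error"))
    cond$best_candidate <- result
    stop(cond)
  }
  result
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> '%s': ymax = %.4f, t_half = %.3f s (SSR %.4g, n = %d)\n",
              x$id, x$ymax, x$t_half, x$ssr, x$n_points))
  invisible(x)
}

normalize_group <- function(traces, label) {
  if (length(traces) < 3L)
    validation_error(sprintf("group '%s' has %d trace(s); at least 3 are required",
                             label, length(traces)))
  failed <- character(0)
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    ok <- tryCatch({
      out[[i]] <- if (is_normalized(tr)) tr else normalize_trace(tr)
      if (length(out[[i]]$times) < 6L)
        validation_error("too few points")
      TRUE
    }, trapint_error = function(e) FALSE)
    if (!ok) failed <- c(failed, tr$id %||% as.character(i))
  }
  if (length(failed)) {
    cond <- errorCondition(
      sprintf("unfittable trace(s) in group '%s': %s", label,
              paste(failed, collapse = ", ")),
      class = c("trapint_fit_failure", "trapint_error"))
    stop(cond)
  }
  out
}

# SSR for a set of traces sharing one t_half, each with its own closed-form
# plateau.
group_ssr <- function(traces, t_half) {
  sum(vapply(traces, function(tr)
    profile_fit(tr$times, tr$intensities, t_half)$ssr, 0))
}

#' Compare recovery half-times by the extra-sum-of-squares F-test
#'
#' Fits the nested pair of models: the null shares one `t_half` across all
#' traces of both groups, the alternative allows one `t_half` per group.
#' Every trace keeps its own free plateau in both models, so only the
#' half-time is contested. The improvement in residual sum of squares is
#' referred to the F distribution:
#' `F = ((SSR0 - SSR1) / (df0 - df1)) / (SSR1 / df1)`.
#'
#' @param group_a,group_b lists of `frap_trace`s (at least 3 per group).
#' @return Object of class `f_test_result`: `f_stat`, `df_num`, `df_den`,
#'   `p_value`, plus the per-group half-time estimates `t_half_a`,
#'   `t_half_b` and the shared-fit `t_half_shared`.
#' @export
compare_t_half <- function(group_a, group_b) {
  a <- normalize_group(group_a, "a")
  b <- normalize_group(group_b, "b")
  all_traces <- c(a, b)
  n_points <- sum(vapply(all_traces, function(tr) length(tr$times), 0L))
  n_traces <- length(all_traces)
  opt0 <- optimize_t_half(function(th) group_ssr(all_traces, th))
  opta <- optimize_t_half(function(th) group_ssr(a, th))
  optb <- optimize_t_half(function(th) group_ssr(b, th))
  ssr0 <- opt0$objective
  ssr1 <- opta$objective + optb$objective
  df0 <- n_points - (n_traces + 1L)
  df1 <- n_points - (n_traces + 2L)
  if (df1 <= 0L)
    validation_error("not enough data points for the F-test")
  extra <- max(ssr0 - ssr1, 0)
  f_stat <- if (ssr1 <= .Machine$double.eps * n_points) {
    if (extra <= .Machine$double.eps * n_points) 0 else Inf
  } else {
    (extra / (df0 - df1)) / (ssr1 / df1)
  }
  p <- stats::pf(f_stat, df0 - df1, df1, lower.tail = FALSE)
  structure(list(f_stat = f_stat, df_num = df0 - df1, df_den = df1,
                 p_value = p,
                 t_half_a = opta$minimum, t_half_b = optb$minimum,
                 t_half_shared = opt0$minimum,
                 ssr_null = ssr0, ssr_alt = ssr1),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf(
    "<f_test_result> F(%d, %d) = %.4g, p = %.4g\n  t_half: %.3f s vs %.3f s (shared %.3f s)\n",
    x$df_num, x$df_den, x$f_stat, x$p_value, x$t_half_a, x$t_half_b,
    x$t_half_shared))
  invisible(x)
}

#' Read FRAP traces from long-format delimited text
#'
#' Expected columns: `trace_id`, `time_s`, `intensity`, `phase` with phase
#' in `pre`, `bleach`, `post`. The pre-bleach anchor is the last `pre`
#' intensity, the post-bleach anchor the first `post` intensity; post-bleach
#' times are re-zeroed at the first post frame.
#'
#' @param path file path.
#' @return Named list of `frap_trace`s.
#' @export
read_frap_traces <- function(path) {
  df <- read_delim_auto(path)
  need <- c("trace_id", "time_s", "intensity", "phase")
  missing <- setdiff(need, names(df))
  if (length(missing))
    format_error(sprintf("missing column(s) in '%s': %s", path,
                         paste(missing, collapse = ", ")))
  if (!all(df$phase %in% c("pre", "bleach", "post")))
    validation_error("phase must be one of 'pre', 'bleach', 'post'")
  traces <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    pre <- d[d$phase == "pre", , drop = FALSE]
    post <- d[d$phase == "post", , drop = FALSE]
    if (!nrow(pre) || !nrow(post))
      validation_error(sprintf("trace '%s' lacks pre or post frames",
                               d$trace_id[[1]]))
    frap_trace(times = post$time_s - post$time_s[[1]],
               intensities = post$intensity,
               prebleach_value = pre$intensity[[nrow(pre)]],
               postbleach_value = post$intensity[[1]],
               id = as.character(d$trace_id[[1]]))
  })
  traces[order(names(traces))]
}

#' Write FRAP traces to long-format delimited text
#'
#' Inverse of [read_frap_traces()]: each trace contributes one `pre` frame
#' carrying the pre-bleach anchor followed by its post-bleach frames.
#'
#' @param traces list of `frap_trace`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frap_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(trace_id = tr$id,
               time_s = c(-1, tr$times),
               intensity = c(tr$prebleach_value, tr$intensities),
               phase = c("pre", rep("post", length(tr$times))),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
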