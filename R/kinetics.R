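#' Extract the aggregate-bound ThT trace from a time-lapse stack
#'
#' Per frame, aggregates are detected with the kinetics-imaging rule (pixels
#' above 250 a.u. out of 65535, components of more than 9 pixels) and the
#' intensity over all detected-aggregate pixels is summed; the per-frame sums
#' form the trace on the frame time grid.
#'
#' @param stack list of \code{\link{MicroImage}} frames.
#' @param times frame times in minutes (uniform grid; default 10-min spacing).
#' @param threshold detection threshold, a.u. (default 250).
#' @param minAreaExclusive exclusive minimum area, px (default 9).
#' @param condition,replicateId trace tags.
#' @return a \code{\link{KineticsTrace}}.
#' @export
extractTrace <- function(stack, times = (seq_along(stack) - 1) * 10,
                         threshold = 250, minAreaExclusive = 9,
                         condition = "unseeded", replicateId = 1L) {
  if (length(times) != length(stack))
    stop("times must match the number of frames")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
      stop("frame intervals must be uniform and increasing")
  }
  vals <- vapply(stack, function(frame) {
    regs <- segmentAggregates(frame, intensityThreshold = threshold,
                              minAreaExclusive = minAreaExclusive)
    if (!length(regs)) 0 else sum(vapply(regs, function(r) r@totalIntensity,
                                         numeric(1)))
  }, numeric(1))
  KineticsTrace(times, vals, condition = condition, replicateId = replicateId)
}

#' Subtract a blank trace
#'
#' @param trace,blank \code{\link{KineticsTrace}}s on the same time grid.
#' @return the pointwise difference, keeping \code{trace}'s tags.
#' @export
blankSubtract <- function(trace, blank) {
  stopifnot(is(trace, "KineticsTrace"), is(blank, "KineticsTrace"))
  if (length(traceTimes(trace)) != length(traceTimes(blank)) ||
      any(abs(traceTimes(trace) - traceTimes(blank)) > 1e-9))
    stop("time grids do not match")
  KineticsTrace(traceTimes(trace), traceIntensity(trace) - traceIntensity(blank),
                condition = condition(trace), replicateId = trace@replicateId)
}

#' Fit a logistic to an aggregation time course
#'
#' Least-squares fit of \code{baseline + amplitude / (1 + exp(-rate (t -
#' tMid)))} (Levenberg-Marquardt, multi-start over a grid of tMid values).
#' The lag time is the maximum-slope tangent's intercept with the baseline
#' (\code{tMid - 2/rate} for the logistic) and the plateau time is where the
#' fitted curve reaches baseline + 95\% amplitude (\code{tMid + log(19)/rate}).
#' A flat trace (fitted amplitude below \code{flatFraction} of the intensity
#' range, or a degenerate range) is returned flagged with amplitude ~ 0 and
#' an undefined lag rather than as an error.
#'
#' @param trace a \code{\link{KineticsTrace}} with at least 10 points.
#' @param nStarts number of tMid grid starts.
#' @param flatFraction relative amplitude under which a trace counts as flat.
#' @return a \code{\link{KineticsFit}}.
#' @examples
#' tr <- simulateKinetics(kineticsParams(lagTime = 300))
#' fitSigmoid(tr)
#' @export
fitSigmoid <- function(trace, nStarts = 8, flatFraction = 0.02) {
  stopifnot(is(trace, "KineticsTrace"))
  t <- traceTimes(trace); y <- traceIntensity(trace)
  if (length(t) < 10) stop("need at least 10 time points")
  rng <- diff(range(y))
  flatFit <- function() new("KineticsFit", baseline = mean(y), amplitude = 0,
    tMid = NA_real_, growthRate = NA_real_, lagTime = NA_real_,
    plateauTime = NA_real_, rmse = sd(y), lagDefined = FALSE,
    condition = condition(trace), replicateId = trace@replicateId)
  if (rng <= max(1e-12, flatFraction * max(abs(y), 1e-12))) return(flatFit())
  span <- diff(range(t))
  best <- NULL
  for (tm in seq(min(t) + 0.1 * span, max(t) - 0.1 * span,
                 length.out = nStarts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + a / (1 + exp(-k * (t - tm))),
        start = list(b = min(y), a = rng, k = 8 / span, tm = tm),
        lower = c(b = -Inf, a = 0, k = 1e-6, tm = min(t) - span),
        upper = c(b = Inf, a = Inf, k = Inf, tm = max(t) + span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from all starts")
  cf <- coef(best$fit)
  if (cf[["a"]] < flatFraction * max(abs(y))) return(flatFit())
  lag <- cf[["tm"]] - 2 / cf[["k"]]
  plateau <- cf[["tm"]] + log(19) / cf[["k"]]
  new("KineticsFit", baseline = cf[["b"]], amplitude = cf[["a"]],
      tMid = cf[["tm"]], growthRate = cf[["k"]], lagTime = lag,
      plateauTime = plateau,
      rmse = sqrt(mean(residuals(best$fit)^2)), lagDefined = TRUE,
      condition = condition(trace), replicateId = trace@replicateId)
}

#' Summarize fits per condition and compare seeded vs unseeded lag
#'
#' @param fits list of \code{\link{KineticsFit}} objects.
#' @return list with \code{table} (per-condition mean and sd of lag, plateau
#'   and amplitude; sd is NA for single replicates) and \code{lagReduction}
#'   (mean unseeded lag minus mean seeded lag, NA when either is absent).
#' @export
compareConditions <- function(fits) {
  conds <- vapply(fits, condition, character(1))
  getv <- function(f, what) switch(what, lag = lagTime(f),
                                   plateau = plateauTime(f),
                                   amplitude = f@amplitude)
  tab <- do.call(rbind, lapply(unique(conds), function(cd) {
    sel <- fits[conds == cd]
    row <- data.frame(condition = cd, n = length(sel))
    for (what in c("lag", "plateau", "amplitude")) {
      v <- vapply(sel, getv, numeric(1), what = what)
      row[[paste0(what, "_mean")]] <- mean(v)
      row[[paste0(what, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
    }
    row
  }))
  lagRed <- if (all(c("seeded", "unseeded") %in% conds))
    tab$lag_mean[tab$condition == "unseeded"] -
      tab$lag_mean[tab$condition == "seeded"]
  else NA_real_
  list(table = tab, lagReduction = lagRed)
}

#' Read plate-reader kinetics tables
#'
#' Accepts wide CSV (column \code{time_min} plus one column per replicate) or
#' long CSV (columns \code{time_min}, \code{replicate_id}, \code{intensity_au}
#' and optionally \code{condition}).
#'
#' @param path CSV file.
#' @param format "wide" or "long".
#' @param condition condition tag for wide files.
#' @return list of \code{\link{KineticsTrace}}.
#' @export
readKineticsCsv <- function(path, format = c("long", "wide"),
                            condition = "unseeded") {
  format <- match.arg(format)
  df <- read.csv(path)
  if (format == "wide") {
    reps <- setdiff(names(df), "time_min")
    lapply(seq_along(reps), function(i)
      KineticsTrace(df$time_min, df[[reps[i]]], condition = condition,
                    replicateId = i))
  } else {
    ids <- unique(df$replicate_id)
    lapply(ids, function(id) {
      sub <- df[df$replicate_id == id, ]
      sub <- sub[order(sub$time_min), ]
      KineticsTrace(sub$time_min, sub$intensity_au,
                    condition = if ("condition" %in% names(sub))
                      as.character(sub$condition[1]) else condition,
                    replicateId = as.integer(id))
    })
  }
}

#' Write kinetics traces as a long CSV
#'
#' Columns: \code{time_min}, \code{replicate_id}, \code{intensity_au},
#' \code{condition}.
#'
#' @param traces list of \code{\link{KineticsTrace}}.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeKineticsCsv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_min = traceTimes(tr), replicate_id = tr@replicateId,
               intensity_au = traceIntensity(tr), condition = condition(tr))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
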