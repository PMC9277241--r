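## Dive detection from time-depth records, the two-process bout-ending
## criterion, bout grouping, and attachment of dives to track points.

#' Subsample a depth series to a target rate
#'
#' Keeps every k-th sample where k = source rate / target rate; k must be a
#' whole number (pure decimation, no interpolation). Timestamps of kept
#' samples are preserved.
#'
#' @param series data.frame with `timestamp` (POSIXct) and `depth_m` at a
#'   constant source rate.
#' @param target_hz target sampling rate (default 0.5 Hz).
#' @return the decimated series.
#' @export
subsample_depth <- function(series, target_hz = 0.5) {
  tt <- as.numeric(series$timestamp)
  dt <- diff(tt)
  stopifnot(length(dt) > 0)
  src_hz <- 1 / median(dt)
  k <- src_hz / target_hz
  if (abs(k - round(k)) > 1e-6) {
    stop(sprintf("source rate %.3g Hz is not an integer multiple of target %.3g Hz",
                 src_hz, target_hz))
  }
  k <- as.integer(round(k))
  if (k < 1) stop("source rate below target rate")
  series[seq(1, nrow(series), by = k), , drop = FALSE]
}

#' Detect dives in a depth series
#'
#' A dive is a maximal run of consecutive samples with depth strictly greater
#' than `threshold_m`. Duration is run length divided by the sampling rate;
#' maximum depth is the run maximum. Negative depths (sensor noise at the
#' surface) are clipped to 0 with a warning giving the count.
#'
#' @param series data.frame with `timestamp` (POSIXct, constant rate) and
#'   `depth_m` (positive down), optionally `bird_id`.
#' @param threshold_m dive threshold (default 1 m, strict `>`).
#' @return data.frame of dives: `bird_id`, `start`, `end`, `duration_s`,
#'   `max_depth_m`, `n_samples`.
#' @export
detect_dives <- function(series, threshold_m = 1.0) {
  tt <- as.numeric(series$timestamp)
  if (is.unsorted(tt)) stop("depth series must be time-sorted")
  rate_hz <- 1 / median(diff(tt))
  depth <- series$depth_m
  neg <- depth < 0
  if (any(neg)) {
    warning(sprintf("detect_dives: %d negative depths clipped to 0", sum(neg)))
    depth[neg] <- 0
  }
  sub <- depth > threshold_m
  r <- rle(sub)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  bird <- if ("bird_id" %in% names(series)) series$bird_id[1] else NA_character_
  data.frame(
    bird_id = rep(bird, length(keep)),
    start = series$timestamp[starts[keep]],
    end = series$timestamp[ends[keep]],
    duration_s = r$lengths[keep] / rate_hz,
    max_depth_m = vapply(keep, function(k) max(depth[starts[k]:ends[k]]), 0),
    n_samples = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

#' Analytic bout-ending criterion of a two-process interval mixture
#'
#' For a fast/slow mixture of exponential inter-dive intervals with counts
#' `nf`, `ns` and rates `lf > ls`, the bout-ending criterion is the interval
#' length at which the two fitted processes intersect:
#' `log(nf * lf / (ns * ls)) / (lf - ls)`.
#'
#' @param nf,ns process counts (or proportions).
#' @param lf,ls process rates (per second), `lf > ls`.
#' @return criterion in seconds.
#' @export
bec_from_params <- function(nf, lf, ns, ls) log(nf * lf / (ns * ls)) / (lf - ls)

#' Fit the bout-ending criterion by broken-stick nonlinear least squares
#'
#' Bins inter-dive intervals into a histogram (default 5 s bins) and fits the
#' log frequency of the two-process model
#' `log f(t) = log(nf*lf*exp(-lf*t) + ns*ls*exp(-ls*t))`
#' by nonlinear least squares, following the classic log-frequency
#' broken-stick analysis of behavioural bouts. Bins are weighted by their
#' counts (the sampling variance of a log count is approximately the
#' reciprocal count), so the sparse far tail does not dominate the fit. The
#' bout-ending criterion is the intersection of the fitted fast and slow
#' processes.
#'
#' The fit is flagged as failed when it does not converge, when the optimum
#' has `lf <= ls` (single-process data), or when the slow process is nearly
#' empty (`ns < 5`, unstable criterion); callers may then fall back to a
#' fixed criterion.
#'
#' @param intervals inter-dive intervals in seconds (>= 50 recommended).
#' @param bin_s histogram bin width in seconds (default 5).
#' @return list of class `bout_model`: `nf`, `lf`, `ns`, `ls`, `bec_s`,
#'   `converged`, `rss`, `message`.
#' @export
fit_bec <- function(intervals, bin_s = 5) {
  intervals <- intervals[is.finite(intervals) & intervals > 0]
  fail <- function(msg) structure(list(nf = NA, lf = NA, ns = NA, ls = NA,
                                       bec_s = NA, converged = FALSE,
                                       rss = NA, message = msg),
                                  class = "bout_model")
  if (length(intervals) < 50) return(fail("fewer than 50 intervals"))
  br <- seq(0, max(intervals) + bin_s, by = bin_s)
  h <- hist(intervals, breaks = br, plot = FALSE)
  keep <- h$counts > 0
  t_mid <- h$mids[keep]
  logf <- log(h$counts[keep])
  ## starting values: split at an interior quantile, method-of-moments rates
  split <- quantile(intervals, 0.75)
  fast <- intervals[intervals <= split]; slow <- intervals[intervals > split]
  if (length(slow) < 2 || length(fast) < 2) return(fail("degenerate interval distribution"))
  start <- list(lnf = log(length(fast)), llf = log(1 / mean(fast)),
                lns = log(length(slow)), lls = log(1 / mean(slow)))
  model <- logf ~ log(exp(lnf + llf) * exp(-exp(llf) * t_mid) +
                        exp(lns + lls) * exp(-exp(lls) * t_mid))
  wts <- h$counts[keep]
  fit <- tryCatch(
    minpack.lm::nlsLM(model, start = start, weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  cf <- coef(fit)
  nf <- exp(cf[["lnf"]]); lf <- exp(cf[["llf"]])
  ns <- exp(cf[["lns"]]); ls <- exp(cf[["lls"]])
  if (lf < ls) { # relabel so the fast process is first
    tmp <- c(nf, lf); nf <- ns; lf <- ls; ns <- tmp[1]; ls <- tmp[2]
  }
  rss <- sum(resid(fit)^2)
  if (!isTRUE(lf > ls * 1.5)) {
    return(fail("fast and slow rates not separated (single-process data?)"))
  }
  if (ns < 5) return(fail("slow process nearly empty (ns < 5); criterion unstable"))
  structure(list(nf = nf, lf = lf, ns = ns, ls = ls,
                 bec_s = bec_from_params(nf, lf, ns, ls),
                 converged = TRUE, rss = rss, message = "ok"),
            class = "bout_model")
}

#' @export
print.bout_model <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<bout_model> fast: n=%.0f rate=%.4g/s; slow: n=%.0f rate=%.4g/s; BEC=%.1f s\n",
                x$nf, x$lf, x$ns, x$ls, x$bec_s))
  } else cat("<bout_model> fit failed:", x$message, "\n")
  invisible(x)
}

#' Group dives into bouts
#'
#' A new bout starts whenever the surface gap since the previous dive's end
#' exceeds the bout-ending criterion. Dives must be time-sorted within bird.
#'
#' @param dives dive table from [detect_dives()] (may span birds).
#' @param bec_s bout-ending criterion (seconds); `Inf` gives one bout per
#'   bird, 0 one bout per dive.
#' @return list with `dives` (input plus `bout_id`) and `bouts` (per bout:
#'   `bout_id`, `bird_id`, `start`, `end`, `n_dives`, `max_depth_m`).
#' @export
assign_bouts <- function(dives, bec_s) {
  stopifnot(is.numeric(bec_s), length(bec_s) == 1, !is.na(bec_s))
  dives$bout_id <- NA_character_
  bouts <- list()
  for (bird in unique(dives$bird_id)) {
    idx <- which(dives$bird_id == bird)
    db <- dives[idx, , drop = FALSE]
    if (is.unsorted(as.numeric(db$start))) stop("dives must be time-sorted per bird")
    gap <- c(Inf, as.numeric(db$start[-1]) - as.numeric(db$end[-nrow(db)]))
    bout_no <- cumsum(gap > bec_s)
    dives$bout_id[idx] <- sprintf("%s_bout%04d", bird, bout_no)
    for (b in unique(bout_no)) {
      sel <- db[bout_no == b, , drop = FALSE]
      bouts[[length(bouts) + 1]] <- data.frame(
        bout_id = sprintf("%s_bout%04d", bird, b), bird_id = bird,
        start = sel$start[1], end = sel$end[nrow(sel)],
        n_dives = nrow(sel), max_depth_m = max(sel$max_depth_m),
        stringsAsFactors = FALSE
      )
    }
  }
  list(dives = dives, bouts = do.call(rbind, bouts))
}

#' Attach dives to track points
#'
#' Each dive is assigned to the track point whose timestamp is closest to the
#' dive start (ties broken toward the earlier fix). Dives further than half a
#' fix interval outside the track's time span stay unassigned with a warning.
#' Per-fix dive counts are returned for every track point (zeros included),
#' so the sum of counts equals the number of assigned dives.
#'
#' @param dives dive table (per bird).
#' @param segments list of track segment/trip point tables with `bird_id`,
#'   `timestamp`.
#' @param interval_s fix interval (seconds), used for the coverage margin.
#' @return list with `dives` (plus `assigned_fix`, POSIXct or NA) and
#'   `fix_counts` (`bird_id`, `timestamp`, `n_dives`).
#' @export
attach_dives <- function(dives, segments, interval_s = 300) {
  pts <- do.call(rbind, lapply(segments, function(s)
    s[, c("bird_id", "timestamp"), drop = FALSE]))
  dives$assigned_fix <- as.POSIXct(rep(NA_real_, nrow(dives)),
                                   origin = "1970-01-01", tz = "UTC")
  counts <- pts
  counts$n_dives <- 0L
  for (bird in unique(dives$bird_id)) {
    di <- which(dives$bird_id == bird)
    pi_ <- which(pts$bird_id == bird)
    if (!length(pi_)) next
    ft <- as.numeric(pts$timestamp[pi_])
    ord <- order(ft); ft <- ft[ord]; pidx <- pi_[ord]
    dt <- as.numeric(dives$start[di])
    covered <- dt >= ft[1] - interval_s / 2 & dt <= ft[length(ft)] + interval_s / 2
    if (any(!covered)) {
      warning(sprintf("attach_dives: %d dives of bird %s outside track coverage, unassigned",
                      sum(!covered), bird))
    }
    for (j in which(covered)) {
      d <- abs(ft - dt[j])
      k <- which(d == min(d))[1] # tie -> earlier fix
      dives$assigned_fix[di[j]] <- pts$timestamp[pidx[k]]
      counts$n_dives[pidx[k]] <- counts$n_dives[pidx[k]] + 1L
    }
  }
  list(dives = dives, fix_counts = counts)
}
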