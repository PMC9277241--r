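## End-to-end orchestration: simulate -> preprocess -> dives -> annotate ->
## HMM -> penalized-spline models -> report. Every number in the report is
## recomputed from the run's tables; stages log row counts in and out so
## attrition is explicit.

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  v <- utf8ToInt(txt)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Fraction of dive fixes decoded as ARS
#'
#' Of the track points that contain at least one dive, the fraction whose
#' decoded behavioural state is ARS.
#'
#' @param decoded_states integer state vector (1 rest, 2 ARS, 3 transit).
#' @param fix_counts per-point dive counts, same length.
#' @param ars_state state index counted as ARS (default 2).
#' @return fraction in \[0, 1\]; NA with a warning when no fix contains a
#'   dive.
#' @export
dives_in_ars_fraction <- function(decoded_states, fix_counts, ars_state = 2L) {
  stopifnot(length(decoded_states) == length(fix_counts))
  has_dive <- fix_counts > 0
  if (!any(has_dive)) {
    warning("no dive-containing fixes; ARS fraction undefined")
    return(NA_real_)
  }
  mean(decoded_states[has_dive] == ars_state)
}

stage_log <- function(log, stage, n_in, n_out, note = "") {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note, stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline on a synthetic colony
#'
#' Simulates a dataset from `config`, regularizes tracks and segments
#' foraging trips, detects dives and estimates the bout-ending criterion,
#' annotates fixes and bouts with environmental covariates, fits the
#' three-state HMM with and without the Secchi covariate, fits the
#' dive-rate and dive-depth models, and assembles a report. When `out_dir`
#' is given, data tables, intermediate artifacts and the report (JSON +
#' markdown) are written under it (`data/`, `intermediates/`, `fit/`,
#' `report/`).
#'
#' @param config a [sim_config()].
#' @param out_dir optional run directory.
#' @param n_restarts HMM restarts (default 2).
#' @param bec_fallback_s bout criterion used if the broken-stick fit fails
#'   (default 180 s).
#' @param write_data also write the (large) raw GPS/TDR/grid CSVs (default
#'   TRUE when `out_dir` is given).
#' @return list of class `run_report` (see the `report` element for the
#'   flat summary; `fits` carries the fitted objects).
#' @export
run_all <- function(config = sim_config(), out_dir = NULL, n_restarts = 2,
                    bec_fallback_s = 180, write_data = !is.null(out_dir)) {
  log <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    note = character(), stringsAsFactors = FALSE)

  ## stage 1: simulate
  sim <- simulate_dataset(config)
  log <- stage_log(log, "simulate", NA, nrow(sim$gps),
                   sprintf("%d birds", config$n_birds))

  ## stage 2: preprocess tracks
  segments <- interpolate_track(sim$gps, interval_s = config$fix_interval_s)
  trips <- segment_trips(segments, config$colony)
  obs <- hmm_obs_table(trips)
  log <- stage_log(log, "preprocess", nrow(sim$gps), nrow(obs),
                   sprintf("%d trips", nrow(trips)))

  ## stage 3: dives, bout criterion, bouts, per-fix counts
  dives <- do.call(rbind, lapply(sim$tdr, detect_dives))
  intervals <- unlist(lapply(split(dives, dives$bird_id), function(d) {
    d <- d[order(d$start), ]
    as.numeric(d$start[-1]) - as.numeric(d$end[-nrow(d)])
  }), use.names = FALSE)
  bec <- fit_bec(intervals)
  bec_s <- if (bec$converged) bec$bec_s else bec_fallback_s
  bouts <- assign_bouts(dives, bec_s)
  ## dives falling outside trip coverage (e.g. near a trip split) stay
  ## unassigned; record the attrition in the log rather than warning
  attach_notes <- character(0)
  att <- withCallingHandlers(
    attach_dives(bouts$dives, list(obs), interval_s = config$fix_interval_s),
    warning = function(w) {
      attach_notes <<- c(attach_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(attach_notes)) {
    log <- stage_log(log, "attach", nrow(dives),
                     sum(!is.na(att$dives$assigned_fix)),
                     paste(attach_notes, collapse = "; "))
  }
  log <- stage_log(log, "dives", nrow(dives), sum(att$fix_counts$n_dives),
                   sprintf("BEC %.0f s (%s), %d bouts", bec_s,
                           if (bec$converged) "fitted" else "fallback",
                           nrow(bouts$bouts)))

  ## stage 4: annotate fixes and bouts
  fx <- annotate_points(obs, sim$env)
  fx$n_dives <- att$fix_counts$n_dives[match(
    paste(fx$bird_id, fx$timestamp), paste(att$fix_counts$bird_id,
                                           att$fix_counts$timestamp))]
  fx <- fx[!fx$env_missing, ]
  log <- stage_log(log, "annotate", nrow(obs), nrow(fx),
                   sprintf("%d rows dropped (missing covariates)",
                           nrow(obs) - nrow(fx)))

  ## stage 5: movement HMM with and without the Secchi covariate
  set.seed(substream_seed(config$seed, "misc"))
  fx$z <- fx$zsd_m
  fit_null <- fit_hmm(fx, formula = "null", n_restarts = n_restarts)
  fit_zsd <- fit_hmm(fx, formula = "zsd", n_restarts = n_restarts)
  cmp <- compare_models(fit_zsd, fit_null, dive_presence = fx$n_dives > 0)
  ars_frac <- dives_in_ars_fraction(fit_zsd$viterbi, fx$n_dives)
  z_grid <- seq(quantile(fx$zsd_m, 0.05), quantile(fx$zsd_m, 0.95),
                length.out = 25)
  curves <- transition_curves(fit_zsd, z_grid)

  ## stage 6: penalized-spline models
  rate_fit <- fit_dive_rate_model(fx)
  bout_tab <- bouts$bouts
  bi <- vapply(seq_len(nrow(bout_tab)), function(j) {
    cand <- which(fx$bird_id == bout_tab$bird_id[j])
    cand[which.min(abs(as.numeric(fx$timestamp[cand]) -
                         as.numeric(bout_tab$start[j])))]
  }, 1L)
  bout_tab <- cbind(bout_tab,
                    fx[bi, c("solar_deg", "zsd_m", "cloud_pct",
                             "time_of_day_h", "water_depth_m")])
  bout_tab$hmm_state <- fit_zsd$viterbi[bi]
  depth_fit <- tryCatch(fit_dive_depth_model(bout_tab),
                        error = function(e) NULL)
  log <- stage_log(log, "models", nrow(fx), nrow(bout_tab),
                   sprintf("rate n=%d, depth bouts n=%d%s", rate_fit$n_used,
                           nrow(bout_tab),
                           if (is.null(depth_fit)) " (depth model failed)" else ""))

  ## report
  ## dive covariates are appended from the nearest track point, so the
  ## daylight fraction is computed on the fix-level solar angle
  dive_solar <- fx$solar_deg[match(paste(sim$dives$bird_id, sim$dives$fix_time),
                                   paste(fx$bird_id, fx$timestamp))]
  dive_solar <- dive_solar[is.finite(dive_solar)]
  per_day <- aggregate(
    list(n = sim$dives$max_depth_m),
    by = list(bird = sim$dives$bird_id,
              day = as.Date(sim$dives$start, tz = "UTC")), FUN = length)$n

  report <- list(
    seed = config$seed, config_hash = config_hash(config),
    trips = list(count = nrow(trips),
                 mean_duration_h = mean(trips$duration_h),
                 mean_max_range_km = mean(trips$max_range_km)),
    dives = list(total = nrow(dives),
                 assigned = sum(fx$n_dives),
                 per_day_mean = mean(per_day), per_day_sd = sd(per_day),
                 depth_mean_m = mean(dives$max_depth_m),
                 depth_sd_m = sd(dives$max_depth_m),
                 depth_max_m = max(dives$max_depth_m),
                 frac_below_civil_twilight = mean(dive_solar < CIVIL_TWILIGHT_DEG),
                 bec_s = bec_s, bec_fitted = bec$converged,
                 n_bouts = nrow(bouts$bouts)),
    zsd = list(mean_m = mean(fx$zsd_m), sd_m = sd(fx$zsd_m)),
    hmm = list(aic_null = fit_null$aic, aic_zsd = fit_zsd$aic,
               delta_aic = fit_null$aic - fit_zsd$aic,
               state_agreement_pct = 100 * cmp$agreement,
               metrics = cmp$metrics,
               pct_dives_in_ars = 100 * ars_frac,
               betaz_transit_to_ars = fit_zsd$params$betaz[6]),
    rate_model = list(table = rate_fit$table,
                      deviance_explained_pct = 100 * rate_fit$dev_expl,
                      auc = rate_fit$auc, rho = rate_fit$rho,
                      selected_against = rate_fit$selected_against),
    depth_model = if (is.null(depth_fit)) NULL else
      list(table = depth_fit$table,
           deviance_explained_pct = 100 * depth_fit$dev_expl,
           state_contrasts = depth_fit$state_contrasts,
           selected_against = depth_fit$selected_against),
    attrition = log
  )

  out <- structure(list(report = report, log = log,
                        fits = list(hmm_null = fit_null, hmm_zsd = fit_zsd,
                                    rate = rate_fit, depth = depth_fit,
                                    bec = bec, curves = curves),
                        tables = list(fix = fx, trips = trips,
                                      dives = att$dives, bouts = bout_tab),
                        sim = sim),
                   class = "run_report")
  if (!is.null(out_dir)) write_run_dir(out, out_dir, write_data = write_data)
  out
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<run_report> seed=%s hash=%s\n", r$seed, r$config_hash))
  cat(sprintf("  trips: %d (mean %.1f h, max range %.1f km)\n",
              r$trips$count, r$trips$mean_duration_h, r$trips$mean_max_range_km))
  cat(sprintf("  dives: %d (%.1f +/- %.1f per bird-day; depth %.1f +/- %.1f m, max %.1f m)\n",
              r$dives$total, r$dives$per_day_mean, r$dives$per_day_sd,
              r$dives$depth_mean_m, r$dives$depth_sd_m, r$dives$depth_max_m))
  cat(sprintf("  Zsd encountered: %.1f +/- %.1f m\n", r$zsd$mean_m, r$zsd$sd_m))
  cat(sprintf("  HMM: dAIC(null - zsd)=%.1f, agreement %.1f%%, %.1f%% of dive fixes in ARS\n",
              r$hmm$delta_aic, r$hmm$state_agreement_pct, r$hmm$pct_dives_in_ars))
  cat(sprintf("  dive rate: %.1f%% deviance explained, AUC %.2f\n",
              r$rate_model$deviance_explained_pct, r$rate_model$auc))
  if (!is.null(r$depth_model)) {
    cat(sprintf("  dive depth: %.1f%% deviance explained\n",
                r$depth_model$deviance_explained_pct))
  }
  cat(sprintf("  dives below civil twilight: %.2f%%\n",
              100 * r$dives$frac_below_civil_twilight))
  invisible(x)
}

#' Write a run directory
#'
#' Layout: `data/` (raw simulated CSVs), `intermediates/` (fix and bout
#' tables), `fit/` (HMM parameters and curves), `report/report.json` and
#' `report/report.md`.
#'
#' @param run a `run_report` from [run_all()].
#' @param out_dir directory to create.
#' @param write_data include the raw GPS/TDR/grid CSVs.
#' @return invisibly, `out_dir`.
#' @export
write_run_dir <- function(run, out_dir, write_data = TRUE) {
  for (d in c("data", "intermediates", "fit", "report")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  if (write_data) write_sim_csvs(run$sim, file.path(out_dir, "data"))
  fmt <- function(df) {
    for (cl in names(df)) if (inherits(df[[cl]], "POSIXct")) {
      df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    df
  }
  write.csv(fmt(run$tables$fix), file.path(out_dir, "intermediates", "fix_table.csv"),
            row.names = FALSE)
  write.csv(fmt(run$tables$bouts), file.path(out_dir, "intermediates", "bout_table.csv"),
            row.names = FALSE)
  write.csv(fmt(run$tables$trips), file.path(out_dir, "intermediates", "trips.csv"),
            row.names = FALSE)
  p <- run$fits$hmm_zsd$params
  jsonlite::write_json(
    list(mu = p$mu, sigma = p$sigma, pi0 = p$pi0, turn_mean = p$turn_mean,
         kappa = p$kappa, beta0 = p$beta0, betaz = p$betaz,
         betaz_per_m = run$fits$hmm_zsd$betaz_per_m),
    file.path(out_dir, "fit", "hmm_zsd_params.json"),
    auto_unbox = TRUE, digits = NA)
  write.csv(run$fits$curves$transitions,
            file.path(out_dir, "fit", "transition_curves.csv"), row.names = FALSE)
  write.csv(run$fits$curves$stationary,
            file.path(out_dir, "fit", "stationary_curves.csv"), row.names = FALSE)
  jsonlite::write_json(run$report, file.path(out_dir, "report", "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  writeLines(render_report_md(run$report),
             file.path(out_dir, "report", "report.md"))
  invisible(out_dir)
}

render_report_md <- function(r) {
  fmtt <- function(df) {
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(row)
        paste0("| ", paste(vapply(row, function(x)
          if (is.numeric(x)) sprintf("%.3g", x) else as.character(x), ""),
          collapse = " | "), " |")))
  }
  c(sprintf("# Run report (seed %s, config %s)", r$seed, r$config_hash),
    "",
    sprintf("- Foraging trips: %d (mean duration %.1f h, mean max range %.1f km)",
            r$trips$count, r$trips$mean_duration_h, r$trips$mean_max_range_km),
    sprintf("- Dives: %d; %.1f +/- %.1f per bird-day; depth %.1f +/- %.1f m (max %.1f m)",
            r$dives$total, r$dives$per_day_mean, r$dives$per_day_sd,
            r$dives$depth_mean_m, r$dives$depth_sd_m, r$dives$depth_max_m),
    sprintf("- Bout-ending criterion: %.0f s (%s); %d bouts",
            r$dives$bec_s, if (r$dives$bec_fitted) "fitted" else "fallback",
            r$dives$n_bouts),
    sprintf("- Secchi depth encountered: %.1f +/- %.1f m", r$zsd$mean_m, r$zsd$sd_m),
    sprintf("- Dives below civil twilight (solar angle < %d deg): %.2f%%",
            CIVIL_TWILIGHT_DEG, 100 * r$dives$frac_below_civil_twilight),
    "",
    "## Movement HMM",
    sprintf("- AIC: %.1f (no Secchi) vs %.1f (with Secchi); dAIC = %.1f",
            r$hmm$aic_null, r$hmm$aic_zsd, r$hmm$delta_aic),
    sprintf("- State agreement between models: %.1f%%", r$hmm$state_agreement_pct),
    sprintf("- Dive-containing fixes decoded as ARS: %.1f%%", r$hmm$pct_dives_in_ars),
    "",
    "## Dive rate (negative binomial, log link)",
    fmtt(r$rate_model$table),
    sprintf("- Deviance explained: %.1f%%; AUC %.2f; AR(1) rho %.3f",
            r$rate_model$deviance_explained_pct, r$rate_model$auc,
            r$rate_model$rho),
    "",
    if (!is.null(r$depth_model)) c(
      "## Dive depth (Gaussian, bout maxima)",
      fmtt(r$depth_model$table),
      sprintf("- Deviance explained: %.1f%%",
              r$depth_model$deviance_explained_pct),
      if (nrow(r$depth_model$state_contrasts)) fmtt(r$depth_model$state_contrasts)
    ) else "## Dive depth model unavailable (too few bouts)")
}
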