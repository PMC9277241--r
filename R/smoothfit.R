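## Penalized-spline regression layer: smooth-term construction, GAM fitting
## with shrinkage selection (gamma-inflated REML), AR(1) working-model
## whitening for serially correlated count responses, and the two study
## models — negative-binomial dive rate and Gaussian bout depth. The
## penalized fits themselves are delegated to mgcv (the standard tool for
## these models); this layer owns the AR(1) two-step pass, the rho and AUC
## statistics, and the term-selection reporting.

#' Build a smooth-term design block and penalty
#'
#' Constructs the design matrix and penalty matrices for one smooth term:
#' `"shrinkage-spline-1d"` (thin-plate regression spline with null-space
#' shrinkage, so the whole term can be penalized to zero),
#' `"cyclic-cubic-1d"` (periodic on a given range, default \[0, 24) hours),
#' `"tensor-2d"` (tensor product of two shrinkage margins, one penalty per
#' margin), or `"random-intercept"` (indicator columns with a ridge
#' penalty).
#'
#' @param kind term kind (see above).
#' @param data data.frame containing the covariates.
#' @param vars covariate name (length 2 for tensors).
#' @param k basis dimension (per margin for tensors; defaults 10, tensors 5).
#' @param range cyclic range (default `c(0, 24)`).
#' @return list with `X` (design block), `S` (list of penalty matrices),
#'   `term` (the mgcv smooth object), `label`.
#' @export
build_basis <- function(kind = c("shrinkage-spline-1d", "cyclic-cubic-1d",
                                 "tensor-2d", "random-intercept"),
                        data, vars, k = NULL, range = c(0, 24)) {
  kind <- match.arg(kind)
  stopifnot(all(vars %in% names(data)))
  knots <- NULL
  expr <- switch(kind,
    "shrinkage-spline-1d" = {
      if (is.null(k)) k <- 10
      sprintf('mgcv::s(%s, bs = "ts", k = %d)', vars[1], k)
    },
    "cyclic-cubic-1d" = {
      if (is.null(k)) k <- 10
      knots <- setNames(list(seq(range[1], range[2], length.out = k)), vars[1])
      sprintf('mgcv::s(%s, bs = "cc", k = %d)', vars[1], k)
    },
    "tensor-2d" = {
      if (is.null(k)) k <- 5
      sprintf('mgcv::te(%s, %s, bs = c("ts", "ts"), k = c(%d, %d))',
              vars[1], vars[2], k, k)
    },
    "random-intercept" = {
      data[[vars[1]]] <- as.factor(data[[vars[1]]])
      sprintf('mgcv::s(%s, bs = "re")', vars[1])
    }
  )
  spec <- eval(str2lang(expr))
  sm <- mgcv::smoothCon(spec, data = data, knots = knots, absorb.cons = FALSE)[[1]]
  list(X = sm$X, S = sm$S, term = sm, label = sm$label)
}

#' Pooled lag-1 autocorrelation of grouped residuals
#'
#' Estimates the AR(1) working-correlation coefficient rho as the lag-1
#' autocorrelation of (working) residuals, pooled across groups (trips):
#' consecutive pairs are only formed within a group. Constant residuals give
#' 0 with a warning.
#'
#' @param residuals numeric vector, time-ordered within group.
#' @param group group identifier (trip), same length.
#' @return scalar rho in \[-1, 1\].
#' @export
estimate_rho <- function(residuals, group) {
  stopifnot(length(residuals) == length(group))
  same <- c(FALSE, group[-1] == group[-length(group)])
  x <- residuals - mean(residuals)
  denom <- sum(x^2)
  if (denom < .Machine$double.eps * length(x)) {
    warning("estimate_rho: residuals are constant; returning 0")
    return(0)
  }
  num <- sum(x[same] * x[which(same) - 1])
  num / denom
}

## Refit a converged penalized fit after AR(1) whitening of its working
## model: rows are sqrt(working-weight) scaled, consecutive rows within a
## group are replaced by (row_t - rho * row_{t-1}) / sqrt(1 - rho^2), and
## the penalized least-squares problem is re-solved by mgcv::magic with the
## smoothing parameters held at their stage-one REML estimates (a single
## two-step pass; lambda is not re-estimated on the whitened data).
ar1_whiten_refit <- function(fit, rho, group, gamma = 1.2) {
  X <- predict(fit, type = "lpmatrix")
  w <- fit$weights
  eta <- fit$linear.predictors
  mu <- fit$fitted.values
  z <- eta + (fit$y - mu) / fit$family$mu.eta(eta)
  rw <- sqrt(pmax(w, 0))
  Xw <- X * rw
  zw <- z * rw
  lagged <- c(FALSE, group[-1] == group[-length(group)])
  idx <- which(lagged)
  sc <- 1 / sqrt(1 - rho^2)
  Xt <- Xw; zt <- zw
  if (length(idx)) {
    Xt[idx, ] <- (Xw[idx, ] - rho * Xw[idx - 1, ]) * sc
    zt[idx] <- (zw[idx] - rho * zw[idx - 1]) * sc
  }
  S <- list(); off <- integer(0)
  for (sm in fit$smooth) {
    for (j in seq_along(sm$S)) {
      S[[length(S) + 1]] <- sm$S[[j]]
      off[length(off) + 1] <- sm$first.para
    }
  }
  sp <- as.numeric(fit$sp)
  if (length(sp) != length(S)) sp <- rep(-1, length(S))
  mg <- mgcv::magic(zt, Xt, sp = sp, S = S, off = off, gamma = gamma)
  post <- mgcv::magic.post.proc(Xt, mg, w = NULL)
  edf_term <- vapply(fit$smooth, function(sm)
    sum(post$edf[sm$first.para:sm$last.para]), 0)
  names(edf_term) <- vapply(fit$smooth, function(sm) sm$label, "")
  eta_new <- drop(X %*% mg$b)
  mu_new <- fit$family$linkinv(eta_new)
  list(coefficients = mg$b, sp = mg$sp, edf = post$edf, edf_term = edf_term,
       fitted = mu_new, linear_predictor = eta_new, scale = mg$scale)
}

dev_explained <- function(y, mu, family, wt = NULL) {
  if (is.null(wt)) wt <- rep(1, length(y))
  dev <- sum(family$dev.resids(y, mu, wt))
  mu0 <- rep(weighted.mean(y, wt), length(y))
  dev0 <- sum(family$dev.resids(y, mu0, wt))
  1 - dev / dev0
}

term_table <- function(g) {
  s <- summary(g)
  st <- s$s.table
  data.frame(term = rownames(st), edf = st[, "edf"],
             statistic = st[, ncol(st) - 1], p = st[, ncol(st)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a penalized-spline model with shrinkage selection
#'
#' Fits a GAM by penalized IRLS with REML smoothing-parameter selection, the
#' effective-degrees-of-freedom cost inflated by `gamma` (default 1.2) to
#' discourage overfitting; shrinkage bases allow whole terms to be selected
#' against (regressed to ~0). For serially correlated responses, an AR(1)
#' working correlation is absorbed by a single two-step pass: the converged
#' working model is whitened within groups at the supplied (or estimated)
#' rho and re-solved ([estimate_rho()]); coefficient tables then come from
#' the whitened solve, inferential statistics from the stage-one fit and are
#' approximate.
#'
#' @param formula mgcv model formula (use `s(, bs = "ts")`, `s(, bs = "cc")`,
#'   `te()`, `s(, bs = "re")` terms).
#' @param data model frame; rows with missing covariates are dropped and
#'   counted.
#' @param family `mgcv::nb()`, `gaussian()`, etc.
#' @param gamma EDF inflation for smoothing selection (default 1.2).
#' @param rho AR(1) coefficient: `NULL` for none, `"estimate"` to estimate
#'   from working residuals, or a number.
#' @param rho_min whitening is skipped when `|rho|` falls below this
#'   (default 0.05): a negligible autocorrelation does not warrant an AR(1)
#'   structure (the estimated rho is still reported).
#' @param group grouping variable name for the AR(1) structure (e.g. trip).
#' @param knots optional knots list (e.g. `list(time_of_day_h = c(0, 24))`).
#' @param select_edf,select_effect thresholds below which a term is reported
#'   as selected against (EDF < 0.01 and max |effect| < 1e-3 response s.d.).
#' @return object of class `gam_fit`.
#' @export
fit_gam <- function(formula, data, family = stats::gaussian(), gamma = 1.2,
                    rho = NULL, rho_min = 0.05, group = NULL, knots = NULL,
                    select_edf = 0.01, select_effect = 1e-3) {
  resp <- all.vars(formula)[1]
  used_vars <- intersect(all.vars(formula), names(data))
  cc <- complete.cases(data[, used_vars, drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  if (!is.finite(sum(data[[resp]]))) stop("non-finite response values")

  g <- mgcv::gam(formula, data = data, family = family, method = "REML",
                 gamma = gamma, knots = knots)

  theta <- tryCatch(g$family$getTheta(TRUE), error = function(e) NA_real_)

  rho_hat <- NULL
  whitened <- NULL
  if (!is.null(rho)) {
    stopifnot(!is.null(group), group %in% names(data))
    grp <- data[[group]]
    if (identical(rho, "estimate")) {
      wres <- residuals(g, type = "working")
      rho_hat <- estimate_rho(wres, grp)
    } else {
      rho_hat <- rho
    }
    if (abs(rho_hat) > 0.999) stop("estimated rho is not in (-1, 1)")
    if (abs(rho_hat) >= rho_min) {
      whitened <- ar1_whiten_refit(g, rho_hat, grp, gamma = gamma)
    }
  }

  mu <- if (is.null(whitened)) g$fitted.values else whitened$fitted
  de <- dev_explained(g$y, mu, g$family, g$prior.weights)

  tab <- term_table(g)
  if (!is.null(whitened)) {
    m <- match(tab$term, names(whitened$edf_term))
    tab$edf <- ifelse(is.na(m), tab$edf, whitened$edf_term[m])
  }

  ## selection-against report: tiny EDF and a numerically flat effect
  ysd <- sd(g$y)
  pt <- predict(g, type = "terms")
  sel <- vapply(tab$term, function(lbl) {
    col <- grep(lbl, colnames(pt), fixed = TRUE)
    rng <- if (length(col)) diff(range(pt[, col[1]])) else Inf
    ed <- tab$edf[tab$term == lbl]
    ed < select_edf && rng < select_effect * ysd
  }, TRUE)

  structure(list(
    gam = g, formula = formula, family_name = g$family$family, theta = theta,
    rho = rho_hat, whitened = whitened, table = tab,
    dev_expl = de, aic = stats::AIC(g), loglik = as.numeric(stats::logLik(g)),
    coefficients = if (is.null(whitened)) coef(g) else drop(whitened$coefficients),
    fitted = mu, n_used = nrow(data), n_dropped = n_dropped,
    selected_against = tab$term[sel], data = data
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<gam_fit> %s, n=%d (%d dropped), deviance explained=%.1f%%%s\n",
              x$family_name, x$n_used, x$n_dropped, 100 * x$dev_expl,
              if (!is.null(x$rho)) sprintf(", AR(1) rho=%.3f", x$rho) else ""))
  print(x$table, digits = 3)
  if (length(x$selected_against)) {
    cat("selected against:", paste(x$selected_against, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Negative-binomial dive-rate model
#'
#' Models the dive count per 5-min track point with a log link: a tensor
#' product of solar angle and Secchi depth (shrinkage margins; the two
#' covariates act jointly on underwater light but have different scales), a
#' 1-d shrinkage spline of cloud cover, a cyclic cubic spline of time of day
#' on \[0, 24), and a random intercept per bird. Serial correlation along
#' trips is absorbed with an AR(1) working correlation whose rho is the
#' pooled lag-1 autocorrelation of working residuals. Reports a Table-style
#' summary (term, EDF, statistic, p), deviance explained and the
#' presence/absence AUC.
#'
#' @param fix_table per-fix table with `n_dives`, `solar_deg`, `zsd_m`,
#'   `cloud_pct`, `time_of_day_h`, `bird_id`, `trip_id`.
#' @param k_tensor tensor margin basis dimension (default 5).
#' @param k1 1-d basis dimension (default 10).
#' @param use_ar1 absorb AR(1) serial correlation (default TRUE).
#' @return `gam_fit` with an `auc` element.
#' @export
fit_dive_rate_model <- function(fix_table, k_tensor = 5, k1 = 10,
                                use_ar1 = TRUE) {
  fix_table$bird_id <- as.factor(fix_table$bird_id)
  if (all(fix_table$n_dives == 0)) {
    stop("all dive counts are zero; dive-rate model undefined")
  }
  form <- n_dives ~ te(solar_deg, zsd_m, bs = c("ts", "ts"),
                       k = c(k_tensor, k_tensor)) +
    s(cloud_pct, bs = "ts", k = k1) +
    s(time_of_day_h, bs = "cc", k = k1) +
    s(bird_id, bs = "re")
  fit <- fit_gam(form, fix_table, family = mgcv::nb(), gamma = 1.2,
                 rho = if (use_ar1) "estimate" else NULL, group = "trip_id",
                 knots = list(time_of_day_h = c(0, 24)))
  fit$auc <- tryCatch(auc_presence(fit), warning = function(w) NA_real_,
                      error = function(e) NA_real_)
  fit
}

## rank-statistic AUC (Mann-Whitney U / (n1*n0)); ties get mid-ranks
auc_rank <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) {
    warning("one class absent; AUC undefined")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Presence/absence AUC of a fitted count model
#'
#' Converts the fitted negative-binomial mean into a predicted probability of
#' at least one dive, `P(N > 0) = 1 - (theta / (theta + mu))^theta`, and
#' scores it against observed dive presence with the rank-statistic AUC
#' (equivalent to Mann-Whitney U / (n1 n0)).
#'
#' @param fit `gam_fit` from [fit_dive_rate_model()] (negative binomial).
#' @param newdata optional table with the model covariates and `n_dives`;
#'   default the fitted data.
#' @return AUC in \[0, 1\]; NA with a warning when one class is absent.
#' @export
auc_presence <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "gam_fit"))
  if (!grepl("Negative Binomial", fit$family_name, ignore.case = TRUE)) {
    stop("auc_presence requires a negative-binomial fit")
  }
  theta <- fit$theta
  if (is.null(newdata)) {
    mu <- fit$fitted
    y <- fit$gam$y
  } else {
    X <- predict(fit$gam, newdata = newdata, type = "lpmatrix")
    mu <- fit$gam$family$linkinv(drop(X %*% fit$coefficients))
    y <- newdata$n_dives
  }
  p_dive <- 1 - (theta / (theta + mu))^theta
  auc_rank(p_dive, y > 0)
}

#' Gaussian bout-depth model
#'
#' Models the maximum dive depth per bout (identity link): tensor product of
#' solar angle and Secchi depth, shrinkage splines of cloud cover and water
#' depth, cyclic time of day, a random bird intercept, and the decoded HMM
#' behavioural state as a categorical covariate (contrasts against rest). No
#' AR(1) structure (bout maxima show no serial correlation). A
#' per-individual variant fits the solar x Secchi tensor separately for each
#' bird (`per_individual = TRUE`).
#'
#' @param bout_table per-bout table with `max_depth_m`, `solar_deg`, `zsd_m`,
#'   `cloud_pct`, `time_of_day_h`, `water_depth_m`, `bird_id`, `hmm_state`
#'   (factor with levels rest/ARS/transit or 1/2/3).
#' @param per_individual fit the tensor per bird (default FALSE).
#' @param k_tensor,k1 basis dimensions as in [fit_dive_rate_model()].
#' @return `gam_fit` with a `state_contrasts` data.frame (level, estimate_m,
#'   se, p; contrasts relative to rest).
#' @export
fit_dive_depth_model <- function(bout_table, per_individual = FALSE,
                                 k_tensor = 5, k1 = 10) {
  bout_table$bird_id <- as.factor(bout_table$bird_id)
  st <- bout_table$hmm_state
  if (!is.factor(st)) {
    st <- factor(c("rest", "ARS", "transit")[as.integer(st)],
                 levels = c("rest", "ARS", "transit"))
  }
  bout_table$hmm_state <- droplevels(st)
  form <- if (per_individual) {
    max_depth_m ~ te(solar_deg, zsd_m, bs = c("ts", "ts"),
                     k = c(k_tensor, k_tensor), by = bird_id) +
      s(cloud_pct, bs = "ts", k = k1) +
      s(time_of_day_h, bs = "cc", k = k1) +
      s(water_depth_m, bs = "ts", k = k1) +
      s(bird_id, bs = "re") + hmm_state
  } else {
    max_depth_m ~ te(solar_deg, zsd_m, bs = c("ts", "ts"),
                     k = c(k_tensor, k_tensor)) +
      s(cloud_pct, bs = "ts", k = k1) +
      s(time_of_day_h, bs = "cc", k = k1) +
      s(water_depth_m, bs = "ts", k = k1) +
      s(bird_id, bs = "re") + hmm_state
  }
  fit <- fit_gam(form, bout_table, family = stats::gaussian(), gamma = 1.2,
                 knots = list(time_of_day_h = c(0, 24)))
  ## parametric state contrasts vs rest
  ps <- summary(fit$gam)$p.table
  rows <- grep("^hmm_state", rownames(ps))
  fit$state_contrasts <- data.frame(
    level = sub("^hmm_state", "", rownames(ps)[rows]),
    estimate_m = ps[rows, "Estimate"], se = ps[rows, "Std. Error"],
    p = ps[rows, 4], row.names = NULL, stringsAsFactors = FALSE
  )
  fit
}

#' Evaluate a fitted tensor surface on a grid
#'
#' Predicts the solar-angle x Secchi-depth smooth (term contribution only)
#' over a regular grid, for surface-recovery checks and plotting.
#'
#' @param fit `gam_fit` containing a `te(solar_deg, zsd_m)` term.
#' @param solar_range,zsd_range grid ranges.
#' @param n grid points per side (default 20).
#' @return data.frame `solar_deg`, `zsd_m`, `effect`.
#' @export
tensor_surface <- function(fit, solar_range, zsd_range, n = 20) {
  g <- fit$gam
  grid <- expand.grid(
    solar_deg = seq(solar_range[1], solar_range[2], length.out = n),
    zsd_m = seq(zsd_range[1], zsd_range[2], length.out = n)
  )
  ## fill remaining covariates with typical values
  mf <- g$model
  for (v in names(mf)) {
    if (v %in% names(grid) || v == as.character(g$formula[[2]])) next
    col <- mf[[v]]
    grid[[v]] <- if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
      else median(col)
  }
  pt <- predict(g, newdata = grid, type = "terms")
  col <- grep("te(solar_deg,zsd_m)", colnames(pt), fixed = TRUE)[1]
  grid$effect <- pt[, col]
  grid[, c("solar_deg", "zsd_m", "effect")]
}
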