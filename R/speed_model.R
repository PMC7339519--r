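# The walking-speed model: an additive fixed-effect structure (intercept,
# non-linear slope smooth, rainfall per 10 mm, cumulative-distance fatigue
# category, land-cover and walker-class effects) plus a per-track random
# intercept. This file houses exact evaluation with the published
# coefficient set, a backfitting fitter for PairObservation data, and the
# variance decomposition.

#' Construct a speed model
#'
#' @param intercept_kmh baseline speed (km/h) at reference covariates:
#'   flat ground, no rain, short-distance category, mixed land cover,
#'   community-staff walker.
#' @param slope_smooth list describing the slope term; either
#'   `list(family = "exponential", a, b)` for
#'   `f(|s|) = -a * (exp(b * |s|) - 1)`, or
#'   `list(family = "bspline", boundary, knots, coef)` for a B-spline in
#'   `|s|` vanishing at 0.
#' @param rain_per10mm speed change per 10 mm of daily rainfall.
#' @param longdist_effect speed change once cumulative distance exceeds
#'   13 km.
#' @param landcover_effects named over [segment_lc_labels], `mixed` must be
#'   exactly 0 (reference).
#' @param individual_effects named over [individual_classes],
#'   `community_staff` must be exactly 0 (reference).
#' @param sigma_b SD of the track-level random intercept (km/h).
#' @param sigma_eps residual SD of a 10 s point-pair speed (km/h).
#' @param speed_floor evaluation lower clamp (km/h); the additive algebra
#'   can go non-positive on extreme slopes.
#' @return a `speed_model`.
#' @export
speed_model <- function(intercept_kmh,
                        slope_smooth = list(family = "exponential",
                                            a = 0.1, b = 0.05),
                        rain_per10mm = 0,
                        longdist_effect = 0,
                        landcover_effects = c(water = 0, forest = 0,
                                              rice_field = 0, savanna = 0,
                                              residential = 0, mixed = 0),
                        individual_effects = c(community_staff = 0,
                                               research_team = 0,
                                               local_population = 0),
                        sigma_b = 0, sigma_eps = 0,
                        speed_floor = 0.1) {
  stopifnot_scalar_number(intercept_kmh, "intercept_kmh")
  if (!setequal(names(landcover_effects), segment_lc_labels)) {
    wa_stop("`landcover_effects` must be named over: ",
            paste(segment_lc_labels, collapse = ", "))
  }
  if (!setequal(names(individual_effects), individual_classes)) {
    wa_stop("`individual_effects` must be named over: ",
            paste(individual_classes, collapse = ", "))
  }
  if (landcover_effects[["mixed"]] != 0) {
    wa_stop("`mixed` is the land-cover reference level and must carry effect 0")
  }
  if (individual_effects[["community_staff"]] != 0) {
    wa_stop("`community_staff` is the walker reference level and must carry effect 0")
  }
  if (sigma_b < 0 || sigma_eps < 0) wa_stop("variance components must be >= 0")
  if (abs(smooth_eval(slope_smooth, 0)) > 1e-12) {
    wa_stop("the slope smooth must vanish at slope 0")
  }
  m <- list(intercept_kmh = intercept_kmh,
            slope_smooth = slope_smooth,
            rain_per10mm = rain_per10mm,
            longdist_effect = longdist_effect,
            landcover_effects = landcover_effects[segment_lc_labels],
            individual_effects = individual_effects[individual_classes],
            sigma_b = sigma_b, sigma_eps = sigma_eps,
            speed_floor = speed_floor)
  class(m) <- "speed_model"
  m
}

#' @export
print.speed_model <- function(x, ...) {
  cat(sprintf("<speed_model> intercept %.2f km/h, rain %.3f per 10 mm, long-distance %.3f\n",
              x$intercept_kmh, x$rain_per10mm, x$longdist_effect))
  cat("land cover: ", paste(sprintf("%s %+.2f", names(x$landcover_effects),
                                    x$landcover_effects), collapse = ", "), "\n")
  cat("individual: ", paste(sprintf("%s %+.2f", names(x$individual_effects),
                                    x$individual_effects), collapse = ", "), "\n")
  cat(sprintf("slope smooth: %s; sigma_b %.3f, sigma_eps %.3f, floor %.2f km/h\n",
              x$slope_smooth$family, x$sigma_b, x$sigma_eps, x$speed_floor))
  invisible(x)
}

# evaluate a slope smooth at (vector) slope percent; smooths act on |s|
smooth_eval <- function(sm, slope_pct) {
  s <- abs(slope_pct)
  switch(sm$family,
    exponential = -sm$a * (exp(sm$b * s) - 1),
    bspline = {
      s <- pmin(s, sm$boundary[2]) # clamp beyond the fitted range
      B <- splines::bs(s, knots = sm$knots, degree = 3,
                       Boundary.knots = sm$boundary, intercept = FALSE)
      as.numeric(B %*% sm$coef)
    },
    wa_stop("unknown slope smooth family: ", sm$family)
  )
}

#' The published travel-speed coefficient set
#'
#' The multivariate fit reported for the Ifanadiana walking-track sample:
#' intercept 3.27 km/h, -0.06 km/h per 10 mm rainfall, -0.38 km/h beyond
#' 13 km walked, land-cover effects relative to mixed cover, and walker
#' effects relative to community staff. The published slope term is a
#' non-linear smooth; here it is carried by a parametric exponential-decay
#' family (configurable) with the same qualitative shape. Variance
#' components are calibrated so the track random intercepts account for
#' 39.45% of residual variance, with a residual SD of 0.8 km/h.
#'
#' @param sigma_eps residual SD (km/h) used to back out `sigma_b` from the
#'   39.45% random-intercept variance share.
#' @return a `speed_model`.
#' @export
published_model <- function(sigma_eps = 0.8) {
  share <- 0.3945
  speed_model(
    intercept_kmh = 3.27,
    slope_smooth = list(family = "exponential", a = 0.1, b = 0.05),
    rain_per10mm = -0.06,
    longdist_effect = -0.38,
    landcover_effects = c(water = -1.32, forest = 0.01, rice_field = -0.46,
                          savanna = -0.05, residential = -0.52, mixed = 0),
    individual_effects = c(community_staff = 0, research_team = 1.20,
                           local_population = 1.29),
    sigma_b = sigma_eps * sqrt(share / (1 - share)),
    sigma_eps = sigma_eps,
    speed_floor = 0.1
  )
}

#' Evaluate predicted walking speed
#'
#' Strictly additive above the floor:
#' `speed = max(floor, b0 + f(|slope|) + br * rain/10 + bd * 1[long] +
#' bL[label] + bI[class] + b_i)`.
#'
#' @param model a `speed_model`.
#' @param slope_pct signed slope percent (the smooth uses its absolute
#'   value).
#' @param rainfall_mm daily rainfall in mm.
#' @param cumdist_category `"short"` or `"long"`.
#' @param landcover_label one of [segment_lc_labels].
#' @param individual_class one of [individual_classes].
#' @param b_i track random intercept (default 0: population prediction).
#' @return speed in km/h (vectorised over the covariate arguments).
#' @export
predict_speed <- function(model, slope_pct = 0, rainfall_mm = 0,
                          cumdist_category = "short",
                          landcover_label = "mixed",
                          individual_class = "community_staff",
                          b_i = 0) {
  if (!inherits(model, "speed_model")) wa_stop("`model` must be a speed_model")
  if (!all(cumdist_category %in% c("short", "long"))) {
    wa_stop("unknown cumulative-distance category: ",
            paste(setdiff(cumdist_category, c("short", "long")), collapse = ", "))
  }
  if (!all(landcover_label %in% segment_lc_labels)) {
    wa_stop("unknown land-cover label: ",
            paste(setdiff(landcover_label, segment_lc_labels), collapse = ", "))
  }
  if (!all(individual_class %in% individual_classes)) {
    wa_stop("unknown individual class: ",
            paste(setdiff(individual_class, individual_classes), collapse = ", "))
  }
  mu <- model$intercept_kmh +
    smooth_eval(model$slope_smooth, slope_pct) +
    model$rain_per10mm * rainfall_mm / 10 +
    model$longdist_effect * (cumdist_category == "long") +
    model$landcover_effects[landcover_label] +
    model$individual_effects[individual_class] +
    b_i
  unname(pmax(mu, model$speed_floor))
}

#' Share of residual variance carried by the track random intercepts
#'
#' Defined as `sigma_b^2 / (sigma_b^2 + sigma_eps^2)`; errors when both
#' components are zero (the share is then undefined).
#'
#' @param fit a `speed_fit` or `speed_model`.
#' @return fraction in [0, 1].
#' @export
variance_share <- function(fit) {
  m <- if (inherits(fit, "speed_fit")) fit$model else fit
  if (!inherits(m, "speed_model")) wa_stop("`fit` must be a speed_fit or speed_model")
  denom <- m$sigma_b^2 + m$sigma_eps^2
  if (denom == 0) wa_stop("variance share undefined: both variance components are zero")
  m$sigma_b^2 / denom
}

# ---------------------------------------------------------------------------
# Fitting

fe_terms <- c("rainfall", "longdist", "landcover", "individual", "slope")

# fixed-effect design matrix (without the smooth column); factors carry the
# full level sets so absent levels surface as all-zero columns
fit_design <- function(pairs, drop = character()) {
  X <- list(intercept = rep(1, nrow(pairs)))
  if (!"rainfall" %in% drop) X$rain_per10mm <- pairs$rainfall_mm / 10
  if (!"longdist" %in% drop) {
    X$longdist <- as.numeric(pairs$cumdist_category == "long")
  }
  if (!"landcover" %in% drop) {
    for (lv in setdiff(segment_lc_labels, "mixed")) {
      X[[paste0("landcover_", lv)]] <- as.numeric(pairs$landcover_label == lv)
    }
  }
  if (!"individual" %in% drop) {
    for (lv in setdiff(individual_classes, "community_staff")) {
      X[[paste0("individual_", lv)]] <- as.numeric(pairs$individual_class == lv)
    }
  }
  do.call(cbind, X)
}

validate_pairs <- function(pairs, drop) {
  need <- c("track_id", "individual_class", "speed_kmh", "slope_pct",
            "rainfall_mm", "cumdist_category", "landcover_label")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) wa_stop("`pairs` lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(pairs$speed_kmh)) || any(pairs$speed_kmh <= 0)) {
    wa_stop("pair speeds must be positive and finite (filter first)")
  }
  if (length(unique(pairs$track_id)) < 2L) {
    wa_stop("at least two tracks are required to separate the random intercept from the intercept")
  }
  if (!"landcover" %in% drop) {
    absent <- setdiff(segment_lc_labels, unique(pairs$landcover_label))
    if (length(absent)) {
      wa_stop("rank-deficient design: no observations for land-cover level(s) ",
              paste(absent, collapse = ", "))
    }
  }
  if (!"individual" %in% drop) {
    absent <- setdiff(individual_classes, unique(pairs$individual_class))
    if (length(absent)) {
      wa_stop("rank-deficient design: no observations for individual class(es) ",
              paste(absent, collapse = ", "))
    }
  }
  if (!"longdist" %in% drop &&
      length(unique(pairs$cumdist_category)) < 2L) {
    wa_stop("rank-deficient design: cumulative-distance category '",
            setdiff(c("short", "long"), unique(pairs$cumdist_category)),
            "' has no observations")
  }
  invisible(TRUE)
}

#' Fit the travel-speed model to pair observations
#'
#' Backfitting estimation of the mixed additive model: iterate (i) least
#' squares for the fixed effects and the slope smooth on speeds net of the
#' current track BLUPs, (ii) BLUP shrinkage of per-track mean residuals,
#' (iii) one-way ANOVA moment updates of the variance components, until the
#' largest coefficient change drops below `tol`. This is Gauss-Seidel on
#' Henderson's mixed-model equations, so the fixed effects converge to the
#' GLS solution; Wald standard errors are computed at convergence from the
#' partially demeaned (GLS-transform) regression.
#'
#' @param pairs PairObservation data frame (see [pair_speeds()]).
#' @param smooth `"exponential"` fits the parametric decay family (shape
#'   parameter profiled by 1-D optimisation); `"bspline"` fits a cubic
#'   B-spline in `|slope|` constrained to vanish at 0.
#' @param spline_df degrees of freedom of the B-spline smooth.
#' @param spline_penalty ridge penalty on the B-spline coefficients
#'   (0 = unpenalised; the fixed `spline_df` is the effective smoothing
#'   control).
#' @param drop character subset of
#'   `c("rainfall", "longdist", "landcover", "individual", "slope")` to
#'   exclude (used for AIC-based term deletion).
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter iteration cap.
#' @return a `speed_fit`: `model` (fitted `speed_model`), `coefficients`,
#'   `standard_errors`, `p_values`, `variance_share_random`, `n_pairs`,
#'   `n_tracks`, `blups`, `logLik`, `aic`, `convergence`.
#' @export
fit_speed_model <- function(pairs, smooth = c("exponential", "bspline"),
                            spline_df = 8, spline_penalty = 0,
                            drop = character(), tol = 1e-6, max_iter = 200L) {
  smooth <- match.arg(smooth)
  drop <- as.character(drop)
  if (!all(drop %in% fe_terms)) {
    wa_stop("unknown term in `drop`: ",
            paste(setdiff(drop, fe_terms), collapse = ", "))
  }
  validate_pairs(pairs, drop)

  y <- pairs$speed_kmh
  n <- length(y)
  track <- factor(pairs$track_id)
  m <- nlevels(track)
  ti <- as.integer(track)
  n_i <- tabulate(ti, m)
  s_abs <- abs(pairs$slope_pct)
  fit_slope <- !"slope" %in% drop && any(s_abs > 1e-9)

  X0 <- fit_design(pairs, drop)
  zero_cols <- colSums(abs(X0)) == 0 & colnames(X0) != "intercept"
  if (any(zero_cols)) {
    wa_stop("rank-deficient design: all-zero column(s) ",
            paste(colnames(X0)[zero_cols], collapse = ", "))
  }

  # B-spline basis is fixed across iterations; exponential column depends
  # on the profiled shape parameter g
  Bspl <- NULL
  if (fit_slope && smooth == "bspline") {
    bnd <- c(0, max(s_abs))
    qs <- stats::quantile(s_abs, probs = seq_len(spline_df - 3) /
                            (spline_df - 2))
    Bspl <- splines::bs(s_abs, knots = qs, degree = 3, Boundary.knots = bnd,
                        intercept = FALSE)
  }
  make_X <- function(g) {
    if (!fit_slope) return(X0)
    if (smooth == "bspline") cbind(X0, Bspl)
    else cbind(X0, slope_a = -(exp(g * s_abs) - 1))
  }
  solve_beta <- function(X, yy) {
    if (spline_penalty > 0 && smooth == "bspline" && fit_slope) {
      p0 <- ncol(X0)
      P <- diag(c(rep(0, p0), rep(spline_penalty, ncol(X) - p0)))
      qr.solve(crossprod(X) + P, crossprod(X, yy))
    } else {
      stats::lm.fit(X, yy)$coefficients
    }
  }

  # Backfitting between the fixed-effect/smooth block and the variance
  # components. The fixed-effect update solves the random-intercept GLS
  # exactly via the partial within-track demeaning transform (weight
  # lambda_i = 1 - sqrt(sige2 / (sige2 + n_i * sigb2))), which is the
  # fixed point the Gauss-Seidel BLUP sweep converges to; iterating it
  # with the moment updates of (sigb2, sige2) converges in a handful of
  # passes even with thousands of observations per track.
  sigb2 <- 0; sige2 <- 0
  g <- 0.05
  beta <- NULL
  Xs <- NULL
  conv <- data.frame(iter = integer(), max_delta = numeric())
  for (it in seq_len(max_iter)) {
    lam <- if (sige2 > 0) 1 - sqrt(sige2 / (sige2 + n_i * sigb2)) else rep(0, m)
    demean <- function(M) {
      M <- as.matrix(M)
      M - lam[ti] * (rowsum(M, ti) / n_i)[ti, , drop = FALSE]
    }
    ys <- as.numeric(demean(y))
    if (fit_slope && smooth == "exponential") {
      rss_g <- function(gg) {
        sum(stats::lm.fit(demean(make_X(gg)), ys)$residuals^2)
      }
      g <- stats::optimize(rss_g, interval = c(1e-4, 0.5), tol = 1e-7)$minimum
    }
    X <- make_X(g)
    Xs <- demean(X)
    beta_new <- as.numeric(solve_beta(Xs, ys))
    names(beta_new) <- colnames(X)
    r <- y - as.numeric(X %*% beta_new)

    # one-way random-effects ANOVA moment estimators on the residuals
    rbar <- as.numeric(rowsum(r, ti) / n_i)
    ssw <- sum((r - rbar[ti])^2)
    sige2 <- ssw / max(n - m, 1)
    msb <- sum(n_i * (rbar - mean(r))^2) / max(m - 1, 1)
    n0 <- (n - sum(n_i^2) / n) / max(m - 1, 1)
    sigb2 <- max(0, (msb - sige2) / n0)

    delta <- if (is.null(beta)) Inf else max(abs(beta_new - beta))
    conv <- rbind(conv, data.frame(iter = it, max_delta = delta))
    beta <- beta_new
    if (delta < tol) break
  }
  if (conv$max_delta[nrow(conv)] >= tol) {
    warning("fit_speed_model: backfitting stopped at max_iter without meeting tol")
  }
  # BLUP shrinkage of per-track mean residuals at the converged solution
  rbar <- as.numeric(rowsum(y - as.numeric(X %*% beta), ti) / n_i)
  b_hat <- if (sige2 > 0) (n_i * sigb2 / (n_i * sigb2 + sige2)) * rbar
           else if (sigb2 > 0) rbar else rep(0, m)

  # Wald SEs from the final GLS-transformed regression
  se <- rep(0, length(beta))
  if (sige2 > 0) {
    V <- tryCatch(solve(crossprod(Xs)) * sige2, error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
  }
  names(se) <- names(beta)
  pval <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta / se)), NA_real_)

  # marginal Gaussian log likelihood (ML plug-in) and AIC
  ll <- mixed_loglik(r, ti, n_i, sigb2, sige2)
  n_par <- length(beta) + 2 + (fit_slope && smooth == "exponential")
  aic <- -2 * ll + 2 * n_par

  sm <- if (!fit_slope) {
    list(family = "exponential", a = 0, b = 0.05)
  } else if (smooth == "exponential") {
    list(family = "exponential", a = unname(beta["slope_a"]), b = g)
  } else {
    list(family = "bspline", boundary = attr(Bspl, "Boundary.knots"),
         knots = attr(Bspl, "knots"),
         coef = unname(beta[seq.int(ncol(X0) + 1, length(beta))]))
  }
  lc_eff <- stats::setNames(rep(0, length(segment_lc_labels)), segment_lc_labels)
  ind_eff <- stats::setNames(rep(0, length(individual_classes)), individual_classes)
  for (lv in setdiff(segment_lc_labels, "mixed")) {
    nm <- paste0("landcover_", lv)
    if (nm %in% names(beta)) lc_eff[lv] <- beta[[nm]]
  }
  for (lv in setdiff(individual_classes, "community_staff")) {
    nm <- paste0("individual_", lv)
    if (nm %in% names(beta)) ind_eff[lv] <- beta[[nm]]
  }
  model <- speed_model(
    intercept_kmh = beta[["intercept"]],
    slope_smooth = sm,
    rain_per10mm = if ("rain_per10mm" %in% names(beta)) beta[["rain_per10mm"]] else 0,
    longdist_effect = if ("longdist" %in% names(beta)) beta[["longdist"]] else 0,
    landcover_effects = lc_eff,
    individual_effects = ind_eff,
    sigma_b = sqrt(sigb2), sigma_eps = sqrt(sige2)
  )
  fit <- list(model = model, coefficients = beta, standard_errors = se,
              p_values = pval,
              variance_share_random = if (sigb2 + sige2 > 0)
                sigb2 / (sigb2 + sige2) else NA_real_,
              n_pairs = n, n_tracks = m,
              blups = stats::setNames(b_hat, levels(track)),
              logLik = ll, aic = aic, convergence = conv,
              smooth_type = smooth, dropped_terms = drop)
  class(fit) <- "speed_fit"
  fit
}

# marginal log likelihood of the random-intercept model given fixed-effect
# residuals r, grouped by ti (closed form per track)
mixed_loglik <- function(r, ti, n_i, sigb2, sige2) {
  if (sige2 <= 0) return(Inf) # degenerate noiseless fit
  rs <- as.numeric(rowsum(r, ti))
  rss <- as.numeric(rowsum(r^2, ti))
  d <- 1 + n_i * sigb2 / sige2
  quad <- rss / sige2 - (sigb2 / (sige2 * (sige2 + n_i * sigb2))) * rs^2
  -0.5 * sum(n_i * log(2 * pi * sige2) + log(d) + quad)
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("<speed_fit> %d pairs, %d tracks, %d backfitting iterations\n",
              x$n_pairs, x$n_tracks, nrow(x$convergence)))
  tab <- data.frame(coef = round(x$coefficients, 4),
                    se = round(x$standard_errors, 4),
                    p = signif(x$p_values, 3))
  print(tab)
  cat(sprintf("sigma_b %.3f, sigma_eps %.3f, random-effect variance share %.2f%%\n",
              x$model$sigma_b, x$model$sigma_eps,
              100 * x$variance_share_random))
  invisible(x)
}

#' @export
AIC.speed_fit <- function(object, ..., k = 2) object$aic

#' Coefficient/SE/p table of a speed fit
#' @param fit a `speed_fit`.
#' @return data frame with columns `term`, `estimate`, `se`, `p`.
#' @export
fit_report <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$standard_errors),
             p = unname(fit$p_values), stringsAsFactors = FALSE)
}
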