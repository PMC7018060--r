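#' Phantom beam-hardening calibration
#'
#' Models the scanner's residual beam-hardening artifact from QCT phantom
#' observations. Each phantom region (nominal 0, 50, 100, 200 mg/ml calcium
#' hydroxyapatite in regions P1-P4) contributes ROI mean CT numbers measured
#' on slices of varying subject size; within a region the relationship is
#' log-linear,
#'
#' \deqn{CT\# = B - A \ln(\mathrm{size\ index})}
#'
#' so `B` is the region's CT number at size index 1 and `A` (reported
#' positive) is the HU lost per e-fold of subject size. `ct_calibration()`
#' fits each region by ordinary least squares, tests slope homogeneity of the
#' pooling regions with a Wald test of the region-by-ln(size) interaction,
#' fits the common-slope model for those regions, and — when both TSI and CSA
#' are recorded — compares the two size indices by AIC of the full
#' four-region interaction model.
#'
#' Soft tissue falls between the P1 and P2 densities, so the pooled P1-P2
#' slope is the correction coefficient passed to [correct_ct_number()].
#'
#' @param obs data.frame of phantom observations with columns `region`,
#'   `mean_hu`, `size_index` (and optionally both `tsi` and `csa`, in which
#'   case `size_index` is taken from the requested index).
#' @param index which size index drives the calibration: `"tsi"` or `"csa"`.
#'   Ignored when `obs` already has a `size_index` column and no per-index
#'   columns.
#' @param pool_regions regions whose slopes are pooled for the correction
#'   coefficient; default `c("P1", "P2")`.
#' @param alpha significance level of the slope-homogeneity Wald test.
#' @return An object of class `ct_calibration` with components `per_region`
#'   (data.frame of A, B and their SEs per region), `wald` (slope test),
#'   `pooled` (pooled A, SE, per-region intercepts, residual SD),
#'   `comparison` (AIC comparison, or `NULL` when only one index is
#'   available), `index`, and the data used.
#' @seealso [fit_region_calibration()], [wald_slope_test()],
#'   [fit_pooled_calibration()], [compare_size_indices()],
#'   [correct_ct_number()]
#' @export
ct_calibration <- function(obs, index = c("tsi", "csa"),
                           pool_regions = c("P1", "P2"), alpha = 0.05) {
  index <- match.arg(index)
  obs <- as.data.frame(obs)
  if (!"size_index" %in% names(obs)) {
    if (!index %in% names(obs))
      stop("'obs' needs a 'size_index' column or a '", index, "' column",
           call. = FALSE)
    obs$size_index <- obs[[index]]
  }
  check_phantom_obs(obs)
  regions <- sort(unique(as.character(obs$region)))
  per <- do.call(rbind, lapply(regions, function(r) {
    f <- fit_region_calibration(obs[obs$region == r, , drop = FALSE])
    data.frame(region = r, A = f$A, se_A = f$se_A, B = f$B, se_B = f$se_B,
               n = f$n, sigma = f$sigma)
  }))
  rownames(per) <- NULL
  missing_pool <- setdiff(pool_regions, regions)
  if (length(missing_pool))
    stop("pool_regions not present in data: ",
         paste(missing_pool, collapse = ", "), call. = FALSE)
  pool_obs <- obs[obs$region %in% pool_regions, , drop = FALSE]
  wald <- if (length(pool_regions) >= 2L) wald_slope_test(pool_obs, alpha)
  else NULL
  pooled <- fit_pooled_calibration(pool_obs)
  comparison <- if (all(c("tsi", "csa") %in% names(obs)))
    compare_size_indices(obs) else NULL
  structure(list(per_region = per, wald = wald, pooled = pooled,
                 comparison = comparison, index = index,
                 pool_regions = pool_regions, alpha = alpha, data = obs),
            class = "ct_calibration")
}

check_phantom_obs <- function(obs) {
  need <- c("region", "mean_hu", "size_index")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("phantom observations lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(obs$size_index)) || any(obs$size_index <= 0))
    stop("all size_index values must be positive (required for ln)",
         call. = FALSE)
  invisible(obs)
}

#' Per-region calibration fit
#'
#' OLS regression of phantom ROI mean CT number on the natural log of the
#' size index, for a single phantom region. The slope is negated so the
#' coefficients read directly as `CT# = B - A ln(s)`.
#'
#' @param obs observations for one region (`mean_hu`, `size_index`).
#' @return list with `A`, `se_A`, `B`, `se_B`, `sigma` (residual SD), `n`,
#'   `cov` (coefficient covariance on the (B, A) parameterization) and the
#'   underlying `lm` fit.
#' @export
fit_region_calibration <- function(obs) {
  obs <- as.data.frame(obs)
  if (!"region" %in% names(obs)) obs$region <- "r"
  check_phantom_obs(obs)
  if (nrow(obs) < 3L)
    stop("need >= 3 observations per region", call. = FALSE)
  if (length(unique(obs$size_index)) < 2L)
    stop("all size indices are equal; calibration design is rank-deficient",
         call. = FALSE)
  fit <- stats::lm(mean_hu ~ log(size_index), data = obs)
  sm <- summary(fit)
  co <- sm$coefficients
  V <- stats::vcov(fit)
  # negate the slope: Var is unchanged, covariance with B flips sign
  V[1, 2] <- V[2, 1] <- -V[1, 2]
  list(A = -co[2, 1], se_A = co[2, 2], B = co[1, 1], se_B = co[1, 2],
       sigma = sm$sigma, n = nrow(obs), cov = V, lm = fit)
}

#' Wald test of slope homogeneity between two phantom regions
#'
#' Fits `mean_hu ~ region * log(size_index)` over exactly two regions and
#' tests the interaction coefficient with a Wald statistic
#' `(estimate / SE)^2` referred to chi-squared with 1 df (equivalently a
#' standard-normal z test). Pooling the slopes is recommended iff
#' `p >= alpha`.
#'
#' @param obs observations for exactly two regions.
#' @param alpha significance level; default 0.05.
#' @return list of class `slope_test`: `estimate`, `se`, `statistic`
#'   (chi-squared), `p_value`, `pool`, `alpha`, `regions`.
#' @export
wald_slope_test <- function(obs, alpha = 0.05) {
  obs <- as.data.frame(obs)
  check_phantom_obs(obs)
  regions <- unique(as.character(obs$region))
  if (length(regions) != 2L)
    stop("wald_slope_test() needs exactly two regions", call. = FALSE)
  for (r in regions) {
    sub <- obs[obs$region == r, ]
    if (nrow(sub) < 3L || length(unique(sub$size_index)) < 2L)
      stop("region ", r, " has a degenerate design", call. = FALSE)
  }
  obs$region <- factor(obs$region, levels = regions)
  fit <- stats::lm(mean_hu ~ region * log(size_index), data = obs)
  co <- summary(fit)$coefficients
  est <- co[4, 1]; se <- co[4, 2]
  stat <- (est / se)^2
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(estimate = est, se = se, statistic = stat, p_value = p,
                 pool = p >= alpha, alpha = alpha, regions = regions,
                 lm = fit),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Wald test of slope homogeneity (%s vs %s)\n",
              x$regions[1], x$regions[2]))
  cat(sprintf("  interaction = %.4g (SE %.4g), chi-sq(1) = %.4g, p = %.4g\n",
              x$estimate, x$se, x$statistic, x$p_value))
  cat(sprintf("  pooling %s at alpha = %g\n",
              if (x$pool) "supported" else "rejected", x$alpha))
  invisible(x)
}

#' Common-slope (pooled) calibration fit
#'
#' Fits the pooled model `mean_hu ~ region + log(size_index)` over the
#' supplied regions: separate intercepts, one shared slope. The pooled `A`
#' (the negated shared slope) is the coefficient used by the subject-size
#' correction. A single region degenerates to [fit_region_calibration()].
#'
#' @param obs observations for the regions to pool.
#' @return list with `A`, `se_A`, `intercepts` (named per region),
#'   `sigma`, `n`, `regions` and the underlying `lm` fit.
#' @export
fit_pooled_calibration <- function(obs) {
  obs <- as.data.frame(obs)
  check_phantom_obs(obs)
  regions <- unique(as.character(obs$region))
  if (length(regions) == 1L) {
    f <- fit_region_calibration(obs)
    return(list(A = f$A, se_A = f$se_A,
                intercepts = stats::setNames(f$B, regions),
                sigma = f$sigma, n = f$n, regions = regions, lm = f$lm))
  }
  obs$region <- factor(obs$region, levels = regions)
  fit <- stats::lm(mean_hu ~ 0 + region + log(size_index), data = obs)
  co <- summary(fit)$coefficients
  k <- length(regions)
  ints <- stats::setNames(co[seq_len(k), 1], regions)
  list(A = -co[k + 1L, 1], se_A = co[k + 1L, 2], intercepts = ints,
       sigma = summary(fit)$sigma, n = nrow(obs), regions = regions,
       lm = fit)
}

#' AIC comparison of the two size indices
#'
#' Fits the full four-region interaction model `mean_hu ~ region * log(index)`
#' once with TSI and once with CSA as the size index and compares Gaussian
#' maximum-likelihood AIC (`stats::AIC`, i.e. `n log(RSS/n) + 2k` plus the
#' constant `n(1 + log 2*pi)` that cancels in the comparison). The index with
#' the lower AIC explains more of the size-dependent CT-number variation.
#'
#' @param obs observations with both `tsi` and `csa` columns plus `region`,
#'   `mean_hu`.
#' @return list of class `size_index_comparison`: `aic_tsi`, `aic_csa`,
#'   `selected` (`"tsi"`, `"csa"`, or `"tie"`).
#' @export
compare_size_indices <- function(obs) {
  obs <- as.data.frame(obs)
  need <- c("region", "mean_hu", "tsi", "csa")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(obs$tsi) | !is.finite(obs$csa))
  if (length(bad))
    stop("rows with missing/invalid index values: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  obs$region <- factor(obs$region)
  fit_tsi <- stats::lm(mean_hu ~ region * log(tsi), data = obs)
  fit_csa <- stats::lm(mean_hu ~ region * log(csa), data = obs)
  aic_tsi <- stats::AIC(fit_tsi)
  aic_csa <- stats::AIC(fit_csa)
  selected <- if (isTRUE(all.equal(aic_tsi, aic_csa))) "tie"
  else if (aic_tsi < aic_csa) "tsi" else "csa"
  structure(list(aic_tsi = aic_tsi, aic_csa = aic_csa, selected = selected),
            class = "size_index_comparison")
}

#' @export
print.size_index_comparison <- function(x, ...) {
  cat(sprintf("Size-index comparison: AIC(TSI) = %.1f, AIC(CSA) = %.1f -> %s\n",
              x$aic_tsi, x$aic_csa,
              if (x$selected == "tie") "tie" else toupper(x$selected)))
  invisible(x)
}

## ---- S3 methods for ct_calibration ---------------------------------------

#' @export
print.ct_calibration <- function(x, ...) {
  cat("Phantom beam-hardening calibration: CT# = B - A ln(size index)\n")
  cat(sprintf("  size index: %s; %d observations in %d regions\n",
              toupper(x$index), nrow(x$data), nrow(x$per_region)))
  cat(sprintf("  pooled A (%s): %.3f (SE %.3f)\n",
              paste(x$pool_regions, collapse = "+"),
              x$pooled$A, x$pooled$se_A))
  invisible(x)
}

#' @export
summary.ct_calibration <- function(object, ...) {
  structure(list(fit = object), class = "summary.ct_calibration")
}

#' @export
print.summary.ct_calibration <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-region coefficients:\n")
  print(format(f$per_region, digits = 4), row.names = FALSE)
  if (!is.null(f$wald)) { cat("\n"); print(f$wald) }
  if (!is.null(f$comparison)) { cat("\n"); print(f$comparison) }
  invisible(x)
}

#' @export
coef.ct_calibration <- function(object, ...) {
  per <- object$per_region
  out <- c(stats::setNames(per$A, paste0("A_", per$region)),
           stats::setNames(per$B, paste0("B_", per$region)),
           A_pooled = object$pooled$A)
  out
}

#' Predict phantom CT numbers from a calibration
#'
#' Evaluates the per-region fitted lines `B_r - A_r ln(size_index)` at new
#' sizes. At `size_index = 1` the prediction equals the region intercept
#' exactly.
#'
#' @param object a `ct_calibration`.
#' @param newdata data.frame with `region` and `size_index`; defaults to the
#'   training data.
#' @param ... unused.
#' @return numeric vector of predicted mean HU.
#' @export
predict.ct_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  per <- object$per_region
  idx <- match(as.character(newdata$region), per$region)
  if (anyNA(idx))
    stop("unknown region(s): ",
         paste(unique(newdata$region[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (any(newdata$size_index <= 0))
    stop("size_index must be positive", call. = FALSE)
  per$B[idx] - per$A[idx] * log(newdata$size_index)
}

#' @export
residuals.ct_calibration <- function(object, ...) {
  object$data$mean_hu - stats::predict(object)
}

#' @export
fitted.ct_calibration <- function(object, ...) stats::predict(object)

#' Simulate phantom observations from a fitted calibration
#'
#' Draws new `mean_hu` values at the training design points from the fitted
#' per-region lines plus Gaussian noise at each region's residual SD.
#'
#' @param object a `ct_calibration`.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame (nsim = 1) or list of data.frames.
#' @export
simulate.ct_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- stats::predict(object)
    sig <- object$per_region$sigma[match(as.character(object$data$region),
                                         object$per_region$region)]
    sims <- lapply(seq_len(nsim), function(i) {
      out <- object$data
      out$mean_hu <- stats::rnorm(length(mu), mu, sig)
      out
    })
    if (nsim == 1L) sims[[1]] else sims
  })
}

#' Plot a phantom calibration
#'
#' Scatter of phantom ROI CT numbers against ln(size index), one colour per
#' region, with the fitted per-region lines overlaid.
#'
#' @param x a `ct_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ct_calibration <- function(x, ...) {
  d <- x$data
  regs <- x$per_region$region
  cols <- stats::setNames(grDevices::hcl.colors(length(regs), "Dark 3"), regs)
  graphics::plot(log(d$size_index), d$mean_hu,
                 col = cols[as.character(d$region)], pch = 19,
                 xlab = sprintf("ln(%s)", x$index),
                 ylab = "phantom ROI CT number (HU)", ...)
  for (i in seq_along(regs)) {
    graphics::abline(a = x$per_region$B[i], b = -x$per_region$A[i],
                     col = cols[i])
  }
  graphics::legend("topright", legend = regs, col = cols, pch = 19, bty = "n")
  invisible(x)
}

#' Serialize a calibration report to JSON
#'
#' Writes coefficients, SEs, the Wald pooling decision and (when available)
#' the AIC index comparison in the JSON layout the correction and diagnostics
#' steps consume.
#'
#' @param fit a `ct_calibration`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(fit, path) {
  stopifnot(inherits(fit, "ct_calibration"))
  rep <- list(
    model = "CT# = B - A*ln(size_index)",
    index = fit$index,
    per_region = fit$per_region,
    pooled = list(regions = fit$pool_regions, A = fit$pooled$A,
                  se_A = fit$pooled$se_A,
                  intercepts = as.list(fit$pooled$intercepts)),
    wald = if (!is.null(fit$wald))
      list(estimate = fit$wald$estimate, se = fit$wald$se,
           statistic = fit$wald$statistic, p_value = fit$wald$p_value,
           pool = fit$wald$pool, alpha = fit$wald$alpha),
    comparison = if (!is.null(fit$comparison))
      list(aic_tsi = fit$comparison$aic_tsi, aic_csa = fit$comparison$aic_csa,
           selected = fit$comparison$selected)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
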