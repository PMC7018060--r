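#' GEE logistic regression of fibrosis on corrected CT number
#'
#' Fits the marginal logistic model `P(fibrosis) = expit(b0 + b1 * HU)` by
#' generalized estimating equations with an exchangeable working correlation
#' over the repeated measures (two kidney sides) within each animal, and
#' reports cluster-robust ("sandwich") standard errors. The working
#' correlation is estimated by the usual moment estimator from Pearson
#' residuals; with singleton clusters (or zero estimated correlation) the
#' coefficients coincide with ordinary independent-data logistic maximum
#' likelihood.
#'
#' Perfect separation is flagged (fitted probabilities degenerate at 0/1):
#' estimates are still returned, with `separation = TRUE` and a warning.
#'
#' @param records data.frame with the outcome, predictor and cluster id.
#' @param formula model formula; default `fibrotic ~ corrected_hu`. The
#'   response must be logical/0-1.
#' @param id name of the cluster (animal) column; default `"animal"`.
#' @param max_iter,tol Fisher-scoring controls.
#' @return object of class `gee_fit`: `coefficients`, `robust_se`,
#'   `naive_se`, `alpha` (working correlation), `phi` (scale),
#'   `z`, `p_value` (robust Wald), `converged`, `separation`, `n_clusters`.
#' @export
gee_logistic <- function(records, formula = fibrotic ~ corrected_hu,
                         id = "animal", max_iter = 100, tol = 1e-10) {
  records <- as.data.frame(records)
  if (!id %in% names(records)) stop("no cluster column '", id, "'", call. = FALSE)
  vars <- all.vars(formula)
  records <- records[stats::complete.cases(records[, c(vars, id)]), ,
                     drop = FALSE]
  mf <- stats::model.frame(formula, records)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  cl <- factor(records[[id]])
  if (nlevels(cl) < 2L) stop("need >= 2 clusters", call. = FALSE)
  p <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), cl)

  # inverse of the exchangeable working covariance A^1/2 R(alpha) A^1/2,
  # using the closed form R^-1 = [I - alpha/(1+(ni-1)alpha) J] / (1-alpha)
  exch_vinv <- function(Ai, alpha) {
    ni <- length(Ai)
    Rinv <- (diag(ni) - matrix(alpha / (1 + (ni - 1) * alpha), ni, ni)) /
      (1 - alpha)
    Rinv / tcrossprod(Ai)
  }
  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  if (any(!is.finite(beta))) beta <- rep(0, p)
  alpha <- 0
  converged <- FALSE
  v_floor <- 1e-8
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), v_floor)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (n - p)
    # moment estimator of the exchangeable correlation
    num <- 0; npairs <- 0
    for (ii in idx) {
      ni <- length(ii)
      if (ni > 1L) {
        s <- sum(r[ii])
        num <- num + (s^2 - sum(r[ii]^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
    }
    alpha <- if (npairs > p && phi > 0) num / (phi * (npairs - p)) else 0
    # bound away from the +/-1 degeneracies of the exchangeable structure
    max_ni <- max(lengths(idx))
    if (max_ni > 1L)
      alpha <- min(max(alpha, -1 / (max_ni - 1) + 0.05), 0.95)
    U <- numeric(p); H <- matrix(0, p, p)
    for (ii in idx) {
      Vinv <- exch_vinv(sqrt(v[ii]), alpha)
      Di <- X[ii, , drop = FALSE] * v[ii]
      U <- U + crossprod(Di, Vinv %*% (y[ii] - mu[ii]))
      H <- H + crossprod(Di, Vinv %*% Di)
    }
    delta <- tryCatch(solve(H, U), error = function(e) NULL)
    if (is.null(delta)) break  # degenerate information: stop at current beta
    beta <- beta + drop(delta)
    if (max(abs(drop(X %*% beta))) > 200) break  # diverging towards separation
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  v <- pmax(mu * (1 - mu), v_floor)
  # sandwich covariance
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ii in idx) {
    Vinv <- exch_vinv(sqrt(v[ii]), alpha)
    Di <- X[ii, , drop = FALSE] * v[ii]
    ei <- y[ii] - mu[ii]
    B <- B + crossprod(Di, Vinv %*% Di)
    s <- crossprod(Di, Vinv %*% ei)
    M <- M + tcrossprod(s)
  }
  Binv <- tryCatch(solve(B), error = function(e) {
    solve(B + diag(1e-8 * max(diag(B)) + 1e-12, p))
  })
  V_rob <- Binv %*% M %*% Binv
  # separation: every fitted probability degenerate and perfectly classifying
  separation <- all(pmin(mu, 1 - mu) < 1e-6) &&
    all((y == 1) == (mu > 0.5))
  if (separation)
    warning("possible perfect separation; GEE estimates are unstable")
  robust_se <- sqrt(diag(V_rob))
  z <- beta / robust_se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 robust_se = stats::setNames(robust_se, colnames(X)),
                 naive_se = stats::setNames(sqrt(diag(Binv)), colnames(X)),
                 vcov = V_rob, alpha = alpha, phi = phi,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 corstr = "exchangeable", converged = converged,
                 separation = separation, n_clusters = nlevels(cl),
                 n = n, formula = formula),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE logistic regression (exchangeable working correlation)\n")
  cat(sprintf("  %d observations in %d clusters; alpha = %.3f\n",
              x$n, x$n_clusters, x$alpha))
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$robust_se,
               z = x$z, `Pr(>|z|)` = x$p_value)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  if (x$separation) cat("  WARNING: possible perfect separation\n")
  invisible(x)
}

#' Empirical ROC analysis of a continuous fibrosis score
#'
#' Builds the empirical ROC curve of a positively-oriented score (here the
#' corrected CT number) against the binary fibrosis label. Cutoffs are the
#' midpoints between consecutive distinct score values plus `-Inf`/`+Inf`
#' endpoints; a kidney is called positive when its score strictly exceeds the
#' cutoff (ties classified negative). AUC is the trapezoidal area, which for
#' this construction equals the Mann-Whitney concordance probability with the
#' 1/2 tie convention. PPV/NPV at each cutoff use the observed sample
#' prevalence.
#'
#' @param score numeric score vector.
#' @param label logical (or 0/1) fibrosis labels.
#' @return object of class `roc_result`: `curve` (data.frame of cutoff,
#'   sensitivity, specificity, ppv, npv), `auc`, `prevalence`, `n_pos`,
#'   `n_neg`, plus the data for [operating_point()].
#' @export
roc_analysis <- function(score, label) {
  label <- as.logical(label)
  ok <- is.finite(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  if (!any(label) || all(label))
    stop("both outcome classes must be present for ROC analysis",
         call. = FALSE)
  s <- sort(unique(score))
  cutoffs <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  rows <- lapply(cutoffs, function(ct) confusion_metrics(score, label, ct))
  curve <- do.call(rbind, rows)
  curve <- cbind(cutoff = cutoffs, curve)
  # trapezoid over (1-specificity, sensitivity), sorted by FPR
  fpr <- 1 - curve$specificity; tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  structure(list(curve = curve, auc = auc,
                 prevalence = mean(label), n_pos = sum(label),
                 n_neg = sum(!label), score = score, label = label),
            class = "roc_result")
}

confusion_metrics <- function(score, label, cutoff) {
  pos <- score > cutoff
  tp <- sum(pos & label); fp <- sum(pos & !label)
  fn <- sum(!pos & label); tn <- sum(!pos & !label)
  data.frame(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC = %.3f (%d positive, %d negative; prevalence %.0f%%)\n",
              x$auc, x$n_pos, x$n_neg, 100 * x$prevalence))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  fpr <- 1 - x$curve$specificity
  o <- order(fpr, x$curve$sensitivity)
  graphics::plot(fpr[o], x$curve$sensitivity[o], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Operating point of an ROC analysis at a chosen cutoff
#'
#' Confusion-matrix metrics at an arbitrary cutoff (positive call =
#' score strictly above cutoff), with PPV/NPV at the sample's observed
#' prevalence.
#'
#' @param roc a `roc_result`.
#' @param cutoff score threshold (e.g. a candidate HU decision value).
#' @return one-row data.frame: cutoff, sensitivity, specificity, ppv, npv.
#' @export
operating_point <- function(roc, cutoff) {
  stopifnot(inherits(roc, "roc_result"))
  stop_if_not_scalar_number(cutoff, "cutoff")
  cbind(cutoff = cutoff, confusion_metrics(roc$score, roc$label, cutoff))
}

#' Paired left/right kidney comparison
#'
#' Paired t-test of right-minus-left differences for any per-kidney variable
#' (corrected CT number, fibrosis score), over animals with both sides known.
#'
#' @param records cohort data.frame with `animal`, `side` and the variable.
#' @param value column to compare; default `"corrected_hu"`.
#' @return list: `mean_difference` (right - left), `t`, `df`, `p_value`,
#'   `n_pairs`.
#' @export
paired_side_test <- function(records, value = "corrected_hu") {
  records <- as.data.frame(records)
  stopifnot(value %in% names(records))
  l <- records[records$side == "left", c("animal", value)]
  r <- records[records$side == "right", c("animal", value)]
  m <- merge(l, r, by = "animal", suffixes = c("_left", "_right"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need >= 2 animals with both sides for a paired test", call. = FALSE)
  tt <- stats::t.test(m[[paste0(value, "_right")]],
                      m[[paste0(value, "_left")]], paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, n_pairs = nrow(m))
}

#' Correlation between fibrosis measurement methods
#'
#' Estimates the correlation between two per-kidney measurements (e.g.
#' semiquantitative fibrosis score vs corrected CT number, or blue-area
#' fraction vs corrected CT number) while accounting for the repeated
#' measures by side within animal. Both variables are standardized and
#' stacked in a long layout with method as a fixed effect; random intercepts
#' for animal and for kidney-within-animal absorb the shared variation, and
#' the correlation estimate is the proportion of total variance shared by
#' the two methods on the same kidney,
#' `(var_animal + var_kidney) / (var_animal + var_kidney + var_resid)`.
#' When every animal contributes a single kidney the estimate reduces to the
#' Pearson correlation, which is what is returned in that case; the plain
#' Pearson estimate is always reported alongside.
#'
#' @param records cohort data.frame.
#' @param methods length-2 character vector of column names.
#' @param subset `"all"` or `"positive"` (kidneys with fibrosis score > 0).
#' @return list: `estimate`, `pearson`, `methods`, `subset`, `n_kidneys`,
#'   `n_animals`, `model` (description of the estimator used).
#' @export
method_correlation <- function(records,
                               methods = c("fibrosis_score", "corrected_hu"),
                               subset = c("all", "positive")) {
  subset <- match.arg(subset)
  records <- as.data.frame(records)
  stopifnot(length(methods) == 2L, all(methods %in% names(records)))
  if (subset == "positive")
    records <- records[records$fibrosis_score > 0, , drop = FALSE]
  keep <- stats::complete.cases(records[, c("animal", methods)])
  records <- records[keep, , drop = FALSE]
  n_animals <- length(unique(records$animal))
  if (n_animals < 3L)
    stop("need >= 3 animals for a correlation estimate", call. = FALSE)
  x <- records[[methods[1]]]; y <- records[[methods[2]]]
  pearson <- stats::cor(x, y)
  one_per_animal <- all(table(records$animal) == 1L)
  if (one_per_animal) {
    est <- pearson
    model <- "pearson (one kidney per animal)"
  } else {
    kid <- interaction(records$animal, records$side %||% seq_len(nrow(records)),
                       drop = TRUE)
    long <- data.frame(
      z = c(scale(x), scale(y)),
      method = rep(methods, each = nrow(records)),
      animal = rep(records$animal, 2L),
      kidney = rep(as.character(kid), 2L))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(z ~ method + (1 | animal) + (1 | kidney), data = long,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC(action = "ignore", tol = 1e-4)))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_animal <- vc$vcov[vc$grp == "animal"]
    v_kidney <- vc$vcov[vc$grp == "kidney"]
    v_resid <- vc$vcov[vc$grp == "Residual"]
    est <- (v_animal + v_kidney) / (v_animal + v_kidney + v_resid)
    model <- "random intercepts for animal and kidney, method fixed effect"
  }
  list(estimate = unname(est), pearson = unname(pearson), methods = methods,
       subset = subset, n_kidneys = nrow(records), n_animals = n_animals,
       model = model)
}

#' Exposure-group comparison of corrected CT numbers and fibrosis scores
#'
#' Aggregates kidneys to animal-level means first (kidneys within an animal
#' are not independent), then compares two exposure groups with a Welch
#' two-sample t-test.
#'
#' @param records cohort data.frame with `group` labels.
#' @param groups the two group labels to compare.
#' @param value column compared; default `"corrected_hu"`.
#' @return list: `means` (named per group), `difference`, `t`, `df`,
#'   `p_value`, `n` (animals per group).
#' @export
group_comparison <- function(records, groups = c("total_body", "chest_only"),
                             value = "corrected_hu") {
  records <- as.data.frame(records)
  stopifnot(length(groups) == 2L, value %in% names(records))
  per_animal <- stats::aggregate(records[[value]],
                                 by = list(animal = records$animal,
                                           group = records$group),
                                 FUN = mean, na.rm = TRUE)
  a <- per_animal$x[per_animal$group == groups[1]]
  b <- per_animal$x[per_animal$group == groups[2]]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
  list(means = stats::setNames(c(mean(a), mean(b)), groups),
       difference = mean(a) - mean(b),
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       n = stats::setNames(c(length(a), length(b)), groups))
}

#' Run the full diagnostic evaluation of a corrected cohort
#'
#' Convenience wrapper reproducing the study workflow on a cohort table:
#' size-corrects measured HU (unless already corrected), binarizes fibrosis
#' at mean score >= 1, fits the GEE logistic model, runs the ROC analysis
#' (with an operating table), paired side tests, group comparison, and the
#' method correlations for all kidneys and for fibrotic-only kidneys.
#'
#' @param records cohort data.frame.
#' @param calibration a `ct_calibration` (or numeric pooled A); omit when
#'   `corrected_hu` is already filled.
#' @param exclude_unknown_sides drop `unknown`-side rows (sensitivity
#'   analysis); default `FALSE`.
#' @param groups exposure groups compared; default
#'   `c("total_body", "chest_only")`.
#' @return list of class `fibrosis_report` with components `cohort`, `gee`,
#'   `roc`, `operating_table`, `paired`, `groups`, `correlations`,
#'   `prevalence`.
#' @export
evaluate_fibrosis_ct <- function(records, calibration = NULL,
                                 exclude_unknown_sides = FALSE,
                                 groups = c("total_body", "chest_only")) {
  records <- as.data.frame(records)
  if (!is.null(calibration))
    records <- correct_cohort(records, calibration)
  if (!"corrected_hu" %in% names(records) || all(is.na(records$corrected_hu)))
    stop("no corrected_hu available; supply a calibration", call. = FALSE)
  if (exclude_unknown_sides)
    records <- records[records$side != "unknown", , drop = FALSE]
  records$fibrotic <- binarize_fibrosis(records$fibrosis_score)
  gee <- gee_logistic(records)
  roc <- roc_analysis(records$corrected_hu, records$fibrotic)
  paired <- list(
    corrected_hu = tryCatch(paired_side_test(records, "corrected_hu"),
                            error = function(e) NULL),
    fibrosis_score = tryCatch(paired_side_test(records, "fibrosis_score"),
                              error = function(e) NULL))
  grp <- list(
    corrected_hu = tryCatch(group_comparison(records, groups, "corrected_hu"),
                            error = function(e) NULL),
    fibrosis_score = tryCatch(group_comparison(records, groups, "fibrosis_score"),
                              error = function(e) NULL))
  cors <- list(
    score_ct_all = method_correlation(records,
                                      c("fibrosis_score", "corrected_hu"),
                                      "all"),
    score_ct_positive = tryCatch(
      method_correlation(records, c("fibrosis_score", "corrected_hu"),
                         "positive"),
      error = function(e) NULL))
  if (!all(is.na(records$blue_fraction)))
    cors$blue_ct_all <- method_correlation(records,
                                           c("blue_fraction", "corrected_hu"),
                                           "all")
  structure(list(cohort = records, gee = gee, roc = roc,
                 operating_table = roc$curve, paired = paired, groups = grp,
                 correlations = cors, prevalence = roc$prevalence),
            class = "fibrosis_report")
}

#' @export
print.fibrosis_report <- function(x, ...) {
  cat("Fibrosis CT diagnostic report\n")
  cat(sprintf("  kidneys: %d; fibrosis prevalence: %.0f%%\n",
              nrow(x$cohort), 100 * x$prevalence))
  cat(sprintf("  AUC (corrected HU vs fibrosis): %.3f\n", x$roc$auc))
  if (!is.null(x$groups$corrected_hu)) {
    g <- x$groups$corrected_hu
    cat(sprintf("  group means (%s): %.1f vs %.1f HU, p = %.3g\n",
                paste(names(g$means), collapse = " vs "),
                g$means[1], g$means[2], g$p_value))
  }
  cat(sprintf("  r(score, corrected HU) = %.2f\n",
              x$correlations$score_ct_all$estimate))
  invisible(x)
}

#' Write a diagnostic report to JSON (plus an operating-point CSV)
#'
#' @param report a `fibrosis_report`.
#' @param path JSON output path; the operating table goes to the same stem
#'   with extension `.csv`.
#' @return `path`, invisibly.
#' @export
write_diagnostics_report <- function(report, path) {
  stopifnot(inherits(report, "fibrosis_report"))
  out <- list(
    gee = list(coefficients = as.list(report$gee$coefficients),
               robust_se = as.list(report$gee$robust_se),
               alpha = report$gee$alpha,
               separation = report$gee$separation),
    roc = list(auc = report$roc$auc, prevalence = report$prevalence),
    paired = report$paired,
    groups = report$groups,
    correlations = report$correlations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$operating_table,
                   sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
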