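test_that("GEE with singleton clusters equals independent logistic ML", {
  set.seed(14)
  n <- 120
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  d <- data.frame(animal = seq_len(n), corrected_hu = x, fibrotic = y)
  g <- gee_logistic(d)
  m <- stats::glm(fibrotic ~ corrected_hu, binomial, d)
  expect_lt(max(abs(g$coefficients - coef(m))), 1e-6)
  expect_equal(g$alpha, 0)
  expect_false(g$separation)
})

test_that("GEE robust intervals cover a null slope at the nominal rate", {
  cover <- vapply(1:150, function(s) {
    set.seed(3000 + s)
    n_animal <- 30
    u <- rnorm(n_animal)                 # cluster random effect
    d <- data.frame(
      animal = rep(seq_len(n_animal), each = 2),
      corrected_hu = rnorm(2 * n_animal, 50, 5))
    eta <- -0.2 + 1.2 * u[d$animal]      # outcome clustered, slope truly 0
    d$fibrotic <- rbinom(2 * n_animal, 1, plogis(eta))
    g <- tryCatch(suppressWarnings(gee_logistic(d)), error = function(e) NULL)
    if (is.null(g)) return(NA)
    b <- g$coefficients[2]; se <- g$robust_se[2]
    abs(b) <= 1.96 * se
  }, logical(1))
  expect_gte(mean(cover, na.rm = TRUE), 0.88)
  expect_lte(mean(cover, na.rm = TRUE), 0.99)
})

test_that("perfect separation is flagged on a degenerate toy input", {
  d <- data.frame(animal = c(1, 1, 2, 2), fibrotic = c(0, 0, 1, 1),
                  corrected_hu = c(1, 2, 5, 6))
  expect_warning(g <- gee_logistic(d), "separation")
  expect_true(g$separation)
  expect_error(gee_logistic(transform(d, fibrotic = 1)), "single class")
})

test_that("ROC on a fully separated toy gives AUC 1 and a perfect cutoff", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  op <- operating_point(r, 2.5)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals the Mann-Whitney concordance on arbitrary inputs", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    score <- sample(seq(40, 70, by = 0.5), n, replace = TRUE)  # many ties
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) next
    r <- roc_analysis(score, label)
    expect_equal(r$auc, concordance_auc(score, label))
  }
})

test_that("tied scores carry no discrimination and null AUC is 0.5", {
  expect_equal(roc_analysis(rep(3, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(22)
  r <- roc_analysis(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_equal(r$auc, 0.5, tolerance = 0.06)
})

test_that("ROC curve is monotone and cross-checked against pROC", {
  set.seed(25)
  score <- rnorm(60, 50, 6) + 4 * rbinom(60, 1, 0.6)
  label <- score + rnorm(60, 0, 4) > 52
  if (length(unique(label)) == 2) {
    r <- roc_analysis(score, label)
    fpr <- 1 - r$curve$specificity
    o <- order(fpr, r$curve$sensitivity)
    expect_true(all(diff(r$curve$sensitivity[o]) >= 0))
    auc_ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                              direction = "<")))
    expect_equal(r$auc, auc_ref, tolerance = 1e-10)
  }
})

test_that("operating points reproduce confusion-matrix arithmetic", {
  # TP=7 FP=1 FN=2 TN=5 at cutoff 0.5: scores above for 7 pos + 1 neg
  score <- c(rep(1, 7), rep(0, 2), rep(1, 1), rep(0, 5))
  label <- c(rep(1, 9), rep(0, 6))
  r <- roc_analysis(score, label)
  op <- operating_point(r, 0.5)
  expect_equal(op$sensitivity, 7 / 9)
  expect_equal(op$specificity, 5 / 6)
  expect_equal(op$ppv, 7 / 8)
  expect_equal(op$npv, 5 / 7)
  # extremes: everything called positive / negative
  lo <- operating_point(r, -1)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- operating_point(r, 2)
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
})

test_that("paired side test matches the closed-form t statistic", {
  rec <- data.frame(animal = rep(c("a", "b", "c"), each = 2),
                    side = rep(c("left", "right"), 3),
                    corrected_hu = c(10, 11, 20, 22, 30, 33))
  # right-minus-left differences 1, 2, 3: t = mean/ (sd/sqrt(3)) = 2*sqrt(3)
  p <- paired_side_test(rec)
  expect_equal(p$mean_difference, 2)
  expect_equal(p$t, 2 * sqrt(3))
  expect_equal(p$n_pairs, 3L)
  same <- rec; same$corrected_hu <- rep(c(5, 5, 7, 7, 9, 9))
  expect_equal(paired_side_test(same)$mean_difference, 0)
  expect_error(paired_side_test(rec[rec$side == "left", ]), ">= 2 animals")
})

test_that("paired test detects a one-SD systematic shift most of the time", {
  rej <- vapply(1:40, function(s) {
    set.seed(600 + s)
    base <- rnorm(10, 50, 3)
    rec <- data.frame(animal = rep(sprintf("a%d", 1:10), each = 2),
                      side = rep(c("left", "right"), 10),
                      corrected_hu = as.vector(rbind(base, base + rnorm(10, 2, 2))))
    paired_side_test(rec)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("method correlation reduces to Pearson with one kidney per animal", {
  set.seed(31)
  n <- 40
  sc <- runif(n, 0, 4)
  hu <- 46 + 5 * sc + rnorm(n, 0, 3)
  rec <- data.frame(animal = sprintf("a%02d", 1:n), side = "left",
                    fibrosis_score = sc, corrected_hu = hu)
  mc <- method_correlation(rec)
  expect_equal(mc$estimate, cor(sc, hu))
  expect_match(mc$model, "pearson")
  # exactly linear methods correlate perfectly
  lin <- rec; lin$corrected_hu <- 3 * lin$fibrosis_score + 2
  expect_equal(method_correlation(lin)$estimate, 1)
  expect_error(method_correlation(rec[1:2, ]), ">= 3 animals")
})

test_that("mixed-model correlation tracks truth with paired kidneys", {
  set.seed(33)
  n <- 60
  sc <- pmax(0, pmin(4, rep(runif(n, 0, 4), each = 2) + rnorm(2 * n, 0, 0.2)))
  hu <- 46 + 5 * sc + rnorm(2 * n, 0, 2)
  rec <- data.frame(animal = rep(sprintf("a%02d", 1:n), each = 2),
                    side = rep(c("left", "right"), n),
                    fibrosis_score = sc, corrected_hu = hu)
  mc <- method_correlation(rec)
  expect_gt(mc$estimate, 0.8)
  expect_lte(mc$estimate, 1)
  # independent methods: Pearson near zero; the variance-ratio estimate is
  # non-negative by construction, so it only approaches zero from above
  ind <- rec; ind$corrected_hu <- rnorm(2 * n, 50, 5)
  mci <- method_correlation(ind)
  expect_lt(abs(mci$pearson), 0.1)
  expect_lt(mci$estimate, 0.2)
})

test_that("group comparison aggregates to animals before testing", {
  rec <- data.frame(animal = rep(c("a", "b", "c", "d"), each = 2),
                    side = rep(c("left", "right"), 4),
                    group = rep(c("total_body", "chest_only"), each = 4),
                    corrected_hu = c(50, 50, 52, 52, 60, 60, 62, 62))
  g <- group_comparison(rec)
  expect_equal(unname(g$means), c(51, 61))
  expect_equal(unname(g$n), c(2L, 2L))
  same <- rec; same$corrected_hu <- 50
  expect_equal(group_comparison(same)$difference, 0)
  expect_error(group_comparison(rec[rec$group == "total_body", ]), "non-empty")
})

test_that("a 6 HU group shift at SD 3 is usually detected with 10 per arm", {
  rej <- vapply(1:40, function(s) {
    set.seed(700 + s)
    rec <- data.frame(animal = sprintf("a%02d", 1:20), side = "left",
                      group = rep(c("total_body", "chest_only"), each = 10),
                      corrected_hu = c(rnorm(10, 56, 3), rnorm(10, 50, 3)))
    group_comparison(rec)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("the full evaluation wrapper assembles a coherent report", {
  cal <- ct_calibration(simulate_phantom_observations(seed = 41))
  coh <- simulate_cohort(seed = 41)
  rep <- suppressWarnings(evaluate_fibrosis_ct(coh, cal))
  expect_s3_class(rep, "fibrosis_report")
  expect_true(rep$roc$auc >= 0 && rep$roc$auc <= 1)
  expect_equal(rep$prevalence, mean(binarize_fibrosis(coh$fibrosis_score)))
  expect_true(all(c("score_ct_all", "score_ct_positive", "blue_ct_all") %in%
                    names(rep$correlations)))
  f <- withr::local_tempfile(fileext = ".json")
  write_diagnostics_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$roc$auc, rep$roc$auc)
  expect_true(file.exists(sub("\\.json$", ".csv", f)))
  # the unknown-side exclusion flag runs the same pipeline on the subset
  rep2 <- suppressWarnings(evaluate_fibrosis_ct(coh, cal,
                                                exclude_unknown_sides = TRUE))
  expect_s3_class(rep2, "fibrosis_report")
})
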