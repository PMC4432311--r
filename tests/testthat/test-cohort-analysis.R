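test_that("aggregate_patient_g: mean and median paths", {
  expect_equal(aggregate_patient_g(0.92), 0.92)
  expect_equal(aggregate_patient_g(c(0.90, 0.92, 0.94)), 0.92)
  expect_equal(aggregate_patient_g(c(0.90, 0.92, 0.94, 0.99), "median"),
               0.93)
  expect_data_error(aggregate_patient_g(numeric(0)))
})

test_that("g_histogram: half-open binning and count conservation", {
  h <- g_histogram(c(0.905, 0.915, 0.915), 0.01)
  expect_equal(h$count[h$bin_left == 0.90], 1L)
  expect_equal(h$count[abs(h$bin_left - 0.91) < 1e-9], 2L)
  expect_equal(sum(h$count), 3L)
  expect_equal(nrow(g_histogram(numeric(0))), 0L)
  # boundary value lands in the right-hand bin (half-open convention)
  hb <- g_histogram(c(0.91), 0.01)
  expect_equal(hb$bin_left, 0.91)
  set.seed(2)
  v <- runif(500, 0.85, 0.99)
  expect_equal(sum(g_histogram(v)$count), 500L)
  expect_parameter_error(g_histogram(c(0.5), bin_width = 0))
  expect_data_error(g_histogram(c(1.2)))
})

test_that("welch_t_from_summary: identical groups, printed-summary case, raw consistency", {
  w0 <- welch_t_from_summary(0.5, 0.1, 20, 0.5, 0.1, 20)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # reference group summaries: p of order 1e-5 (printed 7.66e-6)
  w <- welch_t_from_summary(0.911, 0.039, 92, 0.935, 0.031, 89)
  expect_lt(w$p, 2e-5)
  expect_gt(w$p, 2e-6)

  set.seed(5)
  x <- rnorm(40, 1, 0.5); y <- rnorm(35, 1.2, 0.4)
  wr <- welch_t_test(x, y)
  ws <- welch_t_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 35)
  expect_identical(wr, ws)
  # and both agree with stats::t.test
  tt <- t.test(x, y)
  expect_equal(wr$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(wr$p, tt$p.value, tolerance = 1e-12)

  expect_data_error(welch_t_test(c(1, 1, 1), c(1, 2, 3)))
  expect_parameter_error(welch_t_from_summary(1, 0, 10, 1, 1, 10))
})

test_that("roc_auc matches brute-force pair counting (including frozen toy case)", {
  # toy case: labels {R, R, N, N}, g {0.90, 0.94, 0.93, 0.95}
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  g <- c(0.90, 0.94, 0.93, 0.95)
  expect_equal(brute_force_auc_low_positive(lab, g), 0.75)
  expect_equal(roc_auc(lab, g)$auc, 0.75)

  # perfect separation
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(0.1, 0.2, 0.9))$auc, 1)

  # property: rank estimator == exhaustive enumeration, with ties
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    g <- round(runif(n, 0.85, 0.99), sample(2:3, 1))  # rounding makes ties
    expect_equal(roc_auc(lab, g)$auc, brute_force_auc_low_positive(lab, g))
  }

  # complementarity on tie-free data
  set.seed(15)
  lab <- c(rep(TRUE, 30), rep(FALSE, 30)); g <- runif(60)
  a1 <- roc_auc(lab, g, direction = "lower_score_positive")$auc
  a2 <- roc_auc(lab, g, direction = "higher_score_positive")$auc
  expect_equal(a1 + a2, 1)

  expect_stat_error(roc_auc(rep(TRUE, 5), runif(5)))
})

test_that("roc_auc converges to 0.5 for label-independent scores", {
  set.seed(16)
  lab <- rep(c(TRUE, FALSE), 2000)
  expect_equal(roc_auc(lab, runif(4000))$auc, 0.5, tolerance = 0.03)
})

test_that("roc_auc bootstrap CI is seeded and brackets the estimate", {
  set.seed(17)
  lab <- rep(c(TRUE, FALSE), each = 40)
  g <- c(rnorm(40, 0.91, 0.04), rnorm(40, 0.935, 0.03))
  r1 <- roc_auc(lab, g, n_boot = 300, seed = 5)
  r2 <- roc_auc(lab, g, n_boot = 300, seed = 5)
  expect_identical(r1, r2)
  expect_lt(r1$ci_lower, r1$auc)
  expect_gt(r1$ci_upper, r1$auc)
})

test_that("sens_spec_at_threshold: extremes, strictness and counting", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  g <- c(0.90, 0.94, 0.93, 0.95)
  lo <- sens_spec_at_threshold(lab, g, threshold = 0.5)
  expect_equal(c(lo$sensitivity, lo$specificity), c(0, 1))
  hi <- sens_spec_at_threshold(lab, g, threshold = 1.5)
  expect_equal(c(hi$sensitivity, hi$specificity), c(1, 0))
  mid <- sens_spec_at_threshold(lab, g, threshold = 0.938)
  expect_equal(mid$sensitivity, 0.5)   # only 0.90 < 0.938 among positives
  expect_equal(mid$specificity, 0.5)   # 0.95 >= 0.938 among negatives
  # strict inequality at the boundary
  at <- sens_spec_at_threshold(lab, g, threshold = 0.94)
  expect_equal(at$sensitivity, 0.5)    # 0.94 is NOT below 0.94
})

test_that("youden_threshold matches exhaustive search and is shift-equivariant", {
  set.seed(18)
  for (i in 1:10) {
    lab <- c(TRUE, FALSE, runif(18) < 0.5)
    g <- runif(20, 0.85, 0.99)
    t_pkg <- youden_threshold(lab, g)
    bf <- brute_force_youden(lab, g)
    ss <- sens_spec_at_threshold(lab, g, t_pkg)
    expect_equal(ss$sensitivity + ss$specificity - 1, bf$j,
                 tolerance = 1e-12)
  }
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  g <- c(0.90, 0.91, 0.95, 0.96)
  expect_equal(youden_threshold(lab, g + 0.02),
               youden_threshold(lab, g) + 0.02, tolerance = 1e-9)
})

test_that("pearson_r: exact lines and direct-formula agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 3), -1)
  y <- c(2.0, 1.0, 4.0, 3.0, 6.0)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_direct)
  expect_stat_error(pearson_r(x, rep(1, 5)))
  expect_data_error(pearson_r(1:2, 1:2))
})

test_that("capra_s_score: floor, PSA component, ceiling and missing fields", {
  best <- capra_s_score(4, 3, 3, FALSE, FALSE, FALSE, FALSE)
  expect_equal(best$total, 0)

  high_psa <- capra_s_score(25, 3, 3, FALSE, FALSE, FALSE, FALSE)
  expect_equal(unname(high_psa$components["psa"]), 3)

  worst <- capra_s_score(25, 4, 5, TRUE, TRUE, TRUE, TRUE)
  expect_equal(worst$total, 12)
  expect_equal(worst$total, sum(worst$components))

  # component boundaries: 6 / 10 / 20 are inclusive on the left bracket
  expect_equal(unname(capra_s_score(6, 3, 3, FALSE, FALSE, FALSE,
                                    FALSE)$components["psa"]), 0)
  expect_equal(unname(capra_s_score(6.01, 3, 3, FALSE, FALSE, FALSE,
                                    FALSE)$components["psa"]), 1)
  expect_equal(unname(capra_s_score(10.5, 3, 3, FALSE, FALSE, FALSE,
                                    FALSE)$components["psa"]), 2)

  # Gleason branches
  gl <- function(p, s) unname(capra_s_score(5, p, s, FALSE, FALSE, FALSE,
                                            FALSE)$components["gleason"])
  expect_equal(gl(3, 4), 1)
  expect_equal(gl(4, 3), 2)
  expect_equal(gl(4, 4), 3)

  err <- tryCatch(capra_s_score(NA, 3, 3, FALSE, FALSE, FALSE, FALSE),
                  error = function(e) e)
  expect_s3_class(err, "qpianiso_error_unscorable")
  expect_true("psa_ng_ml" %in% err$missing_fields)
})

test_that("capra_s totals stay in [0, 12] and equal their component sums", {
  set.seed(20)
  for (i in 1:50) {
    sc <- capra_s_score(exp(rnorm(1, 2, 1)), sample(3:5, 1), sample(3:5, 1),
                        runif(1) < 0.5, runif(1) < 0.5, runif(1) < 0.5,
                        runif(1) < 0.5)
    expect_gte(sc$total, 0); expect_lte(sc$total, 12)
    expect_equal(sc$total, sum(sc$components))
  }
})

test_that("classify_recurrence implements both clauses of the rule", {
  expect_true(classify_recurrence(c(0.1, 0.5)))                 # > 0.4
  expect_true(classify_recurrence(c(0.1, 0.25, 0.30, 0.35)))    # rising run
  expect_false(classify_recurrence(c(0.1, 0.25, 0.20, 0.10)))
  expect_false(classify_recurrence(c(0.1, 0.1, 0.1)))
  expect_false(classify_recurrence(c(0.25, 0.30)))   # only one later rise
  # non-consecutive rising run above the trigger value still counts
  expect_true(classify_recurrence(c(0.25, 0.1, 0.3, 0.1, 0.35)))
  expect_data_error(classify_recurrence(c(0.1, -0.2)))
  expect_data_error(classify_recurrence(numeric(0)))
})

test_that("classify_recurrence monotone sub-properties hold", {
  # raising any single value above the single-test threshold forces TRUE
  set.seed(21)
  for (i in 1:20) {
    v <- runif(6, 0, 0.38)
    j <- sample(6, 1)
    v2 <- v; v2[j] <- 0.45
    expect_true(classify_recurrence(v2))
  }
  # appending ever-larger values never flips TRUE -> FALSE
  v <- c(0.1, 0.25, 0.30, 0.35)
  expect_true(classify_recurrence(c(v, 0.36, 0.39)))
})

test_that("psa_stratified_comparison: boundaries, undefined strata and construction", {
  pts <- data.frame(
    group = rep(c("recurrent", "non-recurrent"), each = 4),
    psa_ng_ml = c(6.0, 6.01, 15, 25, 5, 8, 12, 30),
    g_mean = c(0.90, 0.91, 0.92, 0.93, 0.94, 0.95, 0.96, 0.97),
    capra_s = c(5, 6, 7, 8, 2, 3, 4, 5))
  tab <- psa_stratified_comparison(pts)
  expect_equal(nrow(tab), 4L)
  # PSA = 6.0 in stratum 1, 6.01 in stratum 2
  expect_equal(tab$n_rec, rep(1L, 4))
  expect_equal(tab$n_nonrec, rep(1L, 4))

  one <- data.frame(group = c("recurrent", "non-recurrent"),
                    psa_ng_ml = c(3, 4), g_mean = c(0.9, 0.95),
                    capra_s = c(6, 2))
  t1 <- psa_stratified_comparison(one)
  expect_false(is.na(t1$auc_g[1]))
  expect_true(all(is.na(t1$auc_g[2:4])))  # empty strata undefined

  # group-dependent g, PSA independent: auc_g similar across strata
  spec <- cohort_spec(n_recurrent = 600, n_nonrecurrent = 600,
                      n_unscorable = 0, seed = 77)
  co <- gen_cohort(spec)
  p <- co$patients
  p$capra_s <- 5
  tab2 <- psa_stratified_comparison(p)
  aucs <- tab2$auc_g[tab2$n_rec >= 30 & tab2$n_nonrec >= 30]
  expect_gt(length(aucs), 1)
  expect_lt(diff(range(aucs)), 0.15)
})
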