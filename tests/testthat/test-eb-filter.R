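test_that("fitted site error model matches a grid-search likelihood oracle", {
  alt <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  depth <- rep(500, 10)
  m <- fit_site_error_model(alt, depth)
  expect_equal(predict(m), 0.001, tolerance = 0.25)
  oracle <- bb_grid_mle(alt, depth)
  ll_fit <- sum(lchoose(depth, alt) + lbeta(alt + m$alpha, depth - alt + m$beta) -
                  lbeta(m$alpha, m$beta))
  expect_gte(ll_fit, oracle$loglik - 1e-3)
})

test_that("all-zero panels fall back to the floor model", {
  m <- fit_site_error_model(rep(0L, 21), rep(600L, 21), pseudocount = 0.5)
  expect_true(m$floor)
  expect_gt(predict(m), 0)
  expect_equal(predict(m), 0.5 / 600.5, tolerance = 1e-12)
  expect_error(fit_site_error_model(1, 100), "insufficient panel")
  expect_error(fit_site_error_model(c(5, 1), c(4, 100)), "0 <= alt <= depth")
})

test_that("beta-binomial parameter recovery: mean within 50% over seeds", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    p <- rbeta(21, 2, 1998)
    alt <- rbinom(21, 600, p)
    m <- fit_site_error_model(alt, rep(600L, 21))
    predict(m)
  }, numeric(1))
  truth <- 2 / 2000
  # the MLE mean tracks the pooled alt fraction, whose sampling sd at
  # 21 x 600 reads is ~30% of the truth; most seeds land within 50% and
  # the average over seeds is unbiased well inside that band
  expect_gt(mean(abs(errs - truth) < 0.5 * truth), 0.75)
  expect_lt(abs(mean(errs) - truth), 0.5 * truth)
})

test_that("EB score equals the direct tail-summation oracle", {
  m <- new_beta_binom_model(1, 999)
  expect_identical(compute_eb_score(0, 100, m), 0)
  got <- compute_eb_score(5, 100, m)
  expect_equal(got, bb_tail_oracle_log10(5, 100, 1, 999), tolerance = 1e-12)
  # monotone nondecreasing in alt count at fixed depth
  s <- compute_eb_score(0:100, 100, m)
  expect_true(all(diff(s) >= 0))
  expect_error(compute_eb_score(101, 100, m), "alt_count")
})

test_that("ROC calibration finds the Youden-optimal cutoff", {
  cal <- calibrate_cutoff(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cal$auc, 1.0)
  expect_equal(cal$youden, 1.0)
  expect_gt(cal$cutoff, 3)
  expect_lte(cal$cutoff, 5)
  expect_error(calibrate_cutoff(1:3, c(TRUE, TRUE, TRUE)), "both true and false")

  # random labels: AUC near 0.5; cutoff attains the exhaustive-scan maximum
  set.seed(42)
  sc <- runif(1000); lab <- runif(1000) < 0.5
  cal2 <- calibrate_cutoff(sc, lab)
  expect_lt(abs(cal2$auc - 0.5), 0.05)
  scan <- vapply(sort(unique(sc)), function(t)
    mean(sc[lab] > t) + mean(sc[!lab] <= t) - 1, numeric(1))
  expect_equal(cal2$youden, max(scan), tolerance = 1e-12)
})

test_that("calibration cross-checks against pROC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- c(rnorm(60, 4), rnorm(60, 1)); lab <- rep(c(TRUE, FALSE), each = 60)
  cal <- calibrate_cutoff(sc, lab)
  roc <- pROC::roc(response = lab, predictor = sc, quiet = TRUE,
                   direction = "<")
  expect_equal(cal$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-9)
  best <- pROC::coords(roc, "best", best.method = "youden")
  expect_equal(cal$youden,
               best$sensitivity[1] + best$specificity[1] - 1, tolerance = 1e-9)
})

test_that("post-filter stack applies the documented reason codes", {
  calls <- data.frame(
    depth = c(30, 500, 500, 500, 500, 500, 500),
    alt_count = c(5, 225, 10, 10, 10, 10, 10),
    eb_score = c(5, 5, 5, 2.396, 2.40, 5, 5),
    read_position_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    mappability_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  res <- apply_post_filters(calls, "matched")
  expect_equal(res$reason_codes[1], "min_depth")
  expect_equal(res$reason_codes[2], "germline_vaf")   # vaf 0.45
  expect_equal(res$filter_status[3], "PASS")
  expect_equal(res$reason_codes[4], "eb_score")       # score == cutoff fails
  expect_equal(res$filter_status[5], "PASS")          # 2.40 passes
  expect_equal(res$reason_codes[6], "read_position")
  expect_equal(res$reason_codes[7], "mappability")
  # vaf 0.399 passes the germline rule
  ok <- apply_post_filters(data.frame(depth = 1000, alt_count = 399,
                                      eb_score = 5), "matched")
  expect_equal(ok$filter_status, "PASS")
})

test_that("brain-only mode tightens depth and VAF bounds", {
  calls <- data.frame(depth = c(90, 200, 200), alt_count = c(5, 50, 5),
                      eb_score = 5)
  res <- apply_post_filters(calls, "brain_only")
  expect_equal(res$reason_codes[1], "min_depth")      # 90 < 100
  expect_equal(res$reason_codes[2], "germline_vaf")   # vaf 0.25 >= 0.20
  expect_equal(res$filter_status[3], "PASS")
  expect_error(apply_post_filters(calls, "nonsense"))
})

test_that("min_support requires 3 alt reads and >50% retention", {
  calls <- data.frame(depth = 500, alt_count = c(2, 3, 4, 4),
                      eb_score = 5, raw_alt_count = c(2, 3, 8, 7))
  res <- apply_post_filters(calls, "matched")
  expect_equal(res$reason_codes[1], "min_support")    # < 3 alt reads
  expect_equal(res$filter_status[2], "PASS")
  expect_equal(res$reason_codes[3], "min_support")    # 4/8 = 50% retained
  expect_equal(res$filter_status[4], "PASS")          # 4/7 > 50%
})

test_that("post-filtering is idempotent", {
  set.seed(11)
  calls <- data.frame(depth = rpois(50, 500), alt_count = rpois(50, 8),
                      eb_score = runif(50, 0, 6))
  once <- apply_post_filters(calls, "matched")
  twice <- apply_post_filters(once, "matched")
  expect_equal(once$filter_status, twice$filter_status)
  expect_equal(once$reason_codes, twice$reason_codes)
})
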