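# Empirical-Bayes beta-binomial error model and post-filter stack.
#
# Sequencing/alignment error at a site is modelled as a beta-binomial: the
# per-sample error VAF is Beta(alpha, beta) and alt counts are binomial given
# depth. (alpha, beta) are fitted per site by maximum likelihood on a panel
# of normals; a case sample's evidence is the -log10 upper-tail probability
# of its alt count under that model (the EB score). Strand-pooled counts are
# used throughout: strand is not carried in the count tables, so the
# strand-split variant of the score is deliberately out of scope.

# log pmf of BetaBinomial(size, alpha, beta) at k (vectorised over k)
dbetabinom_log <- function(k, size, alpha, beta) {
  lchoose(size, k) + lbeta(k + alpha, size - k + beta) - lbeta(alpha, beta)
}

bb_negloglik <- function(par, alt, depth) {
  alpha <- exp(par[1]); beta <- exp(par[2])
  if (!is.finite(alpha) || !is.finite(beta)) return(1e10)
  -sum(dbetabinom_log(alt, depth, alpha, beta))
}

#' Fit a per-site beta-binomial error model to a panel of normals
#'
#' Maximises the beta-binomial likelihood of the panel alt counts in
#' log-parameter space (Nelder-Mead, method-of-moments start). A panel with
#' no alt reads at all carries no information about overdispersion; it yields
#' the configured floor model `alpha = pseudocount`, `beta = mean(depth)`,
#' whose mean error rate is `pseudocount / (pseudocount + mean(depth))`.
#'
#' @param alt_counts,depths integer vectors over panel samples (same length)
#' @param pseudocount floor-model pseudocount, default 0.5
#' @return object of class `beta_binom_model` with elements `alpha`, `beta`,
#'   `n_panel`, `pooled_error` (sum(alt)/sum(depth)), `loglik`, `floor`
#' @export
#' @examples
#' m <- fit_site_error_model(c(1, 1, 0, 0, 2), c(500, 480, 520, 501, 499))
#' coef(m)
fit_site_error_model <- function(alt_counts, depths, pseudocount = 0.5) {
  keep <- depths > 0
  alt <- alt_counts[keep]; depth <- depths[keep]
  if (length(alt) < 2L)
    stop("insufficient panel: need >= 2 panel samples with depth > 0",
         call. = FALSE)
  if (any(alt > depth) || any(alt < 0))
    stop("alt counts must satisfy 0 <= alt <= depth", call. = FALSE)
  pooled <- sum(alt) / sum(depth)

  if (all(alt == 0L)) {
    alpha <- pseudocount
    beta <- mean(depth)
    return(new_bb_model(alpha, beta, length(alt), pooled,
                        sum(dbetabinom_log(alt, depth, alpha, beta)),
                        floor = TRUE))
  }

  # method-of-moments start: match pooled mean, modest overdispersion
  p0 <- max(pooled, 1e-8)
  frac <- alt / depth
  v <- stats::var(frac)
  m <- mean(frac)
  # solve Beta moments if the sample variance exceeds the binomial floor
  s0 <- if (is.finite(v) && v > m * (1 - m) / mean(depth) && v < m * (1 - m)) {
    m * (1 - m) / v - 1
  } else 100 / p0  # near-binomial start
  start <- log(c(max(p0 * s0, 1e-6), max((1 - p0) * s0, 1e-3)))
  fit <- stats::optim(start, bb_negloglik, alt = alt, depth = depth,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
  new_bb_model(alpha, beta, length(alt), pooled, -fit$value, floor = FALSE)
}

new_bb_model <- function(alpha, beta, n_panel, pooled_error, loglik, floor) {
  structure(list(alpha = alpha, beta = beta, n_panel = n_panel,
                 pooled_error = pooled_error, loglik = loglik, floor = floor),
            class = "beta_binom_model")
}

#' @export
print.beta_binom_model <- function(x, ...) {
  cat("Beta-binomial site error model",
      if (x$floor) "(floor model: all-zero panel)" else "", "\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g  (mean error %.3g)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  cat(sprintf("  panel: %d samples, pooled alt fraction %.3g\n",
              x$n_panel, x$pooled_error))
  invisible(x)
}

#' @export
coef.beta_binom_model <- function(object, ...)
  c(alpha = object$alpha, beta = object$beta)

#' Expected error VAF under a fitted site error model
#' @param object a `beta_binom_model`
#' @param ... unused
#' @return alpha / (alpha + beta)
#' @export
predict.beta_binom_model <- function(object, ...)
  object$alpha / (object$alpha + object$beta)

#' Simulate panel-like alt counts from a fitted site error model
#' @param object a `beta_binom_model`
#' @param nsim number of samples
#' @param seed optional seed
#' @param depth depth per simulated sample (recycled)
#' @param ... unused
#' @return integer vector of simulated alt counts
#' @export
simulate.beta_binom_model <- function(object, nsim = 1, seed = NULL,
                                      depth = 500, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::rbeta(nsim, object$alpha, object$beta)
  stats::rbinom(nsim, rep_len(depth, nsim), p)
}

#' Empirical Bayes score of an alt count under a site error model
#'
#' Score = -log10 P(X >= alt_count) with X ~ BetaBinomial(depth, alpha,
#' beta). Computed in log space via a reverse-cumulative log-sum-exp over the
#' per-count log pmf, so depths of several hundred do not overflow.
#' Vectorised over `alt_count` at fixed depth and model.
#'
#' @param alt_count integer alt counts (0 <= alt_count <= depth)
#' @param depth total depth at the site
#' @param model a `beta_binom_model`
#' @return numeric scores (>= 0; 0 when alt_count = 0 since the tail is 1)
#' @export
#' @examples
#' m <- new_beta_binom_model(1, 999)
#' compute_eb_score(5, 100, m)
compute_eb_score <- function(alt_count, depth, model) {
  stopifnot(inherits(model, "beta_binom_model"), length(depth) == 1L)
  if (any(alt_count > depth) || any(alt_count < 0))
    stop("alt_count must satisfy 0 <= alt_count <= depth", call. = FALSE)
  lp <- dbetabinom_log(0:depth, depth, model$alpha, model$beta)
  ltail <- rev_cum_logsumexp(lp)           # ltail[k+1] = log P(X >= k)
  ltail[1L] <- 0                           # P(X >= 0) is exactly 1
  ltail <- pmin(ltail, 0)                  # clamp rounding above log(1)
  score <- -ltail[alt_count + 1L] / log(10)
  pmax(score, 0)
}

#' Construct a beta-binomial error model from known parameters
#' @param alpha,beta positive shape parameters
#' @param n_panel,pooled_error optional bookkeeping fields
#' @return a `beta_binom_model`
#' @export
new_beta_binom_model <- function(alpha, beta, n_panel = NA_integer_,
                                 pooled_error = alpha / (alpha + beta)) {
  stopifnot(alpha > 0, beta > 0)
  new_bb_model(alpha, beta, n_panel, pooled_error, NA_real_, floor = FALSE)
}

#' Calibrate the EB score cutoff on labelled calls
#'
#' Builds the ROC over candidate thresholds (midpoints between consecutive
#' distinct scores, plus -Inf/+Inf) with the rule "score > threshold is
#' called positive", and returns the smallest threshold maximising
#' sensitivity + specificity (the Youden-optimal point). AUC is the
#' trapezoid area under the (FPR, TPR) curve.
#'
#' @param scores numeric EB scores
#' @param labels logical; TRUE for validated/true calls
#' @return object of class `eb_calibration`: list with `roc` (data.frame
#'   threshold, sensitivity, specificity), `auc`, `cutoff`, `youden`
#' @export
calibrate_cutoff <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("calibration requires both true and false labels", call. = FALSE)
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] <= t), numeric(1))
  youden <- sens + spec - 1
  best <- max(youden)
  cutoff <- min(thr[youden >= best - 1e-12])
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(list(
    roc = data.frame(threshold = thr, sensitivity = sens, specificity = spec),
    auc = auc, cutoff = cutoff, youden = best,
    n_true = sum(labels), n_false = sum(!labels)),
    class = "eb_calibration")
}

#' @export
print.eb_calibration <- function(x, ...) {
  cat("EB score calibration:", x$n_true, "true /", x$n_false, "false calls\n")
  cat(sprintf("  AUC %.3f; cutoff %.4g (Youden %.3f)\n",
              x$auc, x$cutoff, x$youden))
  invisible(x)
}

#' @export
plot.eb_calibration <- function(x, ...) {
  plot(1 - x$roc$specificity, x$roc$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Apply the reason-coded somatic post-filter stack
#'
#' Matched mode rejects calls for any of: depth < 35 (`min_depth`);
#' VAF >= 0.40, suspected germline (`germline_vaf`); EB score <= cutoff
#' (`eb_score`); all supporting reads at read ends (`read_position`);
#' fewer than 3 alt reads or <= 50% of raw alt reads surviving MQ20/BQ30
#' (`min_support`); poor mappability (`mappability`). Brain-only mode
#' tightens depth (< 100) and VAF (>= 0.20). Rules are independent, so the
#' operation is idempotent and order-free; every failing rule is recorded.
#'
#' @param calls data.frame with columns depth, alt_count, eb_score and
#'   optionally vaf (computed as alt_count/depth when absent),
#'   read_position_flag, mappability_flag, raw_alt_count
#' @param mode "matched" or "brain_only"
#' @param eb_cutoff score cutoff; calls with score strictly greater pass.
#'   Default 2.396, the calibrated operating point used when no calibration
#'   set is supplied.
#' @return `calls` with added/updated columns vaf, filter_status
#'   ("PASS"/"FAIL") and reason_codes (comma-joined string, "" for PASS)
#' @export
apply_post_filters <- function(calls, mode = c("matched", "brain_only"),
                               eb_cutoff = 2.396) {
  mode <- match.arg(mode)
  if (eb_cutoff < 0) stop("eb_cutoff must be nonnegative", call. = FALSE)
  stopifnot(all(c("depth", "alt_count", "eb_score") %in% names(calls)))
  n <- nrow(calls)
  vaf <- calls$vaf %||% NULL
  if (is.null(vaf)) vaf <- ifelse(calls$depth > 0, calls$alt_count / calls$depth, 0)
  min_depth <- if (mode == "matched") 35 else 100
  max_vaf <- if (mode == "matched") 0.40 else 0.20

  reasons <- vector("list", n)
  add <- function(bad, code) {
    bad[is.na(bad)] <- FALSE
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(calls$depth < min_depth, "min_depth")
  add(vaf >= max_vaf, "germline_vaf")
  add(calls$eb_score <= eb_cutoff, "eb_score")
  add(as.logical(calls$read_position_flag %||% rep(FALSE, n)), "read_position")
  raw <- calls$raw_alt_count %||% calls$alt_count
  add(calls$alt_count < 3 | (calls$alt_count / pmax(raw, 1)) <= 0.5,
      "min_support")
  add(as.logical(calls$mappability_flag %||% rep(FALSE, n)), "mappability")

  codes <- vapply(reasons, function(r) paste(unique(r), collapse = ","),
                  character(1))
  calls$vaf <- vaf
  calls$filter_status <- ifelse(codes == "", "PASS", "FAIL")
  calls$reason_codes <- codes
  calls
}
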