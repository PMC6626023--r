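# Amplicon validation against platform background error.
#
# A candidate that was re-sequenced on a deep amplicon platform counts as
# validated when its alt reads are statistically incompatible with the
# platform's per-substitution background error rate: a one-sided exact
# binomial upper-tail test at the class-specific rate.

#' Exact binomial test of amplicon counts against background error
#'
#' @param alt_count,depth amplicon alt reads and total depth (depth > 0)
#' @param ref,alt the substitution (any strand; normalised to the
#'   pyrimidine-centred class before lookup), or pass `class` directly
#' @param class substitution class like "C>T"; overrides ref/alt
#' @param table named background VAFs over the six classes; default
#'   [default_background_errors()]
#' @param alpha one-sided significance level, default 0.05
#' @return list: p_value = P(X >= alt_count | Binomial(depth, rate)),
#'   validated = p_value < alpha, class, rate
#' @export
#' @examples
#' background_error_test(50, 10000, class = "T>G")
background_error_test <- function(alt_count, depth, ref = NULL, alt = NULL,
                                  class = NULL,
                                  table = default_background_errors(),
                                  alpha = 0.05) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (alt_count < 0 || alt_count > depth)
    stop("alt_count must satisfy 0 <= alt_count <= depth", call. = FALSE)
  if (is.null(class)) {
    if (is.null(ref) || is.null(alt))
      stop("supply either class or ref/alt", call. = FALSE)
    class <- normalize_substitution(ref, alt)$class
  }
  if (!class %in% names(table))
    stop("substitution class '", class, "' missing from background table",
         call. = FALSE)
  rate <- table[[class]]
  # one-sided exact binomial upper tail; P(X >= a) = 1 - P(X <= a-1)
  p <- stats::pbinom(alt_count - 1, depth, rate, lower.tail = FALSE)
  list(p_value = p, validated = p < alpha, class = class, rate = rate)
}

#' Summarise amplicon validation records
#'
#' @param records data.frame with logical column `validated` and, for the
#'   VAF concordance, numeric columns `wes_vaf` and `amplicon_vaf`
#' @return list: n_tested, n_validated, precision (percent, 1 decimal),
#'   pearson_r (correlation of WES vs amplicon VAFs over validated records;
#'   NA with fewer than 3 validated records)
#' @export
#' @examples
#' rec <- data.frame(validated = rep(c(TRUE, FALSE), c(67, 17)),
#'                   wes_vaf = runif(84, 0, .1))
#' rec$amplicon_vaf <- rec$wes_vaf
#' validation_summary(rec)$precision  # 79.8
validation_summary <- function(records) {
  if (!is.data.frame(records) || !nrow(records))
    stop("records must be a nonempty data.frame", call. = FALSE)
  stopifnot("validated" %in% names(records))
  n <- nrow(records)
  v <- sum(records$validated)
  r <- NA_real_
  if (v >= 3 && all(c("wes_vaf", "amplicon_vaf") %in% names(records))) {
    ok <- records$validated
    r <- stats::cor(records$wes_vaf[ok], records$amplicon_vaf[ok])
  }
  list(n_tested = n, n_validated = v,
       precision = round(100 * v / n, 1), pearson_r = r)
}
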