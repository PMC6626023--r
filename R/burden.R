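# Mutation burden summaries, the somatic age clock, and genome
# extrapolation.

#' Summarise per-subject mutation burden and VAF structure
#'
#' @param calls data.frame of filtered calls with columns subject_id, tissue,
#'   vaf and optionally consequence_term (for the six-way subtype counts)
#' @param subjects subject table with subject_id (and age, used downstream);
#'   every call's subject_id must appear here
#' @param vaf_threshold low-VAF threshold, default 0.05
#' @return list with `per_subject` (one row per subject x tissue present in
#'   `subjects` x tissues seen: n_snvs, mean_vaf, median_vaf, frac_below
#'   plus one count column per consequence category) and `pooled` (per
#'   tissue: n_snvs, frac_below as a percentage to 1 decimal)
#' @export
summarize_burden <- function(calls, subjects, vaf_threshold = 0.05) {
  stopifnot(all(c("subject_id", "tissue", "vaf") %in% names(calls)))
  orphans <- setdiff(calls$subject_id, subjects$subject_id)
  if (length(orphans))
    stop("calls reference unknown subjects: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  cats <- c("Non-synonymous", "Synonymous", "UTR", "Intronic", "Splicing",
            "Intergenic")
  category <- if ("consequence_term" %in% names(calls)) {
    vapply(calls$consequence_term, classify_consequence, character(1),
           USE.NAMES = FALSE)
  } else rep(NA_character_, nrow(calls))

  tissues <- sort(unique(calls$tissue))
  rows <- list()
  for (ti in tissues) {
    for (s in subjects$subject_id) {
      sel <- calls$tissue == ti & calls$subject_id == s
      v <- calls$vaf[sel]
      cnt <- table(factor(category[sel], levels = cats))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, tissue = ti, n_snvs = sum(sel),
        mean_vaf = if (sum(sel)) mean(v) else NA_real_,
        median_vaf = if (sum(sel)) stats::median(v) else NA_real_,
        frac_below = if (sum(sel)) mean(v < vaf_threshold) else NA_real_,
        as.list(cnt), stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  per_subject <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(tissues, function(ti) {
    v <- calls$vaf[calls$tissue == ti]
    data.frame(tissue = ti, n_snvs = length(v),
               n_below = sum(v < vaf_threshold),
               frac_below_pct = round(100 * mean(v < vaf_threshold), 1))
  }))
  list(per_subject = per_subject, pooled = pooled)
}

#' Fit the somatic mutation age-accumulation rate for one tissue
#'
#' Ordinary least squares of per-subject SNV count on age (the "somatic
#' clock"); the OLS slope is the headline rate in SNVs/exome/year. A Poisson
#' log-link GLM is available via `family = "poisson"` as a count-aware
#' alternative; its slope is on the log scale, not directly comparable.
#'
#' @param burden per-subject burden table (needs n_snvs) or a data.frame with
#'   columns subject_id, n_snvs
#' @param subjects subject table supplying `age`
#' @param tissue tissue to fit ("brain"/"blood"/...); rows are taken from
#'   `burden$tissue`
#' @param family "gaussian" (OLS, default) or "poisson" (log-link GLM)
#' @return object of class `rate_fit`: tissue, slope, intercept, slope_se,
#'   n_subjects, family and the underlying `fit`
#' @export
fit_accumulation_rate <- function(burden, subjects, tissue,
                                  family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (is.list(burden) && !is.data.frame(burden)) burden <- burden$per_subject
  d <- burden[burden$tissue == tissue, c("subject_id", "n_snvs")]
  d$age <- subjects$age[match(d$subject_id, subjects$subject_id)]
  d <- d[!is.na(d$age), ]
  if (nrow(d) < 3) stop("need >= 3 subjects with ages for a rate fit",
                        call. = FALSE)
  if (length(unique(d$age)) < 2)
    stop("degenerate fit: all subjects share one age", call. = FALSE)
  fit <- if (family == "gaussian") stats::lm(n_snvs ~ age, data = d)
         else stats::glm(n_snvs ~ age, data = d, family = stats::poisson())
  cf <- summary(fit)$coefficients
  structure(list(tissue = tissue, slope = unname(cf["age", 1]),
                 intercept = unname(cf["(Intercept)", 1]),
                 slope_se = unname(cf["age", 2]),
                 n_subjects = nrow(d), family = family, fit = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Somatic accumulation rate (%s, %s, n = %d subjects)\n",
              x$tissue, x$family, x$n_subjects))
  cat(sprintf("  %.3g SNVs/exome/year (se %.3g), intercept %.3g\n",
              x$slope, x$slope_se, x$intercept))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.rate_fit <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' Fold ratio of two rates, reported to one decimal
#' @param num,den numerator and denominator rates
#' @param digits decimals for reporting, default 1
#' @return rounded num/den; Inf-marked when den = 0 and num > 0
#' @export
#' @examples
#' fold_ratio(2.55, 0.53)  # 4.8
#' fold_ratio(8.75, 1.8)   # 4.9
fold_ratio <- function(num, den, digits = 1) {
  if (den == 0) return(if (num == 0) NaN else Inf)
  round(num / den, digits)
}

#' Extrapolate exome rates to genome scale and compare tissues
#'
#' @param brain_fit,blood_fit `rate_fit` objects (or bare slopes)
#' @param exome_bp,genome_bp exome and genome sizes in bp; defaults 75 Mb
#'   and 3 Gb
#' @return list: genome_rate_brain, genome_rate_blood (SNVs/genome/year,
#'   unrounded), fold_ratio (blood/brain slope, 1 decimal)
#' @export
#' @examples
#' extrapolate_and_compare(0.53, 2.55)
extrapolate_and_compare <- function(brain_fit, blood_fit, exome_bp = 75e6,
                                    genome_bp = 3e9) {
  slope_of <- function(x) if (inherits(x, "rate_fit")) x$slope else as.numeric(x)
  b <- slope_of(brain_fit); l <- slope_of(blood_fit)
  if (b < 0 || l < 0) stop("slopes must be nonnegative", call. = FALSE)
  if (exome_bp <= 0) stop("exome_bp must be positive", call. = FALSE)
  scale <- genome_bp / exome_bp
  list(genome_rate_brain = b * scale, genome_rate_blood = l * scale,
       fold_ratio = fold_ratio(l, b))
}
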