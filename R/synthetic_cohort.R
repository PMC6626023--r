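# Synthetic cohort generator.
#
# Emulates the derived count structure of a deep-WES brain/blood mosaicism
# study: subjects with AD/non-AD grouping, APOE genotypes and Braak stages;
# truth mosaic variants whose count grows linearly with age (Poisson clock)
# and whose trinucleotide channels follow a configured signature mixture;
# and per-site allele-count tables at ~584x depth with per-substitution
# background error plus a panel of normals. No reads or reference genome are
# involved: trinucleotide contexts are generated directly and are the source
# of truth for the implied reference sequence around each site.

#' Generate a synthetic subject table
#'
#' Ages are uniform over `age_range`; APOE rs429358 (T/C) and rs7412 (C/T)
#' genotypes are drawn under Hardy-Weinberg from group-specific allele
#' frequencies; Braak stage is high (4-6) for AD and low (0-1) for non-AD;
#' onset age (AD only) trails current age by 5-15 years, floored so that
#' age >= onset.
#'
#' @param n_ad,n_nonad numbers of AD and non-AD subjects (total >= 1)
#' @param age_range integer vector `c(lo, hi)` of ages in years, lo <= hi
#' @param seed integer seed; fixed seed gives bit-identical output
#' @param apoe_c_freq frequency of the rs429358 C (epsilon-4-tagging) allele,
#'   by group
#' @param apoe_t_freq frequency of the rs7412 T (epsilon-2-tagging) allele
#' @return data.frame with one row per subject: subject_id, group, age,
#'   onset_age (NA for non-AD), apoe_rs429358, apoe_rs7412 (unphased
#'   genotypes like "C/T"), braak
#' @export
#' @examples
#' subj <- generate_cohort(52, 11, c(57, 96), seed = 1)
#' table(subj$group)
generate_cohort <- function(n_ad, n_nonad, age_range, seed = 1L,
                            apoe_c_freq = c(AD = 0.39, nonAD = 0.14),
                            apoe_t_freq = 0.06) {
  if (n_ad + n_nonad < 1) stop("cohort must contain at least one subject", call. = FALSE)
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[2] < age_range[1])
    stop("age_range must be a nonempty interval c(lo, hi)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- n_ad + n_nonad
  group <- c(rep("AD", n_ad), rep("nonAD", n_nonad))
  age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  gt <- function(p_alt, ref, alt) {
    k <- stats::rbinom(n, 2L, p_alt)  # alt allele count under HWE
    c_allele <- vapply(k, function(x)
      paste(sort(c(rep(alt, x), rep(ref, 2 - x))), collapse = "/"),
      character(1))
    list(gt = c_allele, k = k)
  }
  g1 <- gt(ifelse(group == "AD", apoe_c_freq[["AD"]], apoe_c_freq[["nonAD"]]),
           "T", "C")
  g2 <- gt(apoe_t_freq, "C", "T")
  onset <- ifelse(group == "AD", age - sample(5:15, n, replace = TRUE), NA)
  onset <- pmin(onset, age)
  braak <- ifelse(group == "AD", sample(4:6, n, replace = TRUE),
                  sample(0:1, n, replace = TRUE))
  data.frame(
    subject_id = sprintf("%s_%03d", ifelse(group == "AD", "AD", "CTRL"), seq_len(n)),
    group = group, age = as.integer(age), onset_age = as.integer(onset),
    apoe_rs429358 = g1$gt, apoe_rs7412 = g2$gt, braak = as.integer(braak),
    stringsAsFactors = FALSE
  )
}

#' Draw truth mosaic variants for one subject
#'
#' The variant count is Poisson with mean `intercept + slope * age` (the
#' linear somatic clock; the intercept accommodates developmental mutations).
#' Each variant's 96-channel is drawn from the configured signature mixture
#' and its allele fraction from a Beta distribution truncated to
#' (0.005, 0.40), matching the observed low-VAF mosaic regime.
#'
#' @param subject one row of [generate_cohort()]'s output (or any list with
#'   `subject_id` and `age`)
#' @param slope somatic SNVs per exome per year (>= 0); default 0.53
#' @param intercept expected SNVs at age 0
#' @param signature_mix named numeric vector of mixture weights over
#'   signatures present in `catalog`; must sum to 1
#' @param catalog signature catalog (see [synthetic_signature_catalog()])
#' @param vaf_shape1,vaf_shape2 Beta parameters of the VAF distribution
#' @param vaf_bounds truncation interval for VAFs
#' @param gene_pool character vector of gene symbols to assign from
#' @param pathogenic_rate probability a variant is flagged pathogenic
#' @param seed integer seed
#' @return data.frame of truth variants: subject_id, chrom, pos, ref, alt,
#'   context, channel, true_vaf, gene, pathogenic
#' @export
generate_truth_variants <- function(subject, slope = 0.53, intercept = 2,
                                    signature_mix = c(SBS5 = 0.5, SBS1 = 0.25, SBS18 = 0.25),
                                    catalog = synthetic_signature_catalog(),
                                    vaf_shape1 = 1.2, vaf_shape2 = 40,
                                    vaf_bounds = c(0.005, 0.40),
                                    gene_pool = NULL,
                                    pathogenic_rate = 0.05,
                                    seed = 1L) {
  if (slope < 0) stop("slope must be nonnegative", call. = FALSE)
  if (abs(sum(signature_mix) - 1) > 1e-6)
    stop("signature_mix weights must sum to 1", call. = FALSE)
  if (!all(names(signature_mix) %in% colnames(catalog)))
    stop("signature_mix names must be present in the catalog", call. = FALSE)
  set.seed(as.integer(seed))
  lambda <- intercept + slope * subject$age
  n <- stats::rpois(1L, lambda)
  if (is.null(gene_pool))
    gene_pool <- sprintf("GENE%04d", 1:2000)
  if (n == 0L) {
    return(data.frame(subject_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      context = character(), channel = integer(),
                      true_vaf = numeric(), gene = character(),
                      pathogenic = logical(), stringsAsFactors = FALSE))
  }
  mix_spectrum <- as.numeric(catalog[, names(signature_mix), drop = FALSE] %*%
                               signature_mix)
  ch <- sample(0:95, n, replace = TRUE, prob = mix_spectrum)
  tab <- .CHANNELS[match(ch, .CHANNELS$channel), ]
  # strand: half the variants are reported on the purine strand, as real
  # pipelines would see them before normalisation
  flip <- stats::runif(n) < 0.5
  ref <- substr(tab$class, 1, 1)
  alt <- substr(tab$class, 3, 3)
  ctx <- tab$context
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  vaf <- rbeta_truncated(n, vaf_shape1, vaf_shape2, vaf_bounds)
  data.frame(
    subject_id = subject$subject_id,
    chrom = "chrS",
    pos = sort(sample.int(2e8, n)),
    ref = ref, alt = alt, context = ctx, channel = as.integer(ch),
    true_vaf = vaf,
    gene = sample(gene_pool, n, replace = TRUE),
    pathogenic = stats::runif(n) < pathogenic_rate,
    stringsAsFactors = FALSE
  )
}

# inverse-CDF sampling of a truncated Beta
rbeta_truncated <- function(n, shape1, shape2, bounds) {
  lo <- stats::pbeta(bounds[1], shape1, shape2)
  hi <- stats::pbeta(bounds[2], shape1, shape2)
  stats::qbeta(stats::runif(n, lo, hi), shape1, shape2)
}

#' Default per-substitution background error rates
#'
#' Platform background error VAFs for the six pyrimidine-centred substitution
#' classes, estimated from replicate spike-in amplicon sequencing; used both
#' as the amplicon validation null and as the noise floor of the synthetic
#' count generator.
#'
#' @return named numeric vector over T>A, T>C, T>G, C>T, C>G, C>A
#' @export
default_background_errors <- function() {
  c("T>A" = 0.00312107, "T>C" = 0.007970457, "T>G" = 7.58e-04,
    "C>T" = 0.004071926, "C>G" = 7.65e-04, "C>A" = 0.001847634)
}

#' Generate noisy allele counts for truth variants plus decoy sites
#'
#' For each truth variant, emits one `case_tissue` row with
#' alt ~ Binomial(depth, true_vaf + class error), one `matched_normal` row
#' and `n_panel` panel rows with alt ~ Binomial(depth, class error); depths
#' are Poisson around `depth_mean`. Additionally emits `n_decoys` non-variant
#' sites carrying pure background error in all roles.
#'
#' @param truths truth-variant table from [generate_truth_variants()] (rows
#'   from several subjects may be concatenated)
#' @param depth_mean mean sequencing depth (reads); default 584
#' @param n_panel number of panel-of-normals samples; default 21
#' @param error_table named per-class background VAFs covering all six
#'   substitution classes
#' @param n_decoys number of decoy (error-only) sites to add
#' @param seed integer seed
#' @return data.frame SiteCountTable: chrom, pos, ref, alt, context,
#'   sample_id, role (case_tissue/matched_normal/panel), depth, alt_count,
#'   is_truth
#' @export
generate_allele_counts <- function(truths, depth_mean = 584, n_panel = 21,
                                   error_table = default_background_errors(),
                                   n_decoys = 0, seed = 1L) {
  if (depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  if (!all(SUB_CLASSES %in% names(error_table)))
    stop("error_table must cover all six substitution classes", call. = FALSE)
  set.seed(as.integer(seed))

  sites <- truths[, c("subject_id", "chrom", "pos", "ref", "alt", "context")]
  sites$true_vaf <- truths$true_vaf
  sites$is_truth <- rep(TRUE, nrow(truths))
  if (n_decoys > 0) {
    dch <- sample(0:95, n_decoys, replace = TRUE)
    dtab <- .CHANNELS[match(dch, .CHANNELS$channel), ]
    subj <- if (nrow(truths)) truths$subject_id[1] else "DECOY_SUBJ"
    decoys <- data.frame(
      subject_id = subj, chrom = "chrS",
      pos = sample(2e8 + seq_len(1e8), n_decoys),
      ref = substr(dtab$class, 1, 1), alt = substr(dtab$class, 3, 3),
      context = dtab$context, true_vaf = 0, is_truth = FALSE,
      stringsAsFactors = FALSE)
    sites <- rbind(sites, decoys)
  }
  if (!nrow(sites))
    stop("no sites to emit: empty truth set and n_decoys = 0", call. = FALSE)

  cls <- vapply(seq_len(nrow(sites)), function(i)
    normalize_substitution(sites$ref[i], sites$alt[i])$class, character(1))
  err <- unname(error_table[cls])

  roles <- c("case_tissue", "matched_normal", paste0("panel_", seq_len(n_panel)))
  role_type <- c("case_tissue", "matched_normal", rep("panel", n_panel))
  n_sites <- nrow(sites)
  n_roles <- length(roles)

  idx <- rep(seq_len(n_sites), each = n_roles)
  depth <- stats::rpois(n_sites * n_roles, depth_mean)
  depth[depth == 0L] <- 1L  # emitted rows must have positive depth
  p <- ifelse(rep(role_type, n_sites) == "case_tissue",
              pmin(sites$true_vaf[idx] + err[idx], 1), err[idx])
  alt_count <- stats::rbinom(n_sites * n_roles, depth, p)

  data.frame(
    chrom = sites$chrom[idx], pos = sites$pos[idx],
    ref = sites$ref[idx], alt = sites$alt[idx],
    context = sites$context[idx],
    subject_id = sites$subject_id[idx],
    sample_id = paste0(ifelse(rep(role_type, n_sites) == "panel", "",
                              paste0(sites$subject_id[idx], ".")),
                       rep(roles, n_sites)),
    role = rep(role_type, n_sites),
    depth = as.integer(depth), alt_count = as.integer(alt_count),
    is_truth = sites$is_truth[idx],
    stringsAsFactors = FALSE
  )
}
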