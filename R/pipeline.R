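# End-to-end plumbing: from a site count table to scored, filtered calls.

#' Score candidate sites against their panel of normals
#'
#' For every (chrom, pos, ref, alt) site in the table, fits the per-site
#' beta-binomial error model on the panel rows and scores the case-tissue
#' alt count with [compute_eb_score()].
#'
#' @param site_counts SiteCountTable data.frame (see
#'   [generate_allele_counts()]): chrom, pos, ref, alt, sample_id, role,
#'   depth, alt_count (extra columns such as context/subject_id/is_truth are
#'   carried through from the case row)
#' @param pseudocount floor-model pseudocount for all-zero panels
#' @return data.frame of candidate calls, one per site x case sample, with
#'   eb_score and vaf added
#' @export
score_candidates <- function(site_counts, pseudocount = 0.5) {
  key <- paste(site_counts$chrom, site_counts$pos, site_counts$ref,
               site_counts$alt, sep = ":")
  out <- vector("list", length(unique(key)))
  i <- 0L
  for (rows in split(seq_len(nrow(site_counts)), key)) {
    d <- site_counts[rows, ]
    panel <- d[d$role == "panel", ]
    case <- d[d$role == "case_tissue", ]
    if (!nrow(case)) next
    model <- fit_site_error_model(panel$alt_count, panel$depth,
                                  pseudocount = pseudocount)
    case$eb_score <- vapply(seq_len(nrow(case)), function(j)
      compute_eb_score(case$alt_count[j], case$depth[j], model), numeric(1))
    case$vaf <- case$alt_count / case$depth
    i <- i + 1L
    out[[i]] <- case
  }
  res <- do.call(rbind, out[seq_len(i)])
  rownames(res) <- NULL
  res
}

#' Run the somatic filter on a synthetic cohort's count table
#'
#' Convenience wrapper: [score_candidates()] then [apply_post_filters()].
#'
#' @inheritParams score_candidates
#' @inheritParams apply_post_filters
#' @param use_eb when FALSE, the EB rule is disabled (cutoff effectively
#'   -inf) — used to measure how much the error model itself contributes
#' @return filtered call table
#' @export
filter_cohort_calls <- function(site_counts, mode = "matched",
                                eb_cutoff = 2.396, use_eb = TRUE,
                                pseudocount = 0.5) {
  calls <- score_candidates(site_counts, pseudocount = pseudocount)
  res <- apply_post_filters(calls, mode = mode, eb_cutoff = eb_cutoff)
  if (!use_eb) {
    # strip the EB rule from the reason codes; other rules stand
    codes <- strsplit(res$reason_codes, ",", fixed = TRUE)
    codes <- vapply(codes, function(r) paste(setdiff(r, "eb_score"),
                                             collapse = ","), character(1))
    res$reason_codes <- codes
    res$filter_status <- ifelse(codes == "", "PASS", "FAIL")
  }
  res
}
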