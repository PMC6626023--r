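# Germline risk-site genotyping, APOE epsilon resolution, and carrier
# categorisation (germline-only / somatic-only / both / none).

#' Genotype germline risk sites from allele counts
#'
#' Germline calls use the deep-count VAF directly: VAF < `vaf_het` is
#' hom-ref, `vaf_het` <= VAF < `vaf_hom` is heterozygous, VAF >= `vaf_hom`
#' is hom-alt. The 0.40 het bound is inclusive (a site at exactly 40% is a
#' germline het); the 0.90 hom bound separates one from two alt copies.
#'
#' @param counts data.frame with columns site (e.g. "rs429358"), ref, alt,
#'   depth, alt_count; one row per site for one subject
#' @param vaf_het,vaf_hom genotype boundaries, defaults 0.40 and 0.90
#' @return data.frame: site, ref, alt, vaf, genotype
#'   (hom_ref/het/hom_alt)
#' @export
#' @examples
#' genotype_risk_sites(data.frame(site = "rs429358", ref = "T", alt = "C",
#'                                depth = 500, alt_count = 240))
genotype_risk_sites <- function(counts, vaf_het = 0.40, vaf_hom = 0.90) {
  stopifnot(all(c("site", "depth", "alt_count") %in% names(counts)))
  if (any(counts$depth <= 0))
    stop("depth must be positive at every genotyped site", call. = FALSE)
  vaf <- counts$alt_count / counts$depth
  genotype <- ifelse(vaf >= vaf_hom, "hom_alt",
                     ifelse(vaf >= vaf_het, "het", "hom_ref"))
  data.frame(site = counts$site,
             ref = counts$ref %||% NA_character_,
             alt = counts$alt %||% NA_character_,
             vaf = vaf, genotype = genotype, stringsAsFactors = FALSE)
}

# alt-allele dosage from a genotype string
gt_dosage <- function(genotype) {
  switch(genotype, hom_ref = 0L, het = 1L, hom_alt = 2L,
         stop("unknown genotype '", genotype, "'", call. = FALSE))
}

#' Resolve the APOE epsilon genotype from rs429358 and rs7412
#'
#' Haplotype definitions: epsilon-4 = rs429358 C with rs7412 C; epsilon-3 =
#' T/C; epsilon-2 = T/T; epsilon-1 = C/T (rare). Unphased dosages resolve
#' uniquely except the double heterozygote (C/T at both sites), which is
#' e2/e4 or e1/e3 and is reported as ambiguous with zero countable e4
#' copies and `ambiguous = TRUE`.
#'
#' @param rs429358,rs7412 genotype strings (hom_ref/het/hom_alt) or rows
#'   from [genotype_risk_sites()]; rs429358 alt = C, rs7412 alt = T
#' @return list: label (e.g. "e3/e4"), e4_copies (0/1/2), ambiguous
#' @export
#' @examples
#' apoe_genotype("hom_alt", "hom_ref")  # e4/e4
apoe_genotype <- function(rs429358, rs7412) {
  gt <- function(x) if (is.list(x) || is.data.frame(x)) x$genotype else x
  g1 <- gt(rs429358); g2 <- gt(rs7412)
  if (is.na(g1) || is.na(g2))
    return(list(label = "undetermined", e4_copies = NA_integer_,
                ambiguous = NA))
  c429 <- gt_dosage(g1)   # copies of C at rs429358
  t7412 <- gt_dosage(g2)  # copies of T at rs7412
  if (c429 == 1L && t7412 == 1L) {
    warning("double heterozygote at rs429358/rs7412: e2/e4 vs e1/e3 ",
            "cannot be resolved without phasing; excluded from e4 counts",
            call. = FALSE)
    return(list(label = "ambiguous(e2/e4|e1/e3)", e4_copies = 0L,
                ambiguous = TRUE))
  }
  # copies of C at rs7412 available to pair with rs429358-C into e4
  e4 <- min(c429, 2L - t7412)
  e1 <- c429 - e4                       # leftover C pairs with rs7412-T
  e2 <- min(2L - c429, t7412)
  e3 <- 2L - e4 - e1 - e2
  hap <- rep(c("e1", "e2", "e3", "e4"), c(e1, e2, e3, e4))
  list(label = paste(sort(hap), collapse = "/"), e4_copies = e4,
       ambiguous = FALSE)
}

#' Build per-subject carrier profiles
#'
#' A subject carries a pathogenic germline factor when they have two APOE e4
#' copies or any hit in the risk-modifier catalog; a pathogenic somatic
#' factor when at least one retained putatively pathogenic brain somatic SNV
#' falls in a designated (tau-phosphorylation-related) pathway gene.
#'
#' @param subjects subject table with subject_id
#' @param e4_copies named (by subject_id) integer APOE e4 copy counts
#' @param risk_hits named list (by subject_id) of risk-modifier gene hits;
#'   missing subjects mean no hits
#' @param somatic_genes named list (by subject_id) of genes with retained
#'   putatively pathogenic somatic SNVs
#' @param pathway_genes character vector: the designated pathway gene union
#' @return data.frame: subject_id, apoe_e4_copies, n_risk_modifiers,
#'   has_pathogenic_germline, has_pathogenic_somatic, category
#' @export
carrier_profiles <- function(subjects, e4_copies, risk_hits = list(),
                             somatic_genes = list(), pathway_genes) {
  ids <- subjects$subject_id
  e4 <- unname(e4_copies[ids]); e4[is.na(e4)] <- 0L
  nrisk <- vapply(ids, function(s) length(risk_hits[[s]]), integer(1))
  somhit <- vapply(ids, function(s)
    length(intersect(somatic_genes[[s]], pathway_genes)) > 0, logical(1))
  germ <- e4 == 2L | nrisk > 0L
  category <- ifelse(germ & somhit, "both",
                     ifelse(germ, "germline_only",
                            ifelse(somhit, "somatic_only", "none")))
  data.frame(subject_id = ids, apoe_e4_copies = e4,
             n_risk_modifiers = unname(nrisk),
             has_pathogenic_germline = unname(germ),
             has_pathogenic_somatic = unname(somhit),
             category = unname(category), stringsAsFactors = FALSE)
}

#' Tabulate carrier categories with cohort percentages
#'
#' @param profiles data.frame with a `category` column
#'   (germline_only/somatic_only/both/none), e.g. from [carrier_profiles()]
#' @return list: n, counts (named int), percentages (named, 1 decimal),
#'   somatic_total_pct (somatic_only + both, 1 decimal)
#' @export
#' @examples
#' p <- data.frame(category = rep(c("germline_only", "somatic_only", "both",
#'                                  "none"), c(7, 9, 5, 31)))
#' categorize_carriers(p)
categorize_carriers <- function(profiles) {
  if (!nrow(profiles)) stop("profiles must be nonempty", call. = FALSE)
  lev <- c("germline_only", "somatic_only", "both", "none")
  counts <- table(factor(profiles$category, levels = lev))
  n <- nrow(profiles)
  pct <- round(100 * as.numeric(counts) / n, 1)
  names(pct) <- lev
  list(n = n, counts = stats::setNames(as.integer(counts), lev),
       percentages = pct,
       somatic_total_pct = round(100 * sum(counts[c("somatic_only", "both")]) / n, 1))
}
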