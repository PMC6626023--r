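# Consequence classification, rare/deleterious prioritisation, and
# permutation gene-set enrichment with a hypergeometric oracle.

.CONSEQUENCE_MAP <- local({
  m <- c(
    "missense variant" = "Non-synonymous",
    "stop gained" = "Non-synonymous",
    "start lost" = "Non-synonymous",
    "stop lost" = "Non-synonymous",
    "splice donor" = "Non-synonymous",
    "splice acceptor" = "Non-synonymous",
    "splice donor variant" = "Non-synonymous",
    "splice acceptor variant" = "Non-synonymous",
    "synonymous variant" = "Synonymous",
    "5 prime utr variant" = "UTR",
    "3 prime utr variant" = "UTR",
    "intron variant" = "Intronic",
    "mature mirna variant" = "Intronic",
    "non coding transcript exon variant" = "Intronic",
    "stop retained variant" = "Intronic",
    "splice region variant" = "Splicing",
    "intergenic variant" = "Intergenic",
    "upstream variant" = "Intergenic",
    "downstream variant" = "Intergenic",
    "upstream gene variant" = "Intergenic",
    "downstream gene variant" = "Intergenic"
  )
  m
})

#' Classify a consequence term into the six-way category scheme
#'
#' Categories: Non-synonymous (missense, stop gained/lost, start lost,
#' splice donor/acceptor), Synonymous, UTR (5'/3' UTR), Intronic (intron,
#' mature miRNA, non-coding transcript exon, stop retained), Splicing
#' (splice region), Intergenic (intergenic, upstream, downstream). Unknown
#' terms return "unclassified" rather than erroring.
#'
#' @param term consequence term (VEP-style; underscores, case and typographic
#'   primes are normalised)
#' @return one of the six category names, or "unclassified"
#' @export
#' @examples
#' classify_consequence("missense_variant")
#' classify_consequence("3_prime_UTR_variant")
classify_consequence <- function(term) {
  if (!nzchar(term)) stop("consequence term must be nonempty", call. = FALSE)
  key <- tolower(gsub("[_′’']", " ", term))
  key <- gsub("\\s+", " ", trimws(key))
  unname(.CONSEQUENCE_MAP[key]) %|NA|% "unclassified"
}

`%|NA|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Keep rare, predicted-deleterious non-synonymous variants
#'
#' Retains variants that are Non-synonymous, have a Phred-scaled CADD score
#' strictly above `cadd_cut`, and are absent from the population reference
#' or rarer than `maf_cut` (strict <; a MAF exactly at the cut is removed).
#'
#' @param variants data.frame with columns consequence_term (or category),
#'   cadd, and maf (NA = absent from the population database)
#' @param maf_cut population-frequency cut, default 1e-4 (0.01%)
#' @param cadd_cut CADD cut, default 20
#' @return the retained rows, order preserved
#' @export
filter_putatively_pathogenic <- function(variants, maf_cut = 1e-4,
                                         cadd_cut = 20) {
  if (!"category" %in% names(variants)) {
    stopifnot("consequence_term" %in% names(variants))
    variants$category <- vapply(variants$consequence_term,
                                classify_consequence, character(1),
                                USE.NAMES = FALSE)
  }
  if (!"cadd" %in% names(variants) || anyNA(variants$cadd)) {
    bad <- if ("cadd" %in% names(variants)) which(is.na(variants$cadd))
           else seq_len(nrow(variants))
    stop("missing CADD scores for ", length(bad), " variants (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  maf <- if ("maf" %in% names(variants)) variants$maf else rep(NA_real_, nrow(variants))
  keep <- variants$category == "Non-synonymous" &
    variants$cadd > cadd_cut &
    (is.na(maf) | maf < maf_cut)
  variants[keep, , drop = FALSE]
}

#' Read gene sets from a GMT file
#' @param path GMT file (one pathway per line: name, description, genes)
#' @return named list of character vectors
#' @export
read_gene_sets <- function(path) fgsea::gmtPathways(path)

#' Permutation gene-set enrichment with hypergeometric oracle
#'
#' For each pathway, counts the overlap of `query_genes` with the pathway and
#' compares it with a null of `n_perm` random draws of `draw_size` genes from
#' `pool` without replacement. The permutation p-value uses the +1 correction
#' (never exactly zero). For the unadjusted test, the exact hypergeometric
#' upper-tail probability is reported alongside as an oracle. With
#' `length_adjusted = TRUE`, null draws are stratified by gene-length
#' quintile (computed over the pool) to preserve the query's length-bin
#' composition, neutralising gene-length bias.
#'
#' @param query_genes genes of interest (must lie in `pool`)
#' @param pool universe of genes the query was drawn from
#' @param pathways named list of gene sets (see [read_gene_sets()])
#' @param draw_size genes per null draw; defaults to `length(query_genes)`
#' @param n_perm permutations, default 10000
#' @param seed integer seed
#' @param length_adjusted stratify null draws by gene-length quintile
#' @param gene_lengths named lengths (bp), required when `length_adjusted`
#' @param alpha significance flag threshold, default 0.05 (a report flag,
#'   not a filter)
#' @return data.frame: pathway, pathway_size (within pool), observed_overlap,
#'   perm_p, hypergeom_p (NA when length-adjusted), n_perm, significant
#' @export
permutation_enrichment <- function(query_genes, pool, pathways,
                                   draw_size = length(query_genes),
                                   n_perm = 10000, seed = 1L,
                                   length_adjusted = FALSE,
                                   gene_lengths = NULL, alpha = 0.05) {
  pool <- unique(pool)
  query_genes <- unique(query_genes)
  if (draw_size > length(pool))
    stop("draw_size exceeds the gene pool", call. = FALSE)
  if (!all(query_genes %in% pool))
    stop("query genes must be contained in the pool", call. = FALSE)
  set.seed(as.integer(seed))

  if (length_adjusted) {
    if (is.null(gene_lengths))
      stop("length_adjusted = TRUE requires gene_lengths", call. = FALSE)
    len <- gene_lengths[pool]
    if (anyNA(len)) stop("gene_lengths missing for some pool genes", call. = FALSE)
    qbreaks <- stats::quantile(len, probs = seq(0, 1, 0.2))
    bin <- cut(len, unique(qbreaks), include.lowest = TRUE, labels = FALSE)
    names(bin) <- pool
    qbin <- table(factor(bin[query_genes], levels = sort(unique(bin))))
    pool_by_bin <- split(pool, bin)
    draw_fun <- function() unlist(lapply(names(qbin), function(b) {
      k <- qbin[[b]]
      if (k > 0) sample(pool_by_bin[[b]], k) else character()
    }), use.names = FALSE)
  } else {
    draw_fun <- function() sample(pool, draw_size)
  }

  path_in_pool <- lapply(pathways, intersect, y = pool)
  observed <- vapply(path_in_pool, function(g) length(intersect(query_genes, g)),
                     integer(1))

  exceed <- integer(length(pathways))
  for (i in seq_len(n_perm)) {
    draw <- draw_fun()
    ov <- vapply(path_in_pool, function(g) sum(draw %in% g), integer(1))
    exceed <- exceed + (ov >= observed)
  }
  perm_p <- (1 + exceed) / (n_perm + 1)

  N <- length(pool)
  K <- lengths(path_in_pool)
  hyper <- if (length_adjusted) rep(NA_real_, length(pathways)) else
    stats::phyper(observed - 1, K, N - K, draw_size, lower.tail = FALSE)

  data.frame(pathway = names(pathways), pathway_size = unname(K),
             observed_overlap = unname(observed), perm_p = unname(perm_p),
             hypergeom_p = unname(hyper), n_perm = n_perm,
             significant = unname(perm_p < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
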