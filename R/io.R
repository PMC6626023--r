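# Plain-text interchange: TSV tables and a minimal VCF for truth variants.

#' Write/read a tab-separated table
#' @param x data.frame
#' @param path file path
#' @return `read_tsv_table` returns a data.frame
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a truth-variant set as a minimal VCF
#'
#' Fixed 8-column VCFv4.2 with INFO keys TVAF (true allele fraction), GENE
#' and CHAN (96-channel index); intended for the synthetic truth set, with
#' the TSV mirror ([write_tsv_table()]) as the canonical interchange form.
#'
#' @param truths truth-variant table from [generate_truth_variants()]
#' @param path output path
#' @export
write_truth_vcf <- function(truths, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"True variant allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CHAN,Number=1,Type=Integer,Description=\"96-channel index\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(truths)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tTVAF=%.6g;GENE=%s;CHAN=%d",
    truths$chrom, truths$pos, truths$ref, truths$alt,
    truths$true_vaf, truths$gene, truths$channel) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal truth VCF back into a table
#' @param path VCF written by [write_truth_vcf()]
#' @return data.frame: chrom, pos, ref, alt, true_vaf, gene, channel
#' @export
read_truth_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), true_vaf = numeric(),
                      gene = character(), channel = integer()))
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[`, character(1), 8)
  grab <- function(key) sub(paste0(".*", key, "=([^;]*).*"), "\\1", info)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)),
    ref = vapply(f, `[`, character(1), 4),
    alt = vapply(f, `[`, character(1), 5),
    true_vaf = as.numeric(grab("TVAF")),
    gene = grab("GENE"),
    channel = as.integer(grab("CHAN")),
    stringsAsFactors = FALSE)
}

#' Write filtered calls as a VCF with reason-coded FILTER field
#'
#' FILTER is PASS or a semicolon list of codes (MINDEPTH, GERMVAF, EBSCORE,
#' READPOS, SUPPORT, MAPP); INFO carries EBS (the EB score) and VAF.
#'
#' @param calls output of [apply_post_filters()], needing chrom, pos, ref,
#'   alt, vaf, eb_score, filter_status, reason_codes
#' @param path output path
#' @export
write_filtered_vcf <- function(calls, path) {
  code_map <- c(min_depth = "MINDEPTH", germline_vaf = "GERMVAF",
                eb_score = "EBSCORE", read_position = "READPOS",
                min_support = "SUPPORT", mappability = "MAPP")
  filt <- vapply(strsplit(calls$reason_codes, ",", fixed = TRUE),
                 function(r) if (!length(r) || identical(r, "")) "PASS"
                             else paste(code_map[r], collapse = ";"),
                 character(1))
  filt[calls$filter_status == "PASS"] <- "PASS"
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", code_map,
            c("Depth below minimum", "VAF in germline range",
              "EB score at or below cutoff", "Supporting reads at read ends",
              "Insufficient alt support", "Poor mappability")),
    "##INFO=<ID=EBS,Number=1,Type=Float,Description=\"Empirical Bayes score\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tEBS=%.4g;VAF=%.6g",
    calls$chrom, calls$pos, calls$ref, calls$alt, filt,
    calls$eb_score, calls$vaf) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
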