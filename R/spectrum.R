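# 96-channel single-base-substitution spectrum machinery.
#
# Channel order is fixed: substitution class (C>A, C>G, C>T, T>A, T>C, T>G)
# varying slowest, then 5' flanking base (A,C,G,T), then 3' flanking base
# (A,C,G,T); channels are numbered 0..95 in this order and labelled in the
# conventional "A[C>A]A" style.

BASES <- c("A", "C", "G", "T")

# the six pyrimidine-centred substitution classes, fixed order
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

channel_table <- function() {
  grid <- expand.grid(three = BASES, five = BASES, class = SUB_CLASSES,
                      stringsAsFactors = FALSE)[, c("class", "five", "three")]
  grid <- grid[order(match(grid$class, SUB_CLASSES), match(grid$five, BASES),
                     match(grid$three, BASES)), ]
  ref <- substr(grid$class, 1, 1)
  data.frame(
    channel = 0:95,
    class = grid$class,
    context = paste0(grid$five, ref, grid$three),
    label = paste0(grid$five, "[", grid$class, "]", grid$three),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.CHANNELS <- channel_table()

#' Channel labels of the 96 substitution channels, in canonical order
#' @return character vector of 96 labels like "A[C>A]A"
#' @export
channel_labels <- function() .CHANNELS$label

#' Map a substitution to its 96-channel index
#'
#' @param ref,alt single bases
#' @param context 3-mer centred on `ref`
#' @return integer channel in 0..95 under the pyrimidine-centred convention
#' @export
#' @examples
#' substitution_channel("C", "A", "ACA")  # 0
#' substitution_channel("G", "T", "TGT")  # same channel, opposite strand
substitution_channel <- function(ref, alt, context) {
  norm <- normalize_substitution(ref, alt, context)
  i <- which(.CHANNELS$class == norm$class & .CHANNELS$context == norm$context)
  .CHANNELS$channel[i]
}

#' Build a 96-channel mutation spectrum
#'
#' Counts single-base substitutions over the 96 pyrimidine-centred
#' trinucleotide channels. Purine-reference variants are reverse-complemented
#' onto the pyrimidine strand first.
#'
#' @param variants data.frame with columns `ref`, `alt`, `context` (3-mer
#'   whose middle base equals `ref`)
#' @return object of class `spectrum96`: integer vector of length 96 named by
#'   channel label, with attribute `total`
#' @export
#' @examples
#' sp <- build_mutation_spectrum(
#'   data.frame(ref = "C", alt = "A", context = "ACA"))
#' sum(sp)  # 1
build_mutation_spectrum <- function(variants) {
  stopifnot(is.data.frame(variants),
            all(c("ref", "alt", "context") %in% names(variants)))
  counts <- integer(96)
  if (nrow(variants)) {
    ch <- mapply(substitution_channel, variants$ref, variants$alt,
                 variants$context)
    tab <- tabulate(ch + 1L, nbins = 96L)
    counts <- as.integer(tab)
  }
  names(counts) <- .CHANNELS$label
  structure(counts, total = sum(counts), class = "spectrum96")
}

#' @export
print.spectrum96 <- function(x, ...) {
  cat("96-channel mutation spectrum:", attr(x, "total"), "substitutions\n")
  by_class <- tapply(unclass(x), .CHANNELS$class, sum)[SUB_CLASSES]
  print(by_class)
  invisible(x)
}

as_spectrum96 <- function(counts) {
  stopifnot(length(counts) == 96L, all(counts >= 0))
  counts <- as.integer(round(counts))
  names(counts) <- .CHANNELS$label
  structure(counts, total = sum(counts), class = "spectrum96")
}

cosine_sim <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
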