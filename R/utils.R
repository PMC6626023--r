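# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values
#' @return log(sum(exp(x))) without overflow
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# running reverse-cumulative logsumexp: out[i] = log sum_{j >= i} exp(x[j])
rev_cum_logsumexp <- function(x) {
  n <- length(x)
  out <- numeric(n)
  acc <- -Inf
  for (i in n:1) {
    m <- max(acc, x[i])
    acc <- if (is.finite(m)) m + log(exp(acc - m) + exp(x[i] - m)) else m
    out[i] <- acc
  }
  out
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Normalise a substitution to the pyrimidine-centred convention
#'
#' A purine-reference call (e.g. G>A) is reported on the opposite strand
#' (C>T), with the trinucleotide context reverse-complemented when given.
#'
#' @param ref,alt single reference and alternate bases
#' @param context optional 3-mer centred on the site
#' @return list with `ref`, `alt`, `context` (NULL if not supplied) and
#'   `class` (one of "C>A","C>G","C>T","T>A","T>C","T>G")
#' @export
#' @examples
#' normalize_substitution("G", "T", "TGT")  # becomes C>A in context ACA
normalize_substitution <- function(ref, alt, context = NULL) {
  if (!ref %in% BASES || !alt %in% BASES)
    stop("ref and alt must be single A/C/G/T bases", call. = FALSE)
  if (ref == alt) stop("ref and alt must differ", call. = FALSE)
  if (!is.null(context)) {
    if (nchar(context) != 3L || substr(context, 2, 2) != ref)
      stop("context must be a 3-mer whose middle base equals ref", call. = FALSE)
  }
  if (ref %in% c("G", "A")) {
    ref2 <- comp_base(ref)
    alt2 <- comp_base(alt)
    ctx2 <- if (is.null(context)) NULL else revcomp(context)
  } else {
    ref2 <- ref; alt2 <- alt; ctx2 <- context
  }
  list(ref = ref2, alt = alt2, context = ctx2,
       class = paste0(ref2, ">", alt2))
}
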