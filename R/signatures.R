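# Mutational-signature refitting: exposures of a 96-channel spectrum over a
# reference catalog by multinomial maximum likelihood, with exhaustive
# subset search scored by BIC (cosine similarity breaking ties).
#
# The observed spectrum is modelled as Multinomial(N, sum_i e_i * s_i) with
# exposures e on the simplex. The MLE is found by EM: this mixture admits
# the classic closed-form update e_i <- (1/N) sum_c n_c e_i s_ic / p_c,
# which is monotone in the likelihood and keeps the simplex constraints
# exact. An NNLS-on-fractions mode is kept as a cross-checking alternative.

#' Deterministic synthetic signature catalog
#'
#' A small stand-in catalog of 96-channel signature profiles with the broad
#' shapes of the familiar reference processes — "SBS1" (C>T at NpCpG,
#' 5-methylcytosine deamination), "SBS5" (flat, clock-like), "SBS18" (C>A
#' heavy, reactive-oxygen damage) — plus three filler processes. These are
#' synthetic profiles for testing and simulation, not the published
#' reference vectors; load a real catalog with [read_signature_catalog()]
#' for analysis of real data.
#'
#' @return 96 x 6 matrix; rows in canonical channel order (see
#'   [channel_labels()]), columns named SBS1, SBS5, SBS18, SBSA, SBSB, SBSC;
#'   each column sums to 1
#' @export
synthetic_signature_catalog <- function() {
  ch <- .CHANNELS
  norm <- function(x) x / sum(x)

  sbs1 <- rep(0.05, 96)
  cpg <- ch$class == "C>T" & substr(ch$context, 3, 3) == "G"
  sbs1[cpg] <- 20
  sbs1[ch$class == "C>T" & !cpg] <- 1

  # flat-ish with mild, deterministic channel-to-channel texture
  sbs5 <- 1 + 0.35 * sin(seq_len(96) / 5) + 0.15 * (ch$class %in% c("T>C", "C>T"))

  sbs18 <- rep(0.05, 96)
  sbs18[ch$class == "C>A"] <- 8
  sbs18[ch$class == "C>A" & substr(ch$context, 1, 1) %in% c("G", "T")] <- 14

  sbsa <- rep(0.02, 96); sbsa[ch$class == "T>A"] <- 6
  sbsb <- rep(0.02, 96); sbsb[ch$class == "T>G"] <- 6
  sbsc <- rep(0.02, 96)
  sbsc[ch$class == "C>G"] <- 5
  sbsc[ch$class == "T>C" & substr(ch$context, 1, 1) == "A"] <- 5

  m <- cbind(SBS1 = norm(sbs1), SBS5 = norm(sbs5), SBS18 = norm(sbs18),
             SBSA = norm(sbsa), SBSB = norm(sbsb), SBSC = norm(sbsc))
  rownames(m) <- ch$label
  m
}

#' Read a 96 x S signature catalog from TSV
#'
#' Expects the standard layout: 96 rows in canonical channel order with a
#' first column of channel labels (either "A[C>A]A" or a Type/Subtype pair)
#' and one column per signature.
#'
#' @param path TSV file
#' @return 96 x S numeric matrix, columns renormalised to sum to 1
#' @export
read_signature_catalog <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab_col <- which(vapply(d, is.character, logical(1)))
  if (length(lab_col) >= 2) {
    # Type ("C>A") + Subtype ("ACA") columns
    lab <- paste0(substr(d[[lab_col[2]]], 1, 1), "[", d[[lab_col[1]]], "]",
                  substr(d[[lab_col[2]]], 3, 3))
  } else if (length(lab_col) == 1) {
    lab <- d[[lab_col]]
  } else stop("no channel-label column found", call. = FALSE)
  m <- as.matrix(d[, setdiff(seq_along(d), lab_col), drop = FALSE])
  if (nrow(m) != 96) stop("catalog must have 96 channel rows", call. = FALSE)
  rownames(m) <- lab
  m <- m[match(channel_labels(), lab), , drop = FALSE]
  if (anyNA(m)) stop("catalog rows do not match the canonical channel order",
                     call. = FALSE)
  sweep(m, 2, colSums(m), "/")
}

#' Rescale a genome-derived catalog to exome trinucleotide frequencies
#'
#' Each channel's weight is multiplied by exome_freq/genome_freq of its
#' trinucleotide context, then each signature is renormalised to sum to 1.
#'
#' @param catalog 96 x S matrix in canonical channel order
#' @param genome_freqs,exome_freqs named (by 32 pyrimidine-centred 3-mers)
#'   strictly positive frequencies
#' @return adjusted catalog, columns summing to 1
#' @export
exome_adjust_catalog <- function(catalog, genome_freqs, exome_freqs) {
  ctx <- .CHANNELS$context
  need <- unique(ctx)
  if (!all(need %in% names(genome_freqs)) || !all(need %in% names(exome_freqs)))
    stop("frequency tables must cover all 32 pyrimidine-centred contexts",
         call. = FALSE)
  if (any(genome_freqs[need] <= 0))
    stop("genome frequencies must be strictly positive", call. = FALSE)
  w <- as.numeric(exome_freqs[ctx] / genome_freqs[ctx])
  adj <- catalog * w
  sweep(adj, 2, colSums(adj), "/")
}

# EM for multinomial mixture exposures; returns exposures and loglik
fit_exposures_em <- function(counts, S, tol = 1e-10, maxit = 5000) {
  k <- ncol(S)
  e <- rep(1 / k, k)
  N <- sum(counts)
  nz <- counts > 0
  n <- counts[nz]; Sz <- S[nz, , drop = FALSE]
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    p <- as.numeric(Sz %*% e)
    p <- pmax(p, 1e-300)
    ll <- sum(n * log(p))
    resp <- sweep(Sz, 2, e, "*") / p          # posterior per channel
    e <- as.numeric(crossprod(resp, n)) / N
    e <- e / sum(e)
    if (ll - ll_old < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  p <- pmax(as.numeric(Sz %*% e), 1e-300)
  list(exposures = e, loglik = sum(n * log(p)) + sum(lgamma(N + 1)) -
         sum(lgamma(n + 1)))
}

# NNLS-on-fractions alternative (projected least squares on the simplex by
# NNLS + renormalisation); kept for cross-checking the likelihood route
fit_exposures_nnls <- function(counts, S) {
  y <- counts / sum(counts)
  # active-set NNLS via repeated lm on the positive support
  k <- ncol(S)
  active <- rep(TRUE, k)
  for (it in seq_len(2 * k)) {
    cf <- rep(0, k)
    cf[active] <- stats::coef(stats::lm.fit(S[, active, drop = FALSE], y))
    if (all(cf >= -1e-12)) break
    active[which.min(cf)] <- FALSE
    if (!any(active)) break
  }
  cf[cf < 0] <- 0
  if (sum(cf) == 0) cf <- rep(1 / k, k)
  cf / sum(cf)
}

#' Fit signature exposures for a fixed signature subset
#'
#' @param spectrum a `spectrum96` (or any 96-vector of counts)
#' @param subset character vector of signature names, all in `catalog`
#' @param catalog 96 x S matrix
#' @param method "mle" (multinomial maximum likelihood, default) or "nnls"
#'   (least squares on fractions, renormalised)
#' @return object of class `signature_fit`: selected (names), exposures
#'   (named fractions summing to 1), loglik, bic = k*log(N) - 2*loglik,
#'   cosine (reconstruction vs observed), n_mutations
#' @export
fit_exposures <- function(spectrum, subset, catalog,
                          method = c("mle", "nnls")) {
  method <- match.arg(method)
  counts <- as.numeric(spectrum)
  if (length(counts) != 96 || sum(counts) <= 0)
    stop("spectrum must be a 96-vector with positive total", call. = FALSE)
  if (!length(subset) || !all(subset %in% colnames(catalog)))
    stop("subset must be a nonempty subset of the catalog signatures",
         call. = FALSE)
  S <- catalog[, subset, drop = FALSE]
  if (method == "mle") {
    r <- fit_exposures_em(counts, S)
    e <- r$exposures; ll <- r$loglik
  } else {
    e <- fit_exposures_nnls(counts, S)
    p <- pmax(as.numeric(S %*% e), 1e-300)
    ll <- sum(counts * log(p)) + lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  }
  names(e) <- subset
  recon <- as.numeric(S %*% e)
  N <- sum(counts)
  structure(list(selected = subset, exposures = e, loglik = ll,
                 bic = length(subset) * log(N) - 2 * ll,
                 cosine = cosine_sim(recon, counts / N),
                 n_mutations = N, method = method),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature decomposition (", x$method, "), N =", x$n_mutations,
      "mutations\n")
  e <- sort(x$exposures, decreasing = TRUE)
  for (nm in names(e))
    cat(sprintf("  %-8s %5.1f%%\n", nm, 100 * e[nm]))
  cat(sprintf("  cosine %.4f, BIC %.1f\n", x$cosine, x$bic))
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' Select the best signature combination by BIC
#'
#' Exhaustive search over all subsets of `candidates` of size <= `max_k`;
#' each subset is fitted by [fit_exposures()] and the minimal-BIC model wins,
#' with ties broken by higher cosine similarity, then by smaller subset.
#'
#' @param spectrum a `spectrum96`
#' @param catalog 96 x S matrix
#' @param candidates signature names to search over; default all catalog
#'   columns
#' @param max_k largest subset size, default 5
#' @param max_models combinatorial budget; exceeding it is an error
#' @return the winning `signature_fit`, with the full search table in
#'   `$search` (subset, bic, cosine)
#' @export
select_signature_model <- function(spectrum, catalog,
                                   candidates = colnames(catalog),
                                   max_k = 5, max_models = 20000) {
  if (!length(candidates)) stop("candidates must be nonempty", call. = FALSE)
  if (max_k < 1) stop("max_k must be >= 1", call. = FALSE)
  max_k <- min(max_k, length(candidates))
  n_models <- sum(choose(length(candidates), seq_len(max_k)))
  if (n_models > max_models)
    stop("subset search of ", n_models, " models exceeds the budget of ",
         max_models, call. = FALSE)
  subsets <- unlist(lapply(seq_len(max_k), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, fit_exposures, spectrum = spectrum, catalog = catalog)
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  cosv <- vapply(fits, `[[`, numeric(1), "cosine")
  sz <- lengths(subsets)
  ord <- order(bic, -cosv, sz)
  best <- fits[[ord[1]]]
  best$search <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    k = sz, bic = bic, cosine = cosv)[ord, ]
  best
}
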