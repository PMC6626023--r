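test_that("spectrum builder honours the pyrimidine-centred strand convention", {
  one <- build_mutation_spectrum(data.frame(ref = "C", alt = "A", context = "ACA"))
  expect_equal(sum(one), 1)
  expect_equal(unname(one[["A[C>A]A"]]), 1L)
  # same channel via the purine strand
  two <- build_mutation_spectrum(data.frame(ref = "G", alt = "T", context = "TGT"))
  expect_equal(unclass(one), unclass(two), ignore_attr = TRUE)
  expect_error(build_mutation_spectrum(data.frame(ref = "C", alt = "C",
                                                  context = "ACA")), "differ")
  expect_error(build_mutation_spectrum(data.frame(ref = "C", alt = "A",
                                                  context = "AGA")), "middle base")
})

test_that("sampled spectra stay close to their source signature", {
  cat <- synthetic_signature_catalog()
  sp <- draw_spectrum(1000, cat[, "SBS1"], seed = 2)
  expect_gt(cosine(sp, cat[, "SBS1"]), 0.95)
})

test_that("exome adjustment rescales by context frequency ratios", {
  cat <- synthetic_signature_catalog()
  ctx32 <- unique(vapply(strsplit(channel_labels(), "\\[|\\]|>"),
                         function(p) paste0(p[1], substr(p[2], 1, 1), p[4]),
                         character(1)))
  g <- setNames(rep(1 / 32, 32), ctx32)
  # identity adjustment leaves the catalog unchanged
  expect_equal(exome_adjust_catalog(cat, g, g), cat, tolerance = 1e-12)
  # doubling one context doubles its channels' relative weight
  e <- g; e["ACA"] <- 2 * g[["ACA"]]
  adj <- exome_adjust_catalog(cat, g, e)
  pre <- cat[, "SBS5"]; post <- adj[, "SBS5"]
  hit <- startsWith(channel_labels(), "A[C") & endsWith(channel_labels(), "]A")
  ratio <- (post[hit] / pre[hit]) / (post[!hit][1] / pre[!hit][1])
  expect_equal(unname(ratio), rep(2, sum(hit)), tolerance = 1e-9)
  expect_equal(unname(colSums(adj)), rep(1, ncol(adj)), tolerance = 1e-9)
  bad <- g; bad["ACA"] <- 0
  expect_error(exome_adjust_catalog(cat, bad, e), "strictly positive")
})

test_that("exposure fitting recovers pure and mixed sources", {
  cat <- synthetic_signature_catalog()
  # exactly proportional to one signature: exposure 1, cosine 1
  sp <- as.integer(round(cat[, "SBS18"] * 1e6))
  fit <- fit_exposures(sp, c("SBS18", "SBS1"), cat)
  expect_equal(unname(fit$exposures["SBS18"]), 1, tolerance = 1e-4)
  expect_gt(fit$cosine, 0.9999)
  # 0.7/0.3 mixture at 10,000 draws
  mix <- 0.7 * cat[, "SBS5"] + 0.3 * cat[, "SBS1"]
  sp2 <- draw_spectrum(10000, mix, seed = 5)
  fit2 <- fit_exposures(sp2, c("SBS5", "SBS1"), cat)
  expect_lt(abs(fit2$exposures[["SBS5"]] - 0.7), 0.05)
  expect_lt(abs(fit2$exposures[["SBS1"]] - 0.3), 0.05)
  expect_equal(sum(fit2$exposures), 1, tolerance = 1e-9)
  # optimum at least as good as uniform exposures
  unif <- rep(1 / 2, 2)
  p <- as.numeric(cat[, c("SBS5", "SBS1")] %*% unif)
  ll_unif <- sum(unclass(sp2) * log(p)) + lgamma(sum(sp2) + 1) -
    sum(lgamma(unclass(sp2) + 1))
  expect_gte(fit2$loglik, ll_unif)
  expect_error(fit_exposures(rep(0L, 96), "SBS1", cat), "positive total")
})

test_that("EM exposures match a fine grid search in the two-signature case", {
  cat <- synthetic_signature_catalog()
  mix <- 0.6 * cat[, "SBS18"] + 0.4 * cat[, "SBS5"]
  sp <- draw_spectrum(5000, mix, seed = 11)
  fit <- fit_exposures(sp, c("SBS18", "SBS5"), cat)
  grid <- seq(0, 1, 0.001)
  counts <- as.numeric(sp)
  ll <- vapply(grid, function(e) {
    p <- pmax(e * cat[, "SBS18"] + (1 - e) * cat[, "SBS5"], 1e-300)
    sum(counts * log(p))
  }, numeric(1))
  expect_lt(abs(fit$exposures[["SBS18"]] - grid[which.max(ll)]), 0.005)
})

test_that("NNLS mode agrees with the likelihood route on clean mixtures", {
  cat <- synthetic_signature_catalog()
  mix <- 0.7 * cat[, "SBS5"] + 0.3 * cat[, "SBS18"]
  sp <- draw_spectrum(20000, mix, seed = 13)
  mle <- fit_exposures(sp, c("SBS5", "SBS18"), cat, method = "mle")
  nnls <- fit_exposures(sp, c("SBS5", "SBS18"), cat, method = "nnls")
  expect_lt(max(abs(mle$exposures - nnls$exposures)), 0.05)
})

test_that("BIC model selection identifies the generating subset", {
  cat <- synthetic_signature_catalog()
  # pure source: parsimony picks the single signature
  sp <- draw_spectrum(5000, cat[, "SBS1"], seed = 3)
  best <- select_signature_model(sp, cat, c("SBS1", "SBS5"), max_k = 2)
  expect_equal(best$selected, "SBS1")
  # two-signature mixture: exactly the two sources, exhaustive agreement
  mix <- 0.7 * cat[, "SBS5"] + 0.3 * cat[, "SBS1"]
  sp2 <- draw_spectrum(10000, mix, seed = 4)
  best2 <- select_signature_model(sp2, cat, colnames(cat), max_k = 3)
  expect_setequal(best2$selected, c("SBS5", "SBS1"))
  # the search table is exhaustive over subset sizes <= max_k
  expect_equal(nrow(best2$search), 6 + 15 + 20)
  expect_equal(best2$bic, min(best2$search$bic))
  expect_error(select_signature_model(sp2, cat, colnames(cat), max_k = 6,
                                      max_models = 10), "budget")
})

test_that("reconstructions are probability vectors", {
  cat <- synthetic_signature_catalog()
  sp <- draw_spectrum(2000, 0.5 * cat[, "SBS1"] + 0.5 * cat[, "SBSA"], seed = 8)
  fit <- fit_exposures(sp, c("SBS1", "SBSA", "SBS5"), cat)
  recon <- as.numeric(cat[, fit$selected] %*% fit$exposures)
  expect_true(all(recon >= 0))
  expect_equal(sum(recon), 1, tolerance = 1e-9)
})

test_that("catalog TSV round-trips through the loader", {
  cat <- synthetic_signature_catalog()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(MutationType = channel_labels(), cat, check.names = FALSE)
  write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_signature_catalog(tmp)
  expect_equal(back, cat, tolerance = 1e-12)
})
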