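test_that("generate_cohort sizes groups, bounds ages, and is reproducible", {
  subj <- generate_cohort(52, 11, c(57, 96), seed = 1)
  expect_equal(nrow(subj), 63)
  expect_equal(unname(table(subj$group)[c("AD", "nonAD")]), c(52L, 11L),
               ignore_attr = TRUE)
  expect_true(all(subj$age >= 57 & subj$age <= 96))
  expect_true(all(subj$braak >= 0 & subj$braak <= 6))
  ad <- subj$group == "AD"
  expect_true(all(subj$age[ad] >= subj$onset_age[ad]))
  expect_true(all(is.na(subj$onset_age[!ad])))
  # byte-identical for the same seed, different for another
  expect_identical(subj, generate_cohort(52, 11, c(57, 96), seed = 1))
  expect_false(identical(subj$age, generate_cohort(52, 11, c(57, 96), seed = 2)$age))
})

test_that("generate_cohort rejects empty cohorts and empty age ranges", {
  expect_error(generate_cohort(0, 0, c(60, 90)), "at least one")
  expect_error(generate_cohort(5, 2, c(90, 60)), "age_range")
  expect_error(generate_cohort(5, 2, numeric(0)), "age_range")
})

test_that("truth-variant counts follow the Poisson age clock", {
  subj70 <- list(subject_id = "S70", age = 70)
  subj90 <- list(subject_id = "S90", age = 90)
  # slope 0: age-independent mean equal to the intercept
  n0 <- vapply(1:300, function(s)
    nrow(generate_truth_variants(subj90, slope = 0, intercept = 10, seed = s)),
    numeric(1))
  expect_lt(abs(mean(n0) - 10), 3 * sqrt(10 / 300))
  # slope 0.53: 20 years of ageing adds ~10.6 expected variants
  d <- vapply(1:1000, function(s)
    nrow(generate_truth_variants(subj90, slope = 0.53, intercept = 2, seed = s)) -
      nrow(generate_truth_variants(subj70, slope = 0.53, intercept = 2, seed = 1000 + s)),
    numeric(1))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.53 * 20), 3 * se)
  expect_error(generate_truth_variants(subj70, slope = -1), "nonnegative")
})

test_that("truth variants carry self-consistent contexts and channels", {
  tv <- generate_truth_variants(list(subject_id = "S", age = 95),
                                intercept = 50, seed = 7)
  expect_true(all(substr(tv$context, 2, 2) == tv$ref))
  recomputed <- mapply(substitution_channel, tv$ref, tv$alt, tv$context)
  expect_equal(unname(recomputed), tv$channel)
  expect_true(all(tv$true_vaf > 0.005 & tv$true_vaf < 0.40))
})

test_that("generated channel frequencies converge to a pure signature", {
  cat <- synthetic_signature_catalog()
  subj <- list(subject_id = "S", age = 80)
  tv <- do.call(rbind, lapply(1:60, function(s)
    generate_truth_variants(subj, slope = 0, intercept = 200,
                            signature_mix = c(SBS1 = 1), seed = s)))
  expect_gt(nrow(tv), 10000)
  sp <- build_mutation_spectrum(tv)
  expect_gt(cosine(sp, cat[, "SBS1"]), 0.99)
})

test_that("allele counts follow the binomial sampling model", {
  # forced VAF 0.5 at depth 100 with zero error: alt centred at 50
  tv <- generate_truth_variants(list(subject_id = "S", age = 90),
                                intercept = 300, slope = 0, seed = 1)
  tv$true_vaf <- 0.5
  zero_err <- setNames(rep(0, 6), c("T>A", "T>C", "T>G", "C>T", "C>G", "C>A"))
  sc <- generate_allele_counts(tv, depth_mean = 100, n_panel = 2,
                               error_table = zero_err, seed = 2)
  case <- sc[sc$role == "case_tissue", ]
  expect_lt(abs(mean(case$alt_count / case$depth) - 0.5), 0.01)
  # panel and matched normal see zero alt under zero error
  expect_true(all(sc$alt_count[sc$role != "case_tissue"] == 0))
  expect_true(all(sc$alt_count >= 0 & sc$alt_count <= sc$depth))
  expect_true(all(sc$depth > 0))
})

test_that("decoy-only tables reproduce the configured background rate", {
  empty <- generate_truth_variants(list(subject_id = "S", age = 50),
                                   slope = 0, intercept = 0, seed = 1)
  sc <- generate_allele_counts(empty, depth_mean = 584, n_panel = 1,
                               n_decoys = 10000, seed = 5)
  case <- sc[sc$role == "case_tissue", ]
  cls <- vapply(seq_len(nrow(case)), function(i)
    normalize_substitution(case$ref[i], case$alt[i])$class, character(1))
  ct <- case[cls == "C>T", ]
  pooled <- sum(ct$alt_count) / sum(ct$depth)
  rate <- default_background_errors()[["C>T"]]
  se <- sqrt(rate * (1 - rate) / sum(ct$depth))
  expect_lt(abs(pooled - rate), 4 * se)
  expect_false(any(sc$is_truth))
})

test_that("site count table covers every truth variant and n_panel samples", {
  tv <- generate_truth_variants(list(subject_id = "S", age = 85),
                                intercept = 20, seed = 3)
  sc <- generate_allele_counts(tv, n_panel = 21, n_decoys = 5, seed = 4)
  case <- sc[sc$role == "case_tissue" & sc$is_truth, ]
  expect_setequal(paste(case$pos, case$alt), paste(tv$pos, tv$alt))
  expect_equal(sum(sc$role == "panel") / length(unique(paste(sc$pos, sc$alt))), 21)
  expect_error(generate_allele_counts(tv, error_table = c("C>T" = 1e-3)),
               "six substitution classes")
})
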