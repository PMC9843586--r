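sim_profile <- function(n = 120, n_signal = 3, n_noise = 12, flip = 0.05,
                        seed = 1) {
  # signal pairs follow the status (with a small flip rate), noise pairs are coin flips
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    bits <- rbind(
      t(replicate(n_signal, ifelse(runif(n) < flip, labels, 1 - labels))),
      matrix(rbinom(n_noise * n, 1, 0.5), nrow = n_noise)
    )
  })
  co <- cohort_from_bits(bits, os_time = rexp(n) + 0.01, event = rep(1L, n))
  records <- tibble::tibble(
    gene_i = sprintf("GI%02d", seq_len(n_signal + n_noise)),
    gene_j = sprintf("GJ%02d", seq_len(n_signal + n_noise)),
    orientation = "i>j",
    p_value = seq_len(n_signal + n_noise) * 1e-8
  )
  list(
    profile = pair_profile(co$expression, records),
    labels = labels, cohort = co
  )
}

test_that("stability selection keeps signal pairs and rejects noise", {
  sp <- sim_profile(seed = 31)
  sel <- stability_lasso_select(sp$profile, sp$labels,
                                n_repeats = 20, freq_threshold = 0.8, seed = 5)
  expect_true(all(sel$frequency[1:3] == 1))
  expect_true(all(sel$selected[1:3]))
  expect_true(mean(sel$selected[-(1:3)]) < 0.5)

  sel2 <- stability_lasso_select(sp$profile, sp$labels,
                                 n_repeats = 20, freq_threshold = 0.8, seed = 5)
  expect_identical(sel$frequency, sel2$frequency)
})

test_that("a single stability repeat reduces to one penalized fit's support", {
  sp <- sim_profile(seed = 13)
  sel <- stability_lasso_select(sp$profile, sp$labels,
                                n_repeats = 1, freq_threshold = 0.5, seed = 2)
  expect_true(all(sel$frequency %in% c(0, 1)))
  expect_identical(sel$selected, sel$frequency == 1)
  expect_true(all(sel$selected[1:3]))
})

test_that("constant profile rows are dropped with a warning", {
  bits <- rbind(c(1, 1, 1, 1, 1, 1), c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 1, 0))
  co <- cohort_from_bits(bits, os_time = 1:6, event = rep(1L, 6))
  prof <- pair_profile(co$expression, tibble::tibble(
    gene_i = sprintf("GI%02d", 1:3), gene_j = sprintf("GJ%02d", 1:3),
    orientation = "i>j", p_value = 1e-8
  ))
  expect_warning(
    sel <- stability_lasso_select(prof, c(0, 1, 0, 1, 0, 1), n_repeats = 1, seed = 1),
    "constant"
  )
  expect_identical(nrow(sel), 2L)
})

test_that("fitted signatures separate classes with risk-polarity coefficients", {
  # one pair whose risk ordering exactly matches the unfavorable status
  labels <- c(1, 1, 1, 0, 0, 0, 1, 0) # favorable status
  bits <- matrix(1 - labels, nrow = 1) # risk ordering present iff unfavorable
  co <- cohort_from_bits(bits, os_time = 1:8, event = rep(1L, 8))
  records <- tibble::tibble(gene_i = "GI01", gene_j = "GJ01",
                            orientation = "i>j", p_value = 1e-8)
  prof <- pair_profile(co$expression, records)
  sig <- fit_signature(prof, labels, status_name = "s")
  expect_gt(sig$pairs$coefficient[1], 0)
  expect_true(isTRUE(sig$provenance$separation_fallback)) # perfect separation
  sc <- risk_score(sig, co$expression)
  expect_gt(min(sc$score[labels == 0]), max(sc$score[labels == 1]))

  # risk class equals 1 - status once a cutoff between the two groups is set
  sig$cutoff <- mean(range(sc$score))
  cls <- classify_risk(sig, co$expression)
  expect_identical(cls$risk == "high", labels == 0)
})

test_that("uninformative profiles yield near-chance training discrimination", {
  aucs <- purrr::map_dbl(1:10, function(s) {
    withr::with_seed(100 + s, {
      labels <- rep(c(0L, 1L), each = 150)
      bits <- matrix(rbinom(4 * 300, 1, 0.5), nrow = 4)
    })
    co <- cohort_from_bits(bits, os_time = rep(1, 300), event = rep(1L, 300))
    prof <- pair_profile(co$expression, tibble::tibble(
      gene_i = sprintf("GI%02d", 1:4), gene_j = sprintf("GJ%02d", 1:4),
      orientation = "i>j", p_value = 1e-8
    ))
    sig <- fit_signature(prof, labels)
    label_auc(risk_score(sig, co$expression)$score, 1 - labels)
  })
  # training AUC is optimistically biased by the in-sample fit; with four
  # binary features and n = 300 the bias stays well below 0.1
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("risk scores obey the linear-predictor contract and monotone invariance", {
  labels <- c(1, 1, 0, 0)
  bits <- matrix(1 - labels, nrow = 1)
  co <- cohort_from_bits(bits, os_time = 1:4, event = rep(1L, 4))
  records <- tibble::tibble(gene_i = "GI01", gene_j = "GJ01",
                            orientation = "i>j", p_value = 1e-8)
  sig <- fit_signature(pair_profile(co$expression, records), labels)

  # samples with no risk orderings score exactly the intercept
  sc <- risk_score(sig, co$expression)
  expect_equal(sc$score[labels == 1], rep(sig$intercept, 2))

  # a zero-coefficient pair changes nothing
  sig2 <- sig
  sig2$pairs <- dplyr::bind_rows(
    sig$pairs,
    tibble::tibble(gene_i = "GJ01", gene_j = "GI01", orientation = "i>j",
                   coefficient = 0, p_value = 1e-8, selection_frequency = 1)
  )
  expect_equal(risk_score(sig2, co$expression)$score, sc$score)

  dist <- apply_monotone_distortion(co$expression, seed = 6)
  expect_equal(risk_score(sig, dist)$score, sc$score)

  expect_error(risk_score(sig, co$expression[2, , drop = FALSE]), "lacks")
})

test_that("optimal cutoffs: mean rule, log-rank recovery, and degenerate input", {
  expect_equal(
    optimal_cutoff(c(0, 0, 2, 2), c(1, 2, 3, 4), c(1, 1, 1, 1), method = "mean"),
    1
  )
  expect_error(optimal_cutoff(rep(1, 20), 1:20, rep(1, 20)), "identical")

  withr::with_seed(17, {
    sc <- c(rnorm(40, 0, 0.1), rnorm(40, 5, 0.1))
    times <- c(rexp(40, 0.05), rexp(40, 1))
  })
  cut <- optimal_cutoff(sc, times, rep(1, 80), method = "logrank-max")
  expect_true(all(sc[1:40] <= cut))
  expect_true(all(sc[41:80] > cut))
})

test_that("classification at the cutoff boundary is low risk", {
  labels <- c(1, 1, 0, 0)
  bits <- matrix(1 - labels, nrow = 1)
  co <- cohort_from_bits(bits, os_time = 1:4, event = rep(1L, 4))
  sig <- make_signature(pairs_tbl(1)[, 1:4], intercept = 0, cutoff = 1)
  # risk bit 1 => score = 1 = cutoff exactly => low risk under strict >
  cls <- classify_risk(sig, co$expression)
  expect_true(all(cls$risk == "low"))
  sig$cutoff <- 0.5
  cls2 <- classify_risk(sig, co$expression)
  expect_identical(cls2$risk, ifelse(bits[1, ] == 1, "high", "low"))
})

test_that("build_signature is deterministic end to end", {
  cfg <- sim_config(n_samples = 120, n_genes = 150, n_planted_pairs_s1 = 4,
                    n_planted_pairs_s2 = 0, seed = 19)
  sim <- suppressMessages(generate_cohort(cfg))
  s1 <- suppressWarnings(suppressMessages(
    build_signature(sim$cohort, "status1", top_k = 20, n_repeats = 10, seed = 3)
  ))
  s2 <- suppressWarnings(suppressMessages(
    build_signature(sim$cohort, "status1", top_k = 20, n_repeats = 10, seed = 3)
  ))
  expect_equal(s1$pairs, s2$pairs)
  expect_equal(s1$intercept, s2$intercept)
  expect_equal(s1$cutoff, s2$cutoff)
  expect_s3_class(tidy(s1), "tbl_df")
  expect_identical(glance(s1)$n_pairs, nrow(s1$pairs))
})
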