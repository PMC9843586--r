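test_that("rank transform uses ascending average ranks and demands complete data", {
  m <- matrix(c(5.2, 1.1, 3.3, 2.0, 2.0, 1.0), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  r <- rank_transform(m)
  expect_equal(unname(r[, "S1"]), c(3, 1, 2))
  expect_equal(unname(r[, "S2"]), c(2.5, 2.5, 1))
  expect_equal(unname(colSums(r)), rep(3 * 4 / 2, 2))

  m[2, 1] <- NA
  expect_error(rank_transform(m), "gene 'b'.*sample 'S1'")
})

test_that("rank transform is invariant to random strictly monotone maps", {
  withr::with_seed(21, {
    expr <- matrix(rexp(50 * 8) + 0.1, nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
    for (s in 1:5) {
      expect_identical(
        rank_transform(expr),
        rank_transform(apply_monotone_distortion(expr, seed = s))
      )
    }
  })
})

test_that("mean rank deviation is the between-group mean difference and antisymmetric", {
  ranks <- rbind(
    g1 = c(10, 10, 4, 6),
    g2 = c(3, 3, 3, 3),
    g3 = c(1, 2, 8, 6)
  )
  colnames(ranks) <- sprintf("s%d", 1:4)
  labels <- c(1, 1, 0, 0)
  dev <- mean_rank_deviation(ranks, labels)
  expect_equal(dev$deviation[dev$gene_id == "g1"], 10 - 5)
  expect_equal(dev$deviation[dev$gene_id == "g2"], 0)
  dev_flip <- mean_rank_deviation(ranks, 1 - labels)
  expect_equal(dev_flip$deviation, -dev$deviation)
  expect_error(mean_rank_deviation(ranks, c(1, 1, 1, 1)), "Both status classes")
})

test_that("candidate selection takes floor(fraction*G) per side with deterministic ties", {
  dev <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    deviation = c(10, 9, rep(0, 16), -9, -10)
  )
  cands <- select_candidate_genes(dev, fraction = 0.1)
  expect_identical(cands$up, c("g01", "g02"))
  expect_identical(cands$down, c("g20", "g19"))

  # all-tied deviations: selection falls back to gene-id order, reproducibly
  dev0 <- tibble::tibble(gene_id = sample(sprintf("g%02d", 1:20)), deviation = 0)
  c1 <- select_candidate_genes(dev0, fraction = 0.1)
  c2 <- select_candidate_genes(dev0[sample(1:20), ], fraction = 0.1)
  expect_identical(c1$up, c2$up)
  expect_identical(c1$up, c("g01", "g02"))

  # label inversion swaps the up and down sets
  cands_flip <- select_candidate_genes(
    dplyr::mutate(dev, deviation = -deviation), fraction = 0.1
  )
  expect_identical(cands_flip$up, cands$down)
  expect_identical(cands_flip$down, cands$up)

  expect_error(select_candidate_genes(dev, fraction = 0.01), "below 1")
  pairs <- enumerate_pairs(list(up = cands$up, down = c("x", "y", "z")))
  expect_identical(nrow(pairs), 6L)
  expect_false(any(pairs$gene_i == pairs$gene_j))
})

test_that("pair ordering counts match their definition and drop ties", {
  # 5 status-0 samples with Gi > Gj, 5 status-1 samples with Gi < Gj
  bits <- matrix(c(rep(1, 5), rep(0, 5)), nrow = 1)
  co <- cohort_from_bits(bits, os_time = rep(1, 10), event = rep(1L, 10))
  labels <- c(rep(0, 5), rep(1, 5))
  rec <- pair_order_counts(
    co$expression, tibble::tibble(gene_i = "GI01", gene_j = "GJ01"), labels
  )
  expect_identical(c(rec$a, rec$b, rec$c, rec$d, rec$ties), c(5L, 0L, 0L, 5L, 0L))

  # a tie is counted separately
  expr <- co$expression
  expr["GI01", 1] <- expr["GJ01", 1]
  rec2 <- pair_order_counts(
    expr, tibble::tibble(gene_i = "GI01", gene_j = "GJ01"), labels
  )
  expect_identical(c(rec2$a, rec2$ties), c(4L, 1L))

  # label inversion maps (a,b,c,d) -> (c,d,a,b)
  rec3 <- pair_order_counts(
    co$expression, tibble::tibble(gene_i = "GI01", gene_j = "GJ01"), 1 - labels
  )
  expect_identical(c(rec3$a, rec3$b, rec3$c, rec3$d), c(rec$c, rec$d, rec$a, rec$b))

  expect_error(
    pair_order_counts(co$expression, tibble::tibble(gene_i = "nope", gene_j = "GJ01"), labels),
    "nope"
  )
})

test_that("log-space Fisher test matches enumeration, fisher.test, and symmetry", {
  expect_equal(fisher_reversal_test(5, 5, 5, 5), 1)

  # label inversion leaves p unchanged
  expect_equal(
    fisher_reversal_test(17, 3, 4, 21),
    fisher_reversal_test(4, 21, 17, 3)
  )

  withr::with_seed(12, {
    for (k in 1:40) {
      a <- rpois(1, 8); b <- rpois(1, 8) + 1
      c <- rpois(1, 8) + 1; d <- rpois(1, 8)
      p <- fisher_reversal_test(a, b, c, d)
      expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
      expect_equal(
        p, stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
        tolerance = 1e-9
      )
    }
  })

  # far below double underflow for naive products, still exact and positive
  p_tiny <- fisher_reversal_test(400, 0, 0, 420)
  expect_gt(p_tiny, 0)
  expect_lt(p_tiny, 1e-200)
  lp <- fisher_reversal_test(400, 0, 0, 420, log.p = TRUE)
  expect_equal(exp(lp), p_tiny)

  expect_error(fisher_reversal_test(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_reversal_test(0, 0, 3, 4), "at least one")
})

test_that("detect_reverse_pairs recovers planted pairs and honors its contract", {
  cfg <- sim_config(n_samples = 200, n_genes = 500, n_planted_pairs_s1 = 10,
                    n_planted_pairs_s2 = 0, reversal_strength = 2,
                    noise_sd = 1, seed = 2)
  sim <- suppressMessages(generate_cohort(cfg))
  rec <- detect_reverse_pairs(sim$cohort, "status1", top_k = 50)
  expect_lte(nrow(rec), 50L)
  expect_true(!is.unsorted(rec$p_value))
  truth_key <- paste(sim$truth$planted_pairs_s1$gene_up,
                     sim$truth$planted_pairs_s1$gene_down)
  top10 <- paste(rec$gene_i, rec$gene_j)[1:10]
  expect_gte(sum(top10 %in% truth_key), 9)

  # planted pairs: the favorable-status-typical ordering is gene_up > gene_down,
  # so the risk orientation must be "i<j"
  expect_true(all(rec$orientation[1:10][top10 %in% truth_key] == "i<j"))

  expect_error(detect_reverse_pairs(sim$cohort, "nope"), "not found")
})

test_that("unknown-status samples are excluded from the screen", {
  cfg <- sim_config(n_samples = 60, n_genes = 100, n_planted_pairs_s1 = 2,
                    n_planted_pairs_s2 = 0, seed = 8)
  sim <- suppressMessages(generate_cohort(cfg))
  co <- sim$cohort
  co$clinical$status1[1:10] <- NA
  expect_message(
    rec <- suppressWarnings(detect_reverse_pairs(co, "status1", top_k = 5)),
    "unknown"
  )
  expect_identical(
    attr(rec, "n_status0") + attr(rec, "n_status1"), 50L
  )
})

test_that("pair profiles encode orientations with ties scoring zero", {
  bits <- rbind(c(1, 1, 0, 0), c(0, 1, 0, 1))
  co <- cohort_from_bits(bits, os_time = 1:4, event = rep(1L, 4))
  records <- tibble::tibble(
    gene_i = c("GI01", "GI02"), gene_j = c("GJ01", "GJ02"),
    orientation = c("i>j", "i<j")
  )
  prof <- pair_profile(co$expression, records)
  # pair 1 risk ordering is i>j: risk bits = bits row 1
  expect_equal(unname(prof$risk[1, ]), bits[1, ])
  expect_equal(unname(prof$reversed[1, ]), 1 - bits[1, ])
  # pair 2 risk ordering is i<j: risk bits are the complement of row 2
  expect_equal(unname(prof$risk[2, ]), 1 - bits[2, ])

  expr <- co$expression
  expr["GI01", 1] <- expr["GJ01", 1] # tie
  prof2 <- pair_profile(expr, records)
  expect_equal(prof2$risk[1, 1], 0)
  expect_equal(prof2$reversed[1, 1], 0)

  dist <- apply_monotone_distortion(co$expression, seed = 4)
  prof3 <- pair_profile(dist, records)
  expect_identical(prof$risk, prof3$risk)
  expect_identical(prof$reversed, prof3$reversed)
})
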