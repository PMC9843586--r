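# Independent oracles, deliberately written against the definitions rather
# than against the package internals.

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, point masses from lchoose arithmetic (no dhyper), summing masses
# not exceeding the observed one (same 1e-7 relative tie tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  xs <- lo:hi
  log_mass <- vapply(xs, function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }, numeric(1))
  obs <- log_mass[xs == a]
  sum_keep <- log_mass[log_mass <= obs + 1e-7]
  m <- max(sum_keep)
  min(exp(m) * sum(exp(sum_keep - m)), 1)
}

# Harrell's C by exhaustive pair enumeration. Pairs are comparable when the
# earlier time is an observed event (distinct times assumed in fixtures);
# concordant when the earlier death has the higher risk score, tied scores
# count one half.
oracle_cindex <- function(scores, times, events) {
  num <- 0
  den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      first <- if (times[i] < times[j]) i else j
      second <- if (times[i] < times[j]) j else i
      if (events[first] != 1) next
      den <- den + 1
      if (scores[first] > scores[second]) {
        num <- num + 1
      } else if (scores[first] == scores[second]) {
        num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Horizon AUC by exhaustive case/control pair counting.
oracle_auc <- function(scores, times, events, horizon) {
  case <- which(events == 1 & times <= horizon)
  control <- which(times > horizon)
  num <- 0
  for (i in case) {
    for (j in control) {
      num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  num / (length(case) * length(control))
}

# AUC of a score against binary labels (for status-discrimination checks).
label_auc <- function(score, labels) {
  r <- rank(score)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A tiny cohort with hand-chosen expression orderings.
# bits: pairs x samples matrix of desired risk-ordering indicators for
# orientation "i>j" (1 means gene_i > gene_j in that sample).
cohort_from_bits <- function(bits, os_time, event, status = NULL) {
  n_pairs <- nrow(bits)
  n <- ncol(bits)
  expr <- matrix(0, nrow = 2 * n_pairs, ncol = n)
  genes <- character(2 * n_pairs)
  for (k in seq_len(n_pairs)) {
    gi <- sprintf("GI%02d", k)
    gj <- sprintf("GJ%02d", k)
    genes[2 * k - 1] <- gi
    genes[2 * k] <- gj
    expr[2 * k - 1, ] <- ifelse(bits[k, ] == 1, 2, 1)
    expr[2 * k, ] <- ifelse(bits[k, ] == 1, 1, 2)
  }
  rownames(expr) <- genes
  colnames(expr) <- sprintf("S%03d", seq_len(n))
  clinical <- tibble::tibble(
    sample_id = colnames(expr),
    os_time = os_time,
    event = event
  )
  if (!is.null(status)) clinical$status <- status
  structure(
    list(expression = expr, clinical = clinical),
    class = "pair_cohort"
  )
}

pairs_tbl <- function(n_pairs, orientation = "i>j", source = "status") {
  tibble::tibble(
    gene_i = sprintf("GI%02d", seq_len(n_pairs)),
    gene_j = sprintf("GJ%02d", seq_len(n_pairs)),
    orientation = orientation,
    p_value = seq_len(n_pairs) * 1e-10,
    source = source
  )
}

make_panel <- function(pairs, vote_threshold = 0.5) {
  pairsig:::new_ensemble_panel(
    pairs = pairs, vote_threshold = vote_threshold,
    criterion = "cindex",
    trace = tibble::tibble(
      step = seq_len(nrow(pairs)),
      gene_i = pairs$gene_i, gene_j = pairs$gene_j,
      action = "kept", score = NA_real_
    )
  )
}

make_signature <- function(pairs, intercept = 0, cutoff = 0.5,
                           status_name = "status") {
  pairsig:::new_gene_pair_signature(
    status_name = status_name,
    pairs = dplyr::mutate(
      pairs,
      coefficient = 1, selection_frequency = 1
    ),
    intercept = intercept,
    cutoff = cutoff,
    cutoff_method = "mean",
    provenance = list(seed = 1L)
  )
}
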