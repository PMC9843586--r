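#' Within-sample rank transform
#'
#' Replaces each sample's expression values by their ranks within that sample
#' (1 = lowest expression), with average ranks for exact ties. Every column of
#' the result sums to G(G+1)/2. The transform — and everything downstream of
#' it — is invariant to any strictly increasing per-sample map of the values.
#'
#' @param expr Numeric genes-by-samples matrix with no missing values.
#' @return Matrix of the same shape holding per-sample ranks.
#' @export
rank_transform <- function(expr) {
  if (anyNA(expr)) {
    idx <- which(is.na(expr), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing expression value for gene '%s', sample '%s'; exclude incomplete genes first.",
      rownames(expr)[idx[1]], colnames(expr)[idx[2]]
    ))
  }
  apply(expr, 2, rank, ties.method = "average")
}

#' Mean rank deviation between two status groups
#'
#' For each gene, the mean within-sample rank across status-1 samples minus
#' the mean across status-0 samples. Positive deviation = the gene sits higher
#' in the within-sample ordering when the status is present ("upregulated"
#' in rank space).
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param labels Binary 0/1 vector, one per sample (column).
#' @return A tibble with columns `gene_id` and `deviation`, in gene order.
#' @export
mean_rank_deviation <- function(ranks, labels) {
  labels <- as.integer(labels)
  if (length(labels) != ncol(ranks)) abort("One label per sample required.")
  if (length(unique(labels)) < 2) abort("Both status classes must be present.")
  m1 <- rowMeans(ranks[, labels == 1, drop = FALSE])
  m0 <- rowMeans(ranks[, labels == 0, drop = FALSE])
  tibble(gene_id = rownames(ranks), deviation = unname(m1 - m0))
}

#' Select candidate up- and down-regulated genes by mean rank deviation
#'
#' Takes the `floor(fraction * G)` genes with the largest positive deviation
#' (up in status-1) and the same number with the most negative deviation.
#' Ties in deviation are broken deterministically by gene id so the selection
#' is platform-independent.
#'
#' @param deviation Tibble from [mean_rank_deviation()].
#' @param fraction Fraction of genes per direction, in (0, 0.5]; default 0.10.
#' @return A list with character vectors `up` and `down` (disjoint) and the
#'   `fraction` used.
#' @export
select_candidate_genes <- function(deviation, fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5) abort("fraction must lie in (0, 0.5].")
  g <- nrow(deviation)
  k <- floor(fraction * g)
  if (k < 1) abort("fraction * number of genes is below 1; nothing to select.")
  ord_up <- order(-deviation$deviation, deviation$gene_id)
  ord_down <- order(deviation$deviation, deviation$gene_id)
  up <- deviation$gene_id[ord_up[seq_len(k)]]
  down <- deviation$gene_id[ord_down[seq_len(k)]]
  if (length(intersect(up, down)) > 0) {
    # only possible when 2k = G and deviations tie across the midline
    overlap <- intersect(up, down)
    down <- setdiff(down, overlap)
  }
  list(up = up, down = down, fraction = fraction)
}

#' Enumerate candidate gene pairs as the full up-by-down cross product
#'
#' @param cands Candidate sets from [select_candidate_genes()].
#' @return Tibble with columns `gene_i` (up gene) and `gene_j` (down gene),
#'   in deterministic order (up-major).
#' @export
enumerate_pairs <- function(cands) {
  if (length(cands$up) == 0 || length(cands$down) == 0) {
    abort("Both candidate sets must be nonempty.")
  }
  tidyr::expand_grid(gene_i = cands$up, gene_j = cands$down)
}

#' Count the ordering contingency table of gene pairs across status groups
#'
#' For each pair (i, j) and binary labels, counts
#' `a = #(G_i > G_j | status 0)`, `b = #(G_i < G_j | status 0)`,
#' `c = #(G_i > G_j | status 1)`, `d = #(G_i < G_j | status 1)`.
#' Exact expression ties are counted in `ties` and excluded from a-d (a tie
#' is not evidence of either ordering).
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param pairs Tibble with columns `gene_i`, `gene_j`.
#' @param labels Binary 0/1 vector, one per sample.
#' @return `pairs` with integer columns `a`, `b`, `c`, `d`, `ties` appended.
#' @export
pair_order_counts <- function(expr, pairs, labels) {
  labels <- as.integer(labels)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    abort(paste0("Unknown gene(s): ", paste(missing_genes, collapse = ", ")))
  }
  e_i <- expr[pairs$gene_i, , drop = FALSE]
  e_j <- expr[pairs$gene_j, , drop = FALSE]
  gt <- e_i > e_j
  lt <- e_i < e_j
  s0 <- labels == 0
  s1 <- labels == 1
  pairs |>
    mutate(
      a = as.integer(rowSums(gt[, s0, drop = FALSE])),
      b = as.integer(rowSums(lt[, s0, drop = FALSE])),
      c = as.integer(rowSums(gt[, s1, drop = FALSE])),
      d = as.integer(rowSums(lt[, s1, drop = FALSE])),
      ties = as.integer(sum(s0) + sum(s1) - .data$a - .data$b - .data$c - .data$d)
    )
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(lx - m)))
}

fisher_log_p_one <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  lp <- dhyper(x, r1, r2, c1, log = TRUE)
  lobs <- lp[x == a]
  # two-sided: sum point masses not exceeding the observed mass, with the
  # customary 1e-7 relative tolerance for floating-point knife-edge ties
  min(log_sum_exp(lp[lp <= lobs + 1e-7]), 0)
}

#' Two-sided Fisher's exact test for ordering reversal, in log space
#'
#' Tests independence of the 2x2 table `[[a, b], [c, d]]` of pair-ordering
#' counts by summing all hypergeometric point masses (with the observed
#' margins) that do not exceed the observed mass. All arithmetic is on
#' log-probabilities via the log-gamma function, so p-values far below the
#' double-precision underflow of naive products (down to ~1e-300) are exact;
#' strong reversal pairs in cohorts of several hundred samples routinely
#' reach p ~ 1e-95.
#'
#' @param a,b,c,d Non-negative integer count vectors (recycled to a common
#'   length); each table needs `a + b > 0` and `c + d > 0`.
#' @param log.p If `TRUE`, return the natural-log p-value.
#' @return Numeric vector of two-sided p-values in (0, 1] (or their logs).
#' @export
#' @examples
#' fisher_reversal_test(5, 5, 5, 5) # exactly 1
fisher_reversal_test <- function(a, b, c, d, log.p = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n)
  d <- rep_len(as.integer(d), n)
  if (any(c(a, b, c, d) < 0)) abort("Counts must be non-negative.")
  if (any(a + b == 0) || any(c + d == 0)) {
    abort("Each status group must contribute at least one untied ordering.")
  }
  lp <- vapply(
    seq_len(n),
    function(k) fisher_log_p_one(a[k], b[k], c[k], d[k]),
    numeric(1)
  )
  if (log.p) lp else exp(lp)
}

risk_orientation <- function(a, b) {
  # the ordering commoner among status-0 samples is the risk ordering
  ifelse(a >= b, "i>j", "i<j")
}

#' Detect reverse gene pairs for one genomic status
#'
#' Runs the full screen for a single binary status: within-sample rank
#' transform, mean rank deviation between the status groups, selection of the
#' top `fraction` up- and down-regulated candidate genes, enumeration of all
#' up-by-down pairs, ordering counts, and a two-sided Fisher's exact test per
#' pair. Pairs are Bonferroni-filtered at `alpha` over the full pair search
#' space — all `choose(G, 2)` orderable pairs of included genes, not merely
#' the enumerated up-by-down products, because the candidate sets are chosen
#' with the same labels the test uses and a correction over the enumerated
#' pairs alone would be anti-conservative. Surviving pairs are ranked by
#' ascending p (ties broken by larger normalized odds
#' `|ad - bc| / ((a+b)(c+d))`, then lexicographic pair id), and the top
#' `top_k` returned.
#'
#' Samples with unknown status are excluded from this screen; genes with any
#' missing expression value are excluded from candidate selection.
#'
#' @param cohort A `pair_cohort` from [align_cohort()] or [generate_cohort()].
#' @param status Name of the binary status column in `cohort$clinical`
#'   (1 = the favorable genomic state, e.g. IDH-mutant).
#' @param fraction Candidate-gene fraction per direction (default 0.10).
#' @param top_k Number of reverse pairs to keep (default 50).
#' @param alpha Significance floor before truncation, Bonferroni-corrected
#'   over all orderable gene pairs; `NULL` disables the filter.
#' @return A tibble of reversal records, one row per retained pair, with
#'   columns `gene_i`, `gene_j`, `a`, `b`, `c`, `d`, `ties`, `p_value` and
#'   `orientation` (`"i>j"` or `"i<j"`: the risk ordering, i.e. the one
#'   commoner in status-0 samples). Attributes record the status name, group
#'   sizes and number of enumerated pairs.
#' @export
detect_reverse_pairs <- function(cohort, status, fraction = 0.10,
                                 top_k = 50, alpha = 0.05) {
  stopifnot(inherits(cohort, "pair_cohort"))
  if (!status %in% colnames(cohort$clinical)) {
    abort(sprintf("Status column '%s' not found in clinical table.", status))
  }
  labels_all <- cohort$clinical[[status]]
  keep <- !is.na(labels_all)
  if (sum(keep) < length(labels_all)) {
    inform(sprintf(
      "detect_reverse_pairs: dropping %d sample(s) with unknown '%s' status.",
      sum(!keep), status
    ))
  }
  labels <- as.integer(labels_all[keep])
  if (length(unique(labels)) < 2) {
    abort(sprintf("Status '%s' has a single class among annotated samples.", status))
  }
  expr <- cohort$expression[, keep, drop = FALSE]
  incomplete <- union(
    attr(cohort$expression, "incomplete_genes") %||% character(),
    rownames(expr)[rowSums(is.na(expr)) > 0]
  )
  if (length(incomplete) > 0) {
    inform(sprintf(
      "detect_reverse_pairs: excluding %d gene(s) with missing values.",
      length(incomplete)
    ))
    expr <- expr[setdiff(rownames(expr), incomplete), , drop = FALSE]
  }

  ranks <- rank_transform(expr)
  dev <- mean_rank_deviation(ranks, labels)
  cands <- select_candidate_genes(dev, fraction = fraction)
  pairs <- enumerate_pairs(cands)
  n_enumerated <- nrow(pairs)
  n_tests <- choose(nrow(expr), 2)

  records <- pair_order_counts(expr, pairs, labels)
  usable <- records$a + records$b > 0 & records$c + records$d > 0
  records <- records[usable, , drop = FALSE]
  records$p_value <- fisher_reversal_test(
    records$a, records$b, records$c, records$d
  )
  records$orientation <- risk_orientation(records$a, records$b)

  if (!is.null(alpha)) {
    records <- filter(records, .data$p_value <= alpha / n_tests)
  }
  records <- records |>
    mutate(
      .odds = abs(.data$a * .data$d - .data$b * .data$c) /
        pmax((.data$a + .data$b) * (.data$c + .data$d), 1)
    ) |>
    arrange(.data$p_value, desc(.data$.odds), .data$gene_i, .data$gene_j) |>
    select(-".odds")
  if (nrow(records) < top_k) {
    warn(sprintf(
      "Only %d pair(s) pass the significance floor (top_k = %d requested).",
      nrow(records), top_k
    ))
  }
  records <- head(records, top_k)
  attr(records, "status_name") <- status
  attr(records, "n_status0") <- sum(labels == 0)
  attr(records, "n_status1") <- sum(labels == 1)
  attr(records, "n_enumerated") <- n_enumerated
  attr(records, "n_tests") <- n_tests
  records
}

#' Binary pair-ordering profile of a sample set
#'
#' Converts expression to the per-pair, per-sample ordering indicators used as
#' model features. For each reversal record two complementary encodings are
#' produced: `reversed` is 1 when the sample shows the status-1-typical
#' (favorable-typical) ordering, and `risk` is 1 when it shows the risk
#' (status-0-typical) ordering under the record's orientation. An exact
#' expression tie scores 0 in both (a tie is evidence of neither ordering).
#' Both matrices are invariant to strictly monotone per-sample transforms.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param records Reversal records (tibble with `gene_i`, `gene_j`,
#'   `orientation`).
#' @return A `pair_profile` object: list with `pairs` (the records), and
#'   pairs-by-samples binary matrices `reversed` and `risk`.
#' @export
pair_profile <- function(expr, records) {
  genes <- unique(c(records$gene_i, records$gene_j))
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    abort(paste0("Unknown gene(s): ", paste(missing_genes, collapse = ", ")))
  }
  e_i <- expr[records$gene_i, , drop = FALSE]
  e_j <- expr[records$gene_j, , drop = FALSE]
  gt <- e_i > e_j
  lt <- e_i < e_j
  risk_is_gt <- records$orientation == "i>j"
  risk <- ifelse(risk_is_gt, 1, 0) * gt + ifelse(risk_is_gt, 0, 1) * lt
  reversed <- ifelse(risk_is_gt, 0, 1) * gt + ifelse(risk_is_gt, 1, 0) * lt
  pair_ids <- paste(records$gene_i, records$gene_j, sep = "|")
  dimnames(risk) <- dimnames(reversed) <- list(pair_ids, colnames(expr))
  structure(
    list(
      pairs = records,
      reversed = reversed * 1,
      risk = risk * 1
    ),
    class = "pair_profile"
  )
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf(
    "<pair_profile> %d pairs x %d samples\n",
    nrow(x$reversed), ncol(x$reversed)
  ))
  invisible(x)
}
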