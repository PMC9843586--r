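new_ensemble_panel <- function(pairs, vote_threshold, criterion, trace,
                               provenance = list()) {
  structure(
    list(
      pairs = pairs,
      vote_threshold = vote_threshold,
      criterion = criterion,
      trace = trace,
      provenance = provenance
    ),
    class = "ensemble_panel"
  )
}

#' Pool the oriented pairs of two single-status signatures
#'
#' Combines the pairs of both signatures into one candidate list on a common
#' risk polarity (each pair's risk ordering votes FOR high risk — the
#' ordering typical of the unfavorable state of its source status).
#' Duplicated pairs with the same orientation are merged (keeping the smaller
#' detection p-value); the same pair appearing with contradictory risk
#' orientations in the two signatures is an error. Candidates are ranked by
#' ascending detection p-value, the order later consumed by
#' [forward_select()].
#'
#' @param sig_a,sig_b Fitted `gene_pair_signature` objects.
#' @return Tibble of candidates: `gene_i`, `gene_j`, `orientation`,
#'   `p_value`, `source`.
#' @export
pool_pairs <- function(sig_a, sig_b) {
  stopifnot(
    inherits(sig_a, "gene_pair_signature"),
    inherits(sig_b, "gene_pair_signature")
  )
  grab <- function(sig) {
    sig$pairs |>
      select("gene_i", "gene_j", "orientation", dplyr::any_of("p_value")) |>
      mutate(source = sig$status_name)
  }
  cands <- bind_rows(grab(sig_a), grab(sig_b))
  if (!"p_value" %in% colnames(cands)) cands$p_value <- NA_real_
  # normalize so gene order within a row is canonical for duplicate detection
  key <- purrr::pmap_chr(cands, function(gene_i, gene_j, ...) {
    paste(sort(c(gene_i, gene_j)), collapse = "|")
  })
  flip <- cands$gene_i > cands$gene_j
  canon_orient <- ifelse(
    flip,
    ifelse(cands$orientation == "i>j", "i<j", "i>j"),
    cands$orientation
  )
  conflicting <- tapply(canon_orient, key, function(o) length(unique(o)) > 1)
  if (any(conflicting)) {
    abort(paste0(
      "Contradictory risk orientations for pooled pair(s): ",
      paste(names(conflicting)[conflicting], collapse = ", ")
    ))
  }
  cands$.key <- key
  cands |>
    arrange(.data$p_value, .data$gene_i, .data$gene_j) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(-".key")
}

panel_vote_matrix <- function(pairs, expr) {
  signature_risk_bits(pairs, expr)
}

#' Fraction of panel pairs showing the risk ordering, per sample
#'
#' Expression ties count as not-reversed (no vote for high risk). Flipping a
#' single pair's ordering in one sample changes that sample's fraction by
#' exactly `1 / nrow(panel$pairs)`.
#'
#' @param panel An `ensemble_panel` (or any object with a `pairs` tibble and
#'   `vote_threshold`).
#' @param expr Numeric genes-by-samples matrix containing all panel genes.
#' @return Tibble with columns `sample_id` and `vote_fraction` in \[0, 1\].
#' @export
vote_fraction <- function(panel, expr) {
  bits <- panel_vote_matrix(panel$pairs, expr)
  tibble(
    sample_id = colnames(expr),
    vote_fraction = as.numeric(colMeans(bits))
  )
}

#' Majority-vote risk classification with an ensemble panel
#'
#' A sample is high risk iff its vote fraction strictly exceeds the panel's
#' vote threshold (default 0.5). A fraction of exactly one half is low risk:
#' the tie is resolved toward the favorable class.
#'
#' @inheritParams vote_fraction
#' @return Tibble with columns `sample_id`, `vote_fraction`, `risk`.
#' @export
majority_vote_classify <- function(panel, expr) {
  vote_fraction(panel, expr) |>
    mutate(risk = ifelse(.data$vote_fraction > panel$vote_threshold, "high", "low"))
}

panel_criterion_score <- function(pairs, cohort, criterion, vote_threshold) {
  tmp <- list(pairs = pairs, vote_threshold = vote_threshold)
  cls <- majority_vote_classify(tmp, cohort$expression)
  high <- as.integer(cls$risk == "high")
  surv <- cohort$clinical
  if (length(unique(high)) < 2) {
    return(-Inf)
  }
  if (criterion == "cindex") {
    concordance_index(high, surv$os_time, surv$event)
  } else {
    sd <- survdiff(Surv(surv$os_time, surv$event) ~ high)
    unname(sd$chisq)
  }
}

#' Greedy forward selection of an ensemble gene-pair panel
#'
#' Starting from the top-ranked candidate (smallest detection p-value), each
#' further candidate is tentatively added in rank order; the training cohort
#' is classified by majority vote with the tentative panel and scored with
#' the criterion (Harrell's C-index of the binary vote label against overall
#' survival, or the log-rank statistic). A candidate is kept only when the
#' score strictly improves; equal scores skip the candidate. Selection stops
#' after all candidates have been visited or the panel reaches `max_panel`.
#' The procedure is deterministic.
#'
#' @param candidates Ranked candidate tibble from [pool_pairs()].
#' @param cohort Training `pair_cohort` with survival columns.
#' @param criterion `"cindex"` (default) or `"logrank"`.
#' @param max_panel Maximum panel size (default unlimited).
#' @param vote_threshold Majority-vote threshold, default 0.5.
#' @return An `ensemble_panel` with the selected pairs, the threshold and a
#'   selection `trace` (one row per candidate visited: action and score).
#' @export
forward_select <- function(candidates, cohort,
                           criterion = c("cindex", "logrank"),
                           max_panel = Inf, vote_threshold = 0.5) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(cohort, "pair_cohort"))
  if (nrow(candidates) == 0) abort("No candidate pairs to select from.")
  surv_ok <- !is.na(cohort$clinical$os_time) & !is.na(cohort$clinical$event)
  cohort <- structure(
    list(
      expression = cohort$expression[, surv_ok, drop = FALSE],
      clinical = cohort$clinical[surv_ok, , drop = FALSE]
    ),
    class = "pair_cohort"
  )

  panel_pairs <- candidates[1, , drop = FALSE]
  best <- panel_criterion_score(panel_pairs, cohort, criterion, vote_threshold)
  trace <- tibble(
    step = 1L,
    gene_i = candidates$gene_i[1], gene_j = candidates$gene_j[1],
    action = "kept", score = best
  )
  improved_any <- FALSE
  if (nrow(candidates) > 1) {
    for (k in 2:nrow(candidates)) {
      if (nrow(panel_pairs) >= max_panel) break
      tent <- bind_rows(panel_pairs, candidates[k, , drop = FALSE])
      sc <- panel_criterion_score(tent, cohort, criterion, vote_threshold)
      keep <- is.finite(sc) && sc > best
      if (keep) {
        panel_pairs <- tent
        best <- sc
        improved_any <- TRUE
      }
      trace <- bind_rows(trace, tibble(
        step = k,
        gene_i = candidates$gene_i[k], gene_j = candidates$gene_j[k],
        action = if (keep) "kept" else "skipped", score = sc
      ))
    }
    if (!improved_any) {
      warn("No candidate improved on the singleton panel; returning a 1-pair panel.")
    }
  }
  new_ensemble_panel(
    pairs = panel_pairs,
    vote_threshold = vote_threshold,
    criterion = criterion,
    trace = trace,
    provenance = list(
      n_candidates = nrow(candidates),
      training_score = best
    )
  )
}

#' Build a majority-vote ensemble panel from two signatures
#'
#' Convenience wrapper for [pool_pairs()] then [forward_select()].
#'
#' @inheritParams forward_select
#' @param sig_a,sig_b Fitted `gene_pair_signature` objects.
#' @return An `ensemble_panel`.
#' @export
build_ensemble <- function(sig_a, sig_b, cohort,
                           criterion = c("cindex", "logrank"),
                           max_panel = Inf, vote_threshold = 0.5) {
  cands <- pool_pairs(sig_a, sig_b)
  forward_select(
    cands, cohort,
    criterion = criterion,
    max_panel = max_panel, vote_threshold = vote_threshold
  )
}

#' @export
print.ensemble_panel <- function(x, ...) {
  cat(sprintf(
    "<ensemble_panel> %d pairs (vote threshold %.2f, criterion %s)\n",
    nrow(x$pairs), x$vote_threshold, x$criterion
  ))
  src <- count(x$pairs, .data$source)
  for (i in seq_len(nrow(src))) {
    cat(sprintf("  %s: %d pair(s)\n", src$source[i], src$n[i]))
  }
  invisible(x)
}

#' @describeIn forward_select Tidy the selected oriented pairs.
#' @param x An `ensemble_panel`.
#' @param ... Unused.
#' @method tidy ensemble_panel
#' @export
tidy.ensemble_panel <- function(x, ...) {
  x$pairs
}

#' @describeIn forward_select One-row panel summary.
#' @method glance ensemble_panel
#' @export
glance.ensemble_panel <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    vote_threshold = x$vote_threshold,
    criterion = x$criterion,
    training_score = x$provenance$training_score %||% NA_real_
  )
}

#' @describeIn forward_select Step plot of the greedy selection trace.
#' @param object An `ensemble_panel`.
#' @method autoplot ensemble_panel
#' @export
autoplot.ensemble_panel <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(
    x = .data$step, y = .data$score, colour = .data$action
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Candidate rank", y = sprintf("Training %s", object$criterion),
      title = "Forward selection trace"
    )
}
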