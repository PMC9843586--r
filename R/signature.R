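#' Stability selection of pair features by repeated L1-penalized logistic fits
#'
#' Fits an L1-penalized logistic regression of the status labels on the
#' pair-ordering profile `n_repeats` times, each time on a stratified
#' bootstrap resample of the samples with the penalty chosen by internal
#' cross-validation; a pair is selected when its coefficient is nonzero in at
#' least `freq_threshold` of the repeats. With `n_repeats = 1` no resampling
#' is done and the result is the nonzero support of a single
#' cross-validated fit.
#'
#' Constant profile rows carry no information and are dropped with a warning
#' before fitting.
#'
#' @param profile A [pair_profile()] object.
#' @param labels Binary 0/1 status vector, one per sample.
#' @param n_repeats Number of penalized fits (default 50).
#' @param freq_threshold Minimum selection frequency (default 0.8).
#' @param seed Integer seed; frequencies are reproducible from it.
#' @param nfolds Folds for the internal cross-validation (default 5).
#' @return A tibble with one row per (non-constant) pair: `gene_i`, `gene_j`,
#'   `orientation`, `p_value`, `frequency`, `selected`.
#' @export
stability_lasso_select <- function(profile, labels, n_repeats = 50,
                                   freq_threshold = 0.8, seed = 1L,
                                   nfolds = 5) {
  stopifnot(inherits(profile, "pair_profile"))
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("Both status classes must be present.")
  x <- t(profile$reversed)
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  if (any(!keep)) {
    warn(sprintf(
      "Dropping %d constant pair profile(s) before penalized fitting.",
      sum(!keep)
    ))
  }
  x <- x[, keep, drop = FALSE]
  pairs <- profile$pairs[keep, , drop = FALSE]
  if (ncol(x) < 2) abort("Need at least 2 non-constant pairs for selection.")

  withr::local_seed(as.integer(seed))
  n <- nrow(x)
  idx0 <- which(y == 0)
  idx1 <- which(y == 1)
  nonzero <- matrix(FALSE, nrow = n_repeats, ncol = ncol(x))
  for (r in seq_len(n_repeats)) {
    if (n_repeats == 1) {
      rows <- seq_len(n)
    } else {
      rows <- c(
        sample(idx0, length(idx0), replace = TRUE),
        sample(idx1, length(idx1), replace = TRUE)
      )
    }
    yr <- y[rows]
    foldid <- integer(length(rows))
    foldid[yr == 0] <- sample(rep_len(seq_len(nfolds), sum(yr == 0)))
    foldid[yr == 1] <- sample(rep_len(seq_len(nfolds), sum(yr == 1)))
    cvfit <- glmnet::cv.glmnet(
      x[rows, , drop = FALSE], yr,
      family = "binomial", alpha = 1, foldid = foldid
    )
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
    nonzero[r, ] <- beta != 0
  }
  freq <- colMeans(nonzero)
  pairs |>
    mutate(
      frequency = freq,
      selected = freq >= freq_threshold
    )
}

new_gene_pair_signature <- function(status_name, pairs, intercept, cutoff,
                                    cutoff_method, provenance) {
  structure(
    list(
      status_name = status_name,
      pairs = pairs,
      intercept = intercept,
      cutoff = cutoff,
      cutoff_method = cutoff_method,
      provenance = provenance
    ),
    class = "gene_pair_signature"
  )
}

#' Fit final logistic weights for the selected gene pairs
#'
#' Fits an unpenalized logistic regression of the unfavorable status
#' (`1 - labels`) on the risk-ordering indicator bits of the selected pairs
#' (standard relaxed-lasso practice: selection and weighting are separate
#' steps). The linear predictor of this model is the risk score: it rises
#' with the probability of the unfavorable genomic state, so informative
#' pairs get positive coefficients and a sample showing many risk orderings
#' scores high. Under complete separation the fit automatically falls back to
#' a lightly ridge-penalized fit and flags this in the provenance.
#'
#' @param profile A [pair_profile()] restricted (via `selected`) to the pairs
#'   to weight.
#' @param labels Binary status vector (1 = favorable state present).
#' @param status_name Name recorded in the signature.
#' @param selected Optional logical or integer index of pairs to keep;
#'   default all pairs in the profile.
#' @param frequencies Optional selection frequencies to record per kept pair.
#' @param provenance Optional list of provenance fields to merge.
#' @return A `gene_pair_signature` (cutoff unset until [optimal_cutoff()]).
#' @export
fit_signature <- function(profile, labels, status_name = "status",
                          selected = NULL, frequencies = NULL,
                          provenance = list()) {
  stopifnot(inherits(profile, "pair_profile"))
  y_risk <- 1L - as.integer(labels)
  if (length(unique(y_risk)) < 2) abort("Both status classes must be present.")
  keep <- selected %||% seq_len(nrow(profile$pairs))
  x <- t(profile$risk[keep, , drop = FALSE])
  pairs <- profile$pairs[keep, , drop = FALSE]
  if (ncol(x) < 1) abort("At least one selected pair is required.")

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y_risk ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
        grepl("did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (separation || anyNA(cf) || any(abs(cf) > 20)) {
    separation <- TRUE
    rfit <- glmnet::glmnet(
      cbind(x, 0), y_risk, # pad: glmnet needs >= 2 columns
      family = "binomial", alpha = 0, lambda = 0.01
    )
    cf <- c(as.numeric(rfit$a0), as.numeric(rfit$beta)[seq_len(ncol(x))])
  }
  intercept <- unname(cf[1])
  coefs <- unname(cf[-1])

  pairs <- pairs |>
    mutate(
      coefficient = coefs,
      selection_frequency = frequencies %||% rep(NA_real_, nrow(pairs))
    ) |>
    select(
      "gene_i", "gene_j", "orientation", "coefficient",
      dplyr::any_of("p_value"), "selection_frequency"
    )
  prov <- modifyList(
    list(separation_fallback = separation, penalty_rule = "cv-lambda.min"),
    provenance
  )
  new_gene_pair_signature(
    status_name = status_name, pairs = pairs,
    intercept = intercept, cutoff = NA_real_, cutoff_method = NA_character_,
    provenance = prov
  )
}

signature_risk_bits <- function(pairs, expr) {
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    abort(paste0(
      "Expression matrix lacks signature gene(s): ",
      paste(missing_genes, collapse = ", ")
    ))
  }
  e_i <- expr[pairs$gene_i, , drop = FALSE]
  e_j <- expr[pairs$gene_j, , drop = FALSE]
  risk_is_gt <- pairs$orientation == "i>j"
  bits <- (e_i > e_j) * 1
  bits[!risk_is_gt, ] <- (e_i < e_j)[!risk_is_gt, ] * 1
  rownames(bits) <- paste(pairs$gene_i, pairs$gene_j, sep = "|")
  bits
}

#' Per-sample risk score of a gene-pair signature
#'
#' `score = intercept + sum(coefficient * risk bit)`, where the risk bit of a
#' pair is 1 when the sample shows the pair's risk (unfavorable-typical)
#' ordering and 0 otherwise (ties score 0). Computed directly from raw
#' expression, so it is invariant to strictly monotone per-sample transforms.
#'
#' @param sig A `gene_pair_signature`.
#' @param expr Numeric genes-by-samples matrix containing all signature genes.
#' @return Tibble with columns `sample_id` and `score`.
#' @export
risk_score <- function(sig, expr) {
  stopifnot(inherits(sig, "gene_pair_signature"))
  bits <- signature_risk_bits(sig$pairs, expr)
  score <- sig$intercept + as.numeric(crossprod(bits, sig$pairs$coefficient))
  tibble(sample_id = colnames(expr), score = score)
}

#' Survival-optimal (or mean) cutoff for a risk score
#'
#' `method = "logrank-max"`: candidate cutoffs are the score quantiles 0.1 to
#' 0.9 on a regular grid; the cutoff maximizing the two-group log-rank
#' statistic is returned, considering only splits leaving at least
#' `min_group` samples per stratum. `method = "mean"`: the mean score.
#'
#' @param scores Numeric risk scores.
#' @param os_time,event Overall-survival time and event indicator.
#' @param method `"logrank-max"` (default) or `"mean"`.
#' @param grid Quantile grid for `"logrank-max"`.
#' @param min_group Minimum samples per stratum (default 10).
#' @return The cutoff value (risk = score strictly above it).
#' @export
optimal_cutoff <- function(scores, os_time, event,
                           method = c("logrank-max", "mean"),
                           grid = seq(0.1, 0.9, by = 0.05),
                           min_group = 10) {
  method <- match.arg(method)
  if (length(unique(scores)) < 2) abort("All scores identical; no cutoff exists.")
  if (method == "mean") {
    return(mean(scores))
  }
  cand <- unique(quantile(scores, probs = grid, type = 7))
  best <- NULL
  best_stat <- -Inf
  for (cut in cand) {
    high <- scores > cut
    if (sum(high) < min_group || sum(!high) < min_group) next
    sd <- survdiff(Surv(os_time, event) ~ high)
    if (sd$chisq > best_stat) {
      best_stat <- sd$chisq
      best <- cut
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "No candidate cutoff leaves %d samples per stratum.", min_group
    ))
  }
  best
}

#' Classify samples into high/low risk with a fitted signature
#'
#' High risk iff the risk score is strictly greater than the signature's
#' cutoff; a score exactly at the cutoff is low risk (the favorable class is
#' the conservative default).
#'
#' @param sig A `gene_pair_signature` with a fitted cutoff.
#' @param expr Numeric genes-by-samples matrix.
#' @return Tibble with columns `sample_id`, `score`, `risk`
#'   (`"high"`/`"low"`).
#' @export
classify_risk <- function(sig, expr) {
  if (is.na(sig$cutoff)) abort("Signature cutoff not fitted; run optimal_cutoff() first.")
  scores <- risk_score(sig, expr)
  scores |>
    mutate(risk = ifelse(.data$score > sig$cutoff, "high", "low"))
}

#' Build a single-status gene-pair signature end to end
#'
#' Convenience wrapper chaining [detect_reverse_pairs()],
#' [pair_profile()], [stability_lasso_select()], [fit_signature()] and
#' [optimal_cutoff()] on one cohort and one status column. Samples with
#' unknown status are excluded from detection and weighting; the cutoff is
#' fitted on the same samples' survival.
#'
#' @inheritParams detect_reverse_pairs
#' @inheritParams stability_lasso_select
#' @param cutoff_method Passed to [optimal_cutoff()].
#' @return A fitted `gene_pair_signature`.
#' @export
build_signature <- function(cohort, status, fraction = 0.10, top_k = 50,
                            alpha = 0.05, n_repeats = 50,
                            freq_threshold = 0.8,
                            cutoff_method = c("logrank-max", "mean"),
                            seed = 1L) {
  cutoff_method <- match.arg(cutoff_method)
  records <- detect_reverse_pairs(
    cohort, status,
    fraction = fraction, top_k = top_k, alpha = alpha
  )
  if (nrow(records) == 0) abort("No significant reverse pairs detected.")
  keep <- !is.na(cohort$clinical[[status]])
  expr <- cohort$expression[, keep, drop = FALSE]
  labels <- as.integer(cohort$clinical[[status]][keep])
  profile <- pair_profile(expr, records)

  if (nrow(records) >= 2) {
    sel <- stability_lasso_select(
      profile, labels,
      n_repeats = n_repeats, freq_threshold = freq_threshold, seed = seed
    )
    chosen <- sel |> filter(.data$selected)
    if (nrow(chosen) == 0) {
      warn("No pair reached the selection-frequency threshold; keeping the most frequent pair.")
      chosen <- sel |> arrange(desc(.data$frequency), .data$p_value) |> head(1)
    }
    keep_idx <- match(
      paste(chosen$gene_i, chosen$gene_j),
      paste(profile$pairs$gene_i, profile$pairs$gene_j)
    )
    freqs <- chosen$frequency
  } else {
    keep_idx <- 1L
    freqs <- 1
  }

  sig <- fit_signature(
    profile, labels,
    status_name = status, selected = keep_idx, frequencies = freqs,
    provenance = list(
      seed = as.integer(seed), n_repeats = n_repeats,
      freq_threshold = freq_threshold,
      detection = list(
        fraction = fraction, top_k = top_k, alpha = alpha,
        n_enumerated = attr(records, "n_enumerated")
      )
    )
  )
  scores <- risk_score(sig, expr)
  surv <- cohort$clinical[keep, , drop = FALSE]
  sig$cutoff <- optimal_cutoff(
    scores$score, surv$os_time, surv$event,
    method = cutoff_method
  )
  sig$cutoff_method <- cutoff_method
  sig
}

#' @export
print.gene_pair_signature <- function(x, ...) {
  cat(sprintf(
    "<gene_pair_signature> status '%s': %d pairs, intercept %.3f, cutoff %s (%s)\n",
    x$status_name, nrow(x$pairs), x$intercept,
    if (is.na(x$cutoff)) "<unset>" else sprintf("%.3f", x$cutoff),
    if (is.na(x$cutoff_method)) "-" else x$cutoff_method
  ))
  invisible(x)
}

#' @describeIn fit_signature Tidy the oriented pairs and coefficients of a
#'   signature into a tibble.
#' @param x A `gene_pair_signature`.
#' @param ... Unused.
#' @method tidy gene_pair_signature
#' @export
tidy.gene_pair_signature <- function(x, ...) {
  x$pairs
}

#' @describeIn fit_signature One-row model summary.
#' @method glance gene_pair_signature
#' @export
glance.gene_pair_signature <- function(x, ...) {
  tibble(
    status_name = x$status_name,
    n_pairs = nrow(x$pairs),
    intercept = x$intercept,
    cutoff = x$cutoff,
    cutoff_method = x$cutoff_method,
    separation_fallback = isTRUE(x$provenance$separation_fallback)
  )
}

#' @describeIn fit_signature Bar chart of pair coefficients.
#' @param object A `gene_pair_signature`.
#' @method autoplot gene_pair_signature
#' @export
autoplot.gene_pair_signature <- function(object, ...) {
  df <- object$pairs |>
    mutate(pair = paste(.data$gene_i, .data$gene_j, sep = " | "))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$coefficient),
    y = .data$coefficient
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Risk-model coefficient",
      title = sprintf("Gene-pair signature: %s", object$status_name)
    )
}
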