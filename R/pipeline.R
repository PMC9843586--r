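#' Declarative configuration for the full pipeline run
#'
#' One document holds every downstream parameter; defaults are the method's
#' standard values (candidate fraction 0.10, 50 reverse pairs per status,
#' 50 penalized-regression repeats, majority-vote threshold 0.5). Either a
#' [sim_config()] (synthetic cohort) or paths to an expression matrix and a
#' clinical table must be supplied.
#'
#' @param out_dir Run directory for all artifacts.
#' @param simulation Optional [sim_config()] to generate the cohort.
#' @param expression_path,clinical_path Optional input files used when
#'   `simulation` is `NULL`; `clinical_args` is passed on to
#'   [read_clinical_table()].
#' @param clinical_args List of extra arguments for [read_clinical_table()].
#' @param status_a,status_b Names of the two binary status columns screened.
#' @param fraction,top_k,alpha Detection parameters (see
#'   [detect_reverse_pairs()]).
#' @param n_repeats,freq_threshold Stability-selection parameters.
#' @param cutoff_method Risk-score cutoff rule per signature.
#' @param criterion Forward-selection criterion for the ensemble.
#' @param max_panel Maximum ensemble panel size.
#' @param vote_threshold Majority-vote threshold.
#' @param horizons Fixed-time AUC horizons (units of the clinical `os_time`).
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            simulation = NULL,
                            expression_path = NULL,
                            clinical_path = NULL,
                            clinical_args = list(),
                            status_a = "status1",
                            status_b = "status2",
                            fraction = 0.10,
                            top_k = 50,
                            alpha = 0.05,
                            n_repeats = 50,
                            freq_threshold = 0.8,
                            cutoff_method = "logrank-max",
                            criterion = "cindex",
                            max_panel = Inf,
                            vote_threshold = 0.5,
                            horizons = c(1, 3, 5),
                            seed = 1L) {
  if (is.null(simulation) && (is.null(expression_path) || is.null(clinical_path))) {
    abort("Provide either a simulation config or expression_path + clinical_path.")
  }
  structure(
    list(
      out_dir = out_dir, simulation = simulation,
      expression_path = expression_path, clinical_path = clinical_path,
      clinical_args = clinical_args,
      status_a = status_a, status_b = status_b,
      fraction = fraction, top_k = top_k, alpha = alpha,
      n_repeats = n_repeats, freq_threshold = freq_threshold,
      cutoff_method = cutoff_method, criterion = criterion,
      max_panel = max_panel, vote_threshold = vote_threshold,
      horizons = horizons, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$simulation <- if (is.null(out$simulation)) NULL else unclass(out$simulation)
  out$max_panel <- if (is.infinite(out$max_panel)) "unlimited" else out$max_panel
  out
}

log_line <- function(log_path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", file = log_path, sep = "", append = TRUE)
  inform(msg)
}

#' Run the full study pipeline on one cohort
#'
#' Sequentially: load or simulate the cohort, detect reverse pairs for each
#' of the two statuses, build the two single-status signatures, pool and
#' forward-select the ensemble panel, and evaluate the panel and both
#' signatures on the training cohort. Every artifact is written into the run
#' directory (expression/clinical TSV when simulated, per-status reversal
#' records TSV, signature and panel JSON, evaluation JSON, a structured log
#' and the config echo stamped with its hash and seed). The whole run is a
#' deterministic function of the config, so re-running with the same config
#' and seed reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `cohort`, `truth` (if simulated),
#'   `signatures` (named by status), `panel` and `reports` (`survival_eval`
#'   objects for each signature and the ensemble).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- load or simulate (validate status columns before writing anything)
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- generate_cohort(config$simulation)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    expr <- read_expression_matrix(config$expression_path)
    clin <- do.call(read_clinical_table, c(
      list(path = config$clinical_path), config$clinical_args
    ))
    cohort <- align_cohort(expr, clin)
  }
  for (st in c(config$status_a, config$status_b)) {
    if (!st %in% colnames(cohort$clinical)) {
      abort(sprintf("Status column '%s' not found in clinical table.", st))
    }
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  if (file.exists(log_path)) file.remove(log_path)
  cfg_list <- config_as_list(config)
  cfg_list$config_hash <- rlang::hash(config_as_list(config))
  jsonlite::write_json(
    cfg_list, file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  log_line(
    log_path, "run_pipeline: seed %d, config hash %s",
    config$seed, cfg_list$config_hash
  )

  if (!is.null(truth)) {
    write_expression_matrix(
      cohort$expression, file.path(config$out_dir, "expression.tsv")
    )
    readr::write_tsv(cohort$clinical, file.path(config$out_dir, "clinical.tsv"))
    jsonlite::write_json(
      list(
        planted_pairs_s1 = truth$planted_pairs_s1,
        planted_pairs_s2 = truth$planted_pairs_s2,
        log_hr = as.list(truth$log_hr)
      ),
      file.path(config$out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    log_line(
      log_path, "simulated cohort: %d genes x %d samples",
      nrow(cohort$expression), ncol(cohort$expression)
    )
  }

  # --- per-status signatures
  signatures <- list()
  reports <- list()
  stage_seed <- c(101L, 202L)
  statuses <- c(config$status_a, config$status_b)
  for (k in seq_along(statuses)) {
    st <- statuses[k]
    log_line(log_path, "stage detect+build [%s]", st)
    sig <- withCallingHandlers(
      build_signature(
        cohort, st,
        fraction = config$fraction, top_k = config$top_k,
        alpha = config$alpha, n_repeats = config$n_repeats,
        freq_threshold = config$freq_threshold,
        cutoff_method = config$cutoff_method,
        seed = config$seed + stage_seed[k]
      ),
      message = function(m) {
        cat(conditionMessage(m), file = log_path, append = TRUE)
        invokeRestart("muffleMessage")
      }
    )
    signatures[[st]] <- sig
    records <- detect_reverse_pairs(
      cohort, st,
      fraction = config$fraction, top_k = config$top_k, alpha = config$alpha
    )
    readr::write_tsv(
      records, file.path(config$out_dir, sprintf("records_%s.tsv", st))
    )
    write_signature(
      sig, file.path(config$out_dir, sprintf("signature_%s.json", st))
    )
    keep <- !is.na(cohort$clinical[[st]])
    cls <- classify_risk(sig, cohort$expression[, keep, drop = FALSE])
    reports[[st]] <- evaluate_model(
      cls, cohort$clinical[keep, , drop = FALSE],
      horizons = config$horizons
    )
    log_line(
      log_path, "signature [%s]: %d pairs, training C-index %.3f",
      st, nrow(sig$pairs), reports[[st]]$cindex
    )
  }

  # --- ensemble
  log_line(log_path, "stage ensemble (criterion %s)", config$criterion)
  panel <- build_ensemble(
    signatures[[config$status_a]], signatures[[config$status_b]], cohort,
    criterion = config$criterion, max_panel = config$max_panel,
    vote_threshold = config$vote_threshold
  )
  write_signature(panel, file.path(config$out_dir, "panel.json"))
  cls <- majority_vote_classify(panel, cohort$expression)
  reports$ensemble <- evaluate_model(
    cls, cohort$clinical,
    horizons = config$horizons
  )
  write_eval_report(
    reports$ensemble, file.path(config$out_dir, "evaluation_ensemble.json")
  )
  log_line(
    log_path, "ensemble panel: %d pairs, training C-index %.3f",
    nrow(panel$pairs), reports$ensemble$cindex
  )

  invisible(list(
    cohort = cohort, truth = truth,
    signatures = signatures, panel = panel, reports = reports
  ))
}

#' Apply a frozen panel to external cohorts
#'
#' Classifies each external cohort with the trained panel using expression
#' alone (no refitting, and survival data are never read before
#' classification — there is no leakage), then evaluates the resulting risk
#' groups against that cohort's survival outcomes. Any panel gene absent
#' from a cohort's expression matrix is an explicit error naming the gene.
#'
#' @param panel A trained `ensemble_panel`.
#' @param cohorts Named list of `pair_cohort` objects.
#' @param horizons Fixed-time AUC horizons.
#' @return Named list of `survival_eval` reports, one per cohort.
#' @export
run_external <- function(panel, cohorts, horizons = c(1, 3, 5)) {
  stopifnot(inherits(panel, "ensemble_panel"))
  purrr::imap(cohorts, function(cohort, name) {
    cls <- majority_vote_classify(panel, cohort$expression)
    evaluate_model(cls, cohort$clinical, horizons = horizons)
  })
}
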