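#' Read a genes-by-samples expression matrix from delimited text
#'
#' The file must have sample identifiers in the first row and gene identifiers
#' in the first column. Cells are raw (un-normalized) quantification values on
#' any monotone abundance scale; the downstream pipeline only ever uses
#' within-sample orderings, so the scale never needs to be harmonized across
#' samples or platforms.
#'
#' Missing cells (empty or `NA`) are kept as `NA`; genes with any missing
#' value are recorded in the `"incomplete_genes"` attribute and are excluded
#' from candidate-gene selection later (rank comparisons are undefined on
#' missing cells). A non-numeric, non-missing cell is a parse error that names
#' the offending gene and sample.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @return A numeric matrix with genes in rows and samples in columns,
#'   `dimnames` carrying the identifiers, and an `"incomplete_genes"`
#'   character attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "A\t1.5\t2", "B\t3\t0.5"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, delimiter = "\t") {
  raw <- utils::read.delim(
    path,
    sep = delimiter, header = TRUE, check.names = FALSE,
    colClasses = "character", na.strings = c("NA", ""),
    stringsAsFactors = FALSE
  )
  if (ncol(raw) < 2) {
    abort("Expression file needs a gene-id column plus at least one sample column.")
  }
  gene_ids <- as.character(raw[[1]])
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("Duplicated gene ids: ", paste(dups, collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    dups <- unique(sample_ids[duplicated(sample_ids)])
    abort(paste0("Duplicated sample ids: ", paste(dups, collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Malformed numeric cell '%s' at gene '%s', sample '%s'.",
      cells[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]
    ))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  incomplete <- gene_ids[rowSums(is.na(values)) > 0]
  attr(values, "incomplete_genes") <- incomplete
  values
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]; round-trips exactly up to numeric
#' printing precision (15 significant digits are written).
#'
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delimiter = "\t") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path,
    sep = delimiter, quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Reads a delimited table with one row per sample and coerces the named
#' genomic-status columns to 0/1/`NA` flags via `status_map`. Overall-survival
#' time must be positive where present; a non-positive time is a validation
#' error. Samples with unknown status (`NA` or an unmapped level) are
#' retained and flagged unknown; each detection screen drops them later.
#'
#' @param path Path to the delimited text file.
#' @param sample_col,time_col,event_col Names of the sample-id,
#'   overall-survival time and event-indicator columns.
#' @param status_cols Character vector naming the binary status columns.
#' @param status_map Optional named list; for each status column, a named
#'   vector mapping raw level to 0/1 (e.g. `list(idh = c(mutant = 1, wild = 0))`).
#'   Columns absent from the map must already be coded 0/1.
#' @param delimiter Field delimiter.
#' @return A tibble with columns `sample_id`, one integer 0/1/`NA` column per
#'   status, `os_time` (double) and `event` (integer 0/1).
#' @export
read_clinical_table <- function(path,
                                sample_col = "sample_id",
                                status_cols = character(),
                                time_col = "os_time",
                                event_col = "event",
                                status_map = list(),
                                delimiter = "\t") {
  raw <- utils::read.delim(path,
    sep = delimiter, header = TRUE, check.names = FALSE,
    na.strings = c("NA", ""), stringsAsFactors = FALSE
  )
  needed <- c(sample_col, status_cols, time_col, event_col)
  missing_cols <- setdiff(needed, colnames(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Clinical table lacks mapped column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble(sample_id = as.character(raw[[sample_col]]))
  if (anyDuplicated(out$sample_id)) {
    abort("Duplicated sample ids in clinical table.")
  }
  for (sc in status_cols) {
    v <- raw[[sc]]
    if (!is.null(status_map[[sc]])) {
      m <- status_map[[sc]]
      mapped <- unname(m[as.character(v)])
      unknown_level <- !is.na(v) & is.na(mapped)
      if (any(unknown_level)) {
        abort(sprintf(
          "Non-binary value '%s' in status column '%s' not covered by status_map.",
          v[which(unknown_level)[1]], sc
        ))
      }
      v <- mapped
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- (!is.na(v) & is.na(num)) | (!is.na(num) & !(num %in% c(0, 1)))
    if (any(bad)) {
      abort(sprintf(
        "Non-binary value '%s' in status column '%s' (map it via status_map).",
        v[which(bad)[1]], sc
      ))
    }
    out[[sc]] <- as.integer(num)
  }
  os_time <- suppressWarnings(as.numeric(raw[[time_col]]))
  if (any(!is.na(os_time) & os_time <= 0)) {
    abort(sprintf(
      "Non-positive os_time for sample '%s'.",
      out$sample_id[which(!is.na(os_time) & os_time <= 0)[1]]
    ))
  }
  event <- suppressWarnings(as.numeric(raw[[event_col]]))
  if (any(!is.na(event) & !(event %in% c(0, 1)))) {
    abort("Event indicator must be 0 (censored) or 1 (death).")
  }
  out$os_time <- os_time
  out$event <- as.integer(event)
  out
}

#' Align an expression matrix and a clinical table into a cohort
#'
#' Restricts both components to the intersection of their sample ids (exact
#' string matching) and orders them identically. The number of samples dropped
#' from each side is reported via a message; an empty intersection is an
#' error. Aligning an already-aligned cohort is a no-op.
#'
#' @param expr Numeric genes-by-samples matrix (see [read_expression_matrix()]).
#' @param clinical Clinical tibble (see [read_clinical_table()]).
#' @return A `pair_cohort` object: a list with elements `expression` and
#'   `clinical` over identical, identically ordered sample ids.
#' @export
align_cohort <- function(expr, clinical) {
  expr_ids <- colnames(expr)
  clin_ids <- clinical$sample_id
  shared <- intersect(expr_ids, clin_ids)
  if (length(shared) == 0) {
    abort("No shared sample ids between expression matrix and clinical table.")
  }
  n_drop_expr <- length(expr_ids) - length(shared)
  n_drop_clin <- length(clin_ids) - length(shared)
  if (n_drop_expr > 0 || n_drop_clin > 0) {
    inform(sprintf(
      "align_cohort: dropped %d expression-only and %d clinical-only sample(s).",
      n_drop_expr, n_drop_clin
    ))
  }
  incomplete <- attr(expr, "incomplete_genes")
  expr <- expr[, shared, drop = FALSE]
  attr(expr, "incomplete_genes") <- incomplete
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  structure(
    list(expression = expr, clinical = clinical),
    class = "pair_cohort"
  )
}

#' @export
print.pair_cohort <- function(x, ...) {
  cat(sprintf(
    "<pair_cohort> %d genes x %d samples; clinical columns: %s\n",
    nrow(x$expression), ncol(x$expression),
    paste(colnames(x$clinical), collapse = ", ")
  ))
  invisible(x)
}

pairsig_schema_version <- 1L

signature_to_list <- function(sig) {
  if (inherits(sig, "gene_pair_signature")) {
    list(
      schema_version = pairsig_schema_version,
      type = "gene_pair_signature",
      status_name = sig$status_name,
      pairs = purrr::pmap(sig$pairs, function(gene_i, gene_j, orientation,
                                              coefficient, p_value,
                                              selection_frequency, ...) {
        list(
          gene_up = gene_i, gene_down = gene_j, orientation = orientation,
          coefficient = coefficient, p_value = p_value,
          selection_frequency = selection_frequency
        )
      }),
      intercept = sig$intercept,
      cutoff = sig$cutoff,
      cutoff_method = sig$cutoff_method,
      provenance = sig$provenance
    )
  } else if (inherits(sig, "ensemble_panel")) {
    list(
      schema_version = pairsig_schema_version,
      type = "ensemble_panel",
      pairs = purrr::pmap(sig$pairs, function(gene_i, gene_j, orientation,
                                              p_value, source, ...) {
        list(
          gene_up = gene_i, gene_down = gene_j, orientation = orientation,
          p_value = p_value, source = source
        )
      }),
      vote_threshold = sig$vote_threshold,
      criterion = sig$criterion,
      trace = as.list(sig$trace),
      provenance = sig$provenance
    )
  } else {
    abort("write_signature() handles gene_pair_signature or ensemble_panel objects.")
  }
}

#' Serialize a fitted signature or ensemble panel to JSON
#'
#' The schema is versioned (`schema_version`) and carries the oriented pairs,
#' coefficients/intercept and cutoff (single-status signatures), the vote
#' threshold and selection trace (ensemble panels), and the provenance
#' (seed and fitting parameters), so a signature trained on one cohort can be
#' applied unchanged to any other cohort measuring the same genes.
#'
#' @param sig A `gene_pair_signature` or `ensemble_panel` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(
    signature_to_list(sig), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a serialized signature or ensemble panel
#'
#' @param path Path to a JSON file written by [write_signature()].
#' @return The deserialized `gene_pair_signature` or `ensemble_panel`.
#' @export
read_signature <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("Signature file is not valid JSON (truncated?): ", conditionMessage(e)))
    }
  )
  ver <- obj$schema_version
  if (is.null(ver) || !identical(as.integer(ver), pairsig_schema_version)) {
    abort(sprintf(
      "Signature schema_version %s not supported (expected %d).",
      if (is.null(ver)) "<missing>" else as.character(ver),
      pairsig_schema_version
    ))
  }
  pairs <- dplyr::bind_rows(purrr::map(obj$pairs, as_tibble))
  pairs <- rename(pairs, gene_i = "gene_up", gene_j = "gene_down")
  if (identical(obj$type, "gene_pair_signature")) {
    new_gene_pair_signature(
      status_name = obj$status_name,
      pairs = pairs,
      intercept = obj$intercept,
      cutoff = if (is.null(obj$cutoff)) NA_real_ else obj$cutoff,
      cutoff_method = obj$cutoff_method,
      provenance = obj$provenance
    )
  } else if (identical(obj$type, "ensemble_panel")) {
    new_ensemble_panel(
      pairs = pairs,
      vote_threshold = obj$vote_threshold,
      criterion = obj$criterion,
      trace = as_tibble(purrr::map(obj$trace, unlist)),
      provenance = obj$provenance
    )
  } else {
    abort(sprintf("Unknown signature type '%s'.", as.character(obj$type)))
  }
}
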