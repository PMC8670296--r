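#' Read a sample-by-gene percent-methylation table
#'
#' Accepts comma- or tab-delimited text (auto-detected; CRLF endings
#' tolerated) with a header row. Required columns: `sample_id`, `class`
#' (`carcinoma`/`normal`). Optional columns: `age`, `msi` (`MSI`, `MSS` or
#' `NA`). All remaining columns are parsed as gene \%M values; a malformed
#' or out-of-range cell is reported with its sample and gene coordinates.
#'
#' @param path file path.
#' @return a [methylation_matrix()].
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", "class")) {
    if (!col %in% names(raw)) {
      stop("missing required column '", col, "'", call. = FALSE)
    }
  }
  meta_cols <- intersect(c("sample_id", "class", "age", "msi"), names(raw))
  gene_cols <- setdiff(names(raw), meta_cols)
  if (length(gene_cols) == 0) stop("no gene columns found", call. = FALSE)
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(gene_cols),
                 dimnames = list(raw$sample_id, gene_cols))
  for (g in gene_cols) {
    v <- suppressWarnings(as.numeric(raw[[g]]))
    bad <- which(is.na(v) & !(raw[[g]] %in% c("", "NA")))
    if (length(bad) > 0) {
      stop(sprintf("malformed %%M '%s' at sample '%s', gene '%s'",
                   raw[[g]][bad[1]], raw$sample_id[bad[1]], g),
           call. = FALSE)
    }
    out_of_range <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(out_of_range) > 0) {
      stop(sprintf("%%M out of [0,100] (%g) at sample '%s', gene '%s'",
                   v[out_of_range[1]], raw$sample_id[out_of_range[1]], g),
           call. = FALSE)
    }
    vals[, g] <- v
  }
  methylation_matrix(
    vals, class = raw$class,
    age = if ("age" %in% names(raw)) as.numeric(raw$age) else NULL,
    msi = if ("msi" %in% names(raw)) raw$msi else NULL)
}

#' Write a methylation matrix to delimited text
#'
#' Inverse of [read_methylation_table()]; round-trips without loss.
#'
#' @param matrix a [methylation_matrix()].
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_methylation_table <- function(matrix, path, sep = ",") {
  stopifnot(inherits(matrix, "methylation_matrix"))
  df <- data.frame(sample_id = sample_ids(matrix), class = matrix$class,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(matrix$age)) df$age <- matrix$age
  if (!is.null(matrix$msi)) df$msi <- matrix$msi
  df <- cbind(df, as.data.frame(matrix$values, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe-by-sample beta matrix with its sample annotation
#'
#' The matrix file is tab-delimited with probe ids in the first column
#' (header `probe_id`) and one column per sample; the annotation file is a
#' two-column TSV `sample_id`, `class`. This matches the shape of standard
#' 450K-style beta exports.
#'
#' @param path beta matrix TSV path.
#' @param annotation_path sample annotation TSV path.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, annotation_path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  stopifnot("probe_id" %in% names(raw),
            all(c("sample_id", "class") %in% names(ann)))
  vals <- as.matrix(raw[, setdiff(names(raw), "probe_id"), drop = FALSE])
  rownames(vals) <- raw$probe_id
  missing <- setdiff(colnames(vals), ann$sample_id)
  if (length(missing) > 0) {
    stop("samples without annotation: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- ann$class[match(colnames(vals), ann$sample_id)]
  beta_matrix(vals, class = cls)
}

#' Write a beta matrix and its sample annotation
#'
#' @param beta a [beta_matrix()].
#' @param path matrix TSV path.
#' @param annotation_path annotation TSV path.
#' @export
write_beta_matrix <- function(beta, path, annotation_path) {
  stopifnot(inherits(beta, "beta_matrix"))
  df <- data.frame(probe_id = rownames(beta$values),
                   beta$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(beta$values), class = beta$class),
    annotation_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a locked threshold as JSON
#'
#' The JSON file is the artifact handed from the training step to the test
#' step; [cmipanel_cli()]'s `evaluate` subcommand refuses to run without
#' one.
#'
#' @param locked a [lock_threshold()] result.
#' @param path output path.
#' @export
write_locked_threshold <- function(locked, path) {
  stopifnot(inherits(locked, "locked_threshold"))
  jsonlite::write_json(unclass(locked), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a locked threshold written by [write_locked_threshold()]
#'
#' @param path JSON path.
#' @return a `locked_threshold` object.
#' @export
read_locked_threshold <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("value", "specificity_floor", "training_sensitivity",
              "training_specificity")
  if (!all(needed %in% names(x))) {
    stop("not a locked-threshold file: ", path, call. = FALSE)
  }
  if (is.null(x$provenance)) x$provenance <- NA_character_
  structure(x[c(needed, "provenance")], class = "locked_threshold")
}

#' Write a performance report as JSON
#'
#' @param report an [evaluate_locked()] result.
#' @param path output path.
#' @export
write_performance_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  out <- unclass(report)
  out$confusion <- as.list(out$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a selection result with its per-gene audit trail as JSON
#'
#' @param result a [select_panel()] / [select_panel_from_summaries()]
#'   result.
#' @param path output path.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(
    panel = list(name = result$panel$name, genes = result$panel$genes),
    shortlist_ranked = result$shortlist_ranked,
    discarded_nonsignificant = result$discarded_nonsignificant,
    discarded_background = result$discarded_background,
    criteria = unclass(result$criteria),
    audit = result$audit,
    ties = result$ties
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
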