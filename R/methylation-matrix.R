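#' Sample-by-gene percent-methylation matrix
#'
#' The central container of the package: a numeric samples x genes matrix of
#' percent methylation (%M, 0-100) together with per-sample annotation
#' (tissue class, optional age and microsatellite-instability status).
#' Individual cells may be `NA` to record an undefined measurement (assay
#' dropout); `NA`s are never silently imputed and any downstream operation
#' that needs the value raises an error instead.
#'
#' @param values numeric matrix, samples in rows, genes in columns. Rownames
#'   are sample ids and colnames gene ids; both must be unique and non-empty.
#'   All non-missing values must lie in `[0, 100]`.
#' @param class character or factor of length `nrow(values)` with levels
#'   `"carcinoma"` and `"normal"`.
#' @param age optional numeric vector of ages in years.
#' @param msi optional character/factor with values `"MSI"`, `"MSS"` or
#'   `NA`/`"unknown"` (normalised to `NA`).
#' @return An object of class `methylation_matrix`.
#' @export
#' @examples
#' v <- matrix(c(10, 0, 80, 5), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("MAL", "TMEFF2")))
#' methylation_matrix(v, class = c("carcinoma", "normal"))
methylation_matrix <- function(values, class, age = NULL, msi = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and gene ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%%M out of [0,100] at sample '%s', gene '%s' (value %g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  class <- as.character(class)
  if (length(class) != nrow(values) || anyNA(class)) {
    stop("every sample needs a class label", call. = FALSE)
  }
  if (!all(class %in% c("carcinoma", "normal"))) {
    stop("class labels must be 'carcinoma' or 'normal'", call. = FALSE)
  }
  if (!is.null(age)) {
    age <- as.numeric(age)
    stopifnot(length(age) == nrow(values))
  }
  if (!is.null(msi)) {
    msi <- as.character(msi)
    stopifnot(length(msi) == nrow(values))
    msi[msi %in% c("unknown", "NA", "")] <- NA_character_
    ok <- is.na(msi) | msi %in% c("MSI", "MSS")
    if (!all(ok)) {
      stop("msi labels must be 'MSI', 'MSS' or unknown", call. = FALSE)
    }
  }
  structure(
    list(values = values, class = class, age = age, msi = msi),
    class = "methylation_matrix"
  )
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf(
    "methylation_matrix: %d samples x %d genes (%d carcinoma, %d normal)\n",
    nrow(x$values), ncol(x$values),
    sum(x$class == "carcinoma"), sum(x$class == "normal")))
  if (!is.null(x$msi)) {
    cat(sprintf("  MSI labels: %d MSI, %d MSS, %d unknown\n",
                sum(x$msi == "MSI", na.rm = TRUE),
                sum(x$msi == "MSS", na.rm = TRUE), sum(is.na(x$msi))))
  }
  if (!is.null(x$age)) cat(sprintf("  ages: %s\n",
                                   paste(range(x$age), collapse = "-")))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

#' Sample ids of a methylation matrix
#' @param x a `methylation_matrix`.
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Gene ids of a methylation matrix
#' @param x a `methylation_matrix`.
#' @return character vector.
#' @export
gene_ids <- function(x) colnames(x$values)

#' Named ordered gene panel
#'
#' A panel is the unit over which the cumulative methylation index is summed.
#'
#' @param name panel name.
#' @param genes character vector of gene ids, non-empty, no duplicates.
#' @return An object of class `panel_definition`.
#' @export
panel_definition <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("panel must contain at least one gene",
                               call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("panel contains duplicate genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name)[1], genes = genes),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("panel '%s' (%d genes): %s\n", x$name, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' @export
length.panel_definition <- function(x) length(x$genes)

#' Restrict a methylation matrix to the genes of a panel
#'
#' Columns are reordered to the panel's gene order; samples and their
#' annotation are untouched.
#'
#' @param matrix a `methylation_matrix`.
#' @param panel a `panel_definition` whose genes are all present in `matrix`.
#' @return A `methylation_matrix` with `length(panel)` columns.
#' @export
subset_panel <- function(matrix, panel) {
  stopifnot(inherits(matrix, "methylation_matrix"),
            inherits(panel, "panel_definition"))
  missing <- setdiff(panel$genes, gene_ids(matrix))
  if (length(missing) > 0) {
    stop("panel gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  methylation_matrix(matrix$values[, panel$genes, drop = FALSE],
                     class = matrix$class, age = matrix$age, msi = matrix$msi)
}
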