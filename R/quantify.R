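#' Percent methylation from methylated/unmethylated copy counts
#'
#' Computes \%M = 100 * methylated / (methylated + unmethylated), the
#' per-gene per-sample quantity produced by quantitative multiplex
#' methylation-specific PCR. A total of zero copies is an undefined
#' measurement (assay dropout), not 0\% methylation, and raises an error.
#'
#' @param methylated non-negative count(s) of methylated copies.
#' @param unmethylated non-negative count(s) of unmethylated copies.
#' @return numeric \%M in `[0, 100]`, vectorised over the inputs.
#' @export
#' @examples
#' percent_methylation(50, 50)   # 50
#' percent_methylation(0, 100)   # 0
percent_methylation <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0)) {
    stop("copy counts must be non-negative", call. = FALSE)
  }
  total <- methylated + unmethylated
  if (any(total == 0)) {
    stop("undefined %M: zero total copies (assay dropout, not 0% methylation)",
         call. = FALSE)
  }
  100 * methylated / total
}

#' Cumulative methylation index (CMI) over a panel
#'
#' The CMI of a sample is the sum of \%M over the genes of a panel; it is the
#' classification score for panel-level detection. Gene order is irrelevant.
#' A missing \%M for any panel gene is an error: dropout is surfaced, never
#' imputed as zero.
#'
#' @param matrix a [methylation_matrix()].
#' @param panel a [panel_definition()]; all its genes must be in `matrix`.
#' @return data.frame with columns `sample_id`, `class`, `cmi`
#'   (CMI units, `0` to `100 * length(panel)`), one row per sample in the
#'   matrix's sample order.
#' @export
compute_cmi <- function(matrix, panel) {
  sub <- subset_panel(matrix, panel)
  vals <- sub$values
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing %%M for sample '%s', gene '%s'",
                 rownames(vals)[bad[1]], colnames(vals)[bad[2]]),
         call. = FALSE)
  }
  data.frame(sample_id = rownames(vals),
             class = sub$class,
             cmi = rowSums(vals),
             row.names = NULL, stringsAsFactors = FALSE)
}

# CMI split into carcinoma/normal score vectors, the shape ROC code consumes.
cmi_scores <- function(matrix, panel) {
  cmi <- compute_cmi(matrix, panel)
  list(pos = cmi$cmi[cmi$class == "carcinoma"],
       neg = cmi$cmi[cmi$class == "normal"])
}
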