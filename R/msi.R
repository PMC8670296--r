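#' Per-gene differential methylation between MSI and MSS carcinomas
#'
#' For each gene, compares \%M between microsatellite-unstable (MSI) and
#' microsatellite-stable (MSS) carcinoma samples with a two-tailed
#' Mann-Whitney test. Samples with unknown MSI status (and all normal
#' samples) are excluded internally; the number excluded is reported with a
#' message, and results are identical whether unknowns are pre-filtered by
#' the caller or not.
#'
#' Raw p-values are the primary output; a Bonferroni-adjusted column is
#' emitted alongside as an extension to make the multiple-testing burden
#' visible.
#'
#' @param matrix a [methylation_matrix()] with `msi` labels on carcinoma
#'   samples.
#' @param genes genes to test (default: all genes in the matrix).
#' @param mode Mann-Whitney mode, see [mann_whitney()].
#' @return data.frame with columns `gene`, `n_msi`, `n_mss`, `median_msi`,
#'   `median_mss`, `direction` (sign of `median_msi - median_mss`),
#'   `p_raw`, `p_bonferroni`.
#' @export
msi_differential <- function(matrix, genes = gene_ids(matrix),
                             mode = "auto") {
  stopifnot(inherits(matrix, "methylation_matrix"))
  if (is.null(matrix$msi)) stop("matrix carries no MSI labels", call. = FALSE)
  ca <- matrix$class == "carcinoma"
  msi <- ca & !is.na(matrix$msi) & matrix$msi == "MSI"
  mss <- ca & !is.na(matrix$msi) & matrix$msi == "MSS"
  excluded <- sum(ca) - sum(msi) - sum(mss)
  if (excluded > 0) {
    message(excluded, " carcinoma sample(s) with unknown MSI status excluded")
  }
  if (sum(msi) < 2 || sum(mss) < 2) {
    stop("need at least 2 samples in each of the MSI and MSS groups",
         call. = FALSE)
  }
  missing <- setdiff(genes, gene_ids(matrix))
  if (length(missing) > 0) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    a <- matrix$values[msi, g]
    b <- matrix$values[mss, g]
    mt <- mann_whitney(a, b, mode = mode)
    data.frame(gene = g, n_msi = sum(msi), n_mss = sum(mss),
               median_msi = stats::median(a), median_mss = stats::median(b),
               direction = sign(stats::median(a) - stats::median(b)),
               p_raw = mt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' MSI-vs-MSS comparison of panel-level cumulative methylation
#'
#' Mann-Whitney test of the per-sample CMI of a panel between MSI and MSS
#' carcinomas.
#'
#' @param matrix a [methylation_matrix()] with `msi` labels.
#' @param panel a [panel_definition()].
#' @param mode Mann-Whitney mode.
#' @return one-row data.frame shaped like [msi_differential()] output, with
#'   the panel name in the `gene` column.
#' @export
msi_cmi_test <- function(matrix, panel, mode = "auto") {
  stopifnot(inherits(panel, "panel_definition"))
  if (is.null(matrix$msi)) stop("matrix carries no MSI labels", call. = FALSE)
  cmi <- compute_cmi(matrix, panel)$cmi
  ca <- matrix$class == "carcinoma"
  msi <- ca & !is.na(matrix$msi) & matrix$msi == "MSI"
  mss <- ca & !is.na(matrix$msi) & matrix$msi == "MSS"
  excluded <- sum(ca) - sum(msi) - sum(mss)
  if (excluded > 0) {
    message(excluded, " carcinoma sample(s) with unknown MSI status excluded")
  }
  if (sum(msi) < 2 || sum(mss) < 2) {
    stop("need at least 2 samples in each of the MSI and MSS groups",
         call. = FALSE)
  }
  a <- cmi[msi]; b <- cmi[mss]
  mt <- mann_whitney(a, b, mode = mode)
  data.frame(gene = panel$name, n_msi = sum(msi), n_mss = sum(mss),
             median_msi = stats::median(a), median_mss = stats::median(b),
             direction = sign(stats::median(a) - stats::median(b)),
             p_raw = mt$p_value, p_bonferroni = mt$p_value,
             stringsAsFactors = FALSE)
}
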