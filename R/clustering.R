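#' Probe-by-sample beta-value matrix
#'
#' Array-style methylation fractions (beta values in `[0, 1]`) for CpG
#' probes; a deliberately distinct type from the \%M scale of
#' [methylation_matrix()] to prevent unit confusion. Probes may map
#' many-to-one onto genes via an optional probe-to-gene map.
#'
#' @param values numeric matrix, probes in rows, samples in columns, values
#'   in `[0, 1]` (`NA` allowed; probes with missing values are dropped, with
#'   a message, by the distance computation).
#' @param class per-sample labels, `"carcinoma"` or `"normal"`.
#' @param gene_map optional named character vector, probe id -> gene id.
#' @return object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, class, gene_map = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (probes x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate probe or sample ids", call. = FALSE)
  }
  if (any(!is.na(values) & (values < 0 | values > 1))) {
    stop("beta values must lie in [0,1]", call. = FALSE)
  }
  class <- as.character(class)
  stopifnot(length(class) == ncol(values),
            all(class %in% c("carcinoma", "normal")))
  structure(list(values = values, class = class, gene_map = gene_map),
            class = "beta_matrix")
}

#' Pairwise Euclidean distances between matrix rows
#'
#' Rows containing any missing value are dropped first (with a message
#' reporting how many), so distances are always computed on complete rows.
#'
#' @param x numeric matrix with at least two complete rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(x) {
  stopifnot(is.matrix(x))
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least 2 complete rows", call. = FALSE)
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Agglomerative clustering with unweighted average linkage (UPGMA)
#'
#' Wraps [stats::hclust()] with `method = "average"`, i.e. the inter-cluster
#' distance `d(A+B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)`. The test
#' suite checks the merge sequence against an exhaustive step-by-step
#' recomputation oracle.
#'
#' @param distances symmetric distance matrix (e.g. from
#'   [pairwise_euclidean()]) or a `dist` object.
#' @return an `hclust` object (fields `merge`, `height`, `order`).
#' @export
average_linkage <- function(distances) {
  d <- if (inherits(distances, "dist")) distances else stats::as.dist(distances)
  stats::hclust(d, method = "average")
}

#' Per-probe differential methylation score
#'
#' Mean beta in carcinoma minus mean beta in normal, per probe. This
#' operationalizes the visual "most differentially methylated cluster" pick
#' of a two-way heatmap screen.
#'
#' @param beta a [beta_matrix()] containing both classes.
#' @return named numeric vector of scores, one per probe.
#' @export
differential_score <- function(beta) {
  stopifnot(inherits(beta, "beta_matrix"))
  is_ca <- beta$class == "carcinoma"
  if (!any(is_ca) || all(is_ca)) {
    stop("both classes required", call. = FALSE)
  }
  rowMeans(beta$values[, is_ca, drop = FALSE]) -
    rowMeans(beta$values[, !is_ca, drop = FALSE])
}

#' Nominate a candidate probe cluster from the prescreen
#'
#' Clusters probes (rows) by UPGMA on Euclidean distances, cuts the tree
#' into `k` clusters (or at height `h`), and returns the members of the
#' cluster with the highest mean differential score, filtered to probes
#' whose own score reaches `min_score`. An optional manual `include` list
#' adds probes chosen by inspection outside the winning cluster. When a
#' `gene_map` is present the probe list is collapsed to genes (any
#' qualifying probe qualifies its gene).
#'
#' @param beta a [beta_matrix()].
#' @param k number of clusters to cut into (exclusive with `h`).
#' @param h cut height (used when `k` is `NULL`).
#' @param min_score minimum per-probe differential score (default 0).
#' @param include character vector of probe ids to force-include.
#' @return list with `probes` (selected probe ids), `genes` (collapsed gene
#'   ids, equal to `probes` when no map is attached), `cluster_id`, and
#'   `scores` (per-probe differential scores).
#' @export
candidate_cluster <- function(beta, k = 2, h = NULL, min_score = 0,
                              include = character(0)) {
  stopifnot(inherits(beta, "beta_matrix"))
  score <- differential_score(beta)
  keep <- stats::complete.cases(beta$values)
  vals <- beta$values[keep, , drop = FALSE]
  score <- score[keep]
  hc <- average_linkage(pairwise_euclidean(vals))
  groups <- if (is.null(h)) stats::cutree(hc, k = k)
            else stats::cutree(hc, h = h)
  by_cluster <- tapply(score, groups, mean)
  win <- as.integer(names(by_cluster)[which.max(by_cluster)])
  members <- rownames(vals)[groups == win]
  selected <- members[score[members] >= min_score]
  if (length(selected) == 0) {
    warning("no probe in the winning cluster reaches min_score = ",
            min_score, call. = FALSE)
  }
  selected <- union(selected, intersect(include, rownames(beta$values)))
  genes <- if (is.null(beta$gene_map)) selected else
    unique(unname(beta$gene_map[selected]))
  list(probes = selected, genes = genes, cluster_id = win, scores = score)
}
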