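#' Criteria for the three-stage marker-selection procedure
#'
#' @param alpha two-tailed significance level for the carcinoma-vs-normal
#'   Mann-Whitney filter (default 0.05).
#' @param background_cutoff normal-class 75th-percentile \%M at or above
#'   which a marker is considered to have high background and is eliminated
#'   (inclusive rule; default 10).
#' @param top_k panel size taken from the top of the ranked shortlist
#'   (default 6).
#' @param percentile_method quartile convention passed to
#'   [five_number_summary()].
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(alpha = 0.05, background_cutoff = 10,
                               top_k = 6, percentile_method = "type6") {
  stopifnot(alpha > 0, alpha < 1, background_cutoff >= 0, top_k >= 1)
  structure(list(alpha = alpha, background_cutoff = background_cutoff,
                 top_k = as.integer(top_k),
                 percentile_method = percentile_method),
            class = "selection_criteria")
}

#' Per-marker class-wise summaries and differential-methylation p-values
#'
#' For every gene, the five-number summary of \%M in each class plus the
#' two-tailed carcinoma-vs-normal Mann-Whitney p-value. This is the input
#' shape of the selection filters, and the shape of the packaged reference
#' table ([reference_marker_summaries()]), so selection can be run either
#' from raw data or from published summaries directly.
#'
#' @param matrix a [methylation_matrix()] containing both classes.
#' @param criteria a [selection_criteria()] (for the percentile convention).
#' @param mode Mann-Whitney mode, see [mann_whitney()].
#' @return data.frame with columns `gene`, `ca_min` .. `ca_max`,
#'   `no_min` .. `no_max`, `p_value`.
#' @export
summarize_markers <- function(matrix, criteria = selection_criteria(),
                              mode = "auto") {
  stopifnot(inherits(matrix, "methylation_matrix"))
  is_ca <- matrix$class == "carcinoma"
  if (!any(is_ca) || all(is_ca)) {
    stop("both carcinoma and normal samples are required", call. = FALSE)
  }
  rows <- lapply(gene_ids(matrix), function(g) {
    v <- matrix$values[, g]
    if (anyNA(v)) {
      stop(sprintf("missing %%M for gene '%s'; drop affected samples first", g),
           call. = FALSE)
    }
    ca <- five_number_summary(v[is_ca], criteria$percentile_method)
    no <- five_number_summary(v[!is_ca], criteria$percentile_method)
    p <- mann_whitney(v[is_ca], v[!is_ca], mode = mode)$p_value
    data.frame(gene = g,
               ca_min = ca[["minimum"]], ca_q25 = ca[["q25"]],
               ca_median = ca[["median"]], ca_q75 = ca[["q75"]],
               ca_max = ca[["maximum"]],
               no_min = no[["minimum"]], no_q25 = no[["q25"]],
               no_median = no[["median"]], no_q75 = no[["q75"]],
               no_max = no[["maximum"]],
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_summary_frame <- function(summaries) {
  needed <- c("gene", "ca_median", "ca_q75", "no_median", "no_q75", "p_value")
  missing <- setdiff(needed, names(summaries))
  if (length(missing) > 0) {
    stop("summary table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(summaries$p_value)) {
    stop("p_value required for every gene", call. = FALSE)
  }
  invisible(summaries)
}

#' Stage 1: discard markers not significantly hypermethylated in carcinoma
#'
#' A marker survives when its two-tailed p-value is below `alpha` *and* the
#' difference points the right way (carcinoma median at least the normal
#' median): the criterion is significantly *higher* methylation in
#' carcinoma, not merely different.
#'
#' @param summaries data.frame as produced by [summarize_markers()].
#' @param criteria a [selection_criteria()].
#' @return list with `kept` (data.frame) and `discarded` (character vector
#'   of gene ids).
#' @export
filter_significant <- function(summaries, criteria = selection_criteria()) {
  check_summary_frame(summaries)
  keep <- summaries$p_value < criteria$alpha &
    summaries$ca_median >= summaries$no_median
  list(kept = summaries[keep, , drop = FALSE],
       discarded = summaries$gene[!keep])
}

#' Stage 2: discard markers with high normal-tissue background
#'
#' Background is quantified as the normal-class 75th percentile of \%M; a
#' value at or above the cutoff disqualifies the marker (the boundary value
#' itself is eliminated).
#'
#' @inheritParams filter_significant
#' @return list with `kept` and `discarded` as in [filter_significant()].
#' @export
filter_background <- function(summaries, criteria = selection_criteria()) {
  check_summary_frame(summaries)
  keep <- summaries$no_q75 < criteria$background_cutoff
  list(kept = summaries[keep, , drop = FALSE],
       discarded = summaries$gene[!keep])
}

#' Stage 3: rank surviving markers and take the top k as the panel
#'
#' Markers are sorted by descending carcinoma 75th-percentile \%M. Ties are
#' broken by descending carcinoma median, then lexical gene id; tie events
#' are recorded in the result.
#'
#' @param summaries data.frame of surviving markers (non-empty).
#' @param criteria a [selection_criteria()].
#' @return list with `shortlist_ranked` (gene ids, best first), `panel`
#'   (a [panel_definition()] of the top `top_k`), and `ties` (data.frame of
#'   tied gene pairs, zero rows when ranking was unambiguous).
#' @export
rank_and_select <- function(summaries, criteria = selection_criteria()) {
  check_summary_frame(summaries)
  if (nrow(summaries) == 0) stop("no markers to rank", call. = FALSE)
  ord <- order(-summaries$ca_q75, -summaries$ca_median, summaries$gene)
  ranked <- summaries[ord, , drop = FALSE]
  key <- paste(ranked$ca_q75, ranked$ca_median)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  ties <- data.frame(gene = ranked$gene[dup],
                     ca_q75 = ranked$ca_q75[dup],
                     ca_median = ranked$ca_median[dup],
                     stringsAsFactors = FALSE)
  if (nrow(ties) > 0) {
    message("rank ties broken lexically among: ",
            paste(ties$gene, collapse = ", "))
  }
  k <- min(criteria$top_k, nrow(ranked))
  list(shortlist_ranked = ranked$gene,
       panel = panel_definition(sprintf("top%d", k), ranked$gene[seq_len(k)]),
       ties = ties)
}

#' Full three-stage panel selection from per-marker summaries
#'
#' Applies, in fixed order, the significance filter, the normal-background
#' filter and the carcinoma-75th-percentile ranking with top-k pick, and
#' returns the complete audit trail. The three discard/shortlist sets
#' partition the input genes.
#'
#' @param summaries data.frame as from [summarize_markers()] or
#'   [reference_marker_summaries()].
#' @param criteria a [selection_criteria()].
#' @return object of class `selection_result`: list with `panel`,
#'   `shortlist_ranked`, `discarded_nonsignificant`, `discarded_background`,
#'   `ties`, `audit` (per-gene stage outcome), `criteria`.
#' @export
select_panel_from_summaries <- function(summaries,
                                        criteria = selection_criteria()) {
  check_summary_frame(summaries)
  s1 <- filter_significant(summaries, criteria)
  s2 <- filter_background(s1$kept, criteria)
  s3 <- rank_and_select(s2$kept, criteria)
  audit <- data.frame(
    gene = summaries$gene,
    outcome = ifelse(
      summaries$gene %in% s1$discarded, "discarded_nonsignificant",
      ifelse(summaries$gene %in% s2$discarded, "discarded_background",
             ifelse(summaries$gene %in% s3$panel$genes, "panel",
                    "shortlist_only"))),
    stringsAsFactors = FALSE)
  structure(list(panel = s3$panel,
                 shortlist_ranked = s3$shortlist_ranked,
                 discarded_nonsignificant = s1$discarded,
                 discarded_background = s2$discarded,
                 ties = s3$ties, audit = audit, criteria = criteria),
            class = "selection_result")
}

#' Full three-stage panel selection from raw data
#'
#' Convenience composition: [summarize_markers()] followed by
#' [select_panel_from_summaries()].
#'
#' @param matrix a [methylation_matrix()] with both classes.
#' @param criteria a [selection_criteria()].
#' @param mode Mann-Whitney mode.
#' @return a `selection_result`, see [select_panel_from_summaries()].
#' @export
select_panel <- function(matrix, criteria = selection_criteria(),
                         mode = "auto") {
  select_panel_from_summaries(summarize_markers(matrix, criteria, mode),
                              criteria)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("marker selection\n")
  cat("  discarded (not significant):",
      paste(x$discarded_nonsignificant, collapse = ", "), "\n")
  cat("  discarded (high background):",
      paste(x$discarded_background, collapse = ", "), "\n")
  cat("  shortlist (ranked):", paste(x$shortlist_ranked, collapse = " > "),
      "\n")
  cat("  panel:", paste(x$panel$genes, collapse = ", "), "\n")
  invisible(x)
}
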