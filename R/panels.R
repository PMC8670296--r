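#' Built-in marker panels
#'
#' The four panels used throughout the workflow: the full 13-marker tissue
#' candidate set, the minimal 6-gene tissue panel derived from it by
#' [select_panel()], the 8-gene liquid-biopsy panel (TWIST1 excluded for
#' technical irreproducibility in circulating DNA; the three high
#' tissue-background genes retained because their background is negligible
#' in plasma), and its minimal 5-gene subset.
#'
#' @return named list of [panel_definition()] objects:
#'   `tissue13`, `tissue6`, `plasma8`, `plasma5`.
#' @export
default_panels <- function() {
  list(
    tissue13 = panel_definition("tissue13", c(
      "TMEFF2", "GPX7", "MAL", "ARHGEF7", "TWIST1", "AKR1B1", "HIN1",
      "GAS7", "TM6SF1", "ZNF671", "COL6A2", "APC", "HIST1H3C")),
    tissue6 = panel_definition("tissue6", c(
      "TMEFF2", "GPX7", "MAL", "ARHGEF7", "TWIST1", "AKR1B1")),
    plasma8 = panel_definition("plasma8", c(
      "TMEFF2", "COL6A2", "ZNF671", "ARHGEF7", "TM6SF1", "MAL", "GPX7",
      "AKR1B1")),
    plasma5 = panel_definition("plasma5", c(
      "TMEFF2", "ZNF671", "AKR1B1", "MAL", "COL6A2"))
  )
}

#' Reference per-marker distribution summaries (colon tissue training cohort)
#'
#' Published five-number summaries of percent methylation (%M) for 13
#' candidate markers measured by QM-MSP in a colon-tissue training cohort of
#' 30 carcinomas and 23 adjacent-normal samples, together with the reported
#' carcinoma-vs-normal Mann-Whitney p-values. Quartiles follow the
#' k = p(n+1) percentile convention. P-values reported only as "< 0.0001"
#' are stored as 1e-4; the selection procedure consumes them solely through
#' the `p < alpha` comparison.
#'
#' This table is both the worked example for the marker-selection procedure
#' and the default parameterisation of the synthetic tissue-cohort sampler
#' ([generate_tissue_cohort()]).
#'
#' @return data.frame with one row per gene and columns
#'   `gene`, `ca_min`, `ca_q25`, `ca_median`, `ca_q75`, `ca_max`,
#'   `no_min`, `no_q25`, `no_median`, `no_q75`, `no_max`, `p_value`.
#' @export
reference_marker_summaries <- function() {
  df <- data.frame(
    gene      = c("TMEFF2", "GPX7", "MAL", "ARHGEF7", "TWIST1", "AKR1B1",
                  "HIN1", "GAS7", "TM6SF1", "ZNF671", "COL6A2", "APC",
                  "HIST1H3C"),
    ca_min    = c(0,  0,  9,  0,  6,  0,  0,  0,  0,  0,  0,  0,  0),
    ca_q25    = c(40, 1,  21, 0,  14, 10, 0,  6,  35, 25, 12, 0,  0),
    ca_median = c(59, 33, 33, 8,  18, 16, 5,  9,  47, 39, 34, 0,  1),
    ca_q75    = c(75, 53, 49, 33, 28, 21, 18, 12, 58, 49, 52, 58, 55),
    ca_max    = c(94, 72, 71, 75, 50, 52, 61, 36, 70, 72, 66, 92, 78),
    no_min    = c(0,  0,  0,  0,  1,  0,  0,  0,  1,  2,  1,  0,  0),
    no_q25    = c(0,  0,  1,  0,  3,  0,  0,  0,  5,  7,  4,  1,  0),
    no_median = c(1,  0,  2,  0,  4,  0,  0,  1,  10, 13, 8,  2,  1),
    no_q75    = c(3,  0,  3,  0,  6,  0,  0,  2,  15, 16, 10, 2,  3),
    no_max    = c(11, 2,  7,  2,  11, 1,  0,  4,  40, 20, 23, 7,  8),
    p_value   = c(rep(1e-4, 11), 0.2662, 0.3959),
    stringsAsFactors = FALSE
  )
  df
}

#' Reference cohort sample sizes
#'
#' Sizes of the tissue training cohort the reference summaries describe:
#' 30 carcinomas, 23 adjacent normals.
#'
#' @return named integer vector `c(carcinoma = 30, normal = 23)`.
#' @export
reference_cohort_sizes <- function() c(carcinoma = 30L, normal = 23L)
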