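#' Piecewise-linear quantile function from a five-number summary
#'
#' Interpolates linearly through (0, min), (0.25, q25), (0.5, median),
#' (0.75, q75), (1, max). By construction inverse-transform sampling from
#' the result reproduces the five printed numbers exactly in the large-n
#' limit, including point masses when adjacent summary values coincide, and
#' every draw lies inside `[min, max]`.
#'
#' @param summary numeric of length 5 in the order min, q25, median, q75,
#'   max (e.g. a [five_number_summary()] result); must be non-decreasing.
#' @return object of class `quantile_spec`: list with `fun` (the quantile
#'   function Q on `[0, 1]`) and `support = c(min, max)`.
#' @export
#' @examples
#' q <- fit_quantile_function(c(9, 21, 33, 49, 71))
#' q$fun(0.375)  # 27
fit_quantile_function <- function(summary) {
  summary <- as.numeric(summary)
  stopifnot(length(summary) == 5)
  if (is.unsorted(summary)) {
    stop("five-number summary must be non-decreasing", call. = FALSE)
  }
  fun <- if (summary[1] == summary[5]) {
    function(u) rep(summary[1], length(u))
  } else {
    stats::approxfun(c(0, 0.25, 0.5, 0.75, 1), summary, rule = 2)
  }
  structure(list(fun = fun, support = summary[c(1, 5)], knots = summary),
            class = "quantile_spec")
}

#' Inverse-transform sample from a quantile spec
#'
#' @param spec a [fit_quantile_function()] result.
#' @param n number of draws.
#' @return numeric vector of length `n`, all values within the spec's
#'   support. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
sample_gene <- function(spec, n) {
  stopifnot(inherits(spec, "quantile_spec"), n >= 1)
  spec$fun(stats::runif(n))
}

# Truncated-normal ages with a fixed one-draw-per-sample RNG footprint.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic tissue cohort from per-marker quantile summaries
#'
#' Samples per-gene \%M independently within class by inverse-transform
#' sampling from piecewise-linear quantile functions fit to the supplied
#' five-number summaries (defaults: the packaged reference table, at the
#' reference cohort sizes of 30 carcinomas and 23 normals). Within-class
#' gene-gene independence is a deliberate simplification: only marginals
#' are published, and correlation between hypermethylated genes would only
#' sharpen panel-level separation.
#'
#' A configurable fraction of carcinomas is labelled MSI (default 1/3,
#' matching 20 MSI / 40 MSS in the reference tissue series); an optional
#' additive \%M shift is applied to MSI samples for chosen genes and the
#' result clipped to `[0, 100]`. Ages are truncated-normal (default mean
#' 69 carcinoma / 66 normal, sd 8, range 40-95).
#'
#' @param summaries data.frame shaped like [reference_marker_summaries()].
#' @param n_carcinoma,n_normal class sizes.
#' @param msi_fraction fraction of carcinomas labelled MSI.
#' @param msi_shift named numeric vector, gene -> additive \%M shift applied
#'   to MSI samples (default none).
#' @param age_mean named numeric, per-class mean age in years.
#' @param age_sd,age_range age dispersion and truncation bounds.
#' @param seed integer seed; identical seed and spec give a bit-identical
#'   cohort.
#' @return a [methylation_matrix()] with class, age and (when
#'   `msi_fraction > 0`) MSI labels.
#' @export
generate_tissue_cohort <- function(summaries = reference_marker_summaries(),
                                   n_carcinoma = 30, n_normal = 23,
                                   msi_fraction = 1 / 3,
                                   msi_shift = NULL,
                                   age_mean = c(carcinoma = 69, normal = 66),
                                   age_sd = 8, age_range = c(40, 95),
                                   seed = NULL) {
  stopifnot(n_carcinoma >= 1, n_normal >= 1,
            msi_fraction >= 0, msi_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- summaries$gene
  n <- n_carcinoma + n_normal
  vals <- matrix(NA_real_, nrow = n, ncol = length(genes),
                 dimnames = list(
                   c(sprintf("ca%03d", seq_len(n_carcinoma)),
                     sprintf("no%03d", seq_len(n_normal))), genes))
  for (i in seq_along(genes)) {
    ca_spec <- fit_quantile_function(unlist(
      summaries[i, c("ca_min", "ca_q25", "ca_median", "ca_q75", "ca_max")]))
    no_spec <- fit_quantile_function(unlist(
      summaries[i, c("no_min", "no_q25", "no_median", "no_q75", "no_max")]))
    vals[seq_len(n_carcinoma), i] <- sample_gene(ca_spec, n_carcinoma)
    vals[n_carcinoma + seq_len(n_normal), i] <- sample_gene(no_spec, n_normal)
  }
  cls <- rep(c("carcinoma", "normal"), c(n_carcinoma, n_normal))
  age <- c(rtrunc_norm(n_carcinoma, age_mean[["carcinoma"]], age_sd,
                       age_range[1], age_range[2]),
           rtrunc_norm(n_normal, age_mean[["normal"]], age_sd,
                       age_range[1], age_range[2]))
  msi <- NULL
  if (msi_fraction > 0) {
    msi <- rep(NA_character_, n)
    n_msi <- round(n_carcinoma * msi_fraction)
    which_msi <- sample(seq_len(n_carcinoma), n_msi)
    msi[seq_len(n_carcinoma)] <- "MSS"
    msi[which_msi] <- "MSI"
    if (!is.null(msi_shift) && n_msi > 0) {
      shift_genes <- intersect(names(msi_shift), genes)
      for (g in shift_genes) {
        vals[which_msi, g] <- pmin(100, pmax(0, vals[which_msi, g] +
                                               msi_shift[[g]]))
      }
    }
  }
  methylation_matrix(vals, class = cls, age = age, msi = msi)
}

#' Generate a synthetic plasma cohort (low-background regime)
#'
#' Emulates cell-free-DNA methylation: normal plasma shows negligible
#' background (per gene, \%M is 0 with probability `background_zero_prob`,
#' otherwise uniform on `[0, background_max]`), while carcinoma plasma
#' carries positive signal (per gene, zero with probability
#' `signal_zero_prob`, otherwise gamma-distributed and clipped to
#' `[0, 100]`). These defaults are invented operating conditions for
#' exercising the plasma panel workflow; they are not calibrated to any
#' assay chemistry.
#'
#' @param genes gene ids (default: the 8-gene plasma panel).
#' @param n_carcinoma,n_normal class sizes (default 20/20).
#' @param background_zero_prob,background_max normal-class background
#'   parameters.
#' @param signal_zero_prob,signal_shape,signal_scale carcinoma-class signal
#'   parameters (gamma shape/scale in \%M units).
#' @param seed integer seed.
#' @return a [methylation_matrix()] (no ages or MSI labels).
#' @export
generate_plasma_cohort <- function(genes = default_panels()$plasma8$genes,
                                   n_carcinoma = 20, n_normal = 20,
                                   background_zero_prob = 0.9,
                                   background_max = 2,
                                   signal_zero_prob = 0.2,
                                   signal_shape = 2, signal_scale = 8,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_carcinoma + n_normal
  vals <- matrix(NA_real_, nrow = n, ncol = length(genes),
                 dimnames = list(
                   c(sprintf("ca%03d", seq_len(n_carcinoma)),
                     sprintf("no%03d", seq_len(n_normal))), genes))
  for (i in seq_along(genes)) {
    sig <- pmin(100, stats::rgamma(n_carcinoma, shape = signal_shape,
                                   scale = signal_scale))
    sig[stats::runif(n_carcinoma) < signal_zero_prob] <- 0
    bg <- stats::runif(n_normal, 0, background_max)
    bg[stats::runif(n_normal) < background_zero_prob] <- 0
    vals[, i] <- c(sig, bg)
  }
  methylation_matrix(vals,
                     class = rep(c("carcinoma", "normal"),
                                 c(n_carcinoma, n_normal)))
}

#' Generate a synthetic probe-by-sample beta matrix with block structure
#'
#' Builds a beta-value matrix containing a differential probe block
#' (elevated mean in carcinoma) and a null block (same low mean in both
#' classes), with truncated-Gaussian noise around the block means. With
#' `noise_sd = 0` the design is deterministic, which is the fixture used to
#' validate [candidate_cluster()] exactly.
#'
#' @param n_probes total probes; the first `n_diff` form the differential
#'   block.
#' @param n_diff number of differential probes.
#' @param n_carcinoma,n_normal sample counts per class (defaults match a
#'   450K-style tumor/normal screen, 289/38).
#' @param mean_diff_ca,mean_diff_no,mean_null block means in beta units.
#' @param noise_sd Gaussian noise sd (values clipped to `[0, 1]`).
#' @param seed integer seed.
#' @return a [beta_matrix()]; differential probes are named `"diff<i>"`,
#'   null probes `"null<i>"`.
#' @export
generate_beta_matrix <- function(n_probes = 22, n_diff = 13,
                                 n_carcinoma = 289, n_normal = 38,
                                 mean_diff_ca = 0.7, mean_diff_no = 0.15,
                                 mean_null = 0.15, noise_sd = 0.1,
                                 seed = NULL) {
  stopifnot(n_probes >= 1, n_diff >= 0, n_diff <= n_probes)
  if (!is.null(seed)) set.seed(seed)
  n <- n_carcinoma + n_normal
  probe_ids <- c(if (n_diff > 0) sprintf("diff%02d", seq_len(n_diff)),
                 if (n_probes > n_diff)
                   sprintf("null%02d", seq_len(n_probes - n_diff)))
  mu <- matrix(mean_null, nrow = n_probes, ncol = n)
  if (n_diff > 0) {
    mu[seq_len(n_diff), seq_len(n_carcinoma)] <- mean_diff_ca
    mu[seq_len(n_diff), n_carcinoma + seq_len(n_normal)] <- mean_diff_no
  }
  vals <- mu
  if (noise_sd > 0) {
    vals <- vals + stats::rnorm(length(mu), 0, noise_sd)
    vals <- pmin(pmax(vals, 0), 1)
  }
  dimnames(vals) <- list(probe_ids,
                         c(sprintf("ca%03d", seq_len(n_carcinoma)),
                           sprintf("no%03d", seq_len(n_normal))))
  beta_matrix(vals, class = rep(c("carcinoma", "normal"),
                                c(n_carcinoma, n_normal)))
}

#' Randomized age-balanced train/test split
#'
#' Randomly halves a cohort stratified by class and, when ages are present,
#' by within-class age tertile, so the two sets are matched for lesion-type
#' size (within one sample per stratum) and age. Candidate splits are
#' redrawn until the class-wise mean-age difference between sets is at most
#' `age_tolerance` years (bounded retries; the best candidate seen is kept
#' if the bound is never met). Missing ages degrade gracefully to
#' class-only stratification with a warning.
#'
#' @param matrix a [methylation_matrix()].
#' @param seed integer seed; fixed seed gives an identical split.
#' @param age_tolerance maximum tolerated class-wise mean-age difference
#'   (years, default 3).
#' @param max_retries redraw budget (default 100).
#' @return list with `training` and `test` [methylation_matrix()] objects.
#' @export
split_cohort <- function(matrix, seed = NULL, age_tolerance = 3,
                         max_retries = 100) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(matrix$values)
  has_age <- !is.null(matrix$age) && !anyNA(matrix$age)
  if (!has_age && !is.null(matrix$age)) {
    warning("missing ages: falling back to class-only stratification",
            call. = FALSE)
  }
  strata <- matrix$class
  if (has_age) {
    tert <- rep(NA_character_, n)
    for (cl in unique(matrix$class)) {
      idx <- matrix$class == cl
      cuts <- stats::quantile(matrix$age[idx], c(1, 2) / 3, type = 6)
      tert[idx] <- cut(matrix$age[idx],
                       breaks = c(-Inf, cuts, Inf), labels = FALSE)
    }
    strata <- paste(strata, tert)
  }
  draw_split <- function() {
    train <- logical(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      ns <- length(idx)
      n_tr <- ns %/% 2 + (ns %% 2) * stats::rbinom(1, 1, 0.5)
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  }
  imbalance <- function(train) {
    if (!has_age) return(0)
    max(vapply(unique(matrix$class), function(cl) {
      a <- matrix$age[train & matrix$class == cl]
      b <- matrix$age[!train & matrix$class == cl]
      if (length(a) == 0 || length(b) == 0) return(Inf)
      abs(mean(a) - mean(b))
    }, numeric(1)))
  }
  best <- NULL
  best_im <- Inf
  for (r in seq_len(max_retries)) {
    cand <- draw_split()
    im <- imbalance(cand)
    if (im < best_im) {
      best <- cand
      best_im <- im
    }
    if (best_im <= age_tolerance) break
  }
  take <- function(keep) {
    methylation_matrix(matrix$values[keep, , drop = FALSE],
                       class = matrix$class[keep],
                       age = if (is.null(matrix$age)) NULL
                             else matrix$age[keep],
                       msi = if (is.null(matrix$msi)) NULL
                             else matrix$msi[keep])
  }
  list(training = take(best), test = take(!best))
}
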