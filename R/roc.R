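#' Empirical ROC curve over midpoint thresholds
#'
#' Positive class is carcinoma; the decision rule is
#' `score >= threshold => positive`. Candidate thresholds are the midpoints
#' between consecutive distinct observed scores (pooled over both groups),
#' bracketed by `+Inf` and `-Inf` sentinels so the curve always contains the
#' (sensitivity, specificity) endpoints (0, 1) and (1, 0). Midpoints are the
#' convention that yields half-integer locked thresholds from integer-valued
#' CMI data.
#'
#' @param scores_pos numeric scores of the positive (carcinoma) group.
#' @param scores_neg numeric scores of the negative (normal) group.
#' @return object of class `roc_points`: data.frame with columns
#'   `threshold` (descending), `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  if (anyNA(scores_pos) || anyNA(scores_neg)) {
    stop("missing scores", call. = FALSE)
  }
  pooled <- sort(unique(c(scores_pos, scores_neg)))
  mids <- if (length(pooled) > 1) {
    (pooled[-1] + pooled[-length(pooled)]) / 2
  } else numeric(0)
  thr <- c(Inf, rev(mids), -Inf)                # descending
  sens <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores_neg < t), numeric(1))
  structure(data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec),
            class = c("roc_points", "data.frame"))
}

#' Trapezoidal area under the empirical ROC curve
#'
#' Equals the Mann-Whitney statistic scaled to `[0, 1]`,
#' `U / (n1 * n2)` (with ties counting one half) — an identity the test
#' suite verifies on random instances.
#'
#' @param scores_pos,scores_neg score groups, or pass a precomputed
#'   `roc_points` object as `scores_pos`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_pos, scores_neg = NULL) {
  curve <- if (inherits(scores_pos, "roc_points")) scores_pos
           else roc_curve(scores_pos, scores_neg)
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Lock a classification threshold on training data
#'
#' Among all candidate thresholds whose training specificity is at least
#' `specificity_floor`, picks the one maximizing sensitivity; among equally
#' sensitive candidates the largest (most conservative) threshold wins. The
#' `+Inf` sentinel (specificity 1) guarantees feasibility for any floor.
#' The returned object is the only currency [evaluate_locked()] accepts, so
#' the train-lock-test discipline is enforced structurally: test scores can
#' never alter the threshold.
#'
#' @param scores_pos,scores_neg training score groups.
#' @param specificity_floor minimum training specificity (default 0.90).
#' @param provenance optional character tag (panel name, training-set id).
#' @return object of class `locked_threshold`: list with `value`,
#'   `specificity_floor`, `training_sensitivity`, `training_specificity`,
#'   `provenance`.
#' @export
lock_threshold <- function(scores_pos, scores_neg, specificity_floor = 0.90,
                           provenance = NA_character_) {
  stopifnot(specificity_floor >= 0, specificity_floor <= 1)
  curve <- roc_curve(scores_pos, scores_neg)
  ok <- curve$specificity >= specificity_floor
  cand <- curve[ok, , drop = FALSE]
  best_sens <- max(cand$sensitivity)
  cand <- cand[cand$sensitivity == best_sens, , drop = FALSE]
  pick <- cand[which.max(cand$threshold), , drop = FALSE]
  structure(list(value = pick$threshold,
                 specificity_floor = specificity_floor,
                 training_sensitivity = pick$sensitivity,
                 training_specificity = pick$specificity,
                 provenance = provenance),
            class = "locked_threshold")
}

#' @export
print.locked_threshold <- function(x, ...) {
  cat(sprintf(
    "locked threshold: %g CMI (floor %.0f%%; training sens %.1f%%, spec %.1f%%)%s\n",
    x$value, 100 * x$specificity_floor, 100 * x$training_sensitivity,
    100 * x$training_specificity,
    if (is.na(x$provenance)) "" else paste0(" [", x$provenance, "]")))
  invisible(x)
}

#' Prevalence-adjusted predictive values and accuracy
#'
#' \deqn{\%PPV = 100 \cdot \frac{se \cdot p}{se \cdot p + (1-sp)(1-p)}}
#' \deqn{\%NPV = 100 \cdot \frac{sp (1-p)}{(1-se) p + sp (1-p)}}
#' \deqn{\%Accuracy = 100 \cdot (se \cdot p + sp (1-p))}
#' with sensitivity \eqn{se}, specificity \eqn{sp}, prevalence \eqn{p}.
#' A predictive value whose numerator and denominator are both zero (e.g.
#' PPV at `sensitivity = 0`, `specificity = 1`) is undefined and returned as
#' `NA` with the corresponding `*_defined` flag `FALSE`.
#'
#' @param sensitivity,specificity,prevalence fractions in `[0, 1]`.
#' @return list with `ppv`, `npv`, `accuracy` (percent) and logical
#'   `ppv_defined`, `npv_defined`.
#' @export
#' @examples
#' predictive_values(1, 0.96, 0.01)  # PPV ~ 20.2%, NPV 100%, accuracy 96.04%
predictive_values <- function(sensitivity, specificity, prevalence = 0.01) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  se <- sensitivity; sp <- specificity; p <- prevalence
  ppv_den <- se * p + (1 - sp) * (1 - p)
  npv_den <- (1 - se) * p + sp * (1 - p)
  ppv <- if (ppv_den == 0) NA_real_ else 100 * se * p / ppv_den
  npv <- if (npv_den == 0) NA_real_ else 100 * sp * (1 - p) / npv_den
  list(ppv = ppv, npv = npv,
       accuracy = 100 * (se * p + sp * (1 - p)),
       ppv_defined = ppv_den > 0, npv_defined = npv_den > 0)
}

# Clopper-Pearson exact binomial 95% CI, as a fraction pair.
exact_binomial_ci <- function(x, n, conf = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}

# DeLong standard error of the empirical AUC via placement values.
delong_auc_se <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  v10 <- vapply(scores_pos, function(s)
    mean((s > scores_neg) + 0.5 * (s == scores_neg)), numeric(1))
  v01 <- vapply(scores_neg, function(s)
    mean((scores_pos > s) + 0.5 * (scores_pos == s)), numeric(1))
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n2 > 1) stats::var(v01) else 0
  sqrt(s10 / n1 + s01 / n2)
}

# AUC 95% CI: DeLong when it has positive variance, otherwise a stratified
# percentile bootstrap (degenerate separable data, e.g. AUC exactly 1).
auc_ci <- function(scores_pos, scores_neg, reps = 2000, boot_seed = 1L) {
  a <- roc_auc(scores_pos, scores_neg)
  se <- delong_auc_se(scores_pos, scores_neg)
  if (se > 0) {
    ci <- a + c(-1, 1) * stats::qnorm(0.975) * se
    list(auc = a, lower = max(0, ci[1]), upper = min(1, ci[2]),
         method = "delong")
  } else {
    old <- .Random.seed_safe_get()
    on.exit(.Random.seed_safe_restore(old), add = TRUE)
    set.seed(boot_seed)
    boots <- replicate(reps, roc_auc(
      sample(scores_pos, replace = TRUE),
      sample(scores_neg, replace = TRUE)))
    q <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    list(auc = a, lower = q[1], upper = q[2], method = "bootstrap")
  }
}

.Random.seed_safe_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_safe_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate a locked threshold on an independent test set
#'
#' Classifies with the `score >= threshold` rule at the immutable locked
#' value, and reports the confusion counts, sensitivity and specificity with
#' exact (Clopper-Pearson) 95\% CIs, the test-set AUC with a 95\% CI (DeLong,
#' or stratified bootstrap when the test data are perfectly separated), and
#' prevalence-adjusted PPV/NPV/accuracy.
#'
#' @param scores_pos,scores_neg test score groups.
#' @param locked a [lock_threshold()] result.
#' @param prevalence assumed population prevalence of disease
#'   (default 0.01).
#' @return object of class `performance_report`: list with `threshold`,
#'   `prevalence`, `confusion` (tp/fp/tn/fn), `sensitivity`, `specificity`
#'   and their CIs, `auc`, `auc_ci`, `ppv`, `npv`, `accuracy`.
#' @export
evaluate_locked <- function(scores_pos, scores_neg, locked,
                            prevalence = 0.01) {
  if (!inherits(locked, "locked_threshold")) {
    stop("`locked` must be a locked_threshold produced by lock_threshold()",
         call. = FALSE)
  }
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  stopifnot(prevalence > 0, prevalence < 1)
  thr <- locked$value
  tp <- sum(scores_pos >= thr); fn <- length(scores_pos) - tp
  fp <- sum(scores_neg >= thr); tn <- length(scores_neg) - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ci <- auc_ci(scores_pos, scores_neg)
  pv <- predictive_values(sens, spec, prevalence)
  structure(list(
    threshold = thr,
    specificity_floor = locked$specificity_floor,
    prevalence = prevalence,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = sens,
    sensitivity_ci = exact_binomial_ci(tp, tp + fn),
    specificity = spec,
    specificity_ci = exact_binomial_ci(tn, tn + fp),
    auc = ci$auc, auc_ci = c(ci$lower, ci$upper), auc_ci_method = ci$method,
    ppv = pv$ppv, npv = pv$npv, accuracy = pv$accuracy,
    provenance = locked$provenance
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance at locked threshold %g (prevalence %.2g):\n",
              x$threshold, x$prevalence))
  cat(sprintf("  sensitivity %.1f%% [%.1f, %.1f]\n", 100 * x$sensitivity,
              100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2]))
  cat(sprintf("  specificity %.1f%% [%.1f, %.1f]\n", 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  cat(sprintf("  AUC %.3f [%.3f, %.3f] (%s)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2], x$auc_ci_method))
  cat(sprintf("  PPV %.2f%%  NPV %.2f%%  accuracy %.2f%%\n",
              x$ppv, x$npv, x$accuracy))
  invisible(x)
}
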