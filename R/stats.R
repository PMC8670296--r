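#' Two-sample Mann-Whitney rank test
#'
#' Rank-sum test used throughout marker selection and the MSI association
#' analysis. The U statistic counts pairwise wins of `group_a` over
#' `group_b`, ties counting one half. Two modes are available:
#'
#' * `"exact"`: full enumeration of all `choose(n1 + n2, n1)` assignments of
#'   the observed pooled multiset (ties handled by enumeration); allowed for
#'   `n1 + n2 <= 20`. The two-tailed p doubles the smaller tail, capped at 1.
#' * `"normal_approx"`: tie-corrected normal approximation with continuity
#'   correction.
#'
#' `"auto"` picks exact for pooled sizes up to 12, the approximation
#' otherwise. A pooled sample that is entirely constant carries no rank
#' information: p is 1 by convention and the result is flagged degenerate.
#'
#' @param group_a,group_b numeric vectors of scores (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return object of class `rank_test`: list with `u_statistic` (for
#'   `group_a`), `p_value` (two-tailed), `n1`, `n2`, `method`, `degenerate`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p_value  # 0.1
mann_whitney <- function(group_a, group_b,
                         mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("missing values in rank-test input", call. = FALSE)
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)                      # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(structure(list(u_statistic = n1 * n2 / 2, p_value = 1,
                          n1 = n1, n2 = n2, method = "degenerate",
                          degenerate = TRUE), class = "rank_test"))
  }

  if (mode == "auto") mode <- if (n1 + n2 <= 12) "exact" else "normal_approx"

  if (mode == "exact") {
    if (n1 + n2 > 20) {
      stop("exact mode enumerates all assignments and is limited to ",
           "n1 + n2 <= 20", call. = FALSE)
    }
    sel <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(us <= u)
    p_hi <- mean(us >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(pooled)
    sigma2 <- (n1 * n2 / 12) *
      ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity correction of 0.5 toward the mean
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (abs(u - mu) < 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }

  structure(list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
                 method = mode, degenerate = FALSE),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, n = (%d, %d), two-tailed p = %.4g%s\n",
              x$method, x$u_statistic, x$n1, x$n2, x$p_value,
              if (x$degenerate) " [degenerate: constant pooled data]" else ""))
  invisible(x)
}

#' Five-number summary of a score vector
#'
#' Minimum, lower quartile, median, upper quartile and maximum. Min and max
#' are exact order statistics; the quartiles follow a configurable
#' percentile convention. The default, `"type6"`, is the rank
#' `k = p * (n + 1)` rule with linear interpolation (clamped to `[1, n]`),
#' the convention common in commercial statistics packages and the one the
#' packaged reference summaries are consistent with. `"type7"` is the
#' `k = 1 + p * (n - 1)` rule.
#'
#' @param values non-empty numeric vector.
#' @param percentile_method `"type6"` (default) or `"type7"`.
#' @return named numeric vector
#'   `c(minimum, q25, median, q75, maximum)`.
#' @export
#' @examples
#' five_number_summary(1:5)  # q25 = 1.5, q75 = 4.5 under the default rule
five_number_summary <- function(values,
                                percentile_method = c("type6", "type7")) {
  percentile_method <- match.arg(percentile_method)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("missing values in summary input", call. = FALSE)
  type <- if (percentile_method == "type6") 6 else 7
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = type,
                       names = FALSE)
  c(minimum = min(values), q25 = q[1], median = q[2], q75 = q[3],
    maximum = max(values))
}
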