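# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# Pairwise win-counting AUC: P(pos > neg) + 0.5 P(pos == neg).
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Step-by-step UPGMA on the raw distance matrix: at every step recompute all
# inter-cluster average distances over raw member pairs, merge the minimum.
# Returns merge heights and the member set created by each merge.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merged_sets <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    new <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- new
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    merged_sets[[length(merged_sets) + 1]] <- new
  }
  list(heights = heights, sets = merged_sets)
}

# Member sets created by each hclust merge, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[k, ], function(node) {
      if (node < 0) -node else sets[[node]]
    }))
    sets[[k]] <- sort(members)
  }
  sets
}

# Tiny labelled %M matrix: values chosen by hand, both classes.
toy_matrix <- function() {
  v <- matrix(c(10, 20, 30,
                40, 50, 60,
                 0,  5, 10,
                 1,  2,  3),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("c1", "c2", "n1", "n2"),
                              c("gA", "gB", "gC")))
  methylation_matrix(v, class = c("carcinoma", "carcinoma",
                                  "normal", "normal"))
}

# Random valid %M matrix with both classes.
random_matrix <- function(n_ca, n_no, n_genes) {
  n <- n_ca + n_no
  v <- matrix(round(runif(n * n_genes, 0, 100), 1), nrow = n,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(n_genes))))
  methylation_matrix(v, class = rep(c("carcinoma", "normal"),
                                    c(n_ca, n_no)))
}
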