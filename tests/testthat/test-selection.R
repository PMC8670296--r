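# The reference 13-marker table and its known selection outcome anchor most
# of these tests; the printed shortlist order is
# TMEFF2 > GPX7 > MAL > ARHGEF7 > TWIST1 > AKR1B1 > HIN1 > GAS7.
ref_order <- c("TMEFF2", "GPX7", "MAL", "ARHGEF7", "TWIST1", "AKR1B1",
               "HIN1", "GAS7")

test_that("summarize_markers matches hand-computed class summaries", {
  v <- matrix(c(1, 10,
                2, 20,
                3, 30,
                4, 40,
                5, 50,
                0, 0,
                0, 0,
                10, 5,
                10, 5),
              ncol = 2, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:9), c("gA", "gB")))
  m <- methylation_matrix(v, class = rep(c("carcinoma", "normal"), c(5, 4)))
  s <- summarize_markers(m)
  a <- s[s$gene == "gA", ]
  # carcinoma 1..5 under k = p(n+1): q25 = 1.5, median = 3, q75 = 4.5
  expect_equal(unlist(a[c("ca_min", "ca_q25", "ca_median", "ca_q75",
                          "ca_max")], use.names = FALSE),
               c(1, 1.5, 3, 4.5, 5))
  # normal (0, 0, 10, 10): q25 = 0 (k = 1.25), median = 5, q75 = 10
  expect_equal(unlist(a[c("no_min", "no_q25", "no_median", "no_q75",
                          "no_max")], use.names = FALSE),
               c(0, 0, 5, 10, 10))
  expect_true(all(s$p_value >= 0 & s$p_value <= 1))
})

test_that("a gene constant at zero yields all-zero summaries and p = 1", {
  v <- matrix(0, nrow = 4, ncol = 1, dimnames = list(paste0("s", 1:4), "gZ"))
  m <- methylation_matrix(v, class = c("carcinoma", "carcinoma",
                                       "normal", "normal"))
  s <- summarize_markers(m)
  expect_equal(sum(unlist(s[1, 2:11])), 0)
  expect_equal(s$p_value, 1)
  expect_error(summarize_markers(
    methylation_matrix(v, class = rep("carcinoma", 4))), "both")
})

test_that("significance filter drops the printed non-significant markers", {
  s <- reference_marker_summaries()
  res <- filter_significant(s)
  expect_setequal(res$discarded, c("APC", "HIST1H3C"))  # p 0.2662, 0.3959
  expect_true("TMEFF2" %in% res$kept$gene)              # p < 0.0001
  expect_equal(nrow(res$kept), 11)
})

test_that("significance filter requires the difference to favor carcinoma", {
  s <- data.frame(gene = c("up", "down"),
                  ca_median = c(30, 1), ca_q75 = c(40, 2),
                  no_median = c(1, 30), no_q75 = c(2, 40),
                  p_value = c(0.001, 0.001))
  res <- filter_significant(s)
  expect_equal(res$kept$gene, "up")
  expect_equal(res$discarded, "down")
})

test_that("background filter is inclusive at the cutoff", {
  s <- reference_marker_summaries()
  res <- filter_background(filter_significant(s)$kept)
  # TM6SF1 (15), ZNF671 (16) and the boundary COL6A2 (exactly 10) must go
  expect_setequal(res$discarded, c("TM6SF1", "ZNF671", "COL6A2"))
  expect_true("TWIST1" %in% res$kept$gene)  # normal q75 = 6
  # just under the cutoff survives
  near <- data.frame(gene = c("at", "under"), ca_median = c(5, 5),
                     ca_q75 = c(9, 9), no_median = c(1, 1),
                     no_q75 = c(10, 9.9), p_value = c(0.01, 0.01))
  expect_equal(filter_background(near)$kept$gene, "under")
})

test_that("ranking follows descending carcinoma q75 with logged ties", {
  s <- reference_marker_summaries()
  kept <- filter_background(filter_significant(s)$kept)$kept
  res <- rank_and_select(kept)
  expect_equal(res$shortlist_ranked, ref_order)
  expect_equal(res$panel$genes, ref_order[1:6])
  expect_equal(nrow(res$ties), 0)
  # tie on both q75 and median breaks lexically and is logged
  tied <- data.frame(gene = c("gB", "gA"), ca_median = c(5, 5),
                     ca_q75 = c(20, 20), no_median = c(0, 0),
                     no_q75 = c(1, 1), p_value = c(0.01, 0.01))
  expect_message(res2 <- rank_and_select(tied), "gA")
  expect_equal(res2$shortlist_ranked, c("gA", "gB"))
})

test_that("the staged pipeline partitions genes and audits each decision", {
  s <- reference_marker_summaries()
  res <- select_panel_from_summaries(s)
  accounted <- c(res$discarded_nonsignificant, res$discarded_background,
                 res$shortlist_ranked)
  expect_setequal(accounted, s$gene)
  expect_equal(length(accounted), nrow(s))          # no double counting
  expect_equal(sort(unique(res$audit$outcome)),
               c("discarded_background", "discarded_nonsignificant",
                 "panel", "shortlist_only"))
  expect_true(all(res$panel$genes %in% res$shortlist_ranked))
  # determinism, including order
  expect_identical(res$shortlist_ranked,
                   select_panel_from_summaries(s)$shortlist_ranked)
})

test_that("criteria move the filters monotonically", {
  s <- reference_marker_summaries()
  sig_n <- function(alpha)
    nrow(filter_significant(s, selection_criteria(alpha = alpha))$kept)
  expect_true(sig_n(0.5) >= sig_n(0.05))
  expect_true(sig_n(0.05) >= sig_n(1e-6))
  bg_n <- function(cut)
    nrow(filter_background(s, selection_criteria(background_cutoff = cut))$kept)
  expect_true(bg_n(5) <= bg_n(10))
  expect_true(bg_n(10) <= bg_n(50))
})

test_that("top_k beyond the shortlist returns the whole ranked list", {
  s <- data.frame(gene = c("g1", "g2", "g3"),
                  ca_median = c(30, 20, 10), ca_q75 = c(40, 30, 20),
                  no_median = c(0, 0, 0), no_q75 = c(1, 1, 1),
                  p_value = rep(0.001, 3))
  res <- select_panel_from_summaries(s, selection_criteria(top_k = 99))
  expect_equal(res$panel$genes, c("g1", "g2", "g3"))
})

test_that("end-to-end selection on simulated cohorts keeps the interior markers", {
  # Simulation from marginal quantile specs reproduces the filters'
  # behavior away from decision boundaries: the five markers safely inside
  # every boundary must always be selected, and the sixth slot can only go
  # to one of the near-boundary markers (AKR1B1/HIN1 rank 3 %M apart;
  # COL6A2's normal q75 sits exactly on the inclusive background cutoff).
  s11 <- reference_marker_summaries()[1:11, ]
  interior <- c("TMEFF2", "GPX7", "MAL", "ARHGEF7", "TWIST1")
  for (seed in 1:5) {
    m <- generate_tissue_cohort(summaries = s11, n_carcinoma = 200,
                                n_normal = 200, msi_fraction = 0,
                                seed = seed)
    res <- select_panel(m)
    expect_true(all(interior %in% res$panel$genes))
    sixth <- setdiff(res$panel$genes, interior)
    expect_true(sixth %in% c("AKR1B1", "HIN1", "COL6A2"))
    expect_true(all(c("TM6SF1", "ZNF671") %in% res$discarded_background))
  }
})
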