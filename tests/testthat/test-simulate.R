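test_that("quantile functions interpolate the five knots exactly", {
  q <- fit_quantile_function(c(9, 21, 33, 49, 71))
  expect_equal(q$fun(c(0, 0.25, 0.5, 0.75, 1)), c(9, 21, 33, 49, 71))
  expect_equal(q$fun(0.375), 27)              # halfway up the q25-median leg
  # uniform summary gives the identity-scaled quantile function
  u <- fit_quantile_function(c(0, 25, 50, 75, 100))
  expect_equal(u$fun(c(0.1, 0.6)), c(10, 60))
  # constant summary gives a constant function
  k <- fit_quantile_function(rep(7, 5))
  expect_equal(k$fun(c(0, 0.5, 1)), rep(7, 3))
  expect_error(fit_quantile_function(c(5, 4, 6, 7, 8)), "non-decreasing")
})

test_that("samples stay inside the spec support and recover its quartiles", {
  spec <- fit_quantile_function(c(9, 21, 33, 49, 71))
  set.seed(51)
  x <- sample_gene(spec, 1e5)
  expect_true(all(x >= 9 & x <= 71))
  emp <- five_number_summary(x)
  expect_equal(unname(emp[2:4]), c(21, 33, 49), tolerance = 0.05)
  # constant spec yields constant draws
  expect_equal(sample_gene(fit_quantile_function(rep(3, 5)), 10), rep(3, 10))
})

test_that("tissue cohorts are valid, seeded and annotated", {
  m <- generate_tissue_cohort(seed = 52)
  expect_s3_class(m, "methylation_matrix")
  expect_equal(as.vector(table(m$class)[c("carcinoma", "normal")]),
               c(30L, 23L))
  expect_equal(ncol(m$values), 13)
  expect_true(all(m$values >= 0 & m$values <= 100))
  expect_equal(sum(m$msi == "MSI", na.rm = TRUE), 10)  # round(30/3)
  expect_true(all(m$age >= 40 & m$age <= 95))
  # bit-identical under the same seed, different under another
  m2 <- generate_tissue_cohort(seed = 52)
  expect_identical(m$values, m2$values)
  expect_identical(m$age, m2$age)
  expect_identical(m$msi, m2$msi)
  m3 <- generate_tissue_cohort(seed = 53)
  expect_false(identical(m$values, m3$values))
  # no MSI labels when the fraction is zero
  expect_null(generate_tissue_cohort(msi_fraction = 0, seed = 52)$msi)
})

test_that("large cohorts recover the reference class medians", {
  s <- reference_marker_summaries()
  m <- generate_tissue_cohort(n_carcinoma = 2e4, n_normal = 2e4, seed = 54)
  med_ca <- apply(m$values[m$class == "carcinoma", s$gene], 2,
                  stats::median)
  med_no <- apply(m$values[m$class == "normal", s$gene], 2, stats::median)
  expect_true(all(abs(med_ca - s$ca_median) <= 3))
  expect_true(all(abs(med_no - s$no_median) <= 3))
})

test_that("MAL class supports are disjoint by construction", {
  m <- generate_tissue_cohort(seed = 55)
  mal_ca <- m$values[m$class == "carcinoma", "MAL"]
  mal_no <- m$values[m$class == "normal", "MAL"]
  expect_true(min(mal_ca) >= 9)
  expect_true(max(mal_no) <= 7)
})

test_that("plasma cohorts show negligible normal background", {
  p5 <- default_panels()$plasma5
  m <- generate_plasma_cohort(genes = p5$genes, seed = 56)
  cmi <- compute_cmi(m, p5)
  expect_gte(mean(cmi$cmi[cmi$class == "normal"] < 3.5), 0.9)
  expect_gt(roc_auc(cmi$cmi[cmi$class == "carcinoma"],
                    cmi$cmi[cmi$class == "normal"]), 0.95)
  # zero carcinoma signal makes the classes indistinguishable
  m0 <- generate_plasma_cohort(genes = p5$genes, signal_zero_prob = 1,
                               background_zero_prob = 1, seed = 57)
  cmi0 <- compute_cmi(m0, p5)
  expect_equal(roc_auc(cmi0$cmi[cmi0$class == "carcinoma"],
                       cmi0$cmi[cmi0$class == "normal"]), 0.5)
})

test_that("beta matrices honor their block design", {
  b <- generate_beta_matrix(n_probes = 8, n_diff = 3, n_carcinoma = 10,
                            n_normal = 10, noise_sd = 0.05, seed = 58)
  expect_s3_class(b, "beta_matrix")
  expect_true(all(b$values >= 0 & b$values <= 1))
  sc <- differential_score(b)
  expect_true(all(sc[1:3] > 0.3))
  expect_true(all(abs(sc[4:8]) < 0.15))
  # single probe is valid
  b1 <- generate_beta_matrix(n_probes = 1, n_diff = 1, n_carcinoma = 3,
                             n_normal = 3, seed = 59)
  expect_equal(dim(b1$values), c(1L, 6L))
  # a fully null design centers the score at zero
  b0 <- generate_beta_matrix(n_probes = 40, n_diff = 0, n_carcinoma = 30,
                             n_normal = 30, seed = 60)
  expect_lt(abs(mean(differential_score(b0))), 0.05)
})

test_that("train/test splits are stratified, balanced and reproducible", {
  m <- generate_tissue_cohort(n_carcinoma = 30, n_normal = 24, seed = 61)
  sp <- split_cohort(m, seed = 62)
  n_tr <- table(sp$training$class)
  n_te <- table(sp$test$class)
  expect_true(all(abs(n_tr - n_te) <= 3))  # <=1 per stratum, 3 age strata
  expect_equal(nrow(sp$training$values) + nrow(sp$test$values), 54)
  for (cl in c("carcinoma", "normal")) {
    d <- abs(mean(sp$training$age[sp$training$class == cl]) -
               mean(sp$test$age[sp$test$class == cl]))
    expect_lte(d, 3)
  }
  sp2 <- split_cohort(m, seed = 62)
  expect_identical(sample_ids(sp2$training), sample_ids(sp$training))
})

test_that("age balance holds across many random splits", {
  m <- generate_tissue_cohort(n_carcinoma = 250, n_normal = 250, seed = 63)
  ok <- vapply(1:20, function(s) {
    sp <- split_cohort(m, seed = 100 + s)
    all(vapply(c("carcinoma", "normal"), function(cl) {
      abs(mean(sp$training$age[sp$training$class == cl]) -
            mean(sp$test$age[sp$test$class == cl])) <= 3
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("splitting without ages warns and stratifies by class only", {
  m <- generate_tissue_cohort(n_carcinoma = 10, n_normal = 10, seed = 64)
  m$age[3] <- NA
  expect_warning(sp <- split_cohort(m, seed = 65), "class-only")
  expect_true(abs(sum(sp$training$class == "carcinoma") -
                    sum(sp$test$class == "carcinoma")) <= 1)
})
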