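test_that("TPM normalisation is the exact formula", {
  expect_equal(tpm_normalize(500, 1e6), 500)
  expect_equal(tpm_normalize(0, 123), 0)
  expect_equal(tpm_normalize(123, 123), 1e6)
  expect_error(tpm_normalize(1, 0), "positive")
  expect_error(tpm_normalize(-1, 10), "non-negative")
})

test_that("low-expression revision and exclusion follow the rule", {
  r <- revise_low_expression(0, 3.2)
  expect_equal(c(r$tpm_control, r$tpm_treatment), c(0.01, 3.2))
  expect_false(r$excluded)
  expect_true(revise_low_expression(0.5, 0.9)$excluded)
  r00 <- revise_low_expression(0, 0)
  expect_equal(c(r00$tpm_control, r00$tpm_treatment), c(0.01, 0.01))
  expect_true(r00$excluded)
  # alternative reading: only revise when both are zero
  alt <- revise_low_expression(0, 3.2, revise_when_both_zero = TRUE)
  expect_equal(alt$tpm_control, 0)
})

test_that("fold change is log2 treatment over control", {
  expect_equal(log2_fold_change(2, 1), 1)
  expect_equal(log2_fold_change(1, 2), -1)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("the AC test matches its closed-form anchors", {
  # x = y = 0 with equal totals: p(0|0) = 1/2, both tails >= 1/2, p = 1
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6), 1)
  # symmetry around the mode: equal counts give p = 1
  for (k in c(1, 7, 50)) expect_equal(ac_pvalue(k, k, 5e5, 5e5), 1)
  # extreme imbalance
  expect_lt(ac_pvalue(100, 0, 1e6, 1e6), 1e-20)
  expect_error(ac_pvalue(-1, 2, 10, 10), "non-negative")
  expect_error(ac_pvalue(1.5, 2, 10, 10), "integers")
})

test_that("AC tails agree with the negative-binomial oracle", {
  for (r in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- r * 1e6
    for (x in c(0, 1, 5, 20, 50)) {
      for (y in c(0, 1, 5, 20, 50)) {
        expect_equal(ac_pvalue(x, y, n1, n2), ac_oracle(x, y, n1, n2),
                     tolerance = 1e-12, info = sprintf("r=%g x=%d y=%d", r, x, y))
      }
    }
  }
})

test_that("the conditional distribution normalises to one", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 3, 25)) {
      lp <- mircycle:::ac_log_prob(0:2000, x, log(r), log1p(r))
      expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
    }
  }
})

test_that("swapping control and treatment roles gives equivalent conclusions", {
  # the conditional formulation fixes one count and sums tails over the
  # other, so the swap is not an exact identity; it is exact for equal
  # counts and the two orientations always agree in order of magnitude
  for (k in c(0, 3, 40)) {
    expect_equal(ac_pvalue(k, k, 1e6, 1e6), ac_pvalue(k, k, 1e6, 1e6))
  }
  set.seed(8)
  for (i in 1:20) {
    x <- rpois(1, 30); y <- rpois(1, 10)
    n1 <- sample(c(8e5, 1e6), 1); n2 <- sample(c(1e6, 1.6e6), 1)
    a <- ac_pvalue(x, y, n1, n2)
    b <- ac_pvalue(y, x, n2, n1)
    expect_lt(abs(log10(a) - log10(b)), 1)
  }
})

test_that("significance and ratio classes use the printed boundaries", {
  cls <- classify_de(c(0.005, 0.01, 0.03, 0.05, 0.5),
                     c(3, 2, 1, 0.5, 0.4))
  expect_equal(as.character(cls$sig_class),
               c("p<0.01", "0.01<=p<0.05", "0.01<=p<0.05", "NS", "NS"))
  expect_equal(as.character(cls$ratio_class),
               c("ratio>2", "1/2<ratio<=2", "1/2<ratio<=2",
                 "ratio<=1/2", "ratio<=1/2"))
})

test_that("diff_expression assembles the full per-pair table", {
  expr <- tidyr::expand_grid(mirna_id = c("a", "b", "c"),
                             stage = c("anagen", "catagen", "telogen")) %>%
    dplyr::mutate(count = c(1000, 1000, 250,   # a: 4x down in telogen
                            0, 0, 0,           # b: absent everywhere
                            40, 40, 40))       # c: flat
  totals <- c(anagen = 1e6, catagen = 1e6, telogen = 1e6)
  de <- diff_expression(expr, totals)
  expect_equal(nrow(de), 9)
  a_tel <- de[de$mirna_id == "a" & de$treatment == "telogen" &
                de$control == "anagen", ]
  expect_equal(a_tel$log2fc, -2)
  expect_lt(a_tel$pvalue, 0.01)
  expect_equal(as.character(a_tel$sig_class), "p<0.01")
  b <- de[de$mirna_id == "b", ]
  expect_true(all(b$excluded))
  expect_true(all(b$tpm_control == 0.01 & b$tpm_treatment == 0.01))
  c_row <- de[de$mirna_id == "c" & de$control == "anagen" &
                de$treatment == "catagen", ]
  expect_equal(c_row$pvalue, 1)
  expect_error(diff_expression(expr, c(anagen = 1e6)), "missing stages")
})

test_that("same-mean Poisson pairs keep the type-I error below nominal", {
  set.seed(2024)
  n <- 3000
  x <- rpois(n, 50); y <- rpois(n, 50)
  p <- ac_pvalue(x, y, 1e6, 1e6)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("profile clustering splits separated groups and handles edges", {
  de <- tidyr::expand_grid(
    mirna_id = sprintf("m%02d", 1:10),
    control = "anagen",
    treatment = c("catagen", "telogen")) %>%
    dplyr::mutate(log2fc = ifelse(mirna_id <= "m05", 3, -3) +
                    stats::rnorm(20, 0, 0.05))
  set.seed(1)
  cl <- cluster_profiles(de, k = 2)
  grp1 <- cl$cluster[cl$mirna_id <= "m05"]
  grp2 <- cl$cluster[cl$mirna_id > "m05"]
  expect_equal(length(unique(grp1)), 1)
  expect_equal(length(unique(grp2)), 1)
  expect_true(unique(grp1) != unique(grp2))
  # identical profiles share a cluster
  expect_equal(length(unique(cl$cluster[cl$mirna_id %in% c("m01", "m02")])), 1)
  # k = 1 collapses everything; fewer miRNAs than k separates everything
  expect_equal(length(unique(cluster_profiles(de, k = 1)$cluster)), 1)
  tiny <- de[de$mirna_id %in% c("m01", "m02"), ]
  expect_equal(cluster_profiles(tiny, k = 5)$cluster, 1:2)
})

test_that("glance and autoplot summarise DE results", {
  expr <- tidyr::expand_grid(mirna_id = c("a", "b"),
                             stage = c("anagen", "catagen", "telogen")) %>%
    dplyr::mutate(count = c(500, 500, 100, 50, 50, 50))
  de <- diff_expression(expr, c(anagen = 1e5, catagen = 1e5, telogen = 1e5))
  g <- glance(de)
  expect_equal(nrow(g), 3)
  expect_true(all(abs(g$frac_p_lt_0.01 + g$frac_p_0.01_0.05 + g$frac_ns - 1)
                  < 1e-12))
  expect_s3_class(autoplot(de), "ggplot")
  td <- tidy(de)
  expect_false(inherits(td, "de_result"))
})
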