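test_that("uptake_ratio is the plain regional/whole-brain quotient", {
  expect_equal(uptake_ratio(150, 100), 1.5)
  expect_equal(uptake_ratio(100, 100), 1.0)
  expect_warning(r0 <- uptake_ratio(0, 100), "implausible")
  expect_equal(r0, 0)
  expect_error(uptake_ratio(10, 0), "positive")
  expect_error(uptake_ratio(10, -5), "positive")
})

make_onefactor_cohort <- function(vals_wt, vals_het) {
  n <- length(vals_wt) + length(vals_het)
  up <- cbind(c(vals_wt, vals_het), rep(1, n))  # second region constant-ish
  up[, 2] <- seq(0.9, 1.1, length.out = n)
  md <- data.frame(animal_id = sprintf("a%d", 1:n),
                   genotype = rep(c("WT", "HET"), c(length(vals_wt), length(vals_het))),
                   treatment = "SAL",
                   sex = rep(c("M", "F"), length.out = n),
                   stringsAsFactors = FALSE)
  rownames(up) <- md$animal_id
  cohort_table(up, md, region_table(c("A", "B")))
}

test_that("one-factor ANOVA matches hand computation and the t^2 identity", {
  co <- make_onefactor_cohort(c(1, 2), c(3, 4))
  res <- factorial_anova(co, "A", factors = "genotype")
  expect_equal(res$F, 8, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(1, 2))

  # identical group means, balanced -> F = 0
  co0 <- make_onefactor_cohort(c(1, 2), c(2, 1))
  expect_equal(factorial_anova(co0, "A", factors = "genotype")$F, 0)

  # balanced two-group F equals the squared pooled-t statistic
  set.seed(4)
  co2 <- make_onefactor_cohort(rnorm(6, 1, 0.1), rnorm(6, 1.05, 0.1))
  f <- factorial_anova(co2, "A", factors = "genotype")$F
  tt <- t.test(co2$uptake[1:6, 1], co2$uptake[7:12, 1], var.equal = TRUE)
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("factorial ANOVA reports every effect and flags empty cells", {
  co <- generate_cohort(null_spec(n_regions = 4L,
    n_per_group = c("WT/SAL" = 8L, "WT/KET" = 8L, "HET/SAL" = 8L, "HET/KET" = 8L),
    seed = 8))
  res <- factorial_anova(co, 0L, subset_treatments = c("SAL", "KET"))
  expect_setequal(res$effect,
    c("sex", "genotype", "treatment", "sex:genotype", "sex:treatment",
      "genotype:treatment", "sex:genotype:treatment"))
  expect_true(all(res$F >= 0) && all(res$p >= 0 & res$p <= 1))
  expect_true(isTRUE(attr(res, "genotype_main_effect_accepted")) ||
              isFALSE(attr(res, "genotype_main_effect_accepted")))
  # Type III agrees with Type II on which effects are large here
  res3 <- factorial_anova(co, 0L, subset_treatments = c("SAL", "KET"), ss = "III")
  expect_equal(nrow(res3), nrow(res))
  # empty cell for a requested interaction errors with the cell name
  co_sub <- co
  keep <- !(co$metadata$genotype == "HET" & co$metadata$treatment == "KET")
  co_sub <- cohort_table(co$uptake[keep, ], co$metadata[keep, ], co$regions)
  expect_error(factorial_anova(co_sub, 0L, subset_treatments = c("SAL", "KET")),
               "empty design cell")
})

test_that("bh_adjust applies the step-up rule and matches p.adjust", {
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.04, 10)), rep(0.04, 10))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance + oracle agreement with stats::p.adjust
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  }
})

test_that("posthoc_pairwise runs Welch contrasts with family-wise BH", {
  co <- generate_cohort(synthetic_spec(n_regions = 3L,
    n_per_group = c("WT/SAL" = 200L, "HET/SAL" = 200L, "HET/KET" = 6L),
    hub_regions = integer(0), rcc_regions = integer(0),
    lost_edges_het = NULL, restored_by_ket = NULL,
    mean_shift = data.frame(region = 0L, genotype = "HET",
                            treatment = "SAL", shift = 0.15),
    noise_sd = 0.08, seed = 13))
  tab <- posthoc_pairwise(co, 0L, list(c("WT", "SAL"), c("HET", "SAL")))
  expect_true(tab$significant[1])  # power ~ 1 at +0.15 / 0.08 with n = 200
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  expect_error(posthoc_pairwise(co, 0L, list(c("WT", "SAL"), c("WT", "AMPH"))),
               "unknown or empty cell")
  # identical cells give t = 0, p = 1
  up <- rbind(matrix(1.2, 3, 2), matrix(1.2, 3, 2))
  md <- data.frame(animal_id = sprintf("b%d", 1:6),
                   genotype = rep(c("WT", "HET"), each = 3),
                   treatment = "SAL", sex = "M", stringsAsFactors = FALSE)
  rownames(up) <- md$animal_id
  co_id <- cohort_table(up, md, region_table(c("A", "B")))
  tab0 <- posthoc_pairwise(co_id, "A", list(c("WT", "SAL"), c("HET", "SAL")))
  expect_equal(tab0$t, 0)
  expect_equal(tab0$p_raw, 1)
})
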