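# direct-matrix fits via the internal constructor
fit_xy <- function(X, y, ncomp = 1) metabnet:::plsr_fit_matrix(X, y, ncomp)

test_that("NIPALS solves the orthogonal toy exactly", {
  # 4 samples, y = x1 exactly, x2 orthogonal to x1
  X <- cbind(x1 = c(-1, -1, 1, 1), x2 = c(-1, 1, -1, 1))
  y <- X[, 1]
  fit <- fit_xy(X, y, 1)
  expect_equal(abs(fit$weights[, 1]), c(1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  v <- vip(fit)
  expect_equal(unname(v), c(sqrt(2), 0), tolerance = 1e-12)
})

test_that("one-component weights are proportional to predictor-response correlations", {
  set.seed(67)
  X <- matrix(rnorm(20 * 6), 20, 6)
  colnames(X) <- sprintf("p%d", 1:6)
  y <- X[, 1] * 0.5 + rnorm(20, 0, 0.5)
  fit <- fit_xy(X, y, 1)
  r <- cor(X, y)
  expect_equal(fit$weights[, 1], as.numeric(r / sqrt(sum(r^2))), tolerance = 1e-10)
})

test_that("the VIP mean-square identity holds on every fit", {
  set.seed(71)
  for (i in 1:15) {
    n <- sample(8:25, 1); p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + X %*% rnorm(p, 0, 0.3)
    nc <- sample(1:3, 1)
    v <- vip(fit_xy(X, y, nc))
    expect_equal(mean(v^2), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
  # explained response variance is non-decreasing in components
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- X %*% rnorm(5) + rnorm(30, 0, 0.2)
  fit3 <- fit_xy(X, y, 3)
  expect_true(all(fit3$ssy >= -1e-12))
})

test_that("component and rank preconditions are enforced", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_error(fit_xy(X, rnorm(5), 4), "rank|n_components")
  expect_error(fit_xy(cbind(X, X[, 1] * 0), rnorm(5), 1), "constant predictor")
})

test_that("jackknife VIP tables obey their CI and flag contracts", {
  spec <- synthetic_spec(n_regions = 10L, n_per_group = c("WT/SAL" = 30L),
                         base_corr = 0.1, hub_regions = integer(0),
                         rcc_regions = c(0L, 1L), rcc_corr = 0.8,
                         lost_edges_het = NULL, restored_by_ket = NULL,
                         mean_shift = NULL, seed = 73)
  co <- generate_cohort(spec)
  tab <- vip_jackknife(co, "WT", "SAL", 0L)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$ci_lower <= tab$vip + 1e-12))
  expect_true(all(tab$vip <= tab$ci_upper + 1e-12))
  expect_true(all(tab$ci_lower >= 0))
  expect_identical(tab$significant, tab$ci_lower > 1)
  expect_equal(dim(attr(tab, "pseudo_values")), c(30, 9))
  # the planted partner (region 1) carries the connection
  expect_true(tab$significant[tab$target == co$regions$abbreviation[2]])
})

test_that("compare_vip of a table with itself is all-null", {
  spec <- null_spec(n_regions = 8L, n_per_group = c("WT/SAL" = 10L), seed = 79)
  co <- generate_cohort(spec)
  tab <- vip_jackknife(co, "WT", "SAL", 0L)
  cmp <- compare_vip(tab, tab)
  expect_true(all(cmp$p_adj == 1))
  # Bonferroni arithmetic: raw p times the family size, capped at 1
  expect_equal(pmin(cmp$p_raw * nrow(cmp), 1), cmp$p_adj)
})

test_that("lost/gained/restored classification applies the conjunction rules", {
  mk <- function(ci_lower, vip = ci_lower + 0.2, targets = c("T1", "T2", "T3"),
                 seed = "S", pseudo = NULL) {
    tab <- data.frame(target = targets, vip = vip, se = 0.1,
                      ci_lower = ci_lower, ci_upper = vip + 0.3,
                      significant = ci_lower > 1, stringsAsFactors = FALSE)
    class(tab) <- c("vip_table", "data.frame")
    attr(tab, "pseudo_values") <- pseudo
    attr(tab, "seed_region") <- seed
    attr(tab, "n") <- 10
    tab
  }
  wt <- mk(c(1.3, 1.3, 0.4))
  het <- mk(c(0.6, 1.2, 1.4))
  cmp <- data.frame(target = c("T1", "T2", "T3"),
                    vip_a = wt$vip, vip_b = het$vip,
                    p_raw = c(0.001, 0.001, 0.005),
                    p_adj = c(0.01, 0.01, 0.02))
  ch <- classify_changes(wt, het, comparison = cmp)
  expect_equal(ch$class, c("lost", "unchanged", "gained"))
  # non-significant comparison blocks any call
  cmp$p_adj <- 0.2
  expect_true(all(classify_changes(wt, het, comparison = cmp)$class == "unchanged"))
})

test_that("restoration requires increase, CI > 1, and WT equivalence", {
  spec <- synthetic_spec(n_regions = 10L,
                         n_per_group = c("WT/SAL" = 12L, "HET/SAL" = 12L,
                                         "HET/KET" = 12L),
                         base_corr = 0.1, hub_regions = integer(0),
                         rcc_regions = c(0L, 1L), rcc_corr = 0.85,
                         lost_edges_het = matrix(c(0L, 1L), 1),
                         restored_by_ket = matrix(c(0L, 1L), 1),
                         mean_shift = NULL, seed = 83)
  co <- generate_cohort(spec)
  wt <- vip_jackknife(co, "WT", "SAL", 0L)
  het <- vip_jackknife(co, "HET", "SAL", 0L)
  ket <- vip_jackknife(co, "HET", "KET", 0L)
  target <- co$regions$abbreviation[2]
  rest <- classify_restoration(het, ket, wt, lost_targets = target)
  expect_equal(nrow(rest), 1)
  expect_true(rest$class %in% c("restored", "not_restored"))
  # an edge absent in the drug group too is never restored
  rest2 <- classify_restoration(het, het, wt, lost_targets = target)
  expect_equal(rest2$class, "not_restored")
  expect_error(classify_restoration(het, ket, wt, lost_targets = "ZZ"), "ZZ")
})

test_that("jackknife SE shrinks like 1/sqrt(n)", {
  ns <- c(8, 16, 32, 64)
  mean_se <- vapply(ns, function(n) {
    ses <- vapply(1:6, function(r) {
      spec <- synthetic_spec(n_regions = 8L,
                             n_per_group = stats::setNames(n, "WT/SAL"),
                             base_corr = 0.1, hub_regions = integer(0),
                             rcc_regions = c(0L, 1L), rcc_corr = 0.7,
                             lost_edges_het = NULL, restored_by_ket = NULL,
                             mean_shift = NULL, seed = 1000 * n + r)
      co <- generate_cohort(spec)
      mean(vip_jackknife(co, "WT", "SAL", 0L)$se)
    }, numeric(1))
    mean(ses)
  }, numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[2]
  expect_lt(slope, -0.25)
  expect_gt(slope, -0.85)
})
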