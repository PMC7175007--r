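test_that("G(n,m) draws have the exact requested edge count", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    m <- sample.int(n * (n - 1) / 2, 1)
    A <- metabnet:::er_graph(n, m)
    expect_equal(sum(A) / 2, m)
    expect_true(all(diag(A) == 0) && all(A == t(A)))
  }
  expect_error(metabnet:::er_graph(4, 7), "cannot place")
})

test_that("er_null_z flags planted hubs and is seed-reproducible", {
  # near-noiseless world: hubs correlated 0.7 to everything, base 0.2,
  # n = 500 animals, single threshold between base and hub strength
  spec <- synthetic_spec(n_regions = 30L, n_per_group = c("WT/SAL" = 500L),
                         hub_regions = c(0L, 5L), rcc_regions = integer(0),
                         lost_edges_het = NULL, restored_by_ket = NULL,
                         mean_shift = NULL, seed = 47)
  co <- generate_cohort(spec)
  nw <- threshold_adjacency(correlation_matrix(co, "WT", "SAL"), 0.35)
  h1 <- er_null_z(nw, n_null = 100, seed = 9)
  h2 <- er_null_z(nw, n_null = 100, seed = 9)
  expect_identical(h1, h2)
  flagged <- h1$region[h1$hub & h1$metric == "eigenvector"]
  expect_true(all(co$regions$abbreviation[c(1, 6)] %in% flagged))
  expect_equal(attr(h1, "n_null_total"), 100)
  expect_identical(hub_regions_called(h1), sort(unique(h1$region[h1$hub])))
  # hub flag is exactly mean_z > 1.96
  expect_identical(h1$hub, h1$mean_z > 1.96)
})

test_that("degenerate null SD (complete graph) is excluded with a warning", {
  A <- complete_graph(6)
  expect_warning(h <- er_null_z(adjacency_stack = list(T1 = A), n_null = 100,
                                seed = 1), "degenerate")
  expect_true(all(is.na(h$mean_z[h$metric == "degree"])))
})

test_that("permutation p-values use the +1 correction and detect null truth", {
  spec <- null_spec(seed = 53)
  co <- generate_cohort(spec)
  grid <- c(0.45, 0.5)
  # duplicated group comparison: observed difference exactly 0, p ~ 1
  up2 <- rbind(group_uptake(co, "WT", "SAL"), group_uptake(co, "WT", "SAL"))
  rownames(up2) <- sprintf("d%02d", seq_len(nrow(up2)))
  md2 <- data.frame(animal_id = rownames(up2),
                    genotype = rep(c("WT", "HET"), each = 10),
                    treatment = "SAL", sex = "M", stringsAsFactors = FALSE)
  co2 <- cohort_table(up2, md2, co$regions)
  out <- permute_groups(co2, c("WT", "SAL"), c("HET", "SAL"), "mean_degree",
                        grid, n_perm_per_threshold = 50, seed = 3)
  expect_equal(out$observed, 0)
  expect_gt(out$p, 0.9)
  expect_equal(out$n_total, 100)  # n_perm x n_thresholds counting
  expect_true(out$p >= 1 / (out$n_total + 1))
  # determinism
  out2 <- permute_groups(co2, c("WT", "SAL"), c("HET", "SAL"), "mean_degree",
                         grid, n_perm_per_threshold = 50, seed = 3)
  expect_identical(out$null, out2$null)
  # regional statistic requires a region name
  expect_error(permute_groups(co, c("WT", "SAL"), c("HET", "SAL"), "degree",
                              grid, 10, 1), "needs a region")
})

test_that("a planted between-group difference is detected by permutation", {
  spec <- synthetic_spec(n_regions = 12L,
                         n_per_group = c("WT/SAL" = 20L, "HET/SAL" = 20L),
                         base_corr = 0.6, hub_regions = integer(0),
                         rcc_regions = c(0L, 1L, 2L, 3L, 4L, 5L), rcc_corr = 0.9,
                         lost_edges_het = all_pairs(c(0L, 1L, 2L, 3L, 4L, 5L)),
                         restored_by_ket = NULL, mean_shift = NULL, seed = 59)
  co <- generate_cohort(spec)
  out <- permute_groups(co, c("HET", "SAL"), c("WT", "SAL"), "mean_degree",
                        c(0.7, 0.75), n_perm_per_threshold = 200, seed = 11)
  expect_lt(out$observed, 0)   # HET lost its dense block
  expect_lt(out$p, 0.05)
})

test_that("rich-club detection resolves a clique against an ER null", {
  A <- clique_pendant_graph()
  rc <- rich_club_core(adjacency_stack = list(T1 = A), n_rewire_null = 200,
                       seed = 1, null_model = "er")
  expect_setequal(rc$rcc, sprintf("n%d", 1:5))
  # under the degree-preserving null this graph is undecidable: no legal
  # swap can break the clique, so phi_norm stays at 1 and the core is empty
  rc_rw <- rich_club_core(adjacency_stack = list(T1 = A), n_rewire_null = 100,
                          seed = 1, null_model = "rewire")
  expect_length(rc_rw$rcc, 0)
  tab <- rc_rw$per_threshold[[1]]$table
  expect_true(all(abs(tab$phi_norm[tab$k >= 1 & tab$n_nodes >= 4] - 1) < 1e-12))
  # complete graph: phi = 1 everywhere, nulls identical, empty core
  rck <- rich_club_core(adjacency_stack = list(T1 = complete_graph(8)),
                        n_rewire_null = 100, seed = 1)
  expect_length(rck$rcc, 0)
  expect_true(all(rck$per_threshold[[1]]$table$phi == 1, na.rm = TRUE))
})

test_that("rewiring preserves the degree sequence", {
  set.seed(61)
  for (i in 1:10) {
    repeat {
      A <- metabnet:::er_graph(15, 30)
      if (is_connected(A)) break
    }
    G <- metabnet:::rewire_graph(A, 300)
    expect_equal(rowSums(G), rowSums(A))
    expect_true(all(diag(G) == 0) && all(G == t(G)) && all(G %in% 0:1))
  }
})

test_that("a planted rich-club block is recovered at large n", {
  # at large n the planted block is an exact clique whose edges no legal
  # double-edge swap can move (every candidate swap collides with a hub
  # edge), so the degree-preserving null is degenerate (phi_norm = 1);
  # the density-matched ER null resolves it
  hits <- vapply(1:10, function(s) {
    spec <- synthetic_spec(n_per_group = c("WT/SAL" = 300L), seed = 100 + s)
    co <- generate_cohort(spec)
    nw <- threshold_adjacency(correlation_matrix(co, "WT", "SAL"), 0.40)
    rc <- rich_club_core(nw, n_rewire_null = 50, seed = s, null_model = "er")
    planted <- co$regions$abbreviation[spec$rcc_regions + 1]
    all(planted %in% rc$rcc)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
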