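# Deterministic in-code fixtures; nothing is read from disk except what a
# test itself writes to tempdir().

# 4 animals x 5 regions, strictly positive, no ties
tiny_cohort <- function() {
  up <- matrix(c(
    1.10, 0.95, 1.30, 0.80, 1.05,
    1.20, 1.00, 1.25, 0.85, 1.10,
    0.90, 1.10, 1.15, 0.95, 0.98,
    1.05, 1.02, 1.40, 0.78, 1.22
  ), nrow = 4, byrow = TRUE)
  md <- data.frame(
    animal_id = c("w1", "w2", "h1", "h2"),
    genotype = c("WT", "WT", "WT", "WT"),
    treatment = "SAL", sex = c("M", "F", "M", "F"),
    stringsAsFactors = FALSE
  )
  rownames(up) <- md$animal_id
  cohort_table(up, md, region_table(c("A", "B", "C", "D", "E")))
}

# group_network built directly from a prescribed correlation matrix
network_from_R <- function(R, thresholds = NULL) {
  stopifnot(isSymmetric(R))
  colnames(R) <- rownames(R) <- sprintf("r%02d", seq_len(nrow(R)))
  Z <- suppressWarnings(atanh(R)); diag(Z) <- NA
  nw <- structure(list(group = c(genotype = "WT", treatment = "SAL"),
                       n_animals = NA, R = R, Z = Z,
                       thresholds = NULL, A = NULL),
                  class = "group_network")
  if (!is.null(thresholds)) nw <- threshold_adjacency(nw, thresholds)
  nw
}

# named adjacency helpers
complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L
  dimnames(A) <- list(sprintf("n%d", 1:n), sprintf("n%d", 1:n))
  A
}
path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
star_graph <- function(leaves) {
  n <- leaves + 1
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}
clique_pendant_graph <- function() {
  A <- matrix(0L, 15, 15)
  A[1:5, 1:5] <- 1L; diag(A) <- 0L
  pend <- cbind(rep(1:5, each = 2), 6:15)
  A[pend] <- 1L; A[pend[, 2:1]] <- 1L
  dimnames(A) <- list(sprintf("n%d", 1:15), sprintf("n%d", 1:15))
  A
}

# synthetic spec with all planted structure switched off
null_spec <- function(n_regions = 10L, n_per_group = c("WT/SAL" = 10L, "HET/SAL" = 10L),
                      base_corr = 0.5, seed = 1L, ...) {
  synthetic_spec(n_regions = n_regions, n_per_group = n_per_group,
                 base_corr = base_corr, hub_regions = integer(0),
                 rcc_regions = integer(0), lost_edges_het = NULL,
                 restored_by_ket = NULL, mean_shift = NULL, seed = seed, ...)
}

# the acceptance-scale default world at n = 12/group
recovery_spec <- function(seed) {
  synthetic_spec(
    n_per_group = stats::setNames(rep(12L, 6),
      c("WT/SAL", "WT/KET", "WT/AMPH", "HET/SAL", "HET/KET", "HET/AMPH")),
    seed = seed)
}

# grid selection with data-adaptive t_min, mirroring how the threshold
# window is chosen from the data in the published design
adaptive_grid <- function(networks, start = 0.35) {
  for (tm in seq(start, 0.10, by = -0.05)) {
    g <- tryCatch(select_threshold_grid(networks, t_min = tm),
                  error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  stop("no connected grid found")
}
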