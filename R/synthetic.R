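#' Synthetic cohort specification
#'
#' Describes a simulated 2-genotype x 3-treatment uptake cohort with known
#' ground truth: a baseline inter-regional correlation, planted hub regions
#' (elevated correlation to every other region), a mutually correlated
#' rich-club block, an edge set whose correlation collapses to baseline in
#' untreated and amphetamine-treated mutants (`lost_edges_het`), a subset of
#' those edges re-elevated under ketamine (`restored_by_ket`), and additive
#' group mean shifts (hyper-/hypometabolism). Defaults mirror the design the
#' generator emulates: group sizes 8/9/9 (WT saline/ketamine/amphetamine)
#' and 10/13/11 (HET), 59 regions, thalamic hypermetabolism in untreated
#' mutants that ketamine normalises.
#'
#' Edges are unordered pairs of 0-based region ids (matching
#' `RegionTable$region_id`), given as a 2-column matrix or list of length-2
#' vectors.
#'
#' @param n_regions number of regions (default 59).
#' @param n_per_group named integer vector, names `"GENOTYPE/TREATMENT"`.
#' @param base_corr baseline correlation between unrelated regions.
#' @param hub_regions 0-based ids of planted hubs.
#' @param hub_corr correlation of every hub-incident edge.
#' @param rcc_regions 0-based ids of the rich-club block.
#' @param rcc_corr within-block correlation.
#' @param lost_edges_het edges reduced to `base_corr` in HET/SAL and
#'   HET/AMPH; must all be planted (elevated) edges.
#' @param restored_by_ket subset of `lost_edges_het` re-elevated in HET/KET.
#' @param mean_shift data.frame with columns `region` (0-based id),
#'   `genotype`, `treatment`, `shift` (uptake-ratio units added to the
#'   baseline mean of 1).
#' @param sex_shift optional data.frame with columns `region`, `sex`,
#'   `shift`; default none (sex carries no planted effect).
#' @param noise_sd residual standard deviation of uptake ratios.
#' @param seed RNG seed used by [generate_cohort()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 59L,
                           n_per_group = c("WT/SAL" = 8L, "WT/KET" = 9L,
                                           "WT/AMPH" = 9L, "HET/SAL" = 10L,
                                           "HET/KET" = 13L, "HET/AMPH" = 11L),
                           base_corr = 0.2,
                           hub_regions = c(0L, 1L, 8L),
                           hub_corr = 0.7,
                           rcc_regions = c(1L, 2L, 3L, 4L, 5L, 10L, 12L),
                           rcc_corr = 0.75,
                           lost_edges_het = all_pairs(rcc_regions),
                           restored_by_ket = lost_edges_het,
                           mean_shift = default_mean_shift(),
                           sex_shift = NULL,
                           noise_sd = 0.08,
                           seed = 1L) {
  spec <- structure(list(
    n_regions = as.integer(n_regions),
    n_per_group = n_per_group,
    base_corr = base_corr, hub_regions = as.integer(hub_regions),
    hub_corr = hub_corr, rcc_regions = as.integer(rcc_regions),
    rcc_corr = rcc_corr,
    lost_edges_het = as_edge_matrix(lost_edges_het),
    restored_by_ket = as_edge_matrix(restored_by_ket),
    mean_shift = mean_shift, sex_shift = sex_shift,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' Default mean-shift table: thalamic hypermetabolism (+0.15 uptake units)
#' in untreated and amphetamine-treated mutants, normalised by ketamine.
#' @keywords internal
default_mean_shift <- function() {
  thal <- 1:5  # dRT, vRT, Re, CM, CL in the default region table
  expand <- expand.grid(region = thal, genotype = "HET",
                        treatment = c("SAL", "AMPH"),
                        stringsAsFactors = FALSE)
  expand$shift <- 0.15
  expand
}

#' All unordered pairs of a region id set, as an edge matrix
#' @param ids integer region ids.
#' @export
all_pairs <- function(ids) {
  ids <- as.integer(ids)
  if (length(ids) < 2) return(matrix(integer(0), ncol = 2))
  t(utils::combn(ids, 2))
}

as_edge_matrix <- function(edges) {
  if (is.null(edges)) return(matrix(integer(0), ncol = 2))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2)
  # canonical order i < j
  cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_regions < 2) stop("n_regions must be >= 2")
    if (any(n_per_group < 3))
      stop("every group needs >= 3 animals for correlation estimation; got ",
           paste(names(n_per_group)[n_per_group < 3], collapse = ", "))
    for (v in c(base_corr, hub_corr, rcc_corr))
      if (v <= -1 || v >= 1) stop("correlations must lie strictly in (-1, 1)")
    ids <- c(hub_regions, rcc_regions, as.vector(lost_edges_het),
             as.vector(restored_by_ket))
    if (length(ids) > 0 && (min(ids) < 0 || max(ids) >= n_regions))
      stop("region ids must lie in 0..", n_regions - 1)
    if (noise_sd <= 0) stop("noise_sd must be positive")
  })
  # restored edges must be a subset of lost edges
  if (nrow(spec$restored_by_ket) > 0) {
    key <- function(m) paste(m[, 1], m[, 2])
    extra <- setdiff(key(spec$restored_by_ket), key(spec$lost_edges_het))
    if (length(extra) > 0)
      stop("restored_by_ket edges not in lost_edges_het: ", paste(extra, collapse = "; "))
  }
  invisible(spec)
}

#' Planted correlation value for every edge before group modification
#' @keywords internal
planted_base_matrix <- function(spec) {
  R <- spec$n_regions
  C <- matrix(spec$base_corr, R, R)
  hubs <- spec$hub_regions + 1L
  if (length(hubs) > 0) {
    C[hubs, ] <- pmax(C[hubs, ], spec$hub_corr)
    C[, hubs] <- pmax(C[, hubs], spec$hub_corr)
  }
  rcc <- spec$rcc_regions + 1L
  if (length(rcc) > 1) {
    C[rcc, rcc] <- pmax(C[rcc, rcc], spec$rcc_corr)
  }
  diag(C) <- 1
  C
}

#' Target correlation matrix for one experimental group
#'
#' Starts from the planted structure (baseline everywhere, hub-incident
#' edges at `hub_corr`, rich-club block at `rcc_corr`, overlaps take the
#' larger value), then applies the genotype/treatment modification:
#' `lost_edges_het` collapse to baseline in HET/SAL and HET/AMPH; in
#' HET/KET only the lost edges *not* in `restored_by_ket` collapse. The
#' result is repaired to the nearest positive semi-definite correlation
#' matrix by eigenvalue clipping when needed (`attr(., "repaired")` records
#' this).
#'
#' @param spec a `synthetic_spec`.
#' @param genotype `"WT"` or `"HET"`.
#' @param treatment `"SAL"`, `"KET"` or `"AMPH"`.
#' @return Symmetric unit-diagonal correlation matrix with attribute
#'   `repaired` (logical).
#' @export
build_group_correlation <- function(spec, genotype, treatment) {
  genotype <- match.arg(genotype, GENOTYPE_LEVELS)
  treatment <- match.arg(treatment, TREATMENT_LEVELS)
  C <- planted_base_matrix(spec)
  lost <- spec$lost_edges_het
  if (nrow(lost) > 0) {
    planted <- C[lost + 1L]  # matrix-index into (i, j); edges are 0-based
    not_elevated <- planted <= spec$base_corr
    if (any(not_elevated))
      stop("lost_edges_het contains edge(s) with no planted elevation: ",
           paste(sprintf("(%d,%d)", lost[not_elevated, 1], lost[not_elevated, 2]),
                 collapse = " "))
    drop <- matrix(integer(0), ncol = 2)
    if (genotype == "HET" && treatment %in% c("SAL", "AMPH")) {
      drop <- lost
    } else if (genotype == "HET" && treatment == "KET") {
      key <- function(m) paste(m[, 1], m[, 2])
      drop <- lost[!(key(lost) %in% key(spec$restored_by_ket)), , drop = FALSE]
    }
    if (nrow(drop) > 0) {
      C[drop + 1L] <- spec$base_corr
      C[drop[, 2:1, drop = FALSE] + 1L] <- spec$base_corr
    }
  }
  repair_correlation(C)
}

#' Nearest-PSD repair by eigenvalue clipping
#'
#' Clips eigenvalues below 1e-8, reconstructs, and renormalises to unit
#' diagonal. Deterministic; the `repaired` attribute records whether any
#' clipping occurred.
#' @param C symmetric matrix with unit diagonal.
#' @keywords internal
repair_correlation <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  repaired <- any(e$values < 1e-8)
  if (repaired) {
    vals <- pmax(e$values, 1e-8)
    C <- e$vectors %*% (vals * t(e$vectors))
    C <- stats::cov2cor(C)
    C <- (C + t(C)) / 2
    diag(C) <- 1
  }
  attr(C, "repaired") <- repaired
  C
}

group_mean_vector <- function(spec, genotype, treatment) {
  mu <- rep(1, spec$n_regions)
  ms <- spec$mean_shift
  if (!is.null(ms) && nrow(ms) > 0) {
    sel <- ms$genotype == genotype & ms$treatment == treatment
    if (any(sel)) {
      rows <- ms[sel, , drop = FALSE]
      mu[rows$region + 1L] <- mu[rows$region + 1L] + rows$shift
    }
  }
  mu
}

#' Generate a synthetic cohort with planted ground truth
#'
#' For each experimental group (drawn in fixed alphabetical
#' genotype/treatment order so a seed is portable across spec edits that do
#' not change group sizes), animals are drawn from a multivariate Gaussian
#' with mean `1 + mean_shift` and covariance `noise_sd^2 * C_group`, where
#' `C_group` is [build_group_correlation()]'s target. Values are truncated
#' below at 0.05 to honour positivity of uptake ratios. Sex alternates M/F
#' within each group. Identical spec and seed give bit-identical output.
#'
#' @param spec a `synthetic_spec`.
#' @param regions optional `RegionTable` (defaults to [default_regions()]
#'   when `n_regions` is 59, placeholder abbreviations otherwise).
#' @return A `cohort_table`.
#' @export
generate_cohort <- function(spec, regions = NULL) {
  validate_synthetic_spec(spec)
  if (is.null(regions)) {
    regions <- if (spec$n_regions == 59L) default_regions()
               else region_table(sprintf("R%02d", seq_len(spec$n_regions)))
  }
  if (nrow(regions) != spec$n_regions)
    stop("region table has ", nrow(regions), " rows but spec$n_regions is ",
         spec$n_regions)
  groups <- sort(names(spec$n_per_group))
  set.seed(spec$seed)
  up_list <- list(); md_list <- list()
  for (g in groups) {
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    genotype <- parts[1]; treatment <- parts[2]
    n <- spec$n_per_group[[g]]
    C <- build_group_correlation(spec, genotype, treatment)
    ev <- eigen(C, symmetric = TRUE)
    if (min(ev$values) < -1e-6) stop("non-PSD covariance after repair in group ", g)
    A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    mu <- group_mean_vector(spec, genotype, treatment)
    sexes <- rep(c("M", "F"), length.out = n)
    if (!is.null(spec$sex_shift) && nrow(spec$sex_shift) > 0) {
      shift_mat <- matrix(0, n, spec$n_regions)
      for (k in seq_len(nrow(spec$sex_shift))) {
        row <- spec$sex_shift[k, ]
        shift_mat[sexes == row$sex, row$region + 1L] <-
          shift_mat[sexes == row$sex, row$region + 1L] + row$shift
      }
    } else shift_mat <- 0
    Z <- matrix(stats::rnorm(n * spec$n_regions), n, spec$n_regions)
    X <- sweep(spec$noise_sd * (Z %*% A), 2, mu, "+") + shift_mat
    X <- pmax(X, 0.05)
    ids <- sprintf("%s_%s_%02d", genotype, treatment, seq_len(n))
    rownames(X) <- ids
    up_list[[g]] <- X
    md_list[[g]] <- data.frame(animal_id = ids, genotype = genotype,
                               treatment = treatment, sex = sexes,
                               stringsAsFactors = FALSE)
  }
  cohort_table(do.call(rbind, up_list), do.call(rbind, md_list), regions)
}

#' Write a simulated cohort plus its ground truth to a directory
#'
#' Writes the three interchange CSVs ([write_cohort()]) and
#' `ground_truth.yaml` describing the planted structure, for test
#' harnesses and external consumers.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory.
#' @param regions optional `RegionTable`.
#' @return Invisibly, the generated `cohort_table`.
#' @export
simulate_to_dir <- function(spec, dir, regions = NULL) {
  cohort <- generate_cohort(spec, regions)
  write_cohort(cohort, dir)
  truth <- list(
    seed = spec$seed,
    n_regions = spec$n_regions,
    base_corr = spec$base_corr,
    hub_regions = as.list(spec$hub_regions),
    hub_corr = spec$hub_corr,
    rcc_regions = as.list(spec$rcc_regions),
    rcc_corr = spec$rcc_corr,
    lost_edges_het = apply(spec$lost_edges_het, 1, as.list),
    restored_by_ket = apply(spec$restored_by_ket, 1, as.list),
    mean_shift = spec$mean_shift,
    noise_sd = spec$noise_sd
  )
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(cohort)
}
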