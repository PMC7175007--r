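#' Seed-region partial least squares regression
#'
#' Regresses the seed region's uptake ratios on all other regions across
#' the animals of one experimental group, by sequential NIPALS components
#' with predictor deflation. All columns are centred and scaled to unit
#' variance within the group, so downstream VIP values are scale-free.
#' Deterministic: no random initialisation.
#'
#' @param cohort a `cohort_table`.
#' @param genotype,treatment group label.
#' @param seed_region region abbreviation or 0-based id of the seed.
#' @param n_components latent components (default 2; small groups cannot
#'   support many).
#' @return object of class `plsr_model`: `weights` (predictors x
#'   components, unit columns), `scores`, `loadings`, `q` (response
#'   loadings), `ssy` (response variance explained per component),
#'   `predictors`, `seed_region`, `n`, `group`.
#' @export
plsr_fit <- function(cohort, genotype, treatment, seed_region, n_components = 2) {
  X <- group_uptake(cohort, genotype, treatment)
  seed_idx <- region_index(cohort, seed_region)
  plsr_fit_matrix(X[, -seed_idx, drop = FALSE], X[, seed_idx],
                  n_components = n_components,
                  seed_region = colnames(X)[seed_idx],
                  group = c(genotype, treatment))
}

region_index <- function(cohort, region) {
  if (is.numeric(region)) {
    idx <- as.integer(region) + 1L
    if (idx < 1 || idx > ncol(cohort$uptake)) stop("region id out of range")
    idx
  } else {
    idx <- match(region, cohort$regions$abbreviation)
    if (is.na(idx)) stop("unknown region abbreviation: ", region)
    idx
  }
}

plsr_fit_matrix <- function(X, y, n_components, seed_region = "y",
                            group = c("", "")) {
  n <- nrow(X); p <- ncol(X)
  if (n < n_components + 2)
    stop("group has n = ", n, " animals; need >= n_components + 2 = ",
         n_components + 2)
  if (n_components > min(n - 1, p))
    stop("n_components = ", n_components, " exceeds the data rank bound ",
         min(n - 1, p))
  sx <- apply(X, 2, stats::sd); sy <- stats::sd(y)
  if (any(sx == 0)) stop("constant predictor region(s): ",
                         paste(colnames(X)[sx == 0], collapse = ", "))
  if (sy == 0) stop("constant seed region")
  Xc <- scale(X); yc <- as.numeric(scale(y))
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- ssy <- numeric(n_components)
  Xa <- Xc; ya <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("rank exhausted at component ", a,
                         "; reduce n_components")
    w <- w / nw
    t_a <- as.numeric(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    ssy[a] <- q_a^2 * tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
  }
  structure(list(weights = W, scores = Tm, loadings = P, q = q, ssy = ssy,
                 predictors = colnames(X), seed_region = seed_region,
                 n = n, group = group, n_components = n_components),
            class = "plsr_model")
}

#' Variable importance in the projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ), with unit-norm
#' component weight vectors w_a, p predictors and SSY_a the response
#' variance explained by component a. The mean of VIP^2 over predictors is
#' exactly 1, so VIP > 1 marks predictors carrying more than an equal share
#' of the explained response variance.
#'
#' @param model a `plsr_model`.
#' @return named numeric vector of VIP values (one per predictor).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  tot <- sum(model$ssy)
  if (tot <= 0) stop("model explains no response variance; VIP undefined")
  p <- nrow(model$weights)
  v <- sqrt(p * as.numeric(model$weights^2 %*% model$ssy) / tot)
  stats::setNames(v, model$predictors)
}

#' Seed connectivity by jackknifed VIP
#'
#' Fits the group's seed PLSR, then refits leaving each animal out in turn
#' (re-standardising on the retained animals). The Tukey jackknife SE of
#' each target's VIP gives a normal-approximation 95% CI (point estimate
#' +/- 1.96 SE, floored at 0 since VIP >= 0). A target is a significant
#' functional connection of the seed when the CI lower bound exceeds 1.0.
#' Jackknife pseudo-values (n * full - (n-1) * leave-one-out) are retained
#' for between-group t-tests.
#'
#' @inheritParams plsr_fit
#' @return data.frame (class `vip_table`): `target`, `vip`, `se`,
#'   `ci_lower`, `ci_upper`, `significant`; attributes `pseudo_values`
#'   (n x targets matrix), `seed_region`, `group`, `n`.
#' @export
vip_jackknife <- function(cohort, genotype, treatment, seed_region,
                          n_components = 2) {
  X <- group_uptake(cohort, genotype, treatment)
  if (nrow(X) < 4) stop("jackknife needs >= 4 animals")
  seed_idx <- region_index(cohort, seed_region)
  seed_name <- colnames(X)[seed_idx]
  Xp <- X[, -seed_idx, drop = FALSE]; y <- X[, seed_idx]
  n <- nrow(X)
  full <- vip(plsr_fit_matrix(Xp, y, n_components, seed_name,
                              c(genotype, treatment)))
  loo <- matrix(NA_real_, n, length(full),
                dimnames = list(rownames(X), names(full)))
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      plsr_fit_matrix(Xp[-i, , drop = FALSE], y[-i], n_components,
                      seed_name, c(genotype, treatment)),
      error = function(e) stop("jackknife refit failed leaving out animal '",
                               rownames(X)[i], "': ", conditionMessage(e)))
    loo[i, ] <- vip(fit_i)
  }
  se <- sqrt((n - 1) / n * colSums(sweep(loo, 2, colMeans(loo))^2))
  ci_lower <- pmax(full - 1.96 * se, 0)
  ci_upper <- full + 1.96 * se
  pseudo <- sweep(-(n - 1) * loo, 2, n * full, "+")
  res <- data.frame(target = names(full), vip = unname(full), se = unname(se),
                    ci_lower = unname(ci_lower), ci_upper = unname(ci_upper),
                    significant = unname(ci_lower > 1),
                    stringsAsFactors = FALSE)
  class(res) <- c("vip_table", "data.frame")
  attr(res, "pseudo_values") <- pseudo
  attr(res, "seed_region") <- seed_name
  attr(res, "group") <- c(genotype, treatment)
  attr(res, "n") <- n
  res
}

pseudo_t_test <- function(pa, pb) {
  if (stats::sd(pa) == 0 && stats::sd(pb) == 0) {
    return(if (mean(pa) == mean(pb)) 1 else 0)
  }
  stats::t.test(pa, pb)$p.value
}

#' Between-group comparison of seed VIP profiles
#'
#' Welch two-sample t-tests on the jackknife pseudo-values of each
#' target's VIP (a "t-test" on a single VIP per group is otherwise
#' undefined), Bonferroni-adjusted over the seed's target family
#' (R - 1 targets).
#'
#' @param table_a,table_b `vip_table`s for the same seed and region set.
#' @return data.frame: `target`, `vip_a`, `vip_b`, `p_raw`, `p_adj`.
#' @export
compare_vip <- function(table_a, table_b) {
  if (!identical(table_a$target, table_b$target))
    stop("VIP tables have different target sets")
  if (!identical(attr(table_a, "seed_region"), attr(table_b, "seed_region")))
    stop("VIP tables have different seed regions")
  pa <- attr(table_a, "pseudo_values"); pb <- attr(table_b, "pseudo_values")
  p_raw <- vapply(seq_along(table_a$target), function(j)
    pseudo_t_test(pa[, j], pb[, j]), numeric(1))
  data.frame(target = table_a$target,
             vip_a = table_a$vip, vip_b = table_b$vip,
             p_raw = p_raw,
             p_adj = pmin(p_raw * length(p_raw), 1),
             stringsAsFactors = FALSE)
}

#' Classify lost and gained seed connectivity between genotypes
#'
#' A target is "lost" in the mutant when the WT VIP 95% CI lower bound
#' exceeds 1.0, the mutant's is below 1.0, and the Bonferroni-adjusted
#' between-group p is below `alpha`; "gained" is the mirrored rule;
#' everything else is "unchanged".
#'
#' @param wt,het `vip_table`s for the same seed (WT and mutant group).
#' @param comparison optional precomputed [compare_vip()] output.
#' @param alpha significance level (default 0.05).
#' @return data.frame (class `connectivity_changes`): `seed`, `target`,
#'   `class`, `p_adj`, `wt_ci_lower`, `het_ci_lower`.
#' @export
classify_changes <- function(wt, het, comparison = NULL, alpha = 0.05) {
  comparison <- comparison %||% compare_vip(wt, het)
  cls <- rep("unchanged", nrow(comparison))
  sig <- comparison$p_adj < alpha
  cls[sig & wt$ci_lower > 1 & het$ci_lower < 1] <- "lost"
  cls[sig & wt$ci_lower < 1 & het$ci_lower > 1] <- "gained"
  res <- data.frame(seed = attr(wt, "seed_region"),
                    target = comparison$target, class = cls,
                    p_adj = comparison$p_adj,
                    wt_ci_lower = wt$ci_lower, het_ci_lower = het$ci_lower,
                    stringsAsFactors = FALSE)
  class(res) <- c("connectivity_changes", "data.frame")
  res
}

#' Classify drug-restored seed connectivity
#'
#' Among targets "lost" in the untreated mutant (vs untreated WT), a
#' connection is "restored" by the drug when (i) the drug-treated mutant's
#' VIP is significantly higher than the untreated mutant's (Bonferroni
#' t-test on pseudo-values and an increase in the point estimate), (ii)
#' the drug-treated mutant's VIP 95% CI lower bound exceeds 1.0, and (iii)
#' the drug-treated mutant is not significantly different from the
#' untreated WT after Bonferroni.
#'
#' @param het_sal,het_drug,wt_sal `vip_table`s for the same seed.
#' @param lost_targets character vector of targets classified "lost"
#'   (e.g. from [classify_changes()]); defaults to computing it from
#'   `wt_sal` vs `het_sal`.
#' @param alpha significance level.
#' @return data.frame like [classify_changes()] with classes
#'   `"restored"`/`"not_restored"` over the lost targets.
#' @export
classify_restoration <- function(het_sal, het_drug, wt_sal,
                                 lost_targets = NULL, alpha = 0.05) {
  if (is.null(lost_targets)) {
    ch <- classify_changes(wt_sal, het_sal, alpha = alpha)
    lost_targets <- ch$target[ch$class == "lost"]
  }
  cmp_drug_sal <- compare_vip(het_drug, het_sal)
  cmp_drug_wt <- compare_vip(het_drug, wt_sal)
  idx <- match(lost_targets, het_drug$target)
  if (anyNA(idx)) stop("lost target(s) not in the VIP tables: ",
                       paste(lost_targets[is.na(idx)], collapse = ", "))
  restored <- cmp_drug_sal$p_adj[idx] < alpha &
    het_drug$vip[idx] > het_sal$vip[idx] &
    het_drug$ci_lower[idx] > 1 &
    cmp_drug_wt$p_adj[idx] >= alpha
  res <- data.frame(seed = attr(het_drug, "seed_region"),
                    target = lost_targets,
                    class = ifelse(restored, "restored", "not_restored"),
                    p_increase_adj = cmp_drug_sal$p_adj[idx],
                    p_vs_wt_adj = cmp_drug_wt$p_adj[idx],
                    drug_ci_lower = het_drug$ci_lower[idx],
                    stringsAsFactors = FALSE)
  class(res) <- c("connectivity_changes", "data.frame")
  res
}
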