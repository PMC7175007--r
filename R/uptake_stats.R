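#' Regional uptake ratio
#'
#' The per-animal, per-region input of the whole pipeline: regional isotope
#' concentration divided by the whole-brain concentration of the same
#' animal.
#'
#' @param region_value regional isotope concentration (any consistent unit).
#' @param whole_brain_value whole-brain concentration, strictly positive.
#' @return Dimensionless uptake ratio.
#' @export
uptake_ratio <- function(region_value, whole_brain_value) {
  if (any(!is.finite(whole_brain_value)) || any(whole_brain_value <= 0))
    stop("whole-brain concentration must be positive and finite")
  if (any(region_value == 0))
    warning("uptake ratio of exactly 0 is biologically implausible")
  region_value / whole_brain_value
}

#' Factorial ANOVA on one region's uptake ratios
#'
#' Fits the full factorial model over the requested factors (default
#' sex + genotype + treatment) and reports marginal (Type II)
#' sums-of-squares F tests: each term is tested against the model
#' containing every other term that does not include it, with the residual
#' mean square of the full model as denominator. Type II is the default
#' because group sizes are unbalanced; Type III (sum-to-zero contrasts,
#' drop-one from the full model) is available via `ss`.
#'
#' When no interaction involving genotype reaches `alpha`, the result
#' carries `genotype_main_effect_accepted = TRUE`: the genotype main effect,
#' estimated from all animals, stands as the reported effect. This is a
#' reporting flag, not a refit.
#'
#' @param cohort a `cohort_table`.
#' @param region region abbreviation or 0-based region id.
#' @param factors character vector among `"sex"`, `"genotype"`,
#'   `"treatment"`; the full factorial over these is fitted.
#' @param ss `"II"` (default) or `"III"`.
#' @param alpha significance level for the reporting flag.
#' @param subset_treatments optional treatment levels to retain first (the
#'   drug analyses contrast saline with a single drug).
#' @return A data.frame (class `anova_result`) with one row per effect:
#'   `effect`, `F`, `df1`, `df2`, `p`; attributes `residual_df` and
#'   `genotype_main_effect_accepted`.
#' @export
factorial_anova <- function(cohort, region, factors = c("sex", "genotype", "treatment"),
                            ss = c("II", "III"), alpha = 0.05,
                            subset_treatments = NULL) {
  ss <- match.arg(ss)
  factors <- match.arg(factors, several.ok = TRUE)
  y <- region_vector(cohort, region)
  md <- cohort$metadata
  if (!is.null(subset_treatments)) {
    keep <- md$treatment %in% subset_treatments
    md <- md[keep, , drop = FALSE]
    y <- y[keep]
  }
  dat <- data.frame(y = y, lapply(md[factors], factor))
  for (f in factors)
    if (nlevels(dat[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 levels in this cohort subset")
  # full factorial cells must be populated for the interactions to be estimable
  cells <- table(dat[factors])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)
    lab <- paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                        seq_along(factors), idx[1, ]), collapse = "/")
    stop("empty design cell: ", lab)
  }
  full_formula <- stats::as.formula(paste("y ~", paste(factors, collapse = " * ")))
  old_contr <- options(contrasts = c(
    if (ss == "III") "contr.sum" else "contr.treatment", "contr.poly"))
  on.exit(options(old_contr), add = TRUE)
  full <- stats::lm(full_formula, data = dat)
  rdf <- full$df.residual
  if (rdf < 1) stop("residual degrees of freedom < 1; design saturated")
  mse <- sum(stats::residuals(full)^2) / rdf
  term_labels <- attr(stats::terms(full), "term.labels")
  term_factors <- strsplit(term_labels, ":", fixed = TRUE)
  rows <- lapply(seq_along(term_labels), function(i) {
    if (ss == "II") {
      contains_i <- vapply(term_factors, function(s)
        all(term_factors[[i]] %in% s), logical(1))
      base_terms <- term_labels[!contains_i]
      f0 <- if (length(base_terms) == 0) "y ~ 1"
            else paste("y ~", paste(base_terms, collapse = " + "))
      f1 <- paste(f0, "+", term_labels[i])
      m0 <- stats::lm(stats::as.formula(f0), data = dat)
      m1 <- stats::lm(stats::as.formula(f1), data = dat)
      ssq <- sum(stats::residuals(m0)^2) - sum(stats::residuals(m1)^2)
      df1 <- m0$df.residual - m1$df.residual
    } else {
      asgn <- full$assign
      X <- stats::model.matrix(full)
      keep <- asgn != i
      m0 <- stats::lm.fit(X[, keep, drop = FALSE], dat$y)
      ssq <- sum(m0$residuals^2) - sum(stats::residuals(full)^2)
      df1 <- sum(asgn == i)
    }
    Fv <- (ssq / df1) / mse
    data.frame(effect = term_labels[i], F = Fv, df1 = df1, df2 = rdf,
               p = stats::pf(Fv, df1, rdf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("anova_result", "data.frame")
  attr(res, "residual_df") <- rdf
  geno_int <- grepl("genotype", res$effect) & grepl(":", res$effect)
  attr(res, "genotype_main_effect_accepted") <-
    "genotype" %in% factors && !any(res$p[geno_int] < alpha)
  res
}

region_vector <- function(cohort, region) {
  if (is.numeric(region)) {
    idx <- as.integer(region) + 1L
    if (idx < 1 || idx > ncol(cohort$uptake))
      stop("region id ", region, " out of range")
  } else {
    idx <- match(region, cohort$regions$abbreviation)
    if (is.na(idx)) stop("unknown region abbreviation: ", region)
  }
  cohort$uptake[, idx]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th by m/i, enforces
#' monotone non-increase from the largest down, caps at 1, and restores the
#' input order. Equivalent to `p.adjust(method = "BH")`, implemented
#' directly because the step-up rule is part of the method contract.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  scaled <- pvals[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Post hoc pairwise contrasts between design cells
#'
#' Welch two-sample t-tests (default; pooled-variance optional) on one
#' region's uptake for every pair of the requested genotype/treatment
#' cells, with Benjamini-Hochberg adjustment across this family only.
#'
#' @param cohort a `cohort_table`.
#' @param region region abbreviation or 0-based id.
#' @param cells list of `c(genotype, treatment)` pairs (>= 2 cells).
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @param alpha significance level for the flag column.
#' @return data.frame (class `posthoc_table`): one row per contrast with
#'   `t`, `df`, `p_raw`, `p_adj`, `significant`.
#' @export
posthoc_pairwise <- function(cohort, region, cells, pooled = FALSE, alpha = 0.05) {
  if (length(cells) < 2) stop("need at least two cells to contrast")
  y <- region_vector(cohort, region)
  md <- cohort$metadata
  vals <- lapply(cells, function(cell) {
    sel <- md$genotype == cell[1] & md$treatment == cell[2]
    if (!any(sel)) stop("unknown or empty cell: ", cell[1], "/", cell[2])
    v <- y[sel]
    if (length(v) < 2) stop("cell ", cell[1], "/", cell[2], " has < 2 animals")
    v
  })
  labels <- vapply(cells, paste, character(1), collapse = "/")
  pairs <- utils::combn(length(cells), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = pooled)
    }
    data.frame(cell_a = labels[pr[1]], cell_b = labels[pr[2]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res$significant <- res$p_adj < alpha
  class(res) <- c("posthoc_table", "data.frame")
  res
}
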