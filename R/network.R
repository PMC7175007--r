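#' Group-wise correlation network
#'
#' Builds the functional-connectivity matrix of one experimental group: the
#' Pearson correlation of the uptake ratios between every pair of regions,
#' across the animals of that group, together with its Fisher z-transform
#' (`atanh(r)`; variance-stabilising). For R regions there are R(R-1)/2
#' unordered region pairs (1711 when R = 59). The binary adjacency stack is
#' added by [threshold_adjacency()].
#'
#' @param cohort a `cohort_table`.
#' @param genotype,treatment the group label.
#' @return An object of class `group_network` with elements `group`
#'   (`c(genotype, treatment)`), `n_animals`, `R` (correlation matrix),
#'   `Z` (Fisher z, `NA` on the diagonal and wherever |r| = 1, with a
#'   warning), `thresholds` (`NULL` until thresholded), `A` (`NULL`).
#' @export
correlation_matrix <- function(cohort, genotype, treatment) {
  X <- group_uptake(cohort, genotype, treatment)
  if (nrow(X) < 3)
    stop("group ", genotype, "/", treatment, " has ", nrow(X),
         " animals; >= 3 required for correlation estimation")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s) in group ", genotype, "/", treatment, ": ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  Z <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  off <- upper.tri(R) | lower.tri(R)
  sat <- off & abs(R) >= 1 - 1e-15
  if (any(sat)) {
    warning("correlation(s) with |r| = 1 off-diagonal; Fisher z masked (atanh diverges)")
    ok <- off & !sat
  } else ok <- off
  Z[ok] <- atanh(R[ok])
  structure(
    list(group = c(genotype = genotype, treatment = treatment),
         n_animals = nrow(X), R = R, Z = Z, thresholds = NULL, A = NULL),
    class = "group_network"
  )
}

#' Build a group_network directly from an uptake matrix
#' @param X animals x regions matrix.
#' @param label optional group label.
#' @keywords internal
network_from_matrix <- function(X, label = c(genotype = "WT", treatment = "SAL")) {
  co <- cohort_table(
    X,
    data.frame(animal_id = rownames(X) %||% sprintf("a%02d", seq_len(nrow(X))),
               genotype = label[["genotype"]], treatment = label[["treatment"]],
               sex = rep_len(c("M", "F"), nrow(X)), stringsAsFactors = FALSE),
    region_table(colnames(X) %||% sprintf("R%02d", seq_len(ncol(X))))
  )
  correlation_matrix(co, label[["genotype"]], label[["treatment"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.group_network <- function(x, ...) {
  cat("<group_network> ", x$group[["genotype"]], "/", x$group[["treatment"]],
      ": ", nrow(x$R), " regions, ", x$n_animals, " animals", sep = "")
  if (!is.null(x$thresholds))
    cat(", thresholds ", min(x$thresholds), "-", max(x$thresholds), sep = "")
  cat("\n")
  invisible(x)
}

#' Threshold a correlation network into a binary adjacency stack
#'
#' An edge joins regions i and j at threshold T when the signed Pearson
#' r(i, j) >= T (boundary inclusive; a negative correlation never passes a
#' positive threshold). Set `absolute = TRUE` to threshold |r| instead.
#' Edge sets are monotone: raising T can only remove edges.
#'
#' @param network a `group_network`.
#' @param thresholds strictly increasing vector of thresholds in (0, 1).
#' @param absolute threshold |r| rather than signed r.
#' @return The network with `thresholds` and the adjacency list `A` filled.
#' @export
threshold_adjacency <- function(network, thresholds, absolute = FALSE) {
  stopifnot(inherits(network, "group_network"))
  if (length(thresholds) == 0 || any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  Rm <- if (absolute) abs(network$R) else network$R
  A <- lapply(thresholds, function(t) {
    a <- (Rm >= t) * 1L
    diag(a) <- 0L
    dimnames(a) <- dimnames(network$R)
    a
  })
  names(A) <- format_threshold(thresholds)
  network$thresholds <- thresholds
  network$A <- A
  network
}

format_threshold <- function(t) sprintf("T%.4g", t)

#' Is a binary adjacency matrix one connected component?
#' @param A symmetric 0/1 matrix, zero diagonal.
#' @export
is_connected <- function(A) {
  n <- nrow(A)
  if (n == 0) return(FALSE)
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

#' Select the shared correlation-threshold grid
#'
#' Starting at `t_min` and stepping by `step`, the grid extends to the
#' largest threshold at which every supplied group network is still a
#' single connected component (the published design criterion: the maximum
#' threshold must yield fully connected networks in each group), capped at
#' `t_hard_max` to avoid degenerate near-clique grids.
#'
#' @param networks list of `group_network` objects.
#' @param t_min first threshold (default 0.49).
#' @param step grid increment (default 0.01).
#' @param t_hard_max upper cap (default 0.95).
#' @return Numeric vector of thresholds.
#' @export
select_threshold_grid <- function(networks, t_min = 0.49, step = 0.01,
                                  t_hard_max = 0.95) {
  if (t_min <= 0 || t_min >= 1) stop("t_min must lie in (0, 1)")
  if (step <= 0) stop("step must be positive")
  candidate <- seq(t_min, t_hard_max + step / 2, by = step)
  candidate <- candidate[candidate <= t_hard_max + 1e-12]
  all_connected <- vapply(candidate, function(t) {
    all(vapply(networks, function(nw) {
      a <- (nw$R >= t) * 1L
      diag(a) <- 0L
      is_connected(a)
    }, logical(1)))
  }, logical(1))
  if (!all_connected[1])
    stop("a group network is disconnected already at t_min = ", t_min,
         "; lower t_min")
  t_max_idx <- if (all(all_connected)) length(candidate)
               else which(!all_connected)[1] - 1L
  candidate[seq_len(t_max_idx)]
}

#' Number of unordered region pairs of a network
#' @param network a `group_network` (or region count).
#' @export
n_region_pairs <- function(network) {
  R <- if (inherits(network, "group_network")) nrow(network$R) else as.integer(network)
  R * (R - 1) / 2
}
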