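#' Cohort container
#'
#' A `CohortTable` bundles the animals-by-regions uptake-ratio matrix with
#' per-animal metadata (genotype, treatment, sex) and the `RegionTable` that
#' fixes region order. Uptake values are the dimensionless ratio of regional
#' to whole-brain isotope concentration; they must be strictly positive,
#' finite and complete (no imputation anywhere in the pipeline).
#'
#' @param uptake numeric matrix, animals x regions; rownames are animal ids.
#' @param metadata data.frame with columns `animal_id`, `genotype`
#'   (`WT`/`HET`), `treatment` (`SAL`/`KET`/`AMPH`), `sex` (`M`/`F`).
#' @param regions a `RegionTable`; its row order defines column order.
#' @return A validated object of class `cohort_table`.
#' @export
cohort_table <- function(uptake, metadata, regions) {
  validate_region_table(regions)
  uptake <- as.matrix(uptake)
  storage.mode(uptake) <- "double"
  if (is.null(rownames(uptake))) rownames(uptake) <- metadata$animal_id
  colnames(uptake) <- regions$abbreviation
  obj <- structure(
    list(uptake = uptake, metadata = metadata, regions = regions),
    class = "cohort_table"
  )
  validate_cohort(obj)
}

GENOTYPE_LEVELS <- c("WT", "HET")
TREATMENT_LEVELS <- c("SAL", "KET", "AMPH")
SEX_LEVELS <- c("M", "F")

validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  md <- x$metadata
  req <- c("animal_id", "genotype", "treatment", "sex")
  miss <- setdiff(req, names(md))
  if (length(miss) > 0)
    stop("cohort metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$animal_id))
    stop("duplicate animal_id: ",
         paste(unique(md$animal_id[duplicated(md$animal_id)]), collapse = ", "))
  check_levels <- function(vals, levels, what) {
    bad <- setdiff(unique(as.character(vals)), levels)
    if (length(bad) > 0)
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
           " (expected ", paste(levels, collapse = "/"), ")")
    if (anyNA(vals)) stop("missing ", what, " value")
  }
  check_levels(md$genotype, GENOTYPE_LEVELS, "genotype")
  check_levels(md$treatment, TREATMENT_LEVELS, "treatment")
  check_levels(md$sex, SEX_LEVELS, "sex")
  up <- x$uptake
  extra_md <- setdiff(md$animal_id, rownames(up))
  extra_up <- setdiff(rownames(up), md$animal_id)
  if (length(extra_md) > 0)
    stop("animal(s) in metadata but not in uptake: ", paste(extra_md, collapse = ", "))
  if (length(extra_up) > 0)
    stop("animal(s) in uptake but not in metadata: ", paste(extra_up, collapse = ", "))
  if (nrow(up) != nrow(md))
    stop("uptake has ", nrow(up), " animals but metadata has ", nrow(md))
  if (ncol(up) != nrow(x$regions))
    stop("uptake has ", ncol(up), " regions but region table has ", nrow(x$regions))
  bad <- which(!is.finite(up) | up <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid uptake cell (missing, non-finite or non-positive): animal '",
         rownames(up)[bad[1, 1]], "', region '", colnames(up)[bad[1, 2]], "'")
  }
  # uptake rows reordered to metadata order so group subsetting is stable
  x$uptake <- up[md$animal_id, , drop = FALSE]
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  md <- x$metadata
  cat("<cohort_table> ", nrow(x$uptake), " animals x ", ncol(x$uptake),
      " regions\n", sep = "")
  print(table(genotype = md$genotype, treatment = md$treatment))
  invisible(x)
}

#' Subset a cohort to one experimental group
#'
#' @param cohort a `cohort_table`.
#' @param genotype,treatment group labels.
#' @return The uptake submatrix (animals x regions) for that group.
#' @export
group_uptake <- function(cohort, genotype, treatment) {
  md <- cohort$metadata
  keep <- md$genotype == genotype & md$treatment == treatment
  if (!any(keep)) stop("no animals in group ", genotype, "/", treatment)
  cohort$uptake[md$animal_id[keep], , drop = FALSE]
}

#' Read a cohort from its three CSV files
#'
#' The on-disk uptake table has regions as rows (first column `region`,
#' remaining columns one per animal) and is transposed to animals x regions
#' in memory. Any mismatch between the animal sets of the uptake and
#' metadata files, and any missing or non-positive cell, is an error: no
#' animal is ever silently dropped and nothing is imputed.
#'
#' @param uptake_path CSV, first column `region` then one column per animal.
#' @param metadata_path CSV with columns `animal_id`, `genotype`,
#'   `treatment`, `sex`.
#' @param regions_path CSV with columns `abbreviation`, `name`, `system`.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(uptake_path, metadata_path, regions_path) {
  for (p in c(uptake_path, metadata_path, regions_path))
    if (!file.exists(p)) stop("file not found: ", p)
  regions <- read_regions(regions_path)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  raw <- utils::read.csv(uptake_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "region")
    stop("uptake CSV must have 'region' as its first column")
  if (!identical(raw$region, regions$abbreviation))
    stop("uptake CSV region rows do not match the region table ",
         "(order and abbreviations must agree exactly)")
  up <- t(as.matrix(raw[, -1, drop = FALSE]))  # animals x regions
  colnames(up) <- regions$abbreviation
  cohort_table(up, md, regions)
}

#' Write a cohort to the three-CSV interchange layout
#'
#' Inverse of [read_cohort()]: values round-trip to within 1e-12.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("uptake.csv", "metadata.csv", "regions.csv"))
  up <- cbind(
    data.frame(region = cohort$regions$abbreviation, stringsAsFactors = FALSE),
    as.data.frame(t(cohort$uptake))
  )
  utils::write.csv(format(up, digits = 15, trim = TRUE), paths[1],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$metadata[, c("animal_id", "genotype", "treatment", "sex")],
                   paths[2], row.names = FALSE, quote = FALSE)
  write_regions(cohort$regions, paths[3])
  invisible(paths)
}

#' Export one threshold's edge list
#'
#' One row per edge (i < j) with both abbreviations, the Pearson r and the
#' Fisher z. Re-thresholding the written r values at the same threshold
#' reproduces the adjacency exactly.
#'
#' @param network a `group_network` (see [correlation_matrix()]).
#' @param threshold_index 1-based index into the network's threshold grid.
#' @param path output CSV path.
#' @export
write_edge_list <- function(network, threshold_index, path) {
  stopifnot(inherits(network, "group_network"))
  if (is.null(network$A)) stop("network has no adjacency stack; threshold it first")
  nt <- length(network$thresholds)
  if (threshold_index < 1 || threshold_index > nt)
    stop("threshold_index ", threshold_index, " out of range 1..", nt)
  A <- network$A[[threshold_index]]
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  abbr <- colnames(network$R)
  df <- data.frame(
    region_a = abbr[idx[, 1]],
    region_b = abbr[idx[, 2]],
    r = network$R[idx],
    z = network$Z[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$region_a, abbr), match(df$region_b, abbr)), , drop = FALSE]
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an adjacency matrix as labelled 0/1 CSV
#'
#' @inheritParams write_edge_list
#' @export
write_adjacency <- function(network, threshold_index, path) {
  stopifnot(inherits(network, "group_network"))
  nt <- length(network$thresholds)
  if (threshold_index < 1 || threshold_index > nt)
    stop("threshold_index ", threshold_index, " out of range 1..", nt)
  A <- network$A[[threshold_index]]
  out <- cbind(data.frame(region = colnames(A)), as.data.frame(A))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
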