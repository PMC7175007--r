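#' Pipeline configuration
#'
#' Builds a fully defaulted configuration for [run_pipeline()]. Either
#' supply `cohort_dir` (a directory holding `uptake.csv`, `metadata.csv`,
#' `regions.csv`) or leave it `NULL` to simulate a synthetic cohort from
#' `synthetic` (a [synthetic_spec()], built with `seed` when omitted).
#' Every stochastic stage derives its own recorded seed from `seed`.
#'
#' @param seed master RNG seed (required; all stage seeds derive from it).
#' @param out_dir output directory for stage artifacts and the run log.
#' @param cohort_dir optional directory with the three input CSVs.
#' @param synthetic optional `synthetic_spec`.
#' @param t_min,t_step threshold-grid parameters.
#' @param n_null ER null graphs per threshold (hub stage).
#' @param n_perm permutations per threshold (permutation stage).
#' @param n_rewire rewired nulls per threshold (rich-club stage).
#' @param n_components PLSR components.
#' @param seed_regions seed-region abbreviations for the PLSR stage.
#' @param drug drug treatment contrasted with saline (`"KET"` or `"AMPH"`).
#' @param alpha significance level used throughout.
#' @param yaml_path optional YAML file whose fields override the defaults
#'   (CLI flags override the file in turn).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = NULL, out_dir = "metabnet_run",
                            cohort_dir = NULL, synthetic = NULL,
                            t_min = 0.49, t_step = 0.01,
                            n_null = 1000, n_perm = 5000, n_rewire = 100,
                            n_components = 2,
                            seed_regions = c("Re", "dRT"),
                            drug = "KET", alpha = 0.05,
                            yaml_path = NULL) {
  cfg <- list(seed = seed, out_dir = out_dir, cohort_dir = cohort_dir,
              synthetic = synthetic, t_min = t_min, t_step = t_step,
              n_null = n_null, n_perm = n_perm, n_rewire = n_rewire,
              n_components = n_components, seed_regions = seed_regions,
              drug = drug, alpha = alpha)
  if (!is.null(yaml_path)) {
    over <- yaml::read_yaml(yaml_path)
    for (k in names(over)) cfg[[k]] <- over[[k]]
  }
  if (is.null(cfg$seed))
    stop("pipeline config needs an explicit seed (reproducibility contract)")
  cfg$seed <- as.integer(cfg$seed)
  cfg$drug <- match.arg(cfg$drug, c("KET", "AMPH"))
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, offset) (cfg$seed * 97L + offset) %% 2000000011L

#' Run the full pipeline from one configuration
#'
#' Stages, in dependency order: cohort (simulate or load), regional
#' metabolism statistics, group networks with a shared threshold grid,
#' global/centrality metrics, ER-null hub tables, permutation tests of the
#' global metrics (WT/SAL vs HET/SAL), rich-club cores, and seed-region
#' PLSR connectivity with lost/gained/restored classification. Each stage
#' writes its CSV artifacts under `out_dir` and appends a structured line
#' (stage, elapsed seconds, seed) to `run_log.jsonl`. Identical
#' configurations give bit-identical artifacts.
#'
#' @param cfg a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_stage <- function(stage, seed, t0) {
    entry <- list(stage = stage, seed = seed,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
                  package_version = as.character(utils::packageVersion("metabnet")))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    if (!quiet) message(sprintf("[%s] done in %.1fs (seed %s)", stage,
                                entry$elapsed_s, seed))
  }
  results <- list(config = cfg)

  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$cohort_dir)) {
    cohort <- read_cohort(file.path(cfg$cohort_dir, "uptake.csv"),
                          file.path(cfg$cohort_dir, "metadata.csv"),
                          file.path(cfg$cohort_dir, "regions.csv"))
    log_stage("load_cohort", NA, t0)
  } else {
    spec <- cfg$synthetic %||% synthetic_spec(seed = stage_seed(cfg, 1L))
    cohort <- simulate_to_dir(spec, file.path(cfg$out_dir, "cohort"))
    log_stage("simulate", spec$seed, t0)
  }
  results$cohort <- cohort

  # regional metabolism: saline-vs-drug factorial ANOVA + post hoc
  t0 <- as.numeric(Sys.time())
  treatments <- c("SAL", cfg$drug)
  anova_rows <- lapply(cohort$regions$abbreviation, function(ab) {
    res <- factorial_anova(cohort, ab, subset_treatments = treatments)
    cbind(region = ab, as.data.frame(res))
  })
  anova_tab <- do.call(rbind, anova_rows)
  utils::write.csv(anova_tab, file.path(cfg$out_dir, "anova.csv"),
                   row.names = FALSE)
  cells <- list(c("WT", "SAL"), c("WT", cfg$drug),
                c("HET", "SAL"), c("HET", cfg$drug))
  posthoc_tab <- do.call(rbind, lapply(cohort$regions$abbreviation, function(ab)
    cbind(region = ab, posthoc_pairwise(cohort, ab, cells, alpha = cfg$alpha))))
  utils::write.csv(posthoc_tab, file.path(cfg$out_dir, "posthoc.csv"),
                   row.names = FALSE)
  results$anova <- anova_tab; results$posthoc <- posthoc_tab
  log_stage("metabolism", NA, t0)

  # group networks on the shared grid (saline groups: drug-free architecture)
  t0 <- as.numeric(Sys.time())
  nw_wt <- correlation_matrix(cohort, "WT", "SAL")
  nw_het <- correlation_matrix(cohort, "HET", "SAL")
  grid <- select_threshold_grid(list(nw_wt, nw_het), cfg$t_min, cfg$t_step)
  nw_wt <- threshold_adjacency(nw_wt, grid)
  nw_het <- threshold_adjacency(nw_het, grid)
  for (nw in list(nw_wt, nw_het)) {
    tag <- paste(nw$group, collapse = "_")
    utils::write.csv(data.frame(region = colnames(nw$R), nw$R),
                     file.path(cfg$out_dir, paste0("correlation_", tag, ".csv")),
                     row.names = FALSE)
    write_edge_list(nw, length(grid),
                    file.path(cfg$out_dir, paste0("edges_tmax_", tag, ".csv")))
  }
  results$networks <- list(wt = nw_wt, het = nw_het); results$grid <- grid
  log_stage("networks", NA, t0)

  t0 <- as.numeric(Sys.time())
  met_wt <- network_metrics(nw_wt); met_het <- network_metrics(nw_het)
  utils::write.csv(cbind(group = "WT_SAL", met_wt$global),
                   file.path(cfg$out_dir, "global_metrics_WT_SAL.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(group = "HET_SAL", met_het$global),
                   file.path(cfg$out_dir, "global_metrics_HET_SAL.csv"),
                   row.names = FALSE)
  results$metrics <- list(wt = met_wt, het = met_het)
  log_stage("metrics", NA, t0)

  t0 <- as.numeric(Sys.time())
  s_hub <- stage_seed(cfg, 2L)
  hubs_wt <- er_null_z(nw_wt, n_null = cfg$n_null, seed = s_hub)
  hubs_het <- er_null_z(nw_het, n_null = cfg$n_null, seed = s_hub + 1L)
  utils::write.csv(as.data.frame(hubs_wt),
                   file.path(cfg$out_dir, "hubs_WT_SAL.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(hubs_het),
                   file.path(cfg$out_dir, "hubs_HET_SAL.csv"), row.names = FALSE)
  results$hubs <- list(wt = hubs_wt, het = hubs_het)
  log_stage("hubs", s_hub, t0)

  t0 <- as.numeric(Sys.time())
  s_perm <- stage_seed(cfg, 3L)
  perms <- lapply(c("mean_degree", "path_length", "clustering"), function(st)
    permute_groups(cohort, c("HET", "SAL"), c("WT", "SAL"), st, grid,
                   n_perm_per_threshold = cfg$n_perm, seed = s_perm))
  perm_tab <- do.call(rbind, lapply(perms, function(p)
    data.frame(statistic = p$statistic, observed = p$observed, p = p$p,
               n_total = p$n_total, n_dropped = p$n_dropped)))
  utils::write.csv(perm_tab, file.path(cfg$out_dir, "permutation_tests.csv"),
                   row.names = FALSE)
  results$permutations <- perms
  log_stage("permute", s_perm, t0)

  t0 <- as.numeric(Sys.time())
  s_rc <- stage_seed(cfg, 4L)
  rc_wt <- rich_club_core(nw_wt, n_rewire_null = cfg$n_rewire, seed = s_rc)
  rc_het <- rich_club_core(nw_het, n_rewire_null = cfg$n_rewire, seed = s_rc + 1L)
  writeLines(jsonlite::toJSON(list(WT_SAL = rc_wt$rcc, HET_SAL = rc_het$rcc),
                              pretty = TRUE),
             file.path(cfg$out_dir, "rich_club_core.json"))
  results$rich_club <- list(wt = rc_wt, het = rc_het)
  log_stage("richclub", s_rc, t0)

  t0 <- as.numeric(Sys.time())
  changes <- list()
  for (sr in cfg$seed_regions) {
    wt_tab <- vip_jackknife(cohort, "WT", "SAL", sr, cfg$n_components)
    het_tab <- vip_jackknife(cohort, "HET", "SAL", sr, cfg$n_components)
    drug_tab <- vip_jackknife(cohort, "HET", cfg$drug, sr, cfg$n_components)
    ch <- classify_changes(wt_tab, het_tab, alpha = cfg$alpha)
    rest <- classify_restoration(het_tab, drug_tab, wt_tab, alpha = cfg$alpha)
    utils::write.csv(as.data.frame(wt_tab),
                     file.path(cfg$out_dir, paste0("vip_WT_SAL_", sr, ".csv")),
                     row.names = FALSE)
    changes[[sr]] <- list(changes = ch, restoration = rest)
  }
  change_tab <- do.call(rbind, lapply(changes, function(x) x$changes))
  utils::write.csv(change_tab, file.path(cfg$out_dir, "connectivity_changes.csv"),
                   row.names = FALSE)
  rest_tab <- do.call(rbind, lapply(changes, function(x) x$restoration))
  utils::write.csv(rest_tab, file.path(cfg$out_dir, "connectivity_restoration.csv"),
                   row.names = FALSE)
  results$plsr <- changes
  log_stage("plsr", NA, t0)

  invisible(results)
}
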