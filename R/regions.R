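#' Region-of-interest catalogue
#'
#' A `RegionTable` is a data.frame with columns `region_id` (0-based,
#' contiguous integer index), `abbreviation` (unique short label), `name`
#' (free text) and `system` (neural-system grouping). All downstream
#' matrices are indexed in `RegionTable` row order.
#'
#' @param abbreviation character vector of unique, non-empty labels.
#' @param name character vector of full region names.
#' @param system character vector of neural-system labels.
#' @return A validated `RegionTable` data.frame.
#' @export
region_table <- function(abbreviation, name = abbreviation, system = "Other") {
  abbreviation <- as.character(abbreviation)
  n <- length(abbreviation)
  tab <- data.frame(
    region_id = seq_len(n) - 1L,
    abbreviation = abbreviation,
    name = rep_len(as.character(name), n),
    system = rep_len(as.character(system), n),
    stringsAsFactors = FALSE
  )
  validate_region_table(tab)
  tab
}

validate_region_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  req <- c("region_id", "abbreviation", "name", "system")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("region table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(tab$abbreviation)))
    stop("region abbreviations must be non-empty")
  dup <- tab$abbreviation[duplicated(tab$abbreviation)]
  if (length(dup) > 0)
    stop("duplicate region abbreviation(s): ", paste(unique(dup), collapse = ", "))
  if (!identical(as.integer(tab$region_id), seq_len(nrow(tab)) - 1L))
    stop("region_id must be the contiguous 0-based sequence 0..R-1")
  invisible(tab)
}

#' Default 59-region catalogue
#'
#' The regions of interest used for cerebral glucose-utilisation mapping,
#' grouped by neural system (thalamus, prefrontal cortex, mesolimbic system,
#' basal ganglia, hippocampus, septum/diagonal band, serotonergic nuclei,
#' amygdala, auditory system, and other cortical/subcortical areas).
#' Abbreviations follow the common autoradiography literature; entries the
#' source atlas does not name in running text are numbered placeholders.
#' The table is user-replaceable: every pipeline entry point accepts any
#' valid `RegionTable`.
#'
#' @return A 59-row `RegionTable`.
#' @export
default_regions <- function() {
  spec <- list(
    Thalamus = c(MD = "mediodorsal thalamus", dRT = "dorsal reticular thalamus",
                 vRT = "ventral reticular thalamus", Re = "nucleus reuniens",
                 CM = "centromedial thalamus", CL = "centrolateral thalamus",
                 AM = "anteromedial thalamus", AV = "anteroventral thalamus",
                 VL = "ventrolateral thalamus", LD = "laterodorsal thalamus"),
    PFC = c(aPrL = "anterior prelimbic cortex", pPrL = "posterior prelimbic cortex",
            Cg1 = "cingulate cortex area 1", Cg2 = "cingulate cortex area 2",
            IL = "infralimbic cortex", VO = "ventral orbital cortex",
            LO = "lateral orbital cortex", MO = "medial orbital cortex",
            FRA = "frontal association cortex"),
    Mesolimbic = c(NAcC = "nucleus accumbens core", NAcSh = "nucleus accumbens shell",
                   VTA = "ventral tegmental area", OT = "olfactory tubercle"),
    `Basal ganglia` = c(dlCPu = "dorsolateral caudate putamen",
                        vmCPu = "ventromedial caudate putamen",
                        GP = "globus pallidus", SNC = "substantia nigra pars compacta",
                        SNR = "substantia nigra pars reticulata",
                        STN = "subthalamic nucleus"),
    Hippocampus = c(DHCA1 = "dorsal hippocampus CA1", DHCA2 = "dorsal hippocampus CA2",
                    DHCA3 = "dorsal hippocampus CA3", VHCA1 = "ventral hippocampus CA1",
                    VHCA2 = "ventral hippocampus CA2", VHCA3 = "ventral hippocampus CA3",
                    DG = "dentate gyrus", Sub = "subiculum"),
    `Septum/DB` = c(LS = "lateral septum", MS = "medial septum",
                    VDB = "vertical limb diagonal band", HDB = "horizontal limb diagonal band"),
    `5-HT` = c(DR = "dorsal raphe", MR = "median raphe"),
    Amygdala = c(BLA = "basolateral amygdala", CeA = "central amygdala",
                 MeA = "medial amygdala"),
    Auditory = c(AC = "auditory cortex", MG = "medial geniculate nucleus",
                 IC = "inferior colliculus")
  )
  abbr <- unlist(lapply(spec, names), use.names = FALSE)
  name <- unlist(spec, use.names = FALSE)
  system <- rep(names(spec), vapply(spec, length, integer(1)))
  n_extra <- 59L - length(abbr)
  if (n_extra > 0) {
    idx <- seq_len(n_extra)
    abbr <- c(abbr, sprintf("R%02d", length(abbr) + idx))
    name <- c(name, sprintf("placeholder region %d", length(name) + idx))
    system <- c(system, rep("Other", n_extra))
  }
  region_table(abbr, name, system)
}

#' Read a region catalogue from CSV
#'
#' Expects columns `abbreviation`, `name`, `system`; `region_id` is assigned
#' from row order.
#'
#' @param path CSV file path.
#' @return A `RegionTable`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("abbreviation", "name", "system")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("region CSV missing column(s): ", paste(miss, collapse = ", "))
  region_table(raw$abbreviation, raw$name, raw$system)
}

#' @rdname read_regions
#' @param regions a `RegionTable`.
#' @export
write_regions <- function(regions, path) {
  validate_region_table(regions)
  utils::write.csv(regions[, c("abbreviation", "name", "system")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
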