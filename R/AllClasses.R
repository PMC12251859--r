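#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GeneticMap: an ordered marker scaffold
#'
#' One genetic linkage map: for each chromosome an ordered list of markers
#' with centimorgan (cM) positions. Positions must be non-decreasing and
#' marker names unique within a chromosome. A map may represent one study's
#' linkage map or the high-density reference scaffold onto which QTLs are
#' projected (for maize, an IBM2-Neighbors-like map).
#'
#' @slot mapId Single string identifying the map.
#' @slot markers A data.frame with columns `chromosome` (integer),
#'   `marker` (character) and `position` (numeric cM), sorted by
#'   chromosome then position. (A plain data.frame, not a DataFrame:
#'   marker tables are consulted once per QTL during projection and the
#'   lighter container keeps that path fast.)
#' @export
setClass("GeneticMap",
  representation(mapId = "character", markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (length(object@mapId) != 1L || is.na(object@mapId) || object@mapId == "")
    msg <- c(msg, "mapId must be a single non-empty string")
  m <- object@markers
  need <- c("chromosome", "marker", "position")
  if (!all(need %in% colnames(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) > 0) {
    if (any(is.na(m$position)) || any(m$position < 0))
      msg <- c(msg, "marker positions must be non-negative cM")
    for (chr in unique(m$chromosome)) {
      p <- m$position[m$chromosome == chr]
      nm <- m$marker[m$chromosome == chr]
      if (is.unsorted(p))
        msg <- c(msg, sprintf("positions on chromosome %s are not sorted", chr))
      if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate marker names on chromosome %s", chr))
    }
  }
  if (length(msg) == 0) TRUE else msg
})

#' QTLCompendium: a multi-study QTL table
#'
#' A curated collection of literature QTLs, one row per reported QTL. Each
#' record carries the trait (plant height PH or ear height EH), chromosome
#' (1-10), peak position and 95% confidence interval (CI) on the source
#' study's own genetic map, LOD score, phenotypic variance explained (PVE,
#' percent), the mapping-population design and size, and optional flanking
#' marker names. CI bounds, LOD, PVE and flanking markers may be absent
#' (`NA`); absent CIs can be imputed with [completeCIs()].
#'
#' @slot records A [S4Vectors::DataFrame] with the canonical columns (see
#'   [readQTLTable()] for the file schema).
#' @export
setClass("QTLCompendium", representation(records = "DataFrame"))

.QTL_COLS <- c("qtl_id", "study_ref", "trait", "chromosome", "source_map_id",
               "position", "ci_lo", "ci_hi", "lod", "pve_percent",
               "population_type", "population_size", "flank_left",
               "flank_right")

setValidity("QTLCompendium", function(object) {
  r <- object@records
  msg <- character()
  if (!all(.QTL_COLS %in% colnames(r)))
    return(paste("records must have columns:", paste(.QTL_COLS, collapse = ", ")))
  if (nrow(r) == 0) return(TRUE)
  if (anyDuplicated(r$qtl_id))
    msg <- c(msg, "qtl_id values must be unique")
  if (!all(r$trait %in% .TRAITS))
    msg <- c(msg, "trait must be one of PH, EH")
  if (!all(r$chromosome %in% 1:10))
    msg <- c(msg, "chromosome must be an integer in 1-10")
  if (any(is.na(r$position)) || any(r$position < 0))
    msg <- c(msg, "position must be non-negative cM")
  if (!all(r$population_type %in% .POP_TYPES))
    msg <- c(msg, paste("population_type must be one of:",
                        paste(.POP_TYPES, collapse = ", ")))
  if (any(!is.na(r$population_size) & r$population_size <= 0))
    msg <- c(msg, "population_size must be positive")
  if (any(!is.na(r$pve_percent) & (r$pve_percent <= 0 | r$pve_percent > 100)))
    msg <- c(msg, "pve_percent must lie in (0, 100]")
  if (any(!is.na(r$lod) & r$lod < 0))
    msg <- c(msg, "lod must be non-negative")
  both <- !is.na(r$ci_lo) & !is.na(r$ci_hi)
  if (any(both & (r$ci_lo > r$position | r$position > r$ci_hi)))
    msg <- c(msg, "when both CI bounds are present, ci_lo <= position <= ci_hi")
  if (length(msg) == 0) TRUE else msg
})

#' MQTLSet: meta-QTLs with their model-selection evidence
#'
#' The result of a meta-analysis: one row per consensus locus (MQTL) with
#' its maximum-likelihood position, 95% CI, member QTLs and trait class on
#' the reference map, plus the per-chromosome information-criteria tables
#' that justified the chosen number of clusters.
#'
#' @slot mqtls A [S4Vectors::DataFrame], one row per MQTL: `mqtl_id`,
#'   `chromosome`, `position`, `ci_lo`, `ci_hi`, `se`, `n_qtls`,
#'   `member_qtl_ids` (comma-separated), `trait_class`, `flank_left`,
#'   `flank_right`, `phys_lo`, `phys_hi` (bp; NA until anchored).
#' @slot criteria Named list (one element per chromosome) with elements
#'   `table` (data.frame of k, AIC, AICc, AIC3, BIC, AWE, votes) and
#'   `chosen_k`.
#' @export
setClass("MQTLSet",
  representation(mqtls = "DataFrame", criteria = "list"))

setValidity("MQTLSet", function(object) {
  m <- object@mqtls
  msg <- character()
  need <- c("mqtl_id", "chromosome", "position", "ci_lo", "ci_hi", "se",
            "n_qtls", "member_qtl_ids", "trait_class")
  if (!all(need %in% colnames(m)))
    return(paste("mqtls must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) > 0) {
    if (any(m$ci_lo > m$position | m$position > m$ci_hi))
      msg <- c(msg, "each MQTL must satisfy ci_lo <= position <= ci_hi")
    if (any(m$n_qtls < 1))
      msg <- c(msg, "each MQTL must have at least one member QTL")
  }
  if (length(msg) == 0) TRUE else msg
})

#' ScenarioConfig: synthetic-compendium study conditions
#'
#' Parameters of one synthetic meta-QTL scenario: the chromosome layout and
#' true locus positions, the set of contributing mapping studies (design,
#' size, marker density), per-locus QTL counts, the PVE range from which
#' effect sizes are drawn, and map-distortion / noise settings. Every
#' generated object is a pure function of the config (the seed is part of
#' it); see [scenarioConfig()] for defaults and units.
#'
#' @slot seed Integer RNG seed (mandatory).
#' @slot chromosomes Number of chromosomes simulated.
#' @slot chromosomeLength Chromosome length, cM.
#' @slot trueLoci List (per chromosome) of true locus positions, cM.
#' @slot studies data.frame: `study_ref`, `population_type`,
#'   `population_size`, `marker_spacing` (cM).
#' @slot qtlsPerLocus QTLs reported per true locus when `detectProb` is NA.
#' @slot pveRange Range (percent) of per-QTL phenotypic variance explained.
#' @slot detectProb Per-study detection probability, or NA to sample exactly
#'   `qtlsPerLocus` studies per locus.
#' @slot ciMissingFraction Fraction of records whose CI is omitted.
#' @slot refMarkerSpacing Mean marker spacing of the reference map, cM.
#' @slot keepFraction Fraction of reference markers kept in each source map.
#' @slot lengthJitterSD Log-normal SD of per-interval map length distortion.
#' @slot noiseScale Multiplier on the positional noise SD (1 = calibrated).
#' @slot genesPerChromosome Genes simulated per chromosome.
#' @export
setClass("ScenarioConfig",
  representation(seed = "integer", chromosomes = "integer",
                 chromosomeLength = "numeric", trueLoci = "list",
                 studies = "data.frame", qtlsPerLocus = "integer",
                 pveRange = "numeric", detectProb = "numeric",
                 ciMissingFraction = "numeric", refMarkerSpacing = "numeric",
                 keepFraction = "numeric", lengthJitterSD = "numeric",
                 noiseScale = "numeric", genesPerChromosome = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory (no hidden entropy)")
  if (object@chromosomes < 1)
    msg <- c(msg, "need at least one chromosome")
  if (object@chromosomeLength <= 0)
    msg <- c(msg, "chromosomeLength must be positive")
  if (length(object@trueLoci) != object@chromosomes)
    msg <- c(msg, "trueLoci must have one element per chromosome")
  loci <- unlist(object@trueLoci)
  if (any(loci < 0 | loci > object@chromosomeLength))
    msg <- c(msg, "true loci must lie within the chromosome length")
  if (length(object@pveRange) != 2L || any(object@pveRange <= 0) ||
      object@pveRange[1] > object@pveRange[2])
    msg <- c(msg, "pveRange must be an increasing positive pair")
  if (!all(object@studies$population_type %in% .POP_TYPES))
    msg <- c(msg, "unknown population_type in studies")
  if (!is.na(object@detectProb) &&
      (object@detectProb < 0 || object@detectProb > 1))
    msg <- c(msg, "detectProb must be in [0, 1] or NA")
  if (object@ciMissingFraction < 0 || object@ciMissingFraction > 1)
    msg <- c(msg, "ciMissingFraction must be in [0, 1]")
  if (object@keepFraction <= 0 || object@keepFraction > 1)
    msg <- c(msg, "keepFraction must be in (0, 1]")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg) == 0) TRUE else msg
})
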