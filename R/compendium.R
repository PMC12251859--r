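#' Read a multi-study QTL table
#'
#' Parses a CSV or TSV compendium of literature QTLs into a
#' [QTLCompendium]. The file must have a header with columns `qtl_id`,
#' `study_ref`, `trait`, `chromosome`, `source_map_id`, `position_cM`,
#' `ci_lo_cM`, `ci_hi_cM`, `lod`, `pve_percent`, `population_type`,
#' `population_size`, `flank_left`, `flank_right`. Empty strings denote
#' absent optional values and are kept as `NA`, never coerced to zero.
#' Parse errors name the offending row (1 = first data row) and column.
#'
#' @param path Path to the table; tab-delimited if the extension is
#'   `.tsv`/`.tab`, otherwise comma-delimited.
#' @return A [QTLCompendium]; row numbers are retained in a `row` column
#'   for error reporting downstream.
#' @seealso [qualityFilter()], [completeCIs()]
#' @export
readQTLTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, strip.white = TRUE,
                           blank.lines.skip = TRUE)
  fileCols <- c("qtl_id", "study_ref", "trait", "chromosome",
                "source_map_id", "position_cM", "ci_lo_cM", "ci_hi_cM",
                "lod", "pve_percent", "population_type", "population_size",
                "flank_left", "flank_right")
  missing <- setdiff(fileCols, colnames(raw))
  if (length(missing) > 0)
    stop("header is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  rows <- seq_len(n)
  if (n == 0) {
    r <- DataFrame(qtl_id = character(), study_ref = character(),
                   trait = character(), chromosome = integer(),
                   source_map_id = character(), position = numeric(),
                   ci_lo = numeric(), ci_hi = numeric(), lod = numeric(),
                   pve_percent = numeric(), population_type = character(),
                   population_size = integer(), flank_left = character(),
                   flank_right = character(), row = integer())
    return(new("QTLCompendium", records = r))
  }

  chrom <- .parseNum(raw$chromosome, "chromosome", rows)
  bad <- which(is.na(chrom) | chrom != as.integer(chrom) |
               chrom < 1 | chrom > 10)
  if (length(bad) > 0)
    stop("row ", bad[1], ": chromosome '", raw$chromosome[bad[1]],
         "' is not an integer in 1-10", call. = FALSE)

  dup <- which(duplicated(raw$qtl_id))
  if (length(dup) > 0)
    stop("row ", dup[1], ": duplicate qtl_id '", raw$qtl_id[dup[1]], "'",
         call. = FALSE)
  if (any(.isAbsent(raw$qtl_id)))
    stop("row ", which(.isAbsent(raw$qtl_id))[1], ": qtl_id is empty",
         call. = FALSE)

  badTrait <- which(!raw$trait %in% .TRAITS)
  if (length(badTrait) > 0)
    stop("row ", badTrait[1], ": trait '", raw$trait[badTrait[1]],
         "' is not one of ", paste(.TRAITS, collapse = ", "), call. = FALSE)
  badPop <- which(!raw$population_type %in% .POP_TYPES)
  if (length(badPop) > 0)
    stop("row ", badPop[1], ": population_type '",
         raw$population_type[badPop[1]], "' is not one of ",
         paste(.POP_TYPES, collapse = ", "), call. = FALSE)

  pos <- .parseNum(raw$position_cM, "position_cM", rows)
  if (any(is.na(pos)))
    stop("row ", which(is.na(pos))[1], ": position_cM is absent",
         call. = FALSE)
  ciLo <- .parseNum(raw$ci_lo_cM, "ci_lo_cM", rows)
  ciHi <- .parseNum(raw$ci_hi_cM, "ci_hi_cM", rows)
  one <- which(xor(is.na(ciLo), is.na(ciHi)))
  if (length(one) > 0)
    stop("row ", one[1], ": only one CI bound present (ci_lo_cM/ci_hi_cM)",
         call. = FALSE)
  both <- !is.na(ciLo) & !is.na(ciHi)
  badCI <- which(both & ciLo > ciHi)
  if (length(badCI) > 0)
    stop("row ", badCI[1], ": ci_lo_cM > ci_hi_cM", call. = FALSE)
  badOrd <- which(both & (ciLo > pos | pos > ciHi))
  if (length(badOrd) > 0)
    stop("row ", badOrd[1], ": position_cM outside its own CI", call. = FALSE)

  lod <- .parseNum(raw$lod, "lod", rows)
  pve <- .parseNum(raw$pve_percent, "pve_percent", rows)
  psizeNum <- .parseNum(raw$population_size, "population_size", rows)
  badN <- which(!is.na(psizeNum) & psizeNum <= 0)
  if (length(badN) > 0)
    stop("row ", badN[1], ": population_size must be positive", call. = FALSE)

  absentChr <- function(x) ifelse(.isAbsent(x), NA_character_, x)
  r <- DataFrame(qtl_id = raw$qtl_id, study_ref = raw$study_ref,
                 trait = raw$trait, chromosome = as.integer(chrom),
                 source_map_id = raw$source_map_id, position = pos,
                 ci_lo = ciLo, ci_hi = ciHi, lod = lod, pve_percent = pve,
                 population_type = raw$population_type,
                 population_size = as.integer(psizeNum),
                 flank_left = absentChr(raw$flank_left),
                 flank_right = absentChr(raw$flank_right), row = rows)
  new("QTLCompendium", records = r)
}

#' Quality-filter a QTL compendium
#'
#' Removes QTLs with PVE strictly below 1% or LOD strictly below 1.5, the
#' usual meta-QTL quality check. Absent PVE or LOD values never trigger
#' removal: records missing both are kept but flagged, since the condition
#' cannot be tested for them.
#'
#' @param x A [QTLCompendium].
#' @param pveMin,lodMin Strict removal thresholds (defaults 1% PVE and
#'   1.5 LOD).
#' @return A list with [QTLCompendium] elements `kept` and `removed`
#'   (disjoint, input order preserved, together the input) and `flagged`,
#'   the qtl_ids kept despite missing both PVE and LOD.
#' @examples
#' df <- data.frame(qtl_id = c("a", "b"), study_ref = "s", trait = "PH",
#'   chromosome = 1L, source_map_id = "m", position = c(10, 20),
#'   ci_lo = NA_real_, ci_hi = NA_real_, lod = c(3, 1.2),
#'   pve_percent = c(8, 9), population_type = "F2", population_size = 200L,
#'   flank_left = NA_character_, flank_right = NA_character_)
#' qualityFilter(QTLCompendium(df))$removed
#' @export
qualityFilter <- function(x, pveMin = 1, lodMin = 1.5) {
  stopifnot(is(x, "QTLCompendium"))
  r <- x@records
  drop <- (!is.na(r$pve_percent) & r$pve_percent < pveMin) |
          (!is.na(r$lod) & r$lod < lodMin)
  flagged <- r$qtl_id[is.na(r$pve_percent) & is.na(r$lod) & !drop]
  list(kept = new("QTLCompendium", records = r[!drop, , drop = FALSE]),
       removed = new("QTLCompendium", records = r[drop, , drop = FALSE]),
       flagged = flagged)
}

#' Darvasi-Soller 95% CI width for a QTL
#'
#' Expected 95% confidence-interval width (cM) of a QTL position as a
#' function of mapping-population size and effect size:
#' `530 / (N * R2)` for F2-like designs (F2, BC and the selfed F2-derived
#' families F2:3, F3, F4) and `163 / (N * R2)` for homozygous immortal
#' designs (RIL, DH), where `R2 = pve_percent / 100` is the proportion of
#' phenotypic variance explained. Note the percent-to-proportion
#' conversion: a 10%-PVE QTL in an N = 200 F2 gets a 26.5 cM interval.
#'
#' @param populationType One of `"F2"`, `"BC"`, `"F2:3"`, `"F3"`, `"F4"`
#'   (numerator 530) or `"RIL"`, `"DH"` (numerator 163).
#' @param populationSize Mapping-population size N (> 0).
#' @param pvePercent Phenotypic variance explained, percent (> 0).
#' @return CI width in cM (vectorised over all three arguments).
#' @examples
#' imputeCIWidth("F2", 187, 10)   # 530 / (187 * 0.10)
#' imputeCIWidth("RIL", 163, 100) # 1 cM
#' @export
imputeCIWidth <- function(populationType, populationSize, pvePercent) {
  n <- max(length(populationType), length(populationSize), length(pvePercent))
  populationType <- rep_len(populationType, n)
  populationSize <- rep_len(populationSize, n)
  pvePercent <- rep_len(pvePercent, n)
  if (!all(populationType %in% .POP_TYPES))
    stop("unknown population type: ",
         paste(setdiff(populationType, .POP_TYPES), collapse = ", "),
         call. = FALSE)
  if (any(is.na(populationSize)) || any(populationSize <= 0))
    stop("population size must be positive", call. = FALSE)
  if (any(is.na(pvePercent)) || any(pvePercent <= 0))
    stop("PVE must be positive", call. = FALSE)
  numerator <- ifelse(populationType %in% c("RIL", "DH"), 163, 530)
  numerator / (populationSize * pvePercent / 100)
}

#' Complete missing QTL confidence intervals
#'
#' Records that already carry both CI bounds are returned untouched.
#' Records lacking them receive an interval of Darvasi-Soller width
#' ([imputeCIWidth()]) centered on the peak, with the lower bound floored
#' at 0 cM (the upper bound is not shifted to compensate). The result
#' always satisfies `ci_lo <= position <= ci_hi` and the operation is
#' idempotent.
#'
#' @param x A [QTLCompendium]; every record lacking a CI must carry
#'   `population_type`, `population_size` and `pve_percent`.
#' @return A [QTLCompendium] with all CIs present.
#' @export
completeCIs <- function(x) {
  stopifnot(is(x, "QTLCompendium"))
  r <- x@records
  need <- is.na(r$ci_lo) | is.na(r$ci_hi)
  if (!any(need)) return(x)
  cannot <- need & (is.na(r$population_size) | is.na(r$pve_percent))
  if (any(cannot))
    stop("cannot impute CI (missing population_size or pve_percent) for: ",
         paste(r$qtl_id[cannot], collapse = ", "), call. = FALSE)
  w <- imputeCIWidth(r$population_type[need], r$population_size[need],
                     r$pve_percent[need])
  r$ci_lo[need] <- pmax(0, r$position[need] - w / 2)
  r$ci_hi[need] <- r$position[need] + w / 2
  new("QTLCompendium", records = r)
}
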