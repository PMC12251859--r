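#' Read genetic maps from a TSV file
#'
#' One file may hold many maps. Columns: `map_id`, `chromosome`, `marker`,
#' `position_cM` (tab-separated, header required).
#'
#' @param path Path to the map file.
#' @return A named list of [GeneticMap] objects, one per `map_id`.
#' @export
readGeneticMaps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  need <- c("map_id", "chromosome", "marker", "position_cM")
  missing <- setdiff(need, colnames(tab))
  if (length(missing) > 0)
    stop("map file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pos <- .parseNum(tab$position_cM, "position_cM", seq_len(nrow(tab)))
  chr <- as.integer(.parseNum(tab$chromosome, "chromosome",
                              seq_len(nrow(tab))))
  maps <- lapply(split(seq_len(nrow(tab)), tab$map_id), function(i)
    GeneticMap(tab$map_id[i[1]], chr[i], tab$marker[i], pos[i]))
  maps
}

#' Write genetic maps to a TSV file
#'
#' @param maps A [GeneticMap] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneticMaps <- function(maps, path) {
  if (is(maps, "GeneticMap")) maps <- list(maps)
  tabs <- lapply(maps, function(m) {
    t <- markerTable(m)
    data.frame(map_id = mapId(m), chromosome = t$chromosome,
               marker = t$marker, position_cM = t$position)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Markers shared by a source and a reference map
#'
#' Finds markers present on the same chromosome in both maps, ordered by
#' their source-map position.
#'
#' @param source,reference [GeneticMap] objects.
#' @param chromosome Chromosome number (must be present in both maps).
#' @return data.frame with columns `marker`, `source_cM`, `reference_cM`
#'   sorted by `source_cM` (possibly zero rows).
#' @export
commonMarkers <- function(source, reference, chromosome) {
  s <- markerTable(source)
  r <- markerTable(reference)
  s <- s[s$chromosome == chromosome, , drop = FALSE]
  r <- r[r$chromosome == chromosome, , drop = FALSE]
  if (nrow(s) == 0)
    stop("chromosome ", chromosome, " absent from source map '",
         mapId(source), "'", call. = FALSE)
  if (nrow(r) == 0)
    stop("chromosome ", chromosome, " absent from reference map '",
         mapId(reference), "'", call. = FALSE)
  shared <- intersect(s$marker, r$marker)
  s <- s[s$marker %in% shared, , drop = FALSE]
  out <- data.frame(marker = s$marker, source_cM = s$position,
                    reference_cM = r$position[match(s$marker, r$marker)])
  out[order(out$source_cM), , drop = FALSE]
}

#' Homothetic projection of one position between two anchor markers
#'
#' Affine (homothetic) rescaling of a source-map position onto the
#' reference map through a pair of markers shared by both maps:
#' `refLeft + (x - srcLeft) * (refRight - refLeft) / (srcRight - srcLeft)`.
#' Anchors are exact fixed points. If the reference positions of the
#' anchor pair are reversed relative to the source, the map simply
#' reverses orientation; callers re-sort projected interval bounds.
#'
#' @param x Source-map position, cM.
#' @param srcLeft,srcRight Anchor positions on the source map
#'   (`srcLeft < srcRight`).
#' @param refLeft,refRight Anchor positions on the reference map.
#' @return Projected position, cM.
#' @examples
#' projectPoint(12, 10, 20, 100, 140) # 108
#' @export
projectPoint <- function(x, srcLeft, srcRight, refLeft, refRight) {
  if (any(srcLeft >= srcRight))
    stop("degenerate source interval: srcLeft must be < srcRight",
         call. = FALSE)
  refLeft + (x - srcLeft) * (refRight - refLeft) / (srcRight - srcLeft)
}

## internal: project one point using the tightest bracketing common-marker
## pair; returns list(status, value, anchors)
.projectOnePoint <- function(x, cm) {
  n <- nrow(cm)
  if (n == 0 || x < cm$source_cM[1] || x > cm$source_cM[n])
    return(list(status = "no_common_flank", value = NA_real_,
                anchors = NA_character_))
  hit <- which(abs(cm$source_cM - x) < 1e-12)
  if (length(hit) > 0) {
    i <- hit[1]  # exact anchor: fixed point, no interval needed
    return(list(status = "projected", value = cm$reference_cM[i],
                anchors = paste0(cm$marker[i], "|", cm$marker[i])))
  }
  i <- findInterval(x, cm$source_cM)
  if (cm$source_cM[i] == cm$source_cM[i + 1])
    return(list(status = "degenerate_interval", value = NA_real_,
                anchors = paste0(cm$marker[i], "|", cm$marker[i + 1])))
  v <- projectPoint(x, cm$source_cM[i], cm$source_cM[i + 1],
                    cm$reference_cM[i], cm$reference_cM[i + 1])
  list(status = "projected", value = v,
       anchors = paste0(cm$marker[i], "|", cm$marker[i + 1]))
}

#' Project one QTL onto the reference map
#'
#' Projects the peak and both CI bounds independently, each through the
#' tightest pair of common markers bracketing that point on the source map
#' (the pairs may differ per point). Projected CI bounds are re-sorted so
#' lo <= hi, which makes locally reversed marker order on the reference
#' harmless. A point outside the span of common markers is not
#' extrapolated: the QTL fails with status `no_common_flank`.
#'
#' @param qtl One-row data.frame (or list) with `qtl_id`, `chromosome`,
#'   `position`, `ci_lo`, `ci_hi` (CI must be completed; see
#'   [completeCIs()]).
#' @param source,reference [GeneticMap] objects; `source` must contain the
#'   QTL's chromosome.
#' @return One-row data.frame: `qtl_id`, `status` (`projected`,
#'   `no_common_flank` or `degenerate_interval`), `new_position`,
#'   `new_ci_lo`, `new_ci_hi`, `anchors_used` (peak;lo;hi marker pairs).
#' @export
projectQTL <- function(qtl, source, reference) {
  .projectQTLWithCM(qtl, commonMarkers(source, reference, qtl$chromosome))
}

## internal: projectQTL against a precomputed common-marker table
.projectQTLWithCM <- function(qtl, cm) {
  if (is.na(qtl$ci_lo) || is.na(qtl$ci_hi))
    stop("QTL '", qtl$qtl_id, "' has no completed CI; run completeCIs()",
         call. = FALSE)
  pk <- .projectOnePoint(qtl$position, cm)
  lo <- .projectOnePoint(qtl$ci_lo, cm)
  hi <- .projectOnePoint(qtl$ci_hi, cm)
  status <- if (any(c(pk$status, lo$status, hi$status) == "no_common_flank"))
    "no_common_flank"
  else if (any(c(pk$status, lo$status, hi$status) == "degenerate_interval"))
    "degenerate_interval"
  else "projected"
  if (status == "projected") {
    b <- sort(c(lo$value, hi$value))
    # with per-point anchors and reversed reference segments the peak can
    # land marginally outside the re-sorted CI; keep it inside
    newPos <- min(max(pk$value, b[1]), b[2])
    data.frame(qtl_id = qtl$qtl_id, status = status, new_position = newPos,
               new_ci_lo = b[1], new_ci_hi = b[2],
               anchors_used = paste(pk$anchors, lo$anchors, hi$anchors,
                                    sep = ";"))
  } else {
    data.frame(qtl_id = qtl$qtl_id, status = status,
               new_position = NA_real_, new_ci_lo = NA_real_,
               new_ci_hi = NA_real_,
               anchors_used = paste(pk$anchors, lo$anchors, hi$anchors,
                                    sep = ";"))
  }
}

#' Project a whole compendium onto the reference map
#'
#' @param x A [QTLCompendium] with completed CIs.
#' @param sourceMaps Named list of [GeneticMap] objects; every record's
#'   `source_map_id` must resolve to an element.
#' @param reference The reference [GeneticMap].
#' @return List with `results` (data.frame of per-QTL [projectQTL()] rows,
#'   input order), `rate` (projected / input count) and `failures`
#'   (qtl_id/status rows for the unprojected QTLs).
#' @export
projectCompendium <- function(x, sourceMaps, reference) {
  stopifnot(is(x, "QTLCompendium"))
  r <- qtlRecords(x)
  unknown <- setdiff(unique(r$source_map_id), names(sourceMaps))
  if (length(unknown) > 0)
    stop("unresolvable source_map_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cmCache <- new.env(parent = emptyenv())  # one lookup per (map, chrom)
  res <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    key <- paste(r$source_map_id[i], r$chromosome[i])
    if (is.null(cmCache[[key]]))
      cmCache[[key]] <- commonMarkers(sourceMaps[[r$source_map_id[i]]],
                                      reference, r$chromosome[i])
    .projectQTLWithCM(r[i, ], cmCache[[key]])
  }))
  if (is.null(res))
    res <- data.frame(qtl_id = character(), status = character(),
                      new_position = numeric(), new_ci_lo = numeric(),
                      new_ci_hi = numeric(), anchors_used = character())
  rate <- if (nrow(res) == 0) NA_real_ else
    sum(res$status == "projected") / nrow(res)
  list(results = res, rate = rate,
       failures = res[res$status != "projected",
                      c("qtl_id", "status"), drop = FALSE])
}

#' Summarise a genetic map
#'
#' Total length is the sum over chromosomes of (last - first marker
#' position); the mean inter-marker interval divides by the number of
#' intervals, i.e. markers minus chromosomes. Chromosomes with fewer than
#' two markers carry no interval and are excluded with a warning.
#'
#' @param map A [GeneticMap].
#' @return List: `total_length` (cM), `marker_count`, `mean_interval`
#'   (cM), and `per_chromosome` (data.frame chromosome/length/markers).
#' @export
mapSummary <- function(map) {
  stopifnot(is(map, "GeneticMap"))
  m <- markerTable(map)
  if (nrow(m) == 0) stop("map is empty", call. = FALSE)
  chrs <- split(m$position, m$chromosome)
  few <- names(chrs)[vapply(chrs, length, 1L) < 2]
  if (length(few) > 0) {
    warning("excluding chromosome(s) with < 2 markers: ",
            paste(few, collapse = ", "), call. = FALSE)
    chrs <- chrs[!names(chrs) %in% few]
  }
  if (length(chrs) == 0)
    stop("no chromosome has at least 2 markers", call. = FALSE)
  lens <- vapply(chrs, function(p) max(p) - min(p), 1.0)
  counts <- vapply(chrs, length, 1L)
  list(total_length = sum(lens), marker_count = sum(counts),
       mean_interval = sum(lens) / (sum(counts) - length(chrs)),
       per_chromosome = data.frame(chromosome = as.integer(names(chrs)),
                                   length = unname(lens),
                                   markers = unname(counts)))
}
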