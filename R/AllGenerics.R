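#' @include AllClasses.R
NULL

#' Accessors for qtlMeta classes
#'
#' `mapId()` returns a map's identifier; `markerTable()` its marker table as
#' a data.frame. `qtlRecords()` returns the record table of a
#' [QTLCompendium]. `mqtlTable()` and `criteriaTables()` return the MQTL
#' rows and the per-chromosome information-criteria evidence of an
#' [MQTLSet].
#'
#' @param x A `GeneticMap`, `QTLCompendium` or `MQTLSet`.
#' @return A data.frame (accessors never expose slots directly).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))
#' @rdname accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))
#' @rdname accessors
#' @export
setGeneric("qtlRecords", function(x) standardGeneric("qtlRecords"))
#' @rdname accessors
#' @export
setGeneric("mqtlTable", function(x) standardGeneric("mqtlTable"))
#' @rdname accessors
#' @export
setGeneric("criteriaTables", function(x) standardGeneric("criteriaTables"))

#' @rdname accessors
setMethod("mapId", "GeneticMap", function(x) x@mapId)

#' @rdname accessors
setMethod("markerTable", "GeneticMap", function(x) x@markers)

#' @rdname accessors
setMethod("qtlRecords", "QTLCompendium",
          function(x) as.data.frame(x@records))

#' @rdname accessors
setMethod("mqtlTable", "MQTLSet", function(x) as.data.frame(x@mqtls))

#' @rdname accessors
setMethod("criteriaTables", "MQTLSet", function(x) x@criteria)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat("GeneticMap '", object@mapId, "': ", nrow(m), " markers on ",
      length(unique(m$chromosome)), " chromosome(s)\n", sep = "")
  if (nrow(m) > 0) {
    s <- mapSummary(object)
    cat("  total length ", sprintf("%.2f", s$total_length),
        " cM, mean marker interval ", sprintf("%.2f", s$mean_interval),
        " cM\n", sep = "")
  }
})

setMethod("show", "QTLCompendium", function(object) {
  r <- object@records
  cat("QTLCompendium: ", nrow(r), " QTL record(s)\n", sep = "")
  if (nrow(r) > 0) {
    cat("  traits: ", paste(sprintf("%s=%d", names(table(r$trait)),
                                    table(r$trait)), collapse = ", "),
        "; chromosomes: ", paste(sort(unique(r$chromosome)), collapse = ","),
        "\n  studies: ", length(unique(r$study_ref)),
        "; records lacking a CI: ", sum(is.na(r$ci_lo) | is.na(r$ci_hi)),
        "\n", sep = "")
  }
})

setMethod("show", "MQTLSet", function(object) {
  m <- object@mqtls
  cat("MQTLSet: ", nrow(m), " MQTL(s) on ",
      length(unique(m$chromosome)), " chromosome(s)\n", sep = "")
  if (nrow(m) > 0) {
    w <- m$ci_hi - m$ci_lo
    cat("  CI width (cM): min ", sprintf("%.2f", min(w)), ", mean ",
        sprintf("%.2f", mean(w)), ", max ", sprintf("%.2f", max(w)),
        "; member QTLs: ", sum(m$n_qtls), "\n", sep = "")
  }
})

#' Construct a GeneticMap
#'
#' Rows are sorted by chromosome and position; ties keep input order (a
#' stable sort), so co-located markers keep their file order.
#'
#' @param mapId Single string identifying the map.
#' @param chromosome Integer vector of chromosome numbers.
#' @param marker Character vector of marker names.
#' @param position Numeric vector of cM positions.
#' @return A [GeneticMap] object.
#' @examples
#' GeneticMap("toy", c(1, 1, 1), c("a", "b", "c"), c(0, 10, 25))
#' @export
GeneticMap <- function(mapId, chromosome, marker, position) {
  o <- order(chromosome, position)
  new("GeneticMap", mapId = as.character(mapId),
      markers = data.frame(chromosome = as.integer(chromosome)[o],
                           marker = as.character(marker)[o],
                           position = as.numeric(position)[o]))
}

#' Construct a QTLCompendium from a data.frame
#'
#' @param records data.frame (or DataFrame) with the canonical QTL columns;
#'   see [readQTLTable()] for the schema. Extra columns are preserved.
#' @return A [QTLCompendium].
#' @export
QTLCompendium <- function(records) {
  r <- DataFrame(records)
  r$chromosome <- as.integer(r$chromosome)
  r$population_size <- as.integer(r$population_size)
  for (col in c("position", "ci_lo", "ci_hi", "lod", "pve_percent"))
    r[[col]] <- as.numeric(r[[col]])
  new("QTLCompendium", records = r)
}
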