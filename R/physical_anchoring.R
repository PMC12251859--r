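#' Read a marker physical-anchor table
#'
#' CSV with columns `marker`, `chromosome`, `genetic_pos` (cM) and
#' `physical_pos` (bp, 1-based). Anchors whose physical position runs
#' backwards while the genetic position advances are flagged with a
#' warning (they usually indicate an assembly/map conflict) but kept.
#'
#' @param path Path to the CSV file.
#' @return data.frame sorted by chromosome and genetic position.
#' @export
readMarkerAnchors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- utils::read.csv(path, strip.white = TRUE)
  need <- c("marker", "chromosome", "genetic_pos", "physical_pos")
  missing <- setdiff(need, colnames(a))
  if (length(missing) > 0)
    stop("anchor file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  a <- a[order(a$chromosome, a$genetic_pos), , drop = FALSE]
  for (chr in unique(a$chromosome)) {
    p <- a$physical_pos[a$chromosome == chr]
    if (is.unsorted(p))
      warning("non-monotone physical positions on chromosome ", chr,
              call. = FALSE)
  }
  a
}

#' Convert a genetic interval to physical coordinates
#'
#' Each cM endpoint is piecewise-linearly interpolated between the
#' bracketing marker anchors of its chromosome; endpoints outside the
#' anchored span are clamped to the nearest terminal anchor's physical
#' position (no extrapolation). Interpolating across all anchors rather
#' than looking up only the two CI flanking markers means the conversion
#' degrades gracefully when a flanking marker has no known physical
#' position. When consecutive anchors share a cM position the first one's
#' physical position is used.
#'
#' @param interval Numeric pair of cM positions (any order).
#' @param chromosome Chromosome number.
#' @param anchors Anchor data.frame from [readMarkerAnchors()] (needs at
#'   least two anchors on the chromosome).
#' @return Numeric pair of bp positions, sorted ascending.
#' @examples
#' a <- data.frame(marker = c("a", "b", "c"), chromosome = 1,
#'                 genetic_pos = c(0, 50, 100),
#'                 physical_pos = c(1e6, 3e6, 9e6))
#' geneticToPhysical(c(25, 75), 1, a) # 2 Mb, 6 Mb
#' @export
geneticToPhysical <- function(interval, chromosome, anchors) {
  a <- anchors[anchors$chromosome == chromosome, , drop = FALSE]
  if (nrow(a) < 2)
    stop("need at least 2 anchors on chromosome ", chromosome, call. = FALSE)
  a <- a[order(a$genetic_pos), , drop = FALSE]
  a <- a[!duplicated(a$genetic_pos), , drop = FALSE]  # degenerate-cM guard
  if (nrow(a) < 2)
    stop("anchors on chromosome ", chromosome,
         " collapse to a single genetic position", call. = FALSE)
  bp <- stats::approx(a$genetic_pos, a$physical_pos, xout = interval,
                      rule = 2, ties = "ordered")$y
  sort(bp)
}

#' Read gene models from a GFF3 annotation
#'
#' Imports `gene`-type features (or all features if none are typed
#' `gene`) and extracts a display annotation from the `description`,
#' `Note` or `Name` attribute, in that order of preference.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `annotation`.
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% colnames(mc)) {
    v <- mc[[col]]
    if (is(v, "List")) v <- vapply(v, function(e)
      if (length(e) == 0) NA_character_ else as.character(e[1]), "")
    as.character(v)
  } else rep(NA_character_, length(gr))
  id <- pick("ID")
  if (all(is.na(id))) id <- pick("Name")
  ann <- pick("description")
  ann <- ifelse(is.na(ann), pick("Note"), ann)
  ann <- ifelse(is.na(ann), pick("Name"), ann)
  S4Vectors::mcols(gr) <- NULL
  gr$gene_id <- id
  gr$annotation <- ifelse(is.na(ann), "", ann)
  gr
}

#' Genes overlapping a physical interval
#'
#' Closed-interval, any-overlap semantics (1-based inclusive GFF3
#' coordinates): a gene is returned when `start <= interval hi` and
#' `end >= interval lo`, so a gene exactly abutting an interval edge is
#' included.
#'
#' @param interval Numeric pair of bp positions (sorted or not).
#' @param chromosome Chromosome (matched against the GRanges seqnames).
#' @param genes A [GenomicRanges::GRanges] of gene models (see
#'   [readGeneAnnotation()]).
#' @return The overlapping subset, sorted by start position.
#' @export
genesInInterval <- function(interval, chromosome, genes) {
  if (length(genes) == 0) return(genes)
  interval <- sort(as.numeric(interval))
  q <- GenomicRanges::GRanges(as.character(chromosome),
                              IRanges::IRanges(interval[1], interval[2]))
  hit <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                 as.character(chromosome)]
  hit <- IRanges::subsetByOverlaps(hit, q, ignore.strand = TRUE)
  hit[order(GenomicRanges::start(hit))]
}

#' Default gene-category keyword map
#'
#' The packaged dictionary mapping annotation keywords to the functional
#' categories tallied in plant-architecture candidate-gene mining:
#' hormone, cell wall, sugar, photosynthesis, cytoskeleton.
#'
#' @return data.frame with columns `keyword`, `category`.
#' @export
defaultKeywordMap <- function() {
  utils::read.delim(system.file("extdata", "gene_category_keywords.tsv",
                                package = "qtlMeta"),
                    colClasses = "character")
}

#' Classify candidate genes by annotation keywords
#'
#' Case-insensitive substring matching of each gene's annotation text
#' against a keyword-to-category map. A gene may carry several category
#' tags; a gene matching nothing (including an empty annotation) is
#' tagged `other`. Percentages are reported against the total number of
#' genes with 2-decimal half-up rounding, so multi-tagged genes can make
#' the category percentages sum past 100.
#'
#' @param genes A GRanges (with an `annotation` metadata column) or a
#'   data.frame with columns `gene_id` and `annotation`.
#' @param keywordMap data.frame `keyword`/`category`
#'   (default [defaultKeywordMap()]).
#' @return List: `tags` (data.frame gene_id / categories, comma-joined),
#'   `counts` (named integer, genes per category), `percent` (named
#'   numeric).
#' @export
classifyGenes <- function(genes, keywordMap = defaultKeywordMap()) {
  if (is(genes, "GRanges"))
    genes <- data.frame(gene_id = genes$gene_id,
                        annotation = genes$annotation)
  n <- nrow(genes)
  cats <- unique(keywordMap$category)
  ann <- tolower(ifelse(is.na(genes$annotation), "", genes$annotation))
  tagList <- lapply(ann, function(a) {
    hit <- vapply(seq_len(nrow(keywordMap)), function(i)
      grepl(tolower(keywordMap$keyword[i]), a, fixed = TRUE), TRUE)
    u <- unique(keywordMap$category[hit])
    if (length(u) == 0) "other" else u
  })
  counts <- vapply(c(cats, "other"), function(cc)
    sum(vapply(tagList, function(t) cc %in% t, TRUE)), 1L)
  pct <- if (n == 0) counts * NA_real_ else roundHalfUp(100 * counts / n)
  list(tags = data.frame(gene_id = genes$gene_id,
                         categories = vapply(tagList, paste, "",
                                             collapse = ",")),
       counts = counts, percent = pct)
}

#' Fill MQTL physical intervals and extract candidate genes
#'
#' Converts every MQTL's genetic CI to a physical interval through
#' [geneticToPhysical()] and pulls the overlapping genes from the
#' annotation.
#'
#' @param mqtlSet An [MQTLSet].
#' @param anchors Anchor table ([readMarkerAnchors()]).
#' @param genes GRanges of gene models ([readGeneAnnotation()]), or NULL
#'   to skip gene extraction.
#' @return List: `mqtls` (the [MQTLSet] with `phys_lo`/`phys_hi` filled,
#'   bp) and `genes` (data.frame mqtl_id / gene_id / start / end /
#'   annotation).
#' @export
anchorMQTLs <- function(mqtlSet, anchors, genes = NULL) {
  stopifnot(is(mqtlSet, "MQTLSet"))
  m <- mqtlSet@mqtls
  geneRows <- list()
  for (i in seq_len(nrow(m))) {
    bp <- geneticToPhysical(c(m$ci_lo[i], m$ci_hi[i]), m$chromosome[i],
                            anchors)
    m$phys_lo[i] <- bp[1]; m$phys_hi[i] <- bp[2]
    if (!is.null(genes)) {
      g <- genesInInterval(bp, m$chromosome[i], genes)
      if (length(g) > 0)
        geneRows[[m$mqtl_id[i]]] <- data.frame(
          mqtl_id = m$mqtl_id[i], gene_id = g$gene_id,
          start = GenomicRanges::start(g), end = GenomicRanges::end(g),
          annotation = g$annotation)
    }
  }
  out <- new("MQTLSet", mqtls = m, criteria = mqtlSet@criteria)
  geneTab <- if (length(geneRows) > 0) do.call(rbind, c(geneRows,
                                                        make.row.names = FALSE))
             else data.frame(mqtl_id = character(), gene_id = character(),
                             start = numeric(), end = numeric(),
                             annotation = character())
  list(mqtls = out, genes = geneTab)
}

#' Physical span of each MQTL
#'
#' @param physLo,physHi Physical interval bounds in bp, or an [MQTLSet]
#'   with filled intervals passed as `physLo`.
#' @return List: `spans_mb` (per-MQTL spans in Mb, 2-decimal half-up
#'   rounding), `min`, `max`.
#' @export
physicalSpanSummary <- function(physLo, physHi = NULL) {
  if (is(physLo, "MQTLSet")) {
    m <- mqtlTable(physLo)
    physHi <- m$phys_hi; physLo <- m$phys_lo
    names(physLo) <- m$mqtl_id
  }
  if (any(is.na(physLo)) || any(is.na(physHi)))
    stop("physical intervals are not filled; run anchorMQTLs()",
         call. = FALSE)
  spans <- roundHalfUp((physHi - physLo) / 1e6)
  names(spans) <- names(physLo)
  list(spans_mb = spans, min = min(spans), max = max(spans))
}
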