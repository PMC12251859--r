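#' Load the packaged published maize PH/EH meta-QTL summary
#'
#' A verbatim transcription of a published 29-row meta-QTL summary for
#' maize plant height (PH) and ear height (EH): one row per MQTL with its
#' trait class, chromosome, consensus-map position and 95% CI (cM),
#' member-QTL count, bin address, CI flanking markers, physical interval
#' (Mb) and contigs. It serves as a reference surface for the package's
#' summary statistics. One known quirk of the source table is preserved:
#' MQTL5-1's printed position (586.90 cM) lies outside its own CI
#' (459.20-534.40 cM), so the loader deliberately does not enforce
#' position-in-CI for these rows.
#'
#' @return data.frame with 29 rows; physical bounds are also provided in
#'   bp (`phys_lo`, `phys_hi` = Mb columns times 1e6).
#' @examples
#' tab <- loadPublishedMQTLSummary()
#' mqtlSummary(data.frame(chromosome = tab$chromosome,
#'   ci_lo = tab$ci_lo_cM, ci_hi = tab$ci_hi_cM, n_qtls = tab$n_qtls,
#'   trait_class = tab$trait_class))
#' @export
loadPublishedMQTLSummary <- function() {
  path <- system.file("extdata", "maize_ph_eh_mqtl_summary.tsv",
                      package = "qtlMeta")
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot(nrow(tab) == 29, all(tab$ci_lo_cM <= tab$ci_hi_cM),
            all(tab$phys_lo_Mb <= tab$phys_hi_Mb))
  tab$phys_lo <- tab$phys_lo_Mb * 1e6
  tab$phys_hi <- tab$phys_hi_Mb * 1e6
  tab
}
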