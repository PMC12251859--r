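#' Default multi-study design table
#'
#' Thirteen mapping studies emulating a literature compendium for maize
#' plant/ear height: a mix of F2, F2-derived selfed families (F2:3, F3,
#' F4), RIL and DH designs with population sizes between 120 and 271 and
#' per-study marker densities of 8-15 cM.
#'
#' @return data.frame: `study_ref`, `population_type`, `population_size`,
#'   `marker_spacing` (cM).
#' @export
defaultStudies <- function() {
  data.frame(
    study_ref = sprintf("S%02d", 1:13),
    population_type = c("F2", "F2", "F2", "F2", "F2:3", "F2:3", "F2:3",
                        "F2:3", "F3", "F4", "RIL", "RIL", "DH"),
    population_size = c(187L, 192L, 120L, 250L, 211L, 184L, 202L, 218L,
                        187L, 187L, 271L, 165L, 162L),
    marker_spacing = c(10, 12, 15, 9, 10, 11, 8, 12, 10, 13, 8, 9, 11))
}

#' Build a synthetic-scenario configuration
#'
#' Defaults describe the package's reference simulation: 3 chromosomes of
#' 300 cM, three true loci per chromosome at 50/150/250 cM (100 cM apart),
#' 13 studies ([defaultStudies()]), 8 reported QTLs per true locus, per-QTL
#' PVE drawn uniformly from 3.23-31.93%, a quarter of records with the CI
#' omitted, per-study maps keeping 60% of reference markers with 10%
#' log-normal interval jitter, and positional noise calibrated to the
#' Darvasi-Soller CI (`noiseScale = 1`).
#'
#' @param seed Integer RNG seed (mandatory).
#' @param chromosomes,chromosomeLength Chromosome count and length (cM).
#' @param trueLoci List of per-chromosome true locus positions (cM);
#'   recycled across chromosomes if a single vector is given.
#' @param studies Study design table (see [defaultStudies()]).
#' @param qtlsPerLocus Reported QTLs per locus when `detectProb` is NA.
#' @param pveRange PVE sampling range, percent.
#' @param detectProb Per-study, per-locus detection probability; NA (the
#'   default) samples exactly `qtlsPerLocus` distinct studies per locus.
#' @param ciMissingFraction Fraction of records with the CI omitted.
#' @param refMarkerSpacing Mean reference-map marker spacing, cM.
#' @param keepFraction Fraction of reference markers kept per source map.
#' @param lengthJitterSD Log-normal SD of per-interval map distortion.
#' @param noiseScale Multiplier on the positional noise SD (0 = noiseless).
#' @param genesPerChromosome Simulated genes per chromosome.
#' @return A [ScenarioConfig].
#' @export
scenarioConfig <- function(seed, chromosomes = 3L, chromosomeLength = 300,
                           trueLoci = list(c(50, 150, 250)),
                           studies = defaultStudies(), qtlsPerLocus = 8L,
                           pveRange = c(3.23, 31.93), detectProb = NA_real_,
                           ciMissingFraction = 0.25, refMarkerSpacing = 5,
                           keepFraction = 0.6, lengthJitterSD = 0.1,
                           noiseScale = 1, genesPerChromosome = 40L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!is.list(trueLoci)) trueLoci <- list(trueLoci)
  if (length(trueLoci) == 1L && chromosomes > 1L)
    trueLoci <- rep(trueLoci, chromosomes)
  new("ScenarioConfig", seed = as.integer(seed),
      chromosomes = as.integer(chromosomes),
      chromosomeLength = chromosomeLength, trueLoci = trueLoci,
      studies = studies, qtlsPerLocus = as.integer(qtlsPerLocus),
      pveRange = pveRange, detectProb = as.numeric(detectProb),
      ciMissingFraction = ciMissingFraction,
      refMarkerSpacing = refMarkerSpacing, keepFraction = keepFraction,
      lengthJitterSD = lengthJitterSD, noiseScale = noiseScale,
      genesPerChromosome = as.integer(genesPerChromosome))
}

#' Generate a dense reference map
#'
#' Markers named `m{chr}_{i}` placed from 0 cM with spacings drawn
#' uniformly from (0.5 s, 1.5 s) around the configured mean spacing s; the
#' final marker is placed exactly at the chromosome end so the scaffold
#' spans the full length.
#'
#' @param config A [ScenarioConfig].
#' @param seed Optional seed; NULL (default) uses the current RNG state
#'   so that [simulateScenario()] stays a pure function of the config.
#' @return A [GeneticMap] with mapId `"reference"`.
#' @export
generateReferenceMap <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config@chromosomeLength <= 0)
    stop("chromosome length must be positive", call. = FALSE)
  s <- config@refMarkerSpacing
  chr <- integer(); nm <- character(); pos <- numeric()
  for (c in seq_len(config@chromosomes)) {
    p <- 0
    while (p[length(p)] < config@chromosomeLength) {
      p <- c(p, p[length(p)] + stats::runif(1, 0.5 * s, 1.5 * s))
    }
    p[length(p)] <- config@chromosomeLength
    chr <- c(chr, rep(c, length(p)))
    nm <- c(nm, sprintf("m%d_%d", c, seq_along(p)))
    pos <- c(pos, p)
  }
  GeneticMap("reference", chr, nm, pos)
}

#' Derive a distorted per-study source map from the reference
#'
#' Retains a random marker subset (chromosome ends always kept, so the
#' full span stays anchored) and multiplies each retained inter-marker
#' distance by an independent log-normal factor, emulating per-study map
#' length distortion. Marker order is preserved, and retained markers
#' keep their names, so they remain usable as projection anchors.
#'
#' @param reference The reference [GeneticMap].
#' @param keepFraction Fraction of markers kept per chromosome (ends
#'   always included; must leave at least 2 markers).
#' @param lengthJitterSD Log-normal SD of the interval factors (0 =
#'   identical geometry).
#' @param mapId Identifier for the derived map.
#' @param seed Optional seed (NULL = current RNG state).
#' @return A [GeneticMap].
#' @export
deriveSourceMap <- function(reference, keepFraction, lengthJitterSD,
                            mapId = "source", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must be in (0, 1]", call. = FALSE)
  m <- markerTable(reference)
  chr <- integer(); nm <- character(); pos <- numeric()
  for (c in unique(m$chromosome)) {
    sub <- m[m$chromosome == c, , drop = FALSE]
    n <- nrow(sub)
    nKeep <- round(keepFraction * n)
    if (nKeep < 2)
      stop("keepFraction leaves fewer than 2 markers on chromosome ", c,
           call. = FALSE)
    interior <- if (nKeep > 2 && n > 2)
      sort(sample(2:(n - 1), nKeep - 2)) else integer(0)
    keep <- c(1L, interior, n)
    refPos <- sub$position[keep]
    d <- diff(refPos)
    fac <- stats::rlnorm(length(d), meanlog = 0, sdlog = lengthJitterSD)
    newPos <- refPos[1] + c(0, cumsum(d * fac))
    chr <- c(chr, rep(c, length(keep)))
    nm <- c(nm, sub$marker[keep])
    pos <- c(pos, newPos)
  }
  GeneticMap(mapId, chr, nm, pos)
}

#' Simulate a multi-study QTL compendium from known truth
#'
#' For each chromosome and true locus, a set of studies reports a QTL:
#' PVE is drawn uniformly from the configured range, the 95% CI width
#' follows the Darvasi-Soller equations ([imputeCIWidth()]) for the
#' study's design and size, and the reported peak is the true position
#' (carried onto the study's own distorted map) plus Gaussian noise with
#' `sigma = width / 3.92 * noiseScale` — so with `noiseScale = 1` the
#' simulated CIs are calibrated 95% intervals, the self-consistency the
#' downstream meta-analysis assumes. LOD is coupled to PVE as
#' `2.5 + 0.45 * PVE + N(0, 0.5)`, floored at 1.6; traits are assigned
#' PH/EH with equal probability; a configured fraction of records has the
#' CI omitted to exercise [completeCIs()].
#'
#' @param truth Truth list from [simulateScenario()] (`loci` per
#'   chromosome).
#' @param config A [ScenarioConfig].
#' @param sourceMaps Named list of per-study [GeneticMap]s
#'   (`map_{study_ref}`).
#' @param reference The reference [GeneticMap].
#' @return List: `compendium` (a [QTLCompendium]) and `assignments`
#'   (data.frame qtl_id / chromosome / locus_index / true_position).
#' @export
simulateQTLs <- function(truth, config, sourceMaps, reference) {
  studies <- config@studies
  rows <- list(); assign <- list()
  # cache per-map tables once: marker positions and the shared-marker
  # correspondence used to carry true loci onto each study's coordinates
  mapTabs <- lapply(sourceMaps, markerTable)
  cmCache <- new.env(parent = emptyenv())
  for (chr in seq_along(truth$loci)) {
    loci <- truth$loci[[chr]]
    for (li in seq_along(loci)) {
      if (is.na(config@detectProb)) {
        det <- sort(sample(nrow(studies),
                           min(config@qtlsPerLocus, nrow(studies))))
      } else {
        det <- which(stats::runif(nrow(studies)) < config@detectProb)
      }
      for (si in det) {
        st <- studies[si, ]
        mid <- paste0("map_", st$study_ref)
        key <- paste(mid, chr)
        if (is.null(cmCache[[key]]))
          cmCache[[key]] <- commonMarkers(sourceMaps[[mid]], reference, chr)
        cm <- cmCache[[key]]
        pve <- stats::runif(1, config@pveRange[1], config@pveRange[2])
        w <- imputeCIWidth(st$population_type, st$population_size, pve)
        center <- stats::approx(cm$reference_cM, cm$source_cM,
                                xout = loci[li], rule = 2,
                                ties = "ordered")$y
        peak <- max(0, center + stats::rnorm(1, 0, w / 3.92 *
                                                  config@noiseScale))
        hasCI <- stats::runif(1) >= config@ciMissingFraction
        lod <- max(1.6, 2.5 + 0.45 * pve + stats::rnorm(1, 0, 0.5))
        sm <- mapTabs[[mid]]
        sm <- sm[sm$chromosome == chr, , drop = FALSE]
        fi <- findInterval(peak, sm$position)
        qid <- sprintf("%s_c%d_l%d", st$study_ref, chr, li)
        rows[[qid]] <- data.frame(
          qtl_id = qid, study_ref = st$study_ref,
          trait = sample(.TRAITS, 1), chromosome = as.integer(chr),
          source_map_id = paste0("map_", st$study_ref), position = peak,
          ci_lo = if (hasCI) max(0, peak - w / 2) else NA_real_,
          ci_hi = if (hasCI) peak + w / 2 else NA_real_,
          lod = lod, pve_percent = pve,
          population_type = st$population_type,
          population_size = st$population_size,
          flank_left = if (fi >= 1) sm$marker[fi] else NA_character_,
          flank_right = if (fi < nrow(sm)) sm$marker[fi + 1]
                        else NA_character_)
        assign[[qid]] <- data.frame(qtl_id = qid,
                                    chromosome = as.integer(chr),
                                    locus_index = li,
                                    true_position = loci[li])
      }
    }
  }
  list(compendium = QTLCompendium(do.call(rbind, c(rows,
                                                   make.row.names = FALSE))),
       assignments = do.call(rbind, c(assign, make.row.names = FALSE)))
}

#' Generate marker physical anchors and a toy gene annotation
#'
#' Anchors every fifth reference marker (plus each chromosome's last
#' marker) with a physical position accumulated at a per-interval rate
#' drawn uniformly from 0.5-1.5 Mb/cM, giving a monotone but locally
#' variable recombination landscape. Genes are placed uniformly along the
#' anchored physical span with lengths of 2-10 kb and annotations sampled
#' from a plant-development vocabulary (hormone pathways, cellulose
#' synthase, expansin, photosystem, actin depolymerization factor,
#' MADS-box, ...).
#'
#' @param reference The reference [GeneticMap].
#' @param genesPerChromosome Genes per chromosome (0 gives an empty but
#'   valid annotation).
#' @param seed Optional seed (NULL = current RNG state).
#' @return List: `anchors` (data.frame marker / chromosome / genetic_pos /
#'   physical_pos) and `genes` (a GRanges with `gene_id`, `annotation`,
#'   exportable as GFF3 via [writeScenario()]).
#' @export
generateAnchorsAndGenes <- function(reference, genesPerChromosome = 40L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- c("auxin response factor", "abscisic acid receptor PYL",
             "cytokinin dehydrogenase", "ethylene-responsive factor",
             "gibberellin 20-oxidase", "brassinosteroid signaling kinase",
             "cellulose synthase 10", "expansin B", "expansin A",
             "xyloglucan endotransglucosylase",
             "phenylalanine ammonia-lyase", "sucrose synthase 3",
             "glucose transporter 3", "beta-amylase",
             "photosystem II reaction center protein",
             "chlorophyll a-b binding protein",
             "actin depolymerization factor",
             "MADS-box transcription factor", "hypothetical protein")
  m <- markerTable(reference)
  anchorRows <- list(); geneRows <- list()
  for (chr in unique(m$chromosome)) {
    sub <- m[m$chromosome == chr, , drop = FALSE]
    idx <- unique(c(seq(1, nrow(sub), by = 5), nrow(sub)))
    g <- sub$position[idx]
    rate <- stats::runif(length(idx) - 1, 0.5, 1.5) * 1e6  # bp per cM
    phys <- 1e5 + c(0, cumsum(diff(g) * rate))
    anchorRows[[as.character(chr)]] <- data.frame(
      marker = sub$marker[idx], chromosome = as.integer(chr),
      genetic_pos = g, physical_pos = round(phys))
    if (genesPerChromosome > 0) {
      lo <- min(phys); hi <- max(phys)
      start <- round(stats::runif(genesPerChromosome, lo, hi - 1e4))
      width <- round(stats::runif(genesPerChromosome, 2e3, 1e4))
      geneRows[[as.character(chr)]] <- data.frame(
        chromosome = as.integer(chr), start = start,
        end = start + width - 1,
        gene_id = sprintf("g%d_%03d", chr, seq_len(genesPerChromosome)),
        annotation = sample(vocab, genesPerChromosome, replace = TRUE))
    }
  }
  geneTab <- if (length(geneRows) > 0)
    do.call(rbind, c(geneRows, make.row.names = FALSE))
  else data.frame(chromosome = integer(), start = numeric(),
                  end = numeric(), gene_id = character(),
                  annotation = character())
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(geneTab$chromosome),
    ranges = IRanges::IRanges(start = geneTab$start, end = geneTab$end),
    strand = rep("+", nrow(geneTab)))
  genes$type <- rep("gene", length(genes))
  genes$gene_id <- geneTab$gene_id
  genes$ID <- geneTab$gene_id
  genes$description <- geneTab$annotation
  genes$annotation <- geneTab$annotation
  list(anchors = do.call(rbind, c(anchorRows, make.row.names = FALSE)),
       genes = genes)
}

#' Generate a complete synthetic scenario
#'
#' Seeds the RNG once from the config and generates, in a fixed order,
#' the reference map, the 13 per-study distorted source maps, the QTL
#' compendium with ground-truth assignments, and the marker anchors plus
#' gene annotation. Every output is a pure function of the config.
#'
#' @param config A [ScenarioConfig].
#' @return List: `config`, `reference`, `sourceMaps` (named list),
#'   `compendium` ([QTLCompendium]), `truth` (list with `loci` and
#'   `assignments`), `anchors`, `genes`.
#' @export
simulateScenario <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  set.seed(config@seed)
  reference <- generateReferenceMap(config)
  sourceMaps <- list()
  for (i in seq_len(nrow(config@studies))) {
    id <- paste0("map_", config@studies$study_ref[i])
    sourceMaps[[id]] <- deriveSourceMap(reference, config@keepFraction,
                                        config@lengthJitterSD, mapId = id)
  }
  truth <- list(loci = stats::setNames(config@trueLoci,
                                       seq_len(config@chromosomes)))
  sim <- simulateQTLs(truth, config, sourceMaps, reference)
  truth$assignments <- sim$assignments
  ag <- generateAnchorsAndGenes(reference, config@genesPerChromosome)
  list(config = config, reference = reference, sourceMaps = sourceMaps,
       compendium = sim$compendium, truth = truth, anchors = ag$anchors,
       genes = ag$genes)
}

#' Write a scenario to disk
#'
#' Writes `qtl.csv` (compendium, [readQTLTable()] schema), `maps.tsv`
#' (all source maps), `ref.tsv` (reference map), `anchors.csv`,
#' `genes.gff3` and the ground truth (`truth_loci.csv`,
#' `truth_assignments.csv`), all plain text.
#'
#' @param scenario Result of [simulateScenario()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeScenario <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  r <- qtlRecords(scenario$compendium)
  out <- data.frame(qtl_id = r$qtl_id, study_ref = r$study_ref,
                    trait = r$trait, chromosome = r$chromosome,
                    source_map_id = r$source_map_id,
                    position_cM = r$position, ci_lo_cM = r$ci_lo,
                    ci_hi_cM = r$ci_hi, lod = r$lod,
                    pve_percent = r$pve_percent,
                    population_type = r$population_type,
                    population_size = r$population_size,
                    flank_left = r$flank_left,
                    flank_right = r$flank_right)
  utils::write.csv(out, file.path(outdir, "qtl.csv"), row.names = FALSE,
                   na = "")
  writeGeneticMaps(scenario$sourceMaps, file.path(outdir, "maps.tsv"))
  writeGeneticMaps(scenario$reference, file.path(outdir, "ref.tsv"))
  utils::write.csv(scenario$anchors, file.path(outdir, "anchors.csv"),
                   row.names = FALSE)
  gr <- scenario$genes
  gr$annotation <- NULL
  rtracklayer::export(gr, file.path(outdir, "genes.gff3"), format = "gff3")
  loci <- do.call(rbind, lapply(names(scenario$truth$loci), function(chr)
    data.frame(chromosome = as.integer(chr),
               position_cM = scenario$truth$loci[[chr]])))
  utils::write.csv(loci, file.path(outdir, "truth_loci.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$truth$assignments,
                   file.path(outdir, "truth_assignments.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' Recovery metrics against simulated ground truth
#'
#' Compares an estimated [MQTLSet] to the true loci of the scenario it
#' was run on: per-chromosome error in the chosen number of clusters,
#' root-mean-square position error over nearest-matched (true locus,
#' MQTL) pairs, and CI coverage — the fraction of true loci contained in
#' at least one estimated MQTL CI.
#'
#' @param mqtlSet An [MQTLSet] estimated from a scenario.
#' @param truth The scenario's `truth` list (needs `loci`).
#' @return List: `k_error` (named per chromosome, estimated minus true),
#'   `position_rmse` (cM), `ci_coverage` (proportion), and
#'   `position_errors` (per matched true locus).
#' @export
recoveryMetrics <- function(mqtlSet, truth) {
  m <- mqtlTable(mqtlSet)
  badChr <- setdiff(unique(m$chromosome), as.integer(names(truth$loci)))
  if (length(badChr) > 0)
    stop("MQTLs on chromosome(s) absent from truth: ",
         paste(badChr, collapse = ", "), call. = FALSE)
  kErr <- integer(0); errs <- numeric(0); covered <- logical(0)
  for (chr in names(truth$loci)) {
    tl <- truth$loci[[chr]]
    est <- m[m$chromosome == as.integer(chr), , drop = FALSE]
    kErr[chr] <- nrow(est) - length(tl)
    for (t in tl) {
      if (nrow(est) == 0) {
        covered <- c(covered, FALSE)
      } else {
        errs <- c(errs, min(abs(est$position - t)))
        covered <- c(covered, any(est$ci_lo <= t & t <= est$ci_hi))
      }
    }
  }
  list(k_error = kErr,
       position_rmse = if (length(errs) == 0) NA_real_
                       else sqrt(mean(errs^2)),
       ci_coverage = mean(covered), position_errors = errs)
}

#' Run the full meta-QTL pipeline on a scenario or user data
#'
#' Chains quality filtering, CI completion, projection onto the reference
#' map, per-chromosome meta-analysis and physical anchoring.
#'
#' @param compendium A [QTLCompendium].
#' @param sourceMaps Named list of [GeneticMap]s.
#' @param reference Reference [GeneticMap].
#' @param anchors Optional anchor table for physical anchoring.
#' @param genes Optional gene GRanges for candidate-gene extraction.
#' @param kmax,mode Passed to [metaAnalyze()].
#' @return List: `qc` (kept/removed/flagged), `projection`, `mqtls`
#'   ([MQTLSet]), and when anchors are given `genes` (candidate-gene
#'   table).
#' @export
runMetaPipeline <- function(compendium, sourceMaps, reference,
                            anchors = NULL, genes = NULL, kmax = NULL,
                            mode = "pooled") {
  qc <- qualityFilter(compendium)
  completed <- completeCIs(qc$kept)
  proj <- projectCompendium(completed, sourceMaps, reference)
  qset <- consensusQTLSet(proj, completed)
  mq <- metaAnalyze(qset, kmax = kmax, mode = mode, reference = reference)
  out <- list(qc = qc, projection = proj, mqtls = mq)
  if (!is.null(anchors)) {
    anch <- anchorMQTLs(mq, anchors, genes)
    out$mqtls <- anch$mqtls
    out$genes <- anch$genes
  }
  out
}
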