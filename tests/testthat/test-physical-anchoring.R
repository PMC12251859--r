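anchors3 <- data.frame(marker = c("a", "b", "c"), chromosome = 1,
                       genetic_pos = c(0, 50, 100),
                       physical_pos = c(1e6, 3e6, 9e6))

test_that("geneticToPhysical interpolates piecewise-linearly and clamps", {
  expect_equal(geneticToPhysical(c(0, 50), 1, anchors3), c(1e6, 3e6))
  a2 <- data.frame(marker = c("a", "b"), chromosome = 1,
                   genetic_pos = c(0, 100), physical_pos = c(0, 1e7))
  expect_equal(geneticToPhysical(c(50, 50), 1, a2), c(5e6, 5e6))
  expect_equal(geneticToPhysical(c(25, 75), 1, anchors3), c(2e6, 6e6))
  # outside the anchored span: clamped to terminal anchors
  expect_equal(geneticToPhysical(c(-10, 130), 1, anchors3), c(1e6, 9e6))
  # interval handed in reversed order comes back sorted
  expect_equal(geneticToPhysical(c(75, 25), 1, anchors3), c(2e6, 6e6))
  expect_error(geneticToPhysical(c(0, 1), 2, anchors3), "at least 2")

  # duplicate genetic positions: first anchor's physical position used
  dup <- rbind(anchors3, data.frame(marker = "b2", chromosome = 1,
                                    genetic_pos = 50, physical_pos = 4e6))
  expect_equal(geneticToPhysical(c(50, 50), 1, dup), c(3e6, 3e6))

  # monotone anchors give a monotone conversion
  set.seed(8)
  g <- sort(runif(10, 0, 200)); p <- cumsum(runif(10, 1e5, 2e6))
  aa <- data.frame(marker = letters[1:10], chromosome = 2,
                   genetic_pos = g, physical_pos = p)
  xs <- sort(runif(30, -10, 210))
  ys <- vapply(xs, function(x) geneticToPhysical(c(x, x), 2, aa)[1], 1.0)
  expect_true(all(diff(ys) >= 0))
})

test_that("genesInInterval uses closed-interval any-overlap semantics", {
  tab <- data.frame(chromosome = 1,
                    start = c(100, 300, 500, 700, 900),
                    end = c(199, 399, 599, 799, 999),
                    gene_id = paste0("g", 1:5),
                    annotation = "x")
  gr <- GenomicRanges::GRanges(as.character(tab$chromosome),
                               IRanges::IRanges(tab$start, tab$end))
  gr$gene_id <- tab$gene_id; gr$annotation <- tab$annotation

  # interval covering genes 2-4
  hit <- genesInInterval(c(350, 750), 1, gr)
  expect_equal(hit$gene_id, c("g2", "g3", "g4"))
  # gene abutting the interval edge (end == interval lo) is included
  expect_equal(genesInInterval(c(199, 250), 1, gr)$gene_id, "g1")
  # empty annotation
  expect_length(genesInInterval(c(1, 10), 1, gr[0]), 0)

  # oracle: brute-force all-pairs scan on a random fixture
  set.seed(21)
  n <- 1000
  big <- data.frame(chromosome = sample(1:3, n, replace = TRUE),
                    start = sample.int(1e6, n), gene_id = paste0("r", 1:n),
                    annotation = "y")
  big$end <- big$start + sample.int(5e3, n)
  bigGR <- GenomicRanges::GRanges(as.character(big$chromosome),
                                  IRanges::IRanges(big$start, big$end))
  bigGR$gene_id <- big$gene_id; bigGR$annotation <- big$annotation
  for (rep in 1:10) {
    lo <- runif(1, 0, 1e6); iv <- c(lo, lo + runif(1, 1e3, 2e5))
    chr <- sample(1:3, 1)
    expect_equal(genesInInterval(iv, chr, bigGR)$gene_id,
                 bruteOverlap(iv, chr, big)$gene_id)
  }
})

test_that("classifyGenes tags by keyword and defaults to other", {
  genes <- data.frame(
    gene_id = paste0("g", 1:11),
    annotation = c("cellulose synthase 10", "auxin response factor 3",
                   "gibberellin 20-oxidase", "ABSCISIC acid receptor",
                   "ethylene-responsive TF", "", "hypothetical protein",
                   "photosystem II protein D1", "actin depolymerization factor",
                   "sucrose synthase 3", "60S ribosomal protein"))
  cl <- classifyGenes(genes)
  expect_equal(unname(cl$counts["hormone"]), 4L)
  expect_equal(unname(cl$percent["hormone"]), 36.36)  # 4 of 11, half-up
  expect_equal(unname(cl$counts["cell wall"]), 1L)
  # empty or unmatched annotations fall into "other"
  expect_equal(unname(cl$counts["other"]), 3L)
  expect_equal(cl$tags$categories[1], "cell wall")

  # exclusive single-tag counts partition the genes
  nTags <- lengths(strsplit(cl$tags$categories, ","))
  expect_equal(sum(nTags == 1), nrow(genes))  # no multi-tag gene here
  multi <- classifyGenes(data.frame(gene_id = "m",
    annotation = "auxin-induced cellulose synthase"))
  expect_equal(multi$tags$categories, "hormone,cell wall")
  expect_equal(sum(multi$counts), 2L)  # percentages can pass 100 only so
})

test_that("physicalSpanSummary rounds spans half-up in Mb", {
  tab <- loadPublishedMQTLSummary()
  s <- physicalSpanSummary(tab$phys_lo, tab$phys_hi)
  expect_equal(s$min, 0.04)
  expect_equal(s$spans_mb[tab$mqtl_id == "MQTL2-1"], 0.04,
               ignore_attr = TRUE)
  expect_equal(s$spans_mb[tab$mqtl_id == "MQTL7-1"], 30.08,
               ignore_attr = TRUE)
  expect_equal(s$spans_mb[tab$mqtl_id == "MQTL3-2"], 32.18,
               ignore_attr = TRUE)
  expect_equal(physicalSpanSummary(5e6, 5e6)$spans_mb, 0,
               ignore_attr = TRUE)
  expect_error(physicalSpanSummary(c(1, NA), c(2, 3)), "anchorMQTLs")
})

test_that("anchorMQTLs fills physical intervals and extracts genes", {
  sc <- simulateScenario(scenarioConfig(seed = 6, chromosomes = 1L))
  res <- runMetaPipeline(sc$compendium, sc$sourceMaps, sc$reference,
                         anchors = sc$anchors, genes = sc$genes)
  m <- mqtlTable(res$mqtls)
  expect_true(all(!is.na(m$phys_lo) & m$phys_lo <= m$phys_hi))
  # every reported gene really overlaps its MQTL physical interval
  if (nrow(res$genes) > 0) {
    j <- match(res$genes$mqtl_id, m$mqtl_id)
    expect_true(all(res$genes$start <= m$phys_hi[j] &
                    res$genes$end >= m$phys_lo[j]))
  }
})

test_that("GFF3 round trip preserves gene ids and annotations", {
  sc <- simulateScenario(scenarioConfig(seed = 9, chromosomes = 1L,
                                        genesPerChromosome = 5L))
  dir <- tempfile(); writeScenario(sc, dir)
  gr <- readGeneAnnotation(file.path(dir, "genes.gff3"))
  expect_setequal(gr$gene_id, sc$genes$gene_id)
  i <- match(sc$genes$gene_id, gr$gene_id)
  expect_equal(gr$annotation[i], sc$genes$annotation)
  expect_equal(GenomicRanges::start(gr)[i],
               GenomicRanges::start(sc$genes))
})
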