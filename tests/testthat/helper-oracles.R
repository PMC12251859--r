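# Independent oracles and small fixture builders shared across tests.

# Brute-force best contiguous partition: enumerate every way to cut the
# position-sorted items into k contiguous segments and score each with
# clusterMLE. Independent of the DP in bestPartition.
enumerateBestPartition <- function(xs, sigmas, k) {
  o <- order(xs)
  xs <- xs[o]; sigmas <- sigmas[o]
  n <- length(xs)
  cutsets <- if (k == 1) list(integer(0)) else
    utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- -Inf
  for (cuts in cutsets) {
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    ll <- sum(vapply(seq_len(k), function(m)
      clusterMLE(xs[starts[m]:ends[m]], sigmas[starts[m]:ends[m]])$loglik,
      1.0))
    if (ll > best) best <- ll
  }
  best
}

# Brute-force closed-interval overlap scan (oracle for genesInInterval).
bruteOverlap <- function(interval, chromosome, geneTab) {
  interval <- sort(interval)
  hit <- geneTab$chromosome == chromosome &
    geneTab$start <= interval[2] & geneTab$end >= interval[1]
  g <- geneTab[hit, , drop = FALSE]
  g[order(g$start), , drop = FALSE]
}

# One-row QTL record with sensible defaults, as a data.frame.
makeQTL <- function(qtl_id = "q1", trait = "PH", chromosome = 1L,
                    position = 50, ci_lo = NA_real_, ci_hi = NA_real_,
                    lod = 5, pve_percent = 10, population_type = "F2",
                    population_size = 200L, study_ref = "S01",
                    source_map_id = "map_S01",
                    flank_left = NA_character_,
                    flank_right = NA_character_) {
  data.frame(qtl_id = qtl_id, study_ref = study_ref, trait = trait,
             chromosome = chromosome, source_map_id = source_map_id,
             position = position, ci_lo = ci_lo, ci_hi = ci_hi, lod = lod,
             pve_percent = pve_percent, population_type = population_type,
             population_size = population_size, flank_left = flank_left,
             flank_right = flank_right)
}

makeCompendium <- function(...) QTLCompendium(rbind(...))

# Write a compendium data.frame to a temp CSV in the file schema.
writeQTLCSV <- function(df, path = tempfile(fileext = ".csv")) {
  out <- data.frame(qtl_id = df$qtl_id, study_ref = df$study_ref,
                    trait = df$trait, chromosome = df$chromosome,
                    source_map_id = df$source_map_id,
                    position_cM = df$position, ci_lo_cM = df$ci_lo,
                    ci_hi_cM = df$ci_hi, lod = df$lod,
                    pve_percent = df$pve_percent,
                    population_type = df$population_type,
                    population_size = df$population_size,
                    flank_left = df$flank_left,
                    flank_right = df$flank_right)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

# Published-summary fixture as a consensus-style MQTL table.
fixtureAsMQTLTable <- function() {
  tab <- loadPublishedMQTLSummary()
  data.frame(chromosome = tab$chromosome, ci_lo = tab$ci_lo_cM,
             ci_hi = tab$ci_hi_cM, n_qtls = tab$n_qtls,
             trait_class = tab$trait_class)
}
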