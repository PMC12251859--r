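test_that("sdFromCI divides the 95% width by 3.92", {
  expect_equal(sdFromCI(0, 3.92), 1)
  expect_equal(sdFromCI(10, 17.84), 2)
  expect_equal(sdFromCI(0, 19.9), 19.9 / 3.92)
  expect_error(sdFromCI(5, 5), "positive")
  expect_error(sdFromCI(5, 4), "positive")
})

test_that("clusterMLE is the precision-weighted mean and maximizes loglik", {
  one <- clusterMLE(10, 2)
  expect_equal(c(one$mu, one$se), c(10, 2))

  sym <- clusterMLE(c(0, 10), c(2, 2))
  expect_equal(c(sym$mu, sym$se), c(5, 2 / sqrt(2)))

  fit <- clusterMLE(c(0, 10), c(1, 3))
  expect_equal(fit$mu, 1.0)
  expect_equal(fit$se, sqrt(0.9), tolerance = 1e-9)

  # independent grid-search oracle: no mu on a fine grid beats the MLE
  grid <- seq(0, 10, by = 0.001)
  gridLL <- vapply(grid, function(m)
    sum(dnorm(c(0, 10), m, c(1, 3), log = TRUE)), 1.0)
  expect_equal(grid[which.max(gridLL)], 1.0, tolerance = 1e-3)
  expect_true(all(gridLL <= fit$loglik + 1e-12))

  expect_error(clusterMLE(numeric(0), numeric(0)), "empty")
  expect_error(clusterMLE(c(1, 2), c(1, 0)), "positive")
})

test_that("bestPartition matches closed forms and splits separated groups", {
  xs <- c(1, 4, 9, 16, 25); sg <- c(1, 2, 1, 3, 2)
  # k = n: every item its own cluster, loglik = -sum log(sigma sqrt(2 pi))
  fit <- bestPartition(xs, sg, 5)
  expect_equal(fit$loglik, sum(-log(sg * sqrt(2 * pi))), tolerance = 1e-12)
  # k = 1: one cluster, equal to clusterMLE of everything
  expect_equal(bestPartition(xs, sg, 1)$loglik,
               clusterMLE(xs, sg)$loglik, tolerance = 1e-12)

  # two tight groups near 20 and 80: the k=2 boundary separates them
  xs2 <- c(18, 20, 22, 78, 80, 82); sg2 <- rep(2, 6)
  fit2 <- bestPartition(xs2, sg2, 2)
  expect_equal(vapply(fit2$clusters, function(cl) length(cl$idx), 1L),
               c(3L, 3L))
  expect_equal(vapply(fit2$clusters, `[[`, 1.0, "mu"), c(20, 80))
  # equals brute-force enumeration of all 5 contiguous splits
  expect_equal(fit2$loglik, enumerateBestPartition(xs2, sg2, 2),
               tolerance = 1e-12)

  expect_error(bestPartition(xs, sg, 6), "k must lie")
})

test_that("DP equals exhaustive enumeration and loglik grows with k", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    xs <- runif(n, 0, 100)
    sg <- runif(n, 0.5, 10)
    lls <- numeric(n)
    for (k in seq_len(n)) {
      fit <- bestPartition(xs, sg, k)
      expect_equal(fit$loglik, enumerateBestPartition(xs, sg, k),
                   tolerance = 1e-9)
      lls[k] <- fit$loglik
    }
    expect_true(all(diff(lls) > -1e-9))  # monotone in k
  }
})

test_that("informationCriteria implements the stated formulas", {
  # k = 1: both parameter conventions coincide at p = 1
  ic <- informationCriteria(0, 1, 10)
  expect_equal(unname(ic[c("AIC", "AIC3", "BIC")]), c(2, 3, log(10)))
  # guard: AICc infinite when n - p - 1 <= 0
  expect_equal(unname(informationCriteria(-1, 4, 5, p = 4)["AICc"]), Inf)
  # hand arithmetic at explicit p = k
  ic2 <- informationCriteria(-50, 3, 20, p = 3)
  expect_equal(unname(ic2), c(106, 107.5, 109, 100 + 3 * log(20),
                              100 + 6 * (1.5 + log(20))), tolerance = 1e-9)
  # default counts the k - 1 free boundaries too
  ic3 <- informationCriteria(-50, 3, 20)
  expect_equal(unname(ic3["AIC"]), 110)
  expect_equal(unname(ic3["BIC"]), 100 + 5 * log(20))
})

test_that("selectK votes per criterion and breaks ties toward parsimony", {
  mkcrit <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
    m
  }
  # unanimity at k = 2
  un <- mkcrit(c(5, 5, 5, 5, 5), c(1, 1, 1, 1, 1), c(3, 3, 3, 3, 3))
  expect_equal(selectK(un)$chosen_k, 2L)
  expect_equal(selectK(un)$votes, c(0L, 5L, 0L))
  # 3-2 split: the >= 3 majority wins
  maj <- mkcrit(c(9, 9, 9, 9, 9), c(1, 1, 1, 5, 5), c(2, 2, 2, 1, 1))
  expect_equal(selectK(maj)$chosen_k, 2L)
  expect_equal(selectK(maj)$votes, c(0L, 3L, 2L))
  # no >= 3 consensus, tied plurality 2-2-1: smallest k wins
  tie <- mkcrit(c(1, 1, 5, 5, 5), c(5, 5, 1, 1, 9), c(9, 9, 9, 9, 1))
  expect_equal(selectK(tie)$chosen_k, 1L)
  expect_equal(selectK(tie)$votes, c(2L, 2L, 1L))
  # criterion ties across k go to the smaller k
  flat <- mkcrit(c(1, 1, 1, 1, 1), c(1, 1, 1, 1, 1))
  expect_equal(selectK(flat)$chosen_k, 1L)
})

test_that("metaAnalyzeChromosome recovers two well-separated loci", {
  set.seed(99)
  truth <- c(40, 100)
  qtls <- do.call(rbind, lapply(seq_along(truth), function(i) {
    sg <- runif(6, 2, 5)
    data.frame(qtl_id = sprintf("t%d_%d", i, 1:6),
               x = rnorm(6, truth[i], sg), sigma = sg,
               trait = sample(c("PH", "EH"), 6, replace = TRUE))
  }))
  res <- metaAnalyzeChromosome(qtls, chromosome = 2)
  expect_equal(res$criteria$chosen_k, 2L)
  m <- res$mqtls
  expect_equal(m$mqtl_id, c("MQTL2-1", "MQTL2-2"))
  expect_true(m$ci_lo[1] <= 40 && 40 <= m$ci_hi[1])
  expect_true(m$ci_lo[2] <= 100 && 100 <= m$ci_hi[2])
  expect_equal(m$ci_hi - m$ci_lo, 2 * 1.96 * m$se)

  # single QTL: the MQTL is that QTL
  single <- metaAnalyzeChromosome(
    data.frame(qtl_id = "q", x = 12, sigma = 3, trait = "EH"), 4)
  expect_equal(single$mqtls$position, 12)
  expect_equal(single$mqtls$se, 3)
  expect_equal(single$mqtls$trait_class, "EH")

  # mixed member traits render as "PH, EH"
  mix <- metaAnalyzeChromosome(
    data.frame(qtl_id = c("a", "b", "c"), x = c(10, 11, 12),
               sigma = c(2, 2, 2), trait = c("EH", "PH", "PH")), 1)
  expect_equal(mix$mqtls$trait_class, "PH, EH")
})

test_that("meta-analysis is invariant to input record order", {
  set.seed(17)
  sg <- runif(12, 1, 6)
  qtls <- data.frame(qtl_id = sprintf("q%02d", 1:12),
                     chromosome = 1L,
                     x = rnorm(12, rep(c(30, 120), each = 6), sg),
                     sigma = sg,
                     trait = sample(c("PH", "EH"), 12, replace = TRUE))
  a <- mqtlTable(metaAnalyze(qtls))
  b <- mqtlTable(metaAnalyze(qtls[sample(12), ]))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("every MQTL confidence interval is narrower than its narrowest member", {
  for (seed in c(3, 14, 27)) {
    sc <- simulateScenario(scenarioConfig(seed = seed))
    res <- runMetaPipeline(sc$compendium, sc$sourceMaps, sc$reference)
    qs <- consensusQTLSet(res$projection, completeCIs(res$qc$kept))
    m <- mqtlTable(res$mqtls)
    for (i in seq_len(nrow(m))) {
      members <- strsplit(m$member_qtl_ids[i], ",")[[1]]
      minMemberWidth <- min(3.92 * qs$sigma[qs$qtl_id %in% members])
      expect_lte(m$ci_hi[i] - m$ci_lo[i], minMemberWidth + 1e-9)
    }
  }
})

test_that("mqtlSummary reproduces published-table statistics", {
  s <- mqtlSummary(fixtureAsMQTLTable())
  expect_equal(unname(s$ci_width), c(0.80, 26.27, 75.20))
  expect_equal(s$member_qtls_total, 132)
  expect_equal(c(s$members_min, s$members_max), c(2, 10))
  expect_equal(s$count, 29)
  expect_equal(unname(s$per_chromosome[c("1", "3", "10")]), c(6L, 6L, 4L),
               ignore_attr = TRUE)

  one <- mqtlSummary(data.frame(chromosome = 1, ci_lo = 0, ci_hi = 10,
                                n_qtls = 2, trait_class = "PH"))
  expect_equal(unname(one$ci_width), c(10, 10, 10))
})

test_that("per-trait mode analyses traits separately and re-indexes", {
  set.seed(5)
  qtls <- data.frame(qtl_id = sprintf("q%02d", 1:16), chromosome = 3L,
                     x = rnorm(16, rep(c(50, 200), each = 8), 3),
                     sigma = rep(3, 16),
                     trait = rep(c("PH", "EH"), 8))
  mt <- mqtlTable(metaAnalyze(qtls, mode = "per-trait"))
  expect_equal(mt$mqtl_id, sprintf("MQTL3-%d", seq_len(nrow(mt))))
  expect_true(all(diff(mt$position) >= 0))
  expect_true(all(mt$trait_class %in% c("PH", "EH")))
})
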