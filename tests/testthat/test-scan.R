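# Platform model assembly, the variance-component test, and the
# association / haplotype / epistasis / concordance machinery on small
# simulated cohorts.

scanFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- smallCohort(51, smallCohortConfig(popSizes = c(A = 30L, B = 30L,
                                                           C = 20L)))
      K <- kinshipMatrix(co$ssr)
      mk <- phaseGametes(co$s0, co$siteInfo)
      causal <- data.frame(site = "g1_SNP2", controlled = 0.5,
                           semi_controlled = 3, field = 5)
      ph <- simulatePhenotypes(co, quickEffects(causal = causal), seed = 51)
      cache <<- list(co = co, K = K, mk = mk, ph = ph)
    }
    cache
  }
})

test_that("platform models assemble the documented fixed and random recipes", {
  fx <- scanFixture()
  spec <- platformModel("controlled", fx$ph, fx$co$Q, fx$K)
  xn <- colnames(spec$X)
  expect_true("(Intercept)" %in% xn)
  expect_true(any(startsWith(xn, "year")))
  expect_true(any(startsWith(xn, "temp")))
  expect_equal(sum(startsWith(xn, "Q_")), ncol(qMatrix(fx$co$Q)) - 1L)
  expect_equal(vapply(spec$blocks, `[[`, "", "label"),
               c("chamber", "genotype"))

  specF <- platformModel("field", fx$ph, fx$co$Q, fx$K)
  expect_false("(Intercept)" %in% colnames(specF$X))
  expect_equal(sum(startsWith(colnames(specF$X), "env")),
               length(unique(fx$ph$environment[fx$ph$platform == "field"])))
  expect_equal(vapply(specF$blocks, `[[`, "", "label"),
               c("block", "genotype"))

  specS <- platformModel("semi_controlled", fx$ph, fx$co$Q, fx$K)
  expect_true("trend" %in% colnames(specS$X))
  expect_true(any(grepl(":trend", colnames(specS$X))))
  expect_equal(vapply(specS$blocks, `[[`, "", "label"),
               c("replication", "unit", "genotype"))
  expect_equal(specS$blocks[[2]]$type, "us2")

  # month trend is centered within year; calendar vs rank coding differ
  tcCal <- ryeassoc:::monthTrend(c(2008, 2008, 2008), c(1, 2, 4), "calendar")
  expect_equal(tcCal, c(1, 2, 4) - 7 / 3)
  tcRank <- ryeassoc:::monthTrend(c(2008, 2008, 2008), c(1, 2, 4), "rank")
  expect_equal(tcRank, c(-1, 0, 1))

  # structure-free variant drops the Q columns (phenotypic-analysis model)
  spec0 <- platformModel("controlled", fx$ph, includeQ = FALSE, K = fx$K)
  expect_false(any(startsWith(colnames(spec0$X), "Q_")))

  expect_error(platformModel("greenhouse", fx$ph, fx$co$Q, fx$K),
               "unknown platform")
  Qbad <- StructureMatrix(qMatrix(fx$co$Q)[-1, ])
  expect_error(platformModel("controlled", fx$ph, Qbad, fx$K),
               "missing from Q")
})

test_that("genotype variance-component test detects simulated genetic variance", {
  fx <- scanFixture()
  r <- genotypeVarcompTest(fx$ph, "controlled",
                           list(year = 2008, temperature = -19), fx$K)
  expect_gte(r$logLikFull, r$logLikReduced)   # nesting
  expect_gt(r$sigma2g, 0)
  expect_lt(r$p, 0.01)                        # sigma2_g = 0.25 is large here
  one <- fx$ph[fx$ph$genotype_id == fx$ph$genotype_id[1], ]
  expect_error(genotypeVarcompTest(one, "controlled",
                                   list(year = 2008, temperature = -19),
                                   fx$K),
               "fewer than 2")
})

test_that("the single-site scan reports valid, causal-site-topped results", {
  fx <- scanFixture()
  res <- snpScan(fx$ph, fx$mk, fx$co$Q, fx$K, "field")
  tb <- resultsTable(res)
  expect_equal(nrow(tb), nrow(fx$mk))
  expect_true(all(tb$converged))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  expect_true(all(tb$var_explained_pct >= 0 & tb$var_explained_pct <= 100))
  causalRow <- tb[tb$unit == "g1_SNP2", ]
  expect_lt(causalRow$p, 0.01)
  expect_gt(causalRow$beta, 0)
  # the causal site's gene should top the variance-explained ranking
  expect_equal(tb$gene[which.max(tb$var_explained_pct)], "g1")
})

test_that("the scan consumes replicate-level data, not genotype means", {
  fx <- scanFixture()
  res <- snpScan(fx$ph, fx$mk[1:2, ], fx$co$Q, fx$K, "field")
  # collapse to genotype means inside each environment and rerun
  fld <- fx$ph[fx$ph$platform == "field", ]
  agg <- do.call(rbind, lapply(split(fld, paste(fld$genotype_id,
                                                fld$environment)),
    function(d) { d1 <- d[1, ]; d1$value <- mean(d$value); d1 }))
  rownames(agg) <- NULL
  resMean <- snpScan(agg, fx$mk[1:2, ], fx$co$Q, fx$K, "field")
  expect_false(isTRUE(all.equal(resultsTable(res)$se,
                                resultsTable(resMean)$se)))
})

test_that("haplotype tests gate contrasts on the overall LRT and report missingness", {
  fx <- scanFixture()
  haps <- lapply(unique(fx$co$siteInfo$gene_id),
                 function(g) defineHaplotypes(fx$mk, g))
  res <- haplotypeScan(fx$ph, haps, fx$co$Q, fx$K, "field")
  tb <- resultsTable(res)
  expect_true(all(tb$p[!is.na(tb$p)] >= 0 & tb$p[!is.na(tb$p)] <= 1))
  ov <- tb[tb$haplotype == "overall", ]
  expect_true(all(ov$var_explained_pct >= 0 & ov$var_explained_pct <= 100))
  # g1 carries the causal site: its overall test should fire
  expect_lt(ov$p[ov$gene == "g1"], 0.05)
  # per-haplotype rows exist and carry frequencies
  hap <- tb[tb$haplotype != "overall", ]
  expect_true(all(hap$freq > 0.05))
  expect_true(all(hap$missing_frac == ov$missing_frac[match(hap$gene, ov$gene)]))
})

test_that("reported haplotype missingness equals the brute-force count", {
  fx <- scanFixture()
  hs <- defineHaplotypes(fx$mk, "g2")
  hsF <- filterMAF(hs, 0.4)   # aggressive: most haplotypes become rare
  expect_equal(mean(is.na(haploAssignment(hsF))),
               sum(is.na(haploAssignment(hsF))) /
                 length(haploAssignment(hsF)))
  if (all(c("ref") %in% names(haploFreq(hsF))) &&
      length(haploFreq(hsF)) >= 2) {
    res <- haplotypeScan(fx$ph, list(hsF), fx$co$Q, fx$K, "field", maf = 0.4)
    tb <- resultsTable(res)
    expect_equal(tb$missing_frac[1], mean(is.na(haploAssignment(hsF))))
  }
})

test_that("epistasis LRT is invariant to relabelling haplotypes within a gene", {
  fx <- scanFixture()
  haps <- lapply(c("g1", "g2"), function(g) defineHaplotypes(fx$mk, g))
  res1 <- epistasisScan(fx$ph, haps, fx$co$Q, fx$K, "field")
  # relabel gene 2's non-reference haplotypes (swap names)
  h2 <- haps[[2]]
  labs <- setdiff(names(haploFreq(h2)), "ref")
  if (length(labs) >= 2) {
    swap <- stats::setNames(names(haploSequences(h2)),
                            names(haploSequences(h2)))
    swap[labs[1]] <- labs[2]; swap[labs[2]] <- labs[1]
    h2b <- methods::new("HaplotypeSet", gene = haploGene(h2),
                        sequences = stats::setNames(haploSequences(h2)[names(swap)],
                                                    unname(swap)),
                        assignment = stats::setNames(
                          unname(swap[haploAssignment(h2)]),
                          names(haploAssignment(h2))),
                        freq = stats::setNames(haploFreq(h2)[names(swap)[
                          names(swap) %in% names(haploFreq(h2))]],
                          unname(swap[names(swap) %in% names(haploFreq(h2))])))
    res2 <- epistasisScan(fx$ph, list(haps[[1]], h2b), fx$co$Q, fx$K, "field")
    expect_equal(resultsTable(res1)$statistic, resultsTable(res2)$statistic,
                 tolerance = 1e-6)
  }
  tb <- resultsTable(res1)
  expect_true(all(tb$df >= 1))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
})

test_that("cross-platform correlation behaves at its fixed points", {
  t1 <- data.frame(unit = paste0("s", 1:10), t = rnorm(10), p = runif(10))
  out <- crossPlatformCorrelation(list(a = t1, b = t1))
  expect_equal(out$r, 1)
  expect_equal(out$nUnits, 10L)
  t2 <- t1; t2$t <- -t2$t
  expect_equal(crossPlatformCorrelation(list(a = t1, b = t2))$r, -1)
  expect_error(crossPlatformCorrelation(list(a = t1[1:2, ], b = t1[1:2, ])),
               "fewer than 3")
})

test_that("significance summaries equal a brute-force recount and are monotone", {
  set.seed(61)
  mkTab <- function() data.frame(
    unit = paste0("s", 1:12), gene = rep(c("gA", "gB", "gC"), each = 4),
    t = rnorm(12), p = runif(12), stringsAsFactors = FALSE)
  tabs <- list(controlled = mkTab(), semi_controlled = mkTab(),
               field = mkTab())
  sm <- summarizeSignificant(tabs, alpha = 0.3)
  for (p in names(tabs)) {
    manual <- sum(tabs[[p]]$p < 0.3)
    expect_equal(as.integer(sm$counts[[p]][sm$counts$gene == "total"]), manual)
  }
  expect_true(sm$overlap[["all"]] <= sm$overlap[["atLeast2"]])
  expect_true(sm$overlap[["atLeast2"]] <= sm$overlap[["atLeast1"]])

  none <- lapply(tabs, function(tb) { tb$p <- 1; tb })
  sm0 <- summarizeSignificant(none, alpha = 0.05)
  expect_true(all(sm0$overlap == 0))
})

test_that("permuting marker labels against fixed phenotypes destroys significance", {
  fx <- scanFixture()
  dos <- ryeassoc:::biallelicDosage(fx$mk)["g1_SNP2", ]
  ids <- names(dos)
  spec0 <- platformModel("field", fx$ph, fx$co$Q, fx$K)
  eng0 <- ryeassoc:::makeEngine(spec0)
  fit0 <- ryeassoc:::fitEngine(eng0, "REML")
  gid <- fx$ph$genotype_id[attr(spec0, "rows")]
  set.seed(77)
  pvals <- vapply(1:30, function(r) {
    perm <- stats::setNames(dos[sample(ids)], ids)
    eng <- ryeassoc:::engineWithColumn(eng0, perm[gid], "marker")
    fit <- ryeassoc:::fitEngine(eng, "REML", start = fit0@diagnostics$theta,
                                nStarts = 1L)
    waldTest(fit, "marker")$p
  }, numeric(1))
  # the intact marker is highly significant; permuted versions are null
  intact <- resultsTable(snpScan(fx$ph, fx$mk["g1_SNP2", ], fx$co$Q, fx$K,
                                 "field"))$p
  expect_lt(intact, 0.001)
  expect_lte(mean(pvals < 0.05), 0.2)   # ~alpha up to Monte-Carlo noise
})

test_that("shared causal sites drive positive cross-platform concordance", {
  fx <- scanFixture()
  res <- list(
    controlled = snpScan(fx$ph, fx$mk, fx$co$Q, fx$K, "controlled"),
    field = snpScan(fx$ph, fx$mk, fx$co$Q, fx$K, "field"))
  rAll <- crossPlatformCorrelation(res, "all")
  expect_gt(rAll$r, 0)   # the causal gene is shared across platforms
  rSig <- tryCatch(crossPlatformCorrelation(res, "significant"),
                   error = function(e) NULL)
  if (!is.null(rSig)) expect_gt(rSig$r, rAll$r - 0.25)
})
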