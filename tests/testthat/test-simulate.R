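# Synthetic-cohort generator: study-design fidelity, determinism, and
# generative consistency of the phenotype model.

test_that("the default scenario reproduces the study design counts", {
  sc <- defaultScenario()
  expect_equal(unname(sc$cohort$popSizes),
               c(44L, 68L, 33L, 41L, 15L))
  expect_equal(sum(sc$cohort$popSizes), 201L)
  expect_equal(length(sc$cohort$popSizes), 5L)
  expect_equal(sc$cohort$nSsrLoci, 37L)
  expect_equal(nrow(sc$cohort$genes), 12L)
  expect_equal(sum(sc$cohort$genes$nSites), 170L)
  expect_equal(sum(sc$cohort$genes$nSites) - sum(sc$cohort$genes$nIndels), 161L)
  expect_equal(sum(sc$cohort$genes$nIndels), 9L)
  expect_true(all(sc$cohort$genes$poolSize >= 4L &
                    sc$cohort$genes$poolSize <= 8L))
})

test_that("cohort simulation is deterministic and leaves RNG state alone", {
  cfg <- smallCohortConfig()
  set.seed(999); before <- runif(1)
  co1 <- simulateCohort(cfg, 5)
  co2 <- simulateCohort(cfg, 5)
  expect_identical(co1$truth$gametes, co2$truth$gametes)
  expect_identical(qMatrix(co1$Q), qMatrix(co2$Q))
  expect_identical(SummarizedExperiment::assay(co1$ssr, "allele1"),
                   SummarizedExperiment::assay(co2$ssr, "allele1"))
  co3 <- simulateCohort(cfg, 6)
  expect_false(identical(co1$truth$gametes, co3$truth$gametes))
  set.seed(999)
  expect_identical(runif(1), before)   # RNG state restored

  ph1 <- simulatePhenotypes(co1, quickEffects(), seed = 5)
  ph2 <- simulatePhenotypes(co1, quickEffects(), seed = 5)
  expect_identical(ph1$value, ph2$value)
})

test_that("infinite admixture concentration degenerates to unit memberships", {
  cfg <- smallCohortConfig(popSizes = c(A = 10L, B = 10L),
                           admixAlphaSelf = Inf)
  co <- simulateCohort(cfg, 8)
  Q <- qMatrix(co$Q)
  expect_true(all(Q %in% c(0, 1)))
  expect_equal(unname(rowSums(Q)), rep(1, 20))
})

test_that("zero variances and effects give exactly the platform intercept", {
  co <- smallCohort(41)
  eff <- quickEffects(
    sigma2g = c(controlled = 0, semi_controlled = 0, field = 0),
    residual = c(controlled = 0, semi_controlled = 0, field = 0))
  eff$controlled$sigma2Chamber <- 0
  eff$controlled$yearEffect <- 0; eff$controlled$tempEffect <- 0
  ph <- simulatePhenotypes(co, eff, seed = 41, platforms = "controlled")
  expect_true(all(ph$value == eff$controlled$intercept))
})

test_that("identity-relatedness polygenic draws have the configured variance", {
  co <- smallCohort(42, smallCohortConfig(popSizes = c(A = 60L, B = 60L)))
  s2g <- 0.4
  eff <- quickEffects(sigma2g = c(controlled = s2g, semi_controlled = 0,
                                  field = 0),
                      residual = c(controlled = 1e-4, semi_controlled = 25,
                                   field = 25))
  eff$controlled$sigma2Chamber <- 0
  vars <- vapply(1:25, function(r) {
    ph <- simulatePhenotypes(co, eff, seed = 5000 + r,
                             platforms = "controlled",
                             relatedness = "identity")
    var(tapply(ph$value, ph$genotype_id, mean))
  }, numeric(1))
  mcse <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - s2g), 3 * mcse + 1e-6)
})

test_that("controlled design has genotypes x temps x replicates x years rows", {
  co <- smallCohort(43)
  eff <- quickEffects()
  ph <- simulatePhenotypes(co, eff, seed = 43, platforms = "controlled")
  nG <- ncol(co$truth$gametes)
  expect_equal(nrow(ph),
               nG * length(eff$controlled$temps) * eff$controlled$reps *
                 length(eff$controlled$years))
  # default design: 2 temperatures x 5 replicates x 2 years
  sc <- defaultScenario()
  expect_equal(length(sc$effects$controlled$temps) *
                 sc$effects$controlled$reps *
                 length(sc$effects$controlled$years), 20L)
})

test_that("semi-controlled and field designs follow their layouts", {
  co <- smallCohort(44)
  eff <- quickEffects()
  nG <- ncol(co$truth$gametes)
  ph <- simulatePhenotypes(co, eff, seed = 44,
                           platforms = c("semi_controlled", "field"))
  semi <- ph[ph$platform == "semi_controlled", ]
  expect_equal(nrow(semi), nG * 5L * eff$semi$reps)  # 3 + 2 month-years
  expect_equal(sort(unique(semi$month[semi$year == 2008])), c(1L, 2L, 4L))
  expect_equal(sort(unique(semi$month[semi$year == 2009])), c(2L, 3L))
  fld <- ph[ph$platform == "field", ]
  expect_equal(nrow(fld), nG * sum(eff$field$envReps))
  expect_equal(sort(unique(fld$environment)), sort(names(eff$field$envMeans)))
})

test_that("the default scenario keeps clipping below the monitor threshold", {
  sc <- defaultScenario()
  co <- simulateCohort(sc$cohort, 45)
  ph <- simulatePhenotypes(co, sc$effects, seed = 45)
  expect_true(all(attr(ph, "clipFraction") < 0.01))
  expect_true(all(ph$value[ph$platform == "controlled"] >= 0))
  expect_true(all(ph$value[ph$platform == "controlled"] <= 5))
  expect_true(all(ph$value[ph$platform != "controlled"] >= 0))
  expect_true(all(ph$value[ph$platform != "controlled"] <= 100))
})

test_that("effects referencing unknown sites are rejected", {
  co <- smallCohort(46)
  eff <- quickEffects(causal = data.frame(site = "nope_SNP1", controlled = 1,
                                          semi_controlled = 1, field = 1))
  expect_error(simulatePhenotypes(co, eff, seed = 46), "unknown site")
})

test_that("the private-site pattern concentrates the allele in one population", {
  sc <- defaultScenario()
  co <- simulateCohort(sc$cohort, 47)
  dos <- ryeassoc:::biallelicDosage(phaseGametes(co$s0, co$siteInfo))
  f <- tapply(dos["ScIce2_SNP7", ], co$populations, mean, na.rm = TRUE)
  expect_gt(f[["PR2733"]], 0.35)
  expect_true(all(f[setdiff(names(f), "PR2733")] < 0.25))
  expect_gt(f[["PR2733"]], 2 * max(f[setdiff(names(f), "PR2733")]))
})
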