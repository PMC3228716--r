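# Shared fixtures: small synthetic cohorts and random model specs, all
# built in code at test time.

smallGenes <- function(nGenes = 3L, sites = c(5L, 4L, 6L), pools = c(4L, 5L, 6L)) {
  data.frame(gene = paste0("g", seq_len(nGenes)),
             nSites = rep(sites, length.out = nGenes),
             nIndels = rep(c(1L, 0L), length.out = nGenes),
             poolSize = rep(pools, length.out = nGenes),
             stringsAsFactors = FALSE)
}

smallCohortConfig <- function(popSizes = c(A = 20L, B = 20L, C = 15L),
                              nSsrLoci = 12L, genes = smallGenes(), ...) {
  cohortConfig(popSizes = popSizes, nSsrLoci = nSsrLoci, genes = genes,
               privateSite = NULL, ...)
}

smallCohort <- function(seed = 7L, config = smallCohortConfig()) {
  simulateCohort(config, seed)
}

# reduced-replicate effects configuration for fast fits
quickEffects <- function(causal = NULL, ...) {
  args <- list(...)
  ctl <- list(intercept = 2.9, yearEffect = -0.45, tempEffect = -0.4,
              sigma2Chamber = 0.1, years = c(2008L, 2009L),
              temps = c(-19, -21), chambers = c(`2008` = 2L, `2009` = 2L),
              reps = 2L)
  sem <- list(intercept = 60, yearEffect = -4, trendSlope = -6,
              yearTrend = 2, sigma2Rep = 4, sigma2Int = 40, sigma2Trend = 4,
              corIntTrend = 0.3,
              months = list(`2008` = c(1L, 2L, 4L), `2009` = c(2L, 3L)),
              reps = 2L)
  fld <- list(envMeans = c(E1 = 55, E2 = 65), envReps = c(E1 = 2L, E2 = 2L),
              sigma2Block = 20)
  base <- list(controlled = ctl, semi = sem, field = fld)
  if (!is.null(causal)) base$causal <- causal
  do.call(effectsConfig, utils::modifyList(base, args))
}

# random small spec with iid + intercept-trend + kinship blocks
randomSmallSpec <- function(seed, n = 50L, nGroups = 4L, nUnits = 8L,
                            nGeno = 12L, withUs2 = TRUE) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), marker = rbinom(n, 1, 0.4))
  f1 <- factor(sample(seq_len(nGroups), n, TRUE))
  g <- factor(sample(sprintf("g%02d", seq_len(nGeno)), n, TRUE))
  K <- cov2cor(crossprod(matrix(rnorm(nlevels(g)^2), nlevels(g))) /
                 nlevels(g) + diag(nlevels(g)))
  dimnames(K) <- list(levels(g), levels(g))
  Zg <- stats::model.matrix(~ 0 + g); colnames(Zg) <- levels(g)
  blocks <- list(iidBlock(stats::model.matrix(~ 0 + f1), "grp"))
  if (withUs2) {
    f2 <- factor(sample(seq_len(nUnits), n, TRUE))
    tc <- rnorm(n)
    Zu <- stats::model.matrix(~ 0 + f2)
    blocks <- c(blocks, list(us2Block(Zu, Zu * tc, "unit")))
  }
  blocks <- c(blocks, list(kinshipBlock(Zg, K, "genotype")))
  y <- rnorm(n, X %*% c(1, 0.5, 0.3), 1)
  list(spec = lmmSpec(y, X, blocks), K = K)
}

randomVarcomp <- function(spec, seed) {
  set.seed(seed)
  vc <- list(residual = runif(1, 0.5, 2))
  for (b in spec$blocks) {
    vc[[b$label]] <- if (b$type == "us2")
      c(runif(1, 0.2, 2), runif(1, 0.2, 2), runif(1, -0.6, 0.6))
    else runif(1, 0.2, 2)
  }
  vc
}

# minimal LMMFit carrying just what varianceExplained() needs
fakeGenotypeFit <- function(s2g, y = c(1, 2, 3), method = "REML") {
  methods::new("LMMFit", method = method,
               varcomp = c(genotype = s2g, residual = 1),
               beta = c(`(Intercept)` = 0), se = c(`(Intercept)` = 1),
               tstat = c(`(Intercept)` = 0), pval = c(`(Intercept)` = 1),
               loglik = 0, n = length(y), p = 1L, y = y,
               xnames = "(Intercept)", diagnostics = list())
}

# independent brute-force oracle for the standardized similarity kinship
bruteForceKinship <- function(ssr, hetMode = "half") {
  a1 <- SummarizedExperiment::assay(ssr, "allele1")
  a2 <- SummarizedExperiment::assay(ssr, "allele2")
  nG <- ncol(a1)
  S <- matrix(NA_real_, nG, nG, dimnames = list(colnames(a1), colnames(a1)))
  for (i in seq_len(nG)) for (j in seq_len(nG)) {
    vals <- c();
    for (l in seq_len(nrow(a1))) {
      px <- c(a1[l, i], a2[l, i]); py <- c(a1[l, j], a2[l, j])
      if (anyNA(px) || anyNA(py)) next
      vals <- c(vals, similarityIndex(px, py, hetMode))
    }
    S[i, j] <- mean(vals)
  }
  sMin <- min(S[row(S) != col(S)])
  K <- (S - sMin) / (1 - sMin)
  diag(K) <- 1
  pmin(pmax(K, 0), 1)
}
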