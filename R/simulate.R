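# Synthetic cohorts with the statistical structure the analysis assumes:
# five source populations crossed to one common parent (gamete capture),
# SSR genotypes for kinship, candidate-gene sites with within-gene LD from
# finite haplotype pools, and multi-platform phenotypes generated from the
# same mixed model the scan fits.  Ground truth is stored for every
# estimand.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

stageSeed <- function(seed, stage) {
  offs <- c(cohort = 11L, phenotypes = 23L, kinship = 37L, scan = 53L)
  as.integer((as.numeric(seed) * 97L + offs[[stage]]) %% 2147483587)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

defaultGeneTable <- function() {
  data.frame(
    gene = c("ScCbf2", "ScCbf6", "ScCbf9b", "ScCbf11", "ScCbf12", "ScCbf14",
             "ScCbf15", "ScDhn1", "ScDhn3", "ScDreb2", "ScIce2", "ScVrn1"),
    nSites = c(12L, 8L, 20L, 10L, 18L, 7L, 14L, 6L, 9L, 11L, 37L, 18L),
    nIndels = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L),
    poolSize = c(5L, 4L, 8L, 5L, 8L, 4L, 6L, 4L, 5L, 5L, 7L, 6L),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic gamete-capture cohort
#'
#' Defaults reproduce the motivating study's design: five source
#' populations of 44/68/33/41/15 plants (201 genotypes) crossed to one
#' common parent, 37 SSR loci, and 12 candidate genes carrying 161 SNPs
#' plus 9 Indels (170 sites).  Within-gene linkage disequilibrium arises
#' from finite per-gene ancestral haplotype pools (4-8 pools); population
#' differentiation from population-specific pool frequencies and
#' Dirichlet-distributed admixture proportions.
#'
#' @param popSizes named integer vector of source-population sizes.
#' @param nSsrLoci number of SSR loci.
#' @param ssrAlleleCounts per-locus allele counts (recycled; default 4-8).
#' @param genes data.frame with columns \code{gene}, \code{nSites},
#'   \code{nIndels}, \code{poolSize}.
#' @param admixAlphaSelf,admixAlphaOther Dirichlet concentration on the
#'   own-population component and on each other component;
#'   \code{admixAlphaSelf = Inf} gives unadmixed unit membership rows.
#' @param poolDirichlet concentration of the per-population Dirichlet over
#'   haplotype pools.
#' @param privateSite optional list(gene, index, population, freqIn) that
#'   concentrates a site's non-reference allele in one population (the
#'   large-effect-site pattern of the study).
#' @return validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(popSizes = c(EKOAGRO = 44L, Petkus = 68L,
                                      PR2733 = 33L, ROM103 = 41L,
                                      SMH2502 = 15L),
                         nSsrLoci = 37L, ssrAlleleCounts = NULL,
                         genes = defaultGeneTable(),
                         admixAlphaSelf = 12, admixAlphaOther = 0.5,
                         poolDirichlet = 3,
                         privateSite = list(gene = "ScIce2", index = 7L,
                                            population = "PR2733",
                                            freqIn = 0.55, freqOut = 0.06)) {
  stopifnot(all(popSizes > 0), nSsrLoci >= 1L, nrow(genes) >= 1L,
            all(genes$nSites >= 1L), all(genes$nIndels <= genes$nSites),
            all(genes$poolSize >= 2L), admixAlphaOther > 0)
  if (is.null(names(popSizes)))
    names(popSizes) <- paste0("Pop", seq_along(popSizes))
  if (is.null(ssrAlleleCounts))
    ssrAlleleCounts <- rep(4:8, length.out = nSsrLoci)
  ssrAlleleCounts <- rep(ssrAlleleCounts, length.out = nSsrLoci)
  if (!is.null(privateSite) &&
      !(privateSite$gene %in% genes$gene &&
        privateSite$population %in% names(popSizes)))
    privateSite <- NULL
  structure(list(popSizes = popSizes, nSsrLoci = nSsrLoci,
                 ssrAlleleCounts = ssrAlleleCounts, genes = genes,
                 admixAlphaSelf = admixAlphaSelf,
                 admixAlphaOther = admixAlphaOther,
                 poolDirichlet = poolDirichlet, privateSite = privateSite),
            class = "cohortConfig")
}

#' Simulate a gamete-capture cohort
#'
#' Per gene, an ancestral haplotype pool is built (pool 1 is always the
#' common parent's allele string; the non-reference allele at each site is
#' carried by one to two thirds of the remaining pools, keeping realized
#' minor-allele frequencies comfortably above the 5\% scan filter).  Each
#' genotype draws admixture proportions from a population-specific
#' Dirichlet; for each gene it draws one ancestry component and then one
#' pool haplotype from that component's pool-frequency vector, and its S0
#' call is the sampled gamete plus the parent allele.  SSR genotypes are
#' drawn analogously from ancestry-specific allele frequencies, again with
#' the parent contributing one allele.  Deterministic given the seed.
#'
#' @param config [cohortConfig()].
#' @param seed integer seed.
#' @return list with \code{ssr} ([SsrGenotypes-class]), \code{s0} (list of
#'   diploid allele matrices), \code{siteInfo} (site metadata incl. the
#'   common-parent \code{ref_allele}), \code{Q}
#'   ([StructureMatrix-class], the true admixture), \code{populations}
#'   (named factor) and \code{truth} (gamete matrix, pool assignments,
#'   pools, pool frequencies).
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "cohortConfig"))
  withSeed(stageSeed(seed, "cohort"), {
    pops <- names(config$popSizes)
    nPop <- length(pops)
    ids <- sprintf("G%03d", seq_len(sum(config$popSizes)))
    popOf <- factor(rep(pops, config$popSizes), levels = pops)
    names(popOf) <- ids
    nG <- length(ids)

    # true admixture proportions
    Q <- t(vapply(seq_len(nG), function(i) {
      if (is.infinite(config$admixAlphaSelf)) {
        q <- numeric(nPop); q[as.integer(popOf[i])] <- 1; q
      } else {
        a <- rep(config$admixAlphaOther, nPop)
        a[as.integer(popOf[i])] <- config$admixAlphaSelf
        rdirichlet1(a)
      }
    }, numeric(nPop)))
    dimnames(Q) <- list(ids, pops)

    # candidate-gene haplotype pools
    genes <- config$genes
    siteInfo <- NULL
    gametes <- NULL
    poolAssign <- matrix(NA_integer_, nG, nrow(genes),
                         dimnames = list(ids, genes$gene))
    pools <- list(); poolFreqs <- list()
    bases <- c("A", "C", "G", "T")
    for (gi in seq_len(nrow(genes))) {
      gname <- genes$gene[gi]; s <- genes$nSites[gi]; H <- genes$poolSize[gi]
      type <- rep("SNP", s)
      if (genes$nIndels[gi] > 0L) type[s] <- "Indel"   # last site(s) are Indels
      if (genes$nIndels[gi] > 1L)
        type[seq(s - genes$nIndels[gi] + 1L, s)] <- "Indel"
      ref <- ifelse(type == "SNP", sample(bases, s, replace = TRUE),
                    sample(c("+", "-"), s, replace = TRUE))
      alt <- vapply(seq_len(s), function(j) {
        if (type[j] == "SNP") sample(setdiff(bases, ref[j]), 1L)
        else setdiff(c("+", "-"), ref[j])
      }, character(1))
      # pool x site carrier matrix; pool 1 is the parent string
      carry <- matrix(FALSE, H, s)
      lo <- max(1L, ceiling((H - 1L) / 3)); hi <- max(lo, floor(2 * (H - 1L) / 3))
      for (j in seq_len(s)) {
        m <- if (lo == hi) lo else sample(lo:hi, 1L)
        carry[1L + sample.int(H - 1L, m), j] <- TRUE
      }
      Fp <- t(vapply(pops, function(p)
        rdirichlet1(rep(config$poolDirichlet, H)), numeric(H)))
      rownames(Fp) <- pops
      ps <- config$privateSite
      if (!is.null(ps) && ps$gene == gname && ps$index <= s) {
        # concentrate the non-reference allele in one population: dedicate
        # two carrier pools and reallocate each population's pool
        # frequencies so the focal population draws them with probability
        # freqIn and every other population with probability freqOut
        focal <- ps$population
        freqOut <- if (is.null(ps$freqOut)) 0.06 else ps$freqOut
        margin <- Fp[focal, ] - colMeans(Fp[setdiff(pops, focal), , drop = FALSE])
        carriers <- setdiff(order(margin, decreasing = TRUE), 1L)[1:2]
        rest <- setdiff(seq_len(H), carriers)
        for (p in pops) {
          target <- if (p == focal) ps$freqIn else freqOut
          Fp[p, carriers] <- target * Fp[p, carriers] / sum(Fp[p, carriers])
          Fp[p, rest] <- (1 - target) * Fp[p, rest] / sum(Fp[p, rest])
        }
        carry[, ps$index] <- FALSE
        carry[carriers, ps$index] <- TRUE
      }
      hapStrings <- apply(carry, 1L, function(cr)
        paste(ifelse(cr, alt, ref), collapse = ""))
      # draw per-genotype ancestry component and pool haplotype
      anc <- vapply(seq_len(nG), function(i)
        sample.int(nPop, 1L, prob = Q[i, ]), integer(1))
      hap <- vapply(seq_len(nG), function(i)
        sample.int(H, 1L, prob = Fp[anc[i], ]), integer(1))
      poolAssign[, gi] <- hap
      gm <- t(ifelse(carry[hap, , drop = FALSE],
                     matrix(alt, nG, s, byrow = TRUE),
                     matrix(ref, nG, s, byrow = TRUE)))
      siteIds <- paste0(gname, "_SNP", seq_len(s))
      rownames(gm) <- siteIds; colnames(gm) <- ids
      gametes <- rbind(gametes, gm)
      siteInfo <- rbind(siteInfo, data.frame(
        site_id = siteIds, gene_id = gname, site_index = seq_len(s),
        site_type = type, ref_allele = ref, stringsAsFactors = FALSE))
      pools[[gname]] <- hapStrings
      poolFreqs[[gname]] <- Fp
    }
    rownames(siteInfo) <- siteInfo$site_id

    # S0 diploid calls: sampled gamete + common-parent allele
    refM <- matrix(siteInfo$ref_allele, nrow(gametes), nG)
    a1 <- pmin(gametes, refM); a2 <- pmax(gametes, refM)
    dimnames(a1) <- dimnames(a2) <- dimnames(gametes)

    # SSR genotypes (population gamete + parent allele)
    lociIds <- sprintf("SSR%02d", seq_len(config$nSsrLoci))
    sa1 <- matrix(NA_character_, config$nSsrLoci, nG,
                  dimnames = list(lociIds, ids))
    sa2 <- sa1
    for (l in seq_len(config$nSsrLoci)) {
      nAll <- config$ssrAlleleCounts[l]
      alleles <- as.character(100L + 2L * seq_len(nAll))
      Fl <- t(vapply(pops, function(p) rdirichlet1(rep(1.5, nAll)),
                     numeric(nAll)))
      parent <- alleles[1L]
      anc <- vapply(seq_len(nG), function(i)
        sample.int(nPop, 1L, prob = Q[i, ]), integer(1))
      gam <- alleles[vapply(seq_len(nG), function(i)
        sample.int(nAll, 1L, prob = Fl[anc[i], ]), integer(1))]
      sa1[l, ] <- pmin(gam, parent); sa2[l, ] <- pmax(gam, parent)
    }

    list(ssr = SsrGenotypes(sa1, sa2),
         s0 = list(allele1 = a1, allele2 = a2),
         siteInfo = siteInfo[, c("site_id", "gene_id", "site_index",
                                 "site_type", "ref_allele")],
         Q = StructureMatrix(Q),
         populations = popOf,
         truth = list(gametes = gametes, poolAssign = poolAssign,
                      pools = pools, poolFreqs = poolFreqs, trueQ = Q,
                      seed = seed))
  })
}

#' Configuration of simulated multi-platform phenotypes
#'
#' Phenotypes are generated from exactly the model the association scan
#' fits: platform fixed effects, causal allelic effects on the gamete
#' dosage, a kinship-structured polygenic genotype effect, the platform's
#' random-effect structure and iid Gaussian residuals, with outcomes
#' clipped to their scales (recovery score [0, 5], percentages [0, 100]).
#'
#' @param causal data.frame with columns \code{site}, \code{controlled},
#'   \code{semi_controlled}, \code{field}: allelic effect of the
#'   non-reference allele, in outcome units per platform.
#' @param sigma2g,residual named per-platform variances of the polygenic
#'   genotype effect and the residual.
#' @param controlled,semi,field platform design/effect lists (see
#'   defaults for the fields).
#' @param structureEffects optional list of per-platform numeric vectors
#'   (one entry per ancestry component): genotype-level fixed shifts
#'   Q \%*\% delta that confound phenotype with population structure.
#' @param interaction optional epistatic effect: list(geneA, poolA, geneB,
#'   poolB, controlled, semi_controlled, field); added when a genotype's
#'   pool assignment matches at both genes.
#' @return list of class \code{"effectsConfig"}.
#' @export
effectsConfig <- function(
    causal = data.frame(site = character(), controlled = numeric(),
                        semi_controlled = numeric(), field = numeric()),
    sigma2g = c(controlled = 0.25, semi_controlled = 30, field = 60),
    residual = c(controlled = 0.3, semi_controlled = 25, field = 64),
    controlled = list(intercept = 2.9, yearEffect = -0.45, tempEffect = -0.4,
                      sigma2Chamber = 0.1, years = c(2008L, 2009L),
                      temps = c(-19, -21), chambers = c(`2008` = 3L, `2009` = 4L),
                      reps = 5L),
    semi = list(intercept = 60, yearEffect = -4, trendSlope = -6,
                yearTrend = 2, sigma2Rep = 4, sigma2Int = 40,
                sigma2Trend = 4, corIntTrend = 0.3,
                months = list(`2008` = c(1L, 2L, 4L), `2009` = c(2L, 3L)),
                reps = 3L),
    field = list(envMeans = c(KAS = 55, LIP1 = 60, MIN = 65, SAS1 = 75,
                              SAS2 = 40, LIP2 = 60),
                 envReps = c(KAS = 3L, LIP1 = 3L, MIN = 3L, SAS1 = 2L,
                             SAS2 = 2L, LIP2 = 3L),
                 sigma2Block = 30),
    structureEffects = NULL,
    interaction = NULL) {
  stopifnot(all(sigma2g >= 0), all(residual >= 0),
            controlled$sigma2Chamber >= 0, semi$sigma2Rep >= 0,
            semi$sigma2Int >= 0, semi$sigma2Trend >= 0,
            abs(semi$corIntTrend) <= 1, field$sigma2Block >= 0,
            identical(names(field$envMeans), names(field$envReps)))
  structure(list(causal = causal, sigma2g = sigma2g, residual = residual,
                 controlled = controlled, semi = semi, field = field,
                 structureEffects = structureEffects,
                 interaction = interaction),
            class = "effectsConfig")
}

#' The default study-mimicking scenario
#'
#' Cohort defaults as in [cohortConfig()] (201 genotypes, five
#' populations, 170 sites) plus an effects configuration with three
#' modest-effect causal sites in two Cbf-family genes (two in ScCbf15, one
#' in ScCbf12, the non-synonymous-style pattern) and one large positive
#' field effect at ScIce2 site 7, whose non-reference allele the cohort
#' generator concentrates in the PR2733 population.
#'
#' @return list with elements \code{cohort} and \code{effects}.
#' @export
defaultScenario <- function() {
  # Marginal (LD-stacked) effects stay inside the study's reported allelic
  # effect ranges per platform, and the ScIce2 site 7 effect is the
  # largest positive field effect (its printed value, 4.3)
  causal <- data.frame(
    site = c("ScCbf15_SNP3", "ScCbf15_SNP9", "ScCbf12_SNP5", "ScIce2_SNP7"),
    controlled = c(0.18, 0.15, 0.15, 0.30),
    semi_controlled = c(1.2, 0.9, 0.8, 1.5),
    field = c(1.5, 1.0, 1.5, 4.3),
    stringsAsFactors = FALSE)
  list(cohort = cohortConfig(), effects = effectsConfig(causal = causal))
}

#' Simulate multi-platform phenotypes for a cohort
#'
#' @param cohort result of [simulateCohort()].
#' @param effects [effectsConfig()].
#' @param seed integer seed.
#' @param platforms subset of platforms to generate.
#' @param relatedness covariance of the polygenic draw:
#'   \code{"ssr"} (default; the kinship matrix estimated from the cohort's
#'   own SSRs, self-consistent with the analysis), \code{"identity"}, or a
#'   [KinshipMatrix-class] supplied via \code{K}.
#' @param K optional precomputed kinship matrix.
#' @return long-format phenotype data.frame (see [validatePhenotypes()]);
#'   attributes \code{clipFraction} (named per platform) and \code{truth}
#'   (realized polygenic values and random effects).
#' @export
simulatePhenotypes <- function(cohort, effects = effectsConfig(), seed = 1L,
                               platforms = c("controlled", "semi_controlled",
                                             "field"),
                               relatedness = c("ssr", "identity"), K = NULL) {
  stopifnot(inherits(effects, "effectsConfig"))
  platforms <- match.arg(platforms, several.ok = TRUE)
  relatedness <- if (is.null(K)) match.arg(relatedness) else "supplied"
  ids <- colnames(cohort$truth$gametes)
  nG <- length(ids)
  if (nrow(effects$causal)) {
    unknown <- setdiff(effects$causal$site, rownames(cohort$truth$gametes))
    if (length(unknown))
      stop("causal effect references unknown site(s): ",
           paste(unknown, collapse = ", "))
  }
  Km <- if (!is.null(K)) kinship(K)
        else if (relatedness == "identity") diag(nG)
        else kinship(kinshipMatrix(cohort$ssr))
  L <- covarianceRoot(Km)

  # 0/1 dosage of the non-reference allele at the causal sites
  dosage <- function(site) {
    as.numeric(cohort$truth$gametes[site, ] !=
                 cohort$siteInfo[site, "ref_allele"])
  }
  geneticValue <- function(platform) {
    gv <- numeric(nG)
    for (i in seq_len(nrow(effects$causal)))
      gv <- gv + effects$causal[[platform]][i] * dosage(effects$causal$site[i])
    if (!is.null(effects$interaction)) {
      ia <- effects$interaction
      hit <- cohort$truth$poolAssign[, ia$geneA] == ia$poolA &
             cohort$truth$poolAssign[, ia$geneB] == ia$poolB
      gv <- gv + ia[[platform]] * as.numeric(hit)
    }
    if (!is.null(effects$structureEffects) &&
        !is.null(effects$structureEffects[[platform]]))
      gv <- gv + as.numeric(qMatrix(cohort$Q) %*%
                              effects$structureEffects[[platform]])
    gv
  }

  withSeed(stageSeed(seed, "phenotypes"), {
    g0 <- as.numeric(L %*% stats::rnorm(nG))   # shared standardized polygenic
    rows <- list(); truthRE <- list(); clip <- c()

    if ("controlled" %in% platforms) {
      cf <- effects$controlled
      poly <- sqrt(effects$sigma2g[["controlled"]]) * g0
      gv <- geneticValue("controlled") + poly
      chamberLabels <- unlist(lapply(names(cf$chambers), function(yr)
        paste0(yr, "_c", seq_len(cf$chambers[[yr]]))))
      chamberEff <- stats::setNames(
        stats::rnorm(length(chamberLabels), 0, sqrt(cf$sigma2Chamber)),
        chamberLabels)
      df <- expand.grid(genotype_id = ids, year = cf$years,
                        temperature = cf$temps, replicate = seq_len(cf$reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      df$chamber <- vapply(df$year, function(yr) {
        ch <- chamberLabels[startsWith(chamberLabels, as.character(yr))]
        ch[sample.int(length(ch), 1L)]
      }, character(1))
      mu <- cf$intercept + cf$yearEffect * (df$year == max(cf$years)) +
        cf$tempEffect * (df$temperature == min(cf$temps)) +
        gv[match(df$genotype_id, ids)] + chamberEff[df$chamber] +
        stats::rnorm(nrow(df), 0, sqrt(effects$residual[["controlled"]]))
      val <- pmin(pmax(mu, 0), 5)
      clip["controlled"] <- mean(val != mu)
      rows$controlled <- data.frame(
        genotype_id = df$genotype_id, platform = "controlled",
        year = df$year, environment = NA_character_,
        temperature = df$temperature, month = NA_integer_,
        chamber = df$chamber, replicate = as.character(df$replicate),
        block = NA_character_, value = val, stringsAsFactors = FALSE)
      truthRE$controlled <- list(polygenic = poly, chamber = chamberEff)
    }

    if ("semi_controlled" %in% platforms) {
      sf <- effects$semi
      poly <- sqrt(effects$sigma2g[["semi_controlled"]]) * g0
      gv <- geneticValue("semi_controlled") + poly
      years <- as.integer(names(sf$months))
      repLabels <- as.vector(outer(years, seq_len(sf$reps), paste, sep = "_r"))
      repEff <- stats::setNames(
        stats::rnorm(length(repLabels), 0, sqrt(sf$sigma2Rep)), repLabels)
      # per-unit correlated intercept/trend (unit = genotype x year)
      cv <- sf$corIntTrend * sqrt(sf$sigma2Int * sf$sigma2Trend)
      Sig <- matrix(c(sf$sigma2Int, cv, cv, sf$sigma2Trend), 2L)
      Tchol <- if (all(Sig == 0)) matrix(0, 2L, 2L) else t(chol(Sig + diag(1e-12, 2L)))
      units <- expand.grid(genotype_id = ids, year = years,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      ub <- t(Tchol %*% matrix(stats::rnorm(2L * nrow(units)), 2L))
      df <- do.call(rbind, lapply(seq_along(years), function(k) {
        expand.grid(genotype_id = ids, year = years[k],
                    month = sf$months[[k]], replicate = seq_len(sf$reps),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      }))
      uidx <- match(paste(df$genotype_id, df$year),
                    paste(units$genotype_id, units$year))
      tc <- df$month - vapply(df$year, function(yr)
        mean(sf$months[[as.character(yr)]]), numeric(1))
      isY2 <- df$year == max(years)
      mu <- sf$intercept + sf$yearEffect * isY2 + sf$trendSlope * tc +
        sf$yearTrend * isY2 * tc +
        repEff[paste0(df$year, "_r", df$replicate)] +
        ub[uidx, 1L] + ub[uidx, 2L] * tc +
        gv[match(df$genotype_id, ids)] +
        stats::rnorm(nrow(df), 0, sqrt(effects$residual[["semi_controlled"]]))
      val <- pmin(pmax(mu, 0), 100)
      clip["semi_controlled"] <- mean(val != mu)
      rows$semi_controlled <- data.frame(
        genotype_id = df$genotype_id, platform = "semi_controlled",
        year = df$year, environment = NA_character_,
        temperature = NA_real_, month = df$month,
        chamber = NA_character_, replicate = as.character(df$replicate),
        block = NA_character_, value = val, stringsAsFactors = FALSE)
      truthRE$semi_controlled <- list(polygenic = poly, rep = repEff,
                                      unit = ub)
    }

    if ("field" %in% platforms) {
      ff <- effects$field
      poly <- sqrt(effects$sigma2g[["field"]]) * g0
      gv <- geneticValue("field") + poly
      envs <- names(ff$envMeans)
      blockLabels <- unlist(lapply(envs, function(e)
        paste0(e, "_b", seq_len(ff$envReps[[e]]))))
      blockEff <- stats::setNames(
        stats::rnorm(length(blockLabels), 0, sqrt(ff$sigma2Block)),
        blockLabels)
      df <- do.call(rbind, lapply(envs, function(e) {
        expand.grid(genotype_id = ids, environment = e,
                    replicate = seq_len(ff$envReps[[e]]),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      }))
      df$block <- paste0(df$environment, "_b", df$replicate)
      mu <- ff$envMeans[df$environment] + blockEff[df$block] +
        gv[match(df$genotype_id, ids)] +
        stats::rnorm(nrow(df), 0, sqrt(effects$residual[["field"]]))
      val <- pmin(pmax(mu, 0), 100)
      clip["field"] <- mean(val != mu)
      rows$field <- data.frame(
        genotype_id = df$genotype_id, platform = "field",
        year = NA_integer_, environment = df$environment,
        temperature = NA_real_, month = NA_integer_,
        chamber = NA_character_, replicate = as.character(df$replicate),
        block = df$block, value = val, stringsAsFactors = FALSE)
      truthRE$field <- list(polygenic = poly, block = blockEff)
    }

    out <- validatePhenotypes(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    attr(out, "clipFraction") <- clip
    attr(out, "truth") <- c(truthRE, list(g0 = g0, relatedness = relatedness))
    out
  })
}
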