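# Association scans: single-site Q+K scan, within-gene haplotype tests,
# gene x gene epistasis LRTs, cross-platform concordance and significance
# summaries.

emptyScanRow <- function(unit, gene, platform, n = NA_integer_) {
  data.frame(unit = unit, gene = gene, platform = platform,
             beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
             var_explained_pct = NA_real_, n = n, converged = FALSE,
             stringsAsFactors = FALSE)
}

#' Single-site association scan
#'
#' For every site in the (MAF-filtered, phased) marker panel, fits the
#' platform's Q+K mixed model with the site's 0/1 non-reference-allele
#' indicator as a fixed effect, and reports the allelic effect, its Wald
#' t statistic and two-sided P, and the percent genetic variance explained
#' relative to the same model without the site.  Sites are tested one at a
#' time (single-marker models) on complete cases; per-site failures are
#' flagged and the scan continues.
#'
#' Setting \code{correct = FALSE} omits both the structure covariates and
#' the kinship-structured genotype block (the "naive" scan used as a
#' confounding positive control); variance explained is then undefined.
#'
#' @param phenotypes long-format phenotype data.frame.
#' @param markers phased [MarkerPanel-class] (apply [filterMAF()] first).
#' @param Q [StructureMatrix-class].
#' @param K [KinshipMatrix-class].
#' @param platform platform name.
#' @param alpha significance level recorded with the results.
#' @param correct include the Q and K corrections (default TRUE).
#' @param trendCoding see [platformModel()].
#' @param pReference see [fitLMM()].
#' @return [ScanResults-class] (kind \code{"snp"}).
#' @export
snpScan <- function(phenotypes, markers, Q, K, platform, alpha = 0.05,
                    correct = TRUE, trendCoding = "calendar",
                    pReference = "normal") {
  dos <- biallelicDosage(markers)
  info <- siteInfo(markers)
  spec0 <- platformModel(platform, phenotypes, Q = if (correct) Q else NULL,
                         K = if (correct) K else NULL,
                         includeQ = correct, includeGenotype = correct,
                         trendCoding = trendCoding)
  eng0 <- makeEngine(spec0)
  fit0 <- fitEngine(eng0, "REML", pReference = pReference)
  theta0 <- fit0@diagnostics$theta
  gid <- phenotypes$genotype_id[attr(spec0, "rows")]
  rows <- vector("list", nrow(dos))
  for (i in seq_len(nrow(dos))) {
    site <- rownames(dos)[i]
    gene <- info$gene_id[i]
    rows[[i]] <- tryCatch({
      m <- dos[i, gid]
      if (anyNA(dos[i, unique(gid)])) {
        # complete-case refit on the site's rows (rare path)
        spec <- platformModel(platform, phenotypes,
                              Q = if (correct) Q else NULL,
                              K = if (correct) K else NULL,
                              marker = dos[i, ], includeQ = correct,
                              includeGenotype = correct,
                              trendCoding = trendCoding)
        fit <- fitLMM(spec, "REML", start = theta0, nStarts = 1L,
                      pReference = pReference)
        spec0s <- platformModel(platform,
                                phenotypes[attr(spec, "rows"), , drop = FALSE],
                                Q = if (correct) Q else NULL,
                                K = if (correct) K else NULL,
                                includeQ = correct,
                                includeGenotype = correct,
                                trendCoding = trendCoding)
        fit0s <- fitLMM(spec0s, "REML", start = theta0, nStarts = 1L,
                        pReference = pReference)
        nUsed <- fit@n
      } else {
        eng <- engineWithColumn(eng0, m, "marker")
        fit <- fitEngine(eng, "REML", start = theta0, nStarts = 1L,
                         pReference = pReference)
        fit0s <- fit0
        nUsed <- eng$n
      }
      w <- waldTest(fit, "marker", pReference = pReference)
      ve <- if (correct) as.numeric(varianceExplained(fit0s, fit)) else NA_real_
      data.frame(unit = site, gene = gene, platform = platform,
                 beta = w$estimate, se = w$se, t = w$t, p = w$p,
                 var_explained_pct = ve, n = nUsed, converged = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("snpScan: site ", site, " failed: ", conditionMessage(e))
      emptyScanRow(site, gene, platform)
    })
  }
  out <- methods::new("ScanResults", table = do.call(rbind, rows),
                      kind = "snp")
  out
}

hapIndicatorMatrix <- function(hs, labels) {
  assign <- haploAssignment(hs)
  mk <- matrix(NA_real_, length(assign), length(labels),
               dimnames = list(names(assign),
                               paste0(haploGene(hs), ".", labels)))
  obs <- !is.na(assign)
  for (j in seq_along(labels)) mk[obs, j] <- as.numeric(assign[obs] == labels[j])
  mk
}

#' Within-gene haplotype association tests
#'
#' Per gene: the overall test compares, by an ML likelihood-ratio test,
#' the platform model containing an indicator for every retained
#' non-reference haplotype against the model with none.  Individual
#' haplotype effects are then contrasted against the common-parent
#' reference haplotype with Wald tests from the REML fit (all contrasts
#' are reported; \code{overall_significant} flags whether the overall test
#' passed \code{alpha}).  Haplotypes are frequency-filtered first
#' (strictly > \code{maf}); genotypes carrying removed rare haplotypes are
#' missing for the gene, and genes retaining at most the reference (or
#' losing the reference itself) are skipped.
#'
#' @param phenotypes,Q,K,platform,alpha,trendCoding,pReference as in
#'   [snpScan()].
#' @param haplotypes list of [HaplotypeSet-class] objects (one per gene),
#'   e.g. from [defineHaplotypes()].
#' @param maf haplotype frequency threshold (default 0.05).
#' @return [ScanResults-class] (kind \code{"haplotype"}): one
#'   \code{<gene>:overall} row per tested gene (LRT P, overall variance
#'   explained, missingness fraction) plus one row per haplotype contrast.
#' @export
haplotypeScan <- function(phenotypes, haplotypes, Q, K, platform,
                          alpha = 0.05, maf = 0.05, trendCoding = "calendar",
                          pReference = "normal") {
  if (methods::is(haplotypes, "HaplotypeSet")) haplotypes <- list(haplotypes)
  nullTh <- tryCatch(
    fitLMM(platformModel(platform, phenotypes, Q, K,
                         trendCoding = trendCoding), "ML")@diagnostics$theta,
    error = function(e) NULL)
  nWarm <- if (is.null(nullTh)) 3L else 1L
  rows <- list()
  for (hs in haplotypes) {
    gene <- haploGene(hs)
    hsF <- filterMAF(hs, maf)
    retained <- names(haploFreq(hsF))
    nonref <- setdiff(retained, "ref")
    if (!"ref" %in% retained || !length(nonref)) {
      message("haplotypeScan: ", gene,
              " has <= 1 retained haplotype; excluded")
      next
    }
    res <- tryCatch({
      assign <- haploAssignment(hsF)
      missFrac <- mean(is.na(assign))
      okIds <- names(assign)[!is.na(assign)]
      phSub <- phenotypes[!(phenotypes$platform == platform &
                              !phenotypes$genotype_id %in% okIds), ,
                          drop = FALSE]
      mk <- hapIndicatorMatrix(hsF, nonref)[okIds, , drop = FALSE]
      specFull <- platformModel(platform, phSub, Q, K, marker = mk,
                                trendCoding = trendCoding)
      specRed <- platformModel(platform, phSub, Q, K,
                               trendCoding = trendCoding)
      fullML <- fitLMM(specFull, "ML", start = nullTh, nStarts = nWarm)
      redML <- fitLMM(specRed, "ML", start = fullML@diagnostics$theta,
                      nStarts = 1L)
      hapCols <- intersect(colnames(mk), fullML@xnames)
      overall <- lrt(fullML, redML, df = length(hapCols))
      fullREML <- fitLMM(specFull, "REML",
                         start = fullML@diagnostics$theta, nStarts = 1L)
      redREML <- fitLMM(specRed, "REML", start = redML@diagnostics$theta,
                        nStarts = 1L)
      ve <- as.numeric(varianceExplained(redREML, fullREML))
      out <- data.frame(unit = paste0(gene, ":overall"), gene = gene,
                        platform = platform, haplotype = "overall",
                        beta = NA_real_, se = NA_real_, t = NA_real_,
                        p = overall$p, df = overall$df,
                        var_explained_pct = ve,
                        freq = NA_real_, missing_frac = missFrac,
                        n = fullML@n,
                        overall_significant = overall$p < alpha,
                        converged = TRUE, stringsAsFactors = FALSE)
      for (lab in nonref) {
        cn <- paste0(gene, ".", lab)
        if (!cn %in% fullREML@xnames) next
        w <- waldTest(fullREML, cn, pReference = pReference)
        out <- rbind(out, data.frame(
          unit = paste0(gene, ":", lab), gene = gene, platform = platform,
          haplotype = lab, beta = w$estimate, se = w$se, t = w$t, p = w$p,
          df = 1L, var_explained_pct = NA_real_,
          freq = unname(haploFreq(hsF)[lab]), missing_frac = missFrac,
          n = fullREML@n, overall_significant = overall$p < alpha,
          converged = TRUE, stringsAsFactors = FALSE))
      }
      out
    }, error = function(e) {
      message("haplotypeScan: gene ", gene, " failed: ", conditionMessage(e))
      cbind(emptyScanRow(paste0(gene, ":overall"), gene, platform),
            haplotype = "overall", df = NA_integer_, freq = NA_real_,
            missing_frac = NA_real_, overall_significant = NA)
    })
    rows[[gene]] <- res
  }
  tb <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else emptyScanRow(character(0), character(0), character(0))[0, ]
  methods::new("ScanResults", table = tb, kind = "haplotype")
}

#' Gene-by-gene epistasis scan
#'
#' For each gene pair, compares by an ML likelihood-ratio test the model
#' with both genes' haplotype main-effect indicators plus all pairwise
#' interaction indicators against the main-effects-only model, on
#' complete cases over both genes.  Aliased interaction columns are
#' pruned and the LRT degrees of freedom equal the number of estimable
#' interaction columns; pairs with none are skipped.
#'
#' @param phenotypes,haplotypes,Q,K,platform,maf,trendCoding as in
#'   [haplotypeScan()].
#' @param genePairs optional 2-column matrix (or list of 2-vectors) of
#'   gene names; default all pairs of genes passing the haplotype filter.
#' @return [ScanResults-class] (kind \code{"epistasis"}).
#' @export
epistasisScan <- function(phenotypes, haplotypes, Q, K, platform,
                          genePairs = NULL, maf = 0.05,
                          trendCoding = "calendar") {
  if (methods::is(haplotypes, "HaplotypeSet")) haplotypes <- list(haplotypes)
  names(haplotypes) <- vapply(haplotypes, haploGene, character(1))
  filtered <- lapply(haplotypes, filterMAF, threshold = maf)
  usable <- names(filtered)[vapply(filtered, function(h) {
    r <- names(haploFreq(h)); "ref" %in% r && length(r) >= 2L
  }, logical(1))]
  if (is.null(genePairs)) {
    if (length(usable) < 2L)
      return(methods::new("ScanResults", table = emptyScanRow(character(0),
             character(0), character(0))[0, ], kind = "epistasis"))
    genePairs <- t(utils::combn(usable, 2L))
  } else if (is.list(genePairs)) genePairs <- do.call(rbind, genePairs)
  nullTh <- tryCatch(
    fitLMM(platformModel(platform, phenotypes, Q, K,
                         trendCoding = trendCoding), "ML")@diagnostics$theta,
    error = function(e) NULL)
  nWarm <- if (is.null(nullTh)) 3L else 1L
  rows <- list()
  for (k in seq_len(nrow(genePairs))) {
    ga <- genePairs[k, 1L]; gb <- genePairs[k, 2L]
    unit <- paste0(ga, ":", gb)
    if (!all(c(ga, gb) %in% usable)) {
      message("epistasisScan: pair ", unit, " skipped (gene filtered out)")
      next
    }
    rows[[unit]] <- tryCatch({
      ha <- filtered[[ga]]; hb <- filtered[[gb]]
      aa <- haploAssignment(ha); ab <- haploAssignment(hb)
      okIds <- names(aa)[!is.na(aa) & !is.na(ab[names(aa)])]
      phSub <- phenotypes[!(phenotypes$platform == platform &
                              !phenotypes$genotype_id %in% okIds), ,
                          drop = FALSE]
      mkA <- hapIndicatorMatrix(ha, setdiff(names(haploFreq(ha)), "ref"))[okIds, , drop = FALSE]
      mkB <- hapIndicatorMatrix(hb, setdiff(names(haploFreq(hb)), "ref"))[okIds, , drop = FALSE]
      interCols <- list()
      for (a in colnames(mkA)) for (b in colnames(mkB))
        interCols[[paste0(a, ":", b)]] <- mkA[, a] * mkB[, b]
      inter <- do.call(cbind, interCols)
      rownames(inter) <- okIds
      specFull <- platformModel(platform, phSub, Q, K,
                                marker = cbind(mkA, mkB, inter),
                                trendCoding = trendCoding)
      specRed <- platformModel(platform, phSub, Q, K,
                               marker = cbind(mkA, mkB),
                               trendCoding = trendCoding)
      fullML <- fitLMM(specFull, "ML", start = nullTh, nStarts = nWarm)
      redML <- fitLMM(specRed, "ML", start = fullML@diagnostics$theta,
                      nStarts = 1L)
      # estimable interaction columns relative to the reduced design
      dfI <- fullML@p - redML@p
      if (dfI < 1L) stop("interaction design fully collinear")
      test <- lrt(fullML, redML, df = dfI)
      data.frame(unit = unit, gene = ga, gene2 = gb, platform = platform,
                 statistic = test$statistic, df = dfI, p = test$p,
                 n = fullML@n, converged = TRUE, stringsAsFactors = FALSE)
    }, error = function(e) {
      message("epistasisScan: pair ", unit, " failed: ", conditionMessage(e))
      data.frame(unit = unit, gene = ga, gene2 = gb, platform = platform,
                 statistic = NA_real_, df = NA_integer_, p = NA_real_,
                 n = NA_integer_, converged = FALSE, stringsAsFactors = FALSE)
    })
  }
  tb <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else data.frame(unit = character(0), gene = character(0),
                        gene2 = character(0), platform = character(0),
                        statistic = numeric(0), df = integer(0),
                        p = numeric(0), n = integer(0),
                        converged = logical(0), stringsAsFactors = FALSE)
  methods::new("ScanResults", table = tb, kind = "epistasis")
}

#' Cross-platform concordance of association results
#'
#' Pearson correlation of the per-unit t values between each pair of
#' platforms, over all units tested in both or restricted to units
#' significant (P < \code{alpha}) in at least one member of the pair.
#'
#' @param resultsByPlatform named list of [ScanResults-class] (or plain
#'   data.frames with \code{unit}, \code{t}, \code{p}).
#' @param subset \code{"all"} or \code{"significant"}.
#' @param alpha significance threshold for the restricted subset.
#' @return data.frame with one row per platform pair: \code{platform1},
#'   \code{platform2}, \code{r}, \code{nUnits}.
#' @export
crossPlatformCorrelation <- function(resultsByPlatform,
                                     subset = c("all", "significant"),
                                     alpha = 0.05) {
  subset <- match.arg(subset)
  tabs <- lapply(resultsByPlatform, function(x)
    if (methods::is(x, "ScanResults")) resultsTable(x) else x)
  if (length(tabs) < 2L) stop("need results from at least two platforms")
  prs <- utils::combn(names(tabs), 2L)
  out <- NULL
  for (j in seq_len(ncol(prs))) {
    a <- tabs[[prs[1L, j]]]; b <- tabs[[prs[2L, j]]]
    m <- merge(a[, c("unit", "t", "p")], b[, c("unit", "t", "p")],
               by = "unit", suffixes = c("1", "2"))
    m <- m[stats::complete.cases(m[, c("t1", "t2")]), , drop = FALSE]
    if (subset == "significant")
      m <- m[!is.na(m$p1) & !is.na(m$p2) &
               (m$p1 < alpha | m$p2 < alpha), , drop = FALSE]
    if (nrow(m) < 3L)
      stop("fewer than 3 paired units for platforms ",
           prs[1L, j], " / ", prs[2L, j])
    out <- rbind(out, data.frame(
      platform1 = prs[1L, j], platform2 = prs[2L, j],
      r = stats::cor(m$t1, m$t2), nUnits = nrow(m),
      subset = subset, stringsAsFactors = FALSE))
  }
  out
}

#' Summarize significant associations across platforms
#'
#' Counts significant units per gene and platform, and the overlap of the
#' significant sets across platforms (significant in at least one, at
#' least two, and all platforms -- the Venn decomposition).
#'
#' @param resultsByPlatform named list of [ScanResults-class] or
#'   data.frames with \code{unit}, \code{gene}, \code{p}.
#' @param alpha significance level (default 0.05).
#' @return list with \code{counts} (gene x platform data.frame, plus a
#'   \code{total} row), \code{overlap} (named counts \code{atLeast1},
#'   \code{atLeast2}, \code{all}), and \code{units} (per-unit number of
#'   platforms in which it is significant).
#' @export
summarizeSignificant <- function(resultsByPlatform, alpha = 0.05) {
  tabs <- lapply(resultsByPlatform, function(x)
    if (methods::is(x, "ScanResults")) resultsTable(x) else x)
  genes <- sort(unique(unlist(lapply(tabs, function(tb) tb$gene))))
  counts <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in names(tabs)) {
    tb <- tabs[[p]]
    sig <- tb[!is.na(tb$p) & tb$p < alpha, , drop = FALSE]
    counts[[p]] <- vapply(genes, function(g) sum(sig$gene == g), integer(1))
  }
  allUnits <- sort(unique(unlist(lapply(tabs, function(tb) tb$unit))))
  nSig <- vapply(allUnits, function(u) {
    sum(vapply(tabs, function(tb) {
      i <- tb$unit == u
      any(i & !is.na(tb$p) & tb$p < alpha)
    }, logical(1)))
  }, integer(1))
  overlap <- c(atLeast1 = sum(nSig >= 1L), atLeast2 = sum(nSig >= 2L),
               all = sum(nSig >= length(tabs)))
  totals <- c(gene = "total", lapply(counts[names(tabs)], sum))
  counts <- rbind(counts, as.data.frame(totals, stringsAsFactors = FALSE))
  list(counts = counts, overlap = overlap, units = nSig)
}
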