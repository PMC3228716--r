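# End-to-end pipeline: simulate -> kinship -> varcomp -> scan -> haplotest
# -> epistasis -> xplatform -> summarize -> report, with all artifacts as
# provenance-stamped TSVs in one output directory.  Any contiguous
# sub-chain can be run; stages read what they need from the directory.

logMsg <- function(quiet, ...) if (!quiet) message("[ryeassoc] ", ...)

#' Run the analysis pipeline
#'
#' Executes the requested stages on a synthetic scenario (or on artifacts
#' already present in \code{outdir} when the generating stages are not
#' requested).  All randomness flows from the single \code{seed}, split
#' deterministically per stage, so a rerun with identical arguments
#' reproduces every result table byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param seed root integer seed.
#' @param scenario list(cohort, effects) as from [defaultScenario()].
#' @param stages character vector of stages, in pipeline order; default
#'   all (the \code{demo} preset).
#' @param platforms platforms to analyse.
#' @param alpha significance level.
#' @param maf minor-allele / haplotype frequency threshold (strict >).
#' @param hetMode kinship heterozygote scoring, see [similarityIndex()].
#' @param trendCoding semi-controlled month coding, see [platformModel()].
#' @param genePairs optional restriction of the epistasis scan.
#' @param pReference Wald reference distribution, see [fitLMM()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list of the in-memory artifacts.
#' @export
runPipeline <- function(outdir, seed = 1L, scenario = defaultScenario(),
                        stages = c("simulate", "kinship", "varcomp", "scan",
                                   "haplotest", "epistasis", "xplatform",
                                   "summarize", "report"),
                        platforms = c("controlled", "semi_controlled",
                                      "field"),
                        alpha = 0.05, maf = 0.05, hetMode = "half",
                        trendCoding = "calendar", genePairs = NULL,
                        pReference = "normal", quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  pth <- function(f) file.path(outdir, f)

  if ("simulate" %in% stages) {
    logMsg(quiet, "simulate: cohort + phenotypes (seed ", seed, ")")
    cohort <- simulateCohort(scenario$cohort, seed)
    pheno <- simulatePhenotypes(cohort, scenario$effects, seed,
                                platforms = platforms)
    markers <- phaseGametes(cohort$s0, cohort$siteInfo)
    writeSsrTable(cohort$ssr, pth("ssr.tsv"), seed = seed)
    writeMarkerTable(markers, pth("markers.tsv"), pth("sites.tsv"),
                     seed = seed)
    writeMatrix(cohort$Q, pth("qmatrix.tsv"), seed = seed)
    writePhenotypeTable(pheno, pth("phenotypes.tsv"), seed = seed)
    jsonlite::write_json(
      list(seed = seed,
           populations = as.list(table(cohort$populations)),
           clipFraction = as.list(attr(pheno, "clipFraction")),
           causal = scenario$effects$causal),
      pth("truth.json"), auto_unbox = TRUE, digits = NA)
    art$cohort <- cohort; art$phenotypes <- pheno; art$markers <- markers
  }

  needSsr <- function() {
    if (is.null(art$cohort)) readSsrTable(pth("ssr.tsv")) else art$cohort$ssr
  }
  needMarkers <- function() {
    if (is.null(art$markers))
      art$markers <<- readMarkerTable(pth("markers.tsv"), pth("sites.tsv"))
    art$markers
  }
  needPheno <- function() {
    if (is.null(art$phenotypes))
      art$phenotypes <<- readPhenotypeTable(pth("phenotypes.tsv"))
    art$phenotypes
  }
  needQ <- function() {
    if (is.null(art$Q)) art$Q <<- if (!is.null(art$cohort)) art$cohort$Q
                                  else readQMatrix(pth("qmatrix.tsv"))
    art$Q
  }
  needK <- function() {
    if (is.null(art$K)) art$K <<- readKinshipMatrix(pth("kinship.tsv"),
                                                    hetMode = hetMode)
    art$K
  }

  if ("kinship" %in% stages) {
    logMsg(quiet, "kinship: allele-similarity matrix (het mode ", hetMode, ")")
    art$K <- kinshipMatrix(needSsr(), hetMode = hetMode)
    writeMatrix(art$K, pth("kinship.tsv"), seed = seed)
  }

  if ("varcomp" %in% stages) {
    logMsg(quiet, "varcomp: per-stratum genotypic variance tests")
    pheno <- needPheno(); K <- needK()
    rows <- list()
    for (pf in intersect(platforms, unique(pheno$platform))) {
      sub <- pheno[pheno$platform == pf, , drop = FALSE]
      strata <- switch(pf,
        controlled = unique(sub[, c("year", "temperature")]),
        semi_controlled = unique(sub[, c("year", "month")]),
        field = unique(sub[, "environment", drop = FALSE]))
      for (i in seq_len(nrow(strata))) {
        st <- as.list(strata[i, , drop = FALSE])
        r <- genotypeVarcompTest(pheno, pf, st, K)
        rows[[length(rows) + 1L]] <- data.frame(
          platform = pf,
          stratum = paste(unlist(lapply(st, as.character)), collapse = ":"),
          sigma2g = r$sigma2g, statistic = r$statistic, df = r$df, p = r$p,
          n_genotypes = r$nGenotypes, stringsAsFactors = FALSE)
      }
    }
    art$varcomp <- do.call(rbind, rows)
    writeResults(art$varcomp, pth("varcomp.tsv"), seed = seed)
  }

  scanPlatforms <- NULL
  needScanPlatforms <- function() {
    if (is.null(scanPlatforms))
      scanPlatforms <<- intersect(platforms, unique(needPheno()$platform))
    scanPlatforms
  }

  if ("scan" %in% stages) {
    scanPlatforms <- needScanPlatforms()
    mkF <- filterMAF(needMarkers(), maf)
    logMsg(quiet, "scan: ", nrow(mkF), " sites x ",
           length(scanPlatforms), " platforms")
    art$scan <- list()
    for (pf in scanPlatforms) {
      t0 <- proc.time()[[3L]]
      art$scan[[pf]] <- snpScan(needPheno(), mkF, needQ(), needK(), pf,
                                alpha = alpha, trendCoding = trendCoding,
                                pReference = pReference)
      logMsg(quiet, "  ", pf, ": ", round(proc.time()[[3L]] - t0, 1), "s")
      writeResults(art$scan[[pf]], pth(paste0("scan_", pf, ".tsv")),
                   seed = seed)
    }
  }

  needHaplotypes <- function() {
    if (is.null(art$haplotypes)) {
      mk <- needMarkers()
      genes <- unique(siteInfo(mk)$gene_id)
      art$haplotypes <<- lapply(genes, function(g) defineHaplotypes(mk, g))
    }
    art$haplotypes
  }

  if ("haplotest" %in% stages) {
    logMsg(quiet, "haplotest: within-gene haplotype LRTs and contrasts")
    art$haplo <- list()
    for (pf in needScanPlatforms()) {
      art$haplo[[pf]] <- haplotypeScan(needPheno(), needHaplotypes(),
                                       needQ(), needK(), pf, alpha = alpha,
                                       maf = maf, trendCoding = trendCoding,
                                       pReference = pReference)
      writeResults(art$haplo[[pf]], pth(paste0("haplo_", pf, ".tsv")),
                   seed = seed)
    }
  }

  if ("epistasis" %in% stages) {
    logMsg(quiet, "epistasis: gene x gene interaction LRTs")
    art$epistasis <- list()
    for (pf in needScanPlatforms()) {
      art$epistasis[[pf]] <- epistasisScan(needPheno(), needHaplotypes(),
                                           needQ(), needK(), pf,
                                           genePairs = genePairs, maf = maf,
                                           trendCoding = trendCoding)
      writeResults(art$epistasis[[pf]],
                   pth(paste0("epistasis_", pf, ".tsv")), seed = seed)
    }
  }

  needScanTables <- function() {
    if (is.null(art$scan)) {
      sp <- needScanPlatforms()
      art$scan <<- stats::setNames(lapply(sp, function(pf)
        readResults(pth(paste0("scan_", pf, ".tsv")))), sp)
    }
    art$scan
  }

  if ("xplatform" %in% stages && length(needScanPlatforms()) >= 2L) {
    logMsg(quiet, "xplatform: Pearson correlation of t values")
    art$xplatform <- rbind(
      crossPlatformCorrelation(needScanTables(), "all", alpha),
      tryCatch(crossPlatformCorrelation(needScanTables(), "significant",
                                        alpha),
               error = function(e) NULL))
    writeResults(art$xplatform, pth("xplatform.tsv"), seed = seed)
  }

  if ("summarize" %in% stages) {
    logMsg(quiet, "summarize: significant counts and overlap")
    sm <- summarizeSignificant(needScanTables(), alpha)
    art$summary <- sm
    writeResults(sm$counts, pth("summary_counts.tsv"), seed = seed)
    jsonlite::write_json(as.list(sm$overlap), pth("summary_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    logMsg(quiet, "report: markdown summary")
    renderReport(outdir)
  }

  jsonlite::write_json(
    list(tool = "ryeassoc",
         version = as.character(utils::packageVersion("ryeassoc")),
         seed = seed, stages = stages, platforms = platforms, alpha = alpha,
         maf = maf, hetMode = hetMode, trendCoding = trendCoding,
         pReference = pReference),
    pth("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(art)
}

fmtRow <- function(...) paste(c(...), collapse = " | ")

#' Render a human-readable markdown report from pipeline artifacts
#'
#' Summarizes phenotype distributions (five-number statistics per
#' platform/stratum), the allelic-effect distribution split by
#' significance, the effect-size (variance explained) distribution, a
#' haplotype table (P, effect, percent genetic variation explained) and
#' the cross-platform overlap counts.  Sections whose input artifact is
#' missing are skipped with a notice.
#'
#' @param outdir directory holding the pipeline TSVs.
#' @param alpha significance level used for the splits.
#' @return path to \code{report.md}, invisibly.
#' @export
renderReport <- function(outdir, alpha = 0.05) {
  pth <- function(f) file.path(outdir, f)
  out <- c("# ryeassoc run report", "")
  sec <- function(title, body) out <<- c(out, paste("##", title), "", body, "")

  if (file.exists(pth("phenotypes.tsv"))) {
    ph <- readPhenotypeTable(pth("phenotypes.tsv"))
    body <- c(fmtRow("platform", "n", "min", "q1", "median", "q3", "max"),
              fmtRow("---", "---", "---", "---", "---", "---", "---"))
    for (pf in unique(ph$platform)) {
      v <- ph$value[ph$platform == pf]
      fn <- stats::fivenum(v)
      body <- c(body, fmtRow(pf, length(v), sprintf("%.2f", fn)))
    }
    sec("Phenotype distributions", body)
  } else sec("Phenotype distributions", "*skipped: phenotypes.tsv missing*")

  scans <- Sys.glob(pth("scan_*.tsv"))
  if (length(scans)) {
    body <- c(fmtRow("platform", "tested", "significant", "beta range",
                     "median |beta| (sig)", "median varExpl%", "max varExpl%"),
              fmtRow("---", "---", "---", "---", "---", "---", "---"))
    for (f in scans) {
      tb <- readResults(f)
      pf <- sub("^scan_(.*)\\.tsv$", "\\1", basename(f))
      sig <- !is.na(tb$p) & tb$p < alpha
      body <- c(body, fmtRow(
        pf, nrow(tb), sum(sig),
        sprintf("[%.3f, %.3f]", min(tb$beta, na.rm = TRUE),
                max(tb$beta, na.rm = TRUE)),
        if (any(sig)) sprintf("%.3f", stats::median(abs(tb$beta[sig]))) else "-",
        sprintf("%.2f", stats::median(tb$var_explained_pct, na.rm = TRUE)),
        sprintf("%.2f", max(tb$var_explained_pct, na.rm = TRUE))))
    }
    sec("Allelic effects and effect sizes", body)
  } else sec("Allelic effects and effect sizes", "*skipped: no scan results*")

  haps <- Sys.glob(pth("haplo_*.tsv"))
  if (length(haps)) {
    body <- c(fmtRow("gene", "haplotype", "platform", "P", "beta_Hap",
                     "% genetic variation"),
              fmtRow("---", "---", "---", "---", "---", "---"))
    for (f in haps) {
      tb <- readResults(f)
      for (i in seq_len(nrow(tb))) {
        body <- c(body, fmtRow(
          tb$gene[i], tb$haplotype[i], tb$platform[i],
          ifelse(is.na(tb$p[i]), "-", sprintf("%.4g", tb$p[i])),
          ifelse(is.na(tb$beta[i]), "-", sprintf("%.3f", tb$beta[i])),
          ifelse(is.na(tb$var_explained_pct[i]), "-",
                 sprintf("%.2f", tb$var_explained_pct[i]))))
      }
    }
    sec("Haplotype associations", body)
  } else sec("Haplotype associations", "*skipped: no haplotype results*")

  if (file.exists(pth("summary_overlap.json"))) {
    ov <- jsonlite::read_json(pth("summary_overlap.json"))
    sec("Cross-platform overlap of significant sites",
        c(paste("- significant in at least one platform:", ov$atLeast1),
          paste("- significant in at least two platforms:", ov$atLeast2),
          paste("- significant in all platforms:", ov$all)))
  } else sec("Cross-platform overlap of significant sites",
             "*skipped: summary_overlap.json missing*")

  if (file.exists(pth("xplatform.tsv"))) {
    xp <- readResults(pth("xplatform.tsv"))
    body <- c(fmtRow("platform pair", "subset", "r", "n units"),
              fmtRow("---", "---", "---", "---"))
    for (i in seq_len(nrow(xp)))
      body <- c(body, fmtRow(paste(xp$platform1[i], "vs", xp$platform2[i]),
                             xp$subset[i], sprintf("%.3f", xp$r[i]),
                             xp$nUnits[i]))
    sec("Cross-platform concordance (Pearson r of t values)", body)
  } else sec("Cross-platform concordance (Pearson r of t values)",
             "*skipped: xplatform.tsv missing*")

  writeLines(out, file.path(outdir, "report.md"))
  invisible(file.path(outdir, "report.md"))
}
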