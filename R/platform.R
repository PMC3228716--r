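# Per-platform mixed-model construction: fixed-effect recipes, platform
# random effects, and the kinship-structured genotype block, following the
# one-stage approach (raw replicate-level phenotypes as the response).

incidence <- function(f) {
  f <- factor(f)
  Z <- stats::model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  Z
}

# centered time covariate for the semi-controlled platform
monthTrend <- function(year, month, trendCoding = c("calendar", "rank")) {
  trendCoding <- match.arg(trendCoding)
  tc <- numeric(length(month))
  for (yr in unique(year)) {
    i <- year == yr
    m <- month[i]
    v <- if (trendCoding == "calendar") m else match(m, sort(unique(m)))
    tc[i] <- v - mean(unique(if (trendCoding == "calendar") m
                             else match(m, sort(unique(m)))))
  }
  tc
}

#' Assemble the platform-specific Q+K mixed model
#'
#' Builds the one-stage model specification for one phenotyping platform:
#' fixed effects are an intercept (controlled and semi-controlled), an
#' optional 0/1 marker (or haplotype-indicator) column, the structure
#' covariates Q (the last cluster column is dropped: membership fractions
#' sum to one and would alias the intercept) and the platform recipe
#' (controlled: year + temperature; semi-controlled: year + centered
#' linear month trend + year x trend; field: the full set of environment
#' indicators with no separate intercept).  Random effects are the
#' platform blocks (controlled: chamber; semi-controlled: year-specific
#' replication plus a correlated per-unit random intercept and month
#' trend, unit = genotype x year; field: block nested in environment) plus
#' the genotype block with covariance K sigma2_g embedded through the
#' cholesky root of K.
#'
#' @param platform \code{"controlled"}, \code{"semi_controlled"} or
#'   \code{"field"}.
#' @param phenotypes long-format phenotype data.frame
#'   ([validatePhenotypes()]).
#' @param Q [StructureMatrix-class] (or NULL / \code{includeQ = FALSE} to
#'   omit the structure covariates).
#' @param K [KinshipMatrix-class]; must cover all genotypes present.
#' @param marker optional named 0/1 vector (by genotype id); rows whose
#'   genotype has a missing marker value are dropped (complete-case).
#'   Columns: one per \code{colnames} if a matrix is supplied (haplotype
#'   indicator sets).
#' @param includeQ,includeGenotype switches used for the
#'   phenotypic-analysis models (no Q, with or without the genotype block)
#'   and the naive no-correction scan.
#' @param trendCoding month spacing for the semi-controlled trend:
#'   \code{"calendar"} (default; respects the Jan/Feb/Apr gap) or
#'   \code{"rank"}.
#' @return [lmmSpec()] with attributes \code{genotypes} (column order of
#'   the genotype block) and \code{rows} (row indices of
#'   \code{phenotypes} used).
#' @export
platformModel <- function(platform, phenotypes, Q = NULL, K = NULL,
                          marker = NULL, includeQ = !is.null(Q),
                          includeGenotype = !is.null(K),
                          trendCoding = c("calendar", "rank")) {
  if (!platform %in% c("controlled", "semi_controlled", "field"))
    stop("unknown platform: ", platform)
  trendCoding <- match.arg(trendCoding)
  ph <- phenotypes[phenotypes$platform == platform, , drop = FALSE]
  if (!nrow(ph)) stop("no phenotype rows for platform ", platform)

  markerMat <- NULL
  if (!is.null(marker)) {
    markerMat <- if (is.matrix(marker)) marker else
      matrix(marker, ncol = 1L, dimnames = list(names(marker), "marker"))
    unknown <- setdiff(unique(ph$genotype_id), rownames(markerMat))
    if (length(unknown))
      stop("genotypes missing from marker vector: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    keep <- !apply(markerMat[ph$genotype_id, , drop = FALSE], 1L, anyNA)
    ph <- ph[keep, , drop = FALSE]
    if (!nrow(ph)) stop("no complete-case rows left for platform ", platform)
  }

  ids <- sort(unique(ph$genotype_id))
  y <- ph$value
  n <- nrow(ph)

  # fixed effects
  Xparts <- list()
  if (platform != "field") Xparts$`(Intercept)` <- rep(1, n)
  if (!is.null(markerMat))
    Xparts$marker <- markerMat[ph$genotype_id, , drop = FALSE]
  if (includeQ) {
    if (is.null(Q)) stop("includeQ = TRUE but no Q supplied")
    Qm <- qMatrix(Q)
    unknown <- setdiff(ids, rownames(Qm))
    if (length(unknown))
      stop("genotypes missing from Q: ", paste(utils::head(unknown, 5),
                                               collapse = ", "))
    Qk <- Qm[ph$genotype_id, -ncol(Qm), drop = FALSE]
    colnames(Qk) <- paste0("Q_", colnames(Qm)[-ncol(Qm)])
    Xparts$Q <- Qk
  }
  blocks <- list()
  if (platform == "controlled") {
    yr <- factor(ph$year)
    if (nlevels(yr) > 1L) {
      Xy <- stats::model.matrix(~ yr)[, -1L, drop = FALSE]
      colnames(Xy) <- paste0("year", levels(yr)[-1L])
      Xparts$year <- Xy
    }
    tp <- factor(ph$temperature)
    if (nlevels(tp) > 1L) {
      Xt <- stats::model.matrix(~ tp)[, -1L, drop = FALSE]
      colnames(Xt) <- paste0("temp", levels(tp)[-1L])
      Xparts$temp <- Xt
    }
    blocks <- c(blocks, list(iidBlock(incidence(ph$chamber), "chamber")))
  } else if (platform == "semi_controlled") {
    yr <- factor(ph$year)
    tc <- monthTrend(ph$year, ph$month, trendCoding)
    if (nlevels(yr) > 1L) {
      Xy <- stats::model.matrix(~ yr)[, -1L, drop = FALSE]
      colnames(Xy) <- paste0("year", levels(yr)[-1L])
      Xparts$year <- Xy
      Xi <- Xy * tc
      colnames(Xi) <- paste0("year", levels(yr)[-1L], ":trend")
      Xparts$trend <- cbind(trend = tc, Xi)
    } else Xparts$trend <- cbind(trend = tc)
    repl <- incidence(paste0(ph$year, "_r", ph$replicate))
    blocks <- c(blocks, list(iidBlock(repl, "replication")))
    unitF <- factor(paste(ph$genotype_id, ph$year, sep = "_"))
    Zu <- incidence(unitF)
    if (length(unique(tc)) > 1L)
      blocks <- c(blocks, list(us2Block(Zu, Zu * tc, "unit")))
    else
      blocks <- c(blocks, list(iidBlock(Zu, "unit")))
  } else {  # field
    Xe <- incidence(ph$environment)
    colnames(Xe) <- paste0("env", colnames(Xe))
    Xparts$env <- Xe
    blocks <- c(blocks, list(iidBlock(incidence(ph$block), "block")))
  }
  if (includeGenotype) {
    if (is.null(K)) stop("includeGenotype = TRUE but no K supplied")
    Zg <- incidence(factor(ph$genotype_id, levels = ids))
    blocks <- c(blocks, list(kinshipBlock(Zg, K, "genotype")))
  }

  X <- do.call(cbind, Xparts)
  X <- dropAliased(X, protect = intersect("marker", colnames(X)))
  spec <- lmmSpec(y, X, blocks)
  attr(spec, "genotypes") <- ids
  attr(spec, "rows") <- which(phenotypes$platform == platform)[
    if (!is.null(markerMat)) which(keep) else seq_len(n)]
  attr(spec, "platform") <- platform
  spec
}

#' Per-stratum genotypic variance-component test
#'
#' Fits the platform model for one stratum (controlled: a temperature x
#' year cell; semi-controlled: a month x year cell; field: one
#' environment) with and without the kinship-structured genotype block
#' (no marker, no structure covariates) and reports the genotype variance
#' component with a chi-square(1) likelihood-ratio P value -- a
#' deliberately conservative reference for a variance component on the
#' boundary.
#'
#' @param phenotypes long-format phenotype data.frame.
#' @param platform platform name.
#' @param stratum named list selecting the stratum: controlled
#'   \code{list(year =, temperature =)}; semi-controlled
#'   \code{list(year =, month =)}; field \code{list(environment =)}.
#' @param K [KinshipMatrix-class].
#' @return list with \code{sigma2g}, \code{statistic}, \code{df}, \code{p}
#'   and the number of genotypes \code{nGenotypes}.
#' @export
genotypeVarcompTest <- function(phenotypes, platform, stratum, K) {
  ph <- phenotypes[phenotypes$platform == platform, , drop = FALSE]
  for (nm in names(stratum)) ph <- ph[ph[[nm]] == stratum[[nm]], , drop = FALSE]
  nGeno <- length(unique(ph$genotype_id))
  if (nGeno < 2L)
    stop("stratum has fewer than 2 genotypes")
  y <- ph$value
  n <- nrow(ph)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  blocks <- switch(platform,
    controlled = list(iidBlock(incidence(ph$chamber), "chamber")),
    semi_controlled = list(iidBlock(incidence(paste0(ph$year, "_r", ph$replicate)),
                                    "replication")),
    field = list(iidBlock(incidence(ph$block), "block")),
    stop("unknown platform: ", platform))
  # degenerate single-level platform blocks are dropped (aliased with the
  # intercept/residual in a single stratum)
  blocks <- Filter(function(b) ncol(b$Z) > 1L, blocks)
  ids <- sort(unique(ph$genotype_id))
  Zg <- incidence(factor(ph$genotype_id, levels = ids))
  full <- fitLMM(lmmSpec(y, X, c(blocks, list(kinshipBlock(Zg, K, "genotype")))),
                 method = "REML")
  red <- fitLMM(lmmSpec(y, X, blocks), method = "REML")
  test <- lrt(full, red, df = 1L)
  list(sigma2g = unname(full@varcomp[["genotype"]]),
       statistic = test$statistic, df = 1L, p = test$p,
       nGenotypes = nGeno, logLikFull = full@loglik, logLikReduced = red@loglik)
}
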