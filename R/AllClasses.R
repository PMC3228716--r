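#' @import methods
#' @useDynLib ryeassoc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats pnorm pchisq rnorm runif rgamma var sd setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion combn head
NULL

#' SSR genotype container
#'
#' Diploid, multi-allelic simple-sequence-repeat (microsatellite) genotypes
#' for a panel of individuals.  Built on
#' \linkS4class{SummarizedExperiment}: rows are SSR loci, columns are
#' genotypes, and the two unordered alleles at each locus are stored in the
#' character assays \code{"allele1"} and \code{"allele2"} (sorted so that
#' \code{allele1 <= allele2}; both \code{NA} when the call is missing).
#'
#' @seealso [readSsrTable()], [kinshipMatrix()]
#' @export
setClass("SsrGenotypes", contains = "SummarizedExperiment")

setValidity("SsrGenotypes", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("allele1", "allele2") %in% an))
    return("assays 'allele1' and 'allele2' are required")
  if (nrow(object) < 1L) return("at least one SSR locus is required")
  if (anyDuplicated(colnames(object))) return("duplicated genotype ids")
  if (anyDuplicated(rownames(object))) return("duplicated locus ids")
  a1 <- SummarizedExperiment::assay(object, "allele1")
  a2 <- SummarizedExperiment::assay(object, "allele2")
  if (!identical(is.na(a1), is.na(a2)))
    return("alleles must be missing in pairs (both or neither)")
  TRUE
})

#' Candidate-gene marker panel
#'
#' Single-gamete allele calls at candidate-gene polymorphic sites (SNPs and
#' Indels, the latter treated as ordinary single sites).  Rows are sites,
#' columns are genotypes; the character assay \code{"allele"} holds the
#' gamete allele carried by each genotype against the common-parent
#' reference.  \code{rowData} carries the site metadata: \code{gene_id},
#' \code{site_index} (ordinal position within the gene), \code{site_type}
#' (\code{"SNP"} or \code{"Indel"}) and \code{ref_allele} (the common
#' parent's allele).
#'
#' In a gamete-capture design every individual is a testcross of one
#' source-population gamete onto a homozygous common parent, so exactly one
#' gamete allele per genotype and site is stored.
#'
#' @seealso [phaseGametes()], [defineHaplotypes()], [filterMAF()]
#' @export
setClass("MarkerPanel", contains = "SummarizedExperiment")

setValidity("MarkerPanel", function(object) {
  if (!"allele" %in% SummarizedExperiment::assayNames(object))
    return("assay 'allele' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("gene_id", "site_index", "site_type", "ref_allele")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(object))) return("duplicated site ids")
  if (anyDuplicated(colnames(object))) return("duplicated genotype ids")
  if (!all(rd$site_type %in% c("SNP", "Indel")))
    return("site_type must be 'SNP' or 'Indel'")
  if (any(is.na(rd$ref_allele)))
    return("every site needs a common-parent reference allele")
  TRUE
})

#' Population-structure membership matrix
#'
#' Per-genotype membership fractions in k ancestral clusters (the Q matrix
#' of structured association), used as fixed covariates to absorb
#' population stratification.  Rows are genotypes and must sum to one.
#'
#' @slot Q numeric matrix, genotypes x clusters, rows summing to 1.
#' @export
setClass("StructureMatrix", representation(Q = "matrix"))

setValidity("StructureMatrix", function(object) {
  Q <- object@Q
  if (is.null(rownames(Q))) return("Q needs genotype ids as rownames")
  if (ncol(Q) < 2L) return("at least k = 2 clusters are required")
  if (any(Q < -1e-12)) return("membership fractions must be non-negative")
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    return("each row of Q must sum to 1 (tolerance 1e-6)")
  TRUE
})

#' Standardized allele-similarity kinship matrix
#'
#' Relationship matrix among genotypes estimated by allele similarity over
#' SSR loci and min-standardized so that the smallest off-diagonal
#' relationship is 0 and the diagonal is 1.  Used as the covariance
#' structure of the polygenic genotype random effect.
#'
#' @slot K symmetric numeric matrix with unit diagonal, entries in [0, 1].
#' @slot sMin minimum raw (pre-standardization) off-diagonal similarity.
#' @slot hetMode scoring rule used for partially matching diploid pairs,
#'   \code{"half"} (allele-sharing fraction) or \code{"strict"} ({0,1}).
#' @export
setClass("KinshipMatrix",
         representation(K = "matrix", sMin = "numeric", hetMode = "character"))

setValidity("KinshipMatrix", function(object) {
  K <- object@K
  if (is.null(rownames(K))) return("K needs genotype ids as dimnames")
  if (!isSymmetric(K, tol = 1e-8)) return("K must be symmetric")
  if (max(abs(diag(K) - 1)) > 1e-8) return("diagonal of K must be 1")
  if (min(K) < -1e-8 || max(K) > 1 + 1e-8)
    return("entries of K must lie in [0, 1]")
  TRUE
})

#' Within-gene haplotype assignment
#'
#' The distinct gamete allele strings over one candidate gene's sites,
#' labelled in decreasing frequency order with the common parent's string
#' always labelled \code{"ref"}.
#'
#' @slot gene gene identifier.
#' @slot sequences named character vector of allele strings, one per
#'   haplotype label; \code{sequences["ref"]} is the common parent string.
#' @slot assignment named character vector mapping each genotype to a
#'   haplotype label (\code{NA} when any site in the gene is missing or the
#'   haplotype was removed by frequency filtering).
#' @slot freq named numeric vector of haplotype frequencies over genotypes
#'   with a non-missing assignment (sums to 1).
#' @export
setClass("HaplotypeSet",
         representation(gene = "character", sequences = "character",
                        assignment = "character", freq = "numeric"))

setValidity("HaplotypeSet", function(object) {
  if (length(object@gene) != 1L) return("exactly one gene id")
  if (!"ref" %in% names(object@sequences))
    return("the reference haplotype 'ref' must be present")
  if (length(object@freq) &&
      abs(sum(object@freq) - 1) > 1e-8 && any(!is.na(object@assignment)))
    return("haplotype frequencies must sum to 1 over non-missing genotypes")
  bad <- setdiff(stats::na.omit(unique(object@assignment)),
                 names(object@sequences))
  if (length(bad)) return("assignment refers to unknown haplotype labels")
  TRUE
})

#' Fitted Gaussian linear mixed model
#'
#' Result of [fitLMM()]: REML or ML variance components, GLS fixed-effect
#' estimates with standard errors, the maximized log-likelihood and
#' convergence diagnostics.
#'
#' @slot method \code{"REML"} or \code{"ML"}.
#' @slot varcomp named variance-component estimates (one per random block;
#'   correlated intercept-trend blocks contribute \code{<label>.intercept},
#'   \code{<label>.trend} and \code{<label>.cor}; plus \code{"residual"}).
#' @slot beta,se,tstat,pval named fixed-effect estimates and Wald summaries
#'   (two-sided, standard normal reference by default).
#' @slot loglik maximized (restricted) log-likelihood.
#' @slot n,p number of observations and fixed-effect columns.
#' @slot y the response (kept so that nesting of fits can be verified).
#' @slot xnames fixed-effect column labels.
#' @slot diagnostics list: iterations, convergence code, number of starts,
#'   boundary flags, objective value.
#' @export
setClass("LMMFit",
         representation(method = "character", varcomp = "numeric",
                        beta = "numeric", se = "numeric", tstat = "numeric",
                        pval = "numeric", loglik = "numeric",
                        n = "integer", p = "integer", y = "numeric",
                        xnames = "character", diagnostics = "list"))

setValidity("LMMFit", function(object) {
  if (any(object@varcomp < -1e-12)) return("variance estimates must be >= 0")
  if (!is.finite(object@loglik)) return("log-likelihood must be finite")
  if (any(!is.finite(object@se)) || any(object@se <= 0))
    return("standard errors must be positive and finite")
  TRUE
})

#' Association scan results
#'
#' One row per tested unit (site, haplotype, gene-overall or gene pair) and
#' platform, with effect estimate, Wald/LRT summaries, percent genetic
#' variance explained, and bookkeeping columns.
#'
#' @slot table data.frame of results.
#' @slot kind \code{"snp"}, \code{"haplotype"}, \code{"epistasis"} or
#'   \code{"varcomp"}.
#' @export
setClass("ScanResults", representation(table = "data.frame", kind = "character"))

setValidity("ScanResults", function(object) {
  tb <- object@table
  if (nrow(tb)) {
    if ("p" %in% names(tb)) {
      pv <- tb$p[!is.na(tb$p)]
      if (length(pv) && (min(pv) < 0 || max(pv) > 1))
        return("P values must lie in [0, 1]")
    }
    if ("var_explained_pct" %in% names(tb)) {
      v <- tb$var_explained_pct[!is.na(tb$var_explained_pct)]
      if (length(v) && (min(v) < 0 || max(v) > 100))
        return("variance explained must lie in [0, 100]")
    }
  }
  TRUE
})
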