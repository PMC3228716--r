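# Constructors, accessors and show methods for the core classes.

#' Construct an SsrGenotypes object
#'
#' @param allele1,allele2 character matrices (loci x genotypes) holding the
#'   two unordered alleles per call; they are re-sorted so allele1 <= allele2.
#' @return [SsrGenotypes-class]
#' @export
SsrGenotypes <- function(allele1, allele2) {
  stopifnot(identical(dim(allele1), dim(allele2)))
  a1 <- pmin(allele1, allele2)
  a2 <- pmax(allele1, allele2)
  dimnames(a1) <- dimnames(a2) <- dimnames(allele1)
  methods::new("SsrGenotypes", SummarizedExperiment::SummarizedExperiment(
    assays = list(allele1 = a1, allele2 = a2)))
}

#' Construct a MarkerPanel object
#'
#' @param allele character matrix (sites x genotypes) of gamete alleles.
#' @param siteInfo data.frame with columns \code{gene_id},
#'   \code{site_index}, \code{site_type}, \code{ref_allele}; rownames (or a
#'   \code{site_id} column) identify the sites.
#' @return [MarkerPanel-class]
#' @export
MarkerPanel <- function(allele, siteInfo) {
  if ("site_id" %in% colnames(siteInfo)) {
    rownames(siteInfo) <- siteInfo$site_id
    siteInfo$site_id <- NULL
  }
  stopifnot(identical(rownames(allele), rownames(siteInfo)))
  methods::new("MarkerPanel", SummarizedExperiment::SummarizedExperiment(
    assays = list(allele = allele),
    rowData = S4Vectors::DataFrame(siteInfo)))
}

#' Construct a StructureMatrix
#'
#' Rows off by at most 1e-6 from unit sum are renormalized; larger
#' deviations are an error.
#' @param Q numeric matrix of membership fractions with genotype rownames.
#' @return [StructureMatrix-class]
#' @export
StructureMatrix <- function(Q) {
  rs <- rowSums(Q)
  if (any(abs(rs - 1) > 1e-6))
    stop("Q rows must sum to 1 (tolerance 1e-6); offending genotypes: ",
         paste(utils::head(rownames(Q)[abs(rs - 1) > 1e-6], 5), collapse = ", "))
  methods::new("StructureMatrix", Q = Q / rs)
}

#' @describeIn StructureMatrix membership matrix accessor
#' @param x a StructureMatrix
#' @export
qMatrix <- function(x) x@Q

#' Kinship matrix accessor
#' @param x a [KinshipMatrix-class]
#' @return the standardized relationship matrix
#' @export
kinship <- function(x) x@K

#' Minimum raw similarity retained from standardization
#' @param x a [KinshipMatrix-class]
#' @export
rawMinSimilarity <- function(x) x@sMin

#' Gamete allele matrix accessor
#' @param x a [MarkerPanel-class]
#' @export
alleleMatrix <- function(x) SummarizedExperiment::assay(x, "allele")

#' Site metadata accessor
#' @param x a [MarkerPanel-class]
#' @return data.frame of site metadata (gene_id, site_index, site_type,
#'   ref_allele)
#' @export
siteInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' Haplotype accessors
#' @param x a [HaplotypeSet-class]
#' @export
haploAssignment <- function(x) x@assignment

#' @rdname haploAssignment
#' @export
haploFreq <- function(x) x@freq

#' @rdname haploAssignment
#' @export
haploGene <- function(x) x@gene

#' @rdname haploAssignment
#' @export
haploSequences <- function(x) x@sequences

#' Scan results table accessor
#' @param x a [ScanResults-class]
#' @export
resultsTable <- function(x) x@table

#' Fitted-model accessors
#' @param x an [LMMFit-class]
#' @export
varianceComponents <- function(x) x@varcomp

#' @rdname varianceComponents
#' @export
fixedEffects <- function(x) x@beta

#' @rdname varianceComponents
#' @export
logLikelihood <- function(x) x@loglik

setMethod("show", "SsrGenotypes", function(object) {
  cat("SsrGenotypes:", nrow(object), "SSR loci x", ncol(object),
      "genotypes;", sum(is.na(SummarizedExperiment::assay(object, "allele1"))),
      "missing calls\n")
})

setMethod("show", "MarkerPanel", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("MarkerPanel:", nrow(object), "sites (",
      sum(rd$site_type == "SNP"), "SNP /", sum(rd$site_type == "Indel"),
      "Indel ) in", length(unique(rd$gene_id)), "genes x",
      ncol(object), "genotypes\n")
})

setMethod("show", "StructureMatrix", function(object) {
  cat("StructureMatrix:", nrow(object@Q), "genotypes x k =",
      ncol(object@Q), "clusters\n")
})

setMethod("show", "KinshipMatrix", function(object) {
  off <- object@K[upper.tri(object@K)]
  cat(sprintf(
    "KinshipMatrix: %d genotypes; off-diagonal range [%.3f, %.3f], mean %.3f (het mode: %s)\n",
    nrow(object@K), min(off), max(off), mean(off), object@hetMode))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet for", object@gene, ":", length(object@sequences),
      "haplotypes;", sum(is.na(object@assignment)), "of",
      length(object@assignment), "genotypes missing\n")
})

setMethod("show", "LMMFit", function(object) {
  cat(sprintf("LMMFit (%s): logLik %.3f, n = %d, p = %d\n", object@method,
              object@loglik, object@n, object@p))
  cat("variance components:\n")
  print(round(object@varcomp, 5))
  cat("fixed effects:\n")
  print(round(cbind(estimate = object@beta, se = object@se,
                    t = object@tstat, p = object@pval), 4))
})

setMethod("show", "ScanResults", function(object) {
  cat("ScanResults (", object@kind, "): ", nrow(object@table), " rows\n",
      sep = "")
  if (nrow(object@table)) print(utils::head(object@table, 8))
})
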