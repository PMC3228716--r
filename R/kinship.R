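# Allele-similarity kinship from SSR markers: per-locus similarity index,
# averaging over loci, min-standardization, positive semi-definiteness
# repair, and covariance roots for embedding K in mixed-model designs.

#' Per-locus allele-similarity index between two diploid genotypes
#'
#' The index is 1 when the two unordered allele pairs are identical and 0
#' when they share no allele.  For partially matching pairs the default
#' (\code{hetMode = "half"}) scores the allele-sharing fraction under the
#' best pairing, giving 0.5 for one shared allele; \code{hetMode =
#' "strict"} scores any non-identical pair as 0.
#'
#' @param pairX,pairY length-2 character (or numeric) vectors: the
#'   unordered diploid allele pairs at one locus.
#' @param hetMode \code{"half"} or \code{"strict"}.
#' @return similarity in {0, 0.5, 1}.
#' @examples
#' similarityIndex(c(120, 122), c(120, 122))  # 1
#' similarityIndex(c(120, 122), c(124, 126))  # 0
#' similarityIndex(c(120, 122), c(120, 124))  # 0.5
#' @export
similarityIndex <- function(pairX, pairY, hetMode = c("half", "strict")) {
  hetMode <- match.arg(hetMode)
  if (anyNA(pairX) || anyNA(pairY))
    stop("missing allele pair: exclude this locus from the average")
  x <- sort(as.character(pairX)); y <- sort(as.character(pairY))
  if (identical(x, y)) return(1)
  if (hetMode == "strict") return(0)
  # shared alleles under the best pairing (multiset intersection size / 2)
  shared <- 0L
  yy <- y
  for (a in x) {
    j <- match(a, yy)
    if (!is.na(j)) { shared <- shared + 1L; yy <- yy[-j] }
  }
  shared / 2
}

# Raw similarity matrix averaged over jointly non-missing loci.
rawSimilarityMatrix <- function(ssr, hetMode = "half") {
  a1 <- SummarizedExperiment::assay(ssr, "allele1")
  a2 <- SummarizedExperiment::assay(ssr, "allele2")
  nG <- ncol(a1)
  if (nG < 2L) stop("kinship needs at least 2 genotypes")
  # Vectorized over genotype pairs, one locus at a time: with sorted pairs,
  # identical <=> both alleles equal; one shared allele <=> exactly one of
  # four cross-comparisons matches under the best pairing.
  S <- matrix(0, nG, nG); Nloc <- matrix(0L, nG, nG)
  for (l in seq_len(nrow(a1))) {
    x1 <- a1[l, ]; x2 <- a2[l, ]
    obs <- !is.na(x1)
    idx <- which(obs)
    if (length(idx) < 2L) next
    e11 <- outer(x1[idx], x1[idx], "==")
    e22 <- outer(x2[idx], x2[idx], "==")
    e12 <- outer(x1[idx], x2[idx], "==")
    e21 <- outer(x2[idx], x1[idx], "==")
    ident <- e11 & e22
    if (hetMode == "half") {
      anyShared <- e11 | e22 | e12 | e21
      s <- ifelse(ident, 1, ifelse(anyShared, 0.5, 0))
      # both alleles shared but in crossed order (x = {a,b}, y = {b,a}) is
      # impossible after sorting except a==b; crossed full match (e12 & e21)
      # means identical too
      s[e12 & e21] <- 1
    } else {
      s <- ifelse(ident | (e12 & e21), 1, 0)
    }
    S[idx, idx] <- S[idx, idx] + s
    Nloc[idx, idx] <- Nloc[idx, idx] + 1L
  }
  if (any(Nloc[upper.tri(Nloc)] == 0L))
    stop("genotype pair(s) with zero jointly non-missing loci")
  S <- S / Nloc
  dimnames(S) <- list(colnames(a1), colnames(a1))
  S
}

#' Standardized allele-similarity kinship matrix
#'
#' Averages the per-locus [similarityIndex()] over all jointly non-missing
#' loci for each genotype pair, then standardizes with the minimum
#' off-diagonal raw similarity S_min as
#' \deqn{\hat S_{xy} = (S_{xy} - S_{min}) / (1 - S_{min}),}
#' which maps the observed range onto [0, 1] and forces the least related
#' pair to 0.  The diagonal is pinned at 1 (self-similarity is
#' definitionally maximal).  The result is passed through [ensurePSD()] so
#' a positive semi-definite relationship matrix is guaranteed.
#'
#' @param ssr [SsrGenotypes-class]
#' @param hetMode scoring of partially matching pairs, see
#'   [similarityIndex()].
#' @param standardize set \code{FALSE} to return the raw averaged
#'   similarities (diagnostics only).
#' @return [KinshipMatrix-class]
#' @export
kinshipMatrix <- function(ssr, hetMode = c("half", "strict"),
                          standardize = TRUE) {
  hetMode <- match.arg(hetMode)
  S <- rawSimilarityMatrix(ssr, hetMode)
  sMin <- min(S[row(S) != col(S)])
  K <- if (standardize) (S - sMin) / (1 - sMin) else S
  diag(K) <- 1
  K <- pmin(pmax(K, 0), 1)
  ensurePSD(methods::new("KinshipMatrix", K = K, sMin = sMin,
                         hetMode = hetMode))
}

#' Repair a kinship matrix to positive semi-definiteness
#'
#' If the smallest eigenvalue is below \code{-tol}, negative eigenvalues
#' are clipped to zero, the matrix is reconstructed, and the diagonal is
#' rescaled back to 1; otherwise the input is returned unchanged.  The
#' Frobenius norm of the change is reported via \code{message()}.
#'
#' @param K [KinshipMatrix-class] or symmetric numeric matrix.
#' @param tol eigenvalue tolerance (default 1e-8).
#' @return same class as the input, PSD.
#' @export
ensurePSD <- function(K, tol = 1e-8) {
  obj <- if (methods::is(K, "KinshipMatrix")) K else NULL
  M <- if (is.null(obj)) K else obj@K
  if (max(abs(M - t(M))) > 1e-10) stop("input matrix is not symmetric")
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  if (min(ee$values) >= -tol) {
    out <- M
  } else {
    vals <- pmax(ee$values, 0)
    out <- ee$vectors %*% (vals * t(ee$vectors))
    d <- diag(out)
    d[d <= 0] <- 1
    out <- out / sqrt(d %o% d)      # rescale diagonal to 1
    out <- (out + t(out)) / 2
    dimnames(out) <- dimnames(M)
    message(sprintf("ensurePSD: clipped %d negative eigenvalue(s); Frobenius change %.3e",
                    sum(ee$values < 0), sqrt(sum((out - M)^2))))
  }
  diag(out) <- 1
  if (is.null(obj)) out
  else methods::new("KinshipMatrix", K = out, sMin = obj@sMin,
                    hetMode = obj@hetMode)
}

#' Covariance root of a PSD kinship matrix
#'
#' Returns L with L L' = K: the lower-triangular Cholesky factor when K is
#' positive definite, otherwise the symmetric eigendecomposition root.
#' This is the factor used to embed the kinship-structured genotype effect
#' in a mixed model by multiplying the genotype incidence design.
#'
#' @param K [KinshipMatrix-class] or PSD numeric matrix.
#' @return numeric matrix L with \code{max(abs(L %*% t(L) - K)) <= 1e-8}.
#' @export
covarianceRoot <- function(K) {
  M <- if (methods::is(K, "KinshipMatrix")) kinship(K) else K
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(ee$values) < -1e-8)
    stop("matrix is not positive semi-definite; run ensurePSD() first")
  L <- tryCatch(t(chol(M)), error = function(e) {
    vals <- pmax(ee$values, 0)
    ee$vectors %*% (sqrt(vals) * t(ee$vectors))
  })
  if (max(abs(L %*% t(L) - M)) > 1e-8)
    stop("covariance root reconstruction failed")
  dimnames(L) <- dimnames(M)
  L
}
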