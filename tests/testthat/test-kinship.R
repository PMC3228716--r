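# Allele-similarity kinship: similarity index definition, brute-force
# oracle for the matrix, standardization, PSD repair and covariance roots.

test_that("similarity index matches its definition at all endpoints", {
  expect_equal(similarityIndex(c(120, 122), c(120, 122)), 1)
  expect_equal(similarityIndex(c(120, 122), c(124, 126)), 0)
  expect_equal(similarityIndex(c(120, 122), c(120, 124)), 0.5)
  expect_equal(similarityIndex(c(120, 120), c(120, 122)), 0.5)
  expect_equal(similarityIndex(c(122, 120), c(120, 122)), 1)   # unordered
  expect_equal(similarityIndex(c(120, 122), c(120, 124), hetMode = "strict"), 0)
  expect_error(similarityIndex(c(120, NA), c(120, 122)), "missing")
})

test_that("kinship matrix equals a brute-force pairwise/per-locus oracle", {
  cfg <- smallCohortConfig(popSizes = c(A = 5L, B = 5L), nSsrLoci = 8L)
  for (seed in c(21, 22)) {
    co <- simulateCohort(cfg, seed)
    for (hm in c("half", "strict")) {
      K <- kinshipMatrix(co$ssr, hetMode = hm)
      expect_equal(kinship(K), bruteForceKinship(co$ssr, hm),
                   tolerance = 1e-12)
    }
  }
})

test_that("standardization maps the observed range onto [0,1]", {
  co <- smallCohort(23)
  K <- kinshipMatrix(co$ssr)
  km <- kinship(K)
  off <- km[row(km) != col(km)]
  expect_equal(min(off), 0)
  expect_equal(unname(diag(km)), rep(1, nrow(km)))
  expect_true(all(km >= 0 & km <= 1))
  expect_true(min(eigen(km, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-8)
})

test_that("adding a locus identical across genotypes leaves the standardized matrix unchanged", {
  co <- smallCohort(24)
  a1 <- SummarizedExperiment::assay(co$ssr, "allele1")
  a2 <- SummarizedExperiment::assay(co$ssr, "allele2")
  const1 <- rbind(a1, NEW = rep("500", ncol(a1)))
  const2 <- rbind(a2, NEW = rep("500", ncol(a2)))
  rownames(const1) <- rownames(const2) <- c(rownames(a1), "NEW")
  K1 <- kinshipMatrix(co$ssr)
  K2 <- kinshipMatrix(SsrGenotypes(const1, const2))
  expect_equal(kinship(K1), kinship(K2), tolerance = 1e-12)
  expect_gt(rawMinSimilarity(K2), rawMinSimilarity(K1))
})

test_that("kinship is equivariant under genotype permutation", {
  co <- smallCohort(25)
  K1 <- kinship(kinshipMatrix(co$ssr))
  perm <- rev(colnames(co$ssr))
  K2 <- kinship(kinshipMatrix(co$ssr[, perm]))
  expect_equal(K2, K1[perm, perm], tolerance = 1e-12)
})

test_that("within-population relatedness exceeds between-population relatedness", {
  co <- smallCohort(26, smallCohortConfig(popSizes = c(A = 25L, B = 25L),
                                          nSsrLoci = 20L))
  km <- kinship(kinshipMatrix(co$ssr))
  same <- outer(co$populations, co$populations, "==")
  off <- row(km) != col(km)
  expect_gt(mean(km[same & off]), mean(km[!same]))
})

test_that("ensurePSD repairs indefinite matrices and is a no-op on PSD input", {
  expect_identical(ensurePSD(diag(3)), diag(3))
  M <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3)
  dimnames(M) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_lt(min(eigen(M, only.values = TRUE)$values), -1e-8)
  suppressMessages(R <- ensurePSD(M))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8)
  expect_equal(unname(diag(R)), rep(1, 3))
  A <- M; A[1, 2] <- 0.5
  expect_error(ensurePSD(A), "not symmetric")
})

test_that("covariance roots reconstruct K, including rank-deficient cases", {
  expect_equal(covarianceRoot(diag(4)), diag(4))
  K2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  L <- covarianceRoot(K2)
  expect_equal(L %*% t(L), K2, tolerance = 1e-12)
  # duplicated genotype makes K singular
  K3 <- matrix(c(1, 1, 0.3, 1, 1, 0.3, 0.3, 0.3, 1), 3)
  L3 <- covarianceRoot(K3)
  expect_lt(max(abs(L3 %*% t(L3) - K3)), 1e-8)
  expect_error(covarianceRoot(matrix(c(1, 2, 2, 1), 2)), "not positive")
})
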