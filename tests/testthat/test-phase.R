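# Gamete phasing by parent subtraction, haplotype definition, and
# frequency filtering.

miniSiteInfo <- function(ref, genes = "g1") {
  data.frame(site_id = paste0(genes, "_SNP", seq_along(ref)),
             gene_id = rep(genes, length.out = length(ref)),
             site_index = seq_along(ref),
             site_type = "SNP", ref_allele = ref,
             row.names = paste0(genes, "_SNP", seq_along(ref)),
             stringsAsFactors = FALSE)
}

test_that("phasing subtracts the common parent allele", {
  si <- miniSiteInfo(c("A", "C"))
  a1 <- matrix(c("A", "A", "C", "C"), 2, 2, byrow = TRUE,
               dimnames = list(rownames(si), c("g1", "g2")))
  a2 <- matrix(c("G", "A", "C", "T"), 2, 2, byrow = TRUE,
               dimnames = dimnames(a1))
  mk <- phaseGametes(list(allele1 = a1, allele2 = a2), si)
  al <- alleleMatrix(mk)
  expect_equal(al["g1_SNP1", "g1"], "G")   # het: non-parent member
  expect_equal(al["g1_SNP1", "g2"], "A")   # parent-homozygous
  expect_equal(al["g1_SNP2", "g1"], "C")
  expect_equal(al["g1_SNP2", "g2"], "T")

  # neither allele equals the parent: flagged and set missing
  a2[1, 1] <- "T"; a1[1, 1] <- "G"
  expect_message(mk2 <- phaseGametes(list(allele1 = a1, allele2 = a2), si),
                 "no parent allele")
  expect_true(is.na(alleleMatrix(mk2)["g1_SNP1", "g1"]))
  expect_equal(S4Vectors::metadata(mk2)$nonparental, 1L)

  si$ref_allele[2] <- NA
  expect_error(phaseGametes(list(allele1 = a1, allele2 = a2), si),
               "parent allele absent")
})

test_that("phasing inverts parent addition exactly on simulated cohorts", {
  for (seed in c(31, 32, 33)) {
    co <- smallCohort(seed)
    mk <- phaseGametes(co$s0, co$siteInfo)
    expect_identical(alleleMatrix(mk), co$truth$gametes)
  }
})

test_that("haplotypes are counted, labelled by frequency, and ref-anchored", {
  si <- miniSiteInfo(c("A", "C"))
  al <- matrix(c("A", "A", "A", "A",
                 "G", "G", "T", "G"), 2, 4, byrow = TRUE,
               dimnames = list(rownames(si), paste0("g", 1:4)))
  hs <- defineHaplotypes(MarkerPanel(al, si), "g1")
  expect_equal(haploFreq(hs), c(hap1 = 0.75, hap2 = 0.25))
  expect_equal(haploSequences(hs)[["hap1"]], "AG")
  expect_equal(haploSequences(hs)[["ref"]], "AC")  # always present
  expect_error(defineHaplotypes(MarkerPanel(al, si), "nope"), "zero sites")

  # everyone identical to the parent string
  al2 <- matrix(c("A", "A", "C", "C"), 2, 2, byrow = TRUE,
                dimnames = list(rownames(si), c("g1", "g2")))
  hs2 <- defineHaplotypes(MarkerPanel(al2, si), "g1")
  expect_equal(haploFreq(hs2), c(ref = 1))

  # invariance under genotype reordering
  hs3 <- defineHaplotypes(MarkerPanel(al[, c(3, 1, 4, 2)], si), "g1")
  expect_equal(haploFreq(hs3), haploFreq(hs))
  expect_equal(sum(haploFreq(hs)), 1)
})

test_that("haplotype recovery matches the simulator's pool partition", {
  co <- smallCohort(34)
  mk <- phaseGametes(co$s0, co$siteInfo)
  for (g in co$siteInfo$gene_id[!duplicated(co$siteInfo$gene_id)]) {
    hs <- defineHaplotypes(mk, g)
    lab <- haploAssignment(hs)
    pool <- co$truth$poolAssign[, g]
    # genotypes drawing the same ancestral pool haplotype get the same label
    for (p in unique(pool))
      expect_length(unique(lab[pool == p]), 1L)
  }
})

test_that("MAF filtering is strict, correct, and idempotent", {
  # biallelic site with minor frequency exactly at the threshold: dropped
  si <- miniSiteInfo(c("A", "A"))
  al <- rbind(rep(c("A", "G"), c(19, 1)),        # maf 0.05 -> dropped
              rep(c("A", "G"), c(10, 10)))       # maf 0.50 -> retained
  dimnames(al) <- list(rownames(si), paste0("g", 1:20))
  mk <- MarkerPanel(al, si)
  kept <- filterMAF(mk, 0.05)
  expect_equal(rownames(kept), "g1_SNP2")
  expect_identical(alleleMatrix(filterMAF(kept, 0.05)), alleleMatrix(kept))

  # brute-force recount on a random simulated panel
  co <- smallCohort(35, smallCohortConfig(popSizes = c(A = 100L, B = 100L)))
  mk2 <- phaseGametes(co$s0, co$siteInfo)
  kept2 <- filterMAF(mk2, 0.2)
  manual <- vapply(rownames(alleleMatrix(mk2)), function(s) {
    x <- alleleMatrix(mk2)[s, ]; x <- x[!is.na(x)]
    tab <- sort(table(x), decreasing = TRUE)
    maf <- if (length(tab) < 2) 0 else as.numeric(tab[2]) / length(x)
    maf > 0.2
  }, logical(1))
  expect_identical(rownames(kept2), names(manual)[manual])
})

test_that("rare haplotypes are set missing and frequencies renormalized", {
  assign <- c(rep("ref", 8), rep("hap1", 8), rep("hap2", 1))
  names(assign) <- paste0("g", seq_along(assign))
  hs <- methods::new("HaplotypeSet", gene = "g1",
                     sequences = c(ref = "AA", hap1 = "AG", hap2 = "GG"),
                     assignment = assign,
                     freq = c(ref = 8 / 17, hap1 = 8 / 17, hap2 = 1 / 17))
  out <- filterMAF(hs, 0.1)
  expect_true(is.na(haploAssignment(out)[["g17"]]))
  expect_equal(haploFreq(out), c(ref = 0.5, hap1 = 0.5))
  expect_equal(haploFreq(filterMAF(out, 0.1)), haploFreq(out))
  expect_true("hap2" %in% names(haploSequences(out)))  # kept for reference
})

test_that("multi-allelic sites are coded top non-reference vs reference", {
  si <- miniSiteInfo("A")
  al <- matrix(c("A", "A", "G", "G", "G", "T"), 1,
               dimnames = list(rownames(si), paste0("g", 1:6)))
  d <- ryeassoc:::biallelicDosage(MarkerPanel(al, si))
  expect_equal(unname(d[1, ]), c(0, 0, 1, 1, 1, NA))
})
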