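# Gamete phasing by common-parent subtraction, within-gene haplotype
# definition, and minor-allele / minor-haplotype frequency filtering.

#' Phase gametes by subtracting the common parent's alleles
#'
#' In a gamete-capture testcross every S0 plant carries one gamete of its
#' source population plus one gamete of the homozygous common parent, so
#' the population gamete at each site is the non-parent member of the
#' diploid allele pair.  A pair homozygous for the parent allele phases to
#' the parent allele itself.  A pair in which neither allele equals the
#' parent allele cannot originate from the testcross (genotyping error) and
#' is set missing; the count is reported via \code{message()} and stored in
#' \code{metadata(x)$nonparental}.
#'
#' @param s0 list with character matrices \code{allele1} and \code{allele2}
#'   (sites x genotypes, unordered diploid S0 calls) as produced by
#'   [simulateCohort()].
#' @param siteInfo site metadata data.frame (see [MarkerPanel()]); its
#'   \code{ref_allele} column is the common-parent allele and must be
#'   non-missing at every site.
#' @return [MarkerPanel-class] of phased gamete alleles.
#' @export
phaseGametes <- function(s0, siteInfo) {
  a1 <- s0$allele1; a2 <- s0$allele2
  stopifnot(identical(dim(a1), dim(a2)),
            identical(rownames(a1), rownames(siteInfo)))
  ref <- siteInfo$ref_allele
  if (anyNA(ref)) stop("common-parent allele absent for site(s): ",
                       paste(rownames(siteInfo)[is.na(ref)], collapse = ", "))
  refM <- matrix(ref, nrow = nrow(a1), ncol = ncol(a1))
  is1 <- a1 == refM
  is2 <- a2 == refM
  gam <- matrix(NA_character_, nrow(a1), ncol(a1), dimnames = dimnames(a1))
  gam[which(is1)] <- a2[which(is1)]         # parent is allele1 -> gamete is allele2
  gam[which(!is1 & is2)] <- a1[which(!is1 & is2)]
  nonparental <- sum(!is1 & !is2, na.rm = TRUE)
  if (nonparental > 0)
    message("phaseGametes: ", nonparental,
            " call(s) carried no parent allele; set missing")
  out <- MarkerPanel(gam, siteInfo)
  S4Vectors::metadata(out)$nonparental <- nonparental
  out
}

#' Define within-gene haplotypes from phased gametes
#'
#' Concatenates the gamete alleles over one gene's sites (in
#' \code{site_index} order) into an allele string per genotype; each
#' distinct string is one haplotype.  Genotypes missing any site in the
#' gene are unassigned.  Labels are \code{"hap1"}, \code{"hap2"}, ... in
#' decreasing frequency order, except that the common parent's string is
#' always labelled \code{"ref"}.
#'
#' @param markers phased [MarkerPanel-class].
#' @param gene gene identifier (must have at least one site).
#' @return [HaplotypeSet-class]
#' @export
defineHaplotypes <- function(markers, gene) {
  rd <- siteInfo(markers)
  sel <- which(rd$gene_id == gene)
  if (!length(sel)) stop("gene with zero sites: ", gene)
  sel <- sel[order(rd$site_index[sel])]
  al <- alleleMatrix(markers)[sel, , drop = FALSE]
  refString <- paste(rd$ref_allele[sel], collapse = "")
  strings <- apply(al, 2L, function(x) if (anyNA(x)) NA_character_
                   else paste(x, collapse = ""))
  obs <- strings[!is.na(strings)]
  tab <- sort(table(obs), decreasing = TRUE)
  labs <- character(length(tab))
  nonref <- names(tab) != refString
  labs[nonref] <- paste0("hap", seq_len(sum(nonref)))
  labs[!nonref] <- "ref"
  seqs <- stats::setNames(names(tab), labs)
  if (!"ref" %in% labs) seqs <- c(seqs, ref = refString)
  assignment <- stats::setNames(labs[match(strings, names(tab))], names(strings))
  freq <- stats::setNames(as.numeric(tab) / sum(tab), labs)
  methods::new("HaplotypeSet", gene = gene, sequences = seqs,
               assignment = assignment, freq = freq)
}

#' Minor-allele frequencies of a marker panel
#'
#' Per site, the relative frequency of the second most frequent allele
#' among non-missing gametes (the minor-allele frequency for biallelic
#' sites).
#' @param markers [MarkerPanel-class]
#' @return named numeric vector, one entry per site.
#' @export
mafSites <- function(markers) {
  al <- alleleMatrix(markers)
  apply(al, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) < 2L) return(0)
    as.numeric(tab[2L]) / length(x)
  })
}

#' Filter markers or haplotypes on minor-allele frequency
#'
#' Units whose minor-allele (minor-haplotype) frequency over non-missing
#' gametes is less than or equal to \code{threshold} are removed; the
#' inequality is strict, so a frequency exactly at the threshold is
#' dropped (the "> 5\%" rule).  For a [HaplotypeSet-class], genotypes
#' carrying a removed haplotype become missing and the remaining
#' frequencies are recomputed; the dropped labels are kept in
#' \code{sequences} for reference.  The operation is idempotent.
#'
#' @param x [MarkerPanel-class] or [HaplotypeSet-class].
#' @param threshold frequency threshold in (0, 0.5); default 0.05.
#' @return object of the same class.
#' @export
setGeneric("filterMAF", function(x, threshold = 0.05) standardGeneric("filterMAF"))

#' @rdname filterMAF
#' @export
setMethod("filterMAF", "MarkerPanel", function(x, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 0.5)
  keep <- mafSites(x) > threshold
  if (!any(keep)) message("filterMAF: no sites survive the threshold")
  x[keep, ]
})

#' @rdname filterMAF
#' @export
setMethod("filterMAF", "HaplotypeSet", function(x, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 0.5)
  freq <- x@freq
  drop <- names(freq)[freq <= threshold]
  if (!length(drop)) return(x)
  assignment <- x@assignment
  assignment[assignment %in% drop] <- NA_character_
  obs <- assignment[!is.na(assignment)]
  freq <- if (length(obs)) table(factor(obs, levels = setdiff(names(freq), drop)))
          else table(factor(character(), levels = setdiff(names(freq), drop)))
  freq <- stats::setNames(as.numeric(freq) / max(1L, length(obs)), names(freq))
  methods::new("HaplotypeSet", gene = x@gene, sequences = x@sequences,
               assignment = assignment, freq = freq)
})

# 0/1 dosage of the most frequent non-reference allele vs the reference
# allele; gametes carrying any other allele are set missing for that site
# (single allelic-effect coding).
biallelicDosage <- function(markers) {
  al <- alleleMatrix(markers)
  ref <- siteInfo(markers)$ref_allele
  out <- matrix(NA_real_, nrow(al), ncol(al), dimnames = dimnames(al))
  for (i in seq_len(nrow(al))) {
    x <- al[i, ]
    nonref <- x[!is.na(x) & x != ref[i]]
    out[i, !is.na(x) & x == ref[i]] <- 0
    if (length(nonref)) {
      top <- names(sort(table(nonref), decreasing = TRUE))[1L]
      out[i, !is.na(x) & x == top] <- 1
    }
  }
  out
}
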