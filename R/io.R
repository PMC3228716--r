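# Tab-separated readers and writers for all pipeline artifacts.
# Dialect: UTF-8 TSV with a header row, "NA" as the missing sentinel, and
# provenance comment lines prefixed "#" (tool version, seed, config hash)
# that every reader skips.

provenanceHeader <- function(seed = NULL, extra = character()) {
  h <- paste0("# ryeassoc ", as.character(utils::packageVersion("ryeassoc")))
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  if (length(extra)) h <- c(h, paste0("# ", extra))
  h
}

writeTsv <- function(df, path, seed = NULL, extra = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenanceHeader(seed, extra), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a diploid SSR genotype table
#'
#' One row per genotype with a \code{genotype_id} column.  Each locus is
#' either a single column of \code{"a/b"} allele pairs or a pair of columns
#' \code{<locus>_1}/\code{<locus>_2}.  Cells that cannot be parsed into two
#' alleles become missing with a warning.
#'
#' @param path TSV file path.
#' @return [SsrGenotypes-class]
#' @export
readSsrTable <- function(path) {
  df <- readTsv(path)
  if (!"genotype_id" %in% names(df)) stop("column 'genotype_id' is required")
  ids <- as.character(df$genotype_id)
  if (anyDuplicated(ids))
    stop("duplicated genotype_id: ", ids[duplicated(ids)][1])
  cols <- setdiff(names(df), "genotype_id")
  if (!length(cols)) stop("zero SSR loci in ", path)
  pair1 <- grep("_1$", cols, value = TRUE)
  if (length(pair1) && all(sub("_1$", "_2", pair1) %in% cols)) {
    loci <- sub("_1$", "", pair1)
    a1 <- t(as.matrix(df[paste0(loci, "_1")]))
    a2 <- t(as.matrix(df[paste0(loci, "_2")]))
    mode(a1) <- mode(a2) <- "character"
  } else {
    loci <- cols
    parse <- function(x) {
      parts <- strsplit(as.character(x), "/", fixed = TRUE)
      bad <- lengths(parts) != 2L & !is.na(x)
      if (any(bad)) {
        warning(sum(bad), " unparseable SSR allele cell(s) set to missing")
        parts[bad] <- list(c(NA_character_, NA_character_))
      }
      parts[is.na(x)] <- list(c(NA_character_, NA_character_))
      do.call(cbind, parts)
    }
    mats <- lapply(df[loci], parse)
    a1 <- do.call(rbind, lapply(mats, function(m) m[1L, ]))
    a2 <- do.call(rbind, lapply(mats, function(m) m[2L, ]))
  }
  dimnames(a1) <- dimnames(a2) <- list(loci, ids)
  SsrGenotypes(a1, a2)
}

#' Write a diploid SSR genotype table
#'
#' Inverse of [readSsrTable()] (single-column \code{"a/b"} dialect).
#' @param ssr [SsrGenotypes-class]
#' @param path output TSV path.
#' @param seed optional seed recorded in the provenance header.
#' @export
writeSsrTable <- function(ssr, path, seed = NULL) {
  a1 <- SummarizedExperiment::assay(ssr, "allele1")
  a2 <- SummarizedExperiment::assay(ssr, "allele2")
  pair <- matrix(paste0(a1, "/", a2), nrow = nrow(a1), dimnames = dimnames(a1))
  pair[is.na(a1)] <- NA_character_
  df <- data.frame(genotype_id = colnames(a1), t(pair), check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path, seed = seed)
}

#' Read a candidate-gene marker panel
#'
#' @param path genotype x site TSV (rows = genotypes, \code{genotype_id}
#'   column, one column per site holding the gamete allele).
#' @param siteMetadataPath TSV with columns \code{site_id}, \code{gene_id},
#'   \code{site_index}, \code{site_type}, \code{ref_allele}.
#' @return [MarkerPanel-class]; a site present in the data but absent from
#'   the metadata is an error.
#' @export
readMarkerTable <- function(path, siteMetadataPath) {
  df <- readTsv(path)
  meta <- readTsv(siteMetadataPath)
  if (!"genotype_id" %in% names(df)) stop("column 'genotype_id' is required")
  ids <- as.character(df$genotype_id)
  if (anyDuplicated(ids))
    stop("duplicated genotype_id: ", ids[duplicated(ids)][1])
  sites <- setdiff(names(df), "genotype_id")
  missingMeta <- setdiff(sites, meta$site_id)
  if (length(missingMeta))
    stop("site(s) absent from metadata: ", paste(missingMeta, collapse = ", "))
  meta <- meta[match(sites, meta$site_id), , drop = FALSE]
  allele <- t(as.matrix(df[sites]))
  mode(allele) <- "character"
  dimnames(allele) <- list(sites, ids)
  MarkerPanel(allele, meta)
}

#' Write a marker panel (and its site metadata)
#'
#' @param markers [MarkerPanel-class]
#' @param path output TSV for the genotype x site allele table.
#' @param siteMetadataPath output TSV for the site metadata.
#' @param seed optional seed recorded in the provenance header.
#' @export
writeMarkerTable <- function(markers, path, siteMetadataPath, seed = NULL) {
  al <- alleleMatrix(markers)
  df <- data.frame(genotype_id = colnames(al), t(al), check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path, seed = seed)
  meta <- cbind(site_id = rownames(al), siteInfo(markers))
  writeTsv(meta, siteMetadataPath, seed = seed)
  invisible(path)
}

#' Read a population-structure (Q) matrix
#'
#' Rows off unit sum by at most 1e-6 are renormalized; larger deviations
#' are an error.
#' @param path TSV with \code{genotype_id} plus one column per cluster.
#' @return [StructureMatrix-class]
#' @export
readQMatrix <- function(path) {
  df <- readTsv(path)
  Q <- as.matrix(df[setdiff(names(df), "genotype_id")])
  rownames(Q) <- as.character(df$genotype_id)
  StructureMatrix(Q)
}

#' Write a named numeric matrix (kinship, Q, ...) as TSV
#'
#' @param m matrix with genotype rownames, or a [KinshipMatrix-class] /
#'   [StructureMatrix-class].
#' @param path output TSV path.
#' @param seed optional seed recorded in the provenance header.
#' @export
writeMatrix <- function(m, path, seed = NULL) {
  if (methods::is(m, "KinshipMatrix")) m <- kinship(m)
  if (methods::is(m, "StructureMatrix")) m <- qMatrix(m)
  df <- data.frame(genotype_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path, seed = seed)
}

#' Read a kinship matrix written by [writeMatrix()]
#' @param path TSV path.
#' @param hetMode annotation only; scoring mode recorded on the object.
#' @return [KinshipMatrix-class]
#' @export
readKinshipMatrix <- function(path, hetMode = "half") {
  df <- readTsv(path)
  K <- as.matrix(df[setdiff(names(df), "genotype_id")])
  rownames(K) <- as.character(df$genotype_id)
  K <- (K + t(K)) / 2
  methods::new("KinshipMatrix", K = K, sMin = NA_real_, hetMode = hetMode)
}

phenotypeColumns <- c("genotype_id", "platform", "year", "environment",
                      "temperature", "month", "chamber", "replicate",
                      "block", "value")

#' Validate a long-format multi-platform phenotype table
#'
#' Platforms are \code{"controlled"} (recovery score 0-5; needs year,
#' temperature, chamber, replicate), \code{"semi_controlled"} (% plants
#' with undamaged leaves; needs year, month, replicate) and \code{"field"}
#' (% survival; needs environment, block, replicate).
#'
#' @param df data.frame in the long layout (see
#'   [simulatePhenotypes()] for the writer side).
#' @return the validated data.frame, invisibly classed for downstream use.
#' @export
validatePhenotypes <- function(df) {
  need <- c("genotype_id", "platform", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns ", paste(need, collapse = ", "))
  ok <- df$platform %in% c("controlled", "semi_controlled", "field")
  if (!all(ok)) stop("unknown platform: ", unique(df$platform[!ok])[1])
  requireCols <- function(p, cols) {
    sub <- df[df$platform == p, , drop = FALSE]
    if (!nrow(sub)) return(invisible())
    miss <- cols[!cols %in% names(df)]
    if (length(miss)) stop(p, " rows need column(s) ", paste(miss, collapse = ", "))
    for (cc in cols) if (anyNA(sub[[cc]]))
      stop(p, " rows have missing values in required column ", cc)
  }
  requireCols("controlled", c("year", "temperature", "chamber", "replicate"))
  requireCols("semi_controlled", c("year", "month", "replicate"))
  requireCols("field", c("environment", "block", "replicate"))
  v <- df$value
  ctl <- df$platform == "controlled"
  if (any(v[ctl] < 0 | v[ctl] > 5, na.rm = TRUE))
    stop("controlled recovery scores must lie in [0, 5]")
  if (any(v[!ctl] < 0 | v[!ctl] > 100, na.rm = TRUE))
    stop("percentage outcomes must lie in [0, 100]")
  df
}

#' Read / write phenotype tables
#' @param path TSV path.
#' @return data.frame validated by [validatePhenotypes()].
#' @export
readPhenotypeTable <- function(path) validatePhenotypes(readTsv(path))

#' @rdname readPhenotypeTable
#' @param df phenotype data.frame.
#' @param seed optional seed recorded in the provenance header.
#' @export
writePhenotypeTable <- function(df, path, seed = NULL) {
  writeTsv(validatePhenotypes(df), path, seed = seed)
}

#' Write scan results as TSV
#' @param results [ScanResults-class] or plain data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @export
writeResults <- function(results, path, seed = NULL) {
  tb <- if (methods::is(results, "ScanResults")) resultsTable(results) else results
  writeTsv(tb, path, seed = seed,
           extra = if (methods::is(results, "ScanResults"))
             paste("kind:", results@kind) else character())
}

#' @rdname writeResults
#' @export
readResults <- function(path) readTsv(path)
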