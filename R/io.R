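#' Read/write the wide trio site table as TSV
#'
#' @param sites site table data.frame.
#' @param path file path.
#' @return \code{readSiteTable} returns the data.frame;
#'   \code{writeSiteTable} returns \code{path} invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = ".",
                   stringsAsFactors = FALSE)
  df$LOWQ <- as.logical(df$LOWQ)
  df
}

#' Write DNM calls (and their rejection ledger) as TSV
#'
#' @param callSet a \linkS4class{DnmCallSet} or a calls data.frame.
#' @param path output TSV for the calls.
#' @param rejectionsPath optional output TSV for the rejection ledger.
#' @return \code{path}, invisibly.
#' @export
writeDnmCalls <- function(callSet, path, rejectionsPath = NULL) {
  calls <- if (is(callSet, "DnmCallSet")) callSet@calls else callSet
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rejectionsPath) && is(callSet, "DnmCallSet"))
    write.table(callSet@rejections, rejectionsPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a trio experiment as a minimal multi-sample VCF
#'
#' Writes variant rows (sites with an alternate allele) with per-sample
#' GT:DP:AD genotypes (AD as ref,alt read counts), site mapping quality in
#' INFO/MQ, the carrier-read complexity in INFO/NONREF, and FILTER set to
#' \code{LowQual} for caller-flagged sites. Readable by standard VCF
#' parsers; re-import with \code{\link{readTrioVcf}}.
#'
#' @param experiment a \linkS4class{TrioExperiment}.
#' @param path output path (plain text).
#' @param variantOnly drop rows without an alternate allele (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeSiteVcf <- function(experiment, path, variantOnly = TRUE) {
  sites <- experiment@sites
  samples <- c(experiment@samples$parents, experiment@samples$offspring)
  if (variantOnly) sites <- sites[!is.na(sites$alt), , drop = FALSE]
  lens <- Biostrings::width(experiment@reference)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(experiment@reference), lens),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Site mapping quality\">",
           "##INFO=<ID=NONREF,Number=1,Type=Integer,Description=\"Max non-reference positions on a supporting read\">",
           "##FILTER=<ID=LowQual,Description=\"Flagged low quality by the caller\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read counts\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  if (nrow(sites)) {
    gtBlock <- vapply(seq_len(nrow(sites)), function(i) {
      paste(vapply(samples, function(s) {
        dp <- sites[[.dpCol(s)]][i]
        ad <- sites[[.adCol(s)]][i]
        sprintf("%s:%d:%d,%d", sites[[.gtCol(s)]][i], dp, dp - ad, ad)
      }, character(1)), collapse = "\t")
    }, character(1))
    body <- paste(sites$chrom, sites$pos, ".", sites$ref,
                  ifelse(is.na(sites$alt), ".", sites$alt), ".",
                  ifelse(sites$LOWQ, "LowQual", "PASS"),
                  sprintf("MQ=%g;NONREF=%d", sites$MQ, sites$NONREF),
                  "GT:DP:AD", gtBlock, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Import a multi-sample trio VCF as a wide site table
#'
#' Uses \pkg{VariantAnnotation} to parse the VCF and reshapes the GT/DP/AD
#' genotype fields into the package's wide site-table layout. Site mapping
#' quality is taken from INFO/MQ when present (60 otherwise) and the
#' low-quality flag from FILTER.
#'
#' @param path VCF path.
#' @param parents character(2): sample names of the parents.
#' @return list(sites, samples) ready for \code{\link{callDnms}}.
#' @export
readTrioVcf <- function(path, parents) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    .stopf("readTrioVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  sampleNames <- colnames(vcf)
  if (!all(parents %in% sampleNames))
    .stopf("parents not found among VCF samples")
  offspring <- setdiff(sampleNames, parents)
  alt <- vapply(as.list(rr$ALT), function(a)
    if (length(a) && nchar(as.character(a[1]))) as.character(a[1])
    else NA_character_, character(1))
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  mq <- if ("MQ" %in% names(info)) as.numeric(info$MQ) else rep(60, n)
  nonref <- if ("NONREF" %in% names(info)) as.integer(info$NONREF)
            else rep(1L, n)
  filt <- rr$FILTER
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF), alt = alt, MQ = mq,
    LOWQ = !is.na(filt) & filt != "PASS" & filt != ".",
    NONREF = nonref, stringsAsFactors = FALSE)
  geno <- VariantAnnotation::geno(vcf)
  for (s in sampleNames) {
    sites[[.gtCol(s)]] <- as.character(geno$GT[, s])
    sites[[.dpCol(s)]] <- as.integer(geno$DP[, s])
    ad <- geno$AD[, s]
    sites[[.adCol(s)]] <- vapply(ad, function(z)
      if (length(z) >= 2) as.integer(z[2]) else 0L, integer(1))
  }
  rownames(sites) <- NULL
  list(sites = sites, samples = list(parents = parents,
                                     offspring = offspring))
}

#' Export the reference and annotation of an experiment
#'
#' FASTA via \pkg{Biostrings}; BED (0-based half-open) via \pkg{rtracklayer}.
#'
#' @param experiment a \linkS4class{TrioExperiment}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
exportTracks <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(experiment@reference, fa)
  out <- c(fasta = fa)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gb <- file.path(dir, "genes.bed")
    cb <- file.path(dir, "cpg_islands.bed")
    rtracklayer::export(experiment@genes, gb, format = "BED")
    rtracklayer::export(experiment@cpgIslands, cb, format = "BED")
    out <- c(out, genes = gb, cpgIslands = cb)
  }
  invisible(out)
}

#' Write the simulated truth set as a VCF-like TSV (1-based positions)
#'
#' @param experiment a \linkS4class{TrioExperiment}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeTruthSet <- function(experiment, path) {
  write.table(experiment@truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
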