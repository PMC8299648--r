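# Readers and writers for the standard formats around the pipeline:
# GTF (annotation), BED (site sets), SAM/BAM (alignments), FASTA/FASTQ.

#' Extract 3'UTR intervals from a GTF annotation
#'
#' Uses `three_prime_utr` records when the annotation provides them
#' (GENCODE dialect). Otherwise, for transcripts with a CDS the region of
#' each exon 3' of the annotated stop codon is taken, and for transcripts
#' without a CDS the terminal exon stands in.
#'
#' @param gtf path to a GTF file or a `GRanges` imported from one.
#' @return `GRanges` of 3'UTR intervals with a `gene_id` column.
#' @export
extract_utr3 <- function(gtf) {
  gr <- .import_gtf(gtf)
  if (any(gr$type == "three_prime_utr")) {
    u <- gr[gr$type == "three_prime_utr"]
    out <- GenomicRanges::granges(u, use.mcols = FALSE)
    out$gene_id <- u$gene_id
    return(unname(out))
  }
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx]
    minus <- as.character(GenomicRanges::strand(e)[1L]) == "-"
    ctx <- cds[!is.na(cds$transcript_id) & cds$transcript_id == tx]
    if (length(ctx) > 0L) {
      # region strictly 3' of the CDS, intersected with the exons
      bound <- if (minus) min(GenomicRanges::start(ctx)) else
        max(GenomicRanges::end(ctx))
      reg <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(e)[1L],
        if (minus) IRanges::IRanges(1L, bound - 1L)
        else IRanges::IRanges(bound + 1L, .Machine$integer.max %/% 2L),
        strand = GenomicRanges::strand(e)[1L])
      u <- GenomicRanges::pintersect(e, rep(reg, length(e)),
                                     drop.nohit.ranges = TRUE)
    } else {
      u <- if (minus) e[which.min(GenomicRanges::start(e))]
           else e[which.max(GenomicRanges::end(e))]
    }
    if (length(u) > 0L) {
      u2 <- GenomicRanges::granges(u, use.mcols = FALSE)
      u2$gene_id <- e$gene_id[1L]
      out[[tx]] <- u2
    }
  }
  if (length(out) == 0L)
    stop("no 3'UTR intervals could be derived from the annotation")
  res <- unname(do.call(c, unname(out)))
  res
}

.import_gtf <- function(gtf) {
  if (is(gtf, "GRanges")) gtf else rtracklayer::import(gtf, format = "gtf")
}

#' Derive gene bodies from a GTF annotation
#'
#' Returns one interval per gene: the `gene` record when present, otherwise
#' the union span of the gene's transcripts/exons. Strand is kept.
#'
#' @inheritParams extract_utr3
#' @return `GRanges` with one range per gene and a `gene_id` column.
#' @export
gene_bodies <- function(gtf) {
  gr <- .import_gtf(gtf)
  if (any(gr$type == "gene")) {
    g <- gr[gr$type == "gene"]
    out <- GenomicRanges::granges(g, use.mcols = FALSE)
    out$gene_id <- g$gene_id
    return(unname(out))
  }
  ex <- gr[gr$type %in% c("exon", "transcript")]
  sp <- split(ex, ex$gene_id)
  out <- unlist(GenomicRanges::reduce(GenomicRanges::range(sp)))
  res <- unname(out)
  res$gene_id <- names(out)
  res
}

#' Read an annotated poly(A)-site BED file
#'
#' Expects BED6 single-nucleotide intervals (polyA_DB-style exports).
#'
#' @param path BED file path.
#' @return `GRanges` of single-nt sites.
#' @export
read_sites_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write called sites as BED6
#'
#' Each site becomes a single-nucleotide, 0-based half-open interval; the
#' name is the site id and the score the tag count.
#'
#' @param sites site data.frame (see [call_sites()]).
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos + 1L, width = 1L),
                               strand = sites$strand)
  gr$name <- sprintf("pas_%05d", seq_along(gr))
  gr$score <- sites$tag_count
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# Write a minimal SAM file for a truth alignment table produced by the
# simulator. `aln` needs qname, chrom, strand, pos1 (1-based leftmost),
# seq, cell_barcode, umi, polya_flag.
.write_sam <- function(aln, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(seqlengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, seqlengths[[ch]]), con)
  if (nrow(aln) > 0L) {
    ord <- order(aln$chrom, aln$pos1)
    aln <- aln[ord, ]
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    seq <- ifelse(aln$strand == "-",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(aln$seq))), aln$seq)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s\tXA:i:%d",
                     aln$qname, flag, aln$chrom, aln$pos1, nchar(seq), seq,
                     strrep("I", nchar(seq)), aln$cell_barcode, aln$umi,
                     as.integer(aln$polya_flag))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Convert a SAM text file to sorted, indexed BAM
#'
#' @param sam input SAM path.
#' @param dest output stem (default: input without extension).
#' @return the BAM path.
#' @export
sam_to_bam <- function(sam, dest = sub("\\.sam$", "", sam)) {
  suppressMessages(Rsamtools::asBam(sam, dest, overwrite = TRUE,
                                    indexDestination = TRUE))
}

#' Write an isoform count experiment to a directory
#'
#' Emits `counts.mtx` (MatrixMarket), `isoforms.tsv` (row metadata) and
#' `cells.tsv` (column metadata), the exchange format used by the
#' command-line interface.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay (see
#'   [count_isoforms()]).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_isoform_counts <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(SummarizedExperiment::assay(sce, "counts"),
                              "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(sce)),
                     file.path(dir, "isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cbind(cell = colnames(sce), cd)
  utils::write.table(cd, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an isoform count experiment back from a directory
#'
#' Counterpart of [write_isoform_counts()]; the usage assay is recomputed.
#'
#' @param dir directory holding `counts.mtx`, `isoforms.tsv`, `cells.tsv`.
#' @return `SingleCellExperiment` with `counts` and `usage` assays.
#' @export
read_isoform_counts <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                   "CsparseMatrix")
  rd <- utils::read.delim(file.path(dir, "isoforms.tsv"),
                          stringsAsFactors = FALSE)
  cd <- utils::read.delim(file.path(dir, "cells.tsv"),
                          stringsAsFactors = FALSE)
  dimnames(m) <- list(rd$isoform_id, cd$cell)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(cd[, setdiff(names(cd), "cell"),
                                      drop = FALSE],
                                   row.names = cd$cell))
  add_usage(sce)
}
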