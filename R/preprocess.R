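# Read labeling, poly(A) trimming, alignment deduplication and
# demultiplexing for 3'-tag scRNA-seq libraries.

#' Describe the barcode/UMI layout of read1
#'
#' 3'-tag protocols place a cell barcode and a unique molecular identifier
#' (UMI) at fixed positions of read1 while read2 carries the cDNA. The
#' layout records where each element starts (1-based) and how long it is,
#' plus an optional barcode whitelist for exact-match filtering.
#'
#' @param bc_start,bc_len 1-based start and length (nt) of the cell barcode.
#' @param umi_start,umi_len 1-based start and length (nt) of the UMI.
#' @param whitelist optional character vector of valid barcodes; reads whose
#'   barcode is not listed are dropped (exact match, no error correction).
#' @return a `barcode_layout` object.
#' @export
barcode_layout <- function(bc_start = 1L, bc_len, umi_start, umi_len,
                           whitelist = NULL) {
  bc <- c(bc_start, bc_start + bc_len - 1L)
  um <- c(umi_start, umi_start + umi_len - 1L)
  if (bc_len < 1L || umi_len < 1L || bc_start < 1L || umi_start < 1L)
    stop("barcode and UMI intervals must have positive length")
  if (max(bc[1], um[1]) <= min(bc[2], um[2]))
    stop("barcode and UMI intervals overlap")
  structure(list(bc_start = as.integer(bc_start), bc_len = as.integer(bc_len),
                 umi_start = as.integer(umi_start),
                 umi_len = as.integer(umi_len),
                 whitelist = whitelist),
            class = "barcode_layout")
}

#' Label read2 with the cell barcode and UMI extracted from read1
#'
#' Appends `_CB:<barcode>_UB:<umi>` to each read2 name so the labels survive
#' any downstream aligner. Read pairs whose read1 is shorter than the layout
#' requires, or whose barcode misses the whitelist, are dropped and counted.
#'
#' @param read1,read2 `DNAStringSet` objects of equal length; `read2` may
#'   carry qualities in `mcols(read2)$qualities`.
#' @param layout a [barcode_layout()].
#' @return list with `reads` (labeled read2 `DNAStringSet`, qualities kept),
#'   `barcode` and `umi` character vectors, and a `stats` list
#'   (`n_in`, `n_labeled`, `n_short_read1`, `n_not_whitelisted`,
#'   `n_barcodes`).
#' @export
label_reads <- function(read1, read2, layout) {
  stopifnot(is(layout, "barcode_layout"))
  if (length(read1) != length(read2))
    stop("read1 and read2 must have the same number of records")
  n_in <- length(read1)
  need <- max(layout$bc_start + layout$bc_len,
              layout$umi_start + layout$umi_len) - 1L
  ok <- Biostrings::width(read1) >= need
  n_short <- sum(!ok)
  s1 <- as.character(read1[ok])
  bc <- substr(s1, layout$bc_start, layout$bc_start + layout$bc_len - 1L)
  umi <- substr(s1, layout$umi_start, layout$umi_start + layout$umi_len - 1L)
  keep <- rep(TRUE, length(bc))
  if (!is.null(layout$whitelist)) keep <- bc %in% layout$whitelist
  n_wl <- sum(!keep)
  out <- read2[ok][keep]
  bc <- bc[keep]; umi <- umi[keep]
  if (length(out) > 0L) {
    nm <- names(out)
    if (is.null(nm)) nm <- paste0("read", seq_along(out))
    names(out) <- paste0(nm, "_CB:", bc, "_UB:", umi)
  }
  list(reads = out, barcode = bc, umi = umi,
       stats = list(n_in = n_in, n_labeled = length(out),
                    n_short_read1 = n_short, n_not_whitelisted = n_wl,
                    n_barcodes = length(unique(bc))))
}

#' Trim poly(A) tails and tag reads as polyA / non-polyA
#'
#' Scans each read 5'->3' for the first run of at least `polya_run`
#' consecutive adenines, truncates the read at the start of that run and
#' flags it `polyA`; reads without such a run are kept unchanged and flagged
#' `non-polyA`. Trimmed reads shorter than `min_len` are discarded. `N`
#' bases never count toward a run. The flag is appended to the read name as
#' `_PA:1` / `_PA:0`.
#'
#' @param reads `DNAStringSet` (qualities in `mcols(reads)$qualities`
#'   are trimmed alongside, if present).
#' @param polya_run minimum run length of A calling a tail (default 8).
#' @param min_len minimum post-trim length retained (default 20).
#' @return list with `reads` (trimmed `DNAStringSet`), `polya_flag` logical
#'   vector, and `stats` (`n_in`, `n_kept`, `n_discarded_short`, `n_polya`).
#' @export
trim_polya <- function(reads, polya_run = 8L, min_len = 20L) {
  s <- as.character(reads)
  at <- .first_a_run(s, polya_run)
  flag <- !is.na(at)
  newlen <- ifelse(flag, at - 1L, nchar(s))
  keep <- newlen >= min_len
  out <- reads[keep]
  q <- S4Vectors::mcols(reads)$qualities
  out <- Biostrings::subseq(out, 1L, newlen[keep])
  if (!is.null(q)) {
    S4Vectors::mcols(out)$qualities <-
      Biostrings::subseq(q[keep], 1L, newlen[keep])
  }
  if (length(out) > 0L)
    names(out) <- paste0(names(reads)[keep], "_PA:", as.integer(flag[keep]))
  list(reads = out, polya_flag = flag[keep],
       stats = list(n_in = length(reads), n_kept = length(out),
                    n_discarded_short = sum(!keep),
                    n_polya = sum(flag[keep])))
}

#' Label and trim a FASTQ pair in one pass
#'
#' Convenience wrapper: reads the paired FASTQ files, runs [label_reads()]
#' then [trim_polya()], and optionally writes the labeled, trimmed read2
#' FASTQ ready for an external spliced aligner.
#'
#' @param r1,r2 paths to the read1 / read2 FASTQ files (gzip transparent).
#' @param layout a [barcode_layout()].
#' @param out optional output FASTQ path for the processed read2.
#' @inheritParams trim_polya
#' @return as [trim_polya()], with the labeling stats merged in.
#' @export
preprocess_fastq <- function(r1, r2, layout, polya_run = 8L, min_len = 20L,
                             out = NULL) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  lab <- label_reads(s1, s2, layout)
  trm <- trim_polya(lab$reads, polya_run = polya_run, min_len = min_len)
  if (!is.null(out)) {
    Biostrings::writeXStringSet(trm$reads, out, format = "fastq",
                                qualities = S4Vectors::mcols(trm$reads)$qualities)
  }
  trm$stats <- c(lab$stats, trm$stats[-1L])
  trm
}

#' Read labeled 3'-tag alignments from SAM/BAM
#'
#' Admits primary, mapped, uniquely-mapping records (mapping quality at or
#' above `mapq_min`), and extracts the cell barcode, UMI and polyA flag from
#' the `CB`/`UB`/`XA` aux tags or, failing that, from the
#' `_CB:<bc>_UB:<umi>_PA:<0|1>` read-name suffix. The 3'-most aligned base
#' is reported as a 0-based coordinate: the rightmost base on `+`, the
#' leftmost on `-` (read2 is assumed sense; set `flip_strand = TRUE` for
#' antisense protocols).
#'
#' @param file path to a coordinate-sorted BAM, or a SAM text file (converted
#'   on the fly).
#' @param mapq_min mapping-quality floor defining "uniquely mapped"
#'   (default 20).
#' @param flip_strand logical; flip the tag strand relative to the alignment.
#' @return data.frame with columns `cell_barcode`, `umi`, `chrom`, `strand`,
#'   `end3`, `polya_flag`; attribute `stats` counts skipped records.
#' @export
read_tag_alignments <- function(file, mapq_min = 20L, flip_strand = FALSE) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- suppressMessages(
      Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "mapq"),
    tag = c("CB", "UB", "XA"), flag = flags)
  x <- Rsamtools::scanBam(file, param = p)[[1L]]
  n_admitted <- length(x$qname)
  keep <- !is.na(x$mapq) & x$mapq >= mapq_min
  cb <- x$tag$CB; ub <- x$tag$UB; pa <- x$tag$XA
  if (is.null(cb)) cb <- rep(NA_character_, n_admitted)
  if (is.null(ub)) ub <- rep(NA_character_, n_admitted)
  if (is.null(pa)) pa <- rep(NA_integer_, n_admitted)
  # fall back to the read-name suffix for missing tags
  miss <- is.na(cb) | is.na(ub)
  if (any(miss)) {
    m <- regmatches(x$qname[miss],
                    regexec("_CB:([^_]+)_UB:([^_]+)(?:_PA:([01]))?", x$qname[miss]))
    cb[miss] <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
    ub[miss] <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
    pa_name <- vapply(m, function(g)
      if (length(g) && nzchar(g[4])) as.integer(g[4]) else NA_integer_, 1L)
    pa[miss] <- ifelse(is.na(pa[miss]), pa_name, pa[miss])
  }
  keep <- keep & !is.na(cb) & !is.na(ub)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[keep])
  strand <- as.character(x$strand[keep])
  pos0 <- x$pos[keep] - 1L
  end3 <- ifelse(strand == "+", pos0 + width - 1L, pos0)
  if (flip_strand) strand <- ifelse(strand == "+", "-", "+")
  out <- data.frame(cell_barcode = cb[keep], umi = ub[keep],
                    chrom = as.character(x$rname[keep]), strand = strand,
                    end3 = as.integer(end3),
                    polya_flag = !is.na(pa[keep]) & pa[keep] > 0L,
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- list(n_admitted = n_admitted,
                             n_low_mapq_or_unlabeled = n_admitted - nrow(out))
  out
}

#' Collapse PCR duplicates into deduplicated 3'-end tags
#'
#' One tag survives per distinct (cell barcode, UMI, chromosome, strand,
#' 3'-end coordinate). The polyA flag is merged with OR, so the result does
#' not depend on record order.
#'
#' @param aln data.frame with columns `cell_barcode`, `umi`, `chrom`,
#'   `strand`, `end3`, `polya_flag` (as from [read_tag_alignments()]).
#' @return data.frame of deduplicated tags, sorted by
#'   (chrom, strand, end3, cell_barcode, umi); attribute `stats` records the
#'   number of duplicates removed.
#' @export
dedup_tags <- function(aln) {
  need <- c("cell_barcode", "umi", "chrom", "strand", "end3", "polya_flag")
  stopifnot(all(need %in% names(aln)))
  if (nrow(aln) == 0L) {
    out <- aln[, need]
    attr(out, "stats") <- list(n_in = 0L, n_duplicates = 0L)
    return(out)
  }
  key <- paste(aln$cell_barcode, aln$umi, aln$chrom, aln$strand, aln$end3,
               sep = "\r")
  pa <- tapply(aln$polya_flag, key, any)
  first <- !duplicated(key)
  out <- aln[first, need]
  out$polya_flag <- as.logical(pa[key[first]])
  ord <- order(out$chrom, out$strand, out$end3, out$cell_barcode, out$umi)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "stats") <- list(n_in = nrow(aln),
                             n_duplicates = nrow(aln) - nrow(out))
  out
}

#' Partition deduplicated tags by cell
#'
#' Splits tags into per-cell collections using a barcode-to-cell map; tags
#' whose barcode is not in the map are routed to the `"unassigned"` bucket.
#' Tag counts are conserved: bucket sizes sum to the input size.
#'
#' @param tags deduplicated tag data.frame (see [dedup_tags()]).
#' @param cell_map named character vector, `names` = barcodes,
#'   values = cell ids; must be injective (distinct cell ids).
#' @return named list of data.frames, one per cell id plus `"unassigned"`.
#' @export
demultiplex <- function(tags, cell_map) {
  if (anyDuplicated(cell_map))
    stop("cell_map must be injective (one barcode per cell id)")
  cell <- unname(cell_map[tags$cell_barcode])
  cell[is.na(cell)] <- "unassigned"
  lv <- c(unname(cell_map), "unassigned")
  split(tags, factor(cell, levels = lv))
}
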