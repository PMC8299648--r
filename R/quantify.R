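# From peak regions to per-cell isoform counts, usage fractions and uTPM.

#' Merge peak lists across cell types
#'
#' Interval union per (chromosome, strand): overlapping or bookended peaks
#' are merged. Idempotent.
#'
#' @param peak_lists a peak data.frame (as from [paraclu_cluster()]) or a
#'   list of them.
#' @return data.frame of merged peaks: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @export
merge_peaks <- function(peak_lists) {
  if (is.data.frame(peak_lists)) peak_lists <- list(peak_lists)
  grl <- lapply(peak_lists, .peaks_to_gr)
  gr <- GenomicRanges::reduce(do.call(c, grl))
  gr <- GenomicRanges::sort(gr, ignore.strand = FALSE)
  .gr_to_peaks(gr)
}

.peaks_to_gr <- function(p) {
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end),
                         strand = p$strand)
}

.gr_to_peaks <- function(gr, extra = NULL) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  out
}

#' Keep peaks overlapping gene bodies
#'
#' Peaks with at least 1 bp of same-strand overlap with a gene body are
#' retained. A peak overlapping a single gene is tagged with it; a peak
#' overlapping several genes keeps the candidate list and is resolved by
#' [assign_peaks_to_sites()] (the gene whose body contains the assigned
#' site wins; unresolvable peaks are dropped there).
#'
#' @param peaks merged peak data.frame (see [merge_peaks()]).
#' @param genes `GRanges` of gene bodies with `gene_id` (see
#'   [gene_bodies()]).
#' @return peak data.frame with a `gene_id` column (NA when ambiguous) and
#'   a `gene_candidates` list column.
#' @export
restrict_to_genes <- function(peaks, genes) {
  gr <- .peaks_to_gr(peaks)
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = FALSE)
  cand <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(gr)))
  n <- lengths(cand)
  keep <- n > 0L
  out <- peaks[keep, c("chrom", "strand", "start", "end"), drop = FALSE]
  out$gene_id <- ifelse(n[keep] == 1L,
                        vapply(cand[keep], `[`, "", 1L), NA_character_)
  out$gene_candidates <- unname(cand[keep])
  rownames(out) <- NULL
  out
}

#' Assign peaks to poly(A) sites
#'
#' A peak containing exactly one site is assigned to it. A peak containing
#' several sites is split into sub-peaks at the minimum-pileup position
#' between adjacent sites (ties resolved toward the midpoint). A siteless
#' peak is rescued by the nearest site within `assign_dist` nt, or dropped.
#' Peaks with ambiguous gene candidates are resolved to the gene whose body
#' contains the assigned site; still-ambiguous peaks are dropped.
#'
#' @param peaks gene-tagged peak data.frame (see [restrict_to_genes()]).
#' @param sites site data.frame (`chrom`, `strand`, `pos`); typically the
#'   union of novel and annotated sites.
#' @param pileup 3'-end pileup used for split points (see
#'   [paraclu_cluster()] input); may be NULL, in which case splits fall at
#'   midpoints.
#' @param genes `GRanges` of gene bodies, needed to resolve multi-gene
#'   peaks; may be NULL when no peak is ambiguous.
#' @param assign_dist rescue radius for siteless peaks in nt (default 50).
#' @return data.frame of peak regions: `chrom`, `strand`, `start`, `end`,
#'   `site_pos`, `site_id`, `gene_id`; attribute `stats` counts dropped
#'   peaks.
#' @export
assign_peaks_to_sites <- function(peaks, sites, pileup = NULL, genes = NULL,
                                  assign_dist = 50L) {
  out <- list(); n_siteless <- 0L; n_ambiguous <- 0L
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    sel <- which(sites$chrom == pk$chrom & sites$strand == pk$strand &
                   sites$pos >= pk$start & sites$pos < pk$end)
    if (length(sel) == 0L) {
      same <- which(sites$chrom == pk$chrom & sites$strand == pk$strand)
      if (length(same) > 0L) {
        dist <- pmax(pk$start - sites$pos[same],
                     sites$pos[same] - (pk$end - 1L), 0L)
        j <- same[which.min(dist)]
        if (min(dist) <= assign_dist) {
          out[[length(out) + 1L]] <- .sub_peak(pk, pk$start, pk$end,
                                               sites$pos[j])
          next
        }
      }
      n_siteless <- n_siteless + 1L
    } else if (length(sel) == 1L) {
      out[[length(out) + 1L]] <- .sub_peak(pk, pk$start, pk$end,
                                           sites$pos[sel])
    } else {
      sp <- sort(sites$pos[sel])
      bounds <- pk$start
      for (k in seq_len(length(sp) - 1L))
        bounds <- c(bounds, .split_point(sp[k], sp[k + 1L], pk, pileup))
      bounds <- c(bounds, pk$end)
      for (k in seq_along(sp))
        out[[length(out) + 1L]] <- .sub_peak(pk, bounds[k], bounds[k + 1L],
                                             sp[k])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      site_pos = integer(), gene_id = character())
  # resolve multi-gene peaks: gene body must contain the assigned site
  amb <- is.na(res$gene_id)
  if (any(amb)) {
    if (is.null(genes)) stop("gene bodies needed to resolve multi-gene peaks")
    for (i in which(amb)) {
      cand <- res$gene_candidates[[i]]
      g <- genes[genes$gene_id %in% cand]
      inb <- as.character(GenomicRanges::seqnames(g)) == res$chrom[i] &
        as.character(GenomicRanges::strand(g)) == res$strand[i] &
        GenomicRanges::start(g) - 1L <= res$site_pos[i] &
        GenomicRanges::end(g) > res$site_pos[i]
      if (sum(inb) == 1L) res$gene_id[i] <- g$gene_id[inb]
    }
    n_ambiguous <- sum(is.na(res$gene_id))
    res <- res[!is.na(res$gene_id), , drop = FALSE]
  }
  res$gene_candidates <- NULL
  res$site_id <- sprintf("%s:%d:%s", res$chrom, res$site_pos, res$strand)
  rownames(res) <- NULL
  attr(res, "stats") <- list(n_siteless_dropped = n_siteless,
                             n_gene_ambiguous_dropped = n_ambiguous)
  res
}

.sub_peak <- function(pk, start, end, site_pos) {
  data.frame(chrom = pk$chrom, strand = pk$strand, start = start, end = end,
             site_pos = site_pos, gene_id = pk$gene_id,
             gene_candidates = I(if ("gene_candidates" %in% names(pk))
               pk$gene_candidates else list(pk$gene_id)),
             stringsAsFactors = FALSE)
}

# Boundary between two adjacent sites: the minimum-pileup position in
# (a, b]; among tied minima the one closest to the midpoint (then 5'-most).
.split_point <- function(a, b, pk, pileup) {
  cand <- (a + 1L):b
  cnt <- integer(length(cand))
  if (!is.null(pileup)) {
    sel <- pileup$chrom == pk$chrom & pileup$strand == pk$strand &
      pileup$pos %in% cand
    cnt[match(pileup$pos[sel], cand)] <- pileup$count[sel]
  }
  mins <- which(cnt == min(cnt))
  mid <- (a + b) / 2
  cand[mins[which.min(abs(cand[mins] - mid))]]
}

#' Count per-cell isoform UMIs
#'
#' Counts deduplicated tags (polyA and non-polyA) whose 3'-end falls inside
#' each assigned peak region, per cell. The result is a
#' `SingleCellExperiment` with isoforms as rows (metadata in `rowData`:
#' `gene_id`, `site_id`, `site_pos`, peak interval) and cells as columns.
#'
#' @param tags deduplicated tag data.frame with `cell_barcode`.
#' @param peak_regions assigned peaks (see [assign_peaks_to_sites()]).
#' @param cells optional character vector fixing the cell set/order
#'   (default: sorted barcodes observed in `tags`).
#' @param polya_only count only polyA-flagged tags (default FALSE).
#' @return `SingleCellExperiment` with a sparse `counts` assay; metadata
#'   field `n_unassigned_tags` counts tags outside every peak.
#' @export
count_isoforms <- function(tags, peak_regions, cells = NULL,
                           polya_only = FALSE) {
  if (polya_only) tags <- tags[tags$polya_flag, , drop = FALSE]
  if (is.null(cells)) cells <- sort(unique(tags$cell_barcode))
  # several peak fragments can serve the same poly(A) site; they form one
  # isoform
  peak_iso <- sprintf("%s|%s", peak_regions$gene_id, peak_regions$site_id)
  iso <- unique(peak_iso)
  iso_row <- match(peak_iso, iso)
  tgr <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(tags$end3 + 1L, width = 1L),
                                strand = tags$strand)
  pgr <- .peaks_to_gr(peak_regions)
  hits <- GenomicRanges::findOverlaps(tgr, pgr, ignore.strand = FALSE,
                                      select = "first")
  inpk <- !is.na(hits)
  ci <- match(tags$cell_barcode, cells)
  ok <- inpk & !is.na(ci)
  m <- Matrix::sparseMatrix(i = iso_row[hits[ok]], j = ci[ok], x = 1,
                            dims = c(length(iso), length(cells)))
  dimnames(m) <- list(iso, cells)
  first <- match(iso, peak_iso)
  rd <- S4Vectors::DataFrame(isoform_id = iso,
                             gene_id = peak_regions$gene_id[first],
                             site_id = peak_regions$site_id[first],
                             site_pos = peak_regions$site_pos[first],
                             chrom = peak_regions$chrom[first],
                             strand = peak_regions$strand[first],
                             peak_start = vapply(iso, function(x)
                               min(peak_regions$start[peak_iso == x]), 1L),
                             peak_end = vapply(iso, function(x)
                               max(peak_regions$end[peak_iso == x]), 1L),
                             n_peaks = as.integer(table(peak_iso)[iso]))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")), rowData = rd)
  S4Vectors::metadata(sce)$n_unassigned_tags <- sum(!inpk)
  sce
}

#' Compute per-cell poly(A)-site usage fractions
#'
#' For each (gene, cell) with at least one UMI, the usage of isoform i is
#' its count divided by the gene's total count in that cell — a point on
#' the isoform simplex. Cells where the gene is undetected get NA, never 0,
#' so absence of evidence is not mistaken for absence of usage.
#'
#' @param sce `SingleCellExperiment` from [count_isoforms()] (or any SCE
#'   with a `counts` assay and `rowData$gene_id`).
#' @return the SCE with an additional dense `usage` assay.
#' @export
add_usage <- function(sce) {
  cnt <- SummarizedExperiment::assay(sce, "counts")
  gene <- SummarizedExperiment::rowData(sce)$gene_id
  cm <- as.matrix(cnt)
  tot <- rowsum(cm, gene)                      # genes x cells
  denom <- tot[match(gene, rownames(tot)), , drop = FALSE]
  usage <- cm / denom
  usage[denom == 0] <- NA_real_
  SummarizedExperiment::assay(sce, "usage") <- usage
  sce
}

#' Gene-level expression as unique transcripts per million (uTPM)
#'
#' Sums isoform UMIs per gene and normalizes each cell to one million:
#' `uTPM[g, c] = counts[g, c] * 1e6 / total_counts[c]`. Cells with zero
#' total are excluded.
#'
#' @inheritParams add_usage
#' @param log2 also return `log2(uTPM + 1)` instead of raw uTPM.
#' @return genes x cells matrix; attribute `excluded_cells` lists dropped
#'   zero-total cells.
#' @export
utpm <- function(sce, log2 = FALSE) {
  cnt <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  gene <- SummarizedExperiment::rowData(sce)$gene_id
  g <- rowsum(cnt, gene)
  tot <- colSums(g)
  excluded <- colnames(g)[tot == 0]
  g <- g[, tot > 0, drop = FALSE]
  out <- sweep(g, 2L, colSums(g), "/") * 1e6
  if (log2) out <- log2(out + 1)
  attr(out, "excluded_cells") <- excluded
  out
}

#' Quantify poly(A)-site usage end to end
#'
#' Convenience pipeline: parametric peak clustering on the pooled 3'-end
#' pileup, peak merge, gene-body restriction, site assignment, per-cell
#' counting and usage computation.
#'
#' @param tags deduplicated tag data.frame.
#' @param sites site data.frame (novel plus annotated).
#' @param gtf annotation path or `GRanges`.
#' @inheritParams paraclu_cluster
#' @inheritParams assign_peaks_to_sites
#' @inheritParams count_isoforms
#' @return `SingleCellExperiment` with `counts` and `usage` assays.
#' @export
quantify_apa <- function(tags, sites, gtf, min_total = 10L,
                         max_length = 200L, min_density_ratio = 2,
                         assign_dist = 50L, cells = NULL,
                         polya_only = FALSE) {
  pileup <- .end3_pileup(tags)
  peaks <- paraclu_cluster(pileup, min_total = min_total,
                           max_length = max_length,
                           min_density_ratio = min_density_ratio)
  merged <- merge_peaks(peaks)
  genes <- gene_bodies(gtf)
  tagged <- restrict_to_genes(merged, genes)
  regions <- assign_peaks_to_sites(tagged, sites, pileup = pileup,
                                   genes = genes, assign_dist = assign_dist)
  sce <- count_isoforms(tags, regions, cells = cells,
                        polya_only = polya_only)
  add_usage(sce)
}

# Pileup of all deduplicated 3'-ends (polyA and non-polyA).
.end3_pileup <- function(tags) {
  if (nrow(tags) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), count = integer()))
  key <- paste(tags$chrom, tags$strand, tags$end3, sep = "\r")
  cnt <- table(key)
  first <- !duplicated(key)
  out <- data.frame(chrom = tags$chrom[first], strand = tags$strand[first],
                    pos = tags$end3[first],
                    count = as.integer(cnt[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$strand, out$pos), ]
}
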