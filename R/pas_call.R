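# De novo poly(A)-site identification from pooled polyA-flagged 3'-end tags:
# pileup construction, internal-priming filtering, distance clustering,
# thresholded site calling, annotation comparison and signal-motif profiling.

#' Build a poly(A)-tag pileup
#'
#' Keeps deduplicated polyA-flagged tags and counts them per
#' (chromosome, strand, position). By default only tags falling inside a
#' same-strand 3'UTR interval are retained; disable the restriction (e.g. to
#' look for intronic sites) with `restrict = FALSE`.
#'
#' @param tags deduplicated tag data.frame (see [dedup_tags()]).
#' @param utr3 `GRanges` of 3'UTR intervals (see [extract_utr3()]); required
#'   when `restrict = TRUE`.
#' @param restrict logical; restrict to 3'UTR regions (default TRUE).
#' @return data.frame pileup with columns `chrom`, `strand`, `pos` (0-based),
#'   `count`.
#' @export
collect_polya_tags <- function(tags, utr3 = NULL, restrict = TRUE) {
  pa <- tags[tags$polya_flag, , drop = FALSE]
  if (restrict) {
    if (is.null(utr3) || length(utr3) == 0L)
      stop("3'UTR restriction requested but no 3'UTR intervals supplied")
    gr <- GenomicRanges::GRanges(pa$chrom,
                                 IRanges::IRanges(pa$end3 + 1L, width = 1L),
                                 strand = pa$strand)
    hit <- IRanges::overlapsAny(gr, utr3, ignore.strand = FALSE)
    pa <- pa[hit, , drop = FALSE]
  }
  if (nrow(pa) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), count = integer()))
  key <- paste(pa$chrom, pa$strand, pa$end3, sep = "\r")
  cnt <- table(key)
  first <- !duplicated(key)
  out <- data.frame(chrom = pa$chrom[first], strand = pa$strand[first],
                    pos = pa$end3[first],
                    count = as.integer(cnt[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$strand, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Remove internal-priming artifacts from a pileup
#'
#' Oligo-dT primers can anneal to genomic adenine stretches, generating
#' artifactual 3'-ends. A pileup position is removed when the `window` nt of
#' genomic sequence immediately downstream of it, read on the sense strand
#' in transcription direction, contain a run of at least `min_run`
#' consecutive adenines. Positions close to a chromosome end are examined
#' over the truncated window.
#'
#' @param pileup pileup data.frame (see [collect_polya_tags()]).
#' @param genome `DNAStringSet` or `Rsamtools::FaFile`.
#' @param window downstream window length in nt (default 20).
#' @param min_run minimum adenine run length (default 6).
#' @return the filtered pileup; attribute `stats` records removals.
#' @export
filter_internal_priming <- function(pileup, genome, window = 20L,
                                    min_run = 6L) {
  if (nrow(pileup) == 0L) return(pileup)
  down <- vapply(seq_len(nrow(pileup)), function(i) {
    p <- pileup$pos[i]
    if (pileup$strand[i] == "+")
      .fetch_seq(genome, pileup$chrom[i], p + 1L, p + window, "+")
    else
      .fetch_seq(genome, pileup$chrom[i], p - window, p - 1L, "-")
  }, character(1L))
  bad <- .has_a_run(down, min_run)
  out <- pileup[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- list(n_in = nrow(pileup), n_removed = sum(bad))
  out
}

#' Cluster pileup positions by genomic distance
#'
#' Single-linkage clustering per (chromosome, strand): two positions belong
#' to the same cluster when a chain of consecutive gaps of at most `max_gap`
#' nt connects them (a gap equal to `max_gap` joins). The cluster summit is
#' the member with the highest tag count; ties break to the 5'-most member
#' in transcription direction.
#'
#' @param pileup pileup data.frame.
#' @param max_gap maximum joining distance in nt (default 20).
#' @return data.frame of clusters: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `summit`, `total`, `n_pos`.
#' @export
cluster_tags <- function(pileup, max_gap = 20L) {
  if (nrow(pileup) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), summit = integer(),
                      total = integer(), n_pos = integer()))
  pileup <- pileup[order(pileup$chrom, pileup$strand, pileup$pos), ]
  grp <- paste(pileup$chrom, pileup$strand, sep = "\r")
  res <- lapply(split(pileup, grp), function(d) {
    gap_new <- c(TRUE, diff(d$pos) > max_gap)
    cid <- cumsum(gap_new)
    do.call(rbind, lapply(split(d, cid), function(cl) {
      mx <- cl$count == max(cl$count)
      summit <- if (cl$strand[1] == "+") min(cl$pos[mx]) else max(cl$pos[mx])
      data.frame(chrom = cl$chrom[1], strand = cl$strand[1],
                 start = min(cl$pos), end = max(cl$pos) + 1L,
                 summit = summit, total = sum(cl$count), n_pos = nrow(cl),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$strand, out$start), ]
}

#' Call poly(A) sites from tag clusters
#'
#' A cluster becomes a site when its tag total passes both an absolute
#' threshold and a library-size-normalized threshold (tags per million of
#' all deduplicated polyA tags). The site coordinate is the cluster summit.
#'
#' @param clusters cluster data.frame (see [cluster_tags()]).
#' @param total_polya_tags library-wide deduplicated polyA tag count (> 0).
#' @param min_norm_count minimum normalized count, tags-per-million
#'   (default 1).
#' @param min_raw_count minimum raw tag count (default 3).
#' @return data.frame of sites: `chrom`, `strand`, `pos` (summit, 0-based),
#'   `tag_count`, `norm_count`, plus the source cluster interval.
#' @export
call_sites <- function(clusters, total_polya_tags, min_norm_count = 1,
                       min_raw_count = 3L) {
  if (total_polya_tags <= 0L) stop("total_polya_tags must be positive")
  norm <- clusters$total * 1e6 / total_polya_tags
  keep <- clusters$total >= min_raw_count & norm >= min_norm_count
  out <- data.frame(chrom = clusters$chrom[keep],
                    strand = clusters$strand[keep],
                    pos = clusters$summit[keep],
                    tag_count = clusters$total[keep],
                    norm_count = norm[keep],
                    cluster_start = clusters$start[keep],
                    cluster_end = clusters$end[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare called sites with an annotated poly(A)-site set
#'
#' Computes for every site the signed distance to the nearest same-strand
#' annotated site (positive = the annotated site lies downstream in
#' transcription direction). Sites within `match_dist` nt are labeled
#' `annotated`, the rest `novel`; sites on a chromosome/strand with no
#' annotation get an undefined distance and are `novel`.
#'
#' @param sites site data.frame (see [call_sites()]).
#' @param annotated `GRanges` of annotated single-nt sites (e.g. from
#'   [read_sites_bed()]), or a data.frame with `chrom`, `strand`, `pos`.
#' @param match_dist adjacency threshold in nt (default 24).
#' @return list with `sites` (input plus `nearest_annotated_dist`, `status`)
#'   and `histogram` (data.frame of distance counts over -100..100 nt).
#' @export
classify_vs_annotation <- function(sites, annotated, match_dist = 24L) {
  ann <- .as_site_df(annotated)
  d <- rep(NA_integer_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- ann$chrom == sites$chrom[i] & ann$strand == sites$strand[i]
    if (!any(sel)) next
    delta <- ann$pos[sel] - sites$pos[i]
    if (sites$strand[i] == "-") delta <- -delta
    d[i] <- delta[which.min(abs(delta))]
  }
  sites$nearest_annotated_dist <- d
  sites$status <- ifelse(!is.na(d) & abs(d) <= match_dist,
                         "annotated", "novel")
  h <- d[!is.na(d) & abs(d) <= 100L]
  histogram <- data.frame(dist = -100:100,
                          count = as.integer(table(factor(h, levels = -100:100))))
  list(sites = sites, histogram = histogram)
}

.as_site_df <- function(x) {
  if (is(x, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
               strand = as.character(GenomicRanges::strand(x)),
               pos = GenomicRanges::start(x) - 1L, stringsAsFactors = FALSE)
  } else x
}

#' Profile a poly(A)-signal motif around sites
#'
#' Counts, at each offset in transcription direction relative to the site
#' (site = offset 0), the fraction of sites whose sense-strand sequence has
#' an occurrence of `motif` starting there. The canonical signal AAUAAA is
#' queried as AATAAA on DNA and is expected to peak near -21 nt. Sites whose
#' flanks extend past the chromosome are excluded from the denominator.
#'
#' @param sites site data.frame with `chrom`, `strand`, `pos`.
#' @param genome `DNAStringSet` or `Rsamtools::FaFile`.
#' @param motif DNA hexamer (default `"AATAAA"`).
#' @param flank half-window in nt (default 50; offsets -flank..flank).
#' @param upstream_window integer length-2 vector of offsets over which the
#'   per-site presence fraction is computed (default `c(-50, -1)`).
#' @return list with `profile` (data.frame `offset`, `freq`),
#'   `upstream_fraction`, `n_sites`, `n_excluded`.
#' @export
motif_profile <- function(sites, genome, motif = "AATAAA", flank = 50L,
                          upstream_window = c(-50L, -1L)) {
  ml <- nchar(motif)
  offsets <- seq.int(-flank, flank)
  hitmat <- matrix(FALSE, nrow = nrow(sites), ncol = length(offsets))
  used <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    len <- .chrom_length(genome, sites$chrom[i])
    if (sites$strand[i] == "+") {
      lo <- p - flank; hi <- p + flank + ml - 1L
    } else {
      lo <- p - flank - ml + 1L; hi <- p + flank
    }
    if (lo < 0L || hi >= len) next
    used[i] <- TRUE
    s <- .fetch_seq(genome, sites$chrom[i], lo, hi, sites$strand[i])
    m <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      off <- as.integer(m) - 1L - flank  # string start 1 -> offset -flank
      off <- off[off >= -flank & off <= flank]
      hitmat[i, match(off, offsets)] <- TRUE
    }
  }
  n <- sum(used)
  freq <- if (n > 0L) colSums(hitmat[used, , drop = FALSE]) / n else
    rep(0, length(offsets))
  up <- offsets >= upstream_window[1L] & offsets <= upstream_window[2L]
  upfrac <- if (n > 0L)
    mean(rowSums(hitmat[used, up, drop = FALSE]) > 0L) else 0
  list(profile = data.frame(offset = offsets, freq = freq),
       upstream_fraction = upfrac, n_sites = n,
       n_excluded = nrow(sites) - n)
}

#' Merge per-cell-type site sets
#'
#' Sites called independently per cell type are combined by single-linkage
#' chaining at `match_dist` nt per (chromosome, strand); each chain is
#' represented by its highest-count summit (tie: 5'-most in transcription
#' direction) and carries the summed tag support.
#'
#' @param site_sets list of site data.frames (see [call_sites()]).
#' @param match_dist merge tolerance in nt (default 24).
#' @return merged site data.frame.
#' @export
merge_site_sets <- function(site_sets, match_dist = 24L) {
  all <- do.call(rbind, lapply(site_sets, function(s)
    s[, c("chrom", "strand", "pos", "tag_count")]))
  if (is.null(all) || nrow(all) == 0L) return(all)
  all <- all[order(all$chrom, all$strand, all$pos), ]
  grp <- paste(all$chrom, all$strand, sep = "\r")
  out <- do.call(rbind, lapply(split(all, grp), function(d) {
    cid <- cumsum(c(TRUE, diff(d$pos) > match_dist))
    do.call(rbind, lapply(split(d, cid), function(cl) {
      mx <- cl$tag_count == max(cl$tag_count)
      pos <- if (cl$strand[1] == "+") min(cl$pos[mx]) else max(cl$pos[mx])
      data.frame(chrom = cl$chrom[1], strand = cl$strand[1], pos = pos,
                 tag_count = sum(cl$tag_count), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$strand, out$pos), ]
}

#' Call poly(A) sites end to end
#'
#' Convenience pipeline: pileup construction, internal-priming filtering,
#' distance clustering, thresholded site calling and, when an annotation is
#' given, novel/annotated classification.
#'
#' @inheritParams collect_polya_tags
#' @inheritParams filter_internal_priming
#' @inheritParams cluster_tags
#' @inheritParams call_sites
#' @inheritParams classify_vs_annotation
#' @param annotated optional annotated site set.
#' @return list with `sites`, `clusters`, `pileup`, and (when `annotated`
#'   is given) `histogram`.
#' @export
call_polya_sites <- function(tags, genome, utr3 = NULL, restrict = TRUE,
                             annotated = NULL, max_gap = 20L,
                             ip_window = 20L, ip_run = 6L,
                             min_norm_count = 1, min_raw_count = 3L,
                             match_dist = 24L) {
  pileup <- collect_polya_tags(tags, utr3 = utr3, restrict = restrict)
  pileup <- filter_internal_priming(pileup, genome, window = ip_window,
                                    min_run = ip_run)
  clusters <- cluster_tags(pileup, max_gap = max_gap)
  total <- sum(tags$polya_flag)
  sites <- call_sites(clusters, total, min_norm_count = min_norm_count,
                      min_raw_count = min_raw_count)
  res <- list(sites = sites, clusters = clusters, pileup = pileup)
  if (!is.null(annotated)) {
    cl <- classify_vs_annotation(sites, annotated, match_dist = match_dist)
    res$sites <- cl$sites
    res$histogram <- cl$histogram
  }
  res
}
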