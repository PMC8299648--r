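# Parametric density clustering of tag 3'-end pileups.
#
# For a density parameter d, score an interval I of pileup positions as
# total(I) - d * span(I). As d grows, maximal-scoring intervals shrink and
# nest; each cluster is maximal for a density range (d_min, d_max]. The
# recursion below enumerates the full nested hierarchy: the break density of
# an interval is the minimum density over its proper prefixes and suffixes
# (gap-based lengths between member positions); above it the interval
# splits at the weakest prefix or suffix, and the two parts are explored
# with d_min set to the break density. Single positions have d_max = Inf.

#' Identify peak regions by parametric density clustering
#'
#' Runs the maximal-density-interval recursion per (chromosome, strand) on a
#' pileup of deduplicated read 3'-ends, then keeps clusters with
#' `total >= min_total`, genomic length `<= max_length`, and density
#' stability `d_max / d_min >= min_density_ratio` (single-position clusters
#' have infinite stability; a top-level cluster with `d_min = 0` and finite
#' `d_max` is considered unstable). Of nested passing clusters only the
#' largest is kept.
#'
#' @param pileup data.frame with `chrom`, `strand`, `pos` (0-based),
#'   `count`; typically the 3'-ends of all deduplicated reads, polyA-flagged
#'   or not, so that the whole read body upstream of a poly(A) site supports
#'   its peak.
#' @param min_total minimum summed count (default 10).
#' @param max_length maximum cluster length in nt (default 200).
#' @param min_density_ratio minimum `d_max / d_min` (default 2).
#' @param keep_all return every enumerated cluster, unfiltered (for
#'   inspection; default FALSE).
#' @return data.frame of peaks: `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `total`, `n_pos`, `min_density`, `max_density`.
#' @export
paraclu_cluster <- function(pileup, min_total = 10L, max_length = 200L,
                            min_density_ratio = 2, keep_all = FALSE) {
  empty <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), total = integer(),
                      n_pos = integer(), min_density = numeric(),
                      max_density = numeric())
  if (nrow(pileup) == 0L) return(empty)
  pileup <- pileup[order(pileup$chrom, pileup$strand, pileup$pos), ]
  grp <- paste(pileup$chrom, pileup$strand, sep = "\r")
  res <- lapply(split(pileup, grp), function(d)
    .paraclu_segment(d$pos, d$count, d$chrom[1L], d$strand[1L]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (keep_all) return(out)
  keep <- out$total >= min_total &
    (out$end - out$start) <= max_length &
    .density_stable(out$min_density, out$max_density, min_density_ratio)
  out <- out[keep, , drop = FALSE]
  .drop_nested(out)
}

.density_stable <- function(dmin, dmax, ratio) {
  ifelse(is.infinite(dmax), TRUE,
         ifelse(dmin <= 0, FALSE, dmax / dmin >= ratio))
}

# Keep only the largest passing cluster of each nest.
.drop_nested <- function(cl) {
  if (nrow(cl) <= 1L) { rownames(cl) <- NULL; return(cl) }
  ord <- order(cl$chrom, cl$strand, cl$end - cl$start, decreasing = TRUE)
  ord <- ord[order(cl$chrom[ord], cl$strand[ord])]
  keep <- logical(nrow(cl))
  for (g in split(seq_len(nrow(cl)), paste(cl$chrom, cl$strand, sep = "\r"))) {
    g <- g[order(cl$end[g] - cl$start[g], decreasing = TRUE)]
    kept <- integer(0)
    for (i in g) {
      inside <- any(cl$start[kept] <= cl$start[i] & cl$end[kept] >= cl$end[i])
      if (!inside) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  out <- cl[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$start), ]
  rownames(out) <- NULL
  out
}

# Enumerate all maximal-density clusters of one sorted segment.
.paraclu_segment <- function(pos, val, chrom, strand) {
  acc <- vector("list", 0L)
  stack <- list(list(i = 1L, j = length(pos), dmin = 0))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j; dmin <- fr$dmin
    if (i > j) next
    if (i == j) {
      acc[[length(acc) + 1L]] <-
        list(i = i, j = j, dmin = dmin, dmax = Inf, total = val[i])
      next
    }
    seg <- i:j
    cum <- cumsum(val[seg])
    n <- j - i
    pref_d <- cum[1:n] / (pos[(i + 1L):j] - pos[i])
    suf_sum <- cum[n + 1L] - cum[1:n]
    suf_d <- suf_sum / (pos[j] - pos[i:(j - 1L)])
    kp <- which.min(pref_d)              # weakest prefix = pos[i..i+kp-1]
    ks <- which.min(suf_d)               # weakest suffix = pos[i+ks..j]
    pd <- pref_d[kp]; sd_ <- suf_d[ks]
    brk <- min(pd, sd_)
    if (brk > dmin)
      acc[[length(acc) + 1L]] <-
        list(i = i, j = j, dmin = dmin, dmax = brk, total = cum[n + 1L])
    # children appear only above the largest break density of any ancestor
    dchild <- max(dmin, brk)
    if (pd <= sd_) {
      stack[[length(stack) + 1L]] <- list(i = i, j = i + kp - 1L,
                                          dmin = dchild)
      stack[[length(stack) + 1L]] <- list(i = i + kp, j = j, dmin = dchild)
    } else {
      stack[[length(stack) + 1L]] <- list(i = i, j = i + ks - 1L,
                                          dmin = dchild)
      stack[[length(stack) + 1L]] <- list(i = i + ks, j = j, dmin = dchild)
    }
  }
  if (length(acc) == 0L) return(NULL)
  data.frame(chrom = chrom, strand = strand,
             start = pos[vapply(acc, `[[`, 1L, "i")],
             end = pos[vapply(acc, `[[`, 1L, "j")] + 1L,
             total = vapply(acc, `[[`, numeric(1), "total"),
             n_pos = vapply(acc, `[[`, 1L, "j") -
               vapply(acc, `[[`, 1L, "i") + 1L,
             min_density = vapply(acc, `[[`, numeric(1), "dmin"),
             max_density = vapply(acc, `[[`, numeric(1), "dmax"),
             stringsAsFactors = FALSE)
}
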