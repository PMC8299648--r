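# Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom stats rmultinom rpois rbeta runif rnorm setNames p.adjust
#'   chisq.test fisher.test cor hclust cutree dist var sd rbinom
#' @importFrom utils head tail
NULL

# Position of the first run of >= min_run consecutive 'A' (1-based), or NA.
# N never extends a run because the pattern matches literal A only.
.first_a_run <- function(seqs, min_run) {
  m <- regexpr(sprintf("A{%d,}", min_run), seqs)
  ifelse(m == -1L, NA_integer_, as.integer(m))
}

.has_a_run <- function(seqs, min_run) {
  grepl(sprintf("A{%d,}", min_run), seqs)
}

# Fetch genomic sequence on the sense strand of `strand`, as character.
# start0/end0 are 0-based inclusive genomic coordinates; out-of-bounds parts
# are truncated. `genome` is a DNAStringSet or an Rsamtools::FaFile.
.fetch_seq <- function(genome, chrom, start0, end0, strand) {
  len <- .chrom_length(genome, chrom)
  s <- max(start0, 0L)
  e <- min(end0, len - 1L)
  if (s > e) return("")
  if (is(genome, "FaFile")) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e + 1L))
    seq <- Biostrings::getSeq(genome, gr)[[1L]]
  } else {
    seq <- Biostrings::subseq(genome[[chrom]], s + 1L, e + 1L)
  }
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

.chrom_length <- function(genome, chrom) {
  if (is(genome, "FaFile")) {
    idx <- Rsamtools::seqinfo(genome)
    unname(GenomeInfoDb::seqlengths(idx)[chrom])
  } else {
    length(genome[[chrom]])
  }
}

.check_simplex <- function(x, what = "vector", tol = 1e-6) {
  if (anyNA(x) || any(x < -tol) || abs(sum(x) - 1) > tol)
    stop(what, " must be a probability vector summing to 1", call. = FALSE)
  invisible(TRUE)
}

# Deterministic child seeds below 2^31 derived from one user seed.
.derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12289L) %% 2147483593L + 1L
}
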