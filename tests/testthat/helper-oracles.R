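# Independent oracles used to validate the implementation by a different
# computational route.

# Hellinger distance via the Bhattacharyya coefficient.
oracle_hellinger <- function(u, v) {
  sqrt(max(0, 1 - sum(sqrt(u * v))))
}

# Jensen-Shannon divergence via Shannon entropies (base 2).
oracle_jsd <- function(p, q) {
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  m <- (p + q) / 2
  H(m) - (H(p) + H(q)) / 2
}

# Brute-force single-linkage clustering by transitive closure over all
# position pairs.
oracle_distance_clusters <- function(pos, max_gap) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 1L)
    if (identical(new, comp)) break
    comp <- new
  }
  split(pos, comp)
}

# Brute-force enumeration of maximal-density clusters: an interval of
# pileup positions is maximal at density d when every proper prefix and
# suffix has gap-based density >= d and no strict superinterval does too.
# d_max(I) is the minimum prefix/suffix density (Inf for singletons);
# d_min(I) the largest d_max among strict superintervals (0 at the root).
# I is reported iff d_max(I) > d_min(I).
oracle_paraclu <- function(pos, val) {
  n <- length(pos)
  dmax <- function(i, j) {
    if (i == j) return(Inf)
    ds <- c()
    for (k in i:(j - 1L)) {
      ds <- c(ds, sum(val[i:k]) / (pos[k + 1L] - pos[i]),
              sum(val[(k + 1L):j]) / (pos[j] - pos[k]))
    }
    min(ds)
  }
  out <- list()
  for (i in 1:n) for (j in i:n) {
    dM <- dmax(i, j)
    dm <- 0
    for (a in 1:i) for (b in j:n) {
      if (a == i && b == j) next
      dm <- max(dm, dmax(a, b))
    }
    if (dM > dm)
      out[[length(out) + 1L]] <- data.frame(start = pos[i],
                                            end = pos[j] + 1L,
                                            total = sum(val[i:j]),
                                            min_density = dm,
                                            max_density = dM)
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), ]
}

# Small deduplicated-tag table constructor.
make_tags <- function(cb, umi, chrom = "chr1", strand = "+", end3,
                      polya = TRUE) {
  data.frame(cell_barcode = cb, umi = umi, chrom = chrom, strand = strand,
             end3 = as.integer(end3), polya_flag = polya,
             stringsAsFactors = FALSE)
}

# Random simplex of length k.
rand_simplex <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# Minimal SingleCellExperiment with counts + usage assays for unit tests.
make_sce <- function(counts, gene_id, site_pos, strand = "+",
                     cell_type = NULL) {
  iso <- sprintf("%s|chrT:%d:%s", gene_id, site_pos, strand)
  rownames(counts) <- iso
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  rd <- S4Vectors::DataFrame(isoform_id = iso, gene_id = gene_id,
                             site_id = iso, site_pos = site_pos,
                             chrom = "chrT", strand = strand)
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cell_type)) cd$cell_type <- cell_type
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = rd, colData = cd)
  add_usage(sce)
}
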