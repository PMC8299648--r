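# Modality of distal poly(A)-site usage across cells: binning, reference
# distributions, Jensen-Shannon assignment, and bimodality-driven
# subpopulation demarcation via correlated-gene clustering.

#' Distal poly(A)-site usage per cell
#'
#' The distal site is the 3'-most site in transcription direction: the
#' maximum coordinate on `+` genes, the minimum on `-` genes. Returns that
#' isoform's usage for every cell, NA where the gene is undetected.
#'
#' @param sce `SingleCellExperiment` with a `usage` assay.
#' @param gene gene id (must have at least 2 isoforms).
#' @return named numeric vector over cells, in \[0, 1\] or NA.
#' @export
distal_usage <- function(sce, gene) {
  rd <- SummarizedExperiment::rowData(sce)
  rows <- which(rd$gene_id == gene)
  if (length(rows) < 2L)
    stop("distal usage is defined for genes with >= 2 poly(A) isoforms")
  pos <- rd$site_pos[rows]
  distal <- if (rd$strand[rows[1L]] == "-") rows[which.min(pos)] else
    rows[which.max(pos)]
  SummarizedExperiment::assay(sce, "usage")[distal, ]
}

#' Distal usage for all multi-isoform genes
#'
#' @inheritParams distal_usage
#' @return genes x cells matrix of distal usage (NA = undetected).
#' @export
distal_usage_matrix <- function(sce) {
  rd <- SummarizedExperiment::rowData(sce)
  genes <- unique(rd$gene_id[duplicated(rd$gene_id)])
  m <- t(vapply(genes, function(g) distal_usage(sce, g),
                numeric(ncol(sce))))
  rownames(m) <- genes
  m
}

#' Bin distal usages into thirds
#'
#' Counts the fraction of cells with distal usage in \[0, 1/3\],
#' (1/3, 2/3\] and (2/3, 1\]; boundary values fall into the lower bin.
#'
#' @param values per-cell distal usages (NAs dropped).
#' @param min_cells minimum non-NA cells required (default 10).
#' @return list with `p` (length-3 proportions, low/mid/high) and `n`;
#'   NULL when fewer than `min_cells` cells are available.
#' @export
bin_usage <- function(values, min_cells = 10L) {
  v <- values[!is.na(values)]
  if (length(v) < min_cells) return(NULL)
  low <- v <= 1 / 3
  mid <- !low & v <= 2 / 3
  p <- c(low = mean(low), mid = mean(mid), high = mean(!low & !mid))
  list(p = p, n = length(v))
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = KL(p || m) / 2 + KL(q || m) / 2` with `m = (p + q) / 2`,
#' logarithms base 2 so the value is bounded in \[0, 1\];
#' `0 * log(0 / x)` is taken as 0.
#'
#' @param p,q probability vectors of equal length.
#' @return a number in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  .check_simplex(p, "p"); .check_simplex(q, "q")
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  (kl(p) + kl(q)) / 2
}

#' Reference binned distributions for the five modalities
#'
#' distal (0,0,1): most cells use the distal site; proximal (1,0,0);
#' middle (0,1,0): moderate distal usage throughout; bimodal (1/2,0,1/2):
#' two subpopulations at the extremes; multimodal (1/3,1/3,1/3): usage
#' spread over the whole range.
#'
#' @return 5 x 3 numeric matrix, rows named by modality.
#' @export
modality_references <- function() {
  rbind(distal     = c(0, 0, 1),
        proximal   = c(1, 0, 0),
        middle     = c(0, 1, 0),
        bimodal    = c(1 / 2, 0, 1 / 2),
        multimodal = c(1 / 3, 1 / 3, 1 / 3))
}

#' Assign a modality label to a binned usage distribution
#'
#' Picks the reference distribution with the smallest Jensen-Shannon
#' divergence; ties break in the order distal, proximal, middle, bimodal,
#' multimodal.
#'
#' @param p length-3 binned proportions (see [bin_usage()]).
#' @param refs reference matrix (default [modality_references()]).
#' @return list with `label` and `jsd` (named divergences to all
#'   references).
#' @export
assign_modality <- function(p, refs = modality_references()) {
  d <- apply(refs, 1L, function(r) jsd(p, r))
  list(label = names(d)[which.min(d)], jsd = d)
}

#' Variance of distal usage across cells
#'
#' Sample variance of the non-NA per-cell distal usages; bimodal genes are
#' expected to show the largest values.
#'
#' @param values per-cell distal usages.
#' @return a number, or NA when fewer than 2 values.
#' @export
usage_variability <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  stats::var(v)
}

#' Classify APA modality for all genes, per cell type
#'
#' For every multi-isoform gene detected in at least `min_cells` cells of a
#' type, bins the distal usage, assigns the closest reference modality by
#' Jensen-Shannon divergence, and records the usage variance.
#'
#' @inheritParams distal_usage
#' @param labels named vector cell -> type, or NULL to use
#'   `colData(sce)$cell_type`.
#' @param min_cells minimum detecting cells (default 10).
#' @param refs reference matrix (default [modality_references()]).
#' @return data.frame: `gene_id`, `cell_type`, `modality`, `jsd_*` columns,
#'   `n_cells`, `var_distal`.
#' @export
apa_modality <- function(sce, labels = NULL, min_cells = 10L,
                         refs = modality_references()) {
  labels <- .cell_labels(sce, labels)
  lab <- as.character(labels[colnames(sce)])
  dm <- distal_usage_matrix(sce)
  out <- list()
  for (t in sort(unique(lab))) {
    cols <- lab == t
    for (g in rownames(dm)) {
      b <- bin_usage(dm[g, cols], min_cells = min_cells)
      if (is.null(b)) next
      a <- assign_modality(b$p, refs)
      row <- data.frame(gene_id = g, cell_type = t, modality = a$label,
                        n_cells = b$n,
                        var_distal = usage_variability(dm[g, cols]),
                        stringsAsFactors = FALSE)
      row[paste0("jsd_", names(a$jsd))] <- as.list(a$jsd)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), cell_type = character(),
                      modality = character(), n_cells = integer(),
                      var_distal = numeric())
  rownames(res) <- NULL
  res
}

#' Genes correlated with a bimodal APA event, and the cell partition they
#' induce
#'
#' Computes Pearson correlations between every gene's normalized expression
#' (`log2(uTPM + 1)`) and the target gene's distal usage over the cells
#' where that usage is defined; the top `k` correlated and top `k`
#' anticorrelated genes (genes with undefined correlation, e.g. constant
#' expression, are excluded) are used to cluster the cells hierarchically
#' (average linkage, Euclidean distance on per-gene standardized
#' expression) into two groups.
#'
#' @param expr genes x cells matrix of `log2(uTPM + 1)` (see
#'   [utpm()] with `log2 = TRUE`).
#' @param target_usage named per-cell distal usage of the target gene
#'   (see [distal_usage()]).
#' @param k number of genes per direction (default 50).
#' @param min_cells minimum cells with defined usage (default 10).
#' @return list with `correlated` and `anticorrelated` (data.frames
#'   `gene_id`, `r`), `groups` (named 1/2 assignment per cell), and `r`
#'   (all defined correlations).
#' @export
correlated_genes <- function(expr, target_usage, k = 50L, min_cells = 10L) {
  cells <- intersect(colnames(expr), names(target_usage)[!is.na(target_usage)])
  if (length(cells) < min_cells)
    stop("target usage defined in fewer than min_cells cells")
  E <- expr[, cells, drop = FALSE]
  u <- target_usage[cells]
  r <- suppressWarnings(as.vector(stats::cor(t(E), u)))
  names(r) <- rownames(E)
  r <- r[!is.na(r)]
  ord <- order(r, decreasing = TRUE)
  top <- head(ord, k)
  bot <- head(rev(ord), k)
  sel <- unique(c(names(r)[top], names(r)[bot]))
  Z <- t(scale(t(E[sel, , drop = FALSE])))
  Z <- Z[rowSums(!is.finite(Z)) == 0, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(Z)), method = "average")
  groups <- stats::cutree(hc, k = 2L)
  list(correlated = data.frame(gene_id = names(r)[top], r = unname(r[top])),
       anticorrelated = data.frame(gene_id = names(r)[bot],
                                   r = unname(r[bot])),
       groups = groups, r = r)
}
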