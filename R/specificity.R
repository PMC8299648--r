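# Cell-type specificity of APA: Hellinger-similarity cell networks scored
# by cross-validated neighbor voting (AUROC), corroborated by one-vs-rest
# differential usage on artificial bulk profiles.

#' Hellinger distance between two usage vectors
#'
#' `d(u, v) = (1 / sqrt(2)) * sqrt(sum_i (sqrt(u_i) - sqrt(v_i))^2)`,
#' a metric bounded in \[0, 1\] for probability vectors: 0 iff `u == v`,
#' 1 for disjoint supports.
#'
#' @param u,v numeric vectors on the same simplex (equal length,
#'   non-negative, summing to 1).
#' @return a number in \[0, 1\].
#' @export
hellinger_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("usage vectors must have the same length")
  sqrt(sum((sqrt(u) - sqrt(v))^2)) / sqrt(2)
}

#' Build a gene's cell-to-cell similarity network
#'
#' Over the cells where the gene is detected (non-NA usage), the network
#' weight between cells j and k is `1 - d_jk`, with `d_jk` the Hellinger
#' distance between their usage vectors. Self-similarity is 1.
#'
#' @param sce `SingleCellExperiment` with a `usage` assay (see
#'   [add_usage()]).
#' @param gene gene id.
#' @return list with `gene`, `cells` (character vector) and `S`, the
#'   symmetric similarity matrix; NULL when fewer than 2 cells detect the
#'   gene.
#' @export
build_network <- function(sce, gene) {
  u <- .gene_usage(sce, gene)
  if (is.null(u)) return(NULL)
  det <- !is.na(u[1L, ])
  if (sum(det) < 2L) return(NULL)
  U <- t(u[, det, drop = FALSE])               # cells x isoforms
  R <- sqrt(U)
  G <- R %*% t(R)                               # Bhattacharyya coefficients
  G[G > 1] <- 1
  S <- 1 - sqrt(1 - G)
  diag(S) <- 1
  dimnames(S) <- list(rownames(U), rownames(U))
  list(gene = gene, cells = rownames(U), S = S)
}

.gene_usage <- function(sce, gene) {
  rows <- which(SummarizedExperiment::rowData(sce)$gene_id == gene)
  if (length(rows) < 2L) return(NULL)
  SummarizedExperiment::assay(sce, "usage")[rows, , drop = FALSE]
}

#' Cross-validated neighbor-voting AUROC on a similarity network
#'
#' Repeatedly splits the cells into stratified folds; each held-out cell's
#' vote for type t is the summed similarity to training cells of type t,
#' normalized by its total similarity to the training set (a zero
#' denominator gives the uninformative vote 0.5). Per fold and type, the
#' AUROC of the votes against the true one-vs-rest membership is computed
#' by midranks (Mann-Whitney); folds lacking a positive or a negative
#' held-out cell are skipped for that type. The mean over folds and repeats
#' is reported. Deterministic given `seed`.
#'
#' @param network list from [build_network()].
#' @param labels named character/factor vector, cell -> cell type (must
#'   cover the network's cells).
#' @param folds number of cross-validation folds (default 3).
#' @param repeats number of repeated splits (default 10).
#' @param seed integer seed (required, for reproducibility).
#' @return named numeric vector: mean AUROC per cell type (NA when never
#'   scoreable).
#' @export
neighbor_voting_auroc <- function(network, labels, folds = 3L,
                                  repeats = 10L, seed) {
  S <- network$S
  lab <- as.character(labels[network$cells])
  if (anyNA(lab)) stop("labels missing for some network cells")
  types <- sort(unique(lab))
  n <- length(lab)
  acc <- matrix(0, nrow = length(types), ncol = 2L,
                dimnames = list(types, c("sum", "n")))
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(lab, folds, .derive_seed(seed, r))
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(test) == 0L || length(train) == 0L) next
      V <- S[test, train, drop = FALSE]
      denom <- rowSums(V)
      for (t in types) {
        vote <- rowSums(V[, lab[train] == t, drop = FALSE]) / denom
        vote[denom == 0] <- 0.5
        pos <- lab[test] == t
        np <- sum(pos); nn <- sum(!pos)
        if (np == 0L || nn == 0L) next
        rk <- rank(vote)                       # midranks for ties
        auc <- (sum(rk[pos]) - np * (np + 1) / 2) / (np * nn)
        acc[t, "sum"] <- acc[t, "sum"] + auc
        acc[t, "n"] <- acc[t, "n"] + 1
      }
    }
  }
  out <- ifelse(acc[, "n"] > 0, acc[, "sum"] / acc[, "n"], NA_real_)
  names(out) <- types
  out
}

.stratified_folds <- function(lab, folds, seed) {
  fold <- integer(length(lab))
  set.seed(seed)
  for (t in unique(lab)) {
    idx <- which(lab == t)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Score cell-type specificity of APA for all genes
#'
#' For every gene with at least two poly(A) isoforms, builds the
#' Hellinger-similarity network over detecting cells and computes the
#' cross-validated neighbor-voting AUROC per cell type. A (gene, type)
#' entry is reported only when the gene is detected in at least `min_cells`
#' cells of that type.
#'
#' @inheritParams build_network
#' @inheritParams neighbor_voting_auroc
#' @param labels named vector cell -> type covering `colnames(sce)`, or
#'   NULL to use `colData(sce)$cell_type`.
#' @param min_cells minimum detecting cells per type (default 10).
#' @return data.frame: `gene_id`, `cell_type`, `auroc`, `n_cells`.
#' @export
apa_specificity <- function(sce, labels = NULL, folds = 3L, repeats = 10L,
                            seed, min_cells = 10L) {
  labels <- .cell_labels(sce, labels)
  genes <- unique(SummarizedExperiment::rowData(sce)$gene_id)
  out <- list()
  for (g in genes) {
    nw <- build_network(sce, g)
    if (is.null(nw)) next
    auc <- neighbor_voting_auroc(nw, labels, folds = folds,
                                 repeats = repeats, seed = seed)
    ndet <- table(factor(as.character(labels[nw$cells]),
                         levels = names(auc)))
    keep <- as.integer(ndet) >= min_cells & !is.na(auc)
    if (!any(keep)) next
    out[[g]] <- data.frame(gene_id = g, cell_type = names(auc)[keep],
                           auroc = unname(auc[keep]),
                           n_cells = as.integer(ndet)[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), cell_type = character(),
                      auroc = numeric(), n_cells = integer())
  rownames(res) <- NULL
  res
}

.cell_labels <- function(sce, labels) {
  if (is.null(labels)) {
    labels <- SummarizedExperiment::colData(sce)$cell_type
    if (is.null(labels)) stop("no cell labels supplied")
    names(labels) <- colnames(sce)
  }
  labels
}

#' Select genes with cell-type-specific APA
#'
#' Genes whose mean AUROC strictly exceeds the threshold for a type.
#'
#' @param table specificity data.frame (see [apa_specificity()]).
#' @param threshold AUROC cutoff (default 0.8, strict `>`).
#' @return named list of gene-id vectors, one per cell type.
#' @export
specific_apa_genes <- function(table, threshold = 0.8) {
  if (nrow(table) == 0L) return(list())
  sel <- table[table$auroc > threshold, , drop = FALSE]
  lapply(split(sel$gene_id, factor(sel$cell_type,
                                   levels = sort(unique(table$cell_type)))),
         unique)
}

#' One-vs-rest differential poly(A)-site usage on artificial bulk
#'
#' For each cell type, isoform counts are summed over the type's cells and
#' over all other cells (artificial bulk). Per gene with at least two
#' observed isoforms, the isoform x (type, rest) contingency table is
#' tested for independence: chi-square without continuity correction, or
#' Fisher's exact test for 2x2 tables with any expected cell below 5.
#' P-values are Benjamini-Hochberg adjusted across genes within each type.
#'
#' @inheritParams apa_specificity
#' @return data.frame: `gene_id`, `cell_type`, `stat`, `p`, `q`,
#'   `n_isoforms`, `delta` (max absolute bulk usage difference), `method`.
#' @export
differential_usage <- function(sce, labels = NULL) {
  labels <- .cell_labels(sce, labels)
  cnt <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  gene <- SummarizedExperiment::rowData(sce)$gene_id
  lab <- as.character(labels[colnames(sce)])
  types <- sort(unique(lab))
  if (length(types) < 2L) stop("differential usage needs >= 2 cell types")
  out <- list()
  for (t in types) {
    in_t <- lab == t
    bulk <- cbind(type = rowSums(cnt[, in_t, drop = FALSE]),
                  rest = rowSums(cnt[, !in_t, drop = FALSE]))
    rows <- list()
    for (g in unique(gene)) {
      M <- bulk[gene == g, , drop = FALSE]
      M <- M[rowSums(M) > 0, , drop = FALSE]
      if (nrow(M) < 2L || any(colSums(M) == 0)) {
        rows[[g]] <- data.frame(gene_id = g, cell_type = t, stat = NA_real_,
                                p = NA_real_, n_isoforms = nrow(M),
                                delta = NA_real_, method = "none")
        next
      }
      exp_ <- outer(rowSums(M), colSums(M)) / sum(M)
      if (nrow(M) == 2L && any(exp_ < 5)) {
        p <- stats::fisher.test(M)$p.value
        stat <- NA_real_
        method <- "fisher"
      } else {
        ch <- suppressWarnings(stats::chisq.test(M, correct = FALSE))
        p <- ch$p.value
        stat <- unname(ch$statistic)
        method <- "chisq"
      }
      uT <- M[, 1L] / sum(M[, 1L]); uR <- M[, 2L] / sum(M[, 2L])
      rows[[g]] <- data.frame(gene_id = g, cell_type = t, stat = stat, p = p,
                              n_isoforms = nrow(M),
                              delta = max(abs(uT - uR)), method = method)
    }
    d <- do.call(rbind, rows)
    d$q <- stats::p.adjust(d$p, method = "BH")
    out[[t]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "cell_type", "stat", "p", "q", "n_isoforms", "delta",
          "method")]
}
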