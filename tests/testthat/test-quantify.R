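# Peak -> site assignment, per-cell counting, usage and uTPM.

genes_gr <- GenomicRanges::GRanges(
  "chr1", IRanges::IRanges(c(1, 400), c(300, 700)), strand = "+",
  gene_id = c("gA", "gB"))

test_that("restrict_to_genes keeps genic peaks and tags genes", {
  pk <- data.frame(chrom = "chr1", strand = c("+", "+", "+"),
                   start = c(50L, 320L, 250L), end = c(80L, 380L, 450L))
  out <- restrict_to_genes(pk, genes_gr)
  expect_equal(nrow(out), 2)                 # the intergenic peak is gone
  expect_equal(out$gene_id[1], "gA")
  expect_true(is.na(out$gene_id[2]))         # spans both genes: deferred
  expect_setequal(out$gene_candidates[[2]], c("gA", "gB"))
})

test_that("assign_peaks_to_sites handles single, multiple and missing sites", {
  sites <- data.frame(chrom = "chr1", strand = "+",
                      pos = c(120L, 180L, 650L))
  pileup <- data.frame(chrom = "chr1", strand = "+",
                       pos = c(120L, 121:180), count = c(9L, ifelse(121:180 == 151L, 1L, 5L)))
  pk1 <- data.frame(chrom = "chr1", strand = "+", start = 100L, end = 200L,
                    gene_id = "gA")
  out <- assign_peaks_to_sites(pk1, sites, pileup = pileup)
  expect_equal(nrow(out), 2)                 # split between the two sites
  expect_equal(out$start, c(100L, 151L))
  expect_equal(out$end, c(151L, 200L))
  expect_equal(out$site_pos, c(120L, 180L))

  # exactly one site: whole peak assigned
  one <- assign_peaks_to_sites(
    data.frame(chrom = "chr1", strand = "+", start = 600L, end = 700L,
               gene_id = "gB"), sites, pileup = pileup)
  expect_equal(nrow(one), 1)
  expect_equal(one$site_pos, 650L)

  # siteless peak: rescued within assign_dist, dropped beyond it
  near <- assign_peaks_to_sites(
    data.frame(chrom = "chr1", strand = "+", start = 200L, end = 220L,
               gene_id = "gA"), sites, pileup = NULL)
  expect_equal(near$site_pos, 180L)
  far <- assign_peaks_to_sites(
    data.frame(chrom = "chr1", strand = "+", start = 400L, end = 420L,
               gene_id = "gA"), sites, pileup = NULL)
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "stats")$n_siteless_dropped, 1)
})

test_that("multi-gene peaks resolve to the gene containing the site", {
  pk <- data.frame(chrom = "chr1", strand = "+", start = 250L, end = 450L,
                   gene_id = NA_character_)
  pk$gene_candidates <- list(c("gA", "gB"))
  sites <- data.frame(chrom = "chr1", strand = "+", pos = 420L)
  out <- assign_peaks_to_sites(pk, sites, genes = genes_gr)
  expect_equal(out$gene_id, "gB")
})

test_that("count_isoforms counts tags inside half-open peak intervals", {
  regions <- data.frame(chrom = "chr1", strand = "+", start = 100L,
                        end = 150L, site_pos = 140L, gene_id = "gA",
                        site_id = "chr1:140:+")
  tags <- make_tags(cb = rep("B1", 6), umi = paste0("U", 1:6),
                    end3 = c(100L, 120L, 140L, 149L, 150L, 99L))
  sce <- count_isoforms(tags, regions)
  m <- SummarizedExperiment::assay(sce, "counts")
  expect_equal(as.numeric(m["gA|chr1:140:+", "B1"]), 4)  # 150 and 99 outside
  expect_equal(S4Vectors::metadata(sce)$n_unassigned_tags, 2)
})

test_that("usage fractions live on the simplex with NA for undetected", {
  cnt <- matrix(c(6, 2, 2,   0, 0, 0,   5, 0, 0), nrow = 3,
                dimnames = list(NULL, c("c1", "c2", "c3")))
  sce <- make_sce(cnt, gene_id = rep("gA", 3), site_pos = c(10L, 20L, 30L))
  u <- SummarizedExperiment::assay(sce, "usage")
  expect_equal(unname(u[, "c1"]), c(0.6, 0.2, 0.2))
  expect_true(all(is.na(u[, "c2"])))
  expect_equal(unname(u[, "c3"]), c(1, 0, 0))

  # single-isoform gene gets usage 1 wherever detected
  s1 <- make_sce(matrix(5, 1, 1), gene_id = "gS", site_pos = 10L)
  expect_equal(as.numeric(SummarizedExperiment::assay(s1, "usage")), 1)

  set.seed(23)
  cnt <- matrix(rpois(300, 4), nrow = 6)
  sce <- make_sce(cnt, gene_id = rep(c("g1", "g2"), each = 3),
                  site_pos = rep(c(10L, 20L, 30L), 2))
  u <- SummarizedExperiment::assay(sce, "usage")
  for (g in c("g1", "g2")) {
    rows <- SummarizedExperiment::rowData(sce)$gene_id == g
    sums <- colSums(u[rows, , drop = FALSE])
    expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))
  }
})

test_that("uTPM normalizes each cell to one million", {
  cnt <- matrix(c(5, 49995, 0, 0), nrow = 2,
                dimnames = list(NULL, c("c1", "c2")))
  sce <- make_sce(cnt, gene_id = c("g1", "g2"), site_pos = c(10L, 20L))
  e <- utpm(sce)
  expect_equal(e["g1", "c1"], 100)
  expect_equal(ncol(e), 1)                    # zero-total cell excluded
  expect_equal(attr(e, "excluded_cells"), "c2")

  set.seed(31)
  cnt <- matrix(rpois(200, 10), nrow = 10)
  sce <- make_sce(cnt, gene_id = paste0("g", 1:10),
                  site_pos = seq(10L, 100L, 10L))
  e <- utpm(sce)
  expect_true(all(abs(colSums(e) - 1e6) < 1e-6 * 1e6))
  lg <- utpm(sce, log2 = TRUE)
  expect_equal(unname(lg[1, 1]), log2(unname(e[1, 1]) + 1))
})

test_that("bulk usage equals the count-weighted mean of cell usages", {
  set.seed(41)
  cnt <- matrix(rpois(60, 6), nrow = 3)
  sce <- make_sce(cnt, gene_id = rep("gA", 3), site_pos = c(10L, 20L, 30L))
  u <- SummarizedExperiment::assay(sce, "usage")
  bulk <- rowSums(cnt) / sum(cnt)
  tot <- colSums(cnt)
  keep <- tot > 0
  weighted <- colSums(t(u[, keep]) * tot[keep]) / sum(tot[keep])
  expect_equal(unname(weighted), unname(bulk), tolerance = 1e-12)
})

test_that("usage recovers programmed per-cell vectors at high depth", {
  ref <- make_reference(sim_genome_spec(n_genes = 30L, seed = 4L))
  cspec <- sim_cell_spec(cell_types = c(all = 60L), depth_mean = 60,
                         conc = 10, seed = 4L)
  sce <- add_usage(simulate_counts(ref, cspec))
  est <- SummarizedExperiment::assay(sce, "usage")
  tru <- S4Vectors::metadata(sce)$truth$usage_drawn
  ok <- !is.na(est)
  expect_lt(mean(abs(est[ok] - tru[ok])), 0.05)
})
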