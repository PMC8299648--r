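# Poly(A)-site identification: pileups, internal-priming filter, distance
# clustering, site calling, annotation comparison, motif profiling.

toy_utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                                  strand = "+")

test_that("collect_polya_tags keeps polyA tags inside same-strand 3'UTRs", {
  tags <- rbind(
    make_tags(cb = "B", umi = paste0("U", 1:5), end3 = c(10, 20, 30, 40, 50)),
    make_tags(cb = "B", umi = paste0("V", 1:2), end3 = c(600, 700)),
    make_tags(cb = "B", umi = paste0("W", 1:3), end3 = c(15, 25, 35),
              polya = FALSE))
  p <- collect_polya_tags(tags, toy_utr)
  expect_equal(sum(p$count), 5)
  # restriction disabled: outside-UTR polyA tags return
  p2 <- collect_polya_tags(tags, restrict = FALSE)
  expect_equal(sum(p2$count), 7)
  # strand mismatch excludes
  minus <- make_tags(cb = "B", umi = "M1", strand = "-", end3 = 10)
  expect_equal(nrow(collect_polya_tags(minus, toy_utr)), 0)
  expect_error(collect_polya_tags(tags, NULL, restrict = TRUE), "3'UTR")
})

test_that("filter_internal_priming removes positions with downstream A-runs", {
  # position 9 (0-based): downstream 20 bp carry A x 6 -> removed
  # position 59: downstream max run 2 -> kept
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 10), "TTAAAAAACGTTAGCGTAGC", strrep("G", 30),
    "AATAATAAGTCGTAGCTAGC", strrep("G", 20))))
  pil <- data.frame(chrom = "chr1", strand = "+", pos = c(9L, 59L),
                    count = c(5L, 5L))
  out <- filter_internal_priming(pil, g)
  expect_equal(out$pos, 59L)
  expect_equal(attr(out, "stats")$n_removed, 1)
})

test_that("internal-priming filtering is strand-aware and edge-safe", {
  # '-' strand: downstream is the reverse complement of the genomic left
  # flank, so a genomic T-run upstream reads as an adenine run
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 10), strrep("T", 6), "GCGC", strrep("G", 30))))
  pil <- data.frame(chrom = "chr1", strand = "-", pos = 20L, count = 3L)
  expect_equal(nrow(filter_internal_priming(pil, g)), 0)
  # near the chromosome end the window truncates instead of erroring
  pil2 <- data.frame(chrom = "chr1", strand = "+", pos = 48L, count = 3L)
  expect_equal(nrow(filter_internal_priming(pil2, g)), 1)
})

test_that("raising min_run never removes more positions (monotonicity)", {
  set.seed(3)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                        prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
    g <- Biostrings::DNAStringSet(c(chr1 = seq))
    pil <- data.frame(chrom = "chr1", strand = "+",
                      pos = sort(sample(0:350, 30)), count = 1L)
    kept <- vapply(4:8, function(r)
      nrow(filter_internal_priming(pil, g, min_run = r)), 1L)
    expect_true(all(diff(kept) >= 0))
  }
})

test_that("cluster_tags matches a brute-force transitive-closure oracle", {
  pil <- data.frame(chrom = "chr1", strand = "+",
                    pos = c(100L, 112L, 140L), count = c(5L, 3L, 2L))
  cl <- cluster_tags(pil, max_gap = 20)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$summit, c(100L, 140L))
  expect_equal(cl$total, c(8L, 2L))
  expect_equal(cl$end - cl$start, c(13L, 1L))

  # chain with gaps exactly equal to max_gap joins everything
  pil2 <- data.frame(chrom = "chr1", strand = "+",
                     pos = c(0L, 20L, 40L), count = 1L)
  expect_equal(nrow(cluster_tags(pil2, max_gap = 20)), 1)

  set.seed(5)
  for (i in 1:20) {
    pos <- sort(sample(0:300, 12))
    pil <- data.frame(chrom = "chr1", strand = "+", pos = pos,
                      count = sample(1:9, 12, TRUE))
    cl <- cluster_tags(pil, max_gap = 15)
    oracle <- oracle_distance_clusters(pos, 15)
    got <- lapply(seq_len(nrow(cl)), function(k)
      pos[pos >= cl$start[k] & pos < cl$end[k]])
    expect_equal(length(got), length(oracle))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("cluster summits break ties toward the 5' end per strand", {
  pil <- data.frame(chrom = "chr1", strand = "+", pos = c(10L, 14L),
                    count = c(3L, 3L))
  expect_equal(cluster_tags(pil)$summit, 10L)
  pil$strand <- "-"
  expect_equal(cluster_tags(pil)$summit, 14L)
})

test_that("call_sites applies raw and normalized thresholds", {
  cl <- data.frame(chrom = "chr1", strand = "+", start = 100L, end = 110L,
                   summit = 104L, total = 8L, n_pos = 3L)
  s <- call_sites(cl, total_polya_tags = 1e6, min_norm_count = 5,
                  min_raw_count = 3)
  expect_equal(nrow(s), 1)
  expect_equal(s$norm_count, 8)
  expect_equal(s$pos, 104L)

  cl$total <- 2L
  expect_equal(nrow(call_sites(cl, 1e6, 0, 3)), 0)
  expect_error(call_sites(cl, 0), "positive")
})

test_that("classify_vs_annotation signs distances in transcription direction", {
  sites <- data.frame(chrom = "chr1", strand = c("+", "+", "-"),
                      pos = c(1000L, 2000L, 3000L), tag_count = 5L)
  ann <- data.frame(chrom = "chr1", strand = c("+", "+", "-"),
                    pos = c(1004L, 2100L, 3004L))
  out <- classify_vs_annotation(sites, ann)
  expect_equal(out$sites$nearest_annotated_dist, c(4L, 100L, -4L))
  expect_equal(out$sites$status, c("annotated", "novel", "annotated"))
  expect_equal(sum(out$histogram$count), 3)  # all within the +/-100 window

  # empty annotation: everything novel, empty histogram
  none <- classify_vs_annotation(sites, ann[0, ])
  expect_true(all(none$sites$status == "novel"))
  expect_equal(sum(none$histogram$count), 0)
})

test_that("annotated status is exactly the |dist| <= match_dist predicate", {
  set.seed(9)
  sites <- data.frame(chrom = "chr1", strand = "+",
                      pos = sort(sample(0:5000, 40)), tag_count = 1L)
  ann <- data.frame(chrom = "chr1", strand = "+",
                    pos = sort(sample(0:5000, 25)))
  out <- classify_vs_annotation(sites, ann, match_dist = 24)$sites
  brute <- vapply(sites$pos, function(p) min(abs(ann$pos - p)), 1)
  expect_equal(out$status == "annotated", brute <= 24)
})

test_that("motif_profile locates planted signals on both strands", {
  # one + site and one - site, AATAAA planted to start 21 nt upstream
  left <- strrep("C", 100)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    left, "AATAAA", strrep("C", 15), "G",           # + site at pos 121
    strrep("C", 50),
    "G", strrep("C", 15), "TTTATT", strrep("C", 100))))  # - site at 172
  sites <- data.frame(chrom = "chr1", strand = c("+", "-"),
                      pos = c(121L, 172L))
  mp <- motif_profile(sites, g)
  expect_equal(mp$n_sites, 2)
  expect_equal(mp$profile$freq[mp$profile$offset == -21], 1)
  expect_equal(mp$upstream_fraction, 1)
  # absent motif: all-zero profile
  g0 <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 400)))
  mp0 <- motif_profile(data.frame(chrom = "chr1", strand = "+", pos = 200L),
                       g0)
  expect_true(all(mp0$profile$freq == 0))
})

test_that("multiple occurrences increment both offsets but count one site", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 70), "AATAAA", "CCC", "AATAAA", strrep("C", 21),
    strrep("G", 60))))
  # occurrences start at 0-based 70 and 79; site at 100 -> offsets -30, -21
  sites <- data.frame(chrom = "chr1", strand = "+", pos = 100L)
  mp <- motif_profile(sites, g)
  expect_equal(mp$profile$freq[mp$profile$offset %in% c(-30, -21)], c(1, 1))
  expect_equal(mp$upstream_fraction, 1)
})

test_that("per-type site sets merge by single-linkage chaining", {
  a <- data.frame(chrom = "chr1", strand = "+", pos = c(100L, 300L),
                  tag_count = c(10L, 5L))
  b <- data.frame(chrom = "chr1", strand = "+", pos = c(110L, 320L),
                  tag_count = c(20L, 4L))
  m <- merge_site_sets(list(a, b), match_dist = 24)
  expect_equal(nrow(m), 2)
  expect_equal(m$pos, c(110L, 300L))     # highest-count representative
  expect_equal(m$tag_count, c(30L, 9L))
})
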