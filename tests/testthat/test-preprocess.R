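# Read labeling, poly(A) trimming, deduplication and demultiplexing.

dss <- function(x, names = NULL) {
  s <- Biostrings::DNAStringSet(x)
  if (!is.null(names)) names(s) <- names
  S4Vectors::mcols(s)$qualities <-
    Biostrings::BStringSet(strrep("I", nchar(x)))
  s
}

test_that("label_reads extracts barcode and UMI into the read name", {
  lay <- barcode_layout(1, 8, 9, 6)
  r1 <- dss("ACGTACGTTTCCAA")
  r2 <- dss("GATTACAGATTACAGATTACA", names = "readX")
  out <- label_reads(r1, r2, lay)
  expect_equal(names(out$reads), "readX_CB:ACGTACGT_UB:TTCCAA")
  expect_equal(out$barcode, "ACGTACGT")
  expect_equal(out$umi, "TTCCAA")

  # empty input
  e <- label_reads(dss(character(0)), dss(character(0)), lay)
  expect_length(e$reads, 0)
  expect_equal(e$stats$n_in, 0)

  # three pairs sharing one barcode -> one distinct barcode
  r1b <- dss(rep("ACGTACGTTTCCAA", 3))
  r2b <- dss(rep("GATTACAGATTACA", 3))
  out3 <- label_reads(r1b, r2b, lay)
  expect_equal(out3$stats$n_labeled, 3)
  expect_equal(out3$stats$n_barcodes, 1)
})

test_that("label_reads drops short read1 and non-whitelisted barcodes", {
  lay <- barcode_layout(1, 8, 9, 6, whitelist = "ACGTACGT")
  r1 <- dss(c("ACGTACGTTTCCAA", "TTTTTTTTAAAAAA", "ACGTA"))
  r2 <- dss(c("GATTACAGATTACA", "GATTACAGATTACA", "GATTACAGATTACA"))
  out <- label_reads(r1, r2, lay)
  expect_equal(out$stats$n_labeled, 1)
  expect_equal(out$stats$n_short_read1, 1)
  expect_equal(out$stats$n_not_whitelisted, 1)
})

test_that("barcode_layout rejects overlapping intervals", {
  expect_error(barcode_layout(1, 8, 5, 6), "overlap")
})

test_that("trim_polya truncates at the first A-run and flags the read", {
  # 30 nt read whose last 8 nt are A -> trimmed to 22, flagged
  s <- paste0(strrep("GC", 11), strrep("A", 8))
  out <- trim_polya(dss(s, "r"))
  expect_equal(Biostrings::width(out$reads), 22)
  expect_true(out$polya_flag)
  expect_match(names(out$reads), "_PA:1$")

  # a maximal run of 7 As is below threshold: unchanged, non-polyA
  s7 <- paste0(strrep("GC", 12), strrep("A", 7))
  out7 <- trim_polya(dss(s7, "r"))
  expect_equal(as.character(out7$reads[[1]]), s7)
  expect_false(out7$polya_flag)
  expect_match(names(out7$reads), "_PA:0$")

  # first run at position 11 of a 25-nt read -> trimmed to 10 < 20: discard
  s25 <- paste0("GCGCGCGCGC", strrep("A", 9), "GCGCGC")
  out25 <- trim_polya(dss(s25, "r"))
  expect_length(out25$reads, 0)
  expect_equal(out25$stats$n_discarded_short, 1)
})

test_that("N bases never extend an A-run and lengths never grow", {
  # AAAA N AAA: no run of 8
  s <- paste0(strrep("GC", 10), "AAAANAAA", "GCGC")
  out <- trim_polya(dss(s, "r"))
  expect_false(out$polya_flag)
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE,
                      prob = c(0.5, 1, 1, 1) / 3.5), collapse = "")
    out <- trim_polya(dss(s, "r"), min_len = 1)
    expect_lte(Biostrings::width(out$reads), nchar(s))
  }
})

test_that("dedup_tags keeps one record per key and merges polyA flags", {
  base <- make_tags(cb = c("B1", "B1"), umi = c("U1", "U1"), end3 = c(10, 10),
                    polya = c(TRUE, TRUE))
  expect_equal(nrow(dedup_tags(base)), 1)

  two <- make_tags(cb = c("B1", "B1"), umi = c("U1", "U2"),
                   end3 = c(10, 10), polya = TRUE)
  expect_equal(nrow(dedup_tags(two)), 2)

  # flag merge is order-independent: enumerate all input orders
  mix <- make_tags(cb = "B1", umi = "U1", end3 = 10,
                   polya = c(TRUE, FALSE))
  perms <- list(1:2, 2:1)
  for (p in perms) {
    d <- dedup_tags(mix[p, ])
    expect_equal(nrow(d), 1)
    expect_true(d$polya_flag)
  }
})

test_that("dedup_tags is idempotent and order-invariant on random inputs", {
  set.seed(11)
  for (i in 1:10) {
    n <- 60
    x <- make_tags(cb = sample(c("B1", "B2"), n, TRUE),
                   umi = sample(paste0("U", 1:6), n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE),
                   end3 = sample(1:8, n, TRUE),
                   polya = sample(c(TRUE, FALSE), n, TRUE))
    d1 <- dedup_tags(x)
    d2 <- dedup_tags(d1)
    attr(d1, "stats") <- NULL; attr(d2, "stats") <- NULL
    expect_identical(d1, d2)
    dp <- dedup_tags(x[sample(n), ])
    attr(dp, "stats") <- NULL
    expect_identical(d1, dp)
  }
})

test_that("demultiplex partitions tags and conserves counts", {
  tags <- make_tags(cb = c(rep("B1", 4), rep("B2", 5), "BX"),
                    umi = paste0("U", 1:10), end3 = 1:10)
  cm <- c(B1 = "cellA", B2 = "cellB")
  parts <- demultiplex(tags, cm)
  expect_named(parts, c("cellA", "cellB", "unassigned"))
  expect_equal(sum(vapply(parts, nrow, 1L)), nrow(tags))
  expect_equal(nrow(parts$unassigned), 1)

  # empty map: everything unassigned
  all_un <- demultiplex(tags, setNames(character(0), character(0)))
  expect_equal(nrow(all_un$unassigned), nrow(tags))

  # permuted input gives the identical partition after sorting
  parts2 <- demultiplex(tags[sample(nrow(tags)), ], cm)
  for (nm in names(parts)) {
    a <- parts[[nm]][order(parts[[nm]]$umi), ]
    b <- parts2[[nm]][order(parts2[[nm]]$umi), ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
  expect_error(demultiplex(tags, c(B1 = "x", B2 = "x")), "injective")
})

test_that("read_tag_alignments computes strand-aware 3' ends and filters", {
  sam <- file.path(tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 60, "10M", "*", 0, 0, strrep("A", 10),
          strrep("I", 10), "CB:Z:BC1", "UB:Z:U1", "XA:i:1", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "5M2D5M", "*", 0, 0, strrep("C", 10),
          strrep("I", 10), "CB:Z:BC1", "UB:Z:U2", "XA:i:0", sep = "\t"),
    paste("r3_CB:BC2_UB:U9_PA:1", 0, "chr1", 301, 60, "10M", "*", 0, 0,
          strrep("G", 10), strrep("I", 10), sep = "\t"),
    paste("r4", 0, "chr1", 401, 5, "10M", "*", 0, 0, strrep("T", 10),
          strrep("I", 10), "CB:Z:BC1", "UB:Z:U3", "XA:i:0", sep = "\t")),
    sam)
  aln <- read_tag_alignments(sam, mapq_min = 20)
  expect_equal(nrow(aln), 3)      # r4 fails the mapping-quality floor
  # + strand: rightmost aligned base; 0-based 100 + 10 - 1
  expect_equal(aln$end3[aln$umi == "U1"], 109)
  # - strand: leftmost aligned base
  expect_equal(aln$end3[aln$umi == "U2"], 200)
  expect_equal(aln$strand[aln$umi == "U2"], "-")
  # name-suffix fallback carries barcode, UMI and polyA flag
  r3 <- aln[aln$cell_barcode == "BC2", ]
  expect_equal(r3$umi, "U9")
  expect_true(r3$polya_flag)
})
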