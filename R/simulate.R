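# Deterministic synthetic-data generators: reference genome + annotation
# with planted poly(A) sites, signals and internal-priming decoys;
# per-cell isoform counts with programmed usage structure; and raw
# paired reads with truth alignments, so the whole pipeline can be
# validated without external data or an aligner.

#' Specify a synthetic reference genome
#'
#' One chromosome carrying `n_genes` single-exon genes on alternating
#' strands, separated by intergenic spacers. Each gene carries
#' `sites_per_gene` truth poly(A) sites, a canonical AATAAA signal planted
#' `signal_offset` nt upstream of each site (jittered uniformly by up to
#' `signal_jitter` nt), a downstream 20 nt window scrubbed of adenine runs
#' (so genuine sites survive internal-priming filtering, as real sites
#' overwhelmingly do), and `decoys_per_gene` genomic A-runs of length
#' `decoy_a_run` placed at least 50 nt from every truth site to act as
#' internal-priming decoys.
#'
#' @param n_genes number of genes (default 10).
#' @param sites_per_gene truth poly(A) sites per gene, 1-3 (default 2).
#' @param utr_len gene/3'UTR length in nt (default 600).
#' @param intergenic_len spacer length in nt (default 300).
#' @param signal_offset signal start offset relative to the site, in
#'   transcription direction (default -21).
#' @param signal_jitter maximum absolute jitter on the offset (default 3).
#' @param decoy_a_run decoy adenine-run length (default 10).
#' @param decoys_per_gene decoys per gene (default 1).
#' @param decoy_min_dist minimum distance between a decoy and any truth
#'   site, in nt (default 100, comfortably more than the read footprint so
#'   genuine reads never run into a decoy A-run).
#' @param seed integer seed.
#' @return a `sim_genome_spec` object.
#' @export
sim_genome_spec <- function(n_genes = 10L, sites_per_gene = 2L,
                            utr_len = 600L, intergenic_len = 300L,
                            signal_offset = -21L, signal_jitter = 3L,
                            decoy_a_run = 10L, decoys_per_gene = 1L,
                            decoy_min_dist = 100L, seed = 1L) {
  min_off <- utr_len %/% (sites_per_gene + 1L)
  if (min_off < abs(signal_offset) + signal_jitter + 6L)
    stop("utr_len too small for the requested signal geometry")
  structure(list(n_genes = as.integer(n_genes),
                 sites_per_gene = as.integer(sites_per_gene),
                 utr_len = as.integer(utr_len),
                 intergenic_len = as.integer(intergenic_len),
                 signal_offset = as.integer(signal_offset),
                 signal_jitter = as.integer(signal_jitter),
                 decoy_a_run = as.integer(decoy_a_run),
                 decoys_per_gene = as.integer(decoys_per_gene),
                 decoy_min_dist = as.integer(decoy_min_dist),
                 seed = as.integer(seed)),
            class = "sim_genome_spec")
}

# Plant `seq` on the sense strand of `strand` starting at transcription
# offset `offset` from 0-based position `pos`. `base` is a character vector
# of single letters (the chromosome); returns it modified.
.plant_sense <- function(base, pos, offset, seq, strand) {
  letters_ <- strsplit(seq, "")[[1L]]
  t_off <- offset + seq_along(letters_) - 1L
  if (strand == "+") {
    base[pos + t_off + 1L] <- letters_
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    base[pos - t_off + 1L] <- comp[letters_]
  }
  base
}

#' Build the synthetic reference
#'
#' Deterministic given the spec's seed: genome sequence, gene annotation,
#' truth poly(A) sites and decoy positions.
#'
#' @param spec a [sim_genome_spec()].
#' @return list of class `apa_sim_reference` with `genome` (DNAStringSet),
#'   `gtf` (GRanges with gene/transcript/exon records), `sites`
#'   (data.frame: `chrom`, `strand`, `pos`, `gene_id`, `rank`,
#'   `is_distal`, `signal_start`), `decoys` (data.frame), `seqlengths`,
#'   `spec`.
#' @export
make_reference <- function(spec) {
  stopifnot(is(spec, "sim_genome_spec"))
  set.seed(.derive_seed(spec$seed, 101L))
  chrom <- "simchr"
  unit <- spec$utr_len + spec$intergenic_len
  L <- spec$intergenic_len + spec$n_genes * unit
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  k <- spec$sites_per_gene
  sites <- list(); decoys <- list()
  for (g in seq_len(spec$n_genes)) {
    g0 <- spec$intergenic_len + (g - 1L) * unit
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene_%03d", g)
    offs <- round(spec$utr_len * seq_len(k) / (k + 1L))
    pos <- if (strand == "+") g0 + offs else g0 + spec$utr_len - 1L - offs
    sig <- integer(k)
    for (j in seq_len(k)) {
      o <- spec$signal_offset +
        sample(seq.int(-spec$signal_jitter, spec$signal_jitter), 1L)
      sig[j] <- o
      base <- .plant_sense(base, pos[j], o, "AATAAA", strand)
      # scrub the downstream window: every third base forced non-A, so no
      # sense-strand adenine run longer than 2 can arise there and genuine
      # sites survive the internal-priming filter
      for (t in seq.int(3L, 21L, by = 3L))
        base <- .plant_sense(base, pos[j], t, sample(c("C", "G", "T"), 1L),
                             strand)
    }
    sites[[g]] <- data.frame(chrom = chrom, strand = strand, pos = pos,
                             gene_id = gene_id, rank = seq_len(k),
                             is_distal = seq_len(k) == k,
                             signal_start = sig, stringsAsFactors = FALSE)
    # decoys: transcription offsets well inside the gene, clear of every
    # truth site by decoy_min_dist
    cand <- seq.int(40L, spec$utr_len - 40L - spec$decoy_a_run)
    cand <- cand[vapply(cand,
                        function(x) all(abs(x - offs) >= spec$decoy_min_dist),
                        logical(1L))]
    nd <- min(spec$decoys_per_gene, length(cand))
    if (nd > 0L) {
      dpos_off <- sample(cand, nd)
      dpos <- if (strand == "+") g0 + dpos_off else
        g0 + spec$utr_len - 1L - dpos_off
      for (d in dpos) {
        base <- .plant_sense(base, d, 1L,
                             strrep("A", spec$decoy_a_run), strand)
      }
      decoys[[g]] <- data.frame(chrom = chrom, strand = strand, pos = dpos,
                                gene_id = gene_id, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, sites)
  decoys <- do.call(rbind, decoys)
  genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""),
                                              chrom))
  gtf <- .sim_gtf(spec, chrom, unit)
  structure(list(genome = genome, gtf = gtf, sites = sites, decoys = decoys,
                 seqlengths = setNames(L, chrom), spec = spec),
            class = "apa_sim_reference")
}

.sim_gtf <- function(spec, chrom, unit) {
  g <- seq_len(spec$n_genes)
  g0 <- spec$intergenic_len + (g - 1L) * unit
  strand <- ifelse(g %% 2L == 1L, "+", "-")
  gene_id <- sprintf("gene_%03d", g)
  tx_id <- sprintf("tx_%03d", g)
  one <- function(type, tx) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(g0 + 1L,
                                                  g0 + spec$utr_len),
                                 strand = strand)
    gr$type <- type
    gr$gene_id <- gene_id
    gr$transcript_id <- if (tx) tx_id else NA_character_
    gr
  }
  c(one("gene", FALSE), one("transcript", TRUE), one("exon", TRUE))
}

#' Specify the synthetic cell population
#'
#' Controls cell-type composition, sequencing depth and the per-gene usage
#' models: Dirichlet-distributed usage around per-type means (optionally
#' shifted in one focal type for "specific" genes), per-cell Beta
#' generators for modality genes, and subpopulation-linked bimodal genes
#' with a coupled expression program.
#'
#' @param cell_types named integer vector, cell type -> number of cells.
#' @param depth_mean mean UMIs per gene per cell (Poisson; default 30).
#' @param conc Dirichlet concentration of within-type usage variability
#'   (default 10; `Inf` makes every cell use the type mean exactly).
#' @param base_distal range from which each gene's baseline mean distal
#'   usage is drawn (default `c(0.6, 0.9)`, reflecting the distal
#'   preference of neural tissue).
#' @param specific optional data.frame `gene_id`, `cell_type`, `delta`:
#'   in the focal type the gene's mean distal usage is shifted by `delta`
#'   (baselines for these genes are drawn from
#'   `pmin(base_distal, 1 - delta - 0.05)` so the shift never clips).
#' @param modality optional named character vector gene -> generator in
#'   `distal`, `proximal`, `middle`, `bimodal`, `multimodal`; these genes
#'   draw per-cell distal usage from the corresponding Beta-family
#'   generator instead of the Dirichlet model.
#' @param bimodal_genes genes whose distal usage is tied to a latent
#'   two-subpopulation split (Beta(8,1) in subpopulation 1, Beta(1,8) in
#'   subpopulation 2).
#' @param subpop_frac fraction of cells in subpopulation 1 (default 0.5).
#' @param program optional data.frame `gene_id`, `direction` (+1/-1):
#'   expression program coupled to the subpopulations; these genes'
#'   depth is multiplied by `program_factor` (direction +1) or divided by
#'   it (direction -1) in subpopulation 1, and vice versa in
#'   subpopulation 2.
#' @param program_factor fold change of the expression program (default 3).
#' @param seed integer seed.
#' @return a `sim_cell_spec` object.
#' @export
sim_cell_spec <- function(cell_types = c(all = 200L), depth_mean = 30,
                          conc = 10, base_distal = c(0.6, 0.9),
                          specific = NULL, modality = NULL,
                          bimodal_genes = character(0), subpop_frac = 0.5,
                          program = NULL, program_factor = 3,
                          seed = 1L) {
  structure(list(cell_types = cell_types, depth_mean = depth_mean,
                 conc = conc, base_distal = base_distal,
                 specific = specific, modality = modality,
                 bimodal_genes = bimodal_genes, subpop_frac = subpop_frac,
                 program = program, program_factor = program_factor,
                 seed = as.integer(seed)),
            class = "sim_cell_spec")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = length(alpha))
  sweep(x, 2L, colSums(x), "/")
}

.modality_draw <- function(label, n) {
  switch(label,
         distal = rbeta(n, 8, 1),
         proximal = rbeta(n, 1, 8),
         middle = (1 + rbeta(n, 8, 8)) / 3,
         bimodal = ifelse(rbinom(n, 1L, 0.5) == 1L,
                          rbeta(n, 8, 1), rbeta(n, 1, 8)),
         multimodal = runif(n),
         stop("unknown modality generator: ", label))
}

#' Simulate per-cell isoform counts with known truth
#'
#' Per cell and gene, a UMI total is drawn from the depth model and split
#' across the gene's poly(A) isoforms by a multinomial draw from the cell's
#' usage vector, itself drawn from the gene's programmed model (see
#' [sim_cell_spec()]). All random draws are recorded as truth.
#'
#' @param ref an `apa_sim_reference` (see [make_reference()]).
#' @param cspec a [sim_cell_spec()].
#' @return `SingleCellExperiment` with assay `counts`, `rowData` describing
#'   the isoforms, `colData` with `cell_type`, `barcode`, `subpop`, and
#'   metadata `truth` (list: `usage_drawn`, `usage_realized`, matrices
#'   isoforms x cells; `specific`, `modality`, `bimodal_genes`).
#' @export
simulate_counts <- function(ref, cspec) {
  set.seed(.derive_seed(cspec$seed, 202L))
  sites <- ref$sites
  genes <- unique(sites$gene_id)
  types <- rep(names(cspec$cell_types), cspec$cell_types)
  n_cells <- length(types)
  cell_id <- sprintf("%s_c%04d", types, unlist(lapply(cspec$cell_types,
                                                      seq_len)))
  barcode <- .random_barcodes(n_cells)
  subpop <- 1L + as.integer(runif(n_cells) >= cspec$subpop_frac)
  iso_meta <- sites[order(sites$gene_id, sites$rank), ]
  iso_meta$site_id <- sprintf("%s:%d:%s", iso_meta$chrom, iso_meta$pos,
                              iso_meta$strand)
  iso_meta$isoform_id <- paste0(iso_meta$gene_id, "|", iso_meta$site_id)
  n_iso <- nrow(iso_meta)
  counts <- matrix(0L, n_iso, n_cells,
                   dimnames = list(iso_meta$isoform_id, cell_id))
  usage_drawn <- matrix(NA_real_, n_iso, n_cells,
                        dimnames = dimnames(counts))
  prog_mult <- rep(1, n_cells)
  for (g in genes) {
    rows <- which(iso_meta$gene_id == g)
    k <- length(rows)
    # depth, with the expression program applied for program genes
    mult <- rep(1, n_cells)
    if (!is.null(cspec$program) && g %in% cspec$program$gene_id) {
      dir <- cspec$program$direction[match(g, cspec$program$gene_id)]
      f <- cspec$program_factor
      mult <- ifelse(subpop == 1L, f^dir, f^(-dir))
    }
    N <- rpois(n_cells, cspec$depth_mean * mult)
    # per-cell usage (transcription order: rank 1 .. rank k = distal)
    if (!is.null(cspec$modality) && g %in% names(cspec$modality)) {
      if (k != 2L) stop("modality generators assume 2 isoforms per gene")
      ud <- .modality_draw(cspec$modality[[g]], n_cells)
      u <- rbind(1 - ud, ud)
    } else if (g %in% cspec$bimodal_genes) {
      if (k != 2L) stop("bimodal genes assume 2 isoforms per gene")
      ud <- ifelse(subpop == 1L, rbeta(n_cells, 8, 1), rbeta(n_cells, 1, 8))
      u <- rbind(1 - ud, ud)
    } else {
      spec_row <- NULL
      if (!is.null(cspec$specific) && g %in% cspec$specific$gene_id)
        spec_row <- cspec$specific[match(g, cspec$specific$gene_id), ]
      hi <- if (is.null(spec_row)) cspec$base_distal[2L] else
        min(cspec$base_distal[2L], 1 - spec_row$delta - 0.05)
      lo <- min(cspec$base_distal[1L], hi)
      b <- runif(1L, lo, hi)
      m_distal <- rep(b, n_cells)
      if (!is.null(spec_row))
        m_distal[types == spec_row$cell_type] <- b + spec_row$delta
      if (is.infinite(cspec$conc)) {
        ud <- m_distal
        u <- .usage_from_distal(ud, k)
      } else {
        u <- vapply(seq_len(n_cells), function(ci) {
          m <- .mean_vector(m_distal[ci], k)
          .rdirichlet(1L, cspec$conc * m)[, 1L]
        }, numeric(k))
        if (k == 1L) u <- matrix(u, nrow = 1L)
      }
    }
    usage_drawn[rows, ] <- u
    if (k == 2L) {
      cd <- rbinom(n_cells, N, u[2L, ])
      counts[rows, ] <- rbind(N - cd, cd)
    } else {
      for (ci in which(N > 0L))
        counts[rows, ci] <- rmultinom(1L, N[ci], u[, ci])[, 1L]
    }
  }
  tot <- rowsum(counts, iso_meta$gene_id)
  denom <- tot[match(iso_meta$gene_id, rownames(tot)), , drop = FALSE]
  usage_realized <- counts / denom
  usage_realized[denom == 0] <- NA_real_
  rd <- S4Vectors::DataFrame(iso_meta[, c("isoform_id", "gene_id",
                                          "site_id", "rank", "is_distal",
                                          "chrom", "strand")],
                             site_pos = iso_meta$pos)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = rd,
    colData = S4Vectors::DataFrame(cell_id = cell_id, cell_type = types,
                                   barcode = barcode, subpop = subpop,
                                   row.names = cell_id))
  S4Vectors::metadata(sce)$truth <-
    list(usage_drawn = usage_drawn, usage_realized = usage_realized,
         specific = cspec$specific, modality = cspec$modality,
         bimodal_genes = cspec$bimodal_genes, subpop = setNames(subpop,
                                                                cell_id))
  sce
}

.mean_vector <- function(distal, k) {
  if (k == 1L) return(1)
  rest <- (1 - distal) / (k - 1L)
  c(rep(rest, k - 1L), distal)
}

.usage_from_distal <- function(ud, k) {
  vapply(ud, .mean_vector, numeric(k), k = k)
}

.random_barcodes <- function(n, len = 12L) {
  repeat {
    bc <- apply(matrix(sample(c("A", "C", "G", "T"), n * len,
                              replace = TRUE), n), 1L, paste,
                collapse = "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate raw paired reads with truth alignments
#'
#' Every UMI of the count matrix becomes one read pair: read1 is the cell
#' barcode followed by the UMI; read2 is the sense-strand transcript
#' sequence ending at the molecule's poly(A) site with a templated poly(A)
#' tail appended. A configurable fraction of molecules instead produce
#' tail-less reads ending 5-`body_span` nt upstream (the peak body), the
#' cleavage position jitters by up to 2 nt, a fraction of extra reads are
#' internal-priming artifacts ending at decoy A-runs, and a fraction of
#' reads is duplicated to emulate PCR. The truth alignment table describes
#' where each (trimmed) read maps, so tests can bypass an external
#' aligner via [write_sim_reads()].
#'
#' @param ref an `apa_sim_reference`.
#' @param sce counts from [simulate_counts()].
#' @param read_len read2 length before the tail (default 60).
#' @param tail_len poly(A) tail length, >= 8 (default 12).
#' @param frac_nonpolya fraction of molecules yielding tail-less upstream
#'   reads (default 0.25).
#' @param body_span maximum upstream shift of tail-less reads (default 35).
#' @param frac_internal internal-priming artifact reads as a fraction of
#'   the molecule count (default 0.2).
#' @param dup_rate fraction of reads duplicated once (default 0.1).
#' @param seed integer seed.
#' @return list with `r1`, `r2` (`DNAStringSet`s, qualities attached),
#'   `aln` (truth alignment data.frame), and `molecules` (per-read truth:
#'   origin isoform or decoy).
#' @export
simulate_reads <- function(ref, sce, read_len = 60L, tail_len = 12L,
                           frac_nonpolya = 0.25, body_span = 35L,
                           frac_internal = 0.2, dup_rate = 0.1,
                           seed = 1L) {
  stopifnot(tail_len >= 8L)
  set.seed(.derive_seed(seed, 303L))
  cnt <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  rd <- SummarizedExperiment::rowData(sce)
  cd <- SummarizedExperiment::colData(sce)
  nz <- which(cnt > 0L, arr.ind = TRUE)
  iso_i <- rep(nz[, 1L], cnt[nz])
  cell_i <- rep(nz[, 2L], cnt[nz])
  n_mol <- length(iso_i)
  origin <- rd$site_id[iso_i]
  site_pos <- rd$site_pos[iso_i]
  strand <- rd$strand[iso_i]
  chrom <- rd$chrom[iso_i]
  # internal-priming artifacts at decoys
  n_art <- if (!is.null(ref$decoys)) round(frac_internal * n_mol) else 0L
  if (n_art > 0L) {
    di <- sample(nrow(ref$decoys), n_art, replace = TRUE)
    iso_i <- c(iso_i, rep(NA_integer_, n_art))
    cell_i <- c(cell_i, sample(ncol(cnt), n_art, replace = TRUE))
    origin <- c(origin, paste0("decoy|", ref$decoys$gene_id[di]))
    site_pos <- c(site_pos, ref$decoys$pos[di])
    strand <- c(strand, ref$decoys$strand[di])
    chrom <- c(chrom, ref$decoys$chrom[di])
  }
  n <- length(site_pos)
  if (n == 0L) {
    empty <- Biostrings::DNAStringSet()
    S4Vectors::mcols(empty)$qualities <- Biostrings::BStringSet()
    return(list(r1 = empty, r2 = empty,
                aln = data.frame(qname = character(), chrom = character(),
                                 strand = character(), pos1 = integer(),
                                 seq = character(),
                                 cell_barcode = character(),
                                 umi = character(), polya_flag = logical()),
                molecules = data.frame()))
  }
  is_art <- seq_len(n) > n_mol
  polya <- is_art | (runif(n) >= frac_nonpolya)
  shift <- integer(n)
  jit <- sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
                prob = c(0.05, 0.15, 0.6, 0.15, 0.05))
  shift[polya & !is_art] <- jit[polya & !is_art]
  shift[!polya] <- -sample(seq.int(5L, body_span), sum(!polya),
                           replace = TRUE)
  dir <- ifelse(strand == "+", 1L, -1L)
  end3 <- site_pos + dir * shift
  # sense-strand sequence of read_len nt ending at end3
  chrstr <- as.character(ref$genome[[1L]])
  Lc <- nchar(chrstr)
  up <- pmin(read_len - 1L, ifelse(strand == "+", end3, Lc - 1L - end3))
  lo <- ifelse(strand == "+", end3 - up, end3)
  hi <- ifelse(strand == "+", end3, end3 + up)
  body <- substring(chrstr, lo + 1L, hi + 1L)
  minus <- strand == "-"
  if (any(minus))
    body[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(body[minus])))
  # templated adenines at the 3' end of a tailed molecule are
  # indistinguishable from the tail: fold them into it, so the truth
  # alignment matches what trimming observes
  strip <- ifelse(polya, nchar(body) - nchar(sub("A+$", "", body)), 0L)
  body <- substr(body, 1L, nchar(body) - strip)
  end3 <- end3 - dir * strip
  r2 <- ifelse(polya, paste0(body, strrep("A", tail_len + strip)), body)
  umi_idx <- stats::ave(seq_len(n), cell_i, FUN = seq_along)
  umi <- .encode_umi(umi_idx)
  bc <- cd$barcode[cell_i]
  qname <- sprintf("m%06d", seq_len(n))
  # PCR duplicates
  dup <- which(runif(n) < dup_rate)
  idx <- c(seq_len(n), dup)
  qn <- c(qname, if (length(dup) > 0L) paste0(qname[dup], "_dup"))
  mol <- data.frame(qname = qn, cell = colnames(cnt)[cell_i[idx]],
                    barcode = bc[idx], umi = umi[idx],
                    origin = origin[idx], chrom = chrom[idx],
                    strand = strand[idx], end3 = end3[idx],
                    polya = polya[idx], artifact = is_art[idx],
                    stringsAsFactors = FALSE)
  r1seq <- paste0(mol$barcode, mol$umi)
  r1 <- Biostrings::DNAStringSet(setNames(r1seq, mol$qname))
  S4Vectors::mcols(r1)$qualities <-
    Biostrings::BStringSet(strrep("I", nchar(r1seq)))
  r2seq <- r2[idx]
  r2out <- Biostrings::DNAStringSet(setNames(r2seq, mol$qname))
  S4Vectors::mcols(r2out)$qualities <-
    Biostrings::BStringSet(strrep("I", nchar(r2seq)))
  # truth alignments describe the trimmed read (tail removed)
  tlen <- nchar(body)[idx]
  pos1 <- ifelse(mol$strand == "+", mol$end3 - tlen + 2L, mol$end3 + 1L)
  aln <- data.frame(qname = mol$qname, chrom = mol$chrom,
                    strand = mol$strand, pos1 = pos1, seq = body[idx],
                    cell_barcode = mol$barcode, umi = mol$umi,
                    polya_flag = mol$polya, stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2out, aln = aln, molecules = mol)
}

.encode_umi <- function(idx, len = 8L) {
  letters_ <- c("A", "C", "G", "T")
  out <- character(length(idx))
  x <- idx
  m <- matrix("A", nrow = length(idx), ncol = len)
  for (p in seq_len(len)) {
    m[, p] <- letters_[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(m, 1L, paste, collapse = "")
}

#' Write simulated reads and reference to disk
#'
#' Emits the paired FASTQ, the truth SAM (convertible with
#' [sam_to_bam()]), the genome FASTA, the annotation GTF and the truth
#' sites/decoys BED files.
#'
#' @param ref an `apa_sim_reference`.
#' @param reads output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return named list of paths.
#' @export
write_sim_reads <- function(ref, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(r1 = file.path(dir, "reads_R1.fastq"),
            r2 = file.path(dir, "reads_R2.fastq"),
            sam = file.path(dir, "truth.sam"),
            fasta = file.path(dir, "genome.fa"),
            gtf = file.path(dir, "annotation.gtf"),
            sites = file.path(dir, "truth_sites.bed"),
            decoys = file.path(dir, "truth_decoys.bed"))
  Biostrings::writeXStringSet(reads$r1, p$r1, format = "fastq",
                              qualities = S4Vectors::mcols(reads$r1)$qualities)
  Biostrings::writeXStringSet(reads$r2, p$r2, format = "fastq",
                              qualities = S4Vectors::mcols(reads$r2)$qualities)
  .write_sam(reads$aln, as.list(ref$seqlengths), p$sam)
  Biostrings::writeXStringSet(ref$genome, p$fasta)
  Rsamtools::indexFa(p$fasta)
  rtracklayer::export(ref$gtf, p$gtf, format = "gtf")
  write_sites_bed(data.frame(chrom = ref$sites$chrom,
                             strand = ref$sites$strand,
                             pos = ref$sites$pos,
                             tag_count = 0L), p$sites)
  if (!is.null(ref$decoys))
    write_sites_bed(data.frame(chrom = ref$decoys$chrom,
                               strand = ref$decoys$strand,
                               pos = ref$decoys$pos,
                               tag_count = 0L), p$decoys)
  p
}

#' Ready-made simulation scenarios
#'
#' `"basic"`: 10 two-site genes, 200 cells of one type, reads included —
#' exercises the full read-to-usage pipeline.
#' `"specificity"`: 200 two-site genes (20 with a usage shift of 0.4 in
#' one of 4 cell types, 50 cells each), counts only.
#' `"modality"`: 200 genes, 40 per modality generator, 100 cells.
#' `"bimodal-subpop"`: one subpopulation-linked bimodal gene plus a
#' 20-gene coupled expression program among 201 genes, 100 cells.
#' `"null-homogeneous"`: 100 genes, 100 cells, no between-cell usage
#' variability (every cell draws counts from its gene's shared usage
#' vector) — the calibration null for differential-usage testing.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return list with `ref`, `cspec`, `sce` (counts + usage assays), and
#'   for `"basic"` also `reads`.
#' @export
sim_preset <- function(name = c("basic", "specificity", "modality",
                                "bimodal-subpop", "null-homogeneous"),
                       seed = 1L) {
  name <- match.arg(name)
  s <- as.integer(seed)
  if (name == "basic") {
    ref <- make_reference(sim_genome_spec(n_genes = 10L, seed = s))
    cspec <- sim_cell_spec(cell_types = c(all = 200L), depth_mean = 30,
                           conc = 10, seed = s)
    sce <- simulate_counts(ref, cspec)
    reads <- simulate_reads(ref, sce, seed = s)
    out <- list(ref = ref, cspec = cspec, sce = add_usage(sce),
                reads = reads)
  } else if (name == "specificity") {
    ref <- make_reference(sim_genome_spec(n_genes = 200L, seed = s))
    types <- paste0("type", 1:4)
    specific <- data.frame(gene_id = sprintf("gene_%03d", 1:20),
                           cell_type = rep(types, 5L), delta = 0.4)
    cspec <- sim_cell_spec(cell_types = setNames(rep(50L, 4L), types),
                           depth_mean = 20, conc = 10,
                           base_distal = c(0.25, 0.75),
                           specific = specific, seed = s)
    out <- list(ref = ref, cspec = cspec,
                sce = add_usage(simulate_counts(ref, cspec)))
  } else if (name == "modality") {
    ref <- make_reference(sim_genome_spec(n_genes = 200L, seed = s))
    lab <- rep(c("distal", "proximal", "middle", "bimodal", "multimodal"),
               each = 40L)
    modality <- setNames(lab, sprintf("gene_%03d", 1:200))
    cspec <- sim_cell_spec(cell_types = c(all = 100L), depth_mean = 30,
                           modality = modality, seed = s)
    out <- list(ref = ref, cspec = cspec,
                sce = add_usage(simulate_counts(ref, cspec)))
  } else if (name == "bimodal-subpop") {
    ref <- make_reference(sim_genome_spec(n_genes = 201L, seed = s))
    program <- data.frame(gene_id = sprintf("gene_%03d", 2:21),
                          direction = rep(c(1, -1), each = 10L))
    cspec <- sim_cell_spec(cell_types = c(CHC = 100L), depth_mean = 30,
                           conc = 10, base_distal = c(0.25, 0.75),
                           bimodal_genes = "gene_001", subpop_frac = 0.5,
                           program = program, seed = s)
    out <- list(ref = ref, cspec = cspec,
                sce = add_usage(simulate_counts(ref, cspec)))
  } else {
    ref <- make_reference(sim_genome_spec(n_genes = 100L, seed = s))
    cspec <- sim_cell_spec(cell_types = c(all = 100L), depth_mean = 30,
                           conc = Inf, base_distal = c(0.25, 0.75),
                           seed = s)
    out <- list(ref = ref, cspec = cspec,
                sce = add_usage(simulate_counts(ref, cspec)))
  }
  out
}
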