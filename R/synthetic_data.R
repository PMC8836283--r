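# Synthetic genome + annotation + candidate-TSS generator with planted
# ground truth.  The generator emulates the statistical structure the
# downstream analysis assumes: genes on both strands, gamma-distributed
# 5'UTR lengths, a TATA-box planted upstream of the TSS in a configured
# fraction of promoters, an initiator CA at the TSS, a CG-skew bump around
# the TSS, and codon-wise CDS synthesis with class- and
# position-dependent GC3 realizing a 5'->3' gradient.
#
# Within the scored core-promoter regions ([-40, -20] for TATA starts,
# A at [-2, +2] for CA) the generator *enforces* the drawn motif flags:
# planted motifs are written verbatim and chance background occurrences in
# genes drawn motif-free are disrupted, so observed motif fractions are
# exactly binomial in the configured rates.

#' Synthetic-genome configuration
#'
#' Defaults encode the study conditions the analysis assumes: the default
#' gamma 5'UTR prior (shape 0.62, scale 238.99 bp), a TATA-box plant rate
#' of 0.07 at 30 bp upstream of the TSS (the canonical 20-40 bp band), an
#' initiator CA rate of 0.5, conifer-like background GC of 0.38, and a
#' GC3 gradient of -2e-4 per nt on top of class levels (poor 0.25 / mid
#' 0.45 / rich 0.70) with 10% of genes in each extreme class.  GC3-rich
#' genes are drawn short with few exons and GC3-poor genes long with many
#' exons, mirroring the association the class comparison is meant to
#' detect.
#'
#' @param n_genes Number of gene models.
#' @param genes_per_contig Genes per contig.
#' @param seed Mandatory RNG seed.
#' @param background_gc Background GC fraction for intergenic/UTR/intron
#'   sequence.
#' @param strand_fraction Fraction of genes on the plus strand.
#' @param gamma_k,gamma_theta Gamma prior (shape, scale in bp) for 5'UTR
#'   lengths.
#' @param utr_min,utr_max Rounded gamma draws are clamped to this range.
#' @param tata_rate,tata_offset TATA-box plant rate and offset of the
#'   motif start upstream of the TSS (bp).
#' @param ca_rate Initiator CA plant rate (C at the TSS, A at +1).
#' @param skew_halfwidth,skew_c_bias CG-skew bump around the TSS: within
#'   +/- `skew_halfwidth` bp, a G/C draw becomes C with probability
#'   `skew_c_bias`.
#' @param gc3_poor_frac,gc3_rich_frac Fractions of genes in the extreme
#'   GC3 classes.
#' @param gc3_levels Named vector of base GC3 levels per class.
#' @param gc3_slope GC3 change per nucleotide of CDS position (negative =
#'   5'->3' decline).
#' @param codon_ranges,exon_ranges Per-class ranges (named lists of
#'   length-2 vectors) for codon and exon counts.
#' @param intron_range Intron length range in bp.
#' @param upstream_flank,downstream_flank Flanking sequence per gene (bp);
#'   the upstream flank must accommodate the promoter windows.
#' @param intergenic_gap Gap between gene loci (bp).
#' @param contig_length Optional hard contig length; genes that do not fit
#'   raise an error naming the first offender.
#' @param evidence_fraction Fraction of genes covered by emitted evidence
#'   intervals.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, genes_per_contig = 100, seed = 1,
                       background_gc = 0.38, strand_fraction = 0.5,
                       gamma_k = 0.62, gamma_theta = 238.99,
                       utr_min = 1, utr_max = 5000,
                       tata_rate = 0.07, tata_offset = 30, ca_rate = 0.5,
                       skew_halfwidth = 50, skew_c_bias = 0.65,
                       gc3_poor_frac = 0.10, gc3_rich_frac = 0.10,
                       gc3_levels = c(poor = 0.25, mid = 0.45, rich = 0.70),
                       gc3_slope = -2e-4,
                       codon_ranges = list(poor = c(250, 400),
                                           mid = c(120, 350),
                                           rich = c(80, 180)),
                       exon_ranges = list(poor = c(4, 8), mid = c(1, 6),
                                          rich = c(1, 2)),
                       intron_range = c(60, 200),
                       upstream_flank = 1100, downstream_flank = 300,
                       intergenic_gap = 200, contig_length = NULL,
                       evidence_fraction = 1.0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 0, cfg$gamma_k > 0, cfg$gamma_theta > 0,
            cfg$tata_offset >= 20, cfg$tata_offset <= 40,
            cfg$upstream_flank >= 1000 + cfg$skew_halfwidth,
            cfg$utr_min >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw synthetic 5'UTR lengths
#'
#' Gamma draws rounded to the nearest integer and clamped to
#' `[utr_min, utr_max]` so genes fit on contigs; the clamping distorts
#' the first two moments only negligibly at the default parameters.
#'
#' @param n Number of draws.
#' @param k,theta Gamma shape and scale.
#' @param utr_min,utr_max Clamp range in bp.
#' @return Integer vector of lengths.
#' @export
draw_utr_lengths <- function(n, k = 0.62, theta = 238.99, utr_min = 1,
                             utr_max = 5000) {
  as.integer(clamp(round(stats::rgamma(n, shape = k, scale = theta)),
                   utr_min, utr_max))
}

#' Synthesize a coding sequence codon-wise
#'
#' ATG start, TAA stop, interior codons with first two bases drawn from
#' the background composition and the third base G/C with a
#' position-dependent probability `level + slope * position` (clamped to
#' `[0.02, 0.98]`).  In-frame stop codons are avoided by resampling the
#' first base.
#'
#' @param n_codons Total codon count (>= 3), including start and stop.
#' @param level Baseline third-position GC probability.
#' @param slope GC3 change per nucleotide of position.
#' @param gc Background GC for first/second codon positions.
#' @return Character vector of `3 * n_codons` bases.
#' @export
sim_cds <- function(n_codons, level = 0.45, slope = 0, gc = 0.38) {
  stopifnot(n_codons >= 3)
  ni <- n_codons - 2L
  b1 <- random_dna(ni, gc)
  b2 <- random_dna(ni, gc)
  pos3 <- 3 * (1L + seq_len(ni))            # nt position of each third base
  p <- clamp(level + slope * pos3, 0.02, 0.98)
  is_gc <- stats::runif(ni) < p
  b3 <- ifelse(is_gc, sample(c("C", "G"), ni, replace = TRUE),
               sample(c("A", "T"), ni, replace = TRUE))
  # disrupt in-frame stops (TAA/TAG/TGA) by moving the first base off T
  stop_hit <- b1 == "T" &
    ((b2 == "A" & b3 %in% c("A", "G")) | (b2 == "G" & b3 == "A"))
  if (any(stop_hit)) {
    b1[stop_hit] <- sample(c("A", "C", "G"), sum(stop_hit), replace = TRUE)
  }
  interior <- as.vector(rbind(b1, b2, b3))
  c("A", "T", "G", interior, "T", "A", "A")
}

# base generators: background vs CG-skew bump
.bg_base <- function(n, gc) random_dna(n, gc)
.bump_base <- function(n, gc, c_bias) {
  gc_hit <- stats::runif(n) < gc
  ifelse(gc_hit,
         ifelse(stats::runif(n) < c_bias, "C", "G"),
         sample(c("A", "T"), n, replace = TRUE))
}

# Build the promoter-proximal region of one gene in transcription
# orientation: U bases upstream of the TSS plus D bases at/after it
# (the 5'UTR for the genome generator).  next1/next2 are the two bases
# that immediately follow the returned region (the start of the CDS).
# Returns the characters plus the drawn motif flags.
.build_promoter <- function(U, D, cfg, next1 = "A", next2 = "T") {
  gc <- cfg$background_gc
  chars <- c(.bg_base(U, gc), .bg_base(D, gc))
  Lp <- U + D
  tss <- U + 1L
  bump_lo <- max(1L, tss - cfg$skew_halfwidth)
  bump_hi <- min(Lp, tss + cfg$skew_halfwidth - 1L)
  if (bump_hi >= bump_lo) {
    idx <- bump_lo:bump_hi
    chars[idx] <- .bump_base(length(idx), gc, cfg$skew_c_bias)
  }
  resample_at <- function(p) {
    if (p >= bump_lo && p <= bump_hi) .bump_base(1L, gc, cfg$skew_c_bias)
    else .bg_base(1L, gc)
  }
  char_at <- function(p) {
    if (p <= Lp) chars[p] else c(next1, next2)[p - Lp]
  }

  # --- TATA-box: plant verbatim or scrub the scored region -------------
  tata <- stats::runif(1) < cfg$tata_rate
  tata_rx <- iupac_to_regex("TATAWAW")
  reg_from <- tss - 40L
  reg_to <- tss - 20L                       # allowed match starts (closed)
  if (tata) {
    motif <- c("T", "A", "T", "A", sample(c("A", "T"), 1), "A",
               sample(c("A", "T"), 1))
    s0 <- tss - cfg$tata_offset
    chars[s0:(s0 + 6L)] <- motif
  } else {
    repeat {
      window <- paste0(chars[reg_from:(reg_to + 6L)], collapse = "")
      m <- regexpr(tata_rx, window)
      if (m < 1 || m > (reg_to - reg_from + 1L)) break
      hit <- reg_from + m - 1L
      for (p in hit:(hit + 6L)) chars[p] <- resample_at(p)
    }
  }

  # --- initiator CA: plant at [0, +1] or scrub A positions [-2, +2] ----
  inr <- stats::runif(1) < cfg$ca_rate
  if (inr) {
    chars[tss] <- "C"
    if (D >= 2L) chars[tss + 1L] <- "A"     # if D == 1 the next base is
  } else {                                  # the A of ATG already
    repeat {
      viol <- NULL
      for (s in (tss - 3L):(tss + 1L)) {
        if (char_at(s) == "C" && char_at(s + 1L) == "A") { viol <- s; break }
      }
      if (is.null(viol)) break
      p <- if (viol <= Lp) viol else viol + 1L   # resample an in-region base
      repeat {
        chars[p] <- resample_at(p)
        if (!(char_at(viol) == "C" && char_at(viol + 1L) == "A")) break
      }
    }
  }
  list(chars = chars, tata = tata,
       tata_offset = if (tata) cfg$tata_offset else NA_integer_,
       inr = inr)
}

# map a local 1-based closed segment [s, e] of a locus of length L at
# contig offset `off` to genomic 0-based half-open coordinates
.map_segment <- function(s, e, off, L, strand) {
  if (strand == "+") c(off + s - 1L, off + e) else c(off + L - e, off + L - s + 1L)
}

#' Generate a synthetic genome with planted ground truth
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_genome`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (named list of
#'   [gene_model()]s), `annotation` (GFF3 field data frame), `truth`
#'   (per-gene truth table incl. `true_tss`, `utr_length`,
#'   `tata_offset`, `inr_present`, `gc3_class`, CDS segments),
#'   `evidence` (BED-style intervals) and `config`.  Deterministic for a
#'   fixed seed.
#' @export
generate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  contig_of <- if (n > 0) ((seq_len(n) - 1L) %/% cfg$genes_per_contig) + 1L
               else integer(0)
  n_contigs <- if (n > 0) max(contig_of) else 1L
  contig_names <- sprintf("ctg%03d", seq_len(n_contigs))
  contig_parts <- rep(list(list()), n_contigs)
  offsets <- rep(cfg$intergenic_gap, n_contigs)
  for (ci in seq_len(n_contigs)) {
    contig_parts[[ci]][[1L]] <- .bg_base(cfg$intergenic_gap, cfg$background_gc)
  }

  genes <- list(); truth <- list(); gff <- list(); evid <- list()
  classes <- c("poor", "mid", "rich")
  class_prob <- c(cfg$gc3_poor_frac,
                  1 - cfg$gc3_poor_frac - cfg$gc3_rich_frac,
                  cfg$gc3_rich_frac)

  for (i in seq_len(n)) {
    ci <- contig_of[i]
    seq_id <- contig_names[ci]
    gid <- sprintf("g%05d", i)
    mid <- paste0(gid, ".t1")
    strand <- if (stats::runif(1) < cfg$strand_fraction) "+" else "-"
    cls <- sample(classes, 1, prob = class_prob)
    utr <- draw_utr_lengths(1, cfg$gamma_k, cfg$gamma_theta, cfg$utr_min,
                            cfg$utr_max)
    ncod <- sample(cfg$codon_ranges[[cls]][1]:cfg$codon_ranges[[cls]][2], 1)
    nex <- sample(cfg$exon_ranges[[cls]][1]:cfg$exon_ranges[[cls]][2], 1)
    cds_nt <- 3L * ncod
    nex <- min(nex, cds_nt - 1L)

    prom <- .build_promoter(cfg$upstream_flank, utr, cfg)
    cds_chars <- sim_cds(ncod, level = cfg$gc3_levels[[cls]],
                         slope = cfg$gc3_slope, gc = cfg$background_gc)
    piece_len <- if (nex > 1L) {
      diff(c(0L, sort(sample.int(cds_nt - 1L, nex - 1L)), cds_nt))
    } else cds_nt
    introns <- if (nex > 1L) {
      sample(cfg$intron_range[1]:cfg$intron_range[2], nex - 1L,
             replace = TRUE)
    } else integer(0)

    # assemble the locus in transcription orientation and record local
    # (1-based closed) feature coordinates
    tss_t <- cfg$upstream_flank + 1L
    cstart_t <- tss_t + utr
    body <- list(); cds_segs <- matrix(0L, nex, 2L); p <- cstart_t
    cpos <- 1L
    for (e in seq_len(nex)) {
      body[[length(body) + 1L]] <- cds_chars[cpos:(cpos + piece_len[e] - 1L)]
      cds_segs[e, ] <- c(p, p + piece_len[e] - 1L)
      cpos <- cpos + piece_len[e]
      p <- p + piece_len[e]
      if (e < nex) {
        body[[length(body) + 1L]] <- .bg_base(introns[e], cfg$background_gc)
        p <- p + introns[e]
      }
    }
    locus_t <- c(prom$chars, unlist(body),
                 .bg_base(cfg$downstream_flank, cfg$background_gc))
    L <- length(locus_t)
    exon_segs <- cds_segs
    exon_segs[1L, 1L] <- tss_t             # first exon carries the 5'UTR

    off <- offsets[ci]
    if (!is.null(cfg$contig_length) &&
        off + L + cfg$intergenic_gap > cfg$contig_length) {
      stop("gene ", gid, " does not fit on ", seq_id,
           " at the requested spacing (contig_length = ",
           cfg$contig_length, ")")
    }
    locus_g <- if (strand == "+") locus_t else revcomp_chars(locus_t)
    contig_parts[[ci]][[length(contig_parts[[ci]]) + 1L]] <- locus_g
    contig_parts[[ci]][[length(contig_parts[[ci]]) + 1L]] <-
      .bg_base(cfg$intergenic_gap, cfg$background_gc)
    offsets[ci] <- off + L + cfg$intergenic_gap

    loc2gen <- function(t) if (strand == "+") off + t - 1L else off + L - t
    cds_gen <- t(apply(cds_segs, 1L, function(se) {
      .map_segment(se[1L], se[2L], off, L, strand)
    }))
    exon_gen <- t(apply(exon_segs, 1L, function(se) {
      .map_segment(se[1L], se[2L], off, L, strand)
    }))
    cds_gen <- cds_gen[order(cds_gen[, 1L]), , drop = FALSE]
    exon_gen <- exon_gen[order(exon_gen[, 1L]), , drop = FALSE]

    genes[[mid]] <- gene_model(mid, seq_id, strand, cds_gen,
                               exons = exon_gen, source_line = gid)
    truth[[i]] <- data.frame(
      gene_id = mid, seq_id = seq_id, strand = strand,
      true_tss = loc2gen(tss_t), start_codon = loc2gen(cstart_t),
      utr_length = utr, tata_offset = prom$tata_offset,
      inr_present = prom$inr, gc3_class = cls, n_exons = nex,
      cds_length = cds_nt,
      cds_segments = paste(sprintf("%d-%d", cds_gen[, 1L], cds_gen[, 2L]),
                           collapse = ";"),
      stringsAsFactors = FALSE)

    # GFF3 rows (1-based closed)
    span <- c(min(exon_gen[, 1L]) + 1L, max(exon_gen[, 2L]))
    rows <- list(
      data.frame(seqid = seq_id, source = "promtss_sim", type = "gene",
                 start = span[1L], end = span[2L], score = ".",
                 strand = strand, phase = ".",
                 attributes = sprintf("ID=%s", gid)),
      data.frame(seqid = seq_id, source = "promtss_sim", type = "mRNA",
                 start = span[1L], end = span[2L], score = ".",
                 strand = strand, phase = ".",
                 attributes = sprintf("ID=%s;Parent=%s", mid, gid)))
    for (e in seq_len(nrow(exon_gen))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = seq_id, source = "promtss_sim", type = "exon",
        start = exon_gen[e, 1L] + 1L, end = exon_gen[e, 2L], score = ".",
        strand = strand, phase = ".",
        attributes = sprintf("ID=%s.exon%d;Parent=%s", mid, e, mid))
    }
    # CDS phases accumulate in transcription order
    tx_order <- if (strand == "+") seq_len(nrow(cds_gen)) else
      rev(seq_len(nrow(cds_gen)))
    cum <- 0L
    phase <- integer(nrow(cds_gen))
    for (e in tx_order) {
      phase[e] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (cds_gen[e, 2L] - cds_gen[e, 1L])
    }
    for (e in seq_len(nrow(cds_gen))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = seq_id, source = "promtss_sim", type = "CDS",
        start = cds_gen[e, 1L] + 1L, end = cds_gen[e, 2L], score = ".",
        strand = strand, phase = as.character(phase[e]),
        attributes = sprintf("ID=%s.cds;Parent=%s", mid, mid))
    }
    gff[[i]] <- do.call(rbind, rows)

    if (stats::runif(1) < cfg$evidence_fraction) {
      evid[[length(evid) + 1L]] <- data.frame(
        seq_id = seq_id, start = cds_gen[, 1L], end = cds_gen[, 2L],
        name = mid, stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(contig_parts, function(p) {
    paste0(unlist(p), collapse = "")
  }, character(1)))
  names(genome) <- contig_names

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0))
  evid_df <- if (length(evid)) do.call(rbind, evid) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               name = character(0))
  structure(list(genome = genome, genes = genes,
                 annotation = if (length(gff)) do.call(rbind, gff) else
                   data.frame(seqid = character(0), source = character(0),
                              type = character(0), start = integer(0),
                              end = integer(0), score = character(0),
                              strand = character(0), phase = character(0),
                              attributes = character(0)),
                 truth = truth_df, evidence = evid_df, config = cfg),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome: %d gene(s) on %d contig(s), %d bp total, seed %d>\n",
              length(x$genes), length(x$genome),
              sum(Biostrings::width(x$genome)), x$config$seed))
  invisible(x)
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `truth.tsv` and `evidence.bed`
#' into a directory; byte-identical across reruns with the same config.
#'
#' @param sim A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             truth = file.path(dir, "truth.tsv"),
             evidence = file.path(dir, "evidence.bed"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]], width = 80L)
  write_gff3_table(sim$annotation, paths[["annotation"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(sim$evidence, paths[["evidence"]])
  paths
}

#' Candidate-noise configuration
#'
#' Controls [generate_candidates()]: each gene emits `n_per_gene`
#' candidates; each is independently an in-CDS decoy with probability
#' `decoy_cds_rate` (default 0.14, matching the 13-14% in-CDS fraction
#' the exclusion stage is meant to absorb), a far-upstream decoy beyond
#' the 99.9th prior percentile with probability `extreme_rate`, and
#' otherwise the true TSS with rounded Gaussian positional jitter.  True
#' candidates score higher in expectation than decoys.
#'
#' @param n_per_gene Candidates per gene.
#' @param jitter_sd Positional jitter SD (bp) of true candidates.
#' @param decoy_cds_rate Probability a candidate is an in-CDS decoy.
#' @param extreme_rate Probability a candidate is a far-upstream decoy.
#' @param score_true,score_decoy Mean/sd pairs of the (clamped to
#'   `[0, 1]`) Gaussian score model.
#' @return List of class `candidate_noise`.
#' @export
candidate_noise <- function(n_per_gene = 3, jitter_sd = 2,
                            decoy_cds_rate = 0.14, extreme_rate = 0,
                            score_true = c(0.8, 0.1),
                            score_decoy = c(0.6, 0.15)) {
  structure(as.list(environment()), class = "candidate_noise")
}

#' Generate candidate TSS predictions with configurable noise
#'
#' @param sim A [generate_genome()] result.
#' @param noise A [candidate_noise()].
#' @param seed RNG seed (independent of the genome seed).
#' @return Data frame with `gene_id`, `genomic_pos` (0-based), `strand`,
#'   `score`, plus an `origin` column (`true`, `decoy_cds`,
#'   `decoy_extreme`) retained for validation and dropped by
#'   [write_candidates()].
#' @export
generate_candidates <- function(sim, noise = candidate_noise(), seed = 1) {
  set.seed(seed)
  cfg <- sim$config
  contig_len <- stats::setNames(Biostrings::width(sim$genome),
                                names(sim$genome))
  q_extreme <- stats::qgamma(0.999, shape = cfg$gamma_k,
                             scale = cfg$gamma_theta)
  rows <- vector("list", nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    segs <- do.call(rbind, lapply(strsplit(tr$cds_segments, ";")[[1]],
                                  function(s) as.integer(strsplit(s, "-")[[1]])))
    seg_len <- segs[, 2L] - segs[, 1L]
    cum <- cumsum(seg_len)
    maxpos <- contig_len[[tr$seq_id]] - 1L
    sgn <- if (tr$strand == "+") 1L else -1L
    u <- stats::runif(noise$n_per_gene)
    origin <- ifelse(u < noise$decoy_cds_rate, "decoy_cds",
              ifelse(u < noise$decoy_cds_rate + noise$extreme_rate,
                     "decoy_extreme", "true"))
    pos <- integer(noise$n_per_gene)
    for (j in seq_len(noise$n_per_gene)) {
      pos[j] <- switch(origin[j],
        true = {
          # jitter in transcription orientation, clamped so the candidate
          # stays strictly upstream of the start codon (the predictor's
          # search window)
          j0 <- as.integer(round(stats::rnorm(1, 0, noise$jitter_sd)))
          rel <- min(-tr$utr_length + j0, -1L)
          tr$start_codon + sgn * rel
        },
        decoy_cds = {
          r <- sample.int(sum(seg_len), 1L)
          s <- which(cum >= r)[1L]
          segs[s, 1L] + (r - 1L) - (if (s > 1L) cum[s - 1L] else 0L)
        },
        decoy_extreme = tr$start_codon -
          sgn * as.integer(round(q_extreme + stats::runif(1, 0, 1000))))
      pos[j] <- clamp(pos[j], 0L, maxpos)
    }
    sc <- ifelse(origin == "true",
                 stats::rnorm(noise$n_per_gene, noise$score_true[1],
                              noise$score_true[2]),
                 stats::rnorm(noise$n_per_gene, noise$score_decoy[1],
                              noise$score_decoy[2]))
    rows[[i]] <- data.frame(gene_id = tr$gene_id, genomic_pos = pos,
                            strand = tr$strand,
                            score = clamp(sc, 0, 1), origin = origin,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate standalone synthetic promoter windows
#'
#' Builds TSS-anchored windows with the same promoter architecture as
#' [generate_genome()] (CG-skew bump, enforced TATA/CA plant rates)
#' without the surrounding genome — a light fixture for profiling and
#' classification.
#'
#' @param n Number of promoters.
#' @param config A [sim_config()] (only the promoter-architecture fields
#'   are used).
#' @param rel_start,rel_end Window extent (defaults `[-1000, +200)`).
#' @return A [window_set()] with a `truth` attribute (data frame of
#'   planted `tata`, `tata_offset`, `inr` per promoter).
#' @export
sim_promoters <- function(n, config = sim_config(), rel_start = -1000,
                          rel_end = 200) {
  set.seed(config$seed)
  U <- -rel_start
  D <- rel_end
  stopifnot(U >= 50, D >= 5)
  seqs <- character(n); tata <- logical(n); offs <- integer(n)
  inr <- logical(n)
  for (i in seq_len(n)) {
    p <- .build_promoter(U, D, config)
    seqs[i] <- paste0(p$chars, collapse = "")
    tata[i] <- p$tata; offs[i] <- p$tata_offset; inr[i] <- p$inr
  }
  names(seqs) <- sprintf("p%05d", seq_len(n))
  ws <- window_set(seqs, rel_start, rel_end, anchor = "tss")
  attr(ws, "truth") <- data.frame(gene_id = names(seqs), tata = tata,
                                  tata_offset = offs, inr_present = inr,
                                  stringsAsFactors = FALSE)
  ws
}
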