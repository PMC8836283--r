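# Genome, annotation, and track input/output plus the coordinate and strand
# conventions shared by all stages.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based
# closed) and BED (0-based half-open) are converted at the boundary.

#' Read a genome FASTA into a DNAStringSet
#'
#' Whole contigs are loaded into memory; the package targets desk-scale
#' (megabase) inputs, not multi-gigabase assemblies.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id (first word of
#'   each FASTA header).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Construct a gene model
#'
#' A gene model is one mRNA with its strand, CDS segments and exon
#' structure.  Coordinates are genomic, 0-based half-open, always stored in
#' ascending genomic order regardless of strand.
#'
#' @param gene_id Identifier of the mRNA (one gene model per mRNA).
#' @param seq_id Contig/scaffold identifier.
#' @param strand `"+"` or `"-"`.
#' @param cds Two-column matrix (start, end) of CDS segments, 0-based
#'   half-open, sorted, non-overlapping.
#' @param exons Optional two-column matrix of exon segments on the same
#'   convention; defaults to the CDS segments.
#' @param source_line Optional provenance string.
#' @param coding_complete Whether the spliced CDS is expected to be a
#'   complete open reading frame (length a positive multiple of 3).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, cds, exons = NULL,
                       source_line = NA_character_, coding_complete = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  cds <- matrix(as.numeric(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  if (any(cds[, 1L] >= cds[, 2L])) {
    stop("gene ", gene_id, ": CDS segment with start >= end")
  }
  if (nrow(cds) > 1L && any(cds[-1L, 1L] < cds[-nrow(cds), 2L])) {
    stop("gene ", gene_id, ": overlapping CDS segments")
  }
  if (is.null(exons)) {
    exons <- cds
  } else {
    exons <- matrix(as.numeric(exons), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop("gene ", gene_id, ": overlapping exons")
    }
  }
  # every CDS segment must lie inside some exon
  covered <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons[, 1L] <= cds[i, 1L] & exons[, 2L] >= cds[i, 2L])
  }, logical(1))
  if (!all(covered)) {
    stop("gene ", gene_id, ": CDS not contained in the union of exons")
  }
  len <- sum(cds[, 2L] - cds[, 1L])
  if (coding_complete && len %% 3 != 0) {
    stop("gene ", gene_id, ": spliced CDS length ", len,
         " is not a multiple of 3 but the gene is flagged coding-complete")
  }
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 cds = cds, exons = exons, source_line = source_line,
                 coding_complete = coding_complete),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s  %s:%d-%d (%s)  %d CDS segment(s), %d bp spliced>\n",
              x$gene_id, x$seq_id, min(x$cds[, 1L]), max(x$cds[, 2L]),
              x$strand, nrow(x$cds), spliced_cds_length(x)))
  invisible(x)
}

#' Genomic position of the first base of the start codon
#'
#' The start codon is taken as the first CDS base in transcription
#' orientation: the leftmost CDS base on the plus strand, the rightmost on
#' the minus strand.  Returned 0-based.
#'
#' @param gene A [gene_model()].
#' @return Integer genomic position (0-based).
#' @export
start_codon_pos <- function(gene) {
  unname(if (gene$strand == "+") gene$cds[1L, 1L]
         else gene$cds[nrow(gene$cds), 2L] - 1)
}

#' Spliced CDS length in bp
#' @param gene A [gene_model()].
#' @export
spliced_cds_length <- function(gene) {
  sum(gene$cds[, 2L] - gene$cds[, 1L])
}

#' Spliced CDS sequence in transcription orientation
#'
#' @param gene A [gene_model()].
#' @param genome A [Biostrings::DNAStringSet] containing `gene$seq_id`.
#' @return Character scalar; reverse-complemented for minus-strand genes so
#'   that it starts with the start codon.
#' @export
spliced_cds <- function(gene, genome) {
  if (!gene$seq_id %in% names(genome)) {
    stop("gene ", gene$gene_id, ": unknown seq_id ", gene$seq_id)
  }
  contig <- genome[[gene$seq_id]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    as.character(Biostrings::subseq(contig, gene$cds[i, 1L] + 1L, gene$cds[i, 2L]))
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Read gene models from a GFF3 annotation
#'
#' One `gene_model` is produced per mRNA (or transcript) feature; CDS and
#' exon features are attached through their `Parent` attribute.  Exons are
#' synthesized from the CDS when absent.  GFF3 1-based closed coordinates
#' are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @return Named list of [gene_model()] objects in deterministic
#'   (seq_id, start, gene_id) order.  The number of skipped CDS features
#'   (those whose parent is not an mRNA in the file) is attached as
#'   attribute `n_skipped`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0L) {
    out <- list()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    stop("malformed GFF3 line ", body[which(nf != 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x)[1L] else NA_character_,
           character(1))
  }
  g$parent1 <- if ("Parent" %in% names(g)) first_parent(g$Parent) else NA_character_
  if (!"ID" %in% names(g)) g$ID <- NA_character_

  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds  <- g[g$type == "CDS", , drop = FALSE]
  ex   <- g[g$type == "exon", , drop = FALSE]

  known <- mrna$ID
  skipped <- sum(!cds$parent1 %in% known)
  if (skipped > 0L) {
    warning(skipped, " CDS feature(s) without an mRNA parent were skipped")
  }
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    id <- mrna$ID[i]
    ci <- cds[!is.na(cds$parent1) & cds$parent1 == id, , drop = FALSE]
    if (nrow(ci) == 0L) next
    cds_mat <- cbind(ci$start - 1L, ci$end)
    ei <- ex[!is.na(ex$parent1) & ex$parent1 == id, , drop = FALSE]
    ex_mat <- if (nrow(ei)) cbind(ei$start - 1L, ei$end) else NULL
    len <- sum(cds_mat[, 2L] - cds_mat[, 1L])
    models[[id]] <- gene_model(
      gene_id = id, seq_id = as.character(mrna$seqid[i]),
      strand = as.character(mrna$strand[i]),
      cds = cds_mat, exons = ex_mat,
      source_line = sprintf("%s:%d-%d", mrna$seqid[i], mrna$start[i], mrna$end[i]),
      coding_complete = (len %% 3 == 0)
    )
  }
  ord <- order(vapply(models, function(m) m$seq_id, character(1)),
               vapply(models, function(m) min(m$exons[, 1L]), numeric(1)),
               vapply(models, function(m) m$gene_id, character(1)))
  models <- models[ord]
  attr(models, "n_skipped") <- as.integer(skipped)
  models
}

# Write a data.frame of GFF3 fields (seqid, source, type, start, end, score,
# strand, phase, attributes; start/end 1-based closed) to a file.
write_gff3_table <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  apply_fmt <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                       df$seqid, df$source, df$type,
                       as.integer(df$start), as.integer(df$end),
                       df$score, df$strand, df$phase, df$attributes)
  if (nrow(df)) writeLines(apply_fmt, con)
  invisible(path)
}

#' Extract a promoter window around an anchor position
#'
#' Windows are defined by offsets relative to an anchor (start codon or
#' TSS) in transcription orientation: negative offsets are upstream of the
#' anchor, and position 0 is the anchor base itself.  Minus-strand windows
#' are reverse-complemented.  Positions outside the contig are filled with
#' `N` and the window flagged truncated; the returned sequence always has
#' length `rel_end - rel_start`.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param gene A [gene_model()].
#' @param anchor `"start_codon"` or `"tss"`.
#' @param rel_start,rel_end Window offsets in bp relative to the anchor,
#'   half-open: the window covers relative positions
#'   `[rel_start, rel_end)`.
#' @param tss Genomic 0-based TSS position, required when
#'   `anchor = "tss"`.
#' @return List with elements `gene_id`, `anchor`, `rel_start`, `rel_end`,
#'   `sequence` and `truncated`.
#' @export
extract_window <- function(genome, gene, anchor = c("start_codon", "tss"),
                           rel_start = -1000, rel_end = 250, tss = NULL) {
  anchor <- match.arg(anchor)
  if (!gene$seq_id %in% names(genome)) {
    stop("gene ", gene$gene_id, ": unknown seq_id ", gene$seq_id)
  }
  stopifnot(rel_end > rel_start)
  A <- if (anchor == "tss") {
    if (is.null(tss)) stop("anchor = 'tss' requires a tss position")
    tss
  } else {
    start_codon_pos(gene)
  }
  contig <- genome[[gene$seq_id]]
  L <- length(contig)
  if (gene$strand == "+") {
    gs <- A + rel_start; ge <- A + rel_end       # 0-based half-open
  } else {
    gs <- A - rel_end + 1; ge <- A - rel_start + 1
  }
  cs <- max(gs, 0); ce <- min(ge, L)
  inner <- if (ce > cs) {
    as.character(Biostrings::subseq(contig, cs + 1, ce))
  } else ""
  left_pad <- cs - gs
  right_pad <- ge - ce
  s <- paste0(strrep("N", left_pad), inner, strrep("N", right_pad))
  if (gene$strand == "-") s <- revcomp(s)
  list(gene_id = gene$gene_id, anchor = anchor,
       rel_start = rel_start, rel_end = rel_end,
       sequence = s, truncated = (left_pad > 0 || right_pad > 0))
}

#' Extract windows for many genes into a window set
#'
#' @inheritParams extract_window
#' @param genes List of [gene_model()] objects.
#' @param tss Named numeric vector of genomic 0-based TSS positions (names
#'   are gene ids), required when `anchor = "tss"`.  Genes without a TSS
#'   entry are dropped.
#' @return A `window_set`: list with `sequences` (named character vector,
#'   all the same length), `rel_start`, `rel_end`, `anchor`, `truncated`.
#' @export
extract_windows <- function(genome, genes, anchor = c("start_codon", "tss"),
                            rel_start = -1000, rel_end = 250, tss = NULL) {
  anchor <- match.arg(anchor)
  if (anchor == "tss") {
    genes <- genes[vapply(genes, function(g) g$gene_id %in% names(tss), logical(1))]
  }
  ws <- lapply(genes, function(g) {
    extract_window(genome, g, anchor, rel_start, rel_end,
                   tss = if (anchor == "tss") tss[[g$gene_id]] else NULL)
  })
  window_set(
    sequences = stats::setNames(vapply(ws, `[[`, character(1), "sequence"),
                                vapply(ws, `[[`, character(1), "gene_id")),
    rel_start = rel_start, rel_end = rel_end, anchor = anchor,
    truncated = vapply(ws, `[[`, logical(1), "truncated")
  )
}

#' Construct a window set from aligned sequences
#'
#' A window set holds equal-length sequences anchored at a common relative
#' coordinate system (relative position `rel_start` is the first base;
#' position 0 is the anchor).
#'
#' @param sequences Named character vector of equal-length sequences.
#' @param rel_start,rel_end Relative coordinates covered, half-open.
#' @param anchor Anchor label (`"tss"` or `"start_codon"`).
#' @param truncated Logical vector flagging windows padded with `N`.
#' @export
window_set <- function(sequences, rel_start, rel_end, anchor = "tss",
                       truncated = rep(FALSE, length(sequences))) {
  if (length(sequences)) {
    L <- unique(nchar(sequences))
    if (length(L) != 1L) stop("window sequences must all have the same length")
    if (L != rel_end - rel_start) {
      stop("window length ", L, " != rel_end - rel_start = ", rel_end - rel_start)
    }
  }
  structure(list(sequences = sequences, rel_start = rel_start,
                 rel_end = rel_end, anchor = anchor, truncated = truncated),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d sequence(s), anchor=%s, rel [%d, %d), %d truncated>\n",
              length(x$sequences), x$anchor, x$rel_start, x$rel_end,
              sum(x$truncated)))
  invisible(x)
}

#' @export
length.window_set <- function(x) length(x$sequences)

# relative position of local column c (1-based) in a window set
ws_rel <- function(ws, cols) ws$rel_start + cols - 1L

# local column of a relative position
ws_col <- function(ws, rel) rel - ws$rel_start + 1L

#' Write / read a profile track as TSV
#'
#' The TSV carries a comment header with the statistic name and the window
#' geometry, then columns `rel_position`, `value`, `n_sequences`.
#' `read_track_tsv(write_track_tsv(x))` reproduces `x`.
#'
#' @param track A [profile_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# statistic=%s width=%g step=%g",
                     attr(track, "statistic"), attr(track, "width"),
                     attr(track, "step")), con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("# statistic=(\\S+) width=(\\S+) step=(\\S+)", header))[[1]]
  if (length(m) != 4L) stop("not a track TSV: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  profile_track(df$rel_position, df$value, df$n_sequences,
                statistic = m[2], width = as.numeric(m[3]),
                step = as.numeric(m[4]))
}

#' Write / read intervals as BED
#'
#' Intervals use the internal 0-based half-open convention, which is also
#' BED's, so coordinates pass through unchanged.
#'
#' @param intervals Data frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path File path.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_bed <- function(intervals, path) {
  n <- length(intervals$seq_id)
  df <- data.frame(
    seq_id = intervals$seq_id,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = intervals$name %||% rep(".", n),
    score = intervals$score %||% rep(0, n),
    strand = intervals$strand %||% rep(".", n)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write selected TSS positions as GFF3 features
#'
#' Emits one single-base `TSS` feature per selected gene, with the mRNA id
#' as `Parent`, suitable for loading into a genome browser.
#'
#' @param selected Data frame with columns `gene_id`, `seq_id`,
#'   `genomic_pos` (0-based), `strand` and optionally `score`.
#' @param path Output path.
#' @export
write_tss_gff3 <- function(selected, path) {
  df <- data.frame(
    seqid = selected$seq_id, source = "promtss", type = "TSS",
    start = as.integer(selected$genomic_pos) + 1L,
    end = as.integer(selected$genomic_pos) + 1L,
    score = if (!is.null(selected$score)) sprintf("%g", selected$score) else ".",
    strand = selected$strand, phase = ".",
    attributes = sprintf("ID=TSS:%s;Parent=%s", selected$gene_id,
                         selected$gene_id),
    stringsAsFactors = FALSE
  )
  write_gff3_table(df, path)
}
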