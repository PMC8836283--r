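# Expression-evidence support for gene models: fraction of the spliced CDS
# covered by the union of evidence intervals.  This distills the outcome of
# alignment-based filtering (running the aligners themselves is out of
# scope; their hits arrive as BED intervals).

#' Compute evidence support per gene
#'
#' The covered fraction is the number of spliced-CDS bases overlapped by
#' the *union* of the evidence intervals (overlapping reads are not double
#' counted), divided by the spliced CDS length.  A gene is `supported` when
#' the fraction reaches `min_fraction`.
#'
#' Two evidence tracks (e.g. RNA-seq and protein homology) can be combined
#' by concatenating their interval tables before the call, or by calling
#' twice and combining the verdicts with AND/OR as appropriate.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param evidence Data frame of intervals with columns `seq_id`, `start`,
#'   `end` (0-based half-open, same coordinate system as the genes).
#'   Intervals on contigs without genes trigger a warning and are ignored.
#' @param min_fraction Support threshold in `[0, 1]`; default 0.5.
#' @return Data frame with columns `gene_id`, `covered_fraction`,
#'   `supported`.
#' @export
compute_support <- function(genes, evidence, min_fraction = 0.5) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  gene_seqs <- unique(vapply(genes, function(g) g$seq_id, character(1)))
  if (nrow(evidence)) {
    unknown <- !evidence$seq_id %in% gene_seqs
    if (any(unknown)) {
      warning(sum(unknown), " evidence interval(s) on seq_ids without genes ",
              "were ignored")
      evidence <- evidence[!unknown, , drop = FALSE]
    }
  }
  # union of evidence per contig
  ev_by_seq <- lapply(split(evidence, evidence$seq_id), function(e) {
    IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
  })
  res <- lapply(genes, function(g) {
    cds_ir <- IRanges::IRanges(start = g$cds[, 1L] + 1L, end = g$cds[, 2L])
    ev <- ev_by_seq[[g$seq_id]]
    cov <- if (is.null(ev)) 0L else
      sum(IRanges::width(IRanges::intersect(ev, cds_ir)))
    frac <- cov / spliced_cds_length(g)
    data.frame(gene_id = g$gene_id, covered_fraction = frac,
               supported = frac >= min_fraction)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), covered_fraction = numeric(0),
                      supported = logical(0))
  }
  out
}
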