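# Coding-sequence GC3 analytics: per-gene third-codon-position GC
# fraction, the 5'->3' positional gradient and its slope, quantile-based
# GC3-poor/-rich classes, and Mann-Whitney class comparisons.

#' GC3 of a spliced coding sequence
#'
#' Fraction of G or C among codon third positions.  Third positions that
#' are `N` are dropped from both numerator and denominator.
#'
#' @param spliced_cds Coding sequence string in transcription orientation,
#'   length a positive multiple of 3 (the reading frame starts at the
#'   first base).
#' @return Fraction in `[0, 1]` (`NA` if every third base is `N`).
#' @export
gc3_of_cds <- function(spliced_cds) {
  L <- nchar(spliced_cds)
  if (L == 0 || L %% 3 != 0) {
    stop("CDS length ", L, " is not a positive multiple of 3 (frame error)")
  }
  chars <- strsplit(toupper(spliced_cds), "")[[1]]
  thirds <- chars[seq(3L, L, by = 3L)]
  thirds <- thirds[thirds %in% .DNA]
  if (!length(thirds)) return(NA_real_)
  mean(thirds %in% c("G", "C"))
}

#' Per-gene GC3 record table
#'
#' @param genes Named list of [gene_model()] objects.
#' @param genome A [Biostrings::DNAStringSet].
#' @return Data frame with `gene_id`, `gc3`, `cds_length`, `n_exons`.
#'   Genes whose spliced CDS is not a multiple of 3 (not
#'   coding-complete) are excluded with a warning.
#' @export
gc3_records <- function(genes, genome) {
  ok <- vapply(genes, function(g) isTRUE(g$coding_complete), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) without a complete reading frame excluded ",
            "from GC3 analysis")
  }
  genes <- genes[ok]
  do.call(rbind, c(lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id,
               gc3 = gc3_of_cds(spliced_cds(g, genome)),
               cds_length = spliced_cds_length(g),
               n_exons = nrow(g$exons))
  }), list(make.row.names = FALSE)))
}

#' Positional GC3 gradient across a CDS set
#'
#' For each codon index, the mean third-base GC indicator across all genes
#' long enough to contribute, restricted to the first `max_len`
#' nucleotides of the spliced transcript.  Positions are reported as the
#' nucleotide position of the codon's third base relative to the first
#' coding nucleotide (the A of ATG = position 1).
#'
#' @param cds_set Character vector of spliced CDS sequences (each a
#'   multiple of 3 long).
#' @param max_len Restrict to the first `max_len` nucleotides
#'   (default 1000).
#' @return A [profile_track()] with one point per codon.
#' @export
gc3_positional_gradient <- function(cds_set, max_len = 1000) {
  if (length(cds_set) < 2L) stop("need at least 2 coding sequences")
  max_codons <- floor(max_len / 3)
  sums <- numeric(max_codons)
  ns <- integer(max_codons)
  for (s in cds_set) {
    chars <- strsplit(toupper(s), "")[[1]]
    nc <- min(length(chars) %/% 3L, max_codons)
    if (nc == 0L) next
    thirds <- chars[seq(3L, 3L * nc, by = 3L)]
    valid <- thirds %in% .DNA
    gc <- thirds %in% c("G", "C")
    idx <- which(valid)
    sums[idx] <- sums[idx] + gc[idx]
    ns[idx] <- ns[idx] + 1L
  }
  keep <- ns > 0L
  profile_track(rel_positions = (3L * seq_len(max_codons))[keep],
                values = (sums / pmax(ns, 1L))[keep],
                n_sequences = ns[keep],
                statistic = "gc3_positional_mean", width = 3, step = 3)
}

#' Slope of the GC3 gradient
#'
#' Ordinary least-squares slope of the per-codon mean GC3 against the
#' nucleotide position, over the first `max_len` nucleotides of the
#' spliced transcripts (a single regression on the positional means, not
#' an average of per-gene slopes).
#'
#' @inheritParams gc3_positional_gradient
#' @return Slope in GC3 units per bp.
#' @export
gradient_slope <- function(cds_set, max_len = 1000) {
  tr <- gc3_positional_gradient(cds_set, max_len)
  unname(stats::coef(stats::lm(value ~ rel_position,
                               data = as.data.frame(tr)))[2L])
}

#' Assign GC3 quantile classes
#'
#' Genes at or below the `q_low` empirical quantile of GC3 are `poor`,
#' at or above the `q_high` quantile `rich`, the rest `mid`.  Quantiles
#' use the median-unbiased convention (`type = 8`); ties at a boundary go
#' to the extreme class, so `|poor|` and `|rich|` can differ only by the
#' number of boundary ties.
#'
#' @param records Data frame with a `gc3` column (>= 10 rows).
#' @param q_low,q_high Quantile cut points (defaults 0.10 and 0.90).
#' @return `records` with a `gc3_class` factor column (levels poor, mid,
#'   rich).
#' @export
assign_gc3_classes <- function(records, q_low = 0.10, q_high = 0.90) {
  if (nrow(records) < 10L) stop("need at least 10 records to define classes")
  q <- stats::quantile(records$gc3, probs = c(q_low, q_high), type = 8,
                       names = FALSE, na.rm = TRUE)
  if (q[1L] >= q[2L]) {
    stop("degenerate GC3 distribution: quantile boundaries coincide")
  }
  records$gc3_class <- factor(
    ifelse(records$gc3 <= q[1L], "poor",
           ifelse(records$gc3 >= q[2L], "rich", "mid")),
    levels = c("poor", "mid", "rich"))
  attr(records, "boundaries") <- c(low = q[1L], high = q[2L])
  records
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution (full enumeration, as implemented in
#' [stats::wilcox.test()]) when the smaller sample has at most 8
#' observations and there are no ties; normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (number of (x, y) pairs with x > y, counting ties
#'   as 1/2), `p_value`, `exact`, `n1`, `n2`.
#' @export
mwu_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  use_exact <- min(length(x), length(y)) <= 8 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_value = min(wt$p.value, 1),
       exact = use_exact, n1 = length(x), n2 = length(y))
}

#' Compare GC3-poor and GC3-rich gene classes
#'
#' Mann-Whitney U comparison of a gene property (CDS length or exon
#' count) between the poor and rich classes, with per-class medians and,
#' for exon counts, a 1 / 2 / 3 / 4 / 5+ histogram per class.
#'
#' @param records Output of [assign_gc3_classes()].
#' @param variable `"cds_length"` or `"n_exons"`.
#' @return List of class `class_comparison` with elements `variable`,
#'   `test` (see [mwu_test()]), `median_poor`, `median_rich`,
#'   `direction`, and (for exon counts) `exon_histogram`.
#' @export
compare_classes <- function(records, variable = c("cds_length", "n_exons")) {
  variable <- match.arg(variable)
  poor <- records[[variable]][records$gc3_class == "poor"]
  rich <- records[[variable]][records$gc3_class == "rich"]
  if (!length(poor) || !length(rich)) {
    stop("both GC3 classes must be non-empty")
  }
  test <- mwu_test(poor, rich)
  out <- list(variable = variable, test = test,
              median_poor = stats::median(poor),
              median_rich = stats::median(rich),
              direction = if (stats::median(poor) > stats::median(rich))
                "poor > rich" else "poor <= rich")
  if (variable == "n_exons") {
    bin <- function(v) {
      b <- cut(v, breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, Inf),
               labels = c("1", "2", "3", "4", "5+"))
      table(b)
    }
    out$exon_histogram <- rbind(poor = bin(poor), rich = bin(rich))
  }
  class(out) <- "class_comparison"
  out
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("<class_comparison %s: U = %g, p = %.3g (%s), medians poor %g vs rich %g>\n",
              x$variable, x$test$U, x$test$p_value,
              if (x$test$exact) "exact" else "normal approx.",
              x$median_poor, x$median_rich))
  invisible(x)
}
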