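# One-TSS-per-gene selection: exclude candidates inside coding sequence,
# then rank the remaining upstream candidates by the density of a gamma
# prior on 5'UTR length.

#' Construct a gamma prior on 5'UTR length
#'
#' Shape/scale parameterization: mean `k * theta`, variance `k * theta^2`.
#'
#' @param k Shape (dimensionless), > 0.
#' @param theta Scale (bp), > 0.
#' @param m,v Optional sample mean and variance the prior was fitted from.
#' @return Object of class `gamma_prior`.
#' @export
gamma_prior <- function(k, theta, m = NULL, v = NULL) {
  if (!is.numeric(k) || !is.numeric(theta) || k <= 0 || theta <= 0) {
    stop("gamma prior requires k > 0 and theta > 0")
  }
  structure(list(k = k, theta = theta, m = m, v = v), class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior  k (shape) = %.4g, theta (scale) = %.4g bp;  mean = %.4g bp>\n",
              x$k, x$theta, x$k * x$theta))
  invisible(x)
}

#' Default 5'UTR length prior
#'
#' Shape 0.62 and scale 238.99 bp, derived from pooled annotated 5'UTR
#' lengths of four model plants (*A. thaliana*, *O. sativa*, *S. bicolor*,
#' *P. trichocarpa*).  Users working on other clades can refit with
#' [fit_gamma_moments()].
#'
#' @return A [gamma_prior()].
#' @export
default_gamma_prior <- function() gamma_prior(k = 0.62, theta = 238.99)

#' Fit a gamma distribution by the method of moments
#'
#' With sample mean `m` and unbiased (n-1 denominator) sample variance `v`,
#' the scale is `theta = v / m` and the shape `k = m / theta` (equivalently
#' `m^2 / v`).  The fit reproduces the sample moments exactly:
#' `k * theta == m` and `k * theta^2 == v`.
#'
#' @param utr_lengths Numeric vector of 5'UTR lengths in bp (>= 0), at
#'   least two distinct values.
#' @return A [gamma_prior()] carrying the sample moments.
#' @export
fit_gamma_moments <- function(utr_lengths) {
  x <- as.numeric(utr_lengths)
  if (anyNA(x)) stop("utr_lengths contains NA")
  if (any(x < 0)) stop("utr_lengths must be non-negative")
  if (length(x) < 2L) stop("need at least two 5'UTR lengths")
  m <- mean(x)
  v <- stats::var(x)
  if (v == 0) stop("degenerate sample: zero variance in utr_lengths")
  theta <- v / m
  k <- m / theta
  gamma_prior(k = k, theta = theta, m = m, v = v)
}

#' Gamma prior density
#'
#' Standard gamma density `x^(k-1) exp(-x/theta) / (Gamma(k) theta^k)`.
#' For shape `k < 1` the density is unbounded at zero, so a 5'UTR length of
#' 0 bp (TSS coinciding with the start codon) is evaluated at 1 bp; any
#' monotone cap preserves the ranking among positive lengths.
#'
#' @param x 5'UTR length(s) in bp, >= 0.
#' @param prior A [gamma_prior()].
#' @return Density value(s).
#' @export
gamma_pdf <- function(x, prior = default_gamma_prior()) {
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE)) stop("gamma_pdf requires x >= 0")
  if (prior$k < 1) x[x == 0] <- 1
  stats::dgamma(x, shape = prior$k, scale = prior$theta)
}

#' Read / write a candidate TSS table
#'
#' Tab-separated columns `gene_id`, `genomic_pos` (0-based), `strand`,
#' `score` — the carrier format for predictor output such as TSSPlant's.
#'
#' @param path File path.
#' @export
read_candidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "genomic_pos", "strand", "score")
  if (!all(need %in% names(df))) {
    stop("candidate table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_candidates
#' @param candidates Data frame of candidates.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(
    candidates[, c("gene_id", "genomic_pos", "strand", "score")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map candidates onto their gene models
#'
#' Adds, per candidate: `rel_pos` — offset from the start codon in
#' transcription orientation (negative = upstream); `utr_length` — implied
#' 5'UTR length (`-rel_pos`, defined only for upstream candidates);
#' `in_cds` — whether the candidate falls inside any CDS segment of its
#' gene.
#'
#' @param candidates Data frame with `gene_id`, `genomic_pos`, `strand`.
#' @param genes Named list of [gene_model()] objects.
#' @return The candidate data frame with `rel_pos`, `utr_length`, `in_cds`
#'   columns; candidates whose `gene_id` has no gene model are dropped with
#'   a warning.
#' @export
map_candidates <- function(candidates, genes) {
  known <- candidates$gene_id %in% names(genes)
  if (!all(known)) {
    warning(sum(!known), " candidate(s) for unknown gene ids were dropped")
    candidates <- candidates[known, , drop = FALSE]
  }
  n <- nrow(candidates)
  rel <- numeric(n); incds <- logical(n)
  for (i in seq_len(n)) {
    g <- genes[[candidates$gene_id[i]]]
    p <- candidates$genomic_pos[i]
    a <- start_codon_pos(g)
    rel[i] <- if (g$strand == "+") p - a else a - p
    incds[i] <- any(p >= g$cds[, 1L] & p < g$cds[, 2L])
  }
  candidates$rel_pos <- rel
  candidates$utr_length <- ifelse(rel < 0, -rel, NA_real_)
  candidates$in_cds <- incds
  candidates
}

#' Partition candidates by CDS overlap
#'
#' Predicted TSS positions falling within the coding part of their gene
#' model are excluded before selection.
#'
#' @param candidates Mapped candidates (see [map_candidates()]).
#' @return List with `kept`, `excluded` data frames and
#'   `excluded_fraction`.
#' @export
exclude_in_cds <- function(candidates) {
  stopifnot("in_cds" %in% names(candidates))
  list(kept = candidates[!candidates$in_cds, , drop = FALSE],
       excluded = candidates[candidates$in_cds, , drop = FALSE],
       excluded_fraction = if (nrow(candidates)) mean(candidates$in_cds) else NA_real_)
}

# ranking key for a mapped candidate table
.rank_key <- function(cand, prior, rank_by) {
  pdf <- gamma_pdf(cand$utr_length, prior)
  switch(rank_by,
         pdf = pdf,
         score = cand$score,
         pdf_times_score = pdf * cand$score,
         stop("unknown rank_by: ", rank_by))
}

#' Select the best TSS candidate of one gene
#'
#' Only upstream candidates (`rel_pos < 0`, hence a defined 5'UTR length)
#' are eligible.  The primary ranking key is the gamma-prior density of the
#' implied 5'UTR length; ties are broken by higher predictor score, then
#' smaller 5'UTR length, then genomic position, making the choice fully
#' deterministic and invariant to input order.
#'
#' @param candidates Mapped candidates of a single gene, already
#'   CDS-filtered.
#' @param prior A [gamma_prior()].
#' @param rank_by Primary key: `"pdf"` (default), `"score"`, or
#'   `"pdf_times_score"`.
#' @param min_pdf_quantile Optional: drop candidates whose 5'UTR length
#'   exceeds this quantile of the prior (a hard "better fit" cut before
#'   ranking).  `NULL` disables the cut.
#' @return One-row data frame (with a `pdf` column), or `NULL` if no
#'   candidate is eligible.
#' @export
select_best_tss <- function(candidates, prior = default_gamma_prior(),
                            rank_by = c("pdf", "score", "pdf_times_score"),
                            min_pdf_quantile = NULL) {
  rank_by <- match.arg(rank_by)
  el <- candidates[!is.na(candidates$rel_pos) & candidates$rel_pos < 0, ,
                   drop = FALSE]
  if (!is.null(min_pdf_quantile)) {
    cut <- stats::qgamma(min_pdf_quantile, shape = prior$k, scale = prior$theta)
    el <- el[el$utr_length <= cut, , drop = FALSE]
  }
  if (nrow(el) == 0L) return(NULL)
  el$pdf <- gamma_pdf(el$utr_length, prior)
  key <- .rank_key(el, prior, rank_by)
  ord <- order(-key, -el$score, el$utr_length, el$genomic_pos)
  el[ord[1L], , drop = FALSE]
}

#' Select one TSS per gene over a full candidate table
#'
#' Runs [exclude_in_cds()] then [select_best_tss()] gene by gene.
#'
#' @param candidates Candidate table (will be mapped with
#'   [map_candidates()] if the `rel_pos` column is absent).
#' @param genes Named list of [gene_model()] objects.
#' @inheritParams select_best_tss
#' @return Data frame of selected TSSs (one row per gene with an eligible
#'   candidate) with columns of the input plus `pdf` and `seq_id`.  The
#'   in-CDS excluded fraction is attached as attribute
#'   `excluded_fraction`.
#' @export
select_tss <- function(candidates, genes, prior = default_gamma_prior(),
                       rank_by = c("pdf", "score", "pdf_times_score"),
                       min_pdf_quantile = NULL) {
  rank_by <- match.arg(rank_by)
  if (!"rel_pos" %in% names(candidates)) {
    candidates <- map_candidates(candidates, genes)
  }
  part <- exclude_in_cds(candidates)
  by_gene <- split(part$kept, part$kept$gene_id)
  picks <- lapply(by_gene, select_best_tss, prior = prior, rank_by = rank_by,
                  min_pdf_quantile = min_pdf_quantile)
  picks <- picks[!vapply(picks, is.null, logical(1))]
  out <- if (length(picks)) do.call(rbind, picks) else
    cbind(part$kept[0, , drop = FALSE], pdf = numeric(0))
  rownames(out) <- NULL
  if (nrow(out)) {
    out$seq_id <- vapply(out$gene_id, function(id) genes[[id]]$seq_id,
                         character(1))
    out <- out[order(out$seq_id, out$genomic_pos, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "excluded_fraction") <- part$excluded_fraction
  out
}
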