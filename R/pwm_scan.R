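# MATCH-style position weight matrix scanning: information-weighted,
# min-max normalized similarity scores in [0, 1], double-strand scanning,
# and positional hit-density tracks over promoter windows.

#' Construct a position weight matrix
#'
#' Counts are normalized to per-position base frequencies with an additive
#' pseudocount.  The information weight of position *i* is
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))` (natural log, the MATCH
#' convention); the derived per-position weights `I(i) * f(i,b)` define
#' the min/max score bounds used by [match_score()].
#'
#' @param counts Matrix (positions x 4) of non-negative counts or
#'   frequencies, columns in A, C, G, T order.
#' @param name Matrix name.
#' @param pseudocount Additive pseudocount (default 0.01).
#' @return Object of class `pwm` with elements `name`, `freq`, `info`,
#'   `weights`, `min_score`, `max_score`.
#' @export
pwm <- function(counts, name = "pwm", pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("PWM needs 4 columns (A, C, G, T)")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("PWM counts must be finite and non-negative")
  }
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    stop("PWM row ", which(rs <= 0)[1L], " does not sum to a positive value")
  }
  colnames(counts) <- .DNA
  f <- (counts + pseudocount) / (rs + 4 * pseudocount)
  info <- rowSums(ifelse(f > 0, f * log(4 * f), 0))
  W <- f * info
  structure(list(name = name, freq = f, info = info, weights = W,
                 pseudocount = pseudocount,
                 min_score = sum(apply(W, 1L, min)),
                 max_score = sum(apply(W, 1L, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s': %d positions, consensus %s, score range [%.3f, %.3f]>\n",
              x$name, nrow(x$freq), pwm_consensus(x), x$min_score,
              x$max_score))
  invisible(x)
}

#' @export
length.pwm <- function(x) nrow(x$freq)

#' Consensus sequence of a PWM (highest-frequency base per position)
#' @param x A [pwm()].
#' @export
pwm_consensus <- function(x) {
  paste0(.DNA[apply(x$freq, 1L, which.max)], collapse = "")
}

# PWM describing the reverse complement of the motif
pwm_revcomp <- function(x) {
  counts_rc <- x$freq[rev(seq_len(nrow(x$freq))), c(4L, 3L, 2L, 1L),
                      drop = FALSE]
  colnames(counts_rc) <- .DNA
  pwm(counts_rc, name = paste0(x$name, "_rc"), pseudocount = 0)
}

#' Read a PWM from a TRANSFAC-like flat file
#'
#' Expected dialect: a `NA <name>` (or `ID <name>`) line, an optional
#' `P0 A C G T` column header, one row per position (`<pos> <A> <C> <G>
#' <T>` with an optional trailing consensus letter), terminated by `//` or
#' end of file.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param pseudocount Passed to [pwm()].
#' @return A [pwm()].
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  name <- basename(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^(NA|ID)\\b", ln)) {
      name <- trimws(sub("^(NA|ID)\\s*", "", ln))
      next
    }
    if (grepl("^(P0|PO)\\b", ln) || ln == "//" || grepl("^XX", ln)) next
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) < 5L) {
      stop("PWM row at line ", i, " of ", path,
           ": expected position + 4 counts")
    }
    vals <- suppressWarnings(as.numeric(fields[2:5]))
    if (anyNA(vals)) {
      stop("PWM row at line ", i, " of ", path, ": non-numeric count")
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("no matrix rows found in ", path)
  pwm(do.call(rbind, rows), name = name, pseudocount = pseudocount)
}

#' MATCH matrix similarity score of a subsequence
#'
#' `score = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, b_i)` and Min/Max are the analogous sums
#' over the worst/best base per position.  The consensus scores 1, the
#' anti-consensus 0.  Subsequences containing non-ACGT characters score
#' `NA`.
#'
#' @param x A [pwm()].
#' @param subseq Character string of the same length as the PWM.
#' @return Similarity in `[0, 1]`, or `NA`.
#' @export
match_score <- function(x, subseq) {
  L <- nrow(x$freq)
  if (nchar(subseq) != L) {
    stop("subsequence length ", nchar(subseq), " != PWM length ", L)
  }
  idx <- base_to_int(strsplit(toupper(subseq), "")[[1]])
  if (anyNA(idx)) return(NA_real_)
  cur <- sum(x$weights[cbind(seq_len(L), idx)])
  denom <- x$max_score - x$min_score
  if (denom == 0) return(NA_real_)
  (cur - x$min_score) / denom
}

# vector of match scores at every offset of an integer-encoded sequence
# (values 1..4, NA for N); scores involving NA positions are NA
pwm_scan_scores_int <- function(x, seq_int) {
  L <- nrow(x$freq)
  n_off <- length(seq_int) - L + 1L
  if (n_off < 1L) return(numeric(0))
  cur <- numeric(n_off)
  for (i in seq_len(L)) {
    wi <- x$weights[i, ]
    cur <- cur + wi[seq_int[i:(i + n_off - 1L)]]
  }
  denom <- x$max_score - x$min_score
  if (denom == 0) return(rep(NA_real_, n_off))
  unname((cur - x$min_score) / denom)
}

#' Scan a sequence with a PWM
#'
#' @param x A [pwm()].
#' @param seq Nucleotide string.
#' @return Numeric vector of [match_score()] values at every start offset
#'   (1-based); `NA` where the subsequence contains non-ACGT characters.
#' @export
scan_pwm <- function(x, seq) {
  pwm_scan_scores_int(x, base_to_int(strsplit(toupper(seq), "")[[1]]))
}

#' Positional TFBS hit-density tracks
#'
#' Scans every window on both strands (the reverse strand via the
#' reverse-complement matrix, so hits are reported at their leftmost
#' promoter coordinate regardless of strand); a position is a hit when the
#' similarity score reaches `threshold` on either strand.  Hit counts are
#' aggregated in sliding windows and divided by the number of sequences.
#' Family tracks average the tracks of the family's member PWMs.
#'
#' @param ws A TSS-anchored [window_set()].
#' @param pwms A [pwm()] or list of PWMs.
#' @param threshold Similarity threshold in `[0, 1]` (default 0.85).
#' @param width,step Sliding-window geometry (defaults 20 and 10).
#' @param families Optional named character vector mapping PWM name to
#'   family.
#' @return List with `per_pwm` (named list of [profile_track()]s) and
#'   `per_family` (named list, empty when `families` is `NULL`).
#' @export
positional_hit_density <- function(ws, pwms, threshold = 0.85, width = 20,
                                   step = 10, families = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  geo <- ws_geometry(ws, width, step)
  n <- length(ws$sequences)
  L <- ws$rel_end - ws$rel_start
  seq_ints <- lapply(ws$sequences, function(s) {
    base_to_int(strsplit(toupper(s), "")[[1]])
  })
  per_pwm <- lapply(pwms, function(p) {
    prc <- pwm_revcomp(p)
    counts <- numeric(L)
    for (si in seq_ints) {
      fw <- pwm_scan_scores_int(p, si)
      rc <- pwm_scan_scores_int(prc, si)
      hit <- (!is.na(fw) & fw >= threshold) | (!is.na(rc) & rc >= threshold)
      if (any(hit)) counts[which(hit)] <- counts[which(hit)] + 1
    }
    vals <- vec_win_sums(counts, width, geo$starts)
    profile_track(geo$centers,
                  if (n > 0L) vals / n else rep(NA_real_, length(vals)),
                  rep(n, length(vals)),
                  statistic = paste0("pwm_hits:", p$name),
                  width = width, step = step)
  })
  per_family <- list()
  if (!is.null(families)) {
    fams <- split(names(pwms)[names(pwms) %in% names(families)],
                  families[names(pwms)[names(pwms) %in% names(families)]])
    per_family <- lapply(fams, function(members) {
      vals <- rowMeans(vapply(per_pwm[members], function(t) t$value,
                              numeric(length(geo$centers))))
      profile_track(geo$centers, vals, rep(n, length(vals)),
                    statistic = "pwm_family_hits", width = width,
                    step = step)
    })
  }
  list(per_pwm = per_pwm, per_family = per_family)
}
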