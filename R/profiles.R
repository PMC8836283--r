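# TSS-centered nucleotide-composition statistics: sliding-window motif
# frequency, CG-skew, DNA duplex free-energy profiles, and core-promoter
# classification.
#
# All sliding windows report the window *center* on the x-axis; a motif
# contributes through its match start position.  N positions never match a
# pattern and are dropped from count denominators.

#' Construct a positional profile track
#'
#' @param rel_positions Window-center offsets in bp (anchor = 0), strictly
#'   increasing with constant step.
#' @param values Statistic value per window (`NA` where no sequence
#'   contributed).
#' @param n_sequences Number of sequences contributing per window.
#' @param statistic Name of the statistic.
#' @param width,step Window geometry in bp.
#' @return Data frame of class `profile_track` with attributes
#'   `statistic`, `width`, `step`.
#' @export
profile_track <- function(rel_positions, values, n_sequences, statistic,
                          width, step) {
  stopifnot(length(rel_positions) == length(values),
            length(values) == length(n_sequences))
  if (length(rel_positions) > 1L) {
    d <- diff(rel_positions)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9) {
      stop("rel_positions must be strictly increasing with constant step")
    }
  }
  structure(
    data.frame(rel_position = rel_positions, value = values,
               n_sequences = n_sequences),
    statistic = statistic, width = width, step = step,
    class = c("profile_track", "data.frame"))
}

#' @export
print.profile_track <- function(x, ...) {
  cat(sprintf("<profile_track '%s': %d windows (width %g, step %g)>\n",
              attr(x, "statistic"), nrow(x), attr(x, "width"),
              attr(x, "step")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# character matrix (n sequences x L positions) of a window set
ws_char_matrix <- function(ws) {
  n <- length(ws$sequences)
  L <- ws$rel_end - ws$rel_start
  if (n == 0L) return(matrix(character(0), nrow = 0L, ncol = L))
  matrix(unlist(strsplit(toupper(ws$sequences), ""), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

# shared geometry: window starts (local) and centers (relative coords)
ws_geometry <- function(ws, width, step) {
  L <- ws$rel_end - ws$rel_start
  starts <- win_starts(L, width, step)
  list(starts = starts,
       centers = ws_rel(ws, starts) + (width - 1) / 2)
}

#' Sliding-window motif frequency profile
#'
#' Counts pattern-match start positions inside each sliding window, summed
#' over all sequences, divided by the number of sequences.  The pattern may
#' use IUPAC ambiguity codes (e.g. `TATAWAW` for the TATA-box consensus
#' TATA(A/T)A(A/T)); `N`s in the sequences never match.
#'
#' @param ws A [window_set()].
#' @param pattern IUPAC pattern string.
#' @param width,step Window width and increment in bp (defaults 20 and 10).
#' @return A [profile_track()].
#' @export
motif_frequency_profile <- function(ws, pattern, width = 20, step = 10) {
  if (nchar(pattern) > width) {
    stop("pattern (", nchar(pattern), " bp) longer than window width ", width)
  }
  geo <- ws_geometry(ws, width, step)
  n <- length(ws$sequences)
  L <- ws$rel_end - ws$rel_start
  counts <- numeric(L)
  if (n > 0L) {
    subj <- Biostrings::DNAStringSet(ws$sequences)
    hits <- Biostrings::vmatchPattern(pattern, subj, fixed = "subject")
    starts <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
    if (length(starts)) counts <- tabulate(starts, nbins = L)
  }
  vals <- vec_win_sums(counts, width, geo$starts)
  profile_track(geo$centers,
                if (n > 0L) vals / n else rep(NA_real_, length(vals)),
                rep(n, length(vals)),
                statistic = paste0("motif_freq:", pattern),
                width = width, step = step)
}

#' CG-skew of a sequence
#'
#' `(C - G) / (C + G)` counted on the given strand; `N`s are ignored.
#' Returns `NA` when the sequence contains no C or G.
#'
#' @param seq Nucleotide string.
#' @return Value in `[-1, 1]` or `NA`.
#' @export
cg_skew <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(seq)),
                                   c("C", "G"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["C"]] - f[["G"]]) / tot)
}

#' Sliding-window CG-skew profile
#'
#' Per window and sequence, `(C - G)/(C + G)`; windows with `C + G == 0`
#' in a sequence are missing for that sequence and excluded from the
#' average.  The track value is the mean skew over contributing sequences.
#'
#' @param ws A [window_set()].
#' @param width,step Window geometry in bp (defaults 50 and 10).
#' @return A [profile_track()].
#' @export
cg_skew_profile <- function(ws, width = 50, step = 10) {
  geo <- ws_geometry(ws, width, step)
  n <- length(ws$sequences)
  if (n == 0L || length(geo$starts) == 0L) {
    return(profile_track(geo$centers, rep(NA_real_, length(geo$centers)),
                         rep(0L, length(geo$centers)),
                         statistic = "cg_skew", width = width, step = step))
  }
  M <- ws_char_matrix(ws)
  Cw <- row_win_sums((M == "C") * 1, width, geo$starts)
  Gw <- row_win_sums((M == "G") * 1, width, geo$starts)
  tot <- Cw + Gw
  skew <- ifelse(tot > 0, (Cw - Gw) / tot, NA_real_)
  profile_track(geo$centers,
                colMeans(skew, na.rm = TRUE),
                colSums(!is.na(skew)),
                statistic = "cg_skew", width = width, step = step)
}

#' Load a dinucleotide step free-energy table
#'
#' Reads a two-column TSV (dinucleotide, delta-G in kcal/mol).  The
#' package ships a unified nearest-neighbor table of standard free-energy
#' changes at 37 degrees C for the 16 dinucleotide steps
#' (`system.file("extdata", "dinucleotide_dg37.tsv", package =
#' "promtss")`); users may substitute their own.
#'
#' @param path Path to the table; default: the bundled table.
#' @return Named numeric vector of length 16 (kcal/mol per step).
#' @export
load_dinucleotide_dg <- function(path = system.file("extdata",
                                                    "dinucleotide_dg37.tsv",
                                                    package = "promtss")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  dg <- stats::setNames(df$dg_kcal_mol, toupper(df$dinucleotide))
  need <- paste0(rep(.DNA, each = 4L), .DNA)   # AA, AC, AG, AT, CA, ...
  missing <- setdiff(need, names(dg))
  if (length(missing)) {
    stop("free-energy table lacks steps: ", paste(missing, collapse = ", "))
  }
  dg[need]
}

#' Sliding-window DNA duplex free-energy profile
#'
#' Promoters are locally less stable than bulk DNA; the profile reports,
#' per window, the average standard free energy of the dinucleotide steps
#' it spans (a width-`w` window covers `w - 1` steps), averaged over
#' sequences.  Windows containing an `N` in a sequence are missing for
#' that sequence.  AT-rich windows give less negative (less stable)
#' values than GC-rich ones.
#'
#' @param ws A [window_set()].
#' @param width Window width in bp (default 15); must be >= 2.
#' @param step Window increment in bp (default 1).
#' @param dg Named dinucleotide step energies, see
#'   [load_dinucleotide_dg()].
#' @return A [profile_track()] in kcal/mol per dinucleotide step.
#' @export
free_energy_profile <- function(ws, width = 15, step = 1,
                                dg = load_dinucleotide_dg()) {
  if (width < 2) stop("free-energy window width must be >= 2")
  geo <- ws_geometry(ws, width, step)
  n <- length(ws$sequences)
  if (n == 0L || length(geo$starts) == 0L) {
    return(profile_track(geo$centers, rep(NA_real_, length(geo$centers)),
                         rep(0L, length(geo$centers)),
                         statistic = "free_energy", width = width,
                         step = step))
  }
  M <- ws_char_matrix(ws)
  L <- ncol(M)
  ii <- base_to_int(M)                       # NA for N
  dim(ii) <- dim(M)
  code <- 4L * (ii[, -L, drop = FALSE] - 1L) + ii[, -1L, drop = FALSE]
  E <- matrix(dg[as.vector(code)], nrow = n)  # NA where any N
  bad <- is.na(E)
  E0 <- E; E0[bad] <- 0
  sums <- row_win_sums(E0, width - 1L, geo$starts)
  nbad <- row_win_sums(bad * 1, width - 1L, geo$starts)
  vals <- ifelse(nbad > 0, NA_real_, sums / (width - 1L))
  profile_track(geo$centers,
                colMeans(vals, na.rm = TRUE),
                colSums(!is.na(vals)),
                statistic = "free_energy", width = width, step = step)
}

#' Classify core promoters by TATA-box and initiator CA
#'
#' A promoter `has_tata` when a TATA-box consensus match (default
#' `TATAWAW`) *starts* at a position in the closed interval
#' `tata_region` (default `[-40, -20]`) relative to the TSS, and `has_ca`
#' when a `CA` dinucleotide occurs with its A at a position in `ca_region`
#' (default `[-2, +2]`, the initiator-style +1 adenine).  Windows too
#' short to span both regions yield a missing call.
#'
#' @param ws A TSS-anchored [window_set()] spanning at least
#'   `[tata_region[1], ca_region[2]]`.
#' @param tata_pattern IUPAC pattern for the TATA-box.
#' @param tata_region,ca_region Closed intervals of allowed positions
#'   (match start for TATA; the A position for CA).
#' @return Data frame with `gene_id`, `has_tata`, `has_ca`, `category`
#'   (`TATA_only`, `CA_only`, `both`, `neither`, or `NA` when missing).
#'   A `summary` attribute reports the fraction with TATA, with CA, with
#'   both, the ratio of TATA-containing to TATA-and-CA-containing
#'   promoters, and the number of missing calls.
#' @export
classify_core_promoters <- function(ws, tata_pattern = "TATAWAW",
                                    tata_region = c(-40, -20),
                                    ca_region = c(-2, 2)) {
  plen <- nchar(tata_pattern)
  tata_rx <- iupac_to_regex(tata_pattern)
  n <- length(ws$sequences)
  has_tata <- has_ca <- rep(NA, n)
  # required span: TATA region start through the end of the CA A-window
  spans <- ws$rel_start <= tata_region[1] &&
    (ws$rel_end - 1) >= ca_region[2]
  if (spans && n > 0L) {
    # substring covering all allowed TATA start positions plus pattern tail
    t_from <- ws_col(ws, tata_region[1])
    t_to <- min(ws_col(ws, tata_region[2]) + plen - 1L,
                ws$rel_end - ws$rel_start)
    tsub <- substr(ws$sequences, t_from, t_to)
    m <- gregexpr(tata_rx, tsub)
    has_tata <- vapply(m, function(mm) {
      any(mm > 0 & (mm - 1L) <= (tata_region[2] - tata_region[1]))
    }, logical(1))
    # CA with A at ca_region  <=>  CA starting at ca_region - 1
    c_from <- ws_col(ws, ca_region[1] - 1L)
    c_to <- ws_col(ws, ca_region[2])
    csub <- substr(ws$sequences, c_from, c_to)
    has_ca <- grepl("CA", csub, fixed = TRUE)
  }
  category <- ifelse(is.na(has_tata), NA_character_,
              ifelse(has_tata & has_ca, "both",
              ifelse(has_tata, "TATA_only",
              ifelse(has_ca, "CA_only", "neither"))))
  calls <- data.frame(gene_id = names(ws$sequences) %||% character(n),
                      has_tata = has_tata, has_ca = has_ca,
                      category = category, stringsAsFactors = FALSE)
  ok <- !is.na(calls$has_tata)
  n_tata <- sum(calls$has_tata[ok])
  n_both <- sum(calls$has_tata[ok] & calls$has_ca[ok])
  attr(calls, "summary") <- list(
    n = sum(ok),
    n_missing = sum(!ok),
    fraction_tata = if (any(ok)) mean(calls$has_tata[ok]) else NA_real_,
    fraction_ca = if (any(ok)) mean(calls$has_ca[ok]) else NA_real_,
    fraction_both = if (any(ok)) mean(calls$has_tata[ok] & calls$has_ca[ok])
                    else NA_real_,
    ratio_tata_to_both = if (n_both > 0) n_tata / n_both else NA_real_
  )
  calls
}
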