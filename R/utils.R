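# Internal helpers shared across modules.

.DNA <- c("A", "C", "G", "T")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_chars <- function(x) {
  out <- .COMP[x]
  out[is.na(out)] <- "N"
  unname(out)
}

revcomp_chars <- function(x) rev(comp_chars(x))

revcomp <- function(s) {
  vapply(s, function(si) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(si)))
  }, character(1), USE.NAMES = FALSE)
}

# i.i.d. background sequence with a given GC content, as a character vector
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return(character(0))
  sample(.DNA, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

base_to_int <- function(x) match(x, .DNA)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Start offsets (1-based, local) of complete sliding windows over a sequence
# of length L.  Only full windows are emitted.
win_starts <- function(L, width, step) {
  if (width > L) return(integer(0))
  seq.int(1L, L - width + 1L, by = step)
}

# Window sums over the rows of a numeric matrix (n sequences x L positions).
# M must be NA-free; mask invalid cells upstream and count them separately.
row_win_sums <- function(M, width, starts) {
  if (length(starts) == 0L) {
    return(matrix(numeric(0), nrow = nrow(M), ncol = 0L))
  }
  cs <- t(apply(M, 1L, cumsum))
  if (nrow(M) == 1L) cs <- matrix(cs, nrow = 1L)
  cs0 <- cbind(0, cs)
  ends <- starts + width - 1L
  cs0[, ends + 1L, drop = FALSE] - cs0[, starts, drop = FALSE]
}

# Window sums of a single per-position count vector.
vec_win_sums <- function(v, width, starts) {
  if (length(starts) == 0L) return(numeric(0))
  cs0 <- c(0, cumsum(v))
  ends <- starts + width - 1L
  cs0[ends + 1L] - cs0[starts]
}

# Expand an IUPAC pattern into a regular expression in which ambiguity codes
# match their base sets but subject Ns never match.
iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) {
    stop("unsupported pattern character(s): ", paste(bad, collapse = ", "))
  }
  paste0(map[chars], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
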