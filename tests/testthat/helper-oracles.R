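# Independent brute-force oracles and tiny fixture builders.  Everything
# here recomputes statistics by a different route (regex, per-base loops,
# full enumeration) than the package implementation.

# all (possibly overlapping) match start positions of an IUPAC pattern;
# subject Ns never match because the classes exclude them
oracle_match_starts <- function(seq, pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
           R = "[AG]", Y = "[CT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rx <- paste0("(?=", paste0(map[strsplit(pattern, "")[[1]]], collapse = ""),
               ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m)
}

# brute-force motif frequency track: per window, count match starts
# inside it over all sequences, divided by the number of sequences
oracle_motif_track <- function(ws, pattern, width, step) {
  L <- ws$rel_end - ws$rel_start
  starts <- seq(1, L - width + 1, by = step)
  all_hits <- lapply(ws$sequences, oracle_match_starts, pattern = pattern)
  vals <- vapply(starts, function(s) {
    sum(vapply(all_hits, function(h) sum(h >= s & h <= s + width - 1), 0))
  }, 0) / length(ws$sequences)
  data.frame(rel_position = ws$rel_start + starts - 1 + (width - 1) / 2,
             value = vals)
}

oracle_skew <- function(s) {
  ch <- strsplit(s, "")[[1]]
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  if (nc + ng == 0) NA_real_ else (nc - ng) / (nc + ng)
}

oracle_skew_track <- function(ws, width, step) {
  L <- ws$rel_end - ws$rel_start
  starts <- seq(1, L - width + 1, by = step)
  vapply(starts, function(s) {
    sk <- vapply(ws$sequences, function(q) {
      oracle_skew(substr(q, s, s + width - 1))
    }, 0)
    mean(sk, na.rm = TRUE)
  }, 0)
}

oracle_energy_track <- function(ws, width, step, dg) {
  L <- ws$rel_end - ws$rel_start
  starts <- seq(1, L - width + 1, by = step)
  vapply(starts, function(s) {
    vals <- vapply(ws$sequences, function(q) {
      sub <- substr(q, s, s + width - 1)
      ch <- strsplit(sub, "")[[1]]
      if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
      steps <- paste0(ch[-length(ch)], ch[-1])
      mean(dg[steps])
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
}

# MATCH similarity score computed directly from the counts, independent
# arithmetic path (no reuse of the pwm object internals)
oracle_match_score <- function(counts, sub, pc = 0.01) {
  f <- sweep(counts + pc, 1, rowSums(counts) + 4 * pc, "/")
  info <- apply(f, 1, function(r) sum(ifelse(r > 0, r * log(4 * r), 0)))
  idx <- match(strsplit(sub, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  cur <- sum(info * f[cbind(seq_along(idx), idx)])
  mn <- sum(info * apply(f, 1, min))
  mx <- sum(info * apply(f, 1, max))
  (cur - mn) / (mx - mn)
}

# per-base CDS coverage fraction
oracle_coverage <- function(gene, evidence) {
  cds_pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i) {
    seq(gene$cds[i, 1], gene$cds[i, 2] - 1)
  }))
  ev <- evidence[evidence$seq_id == gene$seq_id, , drop = FALSE]
  covered <- vapply(cds_pos, function(p) {
    any(p >= ev$start & p < ev$end)
  }, logical(1))
  mean(covered)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_p <- function(x, y) {
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- ustat(x, y)
  combos <- utils::combn(length(pool), n1)
  us <- apply(combos, 2, function(ix) ustat(pool[ix], pool[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# random window set with a sprinkling of Ns
rand_ws <- function(n, L, rel_start = -100, n_rate = 0.02) {
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    nn <- which(runif(L) < n_rate)
    ch[nn] <- "N"
    paste0(ch, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%03d", seq_len(n))
  window_set(seqs, rel_start, rel_start + L, anchor = "tss")
}

# one-gene toy fixture: a 30 bp contig with a gene on the given strand
toy_gene <- function(strand = "+", contig = "ACGTTGCAATGGCCTAAGGCATCGATCGTA") {
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  # CDS occupies [9, 18) on + (ATGGCCTAA) or a 9 bp span on -
  g <- if (strand == "+") {
    gene_model("t1", "chr1", "+", cbind(9, 18))
  } else {
    gene_model("t1", "chr1", "-", cbind(9, 18))
  }
  list(genome = genome, gene = g)
}
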