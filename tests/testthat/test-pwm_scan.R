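# PWM construction, MATCH similarity scoring, and positional hit-density
# tracks.

test_that("PWM files parse and normalize to frequencies", {
  p <- read_pwm(system.file("extdata", "pwm_tata_toy.txt",
                            package = "promtss"))
  expect_s3_class(p, "pwm")
  expect_equal(p$name, "TATA_toy")
  expect_equal(nrow(p$freq), 7)
  expect_equal(unname(rowSums(p$freq)), rep(1, 7), tolerance = 1e-12)
  expect_equal(pwm_consensus(p), "TATAAAA")

  # one-hot counts give the consensus directly
  onehot <- pwm(rbind(c(0, 0, 0, 9), c(9, 0, 0, 0), c(0, 0, 0, 9),
                      c(9, 0, 0, 0)), "t")
  expect_equal(pwm_consensus(onehot), "TATA")

  # uniform matrix has zero information content everywhere
  unif <- pwm(matrix(0.25, nrow = 5, ncol = 4), "u")
  expect_equal(unname(unif$info), rep(0, 5), tolerance = 1e-12)

  # mixed matrix: frequencies match hand normalization with pseudocount
  mixed <- pwm(rbind(c(2, 1, 1, 0)), "m", pseudocount = 0.01)
  expect_equal(unname(mixed$freq[1, ]),
               c(2.01, 1.01, 1.01, 0.01) / 4.04, tolerance = 1e-12)

  bad <- tempfile()
  writeLines(c("NA broken", "01 1 2 x 4"), bad)
  expect_error(read_pwm(bad), "non-numeric")
  zero <- tempfile()
  writeLines(c("NA z", "01 0 0 0 0"), zero)
  expect_error(read_pwm(zero), "positive")
})

test_that("consensus scores 1, anti-consensus 0, and hand cases agree", {
  counts <- rbind(c(8, 2, 0, 0), c(1, 1, 1, 7))
  p <- pwm(counts, "toy")
  expect_equal(match_score(p, pwm_consensus(p)), 1)
  # anti-consensus: lowest-frequency base at each position
  anti <- paste0(c("A", "C", "G", "T")[apply(p$freq, 1, which.min)],
                 collapse = "")
  expect_equal(match_score(p, anti), 0)
  # independent arithmetic for an intermediate word
  expect_equal(match_score(p, "AG"), oracle_match_score(counts, "AG"),
               tolerance = 1e-12)
  expect_true(is.na(match_score(p, "AN")))
  expect_error(match_score(p, "ACG"), "length")
})

test_that("scores are monotone in per-position base frequency", {
  set.seed(83)
  for (rep in 1:5) {
    L <- sample(4:8, 1)
    p <- pwm(matrix(rexp(4 * L), nrow = L), "r")
    word <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    s0 <- match_score(p, paste0(word, collapse = ""))
    for (i in seq_len(L)) {
      better <- c("A", "C", "G", "T")[which.max(p$freq[i, ])]
      w2 <- word; w2[i] <- better
      expect_gte(match_score(p, paste0(w2, collapse = "")) + 1e-12, s0)
    }
  }
})

test_that("window scanning equals brute-force all-offsets evaluation", {
  set.seed(89)
  counts <- matrix(rexp(4 * 5), nrow = 5)
  p <- pwm(counts, "r")
  seqs <- vapply(1:3, function(i) {
    paste0(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                  prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1))
  for (s in seqs) {
    got <- scan_pwm(p, s)
    want <- vapply(1:(nchar(s) - 4), function(o) {
      oracle_match_score(counts, substr(s, o, o + 4))
    }, 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("hit-density tracks recover planted sites on either strand", {
  # a PWM whose consensus is planted at -35 in every sequence, half of
  # them as the reverse complement
  set.seed(97)
  p <- pwm(rbind(c(0, 0, 0, 9), c(9, 0, 0, 0), c(9, 0, 0, 0), c(0, 0, 0, 9),
                 c(0, 0, 9, 0), c(0, 9, 0, 0)), "site")  # TAATGC
  n <- 20
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(c("C", "G"), 150, replace = TRUE)
    site <- strsplit(if (i %% 2) "TAATGC" else "GCATTA", "")[[1]]
    ch[66:71] <- site                      # rel -35 .. -30
    paste0(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  ws <- window_set(seqs, -100, 50)
  dens <- positional_hit_density(ws, p, threshold = 1, width = 20, step = 10)
  tr <- dens$per_pwm[["site"]]
  nz <- tr$rel_position[tr$value > 0]
  expect_true(length(nz) > 0)
  expect_true(all(abs(nz - (-35)) <= 15))

  # threshold 0: every scorable offset is a hit; interior windows saturate
  d0 <- positional_hit_density(ws, p, threshold = 0, width = 20, step = 10)
  expect_equal(max(d0$per_pwm[["site"]]$value), 20)

  # no sequences -> empty but well-formed track
  ws0 <- window_set(character(0), -100, 50)
  d_empty <- positional_hit_density(ws0, p, threshold = 0.9)
  expect_true(all(is.na(d_empty$per_pwm[["site"]]$value)) ||
              all(d_empty$per_pwm[["site"]]$value == 0))
})

test_that("AT-rich planted sites produce the expected peak/trough geometry", {
  set.seed(101)
  taat <- pwm(rbind(c(0, 1, 1, 18), c(18, 1, 1, 0), c(18, 1, 1, 0),
                    c(0, 1, 1, 18)), "HD_toy")       # TAAT core
  gcc <- read_pwm(system.file("extdata", "pwm_gcc_toy.txt",
                              package = "promtss"))
  n <- 60
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                 prob = c(0.2, 0.3, 0.3, 0.2))
    ch[57:64] <- strsplit("TTAATAAT", "")[[1]]       # AT-rich at ~ -40
    ch[99:106] <- strsplit("TAATTAAT", "")[[1]]      # AT-rich at ~ 0
    paste0(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  ws <- window_set(seqs, -100, 50)

  hd <- positional_hit_density(ws, taat, threshold = 0.95, width = 20,
                               step = 10)$per_pwm[["HD_toy"]]
  top2 <- hd$rel_position[order(-hd$value)][1:2]
  expect_true(any(abs(top2 - (-40)) <= 15))
  expect_true(any(abs(top2 - 0) <= 15))

  # a GC-rich motif is depleted where the sequence is AT-rich
  gd <- positional_hit_density(ws, gcc, threshold = 0.8, width = 20,
                               step = 10)$per_pwm[["GCC_toy"]]
  at_windows <- abs(gd$rel_position - (-40)) <= 10 |
    abs(gd$rel_position - 0) <= 10
  expect_lt(mean(gd$value[at_windows]), mean(gd$value[!at_windows]))
})
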