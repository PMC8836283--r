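# Sliding-window motif frequency, CG-skew, free-energy profiles and
# core-promoter classification, checked against brute-force recounts and
# planted promoter architecture.

test_that("motif frequency profile handles degenerate and planted cases", {
  # all-A sequences never match a TATA-box
  ws <- window_set(stats::setNames(rep(strrep("A", 120), 3), paste0("s", 1:3)),
                   -100, 20)
  tr <- motif_frequency_profile(ws, "TATAWAW")
  expect_true(all(tr$value == 0))

  # a single TATAAAA planted at relative -30
  ch <- rep("C", 120)
  ch[(-30 - (-100) + 1):(-30 + 100 + 7)] <- strsplit("TATAAAA", "")[[1]]
  ws1 <- window_set(c(s1 = paste0(ch, collapse = "")), -100, 20)
  tr1 <- motif_frequency_profile(ws1, "TATAWAW")
  nz <- tr1$rel_position[tr1$value > 0]
  # nonzero only in windows whose span contains -30
  expect_true(all(abs(nz - (-30)) <= 9.5))
  expect_true(abs(tr1$rel_position[which.max(tr1$value)] - (-30)) <= 9.5)

  # overlapping CA matches on a CACA... sequence, vs brute force
  ws2 <- window_set(c(s1 = strrep("CA", 60)), -100, 20)
  tr2 <- motif_frequency_profile(ws2, "CA")
  orc <- oracle_motif_track(ws2, "CA", 20, 10)
  expect_equal(tr2$value, orc$value)

  expect_error(motif_frequency_profile(ws, strrep("N", 25)), "longer")
})

test_that("cg_skew matches hand counts and is antisymmetric under revcomp", {
  expect_equal(cg_skew("CCGG"), 0)
  expect_equal(cg_skew("CCCC"), 1)
  expect_equal(cg_skew("GGGG"), -1)
  expect_equal(cg_skew("CCGAT"), 1 / 3)
  expect_true(is.na(cg_skew("ATTA")))
  set.seed(5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:20) {
    ch <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    s <- paste0(ch, collapse = "")
    rc <- paste0(rev(comp[ch]), collapse = "")
    sk <- cg_skew(s)
    expect_gte(sk, -1); expect_lte(sk, 1)
    expect_equal(cg_skew(rc), -sk)
  }
})

test_that("free-energy profile reflects duplex stability", {
  dg <- load_dinucleotide_dg()
  # homopolymer: every step is AA
  wsA <- window_set(c(s1 = strrep("A", 30)), 0, 30)
  trA <- free_energy_profile(wsA, width = 15, step = 1)
  expect_true(all(abs(trA$value - dg[["AA"]]) < 1e-12))

  # AT-rich windows are less stable (less negative) than GC-rich ones
  wsM <- window_set(c(a = strrep("AT", 15), g = strrep("GC", 15)), 0, 30)
  trAT <- free_energy_profile(window_set(c(s = strrep("AT", 15)), 0, 30))
  trGC <- free_energy_profile(window_set(c(s = strrep("GC", 15)), 0, 30))
  expect_gt(trAT$value[1], trGC$value[1])

  # 16 bp sequence, width 15, step 1 -> exactly 2 windows
  ws16 <- window_set(c(s1 = strrep("ACGT", 4)), 0, 16)
  expect_equal(nrow(free_energy_profile(ws16, width = 15, step = 1)), 2)

  expect_error(free_energy_profile(wsA, width = 1), ">= 2")
})

test_that("profile engines equal brute-force recounts on random instances", {
  dg <- load_dinucleotide_dg()
  set.seed(61)
  for (rep in 1:4) {
    ws <- rand_ws(n = 6, L = 400, rel_start = -300, n_rate = 0.02)
    for (pat in c("TATAWAW", "CA", "RGWYV")) {
      got <- motif_frequency_profile(ws, pat, width = 20, step = 10)
      exp_ <- oracle_motif_track(ws, pat, 20, 10)
      expect_equal(got$value, exp_$value)
      expect_equal(got$rel_position, exp_$rel_position)
    }
    got_sk <- cg_skew_profile(ws, width = 50, step = 10)
    expect_equal(got_sk$value, oracle_skew_track(ws, 50, 10))
    got_fe <- free_energy_profile(ws, width = 15, step = 7)
    expect_equal(got_fe$value, oracle_energy_track(ws, 15, 7, dg))
  }
})

test_that("core-promoter calls honor the scored regions", {
  # TATAAAA starting at -30 and CA at [0, +1] -> category 'both'
  mk <- function(tata_at = NULL, ca = FALSE) {
    ch <- rep("G", 150)                      # rel -120 .. +29
    col <- function(rel) rel + 121
    if (!is.null(tata_at)) {
      ch[col(tata_at):(col(tata_at) + 6)] <- strsplit("TATAAAA", "")[[1]]
    }
    if (ca) ch[col(0):col(1)] <- c("C", "A")
    paste0(ch, collapse = "")
  }
  ws <- window_set(c(both = mk(-30, TRUE), tata = mk(-30, FALSE),
                     ca = mk(NULL, TRUE), none = mk(NULL, FALSE),
                     far = mk(-50, FALSE), edge = mk(-20, FALSE)),
                   -120, 30)
  calls <- classify_core_promoters(ws)
  expect_equal(calls$category,
               c("both", "TATA_only", "CA_only", "neither", "neither",
                 "TATA_only"))
  s <- attr(calls, "summary")
  expect_equal(s$fraction_tata, 3 / 6)
  expect_equal(s$fraction_both, 1 / 6)
  expect_equal(s$ratio_tata_to_both, 3)

  # windows not spanning [-40, +2] yield missing calls
  short <- window_set(c(s1 = strrep("A", 30)), -20, 10)
  cs <- classify_core_promoters(short)
  expect_true(is.na(cs$category))
  expect_equal(attr(cs, "summary")$n_missing, 1)
})

test_that("observed motif fractions match configured plant rates at n = 5000", {
  ws <- sim_promoters(5000, sim_config(seed = 71, tata_rate = 0.07,
                                       ca_rate = 0.5))
  s <- attr(classify_core_promoters(ws), "summary")
  ci_tata <- 2.576 * sqrt(0.07 * 0.93 / 5000)
  ci_ca <- 2.576 * sqrt(0.5 * 0.5 / 5000)
  expect_lt(abs(s$fraction_tata - 0.07), ci_tata)
  expect_lt(abs(s$fraction_ca - 0.5), ci_ca)
})

test_that("planted promoter architecture is recovered by the tracks", {
  ws <- sim_promoters(1500, sim_config(seed = 73, tata_rate = 0.2,
                                       tata_offset = 30))
  tata <- motif_frequency_profile(ws, "TATAWAW")
  # argmax within one window step of the planted offset
  expect_lte(abs(tata$rel_position[which.max(tata$value)] - (-30)), 10.5)
  skew <- cg_skew_profile(ws)
  # the skew bump spans +-50 bp around the TSS
  expect_lte(abs(skew$rel_position[which.max(skew$value)]), 50)
  expect_gt(max(skew$value), 0.1)
})
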