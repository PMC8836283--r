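# Gamma prior fitting, density, in-CDS exclusion and best-TSS selection.

test_that("method-of-moments fit follows theta = v/m, k = m/theta", {
  # sample with mean 2 and unbiased variance 2
  x <- c(0, 2, 2, 2, 4)
  fit <- fit_gamma_moments(x)
  expect_equal(fit$theta, 1)
  expect_equal(fit$k, 2)
  # the fit reproduces the sample moments algebraically
  set.seed(3)
  y <- rgamma(500, shape = 1.4, scale = 80)
  f2 <- fit_gamma_moments(y)
  expect_equal(f2$k * f2$theta, mean(y), tolerance = 1e-12)
  expect_equal(f2$k * f2$theta^2, var(y), tolerance = 1e-12)
})

test_that("degenerate or invalid 5'UTR samples are rejected", {
  expect_error(fit_gamma_moments(c(1, 1, 1)), "degenerate")
  expect_error(fit_gamma_moments(c(-1, 2, 3)), "non-negative")
  expect_error(fit_gamma_moments(5), "at least two")
})

test_that("gamma density matches closed forms and handles zero lengths", {
  expect_equal(gamma_pdf(1, gamma_prior(1, 1)), exp(-1), tolerance = 1e-12)
  expect_equal(gamma_pdf(1, gamma_prior(2, 1)), 1 * exp(-1),
               tolerance = 1e-12)
  # independent evaluation of the density formula at the default prior
  k <- 0.62; th <- 238.99
  dens <- function(x) x^(k - 1) * exp(-x / th) / (gamma(k) * th^k)
  expect_equal(gamma_pdf(150), dens(150), tolerance = 1e-12)
  expect_gt(gamma_pdf(150), gamma_pdf(5000))
  # k < 1: a zero-length 5'UTR is evaluated at 1 bp
  expect_equal(gamma_pdf(0), gamma_pdf(1))
  expect_error(gamma_pdf(-5), ">= 0")
})

make_mapped <- function(rel_pos, score,
                        gene_id = "m1", genomic_pos = 1000 + rel_pos) {
  data.frame(gene_id = gene_id, genomic_pos = genomic_pos, strand = "+",
             score = score, rel_pos = rel_pos,
             utr_length = ifelse(rel_pos < 0, -rel_pos, NA_real_),
             in_cds = rel_pos >= 0)
}

test_that("candidates inside the CDS are excluded, upstream ones kept", {
  cand <- make_mapped(c(10, -200), c(0.9, 0.8))
  part <- exclude_in_cds(cand)
  expect_equal(part$kept$rel_pos, -200)
  expect_equal(part$excluded$rel_pos, 10)
  expect_equal(part$excluded_fraction, 0.5)
})

test_that("selection prefers the prior mode and applies deterministic tie-breaks", {
  # single eligible candidate
  one <- make_mapped(-300, 0.5)
  expect_equal(select_best_tss(one)$rel_pos, -300)

  # near-mode 5'UTR beats a far-tail one at equal score
  two <- make_mapped(c(-150, -5000), c(0.7, 0.7))
  expect_equal(select_best_tss(two)$utr_length, 150)

  # identical 5'UTR lengths: higher predictor score wins
  tie <- make_mapped(c(-100, -100), c(0.3, 0.9),
                     genomic_pos = c(900, 901))
  expect_equal(select_best_tss(tie)$score, 0.9)

  # no eligible candidate
  expect_null(select_best_tss(make_mapped(20, 0.9)))

  # rank_by = "score" flips the near/far preference when the far one
  # scores higher
  far_scored <- make_mapped(c(-150, -4000), c(0.2, 0.9))
  expect_equal(select_best_tss(far_scored, rank_by = "score")$utr_length,
               4000)
  expect_equal(select_best_tss(far_scored, rank_by = "pdf")$utr_length, 150)
})

test_that("selection is invariant to candidate order", {
  set.seed(19)
  cand <- make_mapped(rel_pos = -sample(1:2000, 8), score = runif(8))
  ref <- select_best_tss(cand)
  for (i in 1:5) {
    perm <- cand[sample(nrow(cand)), , drop = FALSE]
    expect_equal(select_best_tss(perm)$genomic_pos, ref$genomic_pos)
  }
})

test_that("at most one TSS is selected per gene", {
  sim <- generate_genome(sim_config(n_genes = 60, seed = 23))
  cand <- generate_candidates(sim, candidate_noise(), seed = 24)
  sel <- select_tss(cand, sim$genes)
  expect_lte(nrow(sel), length(sim$genes))
  expect_false(any(duplicated(sel$gene_id)))
})

test_that("prior-based ranking beats a score-only baseline on extreme decoys", {
  # every gene: a true candidate near the prior mode plus far-upstream
  # decoys beyond the 99.9th prior percentile that sometimes outscore it
  cfg <- sim_config(n_genes = 150, seed = 29)
  sim <- generate_genome(cfg)
  noise <- candidate_noise(n_per_gene = 4, decoy_cds_rate = 0,
                           extreme_rate = 0.4)
  cand <- generate_candidates(sim, noise, seed = 30)
  truth <- sim$truth
  acc <- function(sel) {
    j <- match(sel$gene_id, truth$gene_id)
    sum(abs(sel$genomic_pos - truth$true_tss[j]) <= 5) / nrow(truth)
  }
  acc_pdf <- acc(select_tss(cand, sim$genes, rank_by = "pdf"))
  acc_score <- acc(select_tss(cand, sim$genes, rank_by = "score"))
  expect_gt(acc_pdf, acc_score)
  expect_gt(acc_pdf, 0.9)
})
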