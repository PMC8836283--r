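# Coordinate conventions, GFF3 parsing, window extraction, track and BED
# round trips.

write_gff_lines <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 1-based closed coordinates convert to 0-based half-open", {
  f <- write_gff_lines(c(
    "chr1\t.\tgene\t11\t19\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t11\t19\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\t.\tCDS\t11\t19\t.\t+\t0\tID=c1;Parent=m1"))
  genes <- read_gff3(f)
  expect_length(genes, 1)
  g <- genes[["m1"]]
  expect_equal(unname(g$cds[1, ]), c(10, 19))
  expect_equal(spliced_cds_length(g), 9)
  expect_equal(start_codon_pos(g), 10)
  # exons synthesized from the CDS when absent
  expect_equal(unname(g$exons), unname(g$cds))
})

test_that("minus-strand start codon is the last base of the CDS span", {
  f <- write_gff_lines(c(
    "chr1\t.\tmRNA\t101\t109\t.\t-\t.\tID=m1",
    "chr1\t.\tCDS\t101\t109\t.\t-\t0\tID=c1;Parent=m1"))
  g <- read_gff3(f)[["m1"]]
  expect_equal(unname(g$cds[1, ]), c(100, 109))
  expect_equal(start_codon_pos(g), 108)
})

test_that("empty and malformed GFF3 inputs are handled", {
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_length(read_gff3(empty), 0)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\t.\tCDS\t11"), bad)
  expect_error(read_gff3(bad), "line 2")

  orphan <- write_gff_lines(c(
    "chr1\t.\tmRNA\t101\t109\t.\t+\t.\tID=m1",
    "chr1\t.\tCDS\t101\t109\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\t.\tCDS\t201\t209\t.\t+\t0\tID=c2;Parent=ghost"))
  expect_warning(genes <- read_gff3(orphan), "skipped")
  expect_equal(attr(genes, "n_skipped"), 1L)
  expect_length(genes, 1)
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("x", "c", "+", cbind(10, 10)), "start >= end")
  expect_error(gene_model("x", "c", "+", rbind(c(0, 10), c(5, 20))),
               "overlapping")
  expect_error(gene_model("x", "c", "+", cbind(0, 10), exons = cbind(2, 10)),
               "not contained")
  expect_error(gene_model("x", "c", "+", cbind(0, 10)), "multiple of 3")
  expect_silent(gene_model("x", "c", "+", cbind(0, 10),
                           coding_complete = FALSE))
})

test_that("plus-strand window extraction slices the expected genomic range", {
  contig <- paste0(rep("ACGT", 2500), collapse = "")  # 10 kb
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  g <- gene_model("m1", "chr1", "+", cbind(1500, 1509))
  w <- extract_window(genome, g, "start_codon", -1000, 250)
  expect_equal(nchar(w$sequence), 1250)
  expect_false(w$truncated)
  expect_equal(w$sequence, substr(contig, 501, 1750))  # [500, 1750) 0-based
})

test_that("minus-strand window extraction reverse-complements a toy contig", {
  contig <- "ACGTTGCAATGGCCTAAGGCATCGATCGTA"  # 30 bp
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  g <- gene_model("m1", "chr1", "-", cbind(9, 18))  # start codon at 17
  w <- extract_window(genome, g, "start_codon", -3, 2)
  # hand derivation: rel r maps to genomic 17 - r; rel -3..+1 are genomic
  # positions 20,19,18,17,16 -> complement of those bases in order
  chars <- strsplit(contig, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expected <- paste0(comp[chars[c(21, 20, 19, 18, 17)]], collapse = "")
  expect_equal(w$sequence, expected)
})

test_that("out-of-contig window positions are N-filled and flagged", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  g <- gene_model("m1", "chr1", "+", cbind(100, 109))
  w <- extract_window(genome, g, "start_codon", -1000, 250)
  expect_true(w$truncated)
  expect_equal(nchar(w$sequence), 1250)
  expect_equal(substr(w$sequence, 1, 900), strrep("N", 900))
  expect_false(grepl("N", substr(w$sequence, 901, 1250)))
})

test_that("relative position 0 round-trips to the anchor base on both strands", {
  set.seed(11)
  contig <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (strand in c("+", "-")) {
    for (a in c(120, 250, 301)) {
      cds <- if (strand == "+") cbind(a, a + 9) else cbind(a - 8, a + 1)
      g <- gene_model("m1", "chr1", strand, cds)
      expect_equal(start_codon_pos(g), a)
      w <- extract_window(genome, g, "start_codon", 0, 1)
      base <- substr(contig, a + 1, a + 1)
      expect_equal(w$sequence,
                   if (strand == "+") base else unname(comp[base]))
    }
  }
})

test_that("track TSV and BED round-trip exactly", {
  tr <- profile_track(c(-40.5, -30.5, -20.5), c(0.1, 0.25, 0),
                      c(10L, 10L, 10L), statistic = "motif_freq:TATAWAW",
                      width = 20, step = 10)
  f <- tempfile(fileext = ".tsv")
  write_track_tsv(tr, f)
  tr2 <- read_track_tsv(f)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
  expect_equal(attr(tr2, "statistic"), attr(tr, "statistic"))
  expect_equal(attr(tr2, "width"), attr(tr, "width"))

  # header-only file for an empty track
  tr0 <- profile_track(numeric(0), numeric(0), integer(0), "cg_skew", 50, 10)
  f0 <- tempfile(fileext = ".tsv")
  write_track_tsv(tr0, f0)
  expect_equal(nrow(read_track_tsv(f0)), 0)

  bed <- data.frame(seq_id = rep("ctg001", 5),
                    start = c(0L, 10L, 25L, 100L, 1000L),
                    end = c(5L, 20L, 75L, 400L, 1200L),
                    name = paste0("iv", 1:5), score = 1:5,
                    strand = c("+", "-", "+", "-", "+"))
  fb <- tempfile(fileext = ".bed")
  write_bed(bed, fb)
  bed2 <- read_bed(fb)
  expect_equal(bed2[, c("seq_id", "start", "end", "strand")],
               bed[, c("seq_id", "start", "end", "strand")])
})
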