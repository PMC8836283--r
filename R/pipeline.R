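# End-to-end orchestration: evidence filtering -> candidate mapping ->
# in-CDS exclusion -> per-gene TSS selection -> TSS-centered profiling,
# PWM scanning and GC3 analytics, with a YAML config, per-stage counts
# and deterministic outputs.

#' Build a pipeline configuration
#'
#' Defaults follow the windows and parameters the analysis is defined
#' over: candidate search windows of -1000/+250 bp around the start
#' codon, profiling windows of -1000/+200 bp around the TSS, the default
#' gamma 5'UTR prior (0.62, 238.99), motif windows of width 20 / step
#' 10, CG-skew windows of width 50 / step 10, a 15 bp free-energy window
#' and 10%/90% GC3 class quantiles.
#'
#' @param genome,gff3,candidates Paths to the genome FASTA, GFF3
#'   annotation and candidate TSV.
#' @param evidence Optional evidence BED path (`NULL` skips the support
#'   filter).
#' @param pwms Optional character vector of PWM flat-file paths.
#' @param families Optional named vector mapping PWM name to family.
#' @param out_dir Output directory.
#' @param codon_window,tss_window Length-2 windows (rel_start, rel_end).
#' @param gamma_k,gamma_theta Gamma prior parameters.
#' @param utr_lengths_file Optional file of 5'UTR lengths (one per line)
#'   to refit the prior from, overriding `gamma_k`/`gamma_theta`.
#' @param rank_by,min_pdf_quantile Passed to [select_tss()].
#' @param min_support_fraction Passed to [compute_support()].
#' @param pwm_threshold Similarity threshold for [positional_hit_density()].
#' @param motif_width,motif_step,skew_width,skew_step,energy_width Window
#'   geometries for the profile tracks.
#' @param q_low,q_high GC3 class quantiles.
#' @param seed RNG seed recorded for provenance.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff3, candidates, evidence = NULL,
                            pwms = NULL, families = NULL,
                            out_dir = "promtss_out",
                            codon_window = c(-1000, 250),
                            tss_window = c(-1000, 200),
                            gamma_k = 0.62, gamma_theta = 238.99,
                            utr_lengths_file = NULL,
                            rank_by = "pdf", min_pdf_quantile = NULL,
                            min_support_fraction = 0.5,
                            pwm_threshold = 0.85,
                            motif_width = 20, motif_step = 10,
                            skew_width = 50, skew_step = 10,
                            energy_width = 15,
                            q_low = 0.10, q_high = 0.90, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full promoter-annotation pipeline
#'
#' Stage order: read inputs -> evidence support filter -> map candidates
#' -> exclude in-CDS candidates -> select one TSS per gene by the gamma
#' prior -> extract TSS-centered windows -> motif / CG-skew /
#' free-energy profiles and core-promoter classification -> optional PWM
#' hit-density tracks -> GC3 analytics.  All outputs are written under
#' `config$out_dir` together with a config snapshot and a JSON manifest
#' of per-stage counts; reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(cfg$out_dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)

  genome <- read_genome(cfg$genome)
  genes <- read_gff3(cfg$gff3)
  counts <- list(genes_in = length(genes))

  # --- evidence support -------------------------------------------------
  if (!is.null(cfg$evidence)) {
    ev <- read_bed(cfg$evidence)
    support <- compute_support(genes, ev, cfg$min_support_fraction)
    utils::write.table(support, file.path(cfg$out_dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- genes[support$gene_id[support$supported]]
  }
  counts$genes_supported <- length(genes)

  # --- prior ------------------------------------------------------------
  prior <- if (!is.null(cfg$utr_lengths_file)) {
    fit_gamma_moments(scan(cfg$utr_lengths_file, what = numeric(),
                           quiet = TRUE))
  } else {
    gamma_prior(cfg$gamma_k, cfg$gamma_theta)
  }

  # --- candidate mapping, exclusion, selection --------------------------
  cand <- read_candidates(cfg$candidates)
  known <- cand$gene_id %in% names(genes)
  counts$candidates_dropped_unsupported <- sum(!known)
  cand <- map_candidates(cand[known, , drop = FALSE], genes)
  counts$candidates <- nrow(cand)
  selected <- select_tss(cand, genes, prior, rank_by = cfg$rank_by,
                         min_pdf_quantile = cfg$min_pdf_quantile)
  counts$excluded_in_cds_fraction <- attr(selected, "excluded_fraction")
  counts$selected_tss <- nrow(selected)
  utils::write.table(selected, file.path(cfg$out_dir, "selected_tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(selected)) {
    write_bed(data.frame(seq_id = selected$seq_id,
                         start = selected$genomic_pos,
                         end = selected$genomic_pos + 1L,
                         name = selected$gene_id, score = selected$score,
                         strand = selected$strand),
              file.path(cfg$out_dir, "selected_tss.bed"))
    write_tss_gff3(selected, file.path(cfg$out_dir, "selected_tss.gff3"))
  }

  # --- TSS-centered profiling -------------------------------------------
  tssv <- stats::setNames(selected$genomic_pos, selected$gene_id)
  ws <- extract_windows(genome, genes[selected$gene_id], anchor = "tss",
                        rel_start = cfg$tss_window[1],
                        rel_end = cfg$tss_window[2], tss = tssv)
  tracks <- list(
    tata = motif_frequency_profile(ws, "TATAWAW", cfg$motif_width,
                                   cfg$motif_step),
    ca = motif_frequency_profile(ws, "CA", cfg$motif_width, cfg$motif_step),
    cg_skew = cg_skew_profile(ws, cfg$skew_width, cfg$skew_step),
    free_energy = free_energy_profile(ws, cfg$energy_width)
  )
  for (nm in names(tracks)) {
    write_track_tsv(tracks[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }
  calls <- classify_core_promoters(ws)
  utils::write.table(calls, file.path(cfg$out_dir, "core_promoter_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$core_promoter <- attr(calls, "summary")

  # --- PWM scanning (optional) ------------------------------------------
  if (!is.null(cfg$pwms) && length(cfg$pwms)) {
    pwm_list <- lapply(cfg$pwms, read_pwm)
    dens <- positional_hit_density(ws, pwm_list,
                                   threshold = cfg$pwm_threshold,
                                   width = cfg$motif_width,
                                   step = cfg$motif_step,
                                   families = cfg$families)
    for (nm in names(dens$per_pwm)) {
      write_track_tsv(dens$per_pwm[[nm]],
                      file.path(tdir, paste0("pwm_", nm, ".tsv")))
    }
    for (nm in names(dens$per_family)) {
      write_track_tsv(dens$per_family[[nm]],
                      file.path(tdir, paste0("family_", nm, ".tsv")))
    }
  }

  # --- GC3 analytics ----------------------------------------------------
  rec <- gc3_records(genes, genome)
  counts$gc3_mean <- mean(rec$gc3)
  counts$gc3_sd <- stats::sd(rec$gc3)
  cds_seqs <- vapply(genes[rec$gene_id], spliced_cds, character(1),
                     genome = genome)
  grad <- gc3_positional_gradient(cds_seqs)
  write_track_tsv(grad, file.path(tdir, "gc3_gradient.tsv"))
  counts$gc3_gradient_slope <- gradient_slope(cds_seqs)
  if (nrow(rec) >= 10L) {
    rec <- assign_gc3_classes(rec, cfg$q_low, cfg$q_high)
    cmp_len <- compare_classes(rec, "cds_length")
    cmp_ex <- compare_classes(rec, "n_exons")
    counts$cds_length_comparison <- list(
      U = cmp_len$test$U, p_value = cmp_len$test$p_value,
      median_poor = cmp_len$median_poor, median_rich = cmp_len$median_rich)
    counts$n_exons_comparison <- list(
      U = cmp_ex$test$U, p_value = cmp_ex$test$p_value)
  }
  utils::write.table(rec, file.path(cfg$out_dir, "gc3_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- provenance -------------------------------------------------------
  snap <- file.path(cfg$out_dir, "config.yaml")
  write_pipeline_config(cfg, snap)
  manifest <- list(
    package = "promtss",
    version = as.character(utils::packageVersion("promtss")),
    config_hash = unname(tools::md5sum(snap)),
    prior = list(k = prior$k, theta = prior$theta),
    counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
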