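#' Run the full footprint-profiling pipeline and write its output bundle
#'
#' Orchestrates one profiling run: scan the regions with the motif, index
#' the reads' 5' ends, build the per-site coverage matrix, aggregate the
#' footprint profile, compute the permuted-motif envelope, and write every
#' artifact to `out_dir`: `hits.bed`, `matrix.tsv`, `profile.tsv`,
#' `envelope.tsv`, plots (`profile.pdf`, `heatmap.pdf`, `sequences.pdf`),
#' and a machine-readable `manifest.json` recording all parameters so a
#' rerun with the same manifest reproduces the numeric outputs bit for bit.
#' Every number that is plotted is also present in a TSV.
#'
#' @param genome FASTA path, `FaFile`, or named `DNAStringSet`.
#' @param regions BED path or `GRanges` of bound regions.
#' @param reads BAM/BED6 path or `GRanges` of aligned reads.
#' @param motif a `pwm`, a `consensus_pattern`, or a motif file path (with
#'   `motif_format`).
#' @param out_dir output directory, created if needed.
#' @param p motif-match p-value for PWM scanning.
#' @param flank flank width in bp around the motif.
#' @param n_perm permutations for the null envelope (PWM motifs only; set 0
#'   to skip).
#' @param min_mapq,dedup read filters, see [build_five_prime_index()].
#' @param seed master seed; all randomness in the run flows from it.
#' @param motif_format motif file dialect when `motif` is a path; the first
#'   motif in the file is used.
#' @param plots write PDF plots (TRUE by default).
#' @return invisibly, a list with the in-memory results (`hits`, `index`,
#'   `matrix`, `profile`, `envelope`, `paths`).
#' @export
run_profile <- function(genome, regions, reads, motif, out_dir,
                        p = 1e-4, flank = 30, n_perm = 50,
                        min_mapq = 1, dedup = FALSE, seed = 1,
                        motif_format = "jaspar", plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[exofootprint] ", ...)

  manifest <- list(
    subcommand = "profile",
    genome = if (is.character(genome)) genome else "<in-memory>",
    regions = if (is.character(regions)) regions else "<in-memory>",
    reads = if (is.character(reads)) reads else "<in-memory>",
    motif = if (is.character(motif)) motif else "<in-memory>",
    p = p, flank = flank, n_perm = n_perm, min_mapq = min_mapq,
    dedup = dedup, seed = seed)

  genome <- genome_handle(genome)
  if (is.character(regions)) regions <- read_regions_bed(regions)
  log_stage("regions read: ", length(regions))
  if (is.character(motif)) {
    motif <- read_motifs(motif, motif_format)[[1]]
  }
  is_pwm <- is(motif, "pwm")
  manifest$motif_id <- if (is_pwm) motif$motif_id else motif$pattern

  hits <- if (is_pwm) {
    scan_regions(genome, regions, motif, p)
  } else {
    scan_regions_consensus(genome, regions, motif)
  }
  log_stage("motif hits found: ", length(hits))
  if (length(hits) == 0) stop("no motif hits in the given regions")

  if (is.character(reads)) reads <- read_alignments(reads)
  index <- build_five_prime_index(reads,
                                  seqlengths = genome_seqlengths(genome),
                                  min_mapq = min_mapq, dedup = dedup)
  log_stage("reads indexed: ", index$n_reads)

  mat <- site_coverage_matrix(index, hits, flank)
  prof <- aggregate_footprint(mat)
  env <- NULL
  if (is_pwm && n_perm >= 2) {
    env <- permutation_envelope(genome, regions, index, motif, p, flank,
                                n_perm, seed)
    ct <- coverage_pvalue(prof, env, motif$motif_id)
    manifest$coverage_p_value <- ct$p_value
    manifest$enrichment <- ct$enrichment
    log_stage(sprintf("coverage p = %.4g, enrichment %.2f",
                      ct$p_value, ct$enrichment))
  }
  manifest$n_sites <- n_sites(mat)
  manifest$coherence <- profile_coherence(prof)

  paths <- c(hits = file.path(out_dir, "hits.bed"),
             matrix = file.path(out_dir, "matrix.tsv"),
             profile = file.path(out_dir, "profile.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  export_hits_bed(hits, paths["hits"])
  ord <- order(-site_totals(mat))
  mat_sorted <- mat
  mat_sorted$values <- mat$values[ord, , , drop = FALSE]
  mat_sorted$hits <- mat$hits[ord]
  export_matrix_tsv(mat_sorted, paths["matrix"])
  export_profile_tsv(prof, paths["profile"])
  if (!is.null(env)) {
    paths["envelope"] <- file.path(out_dir, "envelope.tsv")
    export_envelope_tsv(env, paths["envelope"])
  }
  if (plots) {
    ggsave(file.path(out_dir, "profile.pdf"),
           plot_footprint(prof, env), width = 7, height = 4)
    ggsave(file.path(out_dir, "heatmap.pdf"),
           plot_site_heatmap(mat), width = 7, height = 6)
    ggsave(file.path(out_dir, "sequences.pdf"),
           plot_sequence_chart(mat), width = 5, height = 6)
  }
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(hits = hits, index = index, matrix = mat, profile = prof,
                 envelope = env, paths = paths))
}

#' Rank a motif library and write the ranking report
#'
#' Thin orchestration over [rank_motifs()]: reads inputs from paths if
#' needed, writes `ranking.tsv` (motif_id, n_sites, observed, enrichment,
#' p_value, coherence) and a parameter manifest.
#'
#' @inheritParams run_profile
#' @param motifs list of `pwm`s or a motif file path (all motifs used).
#' @return invisibly, the ranking data.frame.
#' @export
run_rank <- function(genome, regions, reads, motifs, out_dir,
                     p = 1e-4, flank = 30, n_perm = 50, min_mapq = 1,
                     dedup = FALSE, seed = 1, motif_format = "jaspar") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subcommand = "rank", p = p, flank = flank,
                   n_perm = n_perm, min_mapq = min_mapq, dedup = dedup,
                   seed = seed)
  genome <- genome_handle(genome)
  if (is.character(regions)) regions <- read_regions_bed(regions)
  if (is.character(motifs)) motifs <- read_motifs(motifs, motif_format)
  if (is.character(reads)) reads <- read_alignments(reads)
  index <- build_five_prime_index(reads,
                                  seqlengths = genome_seqlengths(genome),
                                  min_mapq = min_mapq, dedup = dedup)
  ranking <- rank_motifs(genome, regions, index, motifs, p, flank,
                         n_perm, seed)
  write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$n_motifs <- nrow(ranking)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ranking)
}

#' Simulate a ChIP-exo dataset and write it to disk
#'
#' Convenience wrapper: [simulate_genome_with_sites()],
#' [simulate_exo_reads()], [write_sim_bundle()], plus a manifest.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory.
#' @return invisibly, list with `sim`, `reads`, `paths`.
#' @export
run_simulate <- function(cfg, out_dir) {
  sim <- simulate_genome_with_sites(cfg)
  reads <- simulate_exo_reads(sim)
  paths <- write_sim_bundle(sim, reads, out_dir)
  manifest <- cfg[setdiff(names(cfg), "motif")]
  manifest$motif <- if (is(cfg$motif, "pwm")) cfg$motif$motif_id else
    cfg$motif$pattern
  manifest$subcommand <- "simulate"
  manifest$n_reads <- length(reads)
  manifest$crosslink_offsets <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, reads = reads, paths = paths))
}
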