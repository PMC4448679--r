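#' Configuration for the synthetic ChIP-exo simulator
#'
#' Describes a toy genome with planted motif sites inside peak regions and a
#' generative model of ChIP-exo reads: each signal read picks a protein:DNA
#' cross-link point from a mixture of offsets around the site anchor, and its
#' 5' end stops a few bases upstream of the cross-link on the protected
#' strand, emulating lambda exonuclease digestion halting at the
#' cross-linked protein. "Upstream" is read on the protected strand's own
#' 5'-to-3' axis: smaller coordinate on the forward strand, larger on the
#' reverse strand.
#'
#' The default cross-link mixture has a dominant outer pair at +/-8 bp
#' (one cross-link per monomer of a dimeric factor, each protecting the
#' strand running into the site) and a minor inner pair at +/-3 bp,
#' producing the characteristic nested peak-pairs of a dimeric footprint.
#' The exonuclease stop distance defaults to 5-6 bp, drawn uniformly.
#'
#' @param genome_length chromosome length in bp.
#' @param n_peaks number of non-overlapping peak regions.
#' @param peak_width peak width in bp; must accommodate the motif plus
#'   2 x (max |offset| + max stop). Default 200, a typical ChIP-seq peak
#'   span: peaks much wider than the motif are essential for the
#'   permuted-motif control, since in motif-sized peaks every chance match
#'   of a shuffled motif would still sit on top of the true footprint.
#' @param motif a `pwm` or `consensus_pattern` to plant, one instance at
#'   each peak center. Default: the 15-bp inverted-repeat glucocorticoid
#'   receptor binding sequence `"nGnACAnnnTGTnCn"`.
#' @param site_strand_prob probability a planted site is on the minus
#'   strand. Default 0.5.
#' @param crosslink_offsets data.frame with columns `offset` (bp relative to
#'   the site anchor, signed on the motif's own orientation), `strand`
#'   (`"forward"`/`"reverse"`, the protected strand), `weight` (mixture
#'   weights, normalized to sum to 1).
#' @param stop_offset integer vector of exonuclease stop distances (bp
#'   upstream of the cross-link); one value is drawn uniformly per read.
#'   Default `5:6`.
#' @param reads_per_site mean signal reads per site (Poisson). Default 20.
#' @param background_rate background reads per bp, placed uniformly with
#'   uniform strand. Default 0.001.
#' @param read_length read length in bp. Default 36.
#' @param plant `"sample"` draws the planted sequence from the motif model
#'   (PWM columns, or uniform over allowed bases for a consensus pattern);
#'   `"consensus"` plants the per-column argmax of a PWM.
#' @param seed master RNG seed for the whole simulation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000,
                       n_peaks = 500,
                       peak_width = 200,
                       motif = consensus_pattern("nGnACAnnnTGTnCn"),
                       site_strand_prob = 0.5,
                       crosslink_offsets = data.frame(
                         offset = c(-8L, 8L, -3L, 3L),
                         strand = c("forward", "reverse",
                                    "forward", "reverse"),
                         weight = c(0.35, 0.35, 0.15, 0.15)),
                       stop_offset = 5:6,
                       reads_per_site = 20,
                       background_rate = 0.001,
                       read_length = 36,
                       plant = c("sample", "consensus"),
                       seed = 1) {
  plant <- match.arg(plant)
  stopifnot(genome_length > 0, n_peaks > 0, peak_width > 0,
            site_strand_prob >= 0, site_strand_prob <= 1,
            all(stop_offset >= 0), reads_per_site >= 0,
            background_rate >= 0, read_length > 0)
  if (!is(motif, "pwm") && !is(motif, "consensus_pattern")) {
    stop("'motif' must be a pwm or consensus_pattern")
  }
  co <- crosslink_offsets
  if (!all(c("offset", "strand", "weight") %in% names(co))) {
    stop("'crosslink_offsets' needs columns offset, strand, weight")
  }
  if (!all(co$strand %in% c("forward", "reverse"))) {
    stop("crosslink offset strand must be 'forward' or 'reverse'")
  }
  if (any(co$weight < 0) || sum(co$weight) <= 0) {
    stop("crosslink offset weights must be non-negative and sum > 0")
  }
  co$weight <- co$weight / sum(co$weight)
  structure(
    list(genome_length = as.integer(genome_length),
         n_peaks = as.integer(n_peaks),
         peak_width = as.integer(peak_width), motif = motif,
         site_strand_prob = site_strand_prob, crosslink_offsets = co,
         stop_offset = as.integer(stop_offset),
         reads_per_site = reads_per_site,
         background_rate = background_rate,
         read_length = as.integer(read_length),
         plant = plant, seed = as.integer(seed)),
    class = "sim_config"
  )
}

motif_sim_length <- function(motif) {
  if (is(motif, "pwm")) pwm_length(motif) else pattern_length(motif)
}

# one planted sequence on the motif's own strand
sample_planted_seq <- function(motif, plant) {
  if (is(motif, "pwm")) {
    if (plant == "consensus") return(pwm_consensus(motif))
    b <- apply(motif$probs, 2, function(p) sample(DNA_BASES, 1, prob = p))
    return(paste(b, collapse = ""))
  }
  b <- sample(DNA_BASES, pattern_length(motif), replace = TRUE)
  for (i in motif$constrained) {
    b[i] <- sample(IUPAC_SETS[[motif$chars[i]]], 1)
  }
  for (i in motif$anti_positions) {
    b[i] <- sample(setdiff(DNA_BASES, IUPAC_SETS[[motif$chars[i]]]), 1)
  }
  paste(b, collapse = "")
}

#' Simulate a genome with planted motif sites in peaks
#'
#' Draws an i.i.d. background genome (single chromosome `chrS`), places
#' `n_peaks` non-overlapping peaks, and plants one motif instance at each
#' peak center on a randomly chosen strand. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @param background length-4 base probabilities for the background genome.
#' @return object of class `exo_simulation`: list with `genome` (named
#'   `DNAStringSet`), `peaks` (`GRanges`), `sites` (`GRanges` truth with
#'   strand and metadata `anchor`, `planted_seq`, `peak_id`), and `cfg`.
#' @export
simulate_genome_with_sites <- function(cfg, background = rep(0.25, 4)) {
  stopifnot(is(cfg, "sim_config"))
  L <- motif_sim_length(cfg$motif)
  need <- L + 2L * (max(abs(cfg$crosslink_offsets$offset)) +
                      max(cfg$stop_offset))
  if (cfg$peak_width < need) {
    stop("peak_width (", cfg$peak_width, ") must be >= motif length + ",
         "2 x (max offset + max stop) = ", need)
  }
  spacing <- cfg$genome_length %/% cfg$n_peaks
  if (spacing < cfg$peak_width) {
    stop("cannot place ", cfg$n_peaks, " non-overlapping peaks of width ",
         cfg$peak_width, " in ", cfg$genome_length, " bp")
  }
  seeds <- derive_seeds(cfg$seed, 2)
  sim <- withr::with_seed(seeds[1], {
    bases <- sample(DNA_BASES, cfg$genome_length, replace = TRUE,
                    prob = background / sum(background))
    jitter <- sample.int(spacing - cfg$peak_width + 1L, cfg$n_peaks,
                         replace = TRUE) - 1L
    peak_start <- (seq_len(cfg$n_peaks) - 1L) * spacing + 1L + jitter
    site_start <- peak_start + (cfg$peak_width - L) %/% 2L
    minus <- stats::runif(cfg$n_peaks) < cfg$site_strand_prob
    planted <- vapply(seq_len(cfg$n_peaks), function(i) {
      sample_planted_seq(cfg$motif, cfg$plant)
    }, character(1))
    genomic_seq <- ifelse(
      minus,
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(planted))),
      planted)
    for (i in seq_len(cfg$n_peaks)) {
      bases[site_start[i]:(site_start[i] + L - 1L)] <-
        strsplit(genomic_seq[i], "")[[1]]
    }
    list(bases = bases, peak_start = peak_start, site_start = site_start,
         minus = minus, planted = planted)
  })
  genome <- Biostrings::DNAStringSet(paste(sim$bases, collapse = ""))
  names(genome) <- "chrS"
  sl <- c(chrS = cfg$genome_length)
  peaks <- GRanges("chrS",
                   IRanges(sim$peak_start, width = cfg$peak_width),
                   seqlengths = sl)
  sites <- GRanges("chrS", IRanges(sim$site_start, width = L),
                   strand = ifelse(sim$minus, "-", "+"), seqlengths = sl)
  mcols(sites)$anchor <- sim$site_start + L %/% 2L
  mcols(sites)$planted_seq <- sim$planted
  mcols(sites)$peak_id <- seq_len(cfg$n_peaks)
  motif_id <- if (is(cfg$motif, "pwm")) cfg$motif$motif_id else
    cfg$motif$pattern
  mcols(sites)$motif_id <- motif_id
  structure(list(genome = genome, peaks = peaks, sites = sites, cfg = cfg),
            class = "exo_simulation")
}

#' @export
print.exo_simulation <- function(x, ...) {
  cat("ChIP-exo simulation:", x$cfg$genome_length, "bp genome,",
      length(x$peaks), "peaks,", length(x$sites), "planted sites\n")
  invisible(x)
}

#' Simulate ChIP-exo reads over a planted-site genome
#'
#' Per site, Poisson(`reads_per_site`) signal reads are emitted. Each read
#' draws a (cross-link offset, protected strand) from the configured mixture
#' (mirrored when the site is on the minus strand), draws a stop distance,
#' and places its 5' end that many bases upstream of the cross-link on the
#' protected strand; the read extends `read_length` bp 3'-ward, truncated at
#' chromosome ends. Background reads are placed uniformly with uniform
#' strand at `background_rate` reads per bp. Deterministic given
#' `cfg$seed`.
#'
#' @param sim an `exo_simulation` from [simulate_genome_with_sites()].
#' @return `GRanges` of reads with truth metadata columns `origin` (site
#'   index, NA for background), `offset` (signed cross-link offset actually
#'   used, on genome orientation), and `stop` (stop distance). Every emitted
#'   read appears in exactly one truth record.
#' @export
simulate_exo_reads <- function(sim) {
  stopifnot(is(sim, "exo_simulation"))
  cfg <- sim$cfg
  len <- cfg$genome_length
  rl <- cfg$read_length
  seeds <- derive_seeds(cfg$seed, 3)
  withr::with_seed(seeds[3], {
    anchors <- mcols(sim$sites)$anchor
    minus <- as.character(strand(sim$sites)) == "-"
    nreads <- rpois(length(anchors), cfg$reads_per_site)
    origin <- rep(seq_along(anchors), nreads)
    n_sig <- length(origin)
    co <- cfg$crosslink_offsets
    comp <- if (n_sig > 0) {
      sample.int(nrow(co), n_sig, replace = TRUE, prob = co$weight)
    } else integer(0)
    off <- co$offset[comp]
    prot <- co$strand[comp]
    flip <- minus[origin]
    off[flip] <- -off[flip]
    prot[flip] <- ifelse(prot[flip] == "forward", "reverse", "forward")
    stopd <- if (length(cfg$stop_offset) == 1) {
      rep(cfg$stop_offset, n_sig)
    } else {
      sample(cfg$stop_offset, n_sig, replace = TRUE)
    }
    crosslink <- anchors[origin] + off
    fivep <- ifelse(prot == "forward", crosslink - stopd, crosslink + stopd)

    n_bg <- rpois(1, cfg$background_rate * len)
    bg5 <- if (n_bg > 0) sample.int(len, n_bg, replace = TRUE) else integer(0)
    bg_prot <- if (n_bg > 0) {
      sample(c("forward", "reverse"), n_bg, replace = TRUE)
    } else character(0)

    all5 <- c(fivep, bg5)
    all_prot <- c(prot, bg_prot)
    all_origin <- c(origin, rep(NA_integer_, n_bg))
    all_off <- c(off, rep(NA_integer_, n_bg))
    all_stop <- c(stopd, rep(NA_integer_, n_bg))
    ok <- all5 >= 1 & all5 <= len
    all5 <- all5[ok]; all_prot <- all_prot[ok]
    all_origin <- all_origin[ok]; all_off <- all_off[ok]
    all_stop <- all_stop[ok]

    fwd <- all_prot == "forward"
    starts <- ifelse(fwd, all5, pmax(1L, all5 - rl + 1L))
    ends <- ifelse(fwd, pmin(len, all5 + rl - 1L), all5)
    reads <- GRanges("chrS", IRanges(starts, ends),
                     strand = ifelse(fwd, "+", "-"),
                     seqlengths = c(chrS = len))
    mcols(reads)$origin <- all_origin
    mcols(reads)$offset <- all_off
    mcols(reads)$stop <- all_stop
    reads
  })
}

#' Write a simulation bundle to disk as plain-text files
#'
#' Writes `genome.fa` (FASTA), `peaks.bed` (BED3), `reads.bed` (BED6; name
#' is the originating site index or `bg`), and `sites.tsv` (truth table).
#'
#' @param sim an `exo_simulation`.
#' @param reads read `GRanges` from [simulate_exo_reads()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_sim_bundle <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             peaks = file.path(dir, "peaks.bed"),
             reads = file.path(dir, "reads.bed"),
             sites = file.path(dir, "sites.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write.table(
    data.frame(chrom = as.character(seqnames(sim$peaks)),
               start = start(sim$peaks) - 1L, end = end(sim$peaks)),
    paths["peaks"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  origin <- mcols(reads)$origin
  write.table(
    data.frame(chrom = as.character(seqnames(reads)),
               start = start(reads) - 1L, end = end(reads),
               name = ifelse(is.na(origin), "bg", paste0("site", origin)),
               score = 0L, strand = as.character(strand(reads))),
    paths["reads"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  s <- sim$sites
  write.table(
    data.frame(chrom = as.character(seqnames(s)), start = start(s) - 1L,
               end = end(s), strand = as.character(strand(s)),
               anchor = mcols(s)$anchor, planted_seq = mcols(s)$planted_seq,
               peak_id = mcols(s)$peak_id),
    paths["sites"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read peak regions from a BED file
#' @param path BED3+ file.
#' @return `GRanges`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("regions BED not found: ", path)
  rtracklayer::import(path, format = "BED")
}
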