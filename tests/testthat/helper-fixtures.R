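# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / string ops, never the package's vectorized paths.

library(GenomicRanges)
library(IRanges)
library(S4Vectors)

BASES <- c("A", "C", "G", "T")

rc_string <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""), function(v) {
    paste(rev(v), collapse = "")
  }, character(1))
}

# random high-information-content PWM with distinct, non-repetitive columns
rand_high_ic_pwm <- function(L, seed, id = "randmotif", dom = 40) {
  withr::with_seed(seed, {
    counts <- sapply(seq_len(L), function(j) {
      v <- rep(1, 4)
      v[sample.int(4, 1)] <- dom
      v
    })
    rownames(counts) <- BASES
    new_pwm(counts, id)
  })
}

# random soft PWM (moderate IC) for score-distribution tests
rand_soft_pwm <- function(L, seed, id = "softmotif") {
  withr::with_seed(seed, {
    counts <- matrix(stats::rgamma(4 * L, shape = 1), nrow = 4,
                     dimnames = list(BASES, NULL))
    new_pwm(counts, id)
  })
}

rand_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  draw <- function() paste(sample(BASES, n, TRUE, prob = prob), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(g) <- paste0("chr", seq_along(seqs))
  g
}

uniform_reads <- function(n, len, read_length = 36, seed = 1,
                          chrom = "chrS") {
  withr::with_seed(seed, {
    fivep <- sample.int(len, n, replace = TRUE)
    str <- sample(c("+", "-"), n, replace = TRUE)
    starts <- ifelse(str == "+", fivep, pmax(1L, fivep - read_length + 1L))
    ends <- ifelse(str == "+", pmin(len, fivep + read_length - 1L), fivep)
    GRanges(chrom, IRanges(starts, ends), strand = str,
            seqlengths = setNames(len, chrom))
  })
}

# oracle: per-position 5' counts by naive loop
oracle_five_prime_counts <- function(reads, len) {
  fwd <- integer(len)
  rev_ <- integer(len)
  for (i in seq_along(reads)) {
    if (as.character(strand(reads)[i]) == "+") {
      p <- start(reads)[i]
      fwd[p] <- fwd[p] + 1L
    } else {
      p <- end(reads)[i]
      rev_[p] <- rev_[p] + 1L
    }
  }
  list(forward = fwd, reverse = rev_)
}

# oracle: site x position x strand matrix by nested loops over the oracle
# counts, following the orientation-normalization definition directly
oracle_site_matrix <- function(oc, hits, flank, len) {
  L <- unique(width(hits))
  positions <- seq(-(flank + L %/% 2L), flank + (L + 1L) %/% 2L - 1L)
  vals <- array(0, dim = c(length(hits), length(positions), 2),
                dimnames = list(NULL, positions, c("forward", "reverse")))
  at <- function(v, p) if (p >= 1 && p <= len) v[p] else 0
  for (i in seq_along(hits)) {
    a <- start(hits)[i] + L %/% 2L
    minus <- as.character(strand(hits)[i]) == "-"
    for (k in seq_along(positions)) {
      r <- positions[k]
      if (!minus) {
        vals[i, k, "forward"] <- at(oc$forward, a + r)
        vals[i, k, "reverse"] <- at(oc$reverse, a + r)
      } else {
        vals[i, k, "forward"] <- at(oc$reverse, a - r)
        vals[i, k, "reverse"] <- at(oc$forward, a - r)
      }
    }
  }
  vals
}

# manual hit GRanges builder for tests that construct hits directly
manual_hits <- function(chrom, starts, L, strands, region_ids = NA_integer_,
                        motif_id = "m", len = NULL) {
  gr <- GRanges(chrom, IRanges(starts, width = L), strand = strands)
  mcols(gr)$motif_id <- motif_id
  mcols(gr)$score <- NA_real_
  mcols(gr)$matched_seq <- NA_character_
  mcols(gr)$region_id <- region_ids
  mcols(gr)$anchor <- starts + L %/% 2L
  if (!is.null(len)) {
    GenomeInfoDb::seqlengths(gr) <-
      setNames(rep(len, length(GenomeInfoDb::seqlevels(gr))),
               GenomeInfoDb::seqlevels(gr))
  }
  gr
}

# mirror a read set onto the reverse-complemented genome of length len
mirror_reads <- function(reads, len) {
  starts <- len + 1L - end(reads)
  ends <- len + 1L - start(reads)
  str <- ifelse(as.character(strand(reads)) == "+", "-", "+")
  GRanges(seqnames(reads), IRanges(starts, ends), strand = str,
          seqlengths = setNames(len, GenomeInfoDb::seqlevels(reads)))
}

mirror_ranges <- function(gr, len) {
  starts <- len + 1L - end(gr)
  ends <- len + 1L - start(gr)
  str <- as.character(strand(gr))
  flipped <- ifelse(str == "+", "-", ifelse(str == "-", "+", "*"))
  GRanges(seqnames(gr), IRanges(starts, ends), strand = flipped,
          seqlengths = setNames(len, GenomeInfoDb::seqlevels(gr)))
}

# standard small simulation used by several files: symmetric outer-only
# cross-link geometry with fixed stop distance
sym_sim_config <- function(n_peaks = 100, seed = 7, motif = NULL,
                           reads_per_site = 20, background_rate = 0.001,
                           stop_offset = 6L, genome_length = n_peaks * 300L,
                           site_strand_prob = 0.5, plant = "sample",
                           peak_width = 200) {
  if (is.null(motif)) motif <- consensus_pattern("nGnACAnnnTGTnCn")
  sim_config(genome_length = genome_length, n_peaks = n_peaks,
             peak_width = peak_width,
             motif = motif,
             site_strand_prob = site_strand_prob,
             crosslink_offsets = data.frame(
               offset = c(-8L, 8L), strand = c("forward", "reverse"),
               weight = c(0.5, 0.5)),
             stop_offset = stop_offset,
             reads_per_site = reads_per_site,
             background_rate = background_rate,
             plant = plant, seed = seed)
}
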