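#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
NULL

# Accepts a genome as a named DNAStringSet, an Rsamtools::FaFile, or a path
# to a FASTA file.
genome_handle <- function(genome) {
  if (is.character(genome) && length(genome) == 1) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    fa <- Rsamtools::FaFile(genome)
    if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
    return(fa)
  }
  if (is(genome, "FaFile") || is(genome, "DNAStringSet")) return(genome)
  stop("'genome' must be a DNAStringSet, FaFile, or FASTA path")
}

#' Chromosome lengths of a genome source
#' @param genome named `DNAStringSet`, `FaFile`, or FASTA path.
#' @return named integer vector of sequence lengths.
#' @export
genome_seqlengths <- function(genome) {
  genome <- genome_handle(genome)
  if (is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    info <- Rsamtools::seqinfo(genome)
    setNames(GenomeInfoDb::seqlengths(info), GenomeInfoDb::seqnames(info))
  }
}

# Forward-strand sequences of regions as a character vector; errors name the
# offending region.
get_region_seqs <- function(genome, regions) {
  genome <- genome_handle(genome)
  sl <- genome_seqlengths(genome)
  chr <- as.character(seqnames(regions))
  missing <- !(chr %in% names(sl))
  if (any(missing)) {
    i <- which(missing)[1]
    stop("region ", chr[i], ":", start(regions)[i], "-", end(regions)[i],
         " references a chromosome absent from the genome")
  }
  if (is(genome, "DNAStringSet")) {
    txts <- vapply(unique(chr), function(cc) as.character(genome[[cc]]),
                   character(1))
    unname(substring(txts[chr], start(regions), end(regions)))
  } else {
    unstranded <- regions
    strand(unstranded) <- "*"
    as.character(Biostrings::getSeq(genome, unstranded))
  }
}

# DNA string -> integer codes: A=1 C=2 G=3 T=4, anything else 5.
seq_to_int <- function(seq) {
  b <- match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
  b[is.na(b)] <- 5L
  b
}

# Concatenate region sequences into one integer vector with L-1 non-ACGT
# spacer symbols between regions, so a single vectorized pass scores all
# windows and windows straddling region boundaries are invalid by
# construction. Returns the concatenation plus the bookkeeping needed to map
# window indices back to (region, local offset).
concat_regions <- function(txts, L) {
  ints <- lapply(txts, seq_to_int)
  lens <- lengths(ints)
  n <- length(ints)
  sep <- rep(5L, L - 1L)
  pieces <- vector("list", 2L * n - 1L)
  pieces[seq(1, 2L * n - 1L, by = 2)] <- ints
  if (n > 1) pieces[seq(2, 2L * n - 2L, by = 2)] <- list(sep)
  starts <- cumsum(c(1L, (lens + L - 1L)[-n]))
  list(cat = unlist(pieces, use.names = FALSE), starts = starts, lens = lens)
}

# Lattice scores for every window of width ncol(li); NA where the window
# contains a non-ACGT base.
scan_lattice_scores <- function(seqint, li) {
  L <- ncol(li)
  n <- length(seqint) - L + 1L
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    colv <- unname(c(li[, j], NA_real_))
    sc <- sc + colv[seqint[j:(j + n - 1L)]]
  }
  sc
}

# windows valid (no N) indicator for width-L windows
valid_windows <- function(seqint, L) {
  bad <- cumsum(c(0L, as.integer(seqint > 4L)))
  n <- length(seqint) - L + 1L
  if (n < 1) return(logical(0))
  (bad[seq_len(n) + L] - bad[seq_len(n)]) == 0L
}

empty_hits <- function(L) {
  gr <- GRanges()
  mcols(gr) <- S4Vectors::DataFrame(motif_id = character(0),
                                    score = numeric(0),
                                    matched_seq = character(0),
                                    region_id = integer(0),
                                    anchor = integer(0))
  gr
}

# Greedy same-motif overlap resolution on plain vectors (all hits width L):
# priority descending score, plus strand on ties, then leftmost; a hit is
# kept when it overlaps no previously kept hit on the same chromosome.
resolve_overlap_keep <- function(chrom, starts, strands, scores, L) {
  n <- length(starts)
  if (n < 2) return(rep(TRUE, n))
  sc <- scores
  if (all(is.na(sc))) sc <- rep(0, n)
  ord <- order(-sc, strands != "+", chrom, starts)
  keep <- logical(n)
  kept_by_chrom <- split(numeric(0), character(0))
  for (i in ord) {
    ks <- kept_by_chrom[[chrom[i]]]
    if (is.null(ks) || !any(abs(ks - starts[i]) < L)) {
      keep[i] <- TRUE
      kept_by_chrom[[chrom[i]]] <- c(ks, starts[i])
    }
  }
  keep
}

# Assemble a hit GRanges from parallel vectors of window indices in the
# concatenated scan space; built in plain vectors and converted to GRanges
# once, already sorted by (chrom, start).
assemble_hits <- function(idx_f, idx_r, cr, regions, txts, L, motif_id,
                          score_f, score_r, seqlengths,
                          resolve_overlaps = FALSE) {
  idx <- c(idx_f, idx_r)
  if (length(idx) == 0) return(empty_hits(L))
  reg <- findInterval(idx, cr$starts)
  local <- idx - cr$starts[reg] + 1L
  starts <- start(regions)[reg] + local - 1L
  strands <- rep(c("+", "-"), c(length(idx_f), length(idx_r)))
  chrom <- as.character(seqnames(regions))[reg]
  scores <- c(score_f, score_r)
  mseq <- substring(txts[reg], local, local + L - 1L)
  if (resolve_overlaps) {
    keep <- resolve_overlap_keep(chrom, starts, strands, scores, L)
    reg <- reg[keep]; starts <- starts[keep]; strands <- strands[keep]
    chrom <- chrom[keep]; scores <- scores[keep]; mseq <- mseq[keep]
  }
  minus <- strands == "-"
  if (any(minus)) {
    mseq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(mseq[minus])))
  }
  ord <- order(chrom, starts, strands != "+")
  si <- if (!is.null(seqlengths) && !anyNA(seqlengths)) {
    GenomeInfoDb::Seqinfo(names(seqlengths), unname(seqlengths))
  } else NULL
  args <- list(chrom[ord], IRanges(starts[ord], width = L),
               strand = strands[ord],
               motif_id = motif_id,
               score = scores[ord],
               matched_seq = mseq[ord],
               region_id = reg[ord],
               anchor = starts[ord] + L %/% 2L)
  if (!is.null(si)) args$seqinfo <- si
  do.call(GRanges, args)
}

#' Scan regions for PWM matches above a p-value threshold
#'
#' Slides the motif over both strands of every region and reports windows
#' whose log-odds score meets the score threshold for match p-value `p`
#' (exact background tail, see [score_threshold()]). Windows containing
#' non-ACGT symbols are skipped. Matches on the minus strand are found by
#' scanning the forward sequence with the reverse-complemented motif;
#' `matched_seq` is always given on the motif strand.
#'
#' @param genome named `DNAStringSet`, `FaFile`, or FASTA path.
#' @param regions `GRanges` of bound regions (e.g. ChIP-seq peaks).
#' @param pwm a `pwm` object.
#' @param p motif-match p-value in (0, 1].
#' @param resolve_overlaps if TRUE (default), same-motif hits overlapping by
#'   >= 1 bp are greedily resolved keeping the higher score; ties prefer the
#'   plus strand, then the leftmost site. Palindromic double-hits keep the
#'   plus strand. This prevents double-counting reads in footprint profiles.
#' @param threshold optional precomputed score threshold overriding `p`.
#'   Useful when rescanning with column-permuted motifs: the background
#'   score distribution is invariant under column permutation, so the
#'   threshold for the original motif applies unchanged.
#' @return `GRanges` of motif hits with metadata columns `motif_id`, `score`
#'   (log2 log-odds), `matched_seq`, `region_id` (index into `regions`), and
#'   `anchor` (genomic position of the site center, `start + floor(L/2)`),
#'   sorted by (chrom, start).
#' @export
scan_regions <- function(genome, regions, pwm, p = 1e-4,
                         resolve_overlaps = TRUE, threshold = NULL) {
  stopifnot(is(regions, "GRanges"))
  if (length(regions) == 0) stop("'regions' must be non-empty")
  genome <- genome_handle(genome)
  txts <- get_region_seqs(genome, regions)
  L <- pwm_length(pwm)
  if (is.null(threshold)) threshold <- score_threshold(pwm, p)
  t_lat <- round(threshold / SCORE_GRID)
  li_f <- pwm_lattice(pwm)
  li_r <- pwm_lattice(pwm_reverse_complement(pwm))
  cr <- concat_regions(txts, L)
  sc_f <- scan_lattice_scores(cr$cat, li_f)
  sc_r <- scan_lattice_scores(cr$cat, li_r)
  idx_f <- which(!is.na(sc_f) & sc_f >= t_lat)
  idx_r <- which(!is.na(sc_r) & sc_r >= t_lat)
  assemble_hits(idx_f, idx_r, cr, regions, txts, L, pwm$motif_id,
                sc_f[idx_f] * SCORE_GRID, sc_r[idx_r] * SCORE_GRID,
                genome_seqlengths(genome), resolve_overlaps)
}

#' Scan regions for constrained-consensus matches
#'
#' Reports every window on either strand of every region that satisfies
#' [match_consensus()] for the pattern: all constrained positions match
#' their IUPAC code and all anti positions mismatch it. Windows containing
#' non-ACGT symbols are skipped. No score is attached and, unlike
#' [scan_regions()], overlapping matches are all reported.
#'
#' @inheritParams scan_regions
#' @param pattern a `consensus_pattern`.
#' @return `GRanges` of hits as in [scan_regions()], with `score = NA`.
#' @export
scan_regions_consensus <- function(genome, regions, pattern) {
  stopifnot(is(regions, "GRanges"))
  L <- pattern_length(pattern)
  if (length(regions) == 0) return(empty_hits(L))
  genome <- genome_handle(genome)
  txts <- get_region_seqs(genome, regions)
  rc_pat <- pattern_reverse_complement(pattern)
  cr <- concat_regions(txts, L)

  match_windows <- function(pat) {
    n <- length(cr$cat) - L + 1L
    if (n < 1) return(logical(0))
    ok <- valid_windows(cr$cat, L)
    for (i in pat$constrained) {
      set <- match(IUPAC_SETS[[pat$chars[i]]], DNA_BASES)
      ok <- ok & (cr$cat[i:(i + n - 1L)] %in% set)
    }
    for (i in pat$anti_positions) {
      set <- match(IUPAC_SETS[[pat$chars[i]]], DNA_BASES)
      ok <- ok & !(cr$cat[i:(i + n - 1L)] %in% set) &
        (cr$cat[i:(i + n - 1L)] <= 4L)
    }
    ok
  }
  idx_f <- which(match_windows(pattern))
  idx_r <- which(match_windows(rc_pat))
  assemble_hits(idx_f, idx_r, cr, regions, txts, L, pattern$pattern,
                rep(NA_real_, length(idx_f)), rep(NA_real_, length(idx_r)),
                genome_seqlengths(genome), resolve_overlaps = FALSE)
}

#' Classify regions by the motifs they contain
#'
#' Partitions regions into those containing hits of motif A only, motif B
#' only, both, or neither, based on the `region_id` carried by each hit.
#'
#' @param regions `GRanges` of regions the hits were scanned from.
#' @param hitsA,hitsB hit `GRanges` from [scan_regions()] or
#'   [scan_regions_consensus()] run on the same `regions`.
#' @return list with `counts` (named integer vector `A_only`, `B_only`,
#'   `both`, `neither`; sums to `length(regions)`) and `class` (factor of
#'   per-region assignments).
#' @export
classify_regions_by_motifs <- function(regions, hitsA, hitsB) {
  n <- length(regions)
  check_ids <- function(h, label) {
    ids <- mcols(h)$region_id
    if (length(h) > 0 && (is.null(ids) || any(ids < 1 | ids > n))) {
      stop("hits", label, " reference regions outside the input list")
    }
    unique(ids)
  }
  inA <- seq_len(n) %in% check_ids(hitsA, "A")
  inB <- seq_len(n) %in% check_ids(hitsB, "B")
  cls <- factor(ifelse(inA & inB, "both",
                ifelse(inA, "A_only",
                ifelse(inB, "B_only", "neither"))),
                levels = c("A_only", "B_only", "both", "neither"))
  list(counts = setNames(as.integer(table(cls)), levels(cls)), class = cls)
}

#' Export motif hits as BED6
#'
#' Writes hits with name = motif id and the BED score column set to the
#' log-odds score linearly scaled and clipped to 0-1000 (0 for score-less
#' consensus hits).
#'
#' @param hits hit `GRanges`.
#' @param path output file.
#' @export
export_hits_bed <- function(hits, path) {
  sc <- mcols(hits)$score
  bed_score <- if (length(sc) == 0 || all(is.na(sc))) {
    rep(0L, length(hits))
  } else {
    as.integer(pmin(pmax(round(sc * 50), 0), 1000))
  }
  df <- data.frame(
    chrom = as.character(seqnames(hits)),
    start = start(hits) - 1L,
    end = end(hits),
    name = if (length(hits)) mcols(hits)$motif_id else character(0),
    score = bed_score,
    strand = as.character(strand(hits))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
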