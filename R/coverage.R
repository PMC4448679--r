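#' Read aligned reads from BAM or BED6
#'
#' Returns reads as a `GRanges` with strand and, for BAM, a `mapq` metadata
#' column. BAM files must be coordinate-sorted and indexed (the standard
#' `samtools index` layout); unmapped and secondary alignments are dropped.
#'
#' @param path BAM or BED file (format inferred from the extension unless
#'   given).
#' @param format `"auto"`, `"bam"`, or `"bed"`.
#' @return `GRanges` of read alignments.
#' @export
read_alignments <- function(path, format = c("auto", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (!file.exists(path)) stop("reads file not found: ", path)
  if (format == "bam") {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
      stop("BAM file ", path, " is not indexed; run samtools index first ",
           "(the file must be coordinate-sorted)")
    }
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE),
      what = "mapq")
    aln <- GenomicAlignments::readGAlignments(path, param = param)
    gr <- GRanges(aln)
    mcols(gr)$mapq <- mcols(aln)$mapq
    gr
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    bad <- !as.character(strand(gr)) %in% c("+", "-")
    if (any(bad)) {
      stop(sum(bad), " read(s) with unknown strand symbol in ", path,
           " (need '+' or '-')")
    }
    gr
  }
}

#' Index the 5'-most base of every read, per strand
#'
#' ChIP-exo signal is read at the most 5' position of each read: it marks
#' the boundary of protection from lambda exonuclease digestion by the
#' cross-linked protein. A plus-strand read contributes at its leftmost
#' base, a minus-strand read at its rightmost base.
#'
#' Deduplication is OFF by default: exonuclease stops legitimately stack at
#' identical 5' positions, so removing "duplicates" would erase the signal.
#'
#' @param reads `GRanges` of alignments (strand required; optional `mapq`
#'   metadata column), or a BAM/BED6 path passed to [read_alignments()].
#' @param seqlengths named integer chromosome lengths. Defaults to the
#'   seqlengths carried by `reads`, falling back to the maximum read end per
#'   chromosome.
#' @param min_mapq minimum mapping quality (applied only when a `mapq`
#'   column is present). Default 1.
#' @param dedup if TRUE, identical (chrom, strand, 5' bp, 3' bp) read tuples
#'   are counted once.
#' @return object of class `five_prime_index`: list with `forward` and
#'   `reverse` (RleList of per-base counts per chromosome), `n_reads`, and
#'   `seqlengths`.
#' @export
build_five_prime_index <- function(reads, seqlengths = NULL, min_mapq = 1,
                                   dedup = FALSE) {
  if (is.character(reads)) reads <- read_alignments(reads)
  stopifnot(is(reads, "GRanges"))
  str <- as.character(strand(reads))
  if (any(str == "*")) stop("reads with unknown strand ('*') cannot be indexed")
  if (!is.null(mcols(reads)$mapq)) {
    keep <- is.na(mcols(reads)$mapq) | mcols(reads)$mapq >= min_mapq
    reads <- reads[keep]
    str <- str[keep]
  }
  if (dedup && length(reads) > 0) {
    key <- paste(seqnames(reads), str, start(reads), end(reads))
    keep <- !duplicated(key)
    reads <- reads[keep]
    str <- str[keep]
  }
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(reads)
    if (any(is.na(sl))) {
      ends <- vapply(split(end(reads), as.character(seqnames(reads))),
                     max, numeric(1))
      sl[names(ends)] <- pmax(sl[names(ends)], ends, na.rm = TRUE)
    }
    seqlengths <- sl
  }
  fivep <- ifelse(str == "+", start(reads), end(reads))
  gr5 <- GRanges(seqnames(reads), IRanges(fivep, width = 1L))
  lv <- names(seqlengths)
  cov_for <- function(sel) {
    g <- gr5[sel]
    GenomeInfoDb::seqlevels(g) <- lv
    GenomeInfoDb::seqlengths(g) <- seqlengths
    coverage(g)
  }
  structure(
    list(forward = cov_for(str == "+"),
         reverse = cov_for(str == "-"),
         n_reads = length(reads),
         seqlengths = seqlengths),
    class = "five_prime_index"
  )
}

#' @export
print.five_prime_index <- function(x, ...) {
  cat("5' coverage index:", x$n_reads, "reads over",
      length(x$seqlengths), "sequence(s)\n")
  invisible(x)
}

# Counts in [from, to] (1-based inclusive) on one strand; positions outside
# the chromosome are zero-filled.
index_window <- function(index, strand, chrom, from, to) {
  out <- numeric(to - from + 1)
  rlel <- index[[strand]]
  if (!chrom %in% names(rlel)) return(out)
  len <- length(rlel[[chrom]])
  a <- max(from, 1L)
  b <- min(to, len)
  if (a <= b) {
    out[(a - from + 1):(b - from + 1)] <- as.numeric(rlel[[chrom]][a:b])
  }
  out
}

# Fast accessor over the index: decodes each needed (strand, chrom) Rle to a
# dense numeric vector once (for chromosomes up to `dense_limit` bp), then
# serves zero-padded windows by plain indexing.
index_fetcher <- function(index, dense_limit = 2e7) {
  cache <- new.env(parent = emptyenv())
  function(strand, chrom, from, to) {
    rlel <- index[[strand]]
    if (!chrom %in% names(rlel)) return(numeric(to - from + 1))
    len <- length(rlel[[chrom]])
    if (len > dense_limit) return(index_window(index, strand, chrom, from, to))
    key <- paste0(strand, ":", chrom)
    if (is.null(cache[[key]])) cache[[key]] <- as.numeric(rlel[[chrom]])
    v <- cache[[key]]
    pos <- from:to
    out <- numeric(length(pos))
    ok <- pos >= 1L & pos <= len
    out[ok] <- v[pos[ok]]
    out
  }
}

#' Per-site, strand-specific 5' coverage matrices around motif hits
#'
#' Extracts a window of `flank` bp beyond each motif end, orientation-
#' normalized to the motif strand: for a minus-strand site, the window is
#' position-reversed and the strand labels are swapped, so "forward" always
#' means the strand the motif itself is on. Relative position 0 is the site
#' anchor (motif center, `start + floor(L/2)` on the forward genome).
#'
#' @param index a `five_prime_index`.
#' @param hits motif hit `GRanges` from the scanners (all of one motif
#'   length).
#' @param flank flank width in bp beyond the motif ends. Default 30, chosen
#'   because single-factor footprints typically span ~30 bp around the
#'   recognition sequence.
#' @return object of class `profile_matrix`: list with `values` (array
#'   sites x positions x strand, strand in `forward`/`reverse`), `positions`
#'   (relative bp), `hits`, `flank`, `motif_length`.
#' @export
site_coverage_matrix <- function(index, hits, flank = 30) {
  stopifnot(is(index, "five_prime_index"), is(hits, "GRanges"))
  if (length(hits) == 0) stop("'hits' must be non-empty")
  if (flank < 0) stop("'flank' must be >= 0")
  L <- unique(width(hits))
  if (length(L) != 1) stop("all hits must have the same motif length")
  positions <- seq(-(flank + L %/% 2L), flank + (L + 1L) %/% 2L - 1L)
  w <- length(positions)
  vals <- array(0, dim = c(length(hits), w, 2),
                dimnames = list(NULL, positions, c("forward", "reverse")))
  chrom <- as.character(seqnames(hits))
  anchor <- mcols(hits)$anchor
  if (is.null(anchor)) anchor <- start(hits) + L %/% 2L
  minus <- as.character(strand(hits)) == "-"
  fetch <- index_fetcher(index)
  for (i in seq_along(hits)) {
    if (!minus[i]) {
      from <- anchor[i] + positions[1]
      to <- anchor[i] + positions[w]
      vals[i, , "forward"] <- fetch("forward", chrom[i], from, to)
      vals[i, , "reverse"] <- fetch("reverse", chrom[i], from, to)
    } else {
      # mirrored: oriented position r maps to genomic anchor - r, and the
      # genome's reverse strand is the site's forward strand
      from <- anchor[i] - positions[w]
      to <- anchor[i] - positions[1]
      vals[i, , "forward"] <- rev(fetch("reverse", chrom[i], from, to))
      vals[i, , "reverse"] <- rev(fetch("forward", chrom[i], from, to))
    }
  }
  structure(
    list(values = vals, positions = positions, hits = hits, flank = flank,
         motif_length = L),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile matrix:", dim(x$values)[1], "sites x",
      dim(x$values)[2], "positions x 2 strands (flank", x$flank, "bp)\n")
  invisible(x)
}

#' Number of sites in a profile matrix
#' @param matrix a `profile_matrix`.
#' @export
n_sites <- function(matrix) dim(matrix$values)[1]

#' Per-site total window counts (occupancy)
#' @param matrix a `profile_matrix`.
#' @export
site_totals <- function(matrix) {
  apply(matrix$values, 1, sum)
}

#' Aggregate a profile matrix into a footprint profile
#'
#' Sums 5' counts over all sites, per relative position and oriented strand.
#' The result is the footprint profile: forward-strand counts mark
#' exonuclease stops upstream of the protein, reverse-strand counts mark
#' stops downstream, so a protected bound region shows a coherent peak-pair
#' with the forward maximum left of the reverse maximum.
#'
#' @param matrix a `profile_matrix`.
#' @return object of class `footprint_profile`: list with `positions`,
#'   `forward`, `reverse` (per-position summed counts), `n_sites`.
#' @export
aggregate_footprint <- function(matrix) {
  stopifnot(is(matrix, "profile_matrix"))
  if (n_sites(matrix) == 0) stop("'matrix' must be non-empty")
  structure(
    list(positions = matrix$positions,
         forward = colSums(matrix$values[, , "forward", drop = FALSE])[, 1],
         reverse = colSums(matrix$values[, , "reverse", drop = FALSE])[, 1],
         n_sites = n_sites(matrix)),
    class = "footprint_profile"
  )
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat("Footprint profile over", length(x$positions), "positions,",
      x$n_sites, "sites; total counts fwd =", sum(x$forward),
      ", rev =", sum(x$reverse), "\n")
  invisible(x)
}

# per-site mean coverage (normalized profile); used for permutation nulls,
# ranking and differencing so site-count differences cancel
normalize_profile <- function(profile) {
  profile$forward <- profile$forward / profile$n_sites
  profile$reverse <- profile$reverse / profile$n_sites
  profile$n_sites <- 1L
  profile
}

#' Write a footprint profile as TSV
#' @param profile a `footprint_profile`.
#' @param path output file.
#' @export
export_profile_tsv <- function(profile, path) {
  write.table(
    data.frame(position = profile$positions, forward = profile$forward,
               reverse = profile$reverse),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a profile matrix as TSV (one row per site)
#'
#' Columns: site locus, strand, occupancy total, then the per-position
#' forward and reverse counts (`fwd_<r>`, `rev_<r>`).
#'
#' @param matrix a `profile_matrix`.
#' @param path output file.
#' @export
export_matrix_tsv <- function(matrix, path) {
  h <- matrix$hits
  fwd <- matrix$values[, , "forward", drop = FALSE][, , 1, drop = FALSE]
  rev_ <- matrix$values[, , "reverse", drop = FALSE][, , 1, drop = FALSE]
  dim(fwd) <- dim(rev_) <- dim(matrix$values)[1:2]
  colnames(fwd) <- paste0("fwd_", matrix$positions)
  colnames(rev_) <- paste0("rev_", matrix$positions)
  df <- cbind(
    data.frame(chrom = as.character(seqnames(h)), start = start(h) - 1L,
               end = end(h), strand = as.character(strand(h)),
               motif_id = mcols(h)$motif_id, total = site_totals(matrix)),
    as.data.frame(fwd), as.data.frame(rev_))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
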