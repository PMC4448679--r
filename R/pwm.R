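#' @importFrom stats rpois runif setNames
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Per-column log-odds values are snapped to a lattice of this width (in log2
# units) so that the exact score-distribution dynamic programme and window
# scoring operate on identical numbers.
SCORE_GRID <- 1e-3

#' Construct a position weight matrix
#'
#' A `pwm` stores per-position base probabilities for a DNA motif together
#' with a background composition. Counts or unnormalized frequencies are
#' regularized with a pseudocount (split across bases proportionally to the
#' background) and renormalized column-wise, so every probability is strictly
#' positive and every column sums to one.
#'
#' @param counts numeric 4 x L matrix (rows A, C, G, T) of counts or
#'   probabilities per motif position.
#' @param motif_id identifier carried through scanning reports.
#' @param background length-4 probability vector over A,C,G,T; defaults to
#'   uniform. May come from a genome-composition estimate.
#' @param pseudocount total pseudo-mass added per column before
#'   renormalization, split across bases by background frequency. Default
#'   0.01 per column.
#' @return an object of class `pwm` with elements `motif_id`, `probs`
#'   (4 x L, rows named A,C,G,T), `background`, `pseudocount`.
#' @examples
#' m <- new_pwm(matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4), "toy")
#' pwm_length(m)
#' @export
new_pwm <- function(counts, motif_id = "motif", background = rep(0.25, 4),
                    pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("'counts' must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("negative counts in motif '", motif_id, "'")
  if (any(colSums(counts) == 0)) {
    stop("motif '", motif_id, "' has a column of all zeros")
  }
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0)) {
    stop("'background' must be 4 strictly positive values")
  }
  background <- background / sum(background)
  # scale each column to unit mass, then mix in pseudocount split by background
  probs <- sweep(counts, 2, colSums(counts), "/")
  probs <- probs + pseudocount * background
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(DNA_BASES, NULL)
  structure(
    list(motif_id = motif_id, probs = probs,
         background = setNames(background, DNA_BASES),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$motif_id, "' (", pwm_length(x), " bp, IC ",
      sprintf("%.2f", pwm_information_content(x)), " bits)\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Motif length in base pairs
#' @param pwm a `pwm` object.
#' @export
pwm_length <- function(pwm) ncol(pwm$probs)

#' Total information content of a motif (bits)
#' @param pwm a `pwm` object.
#' @export
pwm_information_content <- function(pwm) {
  sum(pwm$probs * log2(pwm$probs / pwm$background))
}

#' Consensus (per-column argmax) sequence of a motif
#' @param pwm a `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

# Integer lattice of per-column log-odds, used by both the scanner and the
# exact p-value DP so the two always agree.
pwm_lattice <- function(pwm, grid = SCORE_GRID) {
  round(log2(pwm$probs / pwm$background) / grid)
}

# PWM for the reverse complement of the motif: columns reversed, A<->T and
# C<->G rows swapped. Background is kept as-is (assumed strand-symmetric
# enough for scanning; an asymmetric background is complemented).
pwm_reverse_complement <- function(pwm) {
  probs <- pwm$probs[c(4, 3, 2, 1), rev(seq_len(pwm_length(pwm))), drop = FALSE]
  rownames(probs) <- DNA_BASES
  out <- pwm
  out$probs <- probs
  out$background <- setNames(pwm$background[c(4, 3, 2, 1)], DNA_BASES)
  out
}

#' Read motifs from a JASPAR or TRANSFAC file
#'
#' Parses all motif blocks in the file and converts counts to probabilities
#' with [new_pwm()]. The JASPAR dialect is the 4-row count block
#' (`>ID name` header followed by `A [ 4 0 ... ]`-style rows, brackets
#' optional); the TRANSFAC dialect is the `P0 A C G T` matrix block with
#' numbered rows, terminated by `//`.
#'
#' @param path file path.
#' @param format `"jaspar"` or `"transfac"`.
#' @inheritParams new_pwm
#' @return list of `pwm` objects, named by motif id.
#' @export
read_motifs <- function(path, format = c("jaspar", "transfac"),
                        background = rep(0.25, 4), pseudocount = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  if (format == "jaspar") {
    motifs <- parse_jaspar(lines, path)
  } else {
    motifs <- parse_transfac(lines, path)
  }
  out <- lapply(motifs, function(m) {
    new_pwm(m$counts, motif_id = m$id, background = background,
            pseudocount = pseudocount)
  })
  setNames(out, vapply(out, function(m) m$motif_id, character(1)))
}

parse_jaspar <- function(lines, path) {
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no '>' header found in ", path)
  motifs <- list()
  ends <- c(headers[-1] - 1, length(lines))
  for (i in seq_along(headers)) {
    h <- headers[i]
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    block <- lines[(h + 1):ends[i]]
    block <- block[nzchar(trimws(block))]
    rows <- list()
    for (ln in seq_along(block)) {
      txt <- block[ln]
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", txt))
      if (!base %in% DNA_BASES) {
        stop("malformed JASPAR row (line ", h + ln, " of ", path, "): ", txt)
      }
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", txt))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (length(vals) == 0 || anyNA(vals)) {
        stop("malformed JASPAR counts (line ", h + ln, " of ", path, "): ", txt)
      }
      rows[[base]] <- vals
      if (length(rows) == 4) break
    }
    if (length(rows) != 4) {
      stop("JASPAR block for '", id, "' in ", path, " lacks 4 base rows")
    }
    if (length(unique(lengths(rows))) != 1) {
      stop("JASPAR block for '", id, "' has rows of unequal length")
    }
    counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    motifs[[length(motifs) + 1]] <- list(id = id, counts = counts)
  }
  motifs
}

parse_transfac <- function(lines, path) {
  motifs <- list()
  i <- 1
  cur_id <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^(ID|NA|AC)\\s+", ln) && is.null(cur_id)) {
      cur_id <- trimws(sub("^(ID|NA|AC)\\s+", "", ln))
    } else if (grepl("^P0", ln) || grepl("^PO", ln)) {
      order <- toupper(strsplit(trimws(sub("^P[0O]\\s*", "", ln)), "\\s+")[[1]])
      if (!setequal(order[1:4], DNA_BASES)) {
        stop("malformed TRANSFAC P0 header (line ", i, " of ", path, ")")
      }
      rows <- list()
      j <- i + 1
      while (j <= length(lines) && grepl("^\\s*[0-9]+\\s", lines[j])) {
        flds <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        vals <- suppressWarnings(as.numeric(flds[2:5]))
        if (anyNA(vals)) {
          stop("malformed TRANSFAC row (line ", j, " of ", path, "): ", lines[j])
        }
        rows[[length(rows) + 1]] <- vals
        j <- j + 1
      }
      if (length(rows) == 0) stop("empty TRANSFAC matrix block in ", path)
      mat <- do.call(rbind, rows)
      counts <- t(mat)[match(DNA_BASES, order[1:4]), , drop = FALSE]
      id <- if (is.null(cur_id)) paste0("transfac_", length(motifs) + 1) else cur_id
      motifs[[length(motifs) + 1]] <- list(id = id, counts = counts)
      cur_id <- NULL
      i <- j
      next
    } else if (grepl("^//", ln)) {
      cur_id <- NULL
    }
    i <- i + 1
  }
  if (length(motifs) == 0) stop("no TRANSFAC matrix block found in ", path)
  motifs
}

#' Log-odds score of a sequence under a motif
#'
#' Scores a sequence of exactly the motif length as the sum over positions of
#' `log2(p_motif / p_background)` for the observed base. Per-column log-odds
#' are computed on a fixed 0.001-bit lattice so that scores are directly
#' comparable to thresholds from [score_threshold()].
#'
#' @param pwm a `pwm` object.
#' @param seq character DNA string (A/C/G/T only) of length `pwm_length(pwm)`,
#'   or a character vector of such strings.
#' @return numeric score(s) in log2 units.
#' @export
log_odds_score <- function(pwm, seq) {
  li <- pwm_lattice(pwm)
  L <- ncol(li)
  vapply(seq, function(s) {
    b <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
    if (length(b) != L) {
      stop("sequence length ", length(b), " does not match motif length ", L)
    }
    if (anyNA(b)) stop("sequence contains non-ACGT symbols: ", s)
    sum(li[cbind(b, seq_len(L))]) * SCORE_GRID
  }, numeric(1), USE.NAMES = FALSE)
}

# Exact distribution of lattice scores under the i.i.d. background model.
# Returns list(score = integer lattice values, prob), by dynamic programming
# over motif columns (convolution of the 4-point per-column distributions).
pwm_score_distribution <- function(pwm) {
  li <- pwm_lattice(pwm)
  bg <- pwm$background
  d <- 1
  off <- 0L
  for (j in seq_len(ncol(li))) {
    cmin <- min(li[, j])
    nd <- numeric(length(d) + max(li[, j]) - cmin)
    for (b in 1:4) {
      sh <- li[b, j] - cmin
      idx <- seq_along(d) + sh
      nd[idx] <- nd[idx] + d * bg[b]
    }
    d <- nd
    off <- off + cmin
  }
  keep <- d > 0
  list(score = (off + seq_along(d) - 1L)[keep], prob = d[keep])
}

#' Score threshold for a motif-match p-value
#'
#' Returns the smallest attainable score `t` such that the probability of a
#' background-sampled sequence scoring `>= t` is at most `p`. The score
#' distribution is computed exactly by dynamic programming over the motif
#' columns under the i.i.d. background model, with per-column log-odds on a
#' 0.001-bit lattice (the same lattice used by [log_odds_score()] and the
#' scanners, so threshold comparisons are exact).
#'
#' @param pwm a `pwm` object.
#' @param p match p-value in (0, 1]. `p = 1` returns the minimum attainable
#'   score (every sequence passes).
#' @return numeric score threshold in log2 units.
#' @export
score_threshold <- function(pwm, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("'p' must be a single value in (0, 1]")
  }
  dist <- pwm_score_distribution(pwm)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail <= p + 1e-12)
  if (length(ok) == 0) {
    # only the top score qualifies at most; smallest t with tail <= p is the
    # score just above the maximum -- no sequence can pass
    return((max(dist$score) + 1L) * SCORE_GRID)
  }
  dist$score[min(ok)] * SCORE_GRID
}

#' Exact tail probability of a score under the background model
#'
#' Probability that an i.i.d. background-sampled sequence scores at least
#' `t`, from the same exact dynamic programme as [score_threshold()].
#'
#' @param pwm a `pwm` object.
#' @param t score threshold (log2 units).
#' @return numeric probability.
#' @export
score_pvalue <- function(pwm, t) {
  dist <- pwm_score_distribution(pwm)
  t_lat <- round(t / SCORE_GRID)
  sum(dist$prob[dist$score >= t_lat])
}

#' Randomly permute the columns of a motif
#'
#' Draws a uniformly random non-identity permutation of the motif positions.
#' Shuffled-column motifs preserve base composition and information content
#' and serve as matched nulls for coverage enrichment. The identity
#' permutation is rejected and resampled, since an unshuffled control is not
#' a control.
#'
#' @param pwm a `pwm` object with length >= 2.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @return a `pwm` with reordered columns; its `motif_id` gains a
#'   `"_perm"` suffix.
#' @export
permute_columns <- function(pwm, seed) {
  L <- pwm_length(pwm)
  if (L < 2) stop("cannot permute a motif of length < 2")
  perm <- withr::with_seed(seed, {
    repeat {
      pp <- sample.int(L)
      if (any(pp != seq_len(L))) break
    }
    pp
  })
  out <- pwm
  out$probs <- pwm$probs[, perm, drop = FALSE]
  out$motif_id <- paste0(pwm$motif_id, "_perm")
  out
}
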