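# IUPAC degeneracy codes -> set of matching bases. "n" (any base) is the
# conventional lowercase in degenerate consensus patterns; matching is
# case-insensitive.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a degenerate consensus pattern with constrained positions
#'
#' A consensus pattern is an IUPAC string (e.g. the glucocorticoid receptor
#' binding sequence `"nGnACAnnnTGTnCn"`) together with a set of *constrained*
#' positions that a sequence must match and an optional set of *anti*
#' positions that must NOT match the consensus base there (the
#' "strike-through" positions of an in-silico mutated consensus). Positions
#' in neither set are unconstrained regardless of their code.
#'
#' @param pattern IUPAC string; `n`/`N` means any base.
#' @param constrained integer vector of 1-based positions that must match the
#'   code. Defaults to every non-`n` position of `pattern`.
#' @param anti_positions integer vector of 1-based positions that must
#'   mismatch the code; disjoint from `constrained`.
#' @return an object of class `consensus_pattern`.
#' @examples
#' gbs <- consensus_pattern("nGnACAnnnTGTnCn")
#' match_consensus(gbs, "AGTACATTTTGTACA")
#' @export
consensus_pattern <- function(pattern, constrained = NULL,
                              anti_positions = integer(0)) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) < 1) {
    stop("'pattern' must be a non-empty IUPAC string")
  }
  chars <- toupper(strsplit(pattern, "")[[1]])
  if (!all(chars %in% names(IUPAC_SETS))) {
    stop("unknown IUPAC code(s): ",
         paste(unique(chars[!chars %in% names(IUPAC_SETS)]), collapse = ", "))
  }
  if (is.null(constrained)) constrained <- which(chars != "N")
  constrained <- sort(unique(as.integer(constrained)))
  anti_positions <- sort(unique(as.integer(anti_positions)))
  allpos <- c(constrained, anti_positions)
  if (any(allpos < 1) || any(allpos > length(chars))) {
    stop("constrained/anti positions outside pattern length")
  }
  if (length(intersect(constrained, anti_positions)) > 0) {
    stop("'constrained' and 'anti_positions' must be disjoint")
  }
  if (any(chars[allpos] == "N")) {
    stop("constrained and anti positions must carry a non-'n' code")
  }
  structure(
    list(pattern = pattern, chars = chars, constrained = constrained,
         anti_positions = anti_positions),
    class = "consensus_pattern"
  )
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat("Consensus pattern ", x$pattern, " (", length(x$chars), " bp; ",
      length(x$constrained), " constrained",
      if (length(x$anti_positions) > 0)
        paste0(", anti at ", paste(x$anti_positions, collapse = ",")),
      ")\n", sep = "")
  invisible(x)
}

#' Pattern length in base pairs
#' @param pattern a `consensus_pattern`.
#' @export
pattern_length <- function(pattern) length(pattern$chars)

#' Test whether a sequence matches a constrained consensus
#'
#' TRUE iff the sequence matches the IUPAC code at every constrained position
#' AND mismatches the code at every anti position. Other positions are free.
#'
#' @param pattern a `consensus_pattern`.
#' @param seq DNA string of the same length as the pattern, or a character
#'   vector of such strings.
#' @return logical vector.
#' @export
match_consensus <- function(pattern, seq) {
  vapply(seq, function(s) {
    b <- toupper(strsplit(s, "")[[1]])
    if (length(b) != length(pattern$chars)) {
      stop("sequence length ", length(b), " does not match pattern length ",
           length(pattern$chars))
    }
    ok <- vapply(pattern$constrained, function(i) {
      b[i] %in% IUPAC_SETS[[pattern$chars[i]]]
    }, logical(1))
    anti <- vapply(pattern$anti_positions, function(i) {
      !(b[i] %in% IUPAC_SETS[[pattern$chars[i]]])
    }, logical(1))
    all(ok) && all(anti)
  }, logical(1), USE.NAMES = FALSE)
}

#' Reverse complement of a consensus pattern
#'
#' Complements each IUPAC code and reverses the pattern; constrained and
#' anti position sets are mirrored accordingly.
#'
#' @param pattern a `consensus_pattern`.
#' @export
pattern_reverse_complement <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  L <- length(pattern$chars)
  chars <- rev(unname(comp[pattern$chars]))
  # keep lowercase n convention for unconstrained positions
  pat <- chartr("N", "n", paste(chars, collapse = ""))
  consensus_pattern(pat,
                    constrained = sort(L + 1 - pattern$constrained),
                    anti_positions = sort(L + 1 - pattern$anti_positions))
}

#' A representative sequence matching a consensus pattern
#'
#' Picks the first base of each constrained code, a deliberate mismatch at
#' anti positions, and `fill` elsewhere. Useful for planting sites.
#'
#' @param pattern a `consensus_pattern`.
#' @param fill base used at unconstrained positions.
#' @export
pattern_representative <- function(pattern, fill = "T") {
  b <- rep(fill, length(pattern$chars))
  for (i in pattern$constrained) b[i] <- IUPAC_SETS[[pattern$chars[i]]][1]
  for (i in pattern$anti_positions) {
    b[i] <- setdiff(DNA_BASES, IUPAC_SETS[[pattern$chars[i]]])[1]
  }
  paste(b, collapse = "")
}
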