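# sub-seeds derived once from the master seed so every permutation is
# independently reproducible
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Permuted-motif control profiles and their envelope
#'
#' For each of `n_perm` seeded column permutations of the motif, regions are
#' rescanned at the same match p-value (thresholds recomputed on the
#' permuted matrix, keeping match abundance comparable), the footprint
#' profile is built from the same 5' index, and normalized to mean coverage
#' per site per position. The envelope summarizes the permuted profiles
#' position-wise by median and interquartile range; it is the null band a
#' genuine footprint must escape.
#'
#' @inheritParams scan_regions
#' @param index a `five_prime_index` of the ChIP-exo reads.
#' @param flank flank width passed to [site_coverage_matrix()].
#' @param n_perm number of column permutations (>= 2). Default 50.
#' @param seed master RNG seed; permutation seeds are derived from it.
#' @return object of class `permutation_envelope`: list with `positions`,
#'   per-strand `median`, `q1`, `q3` (each a 2-row matrix `forward` /
#'   `reverse` by position), `profiles` (list of normalized
#'   `footprint_profile`s), `null_totals`, `n_hits` per permutation, and
#'   `n_perm`.
#' @export
permutation_envelope <- function(genome, regions, index, pwm, p = 1e-4,
                                 flank = 30, n_perm = 50, seed = 1) {
  if (n_perm < 2) stop("'n_perm' must be >= 2")
  genome <- genome_handle(genome)
  seeds <- derive_seeds(seed, n_perm)
  L <- pwm_length(pwm)
  w <- L + 2L * flank
  positions <- seq(-(flank + L %/% 2L), flank + (L + 1L) %/% 2L - 1L)
  profiles <- vector("list", n_perm)
  nhits <- integer(n_perm)
  # the background score distribution is column-order invariant, so the
  # threshold at match p-value p is shared by all permuted motifs
  thr <- score_threshold(pwm, p)
  for (k in seq_len(n_perm)) {
    ppwm <- permute_columns(pwm, seeds[k])
    hits <- scan_regions(genome, regions, ppwm, p, threshold = thr)
    nhits[k] <- length(hits)
    if (length(hits) == 0) {
      message("permutation ", k, " of motif '", pwm$motif_id,
              "' yielded zero hits; contributing an all-zero profile")
      profiles[[k]] <- structure(
        list(positions = positions, forward = numeric(w),
             reverse = numeric(w), n_sites = 1L),
        class = "footprint_profile")
    } else {
      m <- site_coverage_matrix(index, hits, flank)
      profiles[[k]] <- normalize_profile(aggregate_footprint(m))
    }
  }
  fwd <- do.call(rbind, lapply(profiles, `[[`, "forward"))
  rev_ <- do.call(rbind, lapply(profiles, `[[`, "reverse"))
  qmat <- function(m, q) apply(m, 2, quantile, probs = q, names = FALSE)
  band <- function(q) rbind(forward = qmat(fwd, q), reverse = qmat(rev_, q))
  structure(
    list(positions = positions,
         median = band(0.5), q1 = band(0.25), q3 = band(0.75),
         profiles = profiles,
         null_totals = rowSums(fwd) + rowSums(rev_),
         n_hits = nhits, n_perm = n_perm, seed = seed),
    class = "permutation_envelope"
  )
}

#' @export
print.permutation_envelope <- function(x, ...) {
  cat("Permutation envelope:", x$n_perm, "permuted-motif profiles over",
      length(x$positions), "positions\n")
  invisible(x)
}

#' Write a permutation envelope as TSV
#' @param envelope a `permutation_envelope`.
#' @param path output file.
#' @export
export_envelope_tsv <- function(envelope, path) {
  write.table(
    data.frame(position = envelope$positions,
               fwd_q1 = envelope$q1["forward", ],
               fwd_median = envelope$median["forward", ],
               fwd_q3 = envelope$q3["forward", ],
               rev_q1 = envelope$q1["reverse", ],
               rev_median = envelope$median["reverse", ],
               rev_q3 = envelope$q3["reverse", ]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

profile_total <- function(profile) {
  p <- normalize_profile(profile)
  sum(p$forward) + sum(p$reverse)
}

#' Empirical coverage enrichment test against permuted-motif nulls
#'
#' The statistic is the total normalized 5' coverage (mean per site, summed
#' over the full window and both strands). The empirical p-value uses the
#' add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it
#' is never 0 and never exceeds 1; enrichment is observed over the median
#' null.
#'
#' @param observed a `footprint_profile` for the true motif.
#' @param null a `permutation_envelope`, or a list of normalized null
#'   `footprint_profile`s.
#' @param motif_id id recorded in the result.
#' @return object of class `coverage_test`: list with `motif_id`,
#'   `observed`, `null_totals`, `p_value`, `enrichment`, `n_perm`.
#' @export
coverage_pvalue <- function(observed, null, motif_id = "motif") {
  null_totals <- if (is(null, "permutation_envelope")) {
    null$null_totals
  } else if (is.list(null)) {
    vapply(null, profile_total, numeric(1))
  } else {
    stop("'null' must be a permutation_envelope or list of profiles")
  }
  n_perm <- length(null_totals)
  if (n_perm == 0) stop("no null profiles supplied")
  obs <- profile_total(observed)
  p <- (1 + sum(null_totals >= obs)) / (1 + n_perm)
  med <- median(null_totals)
  structure(
    list(motif_id = motif_id, observed = obs, null_totals = null_totals,
         p_value = p, enrichment = if (med > 0) obs / med else Inf,
         n_perm = n_perm),
    class = "coverage_test"
  )
}

#' @export
print.coverage_test <- function(x, ...) {
  cat(sprintf("Coverage test '%s': observed %.3f, enrichment %.2f, p = %.4g (%d permutations)\n",
              x$motif_id, x$observed, x$enrichment, x$p_value, x$n_perm))
  invisible(x)
}

#' Peak-pair coherence of a footprint profile
#'
#' TRUE iff the global maximum of the forward-strand profile lies strictly
#' left (smaller relative position) of the reverse-strand maximum — the
#' signature of exonuclease stops flanking a protected bound region. Ties
#' take the first (leftmost) maximum.
#'
#' @param profile a `footprint_profile`.
#' @export
profile_coherence <- function(profile) {
  if (sum(profile$forward) == 0 || sum(profile$reverse) == 0) return(FALSE)
  profile$positions[which.max(profile$forward)] <
    profile$positions[which.max(profile$reverse)]
}

#' Rank a motif library by ChIP-exo coverage enrichment
#'
#' Runs the full footprint pipeline for every motif: scan, per-site coverage
#' matrix, aggregated profile, permuted-motif null, empirical coverage
#' p-value. Motifs are ordered by ascending p-value, then descending
#' enrichment; motifs with zero matches rank last and are flagged. The
#' `coherence` column screens for profiles with forward-strand density
#' upstream of reverse-strand density.
#'
#' @inheritParams permutation_envelope
#' @param pwms list of `pwm` objects.
#' @param adjust if TRUE, add a Benjamini-Hochberg adjusted p-value column.
#'   Off by default: the analysis ranks motifs, it does not threshold them.
#' @return data.frame with columns `motif_id`, `n_sites`, `observed`,
#'   `enrichment`, `p_value`, `coherence` (and `p_adjust` when requested),
#'   one row per motif, plus attribute `profiles` carrying each motif's
#'   observed `footprint_profile` (NULL when unmatched).
#' @export
rank_motifs <- function(genome, regions, index, pwms, p = 1e-4, flank = 30,
                        n_perm = 50, seed = 1, adjust = FALSE) {
  if (length(pwms) == 0) stop("motif library is empty")
  genome <- genome_handle(genome)
  seeds <- derive_seeds(seed, length(pwms))
  rows <- vector("list", length(pwms))
  profs <- vector("list", length(pwms))
  for (i in seq_along(pwms)) {
    pwm <- pwms[[i]]
    hits <- scan_regions(genome, regions, pwm, p)
    if (length(hits) == 0) {
      message("motif '", pwm$motif_id, "' has zero matches; ranked last")
      rows[[i]] <- data.frame(motif_id = pwm$motif_id, n_sites = 0L,
                              observed = NA_real_, enrichment = NA_real_,
                              p_value = NA_real_, coherence = FALSE)
      next
    }
    m <- site_coverage_matrix(index, hits, flank)
    prof <- aggregate_footprint(m)
    env <- permutation_envelope(genome, regions, index, pwm, p, flank,
                                n_perm, seeds[i])
    ct <- coverage_pvalue(prof, env, pwm$motif_id)
    profs[[i]] <- prof
    rows[[i]] <- data.frame(motif_id = pwm$motif_id, n_sites = length(hits),
                            observed = ct$observed,
                            enrichment = ct$enrichment,
                            p_value = ct$p_value,
                            coherence = profile_coherence(prof))
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  ord <- order(is.na(out$p_value), out$p_value, -out$enrichment)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "profiles") <- profs[ord]
  out
}

#' Footprint profile of a random subsample of sites
#'
#' Selects `n` sites uniformly without replacement and aggregates their
#' footprint, e.g. to compare a degenerate-match subset against an
#' equally-sized subsample of full-consensus matches.
#'
#' @param matrix a `profile_matrix`.
#' @param n number of sites to keep, `1 <= n <= n_sites(matrix)`.
#' @param seed RNG seed; deterministic given the seed.
#' @return a `footprint_profile` over the selected sites.
#' @export
subsample_profile <- function(matrix, n, seed = 1) {
  ns <- n_sites(matrix)
  if (n < 1 || n > ns) stop("'n' must be between 1 and ", ns)
  sel <- withr::with_seed(seed, sample.int(ns, n))
  sub <- matrix
  sub$values <- matrix$values[sel, , , drop = FALSE]
  sub$hits <- matrix$hits[sel]
  aggregate_footprint(sub)
}

#' Difference of two per-site-normalized footprint profiles
#'
#' Each profile is divided by its own site count before differencing, so
#' subsets of different sizes are comparable; this is the quantity shown as
#' an under-profile difference heatmap when contrasting degenerate-consensus
#' subsets against the full-consensus profile.
#'
#' @param a,b `footprint_profile`s on identical position axes.
#' @return object of class `profile_difference`: list with `positions`,
#'   `forward`, `reverse` (signed per-position differences a - b).
#' @export
profile_difference <- function(a, b) {
  if (!identical(a$positions, b$positions)) {
    stop("profiles have different position axes")
  }
  an <- normalize_profile(a)
  bn <- normalize_profile(b)
  structure(
    list(positions = a$positions,
         forward = an$forward - bn$forward,
         reverse = an$reverse - bn$reverse),
    class = "profile_difference"
  )
}

#' @export
print.profile_difference <- function(x, ...) {
  cat("Profile difference over", length(x$positions),
      "positions; max |forward| =", sprintf("%.4f", max(abs(x$forward))),
      ", max |reverse| =", sprintf("%.4f", max(abs(x$reverse))), "\n")
  invisible(x)
}
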