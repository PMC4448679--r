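#' Keep the most occupied sites of a profile matrix
#'
#' Selects the `n` sites with the largest total window 5' count, ties broken
#' by genomic coordinate (chrom, start, strand), and orders them by
#' descending occupancy. This is how the "most occupied" sites are chosen
#' before clustering or heatmap display.
#'
#' @param matrix a `profile_matrix`.
#' @param n number of sites to keep.
#' @return a `profile_matrix` of the selected sites.
#' @export
select_top_occupied <- function(matrix, n) {
  ns <- n_sites(matrix)
  if (n > ns) stop("'n' (", n, ") exceeds the number of sites (", ns, ")")
  tot <- site_totals(matrix)
  h <- matrix$hits
  ord <- order(-tot, as.character(seqnames(h)), start(h),
               as.character(strand(h)))
  sel <- ord[seq_len(n)]
  out <- matrix
  out$values <- matrix$values[sel, , , drop = FALSE]
  out$hits <- matrix$hits[sel]
  out
}

# site feature vectors: forward row then reverse row, optionally scaled to
# unit total so occupancy does not dominate shape
site_vectors <- function(matrix, scale_unit = TRUE) {
  v <- cbind(matrix$values[, , "forward", drop = FALSE][, , 1],
             matrix$values[, , "reverse", drop = FALSE][, , 1])
  if (n_sites(matrix) == 1) v <- matrix(v, nrow = 1)
  if (scale_unit) {
    tot <- rowSums(v)
    tot[tot == 0] <- 1
    v <- v / tot
  }
  v
}

#' K-means clustering of per-site footprint vectors
#'
#' Clusters sites on the concatenation of their forward and reverse 5'
#' coverage rows with standard k-means (squared Euclidean, Hartigan-Wong),
#' best of `n_init` seeded restarts by within-cluster sum of squares. With
#' unit-total scaling (the default) each site vector is divided by its total
#' count first, so clusters reflect footprint *shape* — e.g. separating
#' sites bound in opposite orientations — rather than occupancy.
#'
#' @param matrix a `profile_matrix`.
#' @param k number of clusters (`1 <= k <= n_sites`). Default 4.
#' @param seed RNG seed; the clustering is deterministic given the seed.
#' @param n_init number of random restarts. Default 10.
#' @param scale_unit scale each site vector to unit total. Default TRUE.
#' @return object of class `cluster_result`: list with `k`, `assignment`
#'   (integer label per site), `centroids` (k x features), `inertia`
#'   (total within-cluster sum of squares), `sizes`, `hits`.
#' @export
cluster_sites <- function(matrix, k = 4, seed = 1, n_init = 10,
                          scale_unit = TRUE) {
  ns <- n_sites(matrix)
  if (k < 1) stop("'k' must be >= 1")
  if (k > ns) stop("'k' (", k, ") exceeds the number of sites (", ns, ")")
  v <- site_vectors(matrix, scale_unit)
  if (k == 1) {
    centroid <- matrix(colMeans(v), nrow = 1)
    return(structure(
      list(k = 1L, assignment = rep(1L, ns), centroids = centroid,
           inertia = sum(sweep(v, 2, centroid[1, ])^2),
           sizes = ns, hits = matrix$hits),
      class = "cluster_result"))
  }
  km <- withr::with_seed(seed, {
    stats::kmeans(v, centers = k, nstart = n_init, iter.max = 100)
  })
  structure(
    list(k = as.integer(k), assignment = unname(km$cluster),
         centroids = km$centers, inertia = km$tot.withinss,
         sizes = unname(km$size), hits = matrix$hits),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("K-means result: k =", x$k, "; sizes =",
      paste(x$sizes, collapse = ", "),
      sprintf("; inertia = %.3f", x$inertia), "\n")
  invisible(x)
}

#' Per-cluster aggregated footprint profiles
#'
#' @param matrix the `profile_matrix` that was clustered.
#' @param result the matching `cluster_result`.
#' @return list of `footprint_profile`s, one per cluster label.
#' @export
cluster_profiles <- function(matrix, result) {
  lapply(seq_len(result$k), function(cl) {
    sel <- which(result$assignment == cl)
    sub <- matrix
    sub$values <- matrix$values[sel, , , drop = FALSE]
    sub$hits <- matrix$hits[sel]
    aggregate_footprint(sub)
  })
}

#' Write cluster assignments as TSV (site BED6 + cluster label)
#' @param result a `cluster_result`.
#' @param path output file.
#' @export
export_clusters_tsv <- function(result, path) {
  h <- result$hits
  write.table(
    data.frame(chrom = as.character(seqnames(h)), start = start(h) - 1L,
               end = end(h), name = mcols(h)$motif_id, score = 0L,
               strand = as.character(strand(h)),
               cluster = result$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
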