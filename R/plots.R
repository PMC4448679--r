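#' @import ggplot2
NULL

profile_long <- function(profile) {
  data.frame(
    position = rep(profile$positions, 2),
    strand = rep(c("forward", "reverse"), each = length(profile$positions)),
    count = c(profile$forward, profile$reverse))
}

#' Footprint profile plot with optional permutation envelope
#'
#' Forward- and reverse-strand 5' counts per relative position; when an
#' envelope is given, its median is drawn dotted and the interquartile range
#' shaded, per strand, after rescaling the normalized envelope back to the
#' profile's site count.
#'
#' @param profile a `footprint_profile`.
#' @param envelope optional `permutation_envelope` on the same axis.
#' @return a ggplot object.
#' @export
plot_footprint <- function(profile, envelope = NULL) {
  df <- profile_long(profile)
  gg <- ggplot(df, aes(x = .data$position, y = .data$count,
                       colour = .data$strand))
  if (!is.null(envelope)) {
    scale <- profile$n_sites
    env <- data.frame(
      position = rep(envelope$positions, 2),
      strand = rep(c("forward", "reverse"),
                   each = length(envelope$positions)),
      med = c(envelope$median["forward", ], envelope$median["reverse", ]) * scale,
      q1 = c(envelope$q1["forward", ], envelope$q1["reverse", ]) * scale,
      q3 = c(envelope$q3["forward", ], envelope$q3["reverse", ]) * scale)
    gg <- gg +
      geom_ribbon(data = env,
                  aes(x = .data$position, ymin = .data$q1, ymax = .data$q3,
                      fill = .data$strand),
                  alpha = 0.25, inherit.aes = FALSE) +
      geom_line(data = env,
                aes(x = .data$position, y = .data$med,
                    colour = .data$strand),
                linetype = "dotted", inherit.aes = FALSE)
  }
  gg + geom_line() +
    scale_colour_manual(values = c(forward = "#1b6ca8", reverse = "#c0392b")) +
    scale_fill_manual(values = c(forward = "#1b6ca8", reverse = "#c0392b")) +
    labs(x = "position relative to motif center (bp)",
         y = "5' read count",
         title = sprintf("Footprint profile (%d sites)", profile$n_sites)) +
    theme_bw()
}

#' Per-site 5' coverage heatmap
#'
#' One row per site (ordered by descending occupancy), combining the two
#' strands in a diverging palette: forward counts positive (blue), reverse
#' counts negative (red).
#'
#' @param matrix a `profile_matrix`.
#' @param max_sites cap on rows displayed (most occupied first).
#' @return a ggplot object.
#' @export
plot_site_heatmap <- function(matrix, max_sites = 500) {
  m <- select_top_occupied(matrix, min(max_sites, n_sites(matrix)))
  ns <- n_sites(m)
  signed <- m$values[, , "forward"] - m$values[, , "reverse"]
  if (ns == 1) signed <- matrix(signed, nrow = 1)
  df <- data.frame(
    site = rep(seq_len(ns), times = length(m$positions)),
    position = rep(m$positions, each = ns),
    value = as.vector(signed))
  lim <- max(abs(df$value), 1)
  ggplot(df, aes(x = .data$position, y = .data$site, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#c0392b", mid = "white", high = "#1b6ca8",
                         limits = c(-lim, lim),
                         name = "fwd - rev 5' count") +
    scale_y_reverse() +
    labs(x = "position relative to motif center (bp)",
         y = "site (by occupancy)",
         title = "5' coverage heatmap") +
    theme_bw()
}

#' Color chart of matched motif sequences
#'
#' One row per site in the same order as the coverage heatmap, one colored
#' cell per motif position showing the matched base on the motif strand.
#'
#' @param matrix a `profile_matrix` (supplies the site order), or a hit
#'   `GRanges` with a `matched_seq` column.
#' @param max_sites cap on rows displayed.
#' @return a ggplot object.
#' @export
plot_sequence_chart <- function(matrix, max_sites = 500) {
  hits <- if (is(matrix, "profile_matrix")) {
    select_top_occupied(matrix, min(max_sites, n_sites(matrix)))$hits
  } else {
    head(matrix, max_sites)
  }
  seqs <- mcols(hits)$matched_seq
  L <- nchar(seqs[1])
  df <- data.frame(
    site = rep(seq_along(seqs), each = L),
    position = rep(seq_len(L), times = length(seqs)),
    base = unlist(strsplit(seqs, "")))
  ggplot(df, aes(x = .data$position, y = .data$site, fill = .data$base)) +
    geom_raster() +
    scale_fill_manual(values = c(A = "#2ecc71", C = "#3498db",
                                 G = "#f1c40f", T = "#e74c3c")) +
    scale_y_reverse() +
    scale_x_continuous(breaks = seq_len(L)) +
    labs(x = "motif position", y = "site", title = "Matched sequences") +
    theme_bw()
}

#' Difference heatmap between two profiles
#'
#' Renders a [profile_difference()] as a two-row (strand by position)
#' diverging heatmap, the usual companion strip under a subsampled profile.
#'
#' @param diff a `profile_difference`.
#' @return a ggplot object.
#' @export
plot_profile_difference <- function(diff) {
  df <- data.frame(
    position = rep(diff$positions, 2),
    strand = rep(c("forward", "reverse"), each = length(diff$positions)),
    value = c(diff$forward, diff$reverse))
  lim <- max(abs(df$value), 1e-9)
  ggplot(df, aes(x = .data$position, y = .data$strand, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#c0392b", mid = "white", high = "#1b6ca8",
                         limits = c(-lim, lim), name = "difference") +
    labs(x = "position relative to motif center (bp)", y = NULL,
         title = "Profile difference") +
    theme_bw()
}
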