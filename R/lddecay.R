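#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two gene-content vectors over jointly
#' non-missing samples — the genotype-based r2, which matches the haplotype
#' r2 under random mating and is invariant to allele-label flips.
#'
#' @param g1,g2 genotype vectors (0/1/2/NA) of equal length.
#' @return r2 in \[0, 1\]; `NA` when either marker is monomorphic on the
#'   joint non-missing set.
#' @export
pair_r2 <- function(g1, g2) {
  assert_that(length(g1) == length(g2), "genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) abort("fewer than 2 jointly non-missing samples")
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' LD decay curve and decay distance
#'
#' Computes r2 for every intra-chromosomal marker pair within `max_dist_bp`,
#' bins the pairs by distance, and reports the mean r2 per bin. The decay
#' distance is where the binned mean first drops below `r2_threshold`,
#' linearly interpolated between the adjacent bin midpoints. Markers are
#' sorted internally, so input order does not matter; monomorphic-pair r2
#' values are excluded; empty bins report `n_pairs = 0` and `NA` mean.
#'
#' @param md a [marker_data()] object.
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @param bin_width_bp distance bin width (default 10 kb).
#' @param r2_threshold threshold defining the decay distance (default 0.2).
#' @return Object of class `ld_curve`: tibble `bins` (bin_lo, bin_hi,
#'   mid_bp, mean_r2, n_pairs) plus `decay_distance_bp` (NA when the curve
#'   never crosses the threshold).
#' @export
decay_curve <- function(md, max_dist_bp = 1e6, bin_width_bp = 1e4,
                        r2_threshold = 0.2) {
  map <- md$map
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  calls <- md$calls[, ord, drop = FALSE]
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  sum_r2 <- numeric(n_bins)
  n_pair <- integer(n_bins)
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    if (length(idx) < 2) next
    pos <- map$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist_bp) {
        d <- pos[b] - pos[a]
        r2 <- tryCatch(pair_r2(calls[, idx[a]], calls[, idx[b]]),
                       error = function(e) NA_real_)
        if (!is.na(r2) && d > 0) {
          bin <- min(ceiling(d / bin_width_bp), n_bins)
          sum_r2[bin] <- sum_r2[bin] + r2
          n_pair[bin] <- n_pair[bin] + 1L
        }
        b <- b + 1L
      }
    }
  }
  if (sum(n_pair) == 0) abort("no qualifying marker pairs within max_dist_bp")
  bins <- tibble(
    bin_lo = (seq_len(n_bins) - 1) * bin_width_bp,
    bin_hi = seq_len(n_bins) * bin_width_bp,
    mid_bp = (seq_len(n_bins) - 0.5) * bin_width_bp,
    mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(n_pair, 1), NA_real_),
    n_pairs = n_pair
  )
  occ <- dplyr::filter(bins, .data$n_pairs > 0)
  decay <- NA_real_
  below <- which(occ$mean_r2 < r2_threshold)
  if (length(below) > 0) {
    k <- below[1]
    if (k == 1) {
      decay <- occ$mid_bp[1]
    } else {
      x0 <- occ$mid_bp[k - 1]; x1 <- occ$mid_bp[k]
      y0 <- occ$mean_r2[k - 1]; y1 <- occ$mean_r2[k]
      decay <- x0 + (y0 - r2_threshold) / (y0 - y1) * (x1 - x0)
    }
  }
  structure(list(bins = bins, decay_distance_bp = decay,
                 r2_threshold = r2_threshold, max_dist_bp = max_dist_bp),
            class = "ld_curve")
}

#' @export
print.ld_curve <- function(x, ...) {
  cat(sprintf("<ld_curve> %d occupied bins; decay distance at r2 = %.2f: %s\n",
              sum(x$bins$n_pairs > 0), x$r2_threshold,
              if (is.na(x$decay_distance_bp)) "not reached"
              else sprintf("%.0f bp", x$decay_distance_bp)))
  invisible(x)
}
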