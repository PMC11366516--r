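#' Sliding-window percentage of genetic variance
#'
#' For every anchor SNP, the window is the run of consecutive SNPs on the
#' same chromosome starting at the anchor and lying within `window_bp` of it.
#' The window's genetic values a_i = sum_j Z_j u_j are computed over
#' individuals and the statistic is Var(a_i) / sigma_a2 x 100, with
#' population-variance denominator n by default.
#'
#' @param u per-marker SNP effects (e.g. final-iteration `u_hat` from
#'   [run_wssgwas()]), in map order.
#' @param Z centered gene-content matrix (columns in map order).
#' @param map tibble `marker`, `chrom`, `pos` sorted by chromosome and
#'   position; an unsorted map is an error.
#' @param sigma_a2 additive genetic variance (denominator).
#' @param window_bp window span (default 520,000).
#' @param denominator "n" (population variance, default) or "n-1".
#' @return Tibble of class `wssgwas_scan`: chrom, start_bp, end_bp, anchor,
#'   n_snp, pct_var, plus anchor/end column indices `idx_start`, `idx_end`.
#' @export
window_scan <- function(u, Z, map, sigma_a2, window_bp = 520000,
                        denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  assert_that(length(u) == ncol(Z) && nrow(map) == ncol(Z),
              "u, Z and map must agree on marker count")
  assert_that(sigma_a2 > 0, "sigma_a2 must be positive")
  srt <- order(map$chrom, map$pos)
  if (!identical(srt, seq_len(nrow(map))) &&
      !identical(map$pos[srt], map$pos))
    abort("map is not sorted by chromosome and position")
  vfun <- if (denominator == "n") var_pop else function(x) stats::var(x)
  out <- vector("list", length(unique(map$chrom)))
  ci <- 0L
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    pos <- map$pos[idx]
    res <- matrix(0, length(idx), 3)  # idx_end, n_snp, pct
    for (jj in seq_along(idx)) {
      kk <- jj
      while (kk < length(idx) && pos[kk + 1] < pos[jj] + window_bp) kk <- kk + 1L
      cols <- idx[jj:kk]
      a_vec <- Z[, cols, drop = FALSE] %*% u[cols]
      res[jj, ] <- c(kk, kk - jj + 1, vfun(as.numeric(a_vec)) / sigma_a2 * 100)
    }
    ci <- ci + 1L
    out[[ci]] <- tibble(
      chrom = chrom,
      start_bp = pos,
      end_bp = pos[res[, 1]],
      anchor = map$marker[idx],
      n_snp = as.integer(res[, 2]),
      pct_var = res[, 3],
      idx_start = idx,
      idx_end = idx[res[, 1]]
    )
  }
  scan <- dplyr::bind_rows(out)
  class(scan) <- c("wssgwas_scan", class(scan))
  attr(scan, "sigma_a2") <- sigma_a2
  attr(scan, "window_bp") <- window_bp
  scan
}

#' Significant windows merged into regions
#'
#' Anchored windows at or above the threshold are selected and overlapping
#' significant windows on the same chromosome are merged into regions,
#' reported with the span, the maximum window percentage, and the number of
#' distinct SNPs covered.
#'
#' @param wv a [window_scan()] result.
#' @param cfg a [wssgwas_config()]; `sig_threshold_pct` is the cutoff, or,
#'   when `NULL`, `threshold_fold * 100 / n_windows`.
#' @return Tibble: chrom, start_bp, end_bp, pct_var (max), n_snp,
#'   n_windows.
#' @export
significant_windows <- function(wv, cfg = wssgwas_config()) {
  thr <- cfg$sig_threshold_pct %||% (cfg$threshold_fold * 100 / nrow(wv))
  sig <- dplyr::filter(wv, .data$pct_var >= thr)
  if (nrow(sig) == 0)
    return(tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), pct_var = numeric(),
                  n_snp = integer(), n_windows = integer()))
  sig <- dplyr::arrange(sig, .data$chrom, .data$start_bp)
  rows <- list()
  cur <- NULL
  flush <- function(cur) tibble(
    chrom = cur$chrom, start_bp = cur$start, end_bp = cur$end,
    pct_var = cur$pct, n_snp = as.integer(cur$i2 - cur$i1 + 1L),
    n_windows = cur$nw)
  for (r in seq_len(nrow(sig))) {
    w <- sig[r, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$start_bp <= cur$end) {
      cur$end <- max(cur$end, w$end_bp)
      cur$pct <- max(cur$pct, w$pct_var)
      cur$i2 <- max(cur$i2, w$idx_end)
      cur$nw <- cur$nw + 1L
    } else {
      if (!is.null(cur)) rows[[length(rows) + 1]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start_bp, end = w$end_bp,
                  pct = w$pct_var, i1 = w$idx_start, i2 = w$idx_end, nw = 1L)
    }
  }
  rows[[length(rows) + 1]] <- flush(cur)
  dplyr::bind_rows(rows)
}

#' Phenotype means by genotype class at one marker
#'
#' Mean trait value of records grouped by the animals' genotype (0/1/2) at a
#' marker, with record and animal counts — the usual follow-up on a top
#' window's peak SNP. Classes with no genotyped records are absent from the
#' output (not reported as zero).
#'
#' @param data trait records.
#' @param md [marker_data()] holding the marker.
#' @param marker_id marker name.
#' @return Tibble: genotype, n_records, n_animals, mean_value; attribute
#'   `hom_difference` = mean(class 2) - mean(class 0) when both exist.
#' @export
genotype_class_means <- function(data, md, marker_id) {
  j <- match(marker_id, colnames(md$calls))
  if (is.na(j)) abort(sprintf("marker '%s' not present", marker_id))
  g <- md$calls[, j]
  df <- as_tibble(data)
  df$genotype <- unname(g[match(as.character(df$animal), names(g))])
  df <- dplyr::filter(df, !is.na(.data$genotype))
  out <- df |>
    dplyr::group_by(genotype = .data$genotype) |>
    dplyr::summarise(n_records = dplyr::n(),
                     n_animals = dplyr::n_distinct(.data$animal),
                     mean_value = mean(.data$value), .groups = "drop")
  hd <- if (all(c(0, 2) %in% out$genotype))
    out$mean_value[out$genotype == 2] - out$mean_value[out$genotype == 0]
  else NA_real_
  attr(out, "hom_difference") <- hd
  out
}

#' Annotate regions with overlapping genes
#'
#' Reads gene intervals from a BED or GFF3 file (or takes a data frame with
#' `chrom`, `start`, `end`, `gene`) and lists, per region, the genes whose
#' interval overlaps it. Both regions and genes are treated as half-open
#' \[start, end): a gene starting exactly at a region's end does not overlap.
#' Regions on chromosomes absent from the annotation are reported with a
#' message rather than silently unmatched.
#'
#' @param regions tibble from [significant_windows()] (needs `chrom`,
#'   `start_bp`, `end_bp`).
#' @param annotation path to a BED/GFF3 file, or a data frame.
#' @return `regions` with a `genes` column ("-" when no gene overlaps).
#' @export
annotate_windows <- function(regions, annotation) {
  ann <- read_annotation(annotation)
  if (nrow(regions) == 0) {
    regions$genes <- character(0)
    return(regions)
  }
  missing_chr <- setdiff(unique(regions$chrom), unique(ann$chrom))
  if (length(missing_chr) > 0)
    message("chromosome(s) absent from annotation (naming mismatch?): ",
            paste(missing_chr, collapse = ", "))
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- ann$chrom == regions$chrom[i] &
      ann$start < regions$end_bp[i] & ann$end > regions$start_bp[i]
    if (!any(hit)) "-" else paste(unique(ann$gene[hit]), collapse = ", ")
  }, character(1))
  regions
}

read_annotation <- function(annotation) {
  if (is.data.frame(annotation)) {
    assert_that(all(c("chrom", "start", "end", "gene") %in% names(annotation)),
                "annotation data frame needs chrom, start, end, gene")
    return(as_tibble(annotation))
  }
  if (!file.exists(annotation)) abort(paste("annotation file not found:", annotation))
  if (grepl("\\.bed$", annotation, ignore.case = TRUE)) {
    bed <- readr::read_tsv(annotation, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    assert_that(ncol(bed) >= 4, "BED annotation needs a 4th (name) column")
    # BED is 0-based half-open; shift to 1-based half-open [start+1, end+1)
    return(tibble(chrom = as.character(bed[[1]]), start = bed[[2]] + 1,
                  end = bed[[3]] + 1, gene = as.character(bed[[4]])))
  }
  if (grepl("\\.gff3?(\\.gz)?$", annotation, ignore.case = TRUE)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(annotation)
      gr <- gr[gr$type %in% c("gene", "pseudogene")]
      mc <- S4Vectors::mcols(gr)
      nm <- mc$Name %||% mc$gene_name %||% mc$gene_id %||% mc$ID
      # GFF3 is 1-based closed; half-open end is end + 1
      return(tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr) + 1,
                    gene = as.character(nm)))
    }
    gff <- readr::read_tsv(annotation, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    gff <- gff[gff[[3]] %in% c("gene", "pseudogene"), ]
    nm <- sub(".*(?:Name|gene_id|ID)=([^;]+).*", "\\1", gff[[9]], perl = TRUE)
    return(tibble(chrom = as.character(gff[[1]]), start = gff[[4]],
                  end = gff[[5]] + 1, gene = nm))
  }
  abort("annotation must be a data frame or a .bed/.gff/.gff3 file")
}
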