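#' Run the full evaluation pipeline and write its artifacts
#'
#' Orchestrates the stages end to end: read inputs (or accept in-memory
#' objects), marker QC, PBLUP and ssGBLUP REML variance components, the
#' weighted single-step loop, the window-variance scan with significance
#' calls and optional gene annotation, and the LD-decay curve. Every stage's
#' table is written as TSV/YAML into `out_dir`, together with the exact
#' configuration used and the package version, so a rerun with the same
#' inputs reproduces the outputs.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `pedigree` (CSV path or pedigree object), `genotypes` (list with `ped`
#'   and `map` PLINK-text paths, or a `marker_data` object), `phenotypes`
#'   (CSV path or data frame), optional `annotation` (BED/GFF3 path),
#'   optional `qc` (arguments to [qc_config()]), optional `wssgwas`
#'   (arguments to [wssgwas_config()]), optional `tau`.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  ped <- config$pedigree
  if (is.character(ped)) ped <- read_pedigree(ped)
  md <- config$genotypes
  if (!inherits(md, "marker_data"))
    md <- read_plink_text(md$ped, md$map)
  phen <- config$phenotypes
  if (is.character(phen))
    phen <- readr::read_csv(phen, show_col_types = FALSE)

  say("QC: %d markers in", ncol(md$calls))
  qc_cfg <- do.call(qc_config, config$qc %||% list())
  qc <- apply_qc(md, qc_cfg)
  md <- qc$markers
  say("QC: %d markers out", ncol(md$calls))
  yaml::write_yaml(list(
    removed = setNames(as.list(qc$report$removed$n_removed),
                       qc$report$removed$rule),
    n_markers_in = qc$report$n_markers_in,
    n_markers_out = qc$report$n_markers_out), file.path(out_dir, "qc_report.yaml"))

  conflicts <- parentage_check(md, ped, qc_cfg)
  if (nrow(conflicts) > 0)
    readr::write_tsv(conflicts, file.path(out_dir, "parentage_conflicts.tsv"))

  Fv <- inbreeding(ped)
  Ainv <- a_inverse(ped)
  say("REML: PBLUP")
  reml_p <- fit_reml(phen, Ainv)
  ks <- kinship_set(ped, md, tau = config$tau %||% 0.95)
  say("REML: ssGBLUP")
  reml_g <- fit_reml(phen, ks$Hinv)
  vc_tbl <- dplyr::bind_rows(
    dplyr::mutate(tidy(reml_p), method = "PBLUP"),
    dplyr::mutate(tidy(reml_g), method = "ssGBLUP"))
  yaml::write_yaml(list(
    PBLUP = c(as.list(reml_p$vc), h2 = reml_p$h2, h2_se = reml_p$h2_se),
    ssGBLUP = c(as.list(reml_g$vc), h2 = reml_g$h2, h2_se = reml_g$h2_se)),
    file.path(out_dir, "variance_components.yaml"))

  say("WssGWAS loop")
  ws_cfg <- do.call(wssgwas_config, config$wssgwas %||% list())
  run <- run_wssgwas(phen, md, ped, reml_g, cfg = ws_cfg,
                     tau = config$tau %||% 0.95, F = Fv)
  final <- run$iterations[[length(run$iterations)]]
  readr::write_tsv(
    tibble(marker = names(final$u_hat), u_hat = unname(final$u_hat),
           weight = final$weights),
    file.path(out_dir, "snp_effects.tsv"))
  readr::write_tsv(final$fit$solutions, file.path(out_dir, "solutions.tsv"))

  scan <- window_scan(final$u_hat, run$Z, run$map, reml_g$vc[["sigma_a2"]],
                      window_bp = ws_cfg$window_bp)
  readr::write_tsv(scan[, c("chrom", "start_bp", "end_bp", "anchor",
                            "n_snp", "pct_var")],
                   file.path(out_dir, "window_scan.tsv"))
  regions <- significant_windows(scan, ws_cfg)
  if (!is.null(config$annotation))
    regions <- annotate_windows(regions, config$annotation)
  readr::write_tsv(region_report(regions), file.path(out_dir, "significant_regions.tsv"))

  say("LD decay")
  ld <- decay_curve(md)
  readr::write_tsv(ld$bins, file.path(out_dir, "ld_curve.tsv"))
  yaml::write_yaml(list(decay_distance_bp = ld$decay_distance_bp,
                        r2_threshold = ld$r2_threshold),
                   file.path(out_dir, "ld_summary.yaml"))

  yaml::write_yaml(list(
    package_version = as.character(utils::packageVersion("wssgblup")),
    qc = unclass(qc_cfg), wssgwas = unclass(ws_cfg),
    tau = config$tau %||% 0.95), file.path(out_dir, "run_config.yaml"))

  invisible(list(ped = ped, markers = md, qc_report = qc$report,
                 parentage = conflicts, reml_pblup = reml_p,
                 reml_ssgblup = reml_g, varcomp = vc_tbl, wssgwas = run,
                 scan = scan, regions = regions, ld = ld))
}

# human-readable region table: Mb positions rounded to 2 decimals,
# exact bp kept in the machine columns
region_report <- function(regions) {
  if (nrow(regions) == 0) return(regions)
  out <- regions
  out$position_mb <- sprintf("%.2f-%.2f", regions$start_bp / 1e6,
                             regions$end_bp / 1e6)
  out
}
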