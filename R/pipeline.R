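# End-to-end orchestration: ingest/simulate -> QC (gwas + roh profiles) ->
# ROH -> F_ROH -> islands -> GWAS -> consolidated report.

#' Run the full pipeline from one configuration
#'
#' The configuration is an R list (or the path of a YAML file holding one)
#' with elements:
#' \describe{
#'   \item{sim}{arguments for [sim_config()] (simulated input), plus
#'     optional `sweeps` data.frame and `qtl` list as in
#'     [simulate_dataset()]; mutually exclusive with `input`.}
#'   \item{input}{`list(bed, bim, fam)` or `list(ped, map)` paths, plus
#'     optional `pheno` path.}
#'   \item{qc}{overrides for [qc_config()] (applied to both profiles).}
#'   \item{roh}{overrides for [roh_params()].}
#'   \item{islands}{`threshold_pct` (default 30), `min_markers` (default 1).}
#'   \item{gwas}{`traits` (character; default all phenotype columns),
#'     `model` ("glm" or "mlm"), `alpha` (default 0.01), `n_pcs`
#'     (default 3).}
#'   \item{autosome_bp}{F_ROH denominator; defaults to the simulated
#'     autosome length for simulated input and [BTA_AUTOSOME_BP]
#'     otherwise.}
#'   \item{seed}{RNG seed (required for simulated input).}
#' }
#'
#' @param config list or YAML file path.
#' @param out_dir optional directory; when given, all stage tables are
#'   written as TSV/JSON together with a manifest recording inputs,
#'   parameters and seed.
#' @return a `run_report` list with elements `qc_gwas`, `qc_roh`
#'   (QC reports), `segments`, `roh_summary`, `froh`, `froh_summary`,
#'   `islands`, `track`, `gwas` (per-trait scans or NULL), `hits`
#'   (significant-marker table), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$sim) && is.null(config$input)) {
    stop("stage 'input': config needs either 'sim' or 'input'")
  }

  # ---- input ----
  pheno <- NULL
  autosome_bp <- config$autosome_bp
  if (!is.null(config$sim)) {
    simargs <- config$sim
    sweeps <- simargs$sweeps; simargs$sweeps <- NULL
    qtl <- simargs$qtl; simargs$qtl <- NULL
    if (is.null(simargs$seed)) simargs$seed <- config$seed
    if (!is.null(sweeps)) sweeps <- as.data.frame(sweeps)
    cfg <- do.call(sim_config, simargs)
    sim <- simulate_dataset(cfg, sweeps = sweeps, qtl = qtl)
    geno <- sim$geno; map <- sim$map
    if (!is.null(sim$pheno)) {
      pheno <- data.frame(sample_id = names(sim$pheno),
                          protein_pct_305d_l1 = as.numeric(sim$pheno),
                          stringsAsFactors = FALSE)
    }
    if (is.null(autosome_bp)) autosome_bp <- sim$truth$autosome_bp
  } else {
    inp <- config$input
    if (!is.null(inp$bed)) {
      dat <- read_plink_bed(inp$bed, inp$bim, inp$fam)
    } else {
      dat <- read_plink_text(inp$ped, inp$map)
    }
    geno <- dat$geno; map <- dat$map
    if (!is.null(inp$pheno)) {
      pheno <- read_phenotypes(inp$pheno, samples = rownames(geno))
    }
    if (is.null(autosome_bp)) autosome_bp <- BTA_AUTOSOME_BP
  }

  # ---- QC, both profiles ----
  qc_args <- config$qc %||% list()
  ds_gwas <- tryCatch(
    build_dataset(geno, map, do.call(qc_config, c(qc_args, profile = "gwas"))),
    error = function(e) stop("stage 'qc/gwas': ", conditionMessage(e)))
  ds_roh <- tryCatch(
    build_dataset(geno, map, do.call(qc_config, c(qc_args, profile = "roh"))),
    error = function(e) stop("stage 'qc/roh': ", conditionMessage(e)))
  message(sprintf("QC (gwas): left %d out of %d markers in %d animals",
                  ds_gwas$report$markers_out, ds_gwas$report$markers_in,
                  ds_gwas$report$samples_out))
  message(sprintf("QC (roh):  left %d out of %d markers in %d animals",
                  ds_roh$report$markers_out, ds_roh$report$markers_in,
                  ds_roh$report$samples_out))

  # ---- ROH / F_ROH / islands ----
  params <- do.call(roh_params, config$roh %||% list())
  segments <- tryCatch(call_roh_all(ds_roh$geno, ds_roh$map, params),
                       error = function(e) stop("stage 'roh': ",
                                                conditionMessage(e)))
  samples <- rownames(ds_roh$geno)
  roh_sum <- summarize_roh(segments, samples)
  froh_tab <- froh_all(segments, samples, autosome_bp)
  froh_sum <- froh_population_summary(froh_tab)
  isl_cfg <- config$islands %||% list()
  track <- snp_in_roh_frequency(segments, ds_roh$map, length(samples))
  islands <- detect_islands(track, isl_cfg$threshold_pct %||% 30,
                            isl_cfg$min_markers %||% 1L)

  # ---- GWAS ----
  gwas <- NULL
  hits <- data.frame()
  if (is.null(pheno)) {
    message("no phenotypes supplied; GWAS stage skipped")
  } else {
    gw <- config$gwas %||% list()
    traits <- gw$traits %||% setdiff(names(pheno), c("sample_id", "in_genotypes"))
    model <- gw$model %||% "mlm"
    alpha <- gw$alpha %||% 0.01
    n_pcs <- gw$n_pcs %||% 3L
    g <- ds_gwas$geno
    idx <- match(rownames(g), pheno$sample_id)
    K <- compute_kinship(g)
    pcs <- compute_pcs(g, n_pcs)
    gwas <- list()
    for (tr in traits) {
      if (!tr %in% names(pheno)) stop("stage 'gwas': trait not in phenotype table: ", tr)
      y <- pheno[[tr]][idx]
      scan <- tryCatch({
        if (model == "glm") glm_scan(g, ds_gwas$map, y, pcs, alpha)
        else mlm_scan(g, ds_gwas$map, y, K, pcs, alpha)$scan
      }, error = function(e) stop("stage 'gwas' (", tr, "): ",
                                  conditionMessage(e)))
      gwas[[tr]] <- scan
      sig <- scan$result[scan$result$significant, , drop = FALSE]
      if (nrow(sig)) {
        sig$trait <- tr
        hits <- rbind(hits, sig)
      }
    }
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("rohscan")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    sim = if (!is.null(config$sim)) config$sim[setdiff(names(config$sim),
                                                       c("sweeps", "qtl"))],
    autosome_bp = autosome_bp,
    roh_params = unclass(params))

  report <- structure(list(qc_gwas = ds_gwas$report, qc_roh = ds_roh$report,
                           geno_gwas = ds_gwas$geno, map_gwas = ds_gwas$map,
                           geno_roh = ds_roh$geno, map_roh = ds_roh$map,
                           segments = segments, roh_summary = roh_sum,
                           froh = froh_tab, froh_summary = froh_sum,
                           track = track, islands = islands,
                           gwas = gwas, hits = hits,
                           manifest = manifest),
                      class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pfx <- file.path(out_dir, "run")
    write_roh(segments, pfx)
    write_islands(islands, track, pfx)
    utils::write.table(froh_tab, paste0(pfx, ".froh.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(roh_sum$per_animal, paste0(pfx, ".roh_per_animal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gwas)) {
      for (tr in names(gwas)) {
        write_assoc(gwas[[tr]], ds_gwas$geno,
                    paste0(pfx, ".gwas.", tr, ".tsv"))
      }
    }
    jsonlite::write_json(list(qc_gwas = ds_gwas$report, qc_roh = ds_roh$report),
                         paste0(pfx, ".qc.json"), auto_unbox = TRUE)
    jsonlite::write_json(manifest, paste0(pfx, ".manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rohscan pipeline report\n")
  cat(sprintf("  QC (gwas): %d/%d markers, %d animals\n",
              x$qc_gwas$markers_out, x$qc_gwas$markers_in,
              x$qc_gwas$samples_out))
  cat(sprintf("  QC (roh):  %d/%d markers, %d animals\n",
              x$qc_roh$markers_out, x$qc_roh$markers_in,
              x$qc_roh$samples_out))
  cat(sprintf("  ROH: %d segments, %.2f per animal, mean %.2f Mbp\n",
              x$roh_summary$n_segments, x$roh_summary$mean_per_animal,
              x$roh_summary$grand_mean_length_mbp))
  cat(sprintf("  F_ROH: mean %.3f (min %.3f, max %.3f)\n",
              mean(x$froh$f_roh_total), min(x$froh$f_roh_total),
              max(x$froh$f_roh_total)))
  cat(sprintf("  Islands: %d (threshold scan over %d markers)\n",
              nrow(x$islands), nrow(x$track)))
  if (!is.null(x$gwas)) {
    for (tr in names(x$gwas)) {
      s <- x$gwas[[tr]]
      cat(sprintf("  GWAS %s [%s]: lambda %.3f, %d significant\n",
                  tr, s$model, s$lambda_gc, length(s$significant_markers)))
    }
  } else cat("  GWAS: skipped (no phenotypes)\n")
  invisible(x)
}
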