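#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()]:
#' simulation settings (or paths to existing PED/MAP, pedigree and trait
#' files), QC thresholds, ROH rule, PCA and scan settings.  Any element
#' can be overridden in the YAML config file.
#'
#' @return named list.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = TRUE,
    sim = list(),            # overrides passed to sim_config()
    ped_path = NULL, map_path = NULL, pedigree_path = NULL,
    traits_path = NULL,
    qc = list(maf_min = 0.01, hwe_neglogp_max = 3,
              snp_callrate_min = 0.8, ind_missing_max = 0.2),
    roh = list(min_snps = 50L),
    pca = list(k = 5L),
    scan = list(n_perm = 200L),
    regions = list(merge_gap_bp = 1e6, min_span_bp = 1e6),
    windows = list(window_snps = 50L, step_snps = NULL),  # NULL = window
    seed = 1L)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full autozygosity pipeline
#'
#' Executes the stages in dependency order: simulate (or ingest) ->
#' QC -> pedigree F -> ROH -> PCA -> association scans (FPED raw and
#' PC-adjusted, birth year, DPR, SCS, with permutation thresholds for the
#' FPED scan) -> region calling -> haplotype windows (summaries, ROH-HH
#' correlation, additive/recessive trait models).  Outputs are plain TSV
#' files under `out_dir`, and a JSON manifest records the configuration,
#' seeds, input checksums and every output path.  A missing trait table
#' skips the trait scans with a warning instead of failing.
#'
#' @param config path to a YAML configuration file, or a configuration
#'   list (see [default_pipeline_config()]).
#' @param out_dir output directory.
#' @param seed overrides the config seed when given.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "autozyg_run", seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  manifest <- list(config = cfg, seed = cfg$seed,
                   version = as.character(utils::packageVersion("autozyg")),
                   inputs = list(), outputs = list())
  stage <- function(name, expr) {
    .log_line(log_path, "stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- function(...) file.path(out_dir, ...)

  # --- simulate or ingest -------------------------------------------------
  traits <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, cfg$sim)
      simulate_cohort(sc, seed = cfg$seed)
    })
    dir.create(paths("sim"), showWarnings = FALSE)
    sim_paths <- write_sim_output(sim, paths("sim"))
    manifest$outputs$sim <- as.list(sim_paths)
    g_raw <- sim$genotypes
    pedigree <- sim$pedigree
    traits <- sim$traits
    hap <- sim$haplotypes
  } else {
    g_raw <- stage("ingest", read_ped_map(cfg$ped_path, cfg$map_path))
    manifest$inputs$ped <- unname(tools::md5sum(cfg$ped_path))
    manifest$inputs$map <- unname(tools::md5sum(cfg$map_path))
    pedigree <- stage("ingest", read_pedigree(cfg$pedigree_path))
    manifest$inputs$pedigree <- unname(tools::md5sum(cfg$pedigree_path))
    if (!is.null(cfg$traits_path)) {
      traits <- read_traits(cfg$traits_path)
      manifest$inputs$traits <- unname(tools::md5sum(cfg$traits_path))
    }
    hap <- NULL
  }

  # --- qc -----------------------------------------------------------------
  qc <- stage("qc", do.call(apply_qc, c(list(g_raw), cfg$qc)))
  g <- qc$genotypes
  dir.create(paths("qc"), showWarnings = FALSE)
  write_qc_report(qc$report, paths("qc", "qc_report.tsv"))
  write_ped_map(g, paths("qc", "genotypes.ped"), paths("qc", "genotypes.map"))
  manifest$outputs$qc <- list(report = paths("qc", "qc_report.tsv"),
                              ped = paths("qc", "genotypes.ped"),
                              map = paths("qc", "genotypes.map"))
  .log_line(log_path, "qc kept ", ncol(g$geno), "/", ncol(g_raw$geno),
            " SNPs, ", nrow(g$geno), "/", nrow(g_raw$geno), " individuals")

  # --- pedigree F ---------------------------------------------------------
  fped <- stage("fped", compute_fped(pedigree))
  dir.create(paths("fped"), showWarnings = FALSE)
  write_fped(fped, paths("fped", "fped.tsv"))
  manifest$outputs$fped <- list(fped = paths("fped", "fped.tsv"))

  # --- roh ----------------------------------------------------------------
  dir.create(paths("roh"), showWarnings = FALSE)
  defn <- do.call(roh_definition, cfg$roh)
  segments <- stage("roh", detect_roh(g, defn))
  H <- roh_state_matrix(segments, g)
  fr <- froh(H)
  fl <- locus_autozygosity(H)
  write_roh_segments(segments, paths("roh", "segments.tsv"))
  data.table::fwrite(data.frame(animal = names(fr), froh = unname(fr)),
                     paths("roh", "froh.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(snp_id = names(fl), f_l = unname(fl)),
                     paths("roh", "f_l.tsv"), sep = "\t", quote = FALSE)
  manifest$outputs$roh <- list(segments = paths("roh", "segments.tsv"),
                               froh = paths("roh", "froh.tsv"),
                               f_l = paths("roh", "f_l.tsv"))
  .log_line(log_path, nrow(segments), " ROH segments; mean FROH ",
            sprintf("%.4f", mean(fr)))

  # --- pca ----------------------------------------------------------------
  pc <- stage("pca", structure_pca(H, k = min(cfg$pca$k, dim(H) - 1L),
                                   source = "roh-states"))
  dir.create(paths("pca"), showWarnings = FALSE)
  write_pca(pc, paths("pca", "scores.tsv"), paths("pca", "explained.tsv"))
  manifest$outputs$pca <- list(scores = paths("pca", "scores.tsv"),
                               explained = paths("pca", "explained.tsv"))

  # --- association scans --------------------------------------------------
  dir.create(paths("scan"), showWarnings = FALSE)
  ids <- g$ids
  f_resp <- fped[ids]
  by_resp <- pedigree$birth_year[match(ids, pedigree$animal)]
  scans <- list()
  scans$fped_raw <- stage("scan", genome_scan(f_resp, H, map = g$map,
                                              response_name = "FPED"))
  scans$fped_adj <- stage("scan", genome_scan(f_resp, H, map = g$map,
                                              covariates = pc$scores,
                                              response_name = "FPED"))
  if (!all(is.na(by_resp)))
    scans$year_raw <- genome_scan(by_resp, H, map = g$map,
                                  response_name = "birth_year")
  if (!is.null(traits)) {
    tr <- traits[match(ids, traits$animal), ]
    for (t in intersect(c("dpr_pta", "scs_pta"), names(tr)))
      scans[[paste0(sub("_pta", "", t), "_raw")]] <-
        genome_scan(tr[[t]], H, map = g$map, response_name = t)
  } else warning("no trait table: trait scans skipped")
  thr <- stage("permutation", permutation_thresholds(
    f_resp, H, n_perm = cfg$scan$n_perm, seed = cfg$seed))
  data.table::fwrite(data.frame(level = c("suggestive", "significant"),
                                neglog10p = c(thr$suggestive_neglog10p,
                                              thr$significant_neglog10p),
                                n_perm = thr$n_permutations, seed = thr$seed),
                     paths("scan", "thresholds.tsv"), sep = "\t", quote = FALSE)
  manifest$outputs$scan <- list(thresholds = paths("scan", "thresholds.tsv"))
  for (nm in names(scans)) {
    p <- paths("scan", paste0("profile_", nm, ".tsv"))
    write_assoc_profile(scans[[nm]], p)
    manifest$outputs$scan[[paste0("profile_", nm)]] <- p
    reg <- call_regions(scans[[nm]], thr,
                        merge_gap_bp = cfg$regions$merge_gap_bp,
                        min_span_bp = cfg$regions$min_span_bp,
                        f_l = fl, companion = scans$fped_raw)
    rp <- paths("scan", paste0("regions_", nm, ".tsv"))
    data.table::fwrite(reg, rp, sep = "\t", quote = FALSE)
    manifest$outputs$scan[[paste0("regions_", nm)]] <- rp
  }

  # --- haplotype windows --------------------------------------------------
  if (!is.null(hap)) {
    dir.create(paths("windows"), showWarnings = FALSE)
    # restrict haplotypes to QC-retained SNPs and individuals
    keep_snp <- match(g$map$snp_id, hap$map$snp_id)
    keep_ind <- match(ids, hap$ids)
    rows <- as.vector(rbind(2L * keep_ind - 1L, 2L * keep_ind))
    hap_qc <- haplotype_matrix(hap$alleles[rows, keep_snp, drop = FALSE],
                               ids, g$map)
    step <- cfg$windows$step_snps
    win <- make_windows(g$map, cfg$windows$window_snps,
                        if (is.null(step)) cfg$windows$window_snps else step)
    wt <- stage("windows", window_table(hap_qc, win))
    data.table::fwrite(wt, paths("windows", "window_table.tsv"),
                       sep = "\t", quote = FALSE)
    manifest$outputs$windows <- list(
      table = paths("windows", "window_table.tsv"))
    hhr <- hh_vs_roh_correlation(H, hap_qc, win)
    .log_line(log_path, "ROH-HH correlation over windows: ",
              sprintf("%.3f", hhr$r))
    manifest$hh_roh_correlation <- hhr$r
    if (!is.null(traits)) {
      tr <- traits[match(ids, traits$animal), ]
      for (mdl in c("additive", "recessive")) {
        prof <- haplotype_trait_association(hap_qc, win, tr$dpr_pta,
                                            model = mdl)
        p <- paths("windows", paste0("profile_dpr_", mdl, ".tsv"))
        write_assoc_profile(prof, p)
        manifest$outputs$windows[[paste0("dpr_", mdl)]] <- p
      }
    }
  }

  manifest_path <- paths("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  .log_line(log_path, "pipeline complete; manifest at ", manifest_path)
  invisible(manifest)
}
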