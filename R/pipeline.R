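# End-to-end orchestration: simulate (or read) -> QC -> HRR runs + HBD
# segments -> islands -> Tajima windows/signals -> hot spots, overlaps,
# ANOVA, FST. Two QC tiers are kept strictly separate: runs and islands
# consume the missingness-filtered data (QC1) and never see the MAF
# filter; Tajima's D and FST consume the additionally MAF-filtered data
# (QC2).

#' Pipeline configuration
#'
#' Defaults are the package's standard settings: missingness 0.10 on both
#' axes, MAF 0.01, 20 animals per breed, HRR runs at 20 SNPs / 50 kb /
#' 50 kb gap / 3 opposite / 1 missing, HBD classes 2..64 with non-HBD
#' rate 128, top-0.1% island and signal thresholds with at least 2 SNPs
#' per island, 250 kb windows and a one-sided z threshold of 1.645.
#'
#' @param sim A [sim_config()] to simulate input, or `NULL` when reading
#'   files.
#' @param ped_path,map_path PLINK text input (used when `sim` is NULL).
#' @param out_dir Output directory, created if needed.
#' @param max_missing_marker,max_missing_sample QC1 thresholds.
#' @param min_maf QC2 threshold.
#' @param per_breed_n Animals kept per breed by kinship pruning; `NULL`
#'   disables subsampling.
#' @param hrr_params A [run_params()] for HRR detection.
#' @param hbd_spec An [hbd_model_spec()].
#' @param hbd_threshold Posterior threshold for HBD segment calls.
#' @param hbd_max_iter EM iteration cap.
#' @param island_top_percentile,island_min_snp Island-calling settings.
#' @param window_bp,signal_top_fraction Selection-scan settings.
#' @param z_crit Hot-spot Z threshold.
#' @param factor_table data.frame mapping `breed` to factor columns for
#'   the ANOVA stage, or `NULL` to skip it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                            out_dir = "hetscan_out",
                            max_missing_marker = 0.10,
                            max_missing_sample = 0.10, min_maf = 0.01,
                            per_breed_n = 20,
                            hrr_params = run_params("HRR"),
                            hbd_spec = hbd_model_spec(),
                            hbd_threshold = 0.5, hbd_max_iter = 200,
                            island_top_percentile = 0.1,
                            island_min_snp = 2, window_bp = 250000,
                            signal_top_fraction = 0.001, z_crit = 1.645,
                            factor_table = NULL) {
  if (is.null(sim) && (is.null(ped_path) || is.null(map_path)))
    stop("either a simulation block or PED/MAP input paths are required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Demo configuration: five breeds with planted features
#'
#' Five breeds of 20 on two 30 Mb chromosomes (about 4000 markers): one
#' 600 kb heterozygous tract per breed, one 450 kb autozygous tract per
#' breed and five balancing-selection windows shared by all breeds. A
#' two-level geographic-origin factor table is attached for the ANOVA
#' stage.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed (default 7).
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir = "hetscan_demo", seed = 7) {
  feats <- rbind(
    # one tract private to each breed plus one position shared by all
    # five, so cross-breed island hot spots have something to find
    data.frame(kind = "HRR_TRACT", breed = 1:5, chrom = 1,
               start_bp = seq(2e6, 26e6, length.out = 5),
               carrier_fraction = 0.8, intensity = 0.95),
    data.frame(kind = "HRR_TRACT", breed = 1:5, chrom = 1,
               start_bp = 5e6, carrier_fraction = 0.8, intensity = 0.95),
    data.frame(kind = "ROH_TRACT", breed = 1:5, chrom = 2,
               start_bp = seq(3e6, 27e6, length.out = 5),
               carrier_fraction = 0.8, intensity = 0.95),
    data.frame(kind = "ROH_TRACT", breed = 1:5, chrom = 2,
               start_bp = 6e6, carrier_fraction = 0.8, intensity = 0.95),
    data.frame(kind = "BALANCING_WINDOW", breed = 1, chrom = 2,
               start_bp = seq(1.5e6, 25.5e6, by = 6e6),
               carrier_fraction = 1, intensity = 1.3))
  feats$end_bp <- feats$start_bp +
    ifelse(feats$kind == "HRR_TRACT", 6e5,
           ifelse(feats$kind == "ROH_TRACT", 4.5e5, 2.5e5))
  sim <- sim_config(seed, n_breeds = 5, individuals_per_breed = 20,
                    chrom_lengths_bp = c(30e6, 30e6),
                    features = feats[, c("kind", "breed", "chrom",
                                         "start_bp", "end_bp",
                                         "carrier_fraction", "intensity")])
  factors <- data.frame(breed = sprintf("B%02d", 1:5),
                        origin = c("north", "north", "south", "south",
                                   "south"),
                        purpose = c("work", "toy", "work", "toy", "work"))
  pipeline_config(sim = sim, out_dir = out_dir, hbd_max_iter = 30,
                  factor_table = factors)
}

PIPELINE_STAGES <- c("qc", "runs", "hbd", "islands", "tajima", "overlap")

stage_prereqs <- list(qc = character(0), runs = "qc", hbd = "qc",
                      islands = c("runs", "hbd"), tajima = "qc",
                      overlap = c("islands", "tajima"))

#' Run the analysis pipeline
#'
#' Executes the requested stages in order and writes every result table
#' to `config$out_dir` (TSV; islands, signals and hot spots also as BED),
#' plus a `provenance.json` recording all parameters and interpretive
#' decision flags. Outputs are deterministic: re-running with the same
#' configuration reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("qc", "runs", "hbd", "islands", "tajima",
#'   "overlap")` or `"all"`. Every requested stage must have its
#'   prerequisites in the set, otherwise a dependency error is raised.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stopifnot(all(stages %in% PIPELINE_STAGES))
  for (s in stages) {
    miss <- setdiff(stage_prereqs[[s]], stages)
    if (length(miss))
      stop(sprintf("dependency error: stage '%s' requires stage(s) %s",
                   s, paste(sprintf("'%s'", miss), collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                   sprintf(...))
  res <- list()
  tsv <- function(df, name) write_tsv_table(df, file.path(config$out_dir,
                                                          name))

  log_msg("stage input: acquiring genotypes")
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    res$truth <- sim$truth
    g <- sim$genotypes
    write_ped_map(g, file.path(config$out_dir, "simulated.ped"),
                  file.path(config$out_dir, "simulated.map"))
    tsv(sim$truth, "truth.tsv")
  } else {
    g <- read_ped_map(config$ped_path, config$map_path)
  }

  if ("qc" %in% stages) {
    log_msg("stage qc: missingness, MAF, kinship subsampling")
    qc1 <- filter_call_rate(g, config$max_missing_marker,
                            config$max_missing_sample)
    g1 <- qc1$genotypes
    if (!is.null(config$per_breed_n) &&
        any(table(g1$samples$breed) > config$per_breed_n)) {
      k <- kinship_matrix(g1)
      keep <- select_unrelated(k, g1$samples, config$per_breed_n)
      g1 <- subset_genotypes(g1, samples = keep)
    }
    qc2 <- filter_maf(g1, config$min_maf)
    g2 <- qc2$genotypes
    tsv(cbind(tier = c("QC1", "QC2"),
              rbind(qc1$report[, intersect(names(qc1$report),
                                           names(qc2$report))],
                    qc2$report[, intersect(names(qc1$report),
                                           names(qc2$report))])),
        "qc_report.tsv")
    res$qc1 <- g1
    res$qc2 <- g2
  }

  if ("runs" %in% stages) {
    log_msg("stage runs: HRR consecutive-runs scan")
    res$runs <- detect_runs(res$qc1, config$hrr_params)
    res$summaries <- summarize_runs(res$runs, res$qc1)
    tsv(res$runs, "runs.tsv")
    tsv(res$summaries, "summaries.tsv")
    bs <- res$summaries
    if (nrow(bs) >= 3 && var(bs$ho) > 0 && var(bs$n_runs) > 0) {
      res$correlations <- rbind(
        pearson_correlation(bs$ho, bs$n_runs, "Ho~n_runs"),
        pearson_correlation(bs$ho, bs$coverage_fraction,
                            "Ho~coverage_fraction"),
        pearson_correlation(bs$n_runs, bs$coverage_fraction,
                            "n_runs~coverage_fraction"))
      tsv(res$correlations, "correlations.tsv")
    }
  }

  if ("hbd" %in% stages) {
    log_msg("stage hbd: model-based ROH segments")
    res$hbd <- hbd_segments(res$qc1, config$hbd_spec,
                            threshold = config$hbd_threshold,
                            max_iter = config$hbd_max_iter)
    tsv(res$hbd, "hbd_segments.tsv")
  }

  if ("islands" %in% stages) {
    log_msg("stage islands: HRRI and ROHI calling")
    hrri <- islands_by_breed(res$runs, res$qc1, "HRR",
                             top_percentile = config$island_top_percentile,
                             min_snp = config$island_min_snp)
    rohi <- islands_by_breed(res$hbd, res$qc1, "ROH",
                             top_percentile = config$island_top_percentile,
                             min_snp = config$island_min_snp)
    res$islands <- rbind(hrri, rohi)
    tsv(res$islands, "islands.tsv")
    if (nrow(res$islands))
      write_intervals_bed(
        data.frame(chrom = res$islands$chrom,
                   start_bp = res$islands$start_bp,
                   end_bp = res$islands$end_bp,
                   label = paste(res$islands$breed,
                                 res$islands$island_type, sep = "|")),
        file.path(config$out_dir, "islands.bed"))
  }

  if ("tajima" %in% stages) {
    log_msg("stage tajima: windowed D and signal thresholds")
    res$windows <- window_stats_by_breed(res$qc2, config$window_bp)
    res$signals <- threshold_signals(res$windows,
                                     config$signal_top_fraction)
    tsv(res$windows, "windows.tsv")
    tsv(res$signals, "signals.tsv")
    if (nrow(res$signals))
      write_intervals_bed(
        data.frame(chrom = res$signals$chrom,
                   start_bp = res$signals$window_start + 1,
                   end_bp = res$signals$window_end,
                   label = res$signals$breed),
        file.path(config$out_dir, "signals.bed"))
  }

  if ("overlap" %in% stages) {
    log_msg("stage overlap: hot spots, overlaps, ANOVA, FST")
    hrri <- res$islands[res$islands$island_type == "HRRI", , drop = FALSE]
    if (nrow(hrri) >= 1) {
      hs_islands <- hot_spots(hrri, config$z_crit)
      tsv(hs_islands$regions, "island_regions.tsv")
      tsv(hs_islands$hot_spots, "hotspots_islands.tsv")
      if (nrow(hs_islands$hot_spots))
        write_intervals_bed(
          data.frame(chrom = hs_islands$hot_spots$chrom,
                     start_bp = hs_islands$hot_spots$start_bp,
                     end_bp = hs_islands$hot_spots$end_bp,
                     label = hs_islands$hot_spots$breeds),
          file.path(config$out_dir, "hotspots_islands.bed"))
    }
    sig <- res$signals
    hs_signals <- NULL
    if (nrow(sig) >= 1) {
      sig_iv <- data.frame(breed = sig$breed, chrom = sig$chrom,
                           start_bp = sig$window_start + 1,
                           end_bp = sig$window_end)
      hs_signals <- hot_spots(sig_iv, config$z_crit)
      tsv(hs_signals$regions, "signal_regions.tsv")
      tsv(hs_signals$hot_spots, "hotspots_signals.tsv")
      if (nrow(hs_signals$hot_spots))
        write_intervals_bed(
          data.frame(chrom = hs_signals$hot_spots$chrom,
                     start_bp = hs_signals$hot_spots$start_bp,
                     end_bp = hs_signals$hot_spots$end_bp,
                     label = hs_signals$hot_spots$breeds),
          file.path(config$out_dir, "hotspots_signals.bed"))
      res$hot_spots <- list(islands = if (nrow(hrri)) hs_islands else NULL,
                            signals = hs_signals)
    }
    res$overlaps <- count_overlaps(hrri, res$signals)
    tsv(res$overlaps, "overlaps.tsv")
    if (!is.null(config$factor_table) && !is.null(hs_signals) &&
        nrow(hs_signals$regions) >= 3) {
      res$anova <- tryCatch(
        breed_factor_anova(hs_signals$regions, config$factor_table),
        error = function(e) NULL)
      if (!is.null(res$anova)) tsv(res$anova, "anova.tsv")
    }
    if (length(unique(res$qc2$samples$breed)) >= 2) {
      res$fst <- pairwise_fst(res$qc2)
      fst_df <- data.frame(breed = rownames(res$fst), res$fst,
                           check.names = FALSE)
      tsv(fst_df, "fst.tsv")
    }
  }

  prov <- list(
    package = "hetscan",
    # paths are excluded so identical analyses in different directories
    # leave identical provenance
    parameters = config[setdiff(names(config),
                                c("factor_table", "out_dir", "ped_path",
                                  "map_path"))],
    stages = stages,
    decisions = list(
      call_rate_filter = "max missingness 0.10 per marker then per sample",
      island_percentile = "top percentile over all genome-wide per-SNP sharing frequencies, per breed, linear interpolation",
      signal_quantile = "genome-wide per breed over defined D values; positive-D guard",
      hot_spot_unit = "maximal constant-coverage regions from a sweep line",
      anova_coding = "one observation per (region, supporting breed); response = region breed count",
      run_maximality = "all inclusion-maximal feasible intervals emitted"))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null", force = TRUE),
             file.path(config$out_dir, "provenance.json"))
  log_msg("pipeline complete: %s", config$out_dir)
  invisible(res)
}
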