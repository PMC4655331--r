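# End-to-end orchestration: configuration, the full analysis runner and a
# one-command synthetic demo. Stage outputs are plain files so any stage
# can be rerun in isolation; no hidden state between stages.

#' Pipeline configuration
#'
#' All thresholds default to the values used throughout the package:
#' 5-kb zygosity windows with ratio threshold 0.95 and at most 4
#' consecutive failing windows; 30-kb variation-flagging windows; 50-kb
#' ROH windows with 3 hets allowed and 1-Mb minimum segments; LD blocks at
#' all-pairs r2 > 0.8; 500 bootstrap replicates; age model mu = 1.1e-8 per
#' site per generation, 20 years per generation, 6 haploid chromosomes.
#'
#' @param ... Overrides for any default field.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(window_zygosity = 5000, window_variation = 30000,
              roh_window = 50000, roh_max_het = 3, roh_max_gap = 50000,
              roh_min_length = 1e6, ratio_min = 0.95, max_fail_run = 4,
              stretch_min_length = 0, r2_min = 0.8, bootstrap_reps = 500,
              mu = 1.1e-8, gen_years = 20, n_chrom = 6,
              promoter_bp = 1000, detect_limit = 35, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$ratio_min > 0, cfg$ratio_min <= 1, cfg$r2_min >= 0,
            cfg$r2_min <= 1, cfg$max_fail_run >= 0, cfg$mu > 0)
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` / a `PipelineConfig`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full CEH analysis
#'
#' Runs the configured stages over a cohort: per-sample zygosity windows
#' and conserved stretches, haploid splitting and consensus construction,
#' the intra-CEH catalogue with diversity and haplotype-age estimates,
#' variation binning and low/high flags, and optionally feature
#' annotation (gene models given), LD-block analysis (panel given) and
#' RCCX copy-number calling (Ct table given). All tables are written under
#' `out_dir` together with a manifest echoing the configuration and its
#' hash.
#'
#' @param inputs List with `callsets` (list of [diploid_callset()]),
#'   `reference` ([reference_track()]), and optionally `gene_models`,
#'   `panel` (phased 0/1 matrix), `qpcr` (Ct table), `known_sites`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_full_analysis <- function(inputs, config = pipeline_config(),
                              out_dir) {
  stopifnot(inherits(config, "PipelineConfig"),
            !is.null(inputs$callsets), length(inputs$callsets) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list()

  res$profiles <- stage("stretches", {
    profs <- lapply(inputs$callsets, window_zygosity_profile,
                    window_size = config$window_zygosity)
    stretches <- lapply(profs, call_conserved_stretches,
                        ratio_min = config$ratio_min,
                        max_fail_run = config$max_fail_run,
                        min_length = config$stretch_min_length)
    for (s in names(profs)) {
      files <- c(files, write_tsv(profs[[s]],
                                  file.path(out_dir, paste0("windows_", s, ".tsv"))))
      write_bed(stretches[[s]],
                file.path(out_dir, paste0("stretches_", s, ".bed")))
      files <- c(files, file.path(out_dir, paste0("stretches_", s, ".bed")))
    }
    list(windows = profs, stretches = stretches)
  })

  res$consensus <- stage("consensus", {
    haploids <- unlist(lapply(inputs$callsets, split_haploids),
                       recursive = FALSE)
    cons <- build_consensus(haploids, reference = inputs$reference,
                            name = "cohort")
    files <- c(files, write_tsv(cons$sites,
                                 file.path(out_dir, "consensus_sites.tsv")))
    list(haploids = haploids, consensus = cons)
  })

  res$catalog <- stage("catalog", {
    cat <- intra_ceh_catalog(res$consensus$haploids, inputs$callsets)
    if (!is.null(inputs$gene_models))
      cat <- annotate_catalog(cat, inputs$gene_models, inputs$reference,
                              promoter_bp = config$promoter_bp)
    if (!is.null(inputs$known_sites))
      cat <- flag_known_variants(cat, inputs$known_sites)
    files <- c(files, write_tsv(cat, file.path(out_dir, "intra_catalog.tsv")))
    cat
  })

  res$diversity <- stage("diversity", {
    L <- attr(res$catalog, "comparable_length")
    S <- sum(res$catalog$vtype == "SNV")
    ds <- diversity_stats(S, L, catalog = res$catalog)
    age <- estimate_age(S, L, age_model(mu = config$mu,
                                        gen_years = config$gen_years,
                                        n_chrom = config$n_chrom))
    files <- c(files, write_tsv(
      data.frame(S = S, L = L, pi = ds$pi,
                 snv_per_100kb = ds$snv_per_100kb,
                 het_fraction = ds$het_fraction, T_gen = age$T_gen,
                 age_years = age$age_years),
      file.path(out_dir, "diversity.tsv")))
    list(stats = ds, age = age)
  })

  res$variation <- stage("variation", {
    region <- inputs$callsets[[1]]$region
    bv <- bin_variation(res$catalog, region,
                        window = config$window_zygosity)
    flags <- flag_variation_regions(res$catalog, region,
                                    window = config$window_variation)
    files <- c(files, write_tsv(bv$windows,
                                 file.path(out_dir, "variation_windows.tsv")))
    if (nrow(flags)) {
      write_bed(flags, file.path(out_dir, "variation_flags.bed"))
      files <- c(files, file.path(out_dir, "variation_flags.bed"))
    }
    list(bins = bv, flags = flags)
  })

  if (!is.null(inputs$panel)) {
    res$ld <- stage("ld", {
      blocks <- find_ld_blocks(inputs$panel, r2_min = config$r2_min)
      tables <- lapply(seq_len(nrow(blocks)), function(i)
        block_haplotype_table(inputs$panel, blocks[i, ],
                              next_block = if (i < nrow(blocks))
                                blocks[i + 1, ]))
      json <- file.path(out_dir, "ld_blocks.json")
      jsonlite::write_json(list(blocks = blocks, tables = tables), json,
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      files <- c(files, json)
      list(blocks = blocks, tables = tables)
    })
  }

  if (!is.null(inputs$qpcr)) {
    res$rccx <- stage("rccx", {
      calls <- call_rccx(inputs$qpcr, calibration = inputs$calibration)
      files <- c(files, write_tsv(calls, file.path(out_dir, "rccx_calls.tsv")))
      calls
    })
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(files = basename(files),
                   config = unclass(config),
                   config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' One-command synthetic demo
#'
#' Simulates a three-individual CEH cohort (with heterozygous flanks and a
#' hyper-variable cluster), a phased population panel with a planted
#' six-block LD structure and a qPCR plate around the bimodular RCCX
#' configuration, then runs [run_full_analysis()] on them.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (default 1).
#' @return Invisibly, the [run_full_analysis()] result list (with the
#'   simulation truth attached as `truth`).
#' @export
run_ceh_demo <- function(out_dir, seed = 1) {
  seeds <- derive_seeds(seed, 3)
  sim <- simulate_ceh_cohort(ceh_sim_params(
    region_length = 1e6, flank_length = 2e5,
    cluster = list(start = 4e5, length = 1.2e5, fraction = 0.72),
    seed = seeds[[1]]))
  block <- function(h, f) list(haps = h, freqs = f)
  pop <- simulate_population_haplotypes(
    n_hap = 400,
    blocks = rep(list(block(c("000", "111"), c(0.6, 0.4))), 6),
    recomb_between = 0.4, seed = seeds[[2]])
  plate <- simulate_qpcr_plate(
    data.frame(sample = sprintf("SIM%02d", 1:3),
               C4A = 2, C4B = 2, C4L = 2, C4S = 2, TNXA = 2),
    sd = 0.1, seed = seeds[[3]])
  res <- run_full_analysis(
    list(callsets = sim$callsets, reference = sim$reference,
         panel = pop$haplotypes, qpcr = plate),
    pipeline_config(seed = seed), out_dir)
  res$truth <- sim$truth
  invisible(res)
}
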