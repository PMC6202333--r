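# End-to-end pipeline driver: simulate -> prioritize -> impute ->
# associate -> burst -> report. Stage outputs are plain files, so every
# stage can be re-run from its predecessors' artifacts; the JSON summary
# is the machine-readable interface.

.summary_schema_version <- "1.0"

#' Default pipeline run configuration
#'
#' @param out_dir Output directory for stage artifacts and the summary.
#' @param seed Master seed.
#' @param dominant_maf,recessive_maf Prioritization MAF thresholds.
#' @param si_threshold Burst-impairment threshold.
#' @param hard_call_cutoff Dosage above which an individual is hard-called
#'   homozygous (recessive coding from imputed dosages).
#' @param simulation A `simulation_config` for the cohort stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("founderseek_run"),
                       seed = 1L,
                       dominant_maf = 0.0005,
                       recessive_maf = 0.02,
                       si_threshold = 3.0,
                       hard_call_cutoff = 1.5,
                       simulation = simulation_config(seed = seed)) {
  stopifnot(dominant_maf > 0, dominant_maf < 1,
            recessive_maf > 0, recessive_maf < 1, si_threshold > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 dominant_maf = dominant_maf, recessive_maf = recessive_maf,
                 si_threshold = si_threshold,
                 hard_call_cutoff = hard_call_cutoff,
                 simulation = simulation),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `simulation` block
#' mirrors [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- y$seed %||% 1L
  sim <- do.call(simulation_config, sim_args)
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full discovery pipeline
#'
#' Executes, in order: cohort simulation (written as VCF/PED/TSV),
#' candidate prioritization on the packaged proband-family fixture,
#' genealogical imputation of the focal variant with its information
#' score, recessive case-control and quantitative-trait association with
#' impact-class thresholds applied, and burst-assay classification of
#' simulated flow events. Writes per-stage artifacts under
#' `config$out_dir` plus a versioned `summary.json`; reruns with the
#' same seed produce identical summaries.
#'
#' @param config A `run_config`.
#' @return The summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  summary <- list(schema_version = .summary_schema_version,
                  seed = config$seed)

  logmsg("stage simulate: generating cohort")
  cohort <- simulate_cohort(config$simulation)
  write_vcf_genotypes(cohort$gs, file.path(config$out_dir, "cohort.vcf"))
  write_pedigree(cohort$ped, file.path(config$out_dir, "cohort.ped"))
  utils::write.table(cohort$phenotypes,
                     file.path(config$out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  focal_truth <- cohort$truth[[cohort$focal_id]]
  summary$simulate <- list(n_individuals = nrow(cohort$ped),
                           focal_realized_maf = focal_truth$realized_maf)

  logmsg("stage prioritize: proband-family fixture")
  fx <- build_proband_family_fixture(file.path(config$out_dir, "fixture"))
  fam_gs <- read_vcf_genotypes(fx$vcf)
  fam_ped <- read_pedigree(fx$ped)
  freqs <- read_frequency_table(fx$freq)
  cands <- filter_recessive(fam_ped, fam_gs, freqs,
                            threshold = config$recessive_maf)
  write_candidates(cands, file.path(config$out_dir, "candidates.tsv"))
  high <- Filter(function(cd) all(classify_impact(cd$consequence) == "high"),
                 cands)
  summary$prioritize <- list(
    n_candidates = length(cands),
    n_high_impact = length(high),
    candidates = vapply(cands, format, character(1)))

  logmsg("stage impute: focal variant dosages")
  counts <- cohort$gs$genotypes[cohort$focal_id, ]
  obs <- counts
  obs[!cohort$ped$id %in% cohort$typed_ids] <- NA
  p_focal <- max(focal_truth$realized_maf, 1e-6)
  dos <- impute_untyped(cohort$ped, obs, p = p_focal)
  utils::write.table(dos, file.path(config$out_dir, "dosages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  info <- imputation_information(dos)
  summary$impute <- list(info_score = info,
                         n_typed = sum(dos$typed),
                         mean_dosage = mean(dos$theta_hat))

  logmsg("stage associate: population-scale recall cohort")
  # Association power comes from population-scale genotype recall, not
  # from the discovery family: simulate a chip-typed recall cohort under
  # HWE at the realized focal frequency and hard-call homozygotes from
  # dosages.
  set.seed(config$seed + 11L)
  n_recall <- 50000L
  recall_theta <- stats::rbinom(n_recall, 2, p_focal)
  hom <- as.integer(recall_theta > config$hard_call_cutoff)
  phen <- simulate_phenotypes(hom, config$simulation, seed_offset = 11L)
  cov <- phen[, c("sex", "age", "region")]
  testable <- sum(hom) > 0L
  assoc_bin <- if (!testable) NULL else tryCatch(
    fit_recessive_binary(hom, phen$case_status, cov),
    error = function(e) NULL)
  trait_std <- inverse_normal_transform(phen$trait, cov["sex"])
  assoc_qt <- if (!testable) NULL else tryCatch(
    fit_quantitative(trait_std, hom, cov),
    error = function(e) NULL)
  thr <- significance_threshold("high")
  wrap <- function(a) if (is.null(a)) list(status = "untestable: no homozygotes")
    else c(unclass(a), list(significant = a$p_value < thr, threshold = thr))
  summary$associate <- list(n_recall = n_recall,
                            n_homozygotes = sum(hom),
                            binary = wrap(assoc_bin),
                            quantitative = wrap(assoc_qt))

  logmsg("stage burst: stimulation indices")
  si_targets <- c(proband_like = 1.34, carrier_like = 6.0)
  burst <- lapply(seq_along(si_targets), function(i) {
    ev <- simulate_flow_events(si_targets[i], n_events = 5000,
                               seed = config$seed + i)
    r <- stimulation_index(ev$stim, ev$unstim,
                           si_threshold = config$si_threshold)
    list(sample = names(si_targets)[i], si = r$si,
         classification = r$classification)
  })
  summary$burst <- burst

  logmsg("writing summary.json")
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
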