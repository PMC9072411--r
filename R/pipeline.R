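#' Default configuration for an end-to-end synthetic screen run
#'
#' @param out_dir Run directory.
#' @param seed Master seed; every stage derives its own child seed from it.
#' @param scenario Truth scenario for the simulator.
#' @param design_args Arguments for [build_design()].
#' @param sim Arguments for [sim_params()].
#' @param via_fastq Emit FASTQ and deconvolve (`TRUE`) or analyse the
#'   simulated count matrix directly (`FALSE`, default; much faster).
#' @param reads_per_sample,error_rate FASTQ emission settings when
#'   `via_fastq`.
#' @param cutoff_rule,z_threshold,profile QC settings; see
#'   [apply_qc_filters()].
#' @param sa_match_length Deconvolution setting.
#' @param gxe_q_max,gxe_min_delta_z Gene-by-environment hit thresholds.
#' @param fdr_max,pi_min,dead_lfc Interaction curation thresholds.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, scenario = "paper_like",
                       design_args = list(), sim = list(),
                       via_fastq = FALSE, reads_per_sample = 10000,
                       error_rate = 0,
                       cutoff_rule = list(type = "quantile", q = 0.01),
                       z_threshold = -3, profile = "cutting_ctrl",
                       sa_match_length = 21L,
                       gxe_q_max = 0.05, gxe_min_delta_z = 1,
                       fdr_max = 0.02, pi_min = 0.25, dead_lfc = -0.75) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full screen pipeline
#'
#' simulate -> (optionally FASTQ + deconvolve) -> LFC -> QC filters -> GxE ->
#' GxG pi-scores -> GxGxE curation. All tabular outputs are written as TSV
#' into the run directory together with a JSON manifest (seed, per-stage row
#' counts, file checksums). A rerun with the same config reproduces identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`screen`,
#'   `lfc`, `qc`, `gxe`, `gxg`, `hits`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages$failed_at <<- name
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- stage("design", do.call(build_design,
    c(config$design_args, list(seed = derive_seed(config$seed, "design")))))
  params <- stage("sim_params", do.call(sim_params, config$sim))
  truth <- stage("truth", make_truth(design, config$scenario,
                                     seed = derive_seed(config$seed, "truth"),
                                     params = params))
  screen <- stage("simulate", simulate_counts(design, truth, params,
                                seed = derive_seed(config$seed, "simulate")))
  manifest$stages$simulate <- list(n_constructs = nrow(screen$counts),
                                   n_samples = ncol(screen$counts))

  if (isTRUE(config$via_fastq)) {
    fq <- stage("fastq", simulate_fastq(screen,
      file.path(config$out_dir, "fastq"), config$reads_per_sample,
      config$error_rate, seed = derive_seed(config$seed, "fastq")))
    dec <- stage("deconvolve", deconvolve(fq$fastq, screen$sample_meta, design,
      deconv_params(sa_match_length = config$sa_match_length)))
    counts <- dec$counts
    manifest$stages$deconvolve <- as.list(setNames(dec$summary$n,
                                                   dec$summary$status))
  } else {
    counts <- screen$counts
  }
  write_counts_tsv(counts, file.path(config$out_dir, "counts.tsv"))

  lfc <- stage("lfc", compute_lfc(counts, screen$sample_meta,
                                  screen$constructs))
  qc <- stage("qc", apply_qc_filters(lfc, counts, screen$sample_meta,
                                     cutoff_rule = config$cutoff_rule,
                                     z_threshold = config$z_threshold,
                                     profile = config$profile))
  flt <- combine_and_symmetrize(qc$lfc)
  manifest$stages$qc <- lapply(qc$reports, function(r)
    list(n_removed = r$n_removed, n_surviving = r$n_surviving))
  write_lfc <- data.table::copy(flt)
  data.table::fwrite(write_lfc, file.path(config$out_dir, "lfc_filtered.tsv"),
                     sep = "\t")

  sko <- stage("gxe_zscore", zscore_vs_ctrl(flt))
  gxe <- stage("gxe_fit", fit_gxe(sko))
  gxe_hits <- call_gxe_hits(gxe, config$gxe_q_max, config$gxe_min_delta_z)
  data.table::fwrite(gxe$interactions,
                     file.path(config$out_dir, "gxe_interactions.tsv"),
                     sep = "\t")
  manifest$stages$gxe <- list(n_terms = nrow(gxe$interactions),
                              n_hits = nrow(gxe_hits))

  genes <- scored_genes(design)
  all_pairs <- if (length(genes) >= 2) {
    cb <- utils::combn(sort(genes), 2); paste(cb[1, ], cb[2, ], sep = "|")
  } else character(0)
  gxg <- stage("gxg", score_interactions(flt, all_pairs = all_pairs))
  pi_z <- z_transform_pi(gxg$pi)
  data.table::fwrite(pi_z, file.path(config$out_dir, "pi_scores.tsv"),
                     sep = "\t")
  manifest$stages$gxg <- list(n_pairs = length(unique(gxg$pi$gene_pair)),
                              conditions = length(gxg$fits))

  hits <- stage("gxgxe", filter_interactions(gxg$pi,
    params = list(fdr_max = config$fdr_max, pi_min = config$pi_min,
                  dead_lfc = config$dead_lfc)))
  flat <- hits[, c("gene_pair", "verdict", "reason", "small_effect",
                   "ceiling", "deader_than_dead", "min_q")]
  data.table::fwrite(flat, file.path(config$out_dir, "gxgxe_hits.tsv"),
                     sep = "\t")
  manifest$stages$gxgxe <- list(n_candidates = nrow(hits),
                                n_retained = sum(hits$verdict == "retained"))

  tsvs <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(tsvs))
  names(manifest$checksums) <- basename(tsvs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(design = design, truth = truth, screen = screen, lfc = lfc,
                 qc = qc, filtered_lfc = flt, gxe = gxe, gxe_hits = gxe_hits,
                 gxg = gxg, hits = hits, manifest = manifest))
}
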