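# End-to-end driver: simulate (or read) a study, score both panels, run
# enrichment, growth prediction and survival stratification, and write every
# artifact plus a reproducibility manifest.

.default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "prolifsig_run",
    simulate = TRUE,
    inputs = list(cancer_expression = NULL, cancer_growth = NULL,
                  cancer_growth_kind = "doubling_time",
                  normal_expression = NULL, normal_growth = NULL,
                  normal_growth_kind = "growth_rate",
                  gene_sets = NULL, cohort = NULL,
                  expression_is_log2 = TRUE, log2_offset = 1),
    generator = list(),
    epsilon = 0.01,
    alpha = 0.05,
    method = "spearman",
    bin_size = 100L,
    min_set_size = 5,
    lambda = 1e-3,
    n_reps = 10L,
    n_random_sets = 10L,
    n_perm = 10000L,
    cv_folds = 5L,
    top_k = 200L
  )
}

#' Resolve a full-run configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected so
#' typos fail loudly. `config` may be a list or a path to a YAML file.
#'
#' @param config list or YAML path; `NULL` for the defaults.
#' @return The resolved configuration list.
#' @export
resolve_run_config <- function(config = NULL) {
  base <- .default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  merge_into <- function(base, user, prefix = "") {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s",
                   paste0(prefix, unknown, collapse = ", ")))
    for (k in names(user)) {
      if (is.list(base[[k]]) && is.list(user[[k]]) && k != "generator")
        base[[k]] <- merge_into(base[[k]], user[[k]], paste0(prefix, k, "$"))
      else base[[k]] <- user[[k]]
    }
    base
  }
  merge_into(base, config)
}

#' Run the full proliferation-signature pipeline
#'
#' Chains every stage end to end: simulate (or read) the study, compute cPI
#' and nPI, derive dPI, run gene-set shift tests, bin the cPI ranking with
#' fold enrichment of the planted (or supplied) positive set, run the
#' leave-pairs-out growth prediction with random-signature nulls, and run
#' the survival pipeline. All artifacts are written under
#' `config$out_dir` together with a JSON manifest (resolved config, seed,
#' gene/sample counts after every filter, file hashes).
#'
#' @param config list or YAML path, see [resolve_run_config()]. With
#'   `simulate = TRUE` (default) the study comes from [generate_study()];
#'   otherwise every path in `config$inputs` must exist.
#' @return The manifest, invisibly.
#' @export
run_full_study <- function(config = NULL) {
  cfg <- resolve_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(cfg$out_dir, name)
  log_counts <- list()

  if (isTRUE(cfg$simulate)) {
    gen_args <- cfg$generator
    gen_args$seed <- cfg$seed
    gcfg <- do.call(generator_config, gen_args)
    study <- generate_study(gcfg)
    write_fixture(study, art("fixture"))
    cancer_panel <- study$cancer_panel; cancer_growth <- study$cancer_growth
    normal_panel <- study$normal_panel; normal_growth <- study$normal_growth
    gene_sets <- study$gene_sets; cohort <- study$cohort
  } else {
    ins <- cfg$inputs
    for (key in c("cancer_expression", "cancer_growth", "normal_expression",
                  "normal_growth", "gene_sets", "cohort")) {
      if (is.null(ins[[key]]))
        stop(sprintf("input path '%s' missing and simulate = FALSE", key))
      if (!file.exists(ins[[key]]))
        stop(sprintf("input file for '%s' not found: %s", key, ins[[key]]))
    }
    cancer_panel <- read_expression(ins$cancer_expression,
                                    is_log2 = ins$expression_is_log2,
                                    offset = ins$log2_offset)
    cancer_growth <- read_growth(ins$cancer_growth, ins$cancer_growth_kind)
    normal_panel <- read_expression(ins$normal_expression,
                                    is_log2 = ins$expression_is_log2,
                                    offset = ins$log2_offset)
    normal_growth <- read_growth(ins$normal_growth, ins$normal_growth_kind)
    gene_sets <- read_gmt(ins$gene_sets)
    cohort <- read_clinical(ins$cohort, is_log2 = ins$expression_is_log2,
                            offset = ins$log2_offset)
  }
  log_counts$n_genes_cancer <- length(cancer_panel$gene_ids)
  log_counts$n_samples_cancer <- length(cancer_panel$sample_ids)
  log_counts$n_genes_normal <- length(normal_panel$gene_ids)
  log_counts$n_samples_normal <- length(normal_panel$sample_ids)

  cpi <- compute_pi(cancer_panel, cancer_growth, method = cfg$method)
  npi <- compute_pi(normal_panel, normal_growth, method = cfg$method)
  dpi <- compute_dpi(cpi, npi, epsilon = cfg$epsilon)
  write_score_table(cpi, art("cpi.tsv"))
  write_score_table(npi, art("npi.tsv"))
  write_score_table(dpi, art("dpi.tsv"))
  log_counts$n_differential <- nrow(dpi)

  enr <- run_collection(cpi, gene_sets, min_size = cfg$min_set_size)
  utils::write.table(enr, art("enrichment_cpi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_counts$n_sets_tested <- nrow(enr)

  bins <- bin_genes(cpi, bin_size = cfg$bin_size)
  pos_set_name <- intersect(c("planted_cancer_pos", names(gene_sets$sets)[1L]),
                            names(gene_sets$sets))[1L]
  be <- bin_enrichment(bins, gene_sets$sets[[pos_set_name]], cpi$gene_id)
  utils::write.table(be$table, art("bins_cpi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sig_c <- build_signature(cpi, alpha = cfg$alpha)
  run <- leave_pairs_out(cancer_panel, cancer_growth, sig_c,
                         lambda = cfg$lambda, n_reps = cfg$n_reps,
                         seed = cfg$seed + 1L)
  cmp <- compare_to_random(run, cancer_panel, cancer_growth,
                           n_random_sets = cfg$n_random_sets,
                           lambda = cfg$lambda, seed = cfg$seed + 2L)
  growth_report <- list(
    signature_size = run$signature_size,
    mean_R_signature = cmp$mean_R_signature,
    mean_R_random = cmp$mean_R_random,
    p_greater_than_random = cmp$p_value,
    r_values = run$r_values)
  jsonlite::write_json(growth_report, art("growth_prediction.json"),
                       auto_unbox = TRUE, digits = NA)
  log_counts$n_signature_cpi <- length(sig_c$gene_ids)

  surv <- run_survival_pipeline(cancer_panel, cancer_growth,
                                normal_panel, normal_growth,
                                pi_tables = list(cpi = cpi, npi = npi,
                                                 dpi = dpi),
                                cohort = cohort, alpha = cfg$alpha,
                                cv_folds = cfg$cv_folds, seed = cfg$seed + 3L)
  utils::write.table(surv$summary, art("survival_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in intersect(c("cpi", "npi", "dpi"), names(surv)))
    write_km(surv[[m]]$km, art(sprintf("km_%s.tsv", m)))

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, art("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("prolifsig")),
    seed = cfg$seed,
    config = cfg,
    counts = log_counts,
    artifacts = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
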