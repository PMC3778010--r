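# Synthetic study generator: expression panels with planted gene classes,
# growth measurements, gene sets, a survival cohort, and a ground-truth
# ledger, so that every downstream stage is testable without downloads.

#' Configuration for the synthetic study generator
#'
#' The generator emulates the data layout of a proliferation-signature study:
#' a cancer cell-line panel with doubling times, a larger non-cancerous
#' (lymphoblastoid-like) panel with growth rates, gene sets enriched in the
#' planted classes, and a clinical cohort whose hazard increases with a
#' latent proliferation score.
#'
#' Each sample carries a latent proliferation factor; planted genes load on
#' it linearly (in log2 expression units) with Gaussian noise, and the
#' *measured* growth value is a noisy monotone readout of the same factor
#' (`reliability` is the latent correlation between factor and measured
#' growth on the log scale). `effect_size` is the target absolute Spearman
#' correlation between a planted gene's expression and the measured growth
#' values; loadings are calibrated from it in closed form.
#'
#' @param n_genes number of genes in the universe.
#' @param n_cancer_samples,n_normal_samples panel sizes (defaults 60 and 224).
#' @param class_fractions named fractions over the six planted classes
#'   `cancer_pos`, `cancer_neg`, `normal_pos`, `normal_neg`, `differential`,
#'   `null`; must be nonnegative and sum to 1.
#' @param effect_size target |Spearman| between a planted gene's expression
#'   and measured growth at the reference noise level `noise_sd = 1`
#'   (default 0.5). Lower noise strengthens the realized associations up to
#'   the reliability ceiling; the noiseless limit at `reliability = 1` is a
#'   perfect monotone relationship.
#' @param differential_normal_effect target |Spearman| of differential genes
#'   on the *normal* panel (default 0.3): differential genes are strongly
#'   cancer-associated but only modestly normal-associated, which is what
#'   selecting on cancer significance produces in real data.
#' @param effect_heterogeneity half-width of the per-gene effect spread: each
#'   planted gene's target |Spearman| is scaled by a Uniform(1 - h, 1 + h)
#'   multiplier (default 0.4, so effects span roughly 0.3-0.7 around a 0.5
#'   target). Real association scans show a spread of effect sizes rather
#'   than one common value; 0 restores a constant effect.
#' @param noise_sd per-gene expression noise SD in log2 units.
#' @param reliability latent correlation between the proliferation factor and
#'   the measured growth readout, in (0, 1].
#' @param growth_model list with `doubling_time_log_mean`,
#'   `doubling_time_log_sd` (cancer panel; lognormal doubling times in hours)
#'   and `rate_mean`, `rate_sd` (normal panel; truncated-normal growth rates
#'   per hour).
#' @param survival list with `n_patients`, `hazard_ratio` (between the top
#'   and bottom halves of the latent score), `censoring_rate` and
#'   `baseline_hazard` (events per year).
#' @param n_random_sets,random_set_size extra random gene sets emitted in the
#'   collection, alongside one set per planted class.
#' @param seed integer seed; every draw in [generate_study()] derives from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 800L,
                             n_cancer_samples = 60L,
                             n_normal_samples = 224L,
                             class_fractions = c(cancer_pos = 0.15,
                                                 cancer_neg = 0.05,
                                                 normal_pos = 0.05,
                                                 normal_neg = 0.15,
                                                 differential = 0.05,
                                                 null = 0.55),
                             effect_size = 0.5,
                             differential_normal_effect = 0.3,
                             effect_heterogeneity = 0.4,
                             noise_sd = 1,
                             reliability = 0.85,
                             growth_model = list(doubling_time_log_mean = log(30),
                                                 doubling_time_log_sd = 0.30,
                                                 rate_mean = 0.029,
                                                 rate_sd = 0.005),
                             survival = list(n_patients = 250L,
                                             hazard_ratio = 2.5,
                                             censoring_rate = 0.30,
                                             baseline_hazard = 0.14),
                             n_random_sets = 5L,
                             random_set_size = 40L,
                             seed = 1L) {
  classes <- c("cancer_pos", "cancer_neg", "normal_pos", "normal_neg",
               "differential", "null")
  if (!setequal(names(class_fractions), classes))
    stop("`class_fractions` must be named over the six planted classes")
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must be nonnegative and sum to 1")
  for (nm in c("n_genes", "n_cancer_samples", "n_normal_samples"))
    if (get(nm) < 4L) stop(sprintf("`%s` must be >= 4", nm))
  if (survival$n_patients < 4L) stop("`survival$n_patients` must be >= 4")
  if (effect_size < 0 || effect_size >= 0.95)
    stop("`effect_size` must be in [0, 0.95)")
  if (effect_heterogeneity < 0 || effect_heterogeneity >= 1)
    stop("`effect_heterogeneity` must be in [0, 1)")
  if (reliability <= 0 || reliability > 1)
    stop("`reliability` must be in (0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (2 * sin(pi * effect_size / 6) / reliability >= 1)
    stop("`effect_size` unattainable at this `reliability`")
  structure(list(n_genes = as.integer(n_genes),
                 n_cancer_samples = as.integer(n_cancer_samples),
                 n_normal_samples = as.integer(n_normal_samples),
                 class_fractions = class_fractions,
                 effect_size = effect_size,
                 differential_normal_effect = differential_normal_effect,
                 effect_heterogeneity = effect_heterogeneity,
                 noise_sd = noise_sd,
                 reliability = reliability,
                 growth_model = growth_model,
                 survival = survival,
                 n_random_sets = as.integer(n_random_sets),
                 random_set_size = as.integer(random_set_size),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Loading magnitude that yields a target absolute Spearman correlation
# between expression and the measured growth readout at the reference noise
# level (noise_sd = 1). On the latent normal scale the Pearson correlation
# is rho_P = reliability * beta / sqrt(beta^2 + 1), and Spearman relates to
# Pearson for bivariate normal pairs by rho_S = (6/pi) asin(rho_P / 2).
# Loadings are deliberately calibrated at the reference scale so that
# `noise_sd` acts as an independent noise dial: shrinking it below 1
# strengthens every planted association (up to the reliability ceiling)
# instead of rescaling the signal with it.
.loading_for_spearman <- function(rho_s, reliability) {
  if (rho_s == 0) return(0)
  q <- 2 * sin(pi * rho_s / 6) / reliability
  if (q >= 1) stop("target Spearman unattainable at this reliability")
  q / sqrt(1 - q^2)
}

# Run `code` with the RNG seeded by `seed`, restoring global RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic proliferation study
#'
#' Draws a cancer panel (with doubling times), a normal panel (with growth
#' rates), per-class gene sets, a survival cohort and a ground-truth ledger
#' from one seeded generator. Expression follows
#' `x_gj = a_g + beta_g * u_j + noise`, with `u_j` the sample's latent
#' proliferation factor and the measured growth value a noisy monotone
#' readout of `u_j` (see [generator_config()]). Differential genes load
#' positively on the cancer panel and negatively (more weakly) on the normal
#' panel; null genes load on neither.
#'
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(gamma * s_i)` where `s_i` is the standardized
#' linear combination of differential-gene expression recorded in
#' `cohort_latent_score`, and `gamma` is set so the hazard ratio between the
#' top and bottom halves of `s` equals `survival$hazard_ratio`. Censoring is
#' independent exponential, with rate solved so the expected censoring
#' fraction matches `survival$censoring_rate`.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_study`: panels, growth measurements,
#'   `truth` ledger (gene, class, per-panel loading), `gene_sets`, `cohort`,
#'   `cohort_latent_score`, and the `config`.
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, .generate_study_impl(config))
}

.generate_study_impl <- function(config) {
  ng <- config$n_genes
  counts <- round(config$class_fractions * ng)
  counts["null"] <- ng - sum(counts[names(counts) != "null"])
  if (counts["null"] < 0) stop("class fractions leave no room for null genes")
  cls <- rep(names(counts), counts)
  gene_ids <- sprintf("g%0*d", nchar(ng), seq_len(ng))

  es <- config$effect_size
  esd <- config$differential_normal_effect
  rel <- config$reliability
  h <- config$effect_heterogeneity
  # per-gene intrinsic effect multiplier, shared between panels; targets are
  # clipped just under the attainable Spearman ceiling for this reliability
  mult <- stats::runif(ng, 1 - h, 1 + h)
  cap <- 0.98 * (6 / pi) * asin(rel / 2)
  tgt_cancer <- ifelse(cls %in% c("cancer_pos", "differential"), es * mult,
                       ifelse(cls == "cancer_neg", -es * mult, 0))
  tgt_normal <- ifelse(cls == "normal_pos", es * mult,
                       ifelse(cls == "normal_neg", -es * mult,
                              ifelse(cls == "differential", -esd * mult, 0)))
  tgt_cancer <- pmax(pmin(tgt_cancer, cap), -cap)
  tgt_normal <- pmax(pmin(tgt_normal, cap), -cap)
  beta_cancer <- sign(tgt_cancer) *
    vapply(abs(tgt_cancer), .loading_for_spearman, 1, reliability = rel)
  beta_normal <- sign(tgt_normal) *
    vapply(abs(tgt_normal), .loading_for_spearman, 1, reliability = rel)
  baseline <- stats::rnorm(ng, 7, 1.5)

  gm <- config$growth_model

  make_panel <- function(n, beta, prefix) {
    u <- stats::rnorm(n)                                  # latent factor
    m <- rel * u + sqrt(1 - rel^2) * stats::rnorm(n)      # measured readout
    X <- baseline + outer(beta, u) +
      matrix(stats::rnorm(ng * n, 0, config$noise_sd), ng, n)
    ids <- sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
    dimnames(X) <- list(gene_ids, ids)
    list(u = u, m = m, panel = expression_panel(X), ids = ids)
  }

  canc <- make_panel(config$n_cancer_samples, beta_cancer, "C")
  dt <- exp(gm$doubling_time_log_mean - gm$doubling_time_log_sd * canc$m)
  cancer_growth <- growth_measurements(canc$ids, dt, "doubling_time")

  norm <- make_panel(config$n_normal_samples, beta_normal, "N")
  rate <- pmax(1e-6, gm$rate_mean + gm$rate_sd * norm$m)
  normal_growth <- growth_measurements(norm$ids, rate, "growth_rate")

  truth <- data.frame(gene_id = gene_ids, class = cls,
                      beta_cancer = beta_cancer, beta_normal = beta_normal,
                      stringsAsFactors = FALSE)

  sets <- lapply(split(gene_ids, cls), identity)
  names(sets) <- paste0("planted_", names(sets))
  cats <- rep("planted", length(sets))
  for (k in seq_len(config$n_random_sets)) {
    sets[[sprintf("random_%02d", k)]] <-
      sample(gene_ids, min(config$random_set_size, ng))
    cats <- c(cats, "random")
  }
  gene_sets <- gene_set_collection(sets, cats)

  sv <- config$survival
  np <- sv$n_patients
  p_lat <- stats::rnorm(np)
  beta_cohort <- ifelse(cls %in% c("cancer_pos", "cancer_neg", "differential"),
                        beta_cancer, 0)
  Xp <- baseline + outer(beta_cohort, p_lat) +
    matrix(stats::rnorm(ng * np, 0, config$noise_sd), ng, np)
  pat_ids <- sprintf("P%0*d", nchar(np), seq_len(np))
  dimnames(Xp) <- list(gene_ids, pat_ids)

  diff_idx <- which(cls == "differential")
  if (length(diff_idx)) {
    raw_score <- as.vector(crossprod(Xp[diff_idx, , drop = FALSE],
                                     beta_cancer[diff_idx]))
  } else {
    raw_score <- p_lat                     # degenerate config: no differential genes
  }
  s <- as.vector(scale(raw_score))
  # mean gap between upper and lower halves of a standard normal is
  # 2 * E[Z | Z > 0] = 2 * sqrt(2/pi)
  gamma <- log(sv$hazard_ratio) / (2 * sqrt(2 / pi))
  hazard <- sv$baseline_hazard * exp(gamma * s)
  t_event <- stats::rexp(np, hazard)
  if (sv$censoring_rate > 0) {
    cens_rate <- stats::uniroot(
      function(cr) mean(cr / (cr + hazard)) - sv$censoring_rate,
      interval = c(1e-10, 1e6), tol = 1e-12)$root
    t_cens <- stats::rexp(np, cens_rate)
  } else {
    t_cens <- rep(Inf, np)
  }
  time <- pmax(pmin(t_event, t_cens), 1e-9)
  event <- as.integer(t_event <= t_cens)
  cohort <- survival_cohort(expression_panel(Xp), time, event)

  structure(list(cancer_panel = canc$panel, cancer_growth = cancer_growth,
                 normal_panel = norm$panel, normal_growth = normal_growth,
                 truth = truth, gene_sets = gene_sets,
                 cohort = cohort, cohort_latent_score = stats::setNames(s, pat_ids),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d genes | cancer %d samples | ",
                     "normal %d samples | cohort %d patients (seed %d)\n"),
              x$config$n_genes, x$config$n_cancer_samples,
              x$config$n_normal_samples, x$config$survival$n_patients,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits every external format the package reads: two expression TSVs, two
#' growth TSVs, a GMT collection, a clinical cohort TSV, the ground-truth
#' ledger, and a JSON manifest listing all files and the seed.
#'
#' @param study a [generate_study()] result.
#' @param directory output directory (created if missing).
#' @return The manifest, invisibly: list with `files` (8 paths) and `seed`.
#' @export
write_fixture <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cancer_expression = "cancer_expression.tsv",
    cancer_growth = "cancer_growth.tsv",
    normal_expression = "normal_expression.tsv",
    normal_growth = "normal_growth.tsv",
    gene_sets = "gene_sets.gmt",
    cohort = "cohort.tsv",
    truth = "truth.tsv",
    manifest = "manifest.json")
  full <- file.path(directory, paths)
  names(full) <- names(paths)
  write_expression(study$cancer_panel, full[["cancer_expression"]])
  write_growth(study$cancer_growth, full[["cancer_growth"]])
  write_expression(study$normal_panel, full[["normal_expression"]])
  write_growth(study$normal_growth, full[["normal_growth"]])
  write_gmt(study$gene_sets, full[["gene_sets"]])
  write_clinical(study$cohort, full[["cohort"]])
  utils::write.table(study$truth, full[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(files = as.list(paths), seed = study$config$seed,
                   n_genes = study$config$n_genes)
  jsonlite::write_json(manifest, full[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(files = full, seed = study$config$seed))
}
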