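# Survival stratification: panel-trained lasso growth predictor, exact 1-D
# two-means split of predicted growth, logrank separation and Kaplan-Meier
# step tables.

#' Train a panel lasso model with cross-validated penalty
#'
#' Fits a lasso of growth rate on the signature genes' expression, choosing
#' the penalty from `lambda_grid` by mean `cv_folds`-fold cross-validated
#' squared error (folds seeded), then refits on all panel samples at the
#' chosen penalty. With a single-value grid this is identical to
#' [fit_lasso()] at that penalty.
#'
#' The default grid is 50 log-spaced values from the smallest penalty that
#' zeroes every coefficient down to 1e-4.
#'
#' @inheritParams leave_pairs_out
#' @param lambda_grid decreasing vector of candidate penalties; `NULL` for
#'   the default grid.
#' @param cv_folds number of cross-validation folds (default 5).
#' @return A `lasso_model` (see [fit_lasso()]) with attributes `cv_lambda`
#'   (chosen penalty) and `cv_mse` (per-penalty CV error).
#' @export
train_panel_model <- function(panel, growth, signature, lambda_grid = NULL,
                              cv_folds = 5L, seed = NULL) {
  genes <- if (inherits(signature, "signature")) signature$gene_ids else signature
  al <- align_panel_growth(panel, growth)
  y <- to_growth_rate(al$growth)$values
  genes <- intersect(genes, al$panel$gene_ids)
  if (length(genes) < 2L)
    stop("fewer than 2 signature genes present in the panel")
  X <- t(al$panel$values[genes, , drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("dropping %d zero-variance signature gene(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("fewer than 2 usable signature genes")
  n <- nrow(X)

  if (is.null(lambda_grid)) {
    lmax <- max(glmnet::glmnet(X, y, family = "gaussian")$lambda)
    lambda_grid <- exp(seq(log(lmax), log(1e-4), length.out = 50L))
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (any(lambda_grid < 0)) stop("penalties must be nonnegative")
  if (length(lambda_grid) == 1L) {
    model <- fit_lasso(X, y, lambda_grid)
    attr(model, "cv_lambda") <- lambda_grid
    attr(model, "cv_mse") <- NA_real_
    return(model)
  }
  fold_assign <- function() sample(rep(seq_len(cv_folds), length.out = n))
  foldid <- if (is.null(seed)) fold_assign() else with_seed(seed, fold_assign())
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", lambda = lambda_grid,
                          foldid = foldid, type.measure = "mse",
                          standardize = TRUE)
  lam <- cv$lambda.min
  model <- fit_lasso(X, y, lam)
  attr(model, "cv_lambda") <- lam
  attr(model, "cv_mse") <- stats::setNames(cv$cvm, signif(cv$lambda, 6))
  model
}

#' Score a clinical cohort with a panel-trained model
#'
#' The model is restricted to the genes present in the cohort's expression
#' data (weights of absent genes dropped, with a message); each sample's
#' score is the resulting linear predictor.
#'
#' @param model a `lasso_model`.
#' @param cohort a [survival_cohort()].
#' @return Named numeric vector of per-sample scores.
#' @export
apply_model <- function(model, cohort) {
  stopifnot(inherits(model, "lasso_model"), inherits(cohort, "survival_cohort"))
  shared <- intersect(model$gene_ids, cohort$expression$gene_ids)
  if (length(shared) < 2L)
    stop(sprintf("only %d model gene(s) present in the cohort; need >= 2",
                 length(shared)))
  dropped <- length(model$gene_ids) - length(shared)
  if (dropped > 0L)
    message(sprintf("%d model gene(s) absent from the cohort dropped", dropped))
  w <- model$weights[shared]
  scores <- as.vector(crossprod(cohort$expression$values[shared, , drop = FALSE], w)) +
    model$intercept
  stats::setNames(scores, cohort$expression$sample_ids)
}

#' Exact two-means split of one-dimensional scores
#'
#' Partitions samples into "low" and "high" predicted-proliferation groups
#' by the globally optimal two-cluster split: all thresholds in sorted order
#' are scanned and the one minimizing the within-cluster sum of squares is
#' chosen. In one dimension this equals a converged k-means with k = 2, but
#' is deterministic and provably optimal (no initialization).
#'
#' @param scores named numeric vector (>= 4 values, not all identical).
#' @return A `classification`: list with `sample_ids`, `predicted_growth`,
#'   `label` ("low"/"high"), `cluster_centers` (low, high).
#' @export
two_means_split <- function(scores) {
  n <- length(scores)
  if (n < 4L) stop("need >= 4 samples to split")
  if (max(scores) == min(scores)) stop("scores are constant; no split exists")
  o <- order(scores)
  s <- scores[o]
  css <- cumsum(s)
  csq <- cumsum(s^2)
  tot_s <- css[n]
  tot_q <- csq[n]
  k <- seq_len(n - 1L)
  wss <- (csq[k] - css[k]^2 / k) +
    ((tot_q - csq[k]) - (tot_s - css[k])^2 / (n - k))
  cut <- which.min(wss)                       # first minimum: deterministic
  label <- rep("high", n)
  label[o[seq_len(cut)]] <- "low"
  centers <- c(low = mean(scores[label == "low"]),
               high = mean(scores[label == "high"]))
  structure(list(sample_ids = names(scores), predicted_growth = scores,
                 label = stats::setNames(label, names(scores)),
                 cluster_centers = centers),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("classification: %d low / %d high (centers %.3g / %.3g)\n",
              sum(x$label == "low"), sum(x$label == "high"),
              x$cluster_centers[["low"]], x$cluster_centers[["high"]]))
  invisible(x)
}

#' Two-group logrank test of survival separation
#'
#' Standard logrank: at each distinct event time the expected events per
#' group are proportional to the at-risk counts; tied event times share a
#' single risk set. The chi-square statistic is referred to a 1-df
#' chi-square upper tail.
#'
#' @param cohort a [survival_cohort()].
#' @param classification a [two_means_split()] result covering the cohort's
#'   samples.
#' @return A `logrank_result`: list with `chi_square`, `p_value`, `observed`,
#'   `expected`, `n` (all per group).
#' @export
logrank_test <- function(cohort, classification) {
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(classification, "classification"))
  ids <- cohort$expression$sample_ids
  if (!all(ids %in% classification$sample_ids))
    stop("classification does not cover all cohort samples")
  grp <- factor(classification$label[ids], levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("both groups must be nonempty")
  if (sum(cohort$event) == 0L) stop("no events in the cohort")
  sd_fit <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ grp)
  structure(list(chi_square = unname(sd_fit$chisq),
                 p_value = stats::pchisq(sd_fit$chisq, df = 1L,
                                         lower.tail = FALSE),
                 observed = stats::setNames(as.vector(sd_fit$obs),
                                            levels(grp)),
                 expected = stats::setNames(as.vector(sd_fit$exp),
                                            levels(grp)),
                 n = stats::setNames(as.vector(sd_fit$n), levels(grp))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("logrank: chi-square = %.3f, p = %.3g (n = %d low / %d high)\n",
              x$chi_square, x$p_value, x$n[["low"]], x$n[["high"]]))
  invisible(x)
}

#' Kaplan-Meier curves per classification group
#'
#' Product-limit estimates per group, as tidy step tables suitable for TSV
#' export or plotting.
#'
#' @inheritParams logrank_test
#' @return A `km_curves` object: named list (per group) of data frames with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curves <- function(cohort, classification) {
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(classification, "classification"))
  ids <- cohort$expression$sample_ids
  grp <- factor(classification$label[ids], levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("both groups must be nonempty")
  fit <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~ grp)
  sm <- summary(fit, censored = TRUE)
  strata <- sub("^grp=", "", as.character(sm$strata))
  out <- lapply(levels(grp), function(g) {
    sel <- strata == g
    data.frame(time = sm$time[sel], n_risk = sm$n.risk[sel],
               n_event = sm$n.event[sel], n_censor = sm$n.censor[sel],
               survival = sm$surv[sel])
  })
  names(out) <- levels(grp)
  structure(out, class = "km_curves")
}

#' Write Kaplan-Meier step tables as TSV
#' @param curves a [km_curves()] result.
#' @param path output path; group is recorded in a `group` column.
#' @return `path`, invisibly.
#' @export
write_km <- function(curves, path) {
  stopifnot(inherits(curves, "km_curves"))
  tabs <- lapply(names(curves), function(g)
    cbind(group = g, curves[[g]], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Survival stratification pipeline for the three proliferation measures
#'
#' For each measure, builds the Bonferroni signature, trains a lasso growth
#' predictor on its source panel (cancer panel for cPI and dPI, normal panel
#' for nPI) with cross-validated penalty, scores the clinical cohort, splits
#' the samples by the exact two-means rule and tests survival separation by
#' logrank.
#'
#' @param cancer_panel,cancer_growth the cancer panel and its growth
#'   measurements.
#' @param normal_panel,normal_growth the non-cancerous panel and its growth
#'   measurements.
#' @param pi_tables named list with `cpi`, `npi` (`pi_table`s) and `dpi`
#'   (`dpi_table`); any subset of measures may be supplied.
#' @param cohort a [survival_cohort()].
#' @param alpha signature selection level (default 0.05).
#' @param lambda_grid,cv_folds passed to [train_panel_model()].
#' @param seed integer seed; per-measure fold seeds derive from it.
#' @return A `survival_report`: per-measure list with `signature`, `model`,
#'   `scores`, `classification`, `logrank`, `km`, plus a `summary` data
#'   frame.
#' @export
run_survival_pipeline <- function(cancer_panel, cancer_growth,
                                  normal_panel, normal_growth,
                                  pi_tables, cohort, alpha = 0.05,
                                  lambda_grid = NULL, cv_folds = 5L,
                                  seed = NULL) {
  measures <- intersect(c("cpi", "npi", "dpi"), names(pi_tables))
  if (!length(measures)) stop("`pi_tables` must contain cpi, npi and/or dpi")
  out <- list()
  summary_rows <- list()
  for (i in seq_along(measures)) {
    m <- measures[i]
    src_panel <- if (m == "npi") normal_panel else cancer_panel
    src_growth <- if (m == "npi") normal_growth else cancer_growth
    sig <- build_signature(pi_tables[[m]], alpha = alpha)
    model <- train_panel_model(src_panel, src_growth, sig,
                               lambda_grid = lambda_grid,
                               cv_folds = cv_folds,
                               seed = if (is.null(seed)) NULL else seed + i)
    scores <- apply_model(model, cohort)
    cls <- two_means_split(scores)
    lr <- logrank_test(cohort, cls)
    km <- km_curves(cohort, cls)
    out[[m]] <- list(signature = sig, model = model, scores = scores,
                     classification = cls, logrank = lr, km = km)
    summary_rows[[m]] <- data.frame(
      measure = m, n_signature = length(sig$gene_ids),
      n_model_genes = length(model$gene_ids),
      n_model_genes_in_cohort = length(intersect(model$gene_ids,
                                                 cohort$expression$gene_ids)),
      chosen_lambda = attr(model, "cv_lambda"),
      n_low = lr$n[["low"]], n_high = lr$n[["high"]],
      chi_square = lr$chi_square, p_value = lr$p_value,
      stringsAsFactors = FALSE)
  }
  out$summary <- do.call(rbind, summary_rows)
  rownames(out$summary) <- NULL
  class(out) <- "survival_report"
  out
}

#' @export
print.survival_report <- function(x, ...) {
  cat("survival_report:\n")
  print(x$summary)
  invisible(x)
}
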