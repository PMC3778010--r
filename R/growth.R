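# Bonferroni signatures and lasso growth-rate prediction with leave-pairs-out
# cross-validation and random-signature empirical nulls.

#' Build a Bonferroni-significant signature from a score table
#'
#' The signature of a measure is the set of genes whose p-values survive
#' Bonferroni correction: `p <= alpha / n_tests`, with `n_tests` the number
#' of genes carrying a (non-missing) p-value. For dPI tables the p-values
#' are the inherited cPI p-values.
#'
#' @param pi a `pi_table` or `dpi_table`.
#' @param alpha family-wise error target before correction (default 0.05).
#' @return A `signature` object: list with `gene_ids`, `measure`,
#'   `selection_alpha`, `n_tests`.
#' @export
build_signature <- function(pi, alpha = 0.05) {
  p <- pi$p_value
  n_tests <- sum(!is.na(p))
  if (n_tests == 0L) stop("no genes with p-values")
  sel <- !is.na(p) & p <= alpha / n_tests
  if (!any(sel))
    stop(sprintf("empty signature: no gene with p <= %g / %d", alpha, n_tests))
  measure <- if (inherits(pi, "dpi_table")) "dpi" else attr(pi, "method")
  structure(list(gene_ids = pi$gene_id[sel], measure = measure,
                 selection_alpha = alpha, n_tests = n_tests),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature (%s): %d genes at alpha %g / %d tests\n",
              x$measure, length(x$gene_ids), x$selection_alpha, x$n_tests))
  invisible(x)
}

#' Fit a lasso regression of growth on expression
#'
#' L1-penalized least squares minimizing
#' `(1/2n) * sum((y - yhat)^2) + lambda * sum(|w|)` with predictors
#' standardized internally to zero mean and unit variance; returned weights
#' are on the original predictor scale. Zero-variance predictors are dropped
#' with a message. Single-predictor problems are solved by the closed-form
#' soft threshold; everything else goes through `glmnet`.
#'
#' @param X numeric matrix, samples in rows, genes in columns (with column
#'   names).
#' @param y numeric response (growth rates), one per row of `X`.
#' @param lambda penalty (>= 0).
#' @param thresh glmnet convergence threshold.
#' @return A `lasso_model`: list with `gene_ids`, `weights`, `intercept`,
#'   `lambda`, `training_n`.
#' @export
fit_lasso <- function(X, y, lambda, thresh = 1e-9) {
  if (!is.matrix(X) || is.null(colnames(X))) stop("`X` must be a matrix with column names")
  if (nrow(X) != length(y)) stop("`X` rows and `y` length differ")
  if (nrow(X) < 4L) stop("need >= 4 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("dropping %d zero-variance predictor(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no predictors with variance left")
  fit <- .lasso_core(X, y, lambda, thresh)
  structure(list(gene_ids = colnames(X), weights = fit$weights,
                 intercept = fit$intercept, lambda = lambda,
                 training_n = nrow(X)),
            class = "lasso_model")
}

# Minimal fitting core shared by fit_lasso and the resampling loops (which
# skip the argument checks and use a looser convergence threshold).
.lasso_core <- function(X, y, lambda, thresh) {
  n <- nrow(X)
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; the 1-D solution is an exact soft threshold
    # under glmnet's 1/n variance convention
    x <- X[, 1L]
    mx <- mean(x)
    sdx <- sqrt(mean((x - mx)^2))
    xt <- (x - mx) / sdx
    yc <- y - mean(y)
    rho <- mean(xt * yc)
    w_std <- sign(rho) * max(0, abs(rho) - lambda)
    w <- w_std / sdx
    return(list(weights = stats::setNames(w, colnames(X)),
                intercept = mean(y) - w * mx))
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = lambda,
                        standardize = TRUE, thresh = thresh)
  list(weights = stats::setNames(as.vector(fit$beta), colnames(X)),
       intercept = as.numeric(fit$a0))
}

# Resampling-loop variant: approaches the target penalty along a short
# geometric path so glmnet's warm starts cut the coordinate-descent cost on
# collinear signature designs. Final-path coefficients agree with the cold
# single-penalty fit to well within resampling noise.
.lasso_core_fast <- function(X, y, lambda, thresh) {
  if (ncol(X) == 1L) return(.lasso_core(X, y, lambda, thresh))
  lseq <- lambda * c(100, 30, 10, 3, 1)
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = lseq,
                        standardize = TRUE, thresh = thresh)
  k <- length(fit$lambda)
  list(weights = fit$beta[, k], intercept = fit$a0[[k]])
}

#' Predict from a lasso model
#' @param object a `lasso_model`.
#' @param newdata matrix with samples in rows; must contain all model genes
#'   as columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lasso_model <- function(object, newdata, ...) {
  miss <- setdiff(object$gene_ids, colnames(newdata))
  if (length(miss))
    stop(sprintf("newdata lacks %d model gene(s)", length(miss)))
  as.vector(newdata[, object$gene_ids, drop = FALSE] %*% object$weights) +
    object$intercept
}

#' Leave-pairs-out growth-rate prediction
#'
#' Per repetition, the samples are randomly partitioned into disjoint test
#' sets of two (one test set of three if the count is odd, so every sample is
#' predicted). For each test set a lasso model at fixed `lambda` is fit on
#' the remaining samples restricted to the signature genes, and the held-out
#' growth rates are predicted. The repetition's performance is the Spearman
#' correlation between predicted and measured growth rates over all samples.
#'
#' @param panel an [expression_panel()].
#' @param growth a [growth_measurements()] object (doubling times are
#'   converted to rates).
#' @param signature a [build_signature()] result, or a character vector of
#'   gene ids; at least 2 signature genes must be present in the panel.
#' @param lambda fixed lasso penalty (default 1e-3).
#' @param n_reps number of random partitions (default 100).
#' @param seed optional integer seed controlling the partitions.
#' @param thresh glmnet convergence threshold for the many small fits.
#' @return A `prediction_run`: list with `r_values` (length `n_reps`),
#'   `predictions` (samples x reps), `sample_ids`, `signature_size`,
#'   `lambda`, `n_reps`, `seed`.
#' @export
leave_pairs_out <- function(panel, growth, signature, lambda = 1e-3,
                            n_reps = 100L, seed = NULL, thresh = 1e-5) {
  genes <- if (inherits(signature, "signature")) signature$gene_ids else signature
  al <- align_panel_growth(panel, growth)
  y <- to_growth_rate(al$growth)$values
  n <- length(y)
  if (n < 6L) stop(sprintf("need >= 6 samples, got %d", n))
  genes <- intersect(genes, al$panel$gene_ids)
  if (length(genes) < 2L)
    stop("fewer than 2 signature genes present in the panel")
  X <- t(al$panel$values[genes, , drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < 1L) stop("all signature genes have zero variance")

  run <- function() {
    preds <- matrix(NA_real_, n, n_reps)
    r_values <- numeric(n_reps)
    for (rep_i in seq_len(n_reps)) {
      ord <- sample.int(n)
      n_pairs <- n %/% 2L
      # odd count: the leftover sample joins the last pair as a test triple
      fold_of <- c(rep(seq_len(n_pairs), each = 2L),
                   if (n %% 2L) n_pairs)
      folds <- split(ord, fold_of)
      for (f in folds) {
        fit <- .lasso_core_fast(X[-f, , drop = FALSE], y[-f], lambda, thresh)
        preds[f, rep_i] <- as.vector(X[f, , drop = FALSE] %*% fit$weights) +
          fit$intercept
      }
      r_values[rep_i] <- stats::cor(preds[, rep_i], y, method = "spearman")
    }
    list(preds = preds, r_values = r_values)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  dimnames(res$preds) <- list(al$panel$sample_ids, NULL)
  structure(list(r_values = res$r_values, predictions = res$preds,
                 sample_ids = al$panel$sample_ids,
                 signature_size = ncol(X), lambda = lambda,
                 n_reps = as.integer(n_reps), seed = seed),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("prediction_run: %d reps, %d genes, mean R = %.3f\n",
              x$n_reps, x$signature_size, mean(x$r_values)))
  invisible(x)
}

#' Compare a signature's predictions to equal-size random gene sets
#'
#' Each random set (uniform draw of `signature_size` genes from the panel
#' universe) is pushed through the identical [leave_pairs_out()] protocol.
#' The reported p-value is the one-sided Wilcoxon rank-sum comparison of the
#' signature's repetition correlations against the pooled random-set
#' correlations (alternative: signature greater). The opposite one-sided and
#' the two-sided p-values are also reported, since a signature can also
#' significantly *underperform* random sets.
#'
#' @inheritParams leave_pairs_out
#' @param run a [leave_pairs_out()] result for the signature.
#' @param signature_size size of the random sets (defaults to the run's
#'   signature size).
#' @param n_random_sets number of random sets (default 100).
#' @param pooling `"pooled"` compares against all random R values pooled;
#'   `"per_set_mean"` compares against the per-set mean R values.
#' @return List with `p_value` (signature > random), `p_less`, `p_two_sided`,
#'   `mean_R_signature`, `mean_R_random`, `r_random` (matrix reps x sets).
#' @export
compare_to_random <- function(run, panel, growth,
                              signature_size = run$signature_size,
                              n_random_sets = 100L, lambda = run$lambda,
                              seed = NULL, pooling = c("pooled", "per_set_mean"),
                              thresh = 1e-5) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(run, "prediction_run"))
  if (n_random_sets < 1L) stop("`n_random_sets` must be >= 1")
  universe <- panel$gene_ids
  if (length(universe) <= signature_size)
    stop("panel universe must exceed the signature size")
  draw_and_run <- function() {
    sapply(seq_len(n_random_sets), function(k) {
      genes <- sample(universe, signature_size)
      leave_pairs_out(panel, growth, genes, lambda = lambda,
                      n_reps = run$n_reps,
                      seed = sample.int(.Machine$integer.max, 1L),
                      thresh = thresh)$r_values
    })
  }
  r_random <- if (is.null(seed)) draw_and_run() else with_seed(seed, draw_and_run())
  r_random <- matrix(r_random, nrow = run$n_reps)
  ref <- if (pooling == "pooled") as.vector(r_random) else colMeans(r_random)
  wt_g <- suppressWarnings(stats::wilcox.test(run$r_values, ref,
                                              alternative = "greater"))
  wt_l <- suppressWarnings(stats::wilcox.test(run$r_values, ref,
                                              alternative = "less"))
  wt_t <- suppressWarnings(stats::wilcox.test(run$r_values, ref))
  list(p_value = wt_g$p.value, p_less = wt_l$p.value,
       p_two_sided = wt_t$p.value,
       mean_R_signature = mean(run$r_values), mean_R_random = mean(ref),
       r_random = r_random)
}
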