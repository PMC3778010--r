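# Per-gene Proliferation Indices: correlation- and slope-based scoring of
# expression against growth rate, subgroup scoring, and the differential
# (cancer-vs-normal) dPI score.

#' Convert growth measurements to growth rates
#'
#' Doubling times `d` map to rates `ln(2) / d`; growth rates pass through
#' unchanged. The transform is strictly decreasing, so rank-based indices
#' computed on doubling times are the exact negation of those computed on
#' rates.
#'
#' @param growth a [growth_measurements()] object.
#' @return A [growth_measurements()] object with `kind = "growth_rate"`.
#' @export
to_growth_rate <- function(growth) {
  stopifnot(inherits(growth, "growth_measurements"))
  if (growth$kind == "growth_rate") return(growth)
  growth_measurements(growth$sample_ids, log(2) / growth$values, "growth_rate")
}

#' Compute per-gene proliferation indices
#'
#' For every gene, quantifies the association between its (log2) expression
#' and growth rate across the panel. Two variants:
#' \describe{
#'   \item{`spearman`}{nonparametric Spearman correlation (average ranks for
#'     ties), p-value from the t approximation on `n - 2` degrees of freedom.}
#'   \item{`slope`}{ordinary least-squares slope of expression on growth rate,
#'     p-value from the regression F statistic; with `normalize = TRUE`
#'     (default) slopes are divided by the median absolute slope so the
#'     median |PI| is exactly 1.}
#' }
#' Doubling-time measurements are converted to growth rates first. Genes with
#' zero expression variance get a missing index, p-value 1, and are flagged.
#'
#' @param panel an [expression_panel()].
#' @param growth a [growth_measurements()] object; aligned to the panel by
#'   sample id (at least 4 shared samples required).
#' @param method `"spearman"` (default) or `"slope"`.
#' @param normalize for `method = "slope"`, divide by the median absolute
#'   slope. Ignored for `"spearman"`.
#' @return A `pi_table`: data frame with columns `gene_id`, `pi`, `p_value`,
#'   `flagged`, and attributes `method`, `n`, `normalized`.
#' @export
compute_pi <- function(panel, growth, method = c("spearman", "slope"),
                       normalize = TRUE) {
  method <- match.arg(method)
  al <- align_panel_growth(panel, growth)
  r <- to_growth_rate(al$growth)$values
  X <- al$panel$values
  n <- length(r)
  if (n < 4L) stop(sprintf("need >= 4 aligned samples, got %d", n))

  flagged <- apply(X, 1L, function(v) max(v) == min(v))
  if (method == "spearman") {
    R <- t(apply(X, 1L, rank))
    rr <- rank(r)
    Rc <- R - rowMeans(R)
    rc <- rr - mean(rr)
    den <- sqrt(rowSums(Rc^2)) * sqrt(sum(rc^2))
    pi_val <- ifelse(den > 0, as.vector(Rc %*% rc) / den, NA_real_)
    pv <- .spearman_p(pi_val, n)
  } else {
    rc <- r - mean(r)
    Sxx <- sum(rc^2)
    if (Sxx == 0) stop("growth rates are constant; slope undefined")
    Xc <- X - rowMeans(X)
    slope <- as.vector(Xc %*% rc) / Sxx
    ssr <- rowSums(Xc^2) - slope^2 * Sxx          # residual sum of squares
    sigma2 <- pmax(ssr, 0) / (n - 2L)
    fstat <- slope^2 * Sxx / pmax(sigma2, .Machine$double.xmin)
    pv <- stats::pf(fstat, 1L, n - 2L, lower.tail = FALSE)
    pi_val <- slope
  }
  pi_val[flagged] <- NA_real_
  pv[flagged] <- 1
  pv[is.na(pv) & !flagged] <- 1

  normalized <- FALSE
  if (method == "slope" && normalize) {
    med <- stats::median(abs(pi_val), na.rm = TRUE)
    if (!is.finite(med) || med == 0)
      stop("median absolute slope is zero; cannot normalize")
    pi_val <- pi_val / med
    normalized <- TRUE
  }
  if (any(flagged))
    message(sprintf("%d gene(s) with zero expression variance flagged", sum(flagged)))

  tab <- data.frame(gene_id = al$panel$gene_ids, pi = pi_val, p_value = pv,
                    flagged = flagged, stringsAsFactors = FALSE)
  class(tab) <- c("pi_table", "data.frame")
  attr(tab, "method") <- method
  attr(tab, "n") <- n
  attr(tab, "normalized") <- normalized
  tab
}

# Two-sided p for a Spearman rho via the t approximation.
.spearman_p <- function(rho, n) {
  out <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  r2 <- pmin(rho[ok]^2, 1 - 1e-15)
  tt <- abs(rho[ok]) * sqrt((n - 2) / (1 - r2))
  out[ok] <- 2 * stats::pt(-tt, n - 2)
  out
}

#' Proliferation indices within sample subgroups
#'
#' Recomputes [compute_pi()] separately for each sample group (for example
#' per tumor type, or slow- vs fast-growing halves). Groups smaller than
#' `min_group` are skipped with a message, mirroring the exclusion of tumor
#' types with too few panel samples.
#'
#' @inheritParams compute_pi
#' @param grouping named character vector mapping sample id to group label;
#'   must cover all panel samples shared with `growth`.
#' @param min_group minimum samples per group (default 4).
#' @return Named list of `pi_table`s, one per retained group.
#' @export
compute_pi_groups <- function(panel, growth, grouping, min_group = 4L,
                              method = c("spearman", "slope")) {
  method <- match.arg(method)
  al <- align_panel_growth(panel, growth)
  ids <- al$panel$sample_ids
  if (!all(ids %in% names(grouping)))
    stop("`grouping` must assign a label to every aligned sample")
  labels <- grouping[ids]
  out <- list()
  for (lab in unique(labels)) {
    sel <- ids[labels == lab]
    if (length(sel) < min_group) {
      message(sprintf("group '%s' skipped: %d sample(s) < min_group = %d",
                      lab, length(sel), min_group))
      next
    }
    sub_panel <- expression_panel(al$panel$values[, sel, drop = FALSE])
    sub_growth <- growth_measurements(sel,
                                      al$growth$values[match(sel, ids)],
                                      al$growth$kind)
    out[[lab]] <- compute_pi(sub_panel, sub_growth, method = method)
  }
  if (!length(out)) stop("no group reached `min_group` samples")
  out
}

#' Differential proliferation index (dPI)
#'
#' Restricted to genes with positive cancer index (cPI) and negative
#' non-cancer index (nPI), the differential index is
#' \deqn{dPI_i = cPI_i / (nPI_i - nPI_{min} + \epsilon)}
#' where `nPI_min` is the minimum nPI over *all* shared genes (not just the
#' differential subset) and `epsilon` (default 0.01) keeps the denominator
#' positive. The score increases with cPI and increases as nPI decreases.
#' Because dPI combines the two measures, each gene's p-value is inherited
#' from its cPI p-value.
#'
#' @param cpi,npi `pi_table`s over a shared gene universe (cancer and
#'   non-cancer panels respectively).
#' @param epsilon positive stabilizer added to the denominator.
#' @return A `dpi_table`: data frame with columns `gene_id`, `dpi`, `p_value`
#'   and attributes `epsilon`, `npi_min`, `n`.
#' @export
compute_dpi <- function(cpi, npi, epsilon = 0.01) {
  stopifnot(inherits(cpi, "pi_table"), inherits(npi, "pi_table"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be a single positive number")
  shared <- intersect(cpi$gene_id[!is.na(cpi$pi)], npi$gene_id[!is.na(npi$pi)])
  if (!length(shared)) stop("no shared genes with defined cPI and nPI")
  c_pi <- cpi$pi[match(shared, cpi$gene_id)]
  n_pi <- npi$pi[match(shared, npi$gene_id)]
  c_p <- cpi$p_value[match(shared, cpi$gene_id)]
  npi_min <- min(n_pi)                       # over the full shared universe
  sel <- c_pi > 0 & n_pi < 0
  if (!any(sel))
    stop("empty differential subset: no gene with cPI > 0 and nPI < 0")
  dpi <- c_pi[sel] / (n_pi[sel] - npi_min + epsilon)
  tab <- data.frame(gene_id = shared[sel], dpi = dpi, p_value = c_p[sel],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$dpi), ]
  rownames(tab) <- NULL
  class(tab) <- c("dpi_table", "data.frame")
  attr(tab, "epsilon") <- epsilon
  attr(tab, "npi_min") <- npi_min
  attr(tab, "n") <- attr(cpi, "n")
  tab
}

#' Spearman agreement between two PI tables
#'
#' @param a,b `pi_table`s sharing at least 3 genes with defined indices.
#' @return List with `rho`, `p` and `n_shared`.
#' @export
compare_pi_tables <- function(a, b) {
  stopifnot(inherits(a, "pi_table"), inherits(b, "pi_table"))
  shared <- intersect(a$gene_id[!is.na(a$pi)], b$gene_id[!is.na(b$pi)])
  if (length(shared) < 3L)
    stop(sprintf("only %d shared gene(s); need >= 3", length(shared)))
  x <- a$pi[match(shared, a$gene_id)]
  y <- b$pi[match(shared, b$gene_id)]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}
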