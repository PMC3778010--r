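# Gene-set shift tests on PI values, empirical random-set tests, binning of
# the ranked gene list with fold enrichment and covariate means.

#' Rank-sum shift test of a gene set's PI values
#'
#' Compares the (optionally absolute) PI values of the set members against
#' the remaining genes with a two-sided Wilcoxon rank-sum test. For small
#' universes the p-value is computed by exhaustive enumeration over all
#' assignments of set labels (exact even under ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' The default background excludes the set members themselves (a deliberate
#' deviation from comparing against "all genes", avoiding self-comparison);
#' set `include_members_in_background = TRUE` for the inclusive convention.
#'
#' @param pi a `pi_table` (genes with missing PI are excluded).
#' @param members character vector of gene ids.
#' @param transform `"identity"` (signed PI) or `"absolute"` (|PI|).
#' @param include_members_in_background if `TRUE`, the background is the full
#'   universe including members.
#' @param exact_limit enumerate exactly when `choose(n, k)` is at most this.
#' @return One-row data frame (class `enrichment_row`) with `set_name`,
#'   `category`, `set_size_in_universe`, `statistic` (rank sum of the set),
#'   `mean_in_set`, `mean_background`, `direction`, `p_raw`, `p_adjusted`,
#'   `n_tests`.
#' @export
set_shift_test <- function(pi, members, transform = c("identity", "absolute"),
                           include_members_in_background = FALSE,
                           exact_limit = 1e5) {
  transform <- match.arg(transform)
  stopifnot(inherits(pi, "pi_table"))
  vals <- stats::setNames(pi$pi, pi$gene_id)
  vals <- vals[!is.na(vals)]
  if (transform == "absolute") vals <- abs(vals)
  in_set <- names(vals) %in% members
  if (!any(in_set)) stop("no set member present in the PI universe")
  if (!any(!in_set))
    stop("empty background: the set covers the whole universe")
  x <- vals[in_set]
  # background: all other genes (default) or the full universe (inclusive)
  y <- if (include_members_in_background) vals else vals[!in_set]
  pooled_vals <- c(x, y)
  rk <- rank(pooled_vals)
  W <- sum(rk[seq_along(x)])
  p <- .ranksum_p(pooled_vals, length(x), W, exact_limit)
  mean_in <- mean(x)
  mean_bg <- mean(y)
  out <- data.frame(set_name = NA_character_, category = NA_character_,
                    set_size_in_universe = length(x), statistic = W,
                    mean_in_set = mean_in, mean_background = mean_bg,
                    direction = if (mean_in >= mean_bg) "up" else "down",
                    p_raw = p, p_adjusted = p, n_tests = 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_row", "data.frame")
  out
}

# Two-sided rank-sum p-value: exact by enumeration when feasible, else the
# tie-corrected normal approximation with continuity correction.
.ranksum_p <- function(pooled, n1, W, exact_limit = 1e5) {
  n <- length(pooled)
  n2 <- n - n1
  if (n2 == 0L) stop("background is empty")
  if (choose(n, n1) <= exact_limit) {
    rk <- rank(pooled)
    combos <- utils::combn(n, n1)
    sums <- colSums(matrix(rk[combos], nrow = n1))
    tol <- 1e-9
    pl <- mean(sums <= W + tol)
    pu <- mean(sums >= W - tol)
    return(min(1, 2 * min(pl, pu)))
  }
  rk <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Shift tests for a whole gene-set collection
#'
#' Filters sets by their in-universe size (threshold may differ per
#' category), runs [set_shift_test()] on each retained set, and applies a
#' Bonferroni correction *within* each category: `n_tests` for a row equals
#' the number of sets tested in that row's category.
#'
#' @inheritParams set_shift_test
#' @param collection a [gene_set_collection()].
#' @param min_size minimum in-universe set size; either a single number for
#'   all categories or a named vector by category with a `default` entry
#'   (e.g. `c(default = 25, metabolic = 5)`).
#' @return Data frame of `enrichment_row`s sorted by `p_raw`.
#' @export
run_collection <- function(pi, collection, min_size = 25,
                           transform = c("identity", "absolute"),
                           include_members_in_background = FALSE,
                           exact_limit = 1e5) {
  transform <- match.arg(transform)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("empty collection")
  universe <- pi$gene_id[!is.na(pi$pi)]
  size_in <- vapply(collection$sets, function(s) sum(s %in% universe), 1L)
  thr <- vapply(collection$categories, function(cat) {
    if (length(min_size) == 1L && is.null(names(min_size))) return(min_size[[1L]])
    if (cat %in% names(min_size)) return(min_size[[cat]])
    if ("default" %in% names(min_size)) return(min_size[["default"]])
    stop(sprintf("no min_size entry (or default) for category '%s'", cat))
  }, 1)
  keep <- size_in >= thr & size_in < length(universe)
  if (!any(keep)) stop("all sets filtered out by the size thresholds")
  rows <- lapply(which(keep), function(i) {
    r <- set_shift_test(pi, collection$sets[[i]], transform = transform,
                        include_members_in_background = include_members_in_background,
                        exact_limit = exact_limit)
    r$set_name <- names(collection$sets)[i]
    r$category <- collection$categories[i]
    r
  })
  out <- do.call(rbind, rows)
  n_by_cat <- table(out$category)
  out$n_tests <- as.integer(n_by_cat[out$category])
  out$p_adjusted <- pmin(1, out$p_raw * out$n_tests)
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  out
}

#' Empirical random-set test of a gene set's mean PI
#'
#' Compares the mean PI of the set to the means of `n_perm` random gene sets
#' of equal size drawn without replacement from the universe. The p-value
#' uses the add-one estimator `(r + 1) / (n_perm + 1)`, where `r` counts
#' random sets at least as extreme in the chosen direction.
#'
#' @inheritParams set_shift_test
#' @param n_perm number of random sets (>= 100).
#' @param side `"low"`, `"high"`, or `"two"` (two-sided on the distance from
#'   the universe mean).
#' @param seed optional integer seed.
#' @return List with `mean_in_set`, `p_empirical`, `n_perm`, `set_size`.
#' @export
empirical_set_test <- function(pi, members, n_perm = 1e5,
                               side = c("low", "high", "two"), seed = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(pi, "pi_table"))
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  vals <- pi$pi[!is.na(pi$pi)]
  ids <- pi$gene_id[!is.na(pi$pi)]
  k <- sum(ids %in% members)
  if (k == 0L) stop("no set member present in the PI universe")
  if (k >= length(ids)) stop("set size must be smaller than the universe")
  m_obs <- mean(vals[ids %in% members])
  draw <- function() {
    means <- numeric(n_perm)
    N <- length(vals)
    for (i in seq_len(n_perm)) means[i] <- mean(vals[sample.int(N, k)])
    means
  }
  means <- if (is.null(seed)) draw() else with_seed(seed, draw())
  mu <- mean(vals)
  r <- switch(side,
              low = sum(means <= m_obs),
              high = sum(means >= m_obs),
              two = sum(abs(means - mu) >= abs(m_obs - mu)))
  list(mean_in_set = m_obs, p_empirical = (r + 1) / (n_perm + 1),
       n_perm = n_perm, set_size = k)
}

#' Partition the ranked gene list into fixed-size bins
#'
#' Genes are sorted ascending by PI (or |PI|) and split into consecutive bins
#' of `bin_size`; a remainder shorter than `bin_size` is merged into the last
#' bin. Ties are broken by gene id so the binning is deterministic.
#'
#' @param pi a `pi_table`.
#' @param bin_size genes per bin (default 200).
#' @param order `"value"` (signed) or `"absolute"`.
#' @return A `bin_table`: list with `gene_ids` (list of per-bin id vectors)
#'   and `table` (data frame with `bin`, `n`, `mean_pi`).
#' @export
bin_genes <- function(pi, bin_size = 200L, order = c("value", "absolute")) {
  order <- match.arg(order)
  stopifnot(inherits(pi, "pi_table"))
  ok <- !is.na(pi$pi)
  ids <- pi$gene_id[ok]
  vals <- pi$pi[ok]
  if (length(ids) < 2L * bin_size)
    stop(sprintf("need >= %d genes with defined PI, got %d",
                 2L * bin_size, length(ids)))
  key <- if (order == "absolute") abs(vals) else vals
  o <- base::order(key, ids)
  ids <- ids[o]; vals <- vals[o]
  n_bins <- length(ids) %/% bin_size
  idx <- pmin(ceiling(seq_along(ids) / bin_size), n_bins)  # remainder -> last
  gene_ids <- split(ids, idx)
  tab <- data.frame(bin = seq_len(n_bins),
                    n = as.integer(lengths(gene_ids)),
                    mean_pi = vapply(split(vals, idx), mean, 1))
  structure(list(gene_ids = unname(gene_ids), table = tab,
                 order = order, bin_size = as.integer(bin_size)),
            class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins of ~%d genes (order = %s)\n",
              nrow(x$table), x$bin_size, x$order))
  invisible(x)
}

#' Fold enrichment of a special gene class across bins
#'
#' For each bin, the fraction of special genes among the bin's reference
#' genes is divided by the overall fraction of special genes in the
#' reference, and an upper-tail hypergeometric p-value is attached (drawing
#' the bin's reference genes from the reference universe).
#'
#' @param bins a [bin_genes()] result.
#' @param special character vector of special genes (e.g. essential genes);
#'   only its intersection with `reference` counts.
#' @param reference the reference universe (e.g. all screened genes).
#' @return The `bin_table` with columns `n_reference`, `n_special`,
#'   `enrichment_fold` and `hypergeometric_p` added to `$table`.
#' @export
bin_enrichment <- function(bins, special, reference) {
  stopifnot(inherits(bins, "bin_table"))
  special <- intersect(unique(special), unique(reference))
  if (!length(special)) stop("special and reference sets do not intersect")
  N <- length(unique(reference))
  K <- length(special)
  tab <- bins$table
  tab$n_reference <- vapply(bins$gene_ids,
                            function(g) sum(g %in% reference), 1L)
  tab$n_special <- vapply(bins$gene_ids, function(g) sum(g %in% special), 1L)
  global_frac <- K / N
  tab$enrichment_fold <- ifelse(tab$n_reference > 0,
                                (tab$n_special / tab$n_reference) / global_frac,
                                NA_real_)
  tab$hypergeometric_p <- ifelse(
    tab$n_reference > 0,
    stats::phyper(tab$n_special - 1L, K, N - K, tab$n_reference,
                  lower.tail = FALSE),
    NA_real_)
  bins$table <- tab
  bins
}

#' Per-bin means of a gene-level covariate, with correlations
#'
#' Computes the mean of a covariate (e.g. mean expression, network degree)
#' over the covered genes of every bin, plus the Spearman correlation of PI
#' with the covariate at gene level (`raw`) and of per-bin means (`binned`).
#'
#' @param bins a [bin_genes()] result.
#' @param covariate named numeric vector over genes; must cover at least half
#'   the binned genes.
#' @return List with the augmented `bin_table` (column `mean_covariate`) and
#'   the `binned` correlation (`rho`, `p`; `NA` when a side is constant).
#' @export
bin_covariate_means <- function(bins, covariate) {
  stopifnot(inherits(bins, "bin_table"))
  genes <- unlist(bins$gene_ids)
  covered <- genes[genes %in% names(covariate)]
  if (length(covered) < length(genes) / 2)
    stop(sprintf("covariate covers %d of %d genes; need at least half",
                 length(covered), length(genes)))
  tab <- bins$table
  tab$mean_covariate <- vapply(bins$gene_ids, function(g) {
    v <- covariate[g[g %in% names(covariate)]]
    if (length(v)) mean(v) else NA_real_
  }, 1)
  binned <- .spearman_or_na(tab$mean_pi, tab$mean_covariate)
  bins$table <- tab
  list(bins = bins, binned = binned)
}

.spearman_or_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate PI with a covariate at gene level and bin level
#'
#' Convenience wrapper: computes [bin_genes()] means and both the raw
#' (gene-level) and binned Spearman correlations in one call.
#'
#' @inheritParams bin_covariate_means
#' @param pi the `pi_table` the bins were built from.
#' @return List with `bins` (augmented), `raw` and `binned` (each `rho`, `p`).
#' @export
covariate_correlation <- function(pi, bins, covariate) {
  res <- bin_covariate_means(bins, covariate)
  ok <- !is.na(pi$pi) & pi$gene_id %in% names(covariate)
  x <- pi$pi[ok]
  if (bins$order == "absolute") x <- abs(x)
  res$raw <- .spearman_or_na(x, as.numeric(covariate[pi$gene_id[ok]]))
  res
}

#' Most extreme genes of a score table
#'
#' Returns the `k` genes with the highest (or lowest) score from a PI or dPI
#' table. Boundary ties are broken by gene id order, so the selection is
#' deterministic across runs.
#'
#' @param table a `pi_table` or `dpi_table`.
#' @param k number of genes (default 200).
#' @param direction `"highest"` or `"lowest"`.
#' @return Character vector of `k` gene ids.
#' @export
top_k <- function(table, k = 200L, direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  if (inherits(table, "dpi_table")) {
    ids <- table$gene_id; vals <- table$dpi
  } else if (inherits(table, "pi_table")) {
    ids <- table$gene_id[!is.na(table$pi)]
    vals <- table$pi[!is.na(table$pi)]
  } else stop("`table` must be a pi_table or dpi_table")
  if (k > length(ids))
    stop(sprintf("k = %d exceeds the %d-gene universe", k, length(ids)))
  o <- if (direction == "highest") base::order(-vals, ids) else base::order(vals, ids)
  ids[o][seq_len(k)]
}
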