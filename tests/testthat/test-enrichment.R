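test_that("rank-sum shift test matches exact enumeration on the toy case", {
  pt <- make_pi_table(sprintf("g%d", 1:6),
                      c(0.9, 0.8, 0.7, 0.1, 0.0, -0.1))
  row <- set_shift_test(pt, c("g1", "g2", "g3"))
  # in-set holds the 3 largest of 6 values: rank sum 15, exact two-sided
  # p = 2 * (1 / choose(6,3)) = 0.1
  expect_equal(row$statistic, 15)
  expect_equal(row$p_raw, 0.1)
  expect_equal(row$direction, "up")
  expect_equal(row$set_size_in_universe, 3L)

  # identical multisets inside and outside the set: no shift, p = 1
  pt2 <- make_pi_table(sprintf("g%d", 1:6), rep(c(0.1, 0.2, 0.3), 2))
  row2 <- set_shift_test(pt2, c("g1", "g2", "g3"))
  expect_equal(row2$p_raw, 1)

  expect_error(set_shift_test(pt, pt$gene_id), "background")
  expect_error(set_shift_test(pt, "nope"), "no set member")
})

test_that("exact rank-sum p equals the enumeration oracle, ties included", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    n1 <- sample(2:(n - 2), 1)
    vals <- if (i %% 2) rnorm(n) else sample(1:4, n, TRUE)
    pt <- make_pi_table(sprintf("g%02d", 1:n), vals)
    members <- sprintf("g%02d", sample(n, n1))
    got <- set_shift_test(pt, members)$p_raw
    x <- vals[pt$gene_id %in% members]
    y <- vals[!pt$gene_id %in% members]
    expect_equal(got, oracle_ranksum_exact(x, y), tolerance = 1e-12)
  }
})

test_that("collection runs filter by per-category size and correct within category", {
  set.seed(55)
  ids <- sprintf("g%03d", 1:200)
  pt <- make_pi_table(ids, rnorm(200))
  sets <- c(lapply(1:4, function(i) sample(ids, 30)),   # pass at threshold 25
            lapply(1:6, function(i) sample(ids, 10)))   # filtered out
  names(sets) <- sprintf("S%02d", 1:10)
  coll <- gene_set_collection(sets, "go_bp")
  res <- run_collection(pt, coll, min_size = 25)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$n_tests == 4L))
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 4))

  # two categories get independent size thresholds and Bonferroni denominators
  coll2 <- gene_set_collection(sets, rep(c("go_bp", "metabolic"), each = 5))
  res2 <- run_collection(pt, coll2, min_size = c(default = 25, metabolic = 5))
  expect_equal(sum(res2$category == "go_bp"), 4L)       # 30-gene sets only
  expect_equal(sum(res2$category == "metabolic"), 5L)   # all pass at 5
  expect_true(all(res2$n_tests[res2$category == "go_bp"] == 4L))
  expect_true(all(res2$n_tests[res2$category == "metabolic"] == 5L))

  expect_error(run_collection(pt, coll, min_size = 500), "filtered out")
})

test_that("empirical set test hits the closed-form extremes", {
  pt <- make_pi_table(sprintf("g%02d", 1:40), sort(rnorm(40)))
  low5 <- pt$gene_id[1:5]
  res <- empirical_set_test(pt, low5, n_perm = 400, side = "low", seed = 1)
  expect_equal(res$p_empirical, 1 / 401)    # nothing can be lower
  flat <- make_pi_table(sprintf("g%02d", 1:40), rep(0.3, 40))
  res2 <- empirical_set_test(flat, low5, n_perm = 400, side = "low", seed = 1)
  expect_equal(res2$p_empirical, 1)
  expect_error(empirical_set_test(pt, pt$gene_id, n_perm = 400), "universe")
  expect_error(empirical_set_test(pt, low5, n_perm = 50), "100")
})

test_that("binning partitions the ranked list with the remainder in the last bin", {
  set.seed(8)
  pt <- make_pi_table(sprintf("g%03d", 1:450), rnorm(450))
  bins <- bin_genes(pt, bin_size = 200)
  expect_equal(bins$table$n, c(200L, 250L))
  expect_true(all(diff(bins$table$mean_pi) > 0))
  expect_setequal(unlist(bins$gene_ids), pt$gene_id)

  # absolute ordering: a large negative value is more extreme than a small
  # positive one, so it lands in a later bin
  pt2 <- make_pi_table(sprintf("g%03d", 1:40),
                       c(-0.9, 0.1, runif(38, 0.2, 0.8)))
  b2 <- bin_genes(pt2, bin_size = 10, order = "absolute")
  pos_of <- function(g) which(vapply(b2$gene_ids, function(ids) g %in% ids, NA))
  expect_gt(pos_of("g001"), pos_of("g002"))

  expect_error(bin_genes(pt, bin_size = 300), ">=")
})

test_that("bin fold enrichment is neutral at global composition and exact", {
  # bin composition equal to the global composition -> fold exactly 1
  pt <- make_pi_table(sprintf("g%02d", 1:40), sort(rnorm(40)))
  bins <- bin_genes(pt, bin_size = 10)
  special <- unlist(lapply(bins$gene_ids, `[`, 1:2))  # 2 of 10 in every bin
  be <- bin_enrichment(bins, special, pt$gene_id)
  expect_equal(be$table$enrichment_fold, rep(1, 4))

  # derived toy: universe 10, special 4, bin of 5 containing all 4 specials
  pt2 <- make_pi_table(sprintf("g%02d", 1:10), 1:10)
  bins2 <- bin_genes(pt2, bin_size = 5)
  special2 <- bins2$gene_ids[[1]][1:4]
  be2 <- bin_enrichment(bins2, special2, pt2$gene_id)
  expect_equal(be2$table$hypergeometric_p[1], 6 / 252, tolerance = 1e-12)
  expect_equal(be2$table$hypergeometric_p[1],
               oracle_hyper_upper(4, 4, 10, 5), tolerance = 1e-12)

  expect_error(bin_enrichment(bins, c("zz1", "zz2"), pt$gene_id),
               "do not intersect")
})

test_that("hypergeometric bin p-values equal enumeration on small references", {
  set.seed(77)
  for (i in 1:15) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    ids <- sprintf("g%02d", 1:N)
    pt <- make_pi_table(ids, rnorm(N))
    bins <- bin_genes(pt, bin_size = N %/% 2)
    special <- ids[1:K]
    be <- bin_enrichment(bins, special, ids)
    for (b in seq_len(nrow(be$table))) {
      expect_equal(be$table$hypergeometric_p[b],
                   oracle_hyper_upper(be$table$n_special[b], K, N,
                                      be$table$n_reference[b]),
                   tolerance = 1e-12)
    }
  }
})

test_that("covariate means recover identity and flag degenerate covariates", {
  set.seed(12)
  pt <- make_pi_table(sprintf("g%03d", 1:100), rnorm(100))
  bins <- bin_genes(pt, bin_size = 20)
  covar <- setNames(pt$pi, pt$gene_id)
  res <- covariate_correlation(pt, bins, covar)
  expect_equal(res$binned$rho, 1)
  expect_equal(res$raw$rho, 1)
  expect_equal(res$bins$table$mean_covariate, res$bins$table$mean_pi)

  const <- setNames(rep(2, 100), pt$gene_id)
  res2 <- covariate_correlation(pt, bins, const)
  expect_true(is.na(res2$binned$rho) && is.na(res2$raw$rho))

  sparse <- covar[1:20]
  expect_error(bin_covariate_means(bins, sparse), "half")
})

test_that("top_k selects extremes deterministically, ties broken by id", {
  pt <- make_pi_table(c("b", "a", "c", "d"), c(0.5, 0.5, 0.2, 0.9))
  expect_setequal(top_k(pt, 4, "highest"), pt$gene_id)
  # tie at rank 2 between "a" and "b": id order wins
  expect_equal(top_k(pt, 2, "highest"), c("d", "a"))
  expect_equal(top_k(pt, 2, "lowest"), c("c", "a"))
  expect_error(top_k(pt, 5), "universe")

  cpi <- make_pi_table(letters[1:6], c(0.9, 0.5, 0.4, 0.3, 0.2, 0.1))
  npi <- make_pi_table(letters[1:6], c(-0.1, -0.8, -0.2, -0.3, -0.1, -0.2))
  d <- compute_dpi(cpi, npi)
  expect_true(d$gene_id[which.max(d$dpi)] %in% top_k(d, 2, "highest"))
})
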