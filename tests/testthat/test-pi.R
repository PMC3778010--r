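test_that("doubling times convert to rates by ln(2)/d, reversing ranks", {
  g <- growth_measurements(c("a", "b", "c"), c(24, 48, 12), "doubling_time")
  r <- to_growth_rate(g)
  expect_equal(r$kind, "growth_rate")
  expect_equal(r$values, log(2) / c(24, 48, 12))
  expect_equal(rank(r$values), length(g$values) + 1 - rank(g$values))
  # growth rates pass through untouched
  expect_identical(to_growth_rate(r), r)
})

test_that("spearman PI matches the hand-derived toy and flags degeneracies", {
  p <- make_panel(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(5, 5, 5, 5)))
  g <- growth_measurements(p$sample_ids, c(10, 20, 15, 40), "growth_rate")
  tab <- quiet(compute_pi(p, g))
  # ranks 1,2,3,4 vs 1,3,2,4: rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(tab$pi[1], 0.8)
  expect_equal(tab$pi[2], -0.8)
  expect_true(is.na(tab$pi[3]) && tab$flagged[3] && tab$p_value[3] == 1)
  expect_equal(attr(tab, "n"), 4L)

  # strictly decreasing expression in growth order -> rho exactly -1
  p2 <- make_panel(matrix(c(8, 6, 4, 2, 1), 1))
  g2 <- growth_measurements(p2$sample_ids, 1:5, "growth_rate")
  expect_equal(compute_pi(p2, g2)$pi, -1)
})

test_that("spearman PI equals the rank oracle and is monotone-invariant", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    x <- if (i %% 3 == 0) sample(1:5, n, TRUE) else rnorm(n)  # with ties
    r <- abs(rnorm(n)) + 0.1
    p <- make_panel(matrix(x, 1))
    g <- growth_measurements(p$sample_ids, r, "growth_rate")
    got <- compute_pi(p, g)$pi
    expect_equal(got, oracle_spearman(x, r), tolerance = 1e-12)
    # strictly increasing transforms of either side leave rho unchanged
    p_t <- make_panel(matrix(exp(x / 2), 1))
    g_t <- growth_measurements(p$sample_ids, r^3 + 1e-6, "growth_rate")
    expect_equal(compute_pi(p_t, g_t)$pi, got, tolerance = 1e-12)
  }
})

test_that("PI on doubling times is the negation of PI on rates", {
  set.seed(7)
  X <- matrix(rnorm(80), 4, 20)
  p <- make_panel(X)
  d <- exp(rnorm(20, 3, 0.3))
  as_dt <- growth_measurements(p$sample_ids, d, "doubling_time")
  as_raw <- growth_measurements(p$sample_ids, d, "growth_rate")  # untransformed
  expect_equal(compute_pi(p, as_dt)$pi, -compute_pi(p, as_raw)$pi,
               tolerance = 1e-12)
})

test_that("slope PI equals cov/var, matches lm p-values, and normalizes", {
  set.seed(13)
  X <- matrix(rnorm(10 * 12, 7), 10, 12)
  p <- make_panel(X)
  r <- abs(rnorm(12, 0.03, 0.01)) + 1e-3
  g <- growth_measurements(p$sample_ids, r, "growth_rate")
  raw <- compute_pi(p, g, method = "slope", normalize = FALSE)
  for (i in c(1, 4, 10)) {
    fit <- lm(X[i, ] ~ r)
    expect_equal(raw$pi[i], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(raw$p_value[i],
                 anova(fit)[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(raw$pi[i], cov(X[i, ], r) / var(r), tolerance = 1e-10)
  }
  norm <- compute_pi(p, g, method = "slope")
  expect_equal(median(abs(norm$pi)), 1, tolerance = 1e-9)
  expect_true(attr(norm, "normalized"))
  # normalization preserves p-values and sign pattern
  expect_equal(norm$p_value, raw$p_value)
  expect_equal(sign(norm$pi), sign(raw$pi))
})

test_that("dPI uses the global nPI minimum, epsilon, and the subset rule", {
  cpi <- make_pi_table(letters[1:5], c(0.5, 0.5, 0.5, -0.2, 0.3),
                       p_value = c(0.01, 0.02, 0.03, 0.04, 0.05))
  npi <- make_pi_table(letters[1:5], c(-0.3, -0.1, -0.3, -0.5, 0.2))
  # nPI_min = -0.5 comes from gene "d", which is itself excluded (cPI < 0)
  d <- compute_dpi(cpi, npi, epsilon = 0.01)
  expect_setequal(d$gene_id, c("a", "b", "c"))
  expect_false("d" %in% d$gene_id)   # cPI < 0
  expect_false("e" %in% d$gene_id)   # nPI > 0
  dpi_of <- function(g) d$dpi[d$gene_id == g]
  expect_equal(dpi_of("a"), 0.5 / (-0.3 + 0.5 + 0.01))
  # equal cPI: the more negative nPI wins
  expect_gt(dpi_of("a"), dpi_of("b"))
  expect_true(all(d$dpi > 0))
  # p-values inherited from cPI
  expect_equal(dpi_of("a"), dpi_of("c"))
  expect_setequal(d$p_value, c(0.01, 0.02, 0.03))

  # gene at the global minimum: denominator reduces to epsilon
  cpi2 <- make_pi_table(c("x", "y"), c(0.5, 0.1))
  npi2 <- make_pi_table(c("x", "y"), c(-0.4, -0.1))
  d2 <- compute_dpi(cpi2, npi2, epsilon = 0.01)
  expect_equal(d2$dpi[d2$gene_id == "x"], 0.5 / 0.01)

  expect_error(compute_dpi(cpi, npi, epsilon = 0), "positive")
  all_neg <- make_pi_table(letters[1:5], rep(-0.1, 5))
  expect_error(compute_dpi(all_neg, npi), "empty differential")
})

test_that("dPI is monotone: increasing in cPI, decreasing in nPI", {
  set.seed(3)
  base_c <- runif(50, 0.05, 0.9)
  base_n <- runif(50, -0.9, -0.05)
  ids <- sprintf("g%02d", 1:50)
  d0 <- compute_dpi(make_pi_table(ids, base_c), make_pi_table(ids, base_n))
  # raise one gene's cPI at fixed nPI -> its dpi strictly increases
  c2 <- base_c; c2[10] <- c2[10] + 0.05
  d1 <- compute_dpi(make_pi_table(ids, c2), make_pi_table(ids, base_n))
  expect_gt(d1$dpi[d1$gene_id == ids[10]], d0$dpi[d0$gene_id == ids[10]])
  # lower one gene's nPI (not the minimum) at fixed cPI -> dpi increases
  stopifnot(which.min(base_n) != 20)
  n2 <- base_n; n2[20] <- n2[20] - 0.03
  d2 <- compute_dpi(make_pi_table(ids, base_c), make_pi_table(ids, n2))
  expect_gt(d2$dpi[d2$gene_id == ids[20]], d0$dpi[d0$gene_id == ids[20]])
})

test_that("PI table comparison handles identity, negation and disjointness", {
  set.seed(9)
  t1 <- make_pi_table(sprintf("g%d", 1:30), rnorm(30))
  expect_equal(compare_pi_tables(t1, t1)$rho, 1)
  t_neg <- make_pi_table(t1$gene_id, -t1$pi)
  expect_equal(compare_pi_tables(t1, t_neg)$rho, -1)
  t2 <- make_pi_table(sprintf("h%d", 1:30), rnorm(30))
  expect_error(compare_pi_tables(t1, t2), ">= 3")
})

test_that("group PIs split correctly, skip small groups, and reduce to the whole", {
  set.seed(21)
  p <- make_panel(matrix(rnorm(5 * 60, 7), 5, 60))
  g <- growth_measurements(p$sample_ids, abs(rnorm(60, 0.03, 0.01)) + 1e-3,
                           "growth_rate")
  grouping <- setNames(rep(c("slow", "fast"), each = 30), p$sample_ids)
  res <- compute_pi_groups(p, g, grouping)
  expect_named(res, c("slow", "fast"))
  expect_equal(attr(res$slow, "n"), 30L)
  expect_equal(attr(res$fast, "n"), 30L)

  # a 2-sample tumor type is skipped, as with under-represented cancer types
  grouping2 <- grouping
  grouping2[1:2] <- "prostate"
  expect_message(res2 <- compute_pi_groups(p, g, grouping2), "skipped")
  expect_false("prostate" %in% names(res2))

  one <- setNames(rep("all", 60), p$sample_ids)
  expect_equal(compute_pi_groups(p, g, one)$all$pi, compute_pi(p, g)$pi)
})
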