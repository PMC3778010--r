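make_cohort <- function(time, event, n_genes = 4) {
  n <- length(time)
  panel <- make_panel(matrix(rnorm(n_genes * n, 7), n_genes, n),
                      samples = sprintf("p%02d", seq_len(n)))
  survival_cohort(panel, time, event)
}

make_classification <- function(cohort, labels) {
  scores <- setNames(ifelse(labels == "high", 2, 1) + rnorm(length(labels), 0, 1e-3),
                     cohort$expression$sample_ids)
  structure(list(sample_ids = names(scores), predicted_growth = scores,
                 label = setNames(labels, names(scores)),
                 cluster_centers = c(low = 1, high = 2)),
            class = "classification")
}

test_that("CV-trained panel model reduces to a direct fit on a 1-point grid", {
  set.seed(41)
  st <- generate_study(generator_config(n_genes = 150, n_cancer_samples = 24,
                                        seed = 6))
  genes <- st$truth$gene_id[st$truth$class == "cancer_pos"][1:12]
  m1 <- quiet(train_panel_model(st$cancer_panel, st$cancer_growth, genes,
                                lambda_grid = 1e-3))
  al <- quiet(align_panel_growth(st$cancer_panel, st$cancer_growth))
  X <- t(al$panel$values[genes, ])
  y <- to_growth_rate(al$growth)$values
  m2 <- fit_lasso(X, y, 1e-3)
  expect_equal(m1$weights, m2$weights)
  expect_equal(m1$intercept, m2$intercept)

  # strong planted signal: CV keeps a finite penalty and nonzero weights
  m3 <- quiet(train_panel_model(st$cancer_panel, st$cancer_growth, genes,
                                seed = 2))
  expect_true(attr(m3, "cv_lambda") > 0)
  expect_gt(sum(m3$weights != 0), 0)
})

test_that("cross-validation shrinks pure-noise models to near-empty", {
  set.seed(17)
  heavy <- 0
  for (s in 1:5) {
    panel <- make_panel(matrix(rnorm(40 * 30, 7), 40, 30))
    y <- abs(rnorm(30, 0.03, 0.01)) + 1e-3          # independent of expression
    growth <- growth_measurements(panel$sample_ids, y, "growth_rate")
    m <- quiet(train_panel_model(panel, growth, rownames(panel$values),
                                 seed = s))
    if (mean(m$weights == 0) >= 0.9) heavy <- heavy + 1
  }
  expect_gte(heavy, 4)
})

test_that("model application intersects genes and ignores zero weights", {
  model <- structure(list(gene_ids = c("a", "b", "c"),
                          weights = c(a = 1, b = -2, c = 0),
                          intercept = 0.5, lambda = 0, training_n = 10L),
                     class = "lasso_model")
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("p1", "p2")))
  cohort <- survival_cohort(expression_panel(vals), c(1, 2), c(1, 0))
  sc <- apply_model(model, cohort)
  expect_equal(unname(sc), c(1 * 1 - 2 * 2 + 0.5, 1 * 4 - 2 * 5 + 0.5))

  # dropping the zero-weight gene changes nothing
  cohort2 <- survival_cohort(expression_panel(vals[c("a", "b"), ]),
                             c(1, 2), c(1, 0))
  expect_message(sc2 <- apply_model(model, cohort2), "absent")
  expect_equal(sc2, sc)

  vals3 <- vals; rownames(vals3) <- c("x", "y", "z")
  cohort3 <- survival_cohort(expression_panel(vals3), c(1, 2), c(1, 0))
  expect_error(apply_model(model, cohort3), ">= 2")
})

test_that("two-means split is the exact 1-D optimum", {
  s1 <- setNames(c(1, 1, 1, 9, 9, 9), sprintf("p%d", 1:6))
  c1 <- two_means_split(s1)
  expect_setequal(names(c1$label)[c1$label == "low"], sprintf("p%d", 1:3))

  s2 <- setNames(c(1, 2, 8, 8.5), sprintf("p%d", 1:4))
  c2 <- two_means_split(s2)
  expect_setequal(names(c2$label)[c2$label == "low"], c("p1", "p2"))

  set.seed(19)
  for (i in 1:30) {
    s <- setNames(rnorm(sample(4:20, 1)), NULL)
    names(s) <- sprintf("p%02d", seq_along(s))
    cl <- two_means_split(s)
    or <- oracle_two_means_wss(s)
    expect_setequal(unname(sort(s[cl$label == "low"])), or$low)
    expect_gt(cl$cluster_centers[["high"]], cl$cluster_centers[["low"]])
  }
  expect_error(two_means_split(setNames(rep(1, 5), sprintf("p%d", 1:5))),
               "constant")
})

test_that("logrank matches the risk-table oracle and the symmetric null", {
  # identical survival experience in both groups
  cohort <- make_cohort(time = c(1, 1, 2, 2, 3, 3), event = rep(1, 6))
  cls <- make_classification(cohort, rep(c("low", "high"), 3))
  lr <- logrank_test(cohort, cls)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(cohort$event))

  # toy with hand-checkable risk sets: A = {1, 2} events, B = {3, 4} events
  cohort2 <- make_cohort(time = c(1, 2, 3, 4), event = rep(1, 4))
  cls2 <- make_classification(cohort2, c("low", "low", "high", "high"))
  lr2 <- logrank_test(cohort2, cls2)
  expect_equal(lr2$chi_square,
               oracle_logrank_chisq(cohort2$time, cohort2$event,
                                    cls2$label[cohort2$expression$sample_ids]),
               tolerance = 1e-10)

  # group B only censored, interleaved with A's events: B contributes no
  # events but still shapes the risk sets
  cohort3 <- make_cohort(time = c(1, 3, 5, 2, 4), event = c(1, 1, 1, 0, 0))
  cls3 <- make_classification(cohort3, c(rep("low", 3), rep("high", 2)))
  lr3 <- logrank_test(cohort3, cls3)
  expect_equal(lr3$observed[["high"]], 0)
  expect_lt(lr3$expected[["low"]], lr3$observed[["low"]])
  expect_equal(lr3$chi_square,
               oracle_logrank_chisq(cohort3$time, cohort3$event,
                                    cls3$label[cohort3$expression$sample_ids]),
               tolerance = 1e-10)

  cohort4 <- make_cohort(time = 1:4, event = rep(0, 4))
  cls4 <- make_classification(cohort4, c("low", "low", "high", "high"))
  expect_error(logrank_test(cohort4, cls4), "no events")
})

test_that("classification and logrank are invariant to score shifts", {
  set.seed(23)
  cohort <- make_cohort(time = rexp(12) + 0.05, event = rbinom(12, 1, 0.7))
  scores <- setNames(rnorm(12), cohort$expression$sample_ids)
  c_a <- two_means_split(scores)
  c_b <- two_means_split(scores + 100)
  expect_equal(c_a$label, c_b$label)
  expect_equal(logrank_test(cohort, c_a)$chi_square,
               logrank_test(cohort, c_b)$chi_square)
})

test_that("Kaplan-Meier step tables give the closed-form product limit", {
  cohort <- make_cohort(time = 1:4, event = rep(1, 4))
  cls <- make_classification(cohort, rep(c("low", "high"), 2))
  # put all four in one group via a direct classification
  cls$label[] <- "low"; cls$label[1] <- "high"  # keep both groups nonempty
  km <- km_curves(cohort, cls)
  expect_equal(km$low$survival, c(2/3, 1/3, 0))
  expect_equal(km$low$time, c(2, 3, 4))

  # all-censored group stays flat at 1
  cohort2 <- make_cohort(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  cls2 <- make_classification(cohort2, c("high", "high", "low", "low"))
  km2 <- km_curves(cohort2, cls2)
  expect_true(all(km2$low$survival == 1))
  expect_true(all(diff(km2$high$survival) <= 0))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_km(km2, tf)
  back <- read.delim(tf)
  expect_setequal(unique(back$group), c("low", "high"))
})

test_that("the survival pipeline emits one stratification per measure", {
  st <- generate_study(generator_config(n_genes = 300, seed = 12))
  cpi <- quiet(compute_pi(st$cancer_panel, st$cancer_growth))
  npi <- quiet(compute_pi(st$normal_panel, st$normal_growth))
  dpi <- compute_dpi(cpi, npi)
  rep <- quiet(run_survival_pipeline(st$cancer_panel, st$cancer_growth,
                                     st$normal_panel, st$normal_growth,
                                     list(cpi = cpi, npi = npi, dpi = dpi),
                                     st$cohort, seed = 31))
  expect_setequal(rep$summary$measure, c("cpi", "npi", "dpi"))
  expect_equal(nrow(rep$summary), 3L)
  for (m in c("cpi", "npi", "dpi")) {
    expect_s3_class(rep[[m]]$logrank, "logrank_result")
    expect_s3_class(rep[[m]]$km, "km_curves")
    expect_length(rep[[m]]$km, 2L)
  }
  expect_true(all(rep$summary$n_low + rep$summary$n_high ==
                    length(st$cohort$time)))
})
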