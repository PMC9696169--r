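test_that("contrast fit reproduces hand-computed two-sample statistics", {
  # constant groups: means 6 vs 5 -> log2fc 1, linear FC 2
  vals <- rbind(c(6, 6, 6, 5, 5, 5))
  expr <- dplyr::bind_cols(tibble::tibble(gene = "G000001"),
                           tibble::as_tibble(matrix(vals, nrow = 1,
                                                    dimnames = list(NULL, toy_samples()$sample))))
  fit <- fit_contrast(expr, toy_samples(), "A", "B")
  expect_equal(fit$log2fc, 1)
  expect_equal(fit$fc, 2)

  # identical groups: log2fc 0, t 0, p 1
  same <- expr
  same[1, -1] <- as.list(rep(5, 6))
  fit0 <- fit_contrast(same, toy_samples(), "A", "B")
  expect_equal(fit0$log2fc, 0)
  expect_equal(fit0$t, 0)
  expect_equal(fit0$p, 1)

  # 5-gene toy matrix against the textbook pooled-variance oracle
  set.seed(12)
  vals <- matrix(rnorm(30, 7, 1), nrow = 5,
                 dimnames = list(NULL, toy_samples()$sample))
  expr5 <- dplyr::bind_cols(tibble::tibble(gene = sprintf("G%06d", 1:5)),
                            tibble::as_tibble(vals))
  fit5 <- fit_contrast(expr5, toy_samples(), "A", "B")
  for (g in 1:5) {
    o <- pooled_t_oracle(vals[g, 1:3], vals[g, 4:6])
    expect_equal(fit5$t[g], o$t, tolerance = 1e-12)
    expect_equal(fit5$p[g], o$p, tolerance = 1e-12)
    expect_equal(fit5$df[g], o$df)
  }
  expect_error(fit_contrast(expr5, toy_samples()[-(1:2), ], "A", "B"),
               "at least 2")
})

test_that("moderation limits collapse to the ordinary t and to the prior", {
  set.seed(5)
  d <- sim_design(c("A", "B"), n_genes = 200, seed = 5)
  ex <- simulate_expression(d)
  fit <- fit_contrast(ex$expr, ex$samples, "A", "B")

  m0 <- moderate(fit, prior_df = 0, prior_var = 1)
  expect_equal(m0$t, fit$t, tolerance = 1e-10)
  expect_equal(m0$s2_post, fit$residual_sd^2, tolerance = 1e-10)

  minf <- moderate(fit, prior_df = Inf, prior_var = 0.05)
  expect_true(all(minf$s2_post == 0.05))
  # with a normal reference, p = 2*pnorm(-|t|)
  expect_equal(minf$p, 2 * pnorm(-abs(minf$t)), tolerance = 1e-12)
})

test_that("variance-prior estimation recovers the generating hyperparameters", {
  d <- sim_design(c("A", "B"), n_genes = 10000,
                  gene_sd_prior = list(d0 = 4, s0 = 0.25), seed = 77)
  ex <- simulate_expression(d)
  fit <- fit_contrast(ex$expr, ex$samples, "A", "B")
  mod <- moderate(fit)
  expect_lt(abs(attr(mod, "d0") - 4) / 4, 0.25)
  expect_lt(abs(attr(mod, "s0_sq") - 0.25^2) / 0.25^2, 0.25)
})

test_that("moderated statistics agree with an independent limma fit", {
  skip_if_not_installed("limma")
  d <- sim_design(c("A", "B"), n_genes = 500, seed = 9)
  ex <- simulate_expression(d)
  fit <- moderate(fit_contrast(ex$expr, ex$samples, "A", "B"))

  m <- as.matrix(ex$expr[-1])
  rownames(m) <- ex$expr$gene
  design <- cbind(B = 1, AvsB = ex$samples$group == "A")
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(fit, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s0_sq"), lfit$s2.prior, tolerance = 1e-8)
  expect_equal(fit$t, unname(lfit$t[, "AvsB"]), tolerance = 1e-8)
  expect_equal(fit$p, unname(lfit$p.value[, "AvsB"]), tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up oracle and its invariances", {
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))

  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }

  # permutation equivariance
  p <- runif(25)
  perm <- sample(25)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))

  # idempotence on evenly spaced monotone inputs (adjustment yields a
  # constant vector, a fixed point of the step-up rule)
  p_grid <- (1:20) * 0.4 / 20
  q <- adjust_bh(p_grid)
  expect_equal(q, rep(0.4, 20))
  expect_equal(adjust_bh(q), q)

  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("DEG calling applies strict joint thresholds", {
  fit <- fake_fit(log2(c(1.6, 1.2, 0.5, 1.51, 0.67, 2.4)))
  fit$p <- c(0.01, 0.01, 0.01, 0.2, 0.04, 0.04)
  fit$q <- c(0.05, 0.05, 0.05, 0.5, 0.09, 0.09)
  fit$df <- 4
  class(fit) <- c("contrast_result", class(fit))
  attr(fit, "moderated") <- TRUE

  call <- call_degs(fit, "fdr", cutoff = 0.10)
  expect_setequal(deg_genes(call, "increased"), c("G000001", "G000006"))
  # G000005 has FC exactly 0.67: strict inequality excludes it
  expect_setequal(deg_genes(call, "decreased"), "G000003")
  # q=0.05, FC=1.2 gene is in neither list
  expect_false("G000002" %in% call$gene)
  expect_length(intersect(deg_genes(call, "increased"),
                          deg_genes(call, "decreased")), 0)

  # brute-force check on a random 20-gene table, both modes
  set.seed(8)
  tab <- fake_fit(rnorm(20, 0, 1))
  tab$p <- runif(20)
  tab$q <- adjust_bh(tab$p)
  class(tab) <- c("contrast_result", class(tab))
  for (mode in c("fdr", "raw_p")) {
    cutoff <- if (mode == "fdr") 0.10 else 0.05
    sig <- if (mode == "fdr") tab$q < cutoff else tab$p < cutoff
    call <- call_degs(tab, mode, cutoff = cutoff)
    expect_setequal(deg_genes(call, "increased"),
                    tab$gene[sig & tab$fc > 1.5])
    expect_setequal(deg_genes(call, "decreased"),
                    tab$gene[sig & tab$fc < 0.67])
  }
  expect_error(call_degs(fit, "fdr", cutoff = 0.1, fc_up = 0.5, fc_down = 0.9),
               "exceed")
})

test_that("moderated p-values are monotone in |t| at fixed df", {
  d <- sim_design(c("A", "B"), n_genes = 300, seed = 2)
  ex <- simulate_expression(d)
  mod <- moderate(fit_contrast(ex$expr, ex$samples, "A", "B"))
  ord <- order(abs(mod$t))
  expect_true(all(diff(mod$p[ord]) <= 1e-14))
})
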