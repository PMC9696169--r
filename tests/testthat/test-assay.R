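test_that("slope fitting matches the closed-form least-squares oracle", {
  # noise-free line: 0,1,2,3 at 0,5,10,15 min -> slope 0.2/min
  a <- tibble::tibble(condition = "CTL", replicate = 1,
                      time_min = c(0, 5, 10, 15),
                      absorbance = c(0, 1, 2, 3))
  expect_equal(fit_slopes(a)$slope, 0.2, tolerance = 1e-12)

  const <- dplyr::mutate(a, absorbance = 0.4)
  expect_equal(fit_slopes(const)$slope, 0, tolerance = 1e-12)

  set.seed(61)
  noisy <- simulate_kinetic_assay(0.04, c(X = 0.4), noise_sd = 0.02, seed = 3)
  got <- fit_slopes(noisy)
  for (cond in c("CTL", "X")) {
    d <- noisy[noisy$condition == cond, ]
    o <- slope_oracle(d$time_min, d$absorbance)
    expect_equal(got$slope[got$condition == cond], o$slope, tolerance = 1e-12)
    expect_equal(got$se[got$condition == cond], o$se, tolerance = 1e-12)
  }
  expect_error(fit_slopes(a[1, ]), "2 distinct timepoints")
})

test_that("percent inhibition follows the slope-ratio formula and is scale-free", {
  expect_equal(percent_inhibition(0.04, 0.04), 0)
  expect_equal(percent_inhibition(0, 0.04), 100)
  expect_equal(percent_inhibition(0.02, 0.04), 50)
  expect_equal(percent_inhibition(0.06, 0.04), -50)
  expect_equal(percent_inhibition(0.06, 0.04, clip = TRUE), 0)
  # invariance to rescaling all absorbances by a positive constant
  expect_equal(percent_inhibition(0.02 * 7, 0.04 * 7),
               percent_inhibition(0.02, 0.04))
  expect_error(percent_inhibition(0.02, 0), "positive")
})

test_that("interaction test equals the normal-equations oracle and has power", {
  # identical generating slopes, noise-free: zero interaction coefficient
  flat <- simulate_kinetic_assay(0.04, c(X = 0), noise_sd = 0, seed = 2)
  it0 <- interaction_test(flat, "X", "CTL")
  expect_equal(it0$slope_difference, 0, tolerance = 1e-12)

  # toy dataset against a direct lm on the interaction design
  set.seed(62)
  a <- simulate_kinetic_assay(0.04, c(X = 0.5), noise_sd = 0.01, seed = 5)
  it <- interaction_test(a, "X", "CTL")
  d <- a[a$condition %in% c("CTL", "X"), ]
  X <- cbind(1, d$time_min, d$condition == "X",
             d$time_min * (d$condition == "X"))
  beta <- solve(crossprod(X), crossprod(X, d$absorbance))
  resid <- d$absorbance - X %*% beta
  s2 <- sum(resid^2) / (nrow(d) - 4)
  se4 <- sqrt(s2 * solve(crossprod(X))[4, 4])
  t4 <- beta[4] / se4
  expect_equal(it$slope_difference, beta[4], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(it$p, 2 * pt(-abs(t4), nrow(d) - 4), tolerance = 1e-10)

  # power: planted 50% inhibition detected in nearly all runs
  hits <- vapply(1:200, function(i) {
    sim <- simulate_kinetic_assay(0.04, c(X = 0.5), noise_sd = 0.01,
                                  seed = 10000 + i)
    interaction_test(sim, "X", "CTL")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inhibition summary recovers planted fractions", {
  a <- simulate_kinetic_assay(0.04, c(VEH = 0, IDL = 0.5, IDC = 0.9),
                              noise_sd = 0.005, seed = 8)
  s <- inhibition_summary(a, control = "CTL")
  expect_true(is.na(s$pct_inhibition[s$condition == "CTL"]))
  expect_equal(s$pct_inhibition[s$condition == "IDL"], 50, tolerance = 0.1)
  expect_equal(s$pct_inhibition[s$condition == "IDC"], 90, tolerance = 0.05)
  expect_lt(s$interaction_p[s$condition == "IDC"], 0.001)
})

test_that("Fisher's LSD matches the pooled-t oracle and letters are valid", {
  set.seed(63)
  d <- tibble::tibble(
    group = rep(c("CTL", "CYT", "TRT"), each = 4),
    value = c(rnorm(4, 10, 1), rnorm(4, 15, 1), rnorm(4, 15.5, 1))
  )
  res <- fisher_lsd(d)

  # oracle: pooled MSE from one-way ANOVA, pairwise t on df_error
  fitaov <- stats::aov(value ~ group, data = d)
  mse <- summary(fitaov)[[1]]["Residuals", "Mean Sq"]
  expect_equal(res$mse, mse, tolerance = 1e-10)
  for (i in seq_len(nrow(res$pairwise))) {
    g1 <- res$pairwise$group1[i]; g2 <- res$pairwise$group2[i]
    v1 <- d$value[d$group == g1]; v2 <- d$value[d$group == g2]
    tstat <- (mean(v1) - mean(v2)) / sqrt(mse * (1 / 4 + 1 / 4))
    expect_equal(res$pairwise$p[i], 2 * pt(-abs(tstat), res$df_error),
                 tolerance = 1e-10)
  }

  # letter validity: shared letter iff non-significant pair
  shares <- function(l1, l2) {
    length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
  }
  lt <- setNames(res$groups$letters, res$groups$group)
  for (i in seq_len(nrow(res$pairwise))) {
    pair_ns <- res$pairwise$p[i] >= 0.05
    expect_equal(shares(lt[[res$pairwise$group1[i]]],
                        lt[[res$pairwise$group2[i]]]), pair_ns)
  }
})

test_that("LSD handles degenerate groups", {
  # identical replicate sets in every group: all p = 1, one shared letter
  same <- tibble::tibble(group = rep(c("A", "B", "C"), each = 3),
                         value = rep(c(1, 2, 3), times = 3))
  res <- fisher_lsd(same)
  expect_true(all(res$pairwise$p == 1))
  expect_length(unique(res$groups$letters), 1)

  # noise-free separated groups: p = 0 pairs, distinct letters
  sep <- tibble::tibble(group = rep(c("A", "B"), each = 3),
                        value = rep(c(1, 5), each = 3))
  res2 <- fisher_lsd(sep)
  expect_equal(res2$pairwise$p, 0)
  expect_false(res2$groups$letters[1] == res2$groups$letters[2])
  expect_error(fisher_lsd(same[1:3, ]), "2 groups")
})

test_that("one-tailed pooled t-test matches the textbook formula", {
  set.seed(64)
  a <- rnorm(3, 12, 1); b <- rnorm(3, 10, 1)
  got <- one_tailed_t(a, b, "greater")
  o <- pooled_t_oracle(a, b)
  expect_equal(got$t, o$t, tolerance = 1e-12)
  expect_equal(got$p, pt(o$t, o$df, lower.tail = FALSE), tolerance = 1e-12)

  # direction reversal complements the p-value
  expect_equal(one_tailed_t(a, b, "less")$p, 1 - got$p, tolerance = 1e-12)

  # identical degenerate groups: one-sided p is 0.5 by symmetry
  expect_equal(one_tailed_t(c(2, 2), c(2, 2), "greater")$p, 0.5)
  expect_error(one_tailed_t(1, c(1, 2)), "replicates")
})

test_that("blank normalisation subtracts per-plate blank means", {
  d <- tibble::tibble(plate = c("P1", "P1", "P2", "P2"),
                      value = c(1.0, 1.2, 2.0, 0.1))
  blanks <- tibble::tibble(plate = c("P1", "P1", "P2"),
                           value = c(0.2, 0.4, 0.5))
  out <- normalize_blank(d, blanks)
  expect_equal(out$value, c(1.0 - 0.3, 1.2 - 0.3, 1.5, -0.4))
  expect_equal(out$below_blank, c(FALSE, FALSE, FALSE, TRUE))

  # zero blank is the identity
  zb <- tibble::tibble(plate = "P1", value = 0)
  expect_equal(normalize_blank(d[1:2, ], zb)$value, d$value[1:2])
  expect_error(normalize_blank(d, blanks[1:2, ]), "No blank")
})
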