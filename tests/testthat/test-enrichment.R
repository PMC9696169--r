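test_that("member detection is case-insensitive and universe-bound", {
  fit <- fake_fit(rnorm(10, 0, 1), genes = c("IL1B", "TNF", "CCL2", "KRT5",
                                             "FLG", "IVL", "TGM1", "SPRR3",
                                             "LCE1E", "CDH1"))
  expect_setequal(detect_members(c("Il1b", "tnf", "NOPE"), fit),
                  c("IL1B", "TNF"))
  expect_setequal(detect_members(fit$gene, fit), fit$gene)
  expect_length(detect_members(c("ABC", "XYZ"), fit), 0)
})

test_that("overlap test equals the brute-force hypergeometric tail", {
  # degenerate cases forced by the definition
  expect_equal(overlap_test(character(), c("A", "B"), 100)$p, 1)
  univ <- sprintf("G%03d", 1:50)
  full <- overlap_test(univ[1:10], univ, 50)
  expect_equal(full$n_overlap, 10)
  expect_equal(full$p, 1)

  # counts as printed for the disease-signature comparison, against the
  # direct tail-sum oracle
  got <- overlap_test(sprintf("D%04d", 1:738),
                      c(sprintf("D%04d", 1:13), sprintf("S%04d", 1:116)),
                      14347)
  expect_equal(got$n_overlap, 13)
  expect_equal(got$p, hyper_tail_oracle(13, 129, 738, 14347), tolerance = 1e-10)

  # random small configurations
  set.seed(14)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    m <- sample(1:15, 1)
    deg_n <- sample(1:15, 1)
    univ <- sprintf("U%03d", seq_len(N))
    detected <- sample(univ, m)
    deg <- sample(univ, deg_n)
    k <- length(intersect(deg, detected))
    expect_equal(overlap_test(deg, detected, N)$p,
                 hyper_tail_oracle(k, m, deg_n, N), tolerance = 1e-10)
  }
  expect_error(overlap_test(sprintf("U%03d", 1:30), "U001", 20), "universe")
})

test_that("resampled mean-FC test attains its bounds and detects planted shifts", {
  # signature = whole universe: every resample equals the observed mean
  fit <- fake_fit(rnorm(40, 0, 0.3))
  expect_equal(resampled_meanfc_test(fit, fit$gene, n_resamples = 99)$p, 1)

  # planted +1 log2 shift on 50 members, tight null: minimum attainable p
  set.seed(3)
  lfc <- rnorm(10000, 0, 0.1)
  lfc[1:50] <- lfc[1:50] + 1
  fit2 <- fake_fit(lfc)
  res <- resampled_meanfc_test(fit2, fit2$gene[1:50], "greater",
                               n_resamples = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
  expect_gte(res$p, 1 / (res$n_resamples + 1))

  # determinism given the seed
  res2 <- resampled_meanfc_test(fit2, fit2$gene[1:50], "greater",
                                n_resamples = 999, seed = 4)
  expect_identical(res, res2)
  expect_error(resampled_meanfc_test(fit2, character()), "No detected")
})

test_that("resampled p-values are approximately uniform under the null", {
  set.seed(51)
  fit <- fake_fit(rnorm(2000, 0, 0.5))
  ps <- vapply(1:500, function(i) {
    members <- sample(fit$gene, 40)
    resampled_meanfc_test(fit, members, "greater", n_resamples = 199,
                          seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("sign-majority test follows the exact binomial distribution", {
  up10 <- fake_fit(rep(0.5, 10))
  res <- sign_majority_test(up10, up10$gene)
  expect_equal(res$up_fraction, 1)
  expect_equal(res$p, 2 * 0.5^10, tolerance = 1e-12)

  mixed <- fake_fit(c(rep(0.5, 5), rep(-0.5, 5)))
  expect_equal(sign_majority_test(mixed, mixed$gene)$p, 1)

  # invariance to rescaling of fold-change magnitudes
  scaled <- fake_fit(c(rep(0.5, 5), rep(-0.5, 5)) * 3)
  expect_equal(sign_majority_test(scaled, scaled$gene)$up_fraction,
               sign_majority_test(mixed, mixed$gene)$up_fraction)

  flat <- fake_fit(rep(0, 4))
  expect_error(sign_majority_test(flat, flat$gene), "exactly 1")
})

test_that("rank enrichment matches exhaustive enumeration on small universes", {
  # members occupying exactly the |S| highest FCs: minimal attainable tail
  set.seed(6)
  lfc <- sort(rnorm(15), decreasing = TRUE)
  fit <- fake_fit(lfc)
  top5 <- fit$gene[1:5]
  got <- rank_enrichment_test(fit, top5, "top")
  expect_equal(got$p, 1 / choose(15, 5), tolerance = 1e-10)
  expect_equal(got$p, rank_enrichment_oracle(lfc, 1:5, "top"),
               tolerance = 1e-10)

  # all member subsets of a 12-gene universe, both tails
  lfc12 <- rnorm(12)
  fit12 <- fake_fit(lfc12)
  for (k in c(2, 4)) {
    subsets <- utils::combn(12, k)
    for (j in seq_len(ncol(subsets))[seq(1, ncol(subsets), by = 7)]) {
      idx <- subsets[, j]
      for (tail in c("top", "bottom")) {
        expect_equal(rank_enrichment_test(fit12, fit12$gene[idx], tail)$p,
                     rank_enrichment_oracle(lfc12, idx, tail),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(rank_enrichment_test(fit12, fit12$gene, "top"), "whole universe")
})

test_that("enrichment statistics are invariant to universe order and symbol case", {
  set.seed(18)
  fit <- fake_fit(rnorm(200, 0.1, 0.5))
  members <- fit$gene[21:60]
  perm <- sample(200)
  fit_perm <- fit[perm, ]
  members_lower <- tolower(members)

  expect_equal(sign_majority_test(fit, members),
               sign_majority_test(fit_perm, members_lower))
  expect_equal(rank_enrichment_test(fit, members, "top")$p,
               rank_enrichment_test(fit_perm, members_lower, "top")$p)
  expect_equal(overlap_test(fit$gene[1:30], members, 200),
               overlap_test(tolower(fit$gene[1:30]), members_lower, 200))
})

test_that("signature reports and marker panels assemble all statistics", {
  set.seed(25)
  lfc <- rnorm(500, 0, 0.3)
  lfc[1:40] <- lfc[1:40] + 1      # planted up block
  lfc[41:60] <- lfc[41:60] - 1    # planted down block
  fit <- fake_fit(lfc)
  fit$p <- 2 * pnorm(-abs(lfc / 0.3))
  fit$q <- adjust_bh(fit$p)
  class(fit) <- c("contrast_result", class(fit))
  degs <- call_degs(fit, "fdr", 0.10)

  rep_up <- signature_report(fit, degs, fit$gene[1:40],
                             alternative = "greater", n_resamples = 499)
  expect_equal(rep_up$n_detected, 40)
  expect_lt(rep_up$resample_p, 0.05)
  expect_lt(rep_up$overlap_p_up, 0.001)
  expect_gt(rep_up$sign_up_fraction, 0.5)
  expect_lt(rep_up$rank_p_top, 0.01)

  panels <- list(up_block = fit$gene[1:40],
                 neutral = fit$gene[101:140],
                 undetected = c("NOPE1", "NOPE2"))
  summ <- marker_panel_summary(fit, panels, n_resamples = 499)
  expect_equal(nrow(summ), 3)
  expect_lt(summ$resample_p[summ$panel == "up_block"], 0.05)
  expect_gt(summ$resample_p[summ$panel == "neutral"], 0.05)
  expect_true(is.na(summ$mean_fc[summ$panel == "undetected"]))

  # fully undetected signature: NA row, not an error
  rep_na <- signature_report(fit, degs, c("NOPE1", "NOPE2"))
  expect_equal(rep_na$n_detected, 0)
  expect_true(is.na(rep_na$resample_p))
})
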