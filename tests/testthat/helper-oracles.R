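# Brute-force oracles kept independent of the package implementation.

# Step-up BH by direct minimisation over suffixes of the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper hypergeometric tail P(X >= k) by direct summation of the pmf.
hyper_tail_oracle <- function(k, n_members, n_deg, universe) {
  if (k > min(n_members, n_deg)) return(0)
  xs <- k:min(n_members, n_deg)
  sum(exp(lchoose(n_members, xs) + lchoose(universe - n_members, n_deg - xs) -
            lchoose(universe, n_deg)))
}

# Two-sample pooled-variance t-test from the textbook formulas.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = na + nb - 2,
       p = 2 * pt(-abs(tstat), na + nb - 2))
}

# Simple linear regression slope and SE from the normal equations.
slope_oracle <- function(t, y) {
  n <- length(t)
  beta <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  alpha <- mean(y) - beta * mean(t)
  resid <- y - alpha - beta * t
  s2 <- sum(resid^2) / (n - 2)
  list(slope = beta, se = sqrt(s2 / sum((t - mean(t))^2)))
}

# Exact one-sided rank-sum enrichment p by enumeration of all same-size
# subsets of the universe: fraction of subsets whose member rank sum is at
# least (tail = "top") or at most ("bottom") as extreme as observed.
rank_enrichment_oracle <- function(fc, member_idx, tail = "top") {
  n <- length(fc)
  k <- length(member_idx)
  r <- rank(fc)
  obs <- sum(r[member_idx])
  subsets <- utils::combn(n, k)
  sums <- colSums(matrix(r[subsets], nrow = k))
  if (tail == "top") mean(sums >= obs) else mean(sums <= obs)
}

# Deterministic toy expression tibble: values follow a fixed arithmetic
# pattern so expectations are hand-checkable.
toy_expr <- function(n_genes = 6, samples = c("A_1", "A_2", "A_3",
                                              "B_1", "B_2", "B_3")) {
  vals <- outer(seq_len(n_genes), seq_along(samples),
                function(g, s) 5 + g * 0.5 + s * 0.1 + ((g * 7 + s * 3) %% 5) / 10)
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene = sprintf("G%06d", seq_len(n_genes))), out)
}

toy_samples <- function(samples = c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")) {
  tibble::tibble(sample = samples, group = sub("_.*", "", samples))
}

# Minimal stand-in for a fitted contrast: the enrichment and comparison
# functions only require gene/log2fc/fc columns.
fake_fit <- function(log2fc, genes = sprintf("G%06d", seq_along(log2fc)),
                     name = "toy contrast") {
  out <- tibble::tibble(gene = genes, log2fc = log2fc, fc = 2^log2fc)
  attr(out, "contrast") <- name
  out
}
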