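# Independent brute-force oracles used across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# U counts pairs (a_i > b_j); tie-free data assumed.
mw_exact_p_enum <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, `>`))
  u_obs <- u_stat(a, b)
  splits <- utils::combn(length(pooled), na)
  u_all <- apply(splits, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Hypergeometric upper-tail P(X >= k) summed from the choose() pmf directly.
hyper_tail_enum <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Classical pooled two-sample t statistic, written out longhand.
pooled_t_enum <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# tiny proteinGroups-style TSV fixture written on the fly
write_toy_protein_groups <- function(path) {
  d <- data.frame(
    `Protein IDs` = c("P1", "P2", "P3"),
    `Gene names` = c("g1", "g2", "g3"),
    `LFQ intensity c_1` = c(2^20, 0, 2^21),
    `LFQ intensity c_2` = c(2^20.1, 2^19, 2^21),
    `LFQ intensity l_1` = c(2^22, 2^19.5, 2^21),
    `LFQ intensity l_2` = c(2^22.2, 2^19.2, 2^21.1),
    Reverse = c("", "", "+"),
    `Potential contaminant` = c("", "", ""),
    `Only identified by site` = c("", "", ""),
    check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

toy_conditions <- c(c_1 = "control", c_2 = "control",
                    l_1 = "lesioned", l_2 = "lesioned")
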