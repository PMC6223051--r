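# Independent oracles used to freeze or cross-check expected values.
# These deliberately use brute force / textbook formulas, not package code.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# assignments of the pooled sample to group A.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  ranks <- rank(pooled)
  u_of <- function(idx) sum(ranks[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, u_of)
  mu <- n * length(b) / 2
  # two-sided: as or more extreme in |U - mean(U)|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Pooled-variance two-sample t statistic, textbook formula written out.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sa2 <- sum((a - mean(a))^2) / (na - 1)
  sb2 <- sum((b - mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * sa2 + (nb - 1) * sb2) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Unimodal template shared by registration tests: background 10, Gaussian
# bump of height 100 centered at position 50, sd 8.
gauss_template <- function(L = 100, center = 50, height = 100, sd = 8, bg = 10) {
  bg + height * exp(-((seq_len(L)) - center)^2 / (2 * sd^2))
}
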