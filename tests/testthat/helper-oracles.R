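# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, direct summation, closed form) kept separate
# from the code paths it checks.

# two-sided Fisher p by full enumeration of the hypergeometric support
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-sided binomial tail P(X >= x | n, p) by direct summation
binom_tail_oracle <- function(x, n, p) {
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# AUROC by brute-force pairwise concordance with 0.5 credit for ties
concordance_oracle <- function(prob, truth) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# digitized sphere mask: radius r (mm) at isotropic spacing sp (mm)
sphere_mask <- function(r, sp, margin = 3) {
  n <- ceiling(2 * r / sp) + 2 * margin
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  g <- expand.grid(x = ax, y = ax, z = ax)
  array(sqrt(g$x^2 + g$y^2 + g$z^2) <= r, c(n, n, n))
}

# labeled volume with standard-normal intensities on a sphere mask
sphere_volume <- function(r, sp, seed = 1, margin = 3) {
  set.seed(seed)
  mask <- sphere_mask(r, sp, margin)
  labeled_volume(array(rnorm(length(mask)), dim(mask)), mask, rep(sp, 3))
}
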