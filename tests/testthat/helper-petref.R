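# shared in-code fixtures for the test suite

# small handmade uptake matrix: 4 subjects x 3 regions
tiny_matrix <- function() {
  vals <- rbind(c(10, 20, 5),
                c(12, 18, 6),
                c(9, 25, 5),
                c(11, 21, 4))
  uptake_matrix(vals, sprintf("S%d", 1:4), c("A", "B", "C"),
                ages = c(30, 45, 60, 75), sexes = c(0L, 1L, 0L, 1L))
}

# random positive uptake matrix for property-style loops
random_matrix <- function(n_sub, n_reg, seed) {
  withr::with_seed(seed, {
    vals <- matrix(runif(n_sub * n_reg, 50, 150), n_sub, n_reg)
    uptake_matrix(vals, sprintf("S%02d", seq_len(n_sub)),
                  sprintf("R%02d", seq_len(n_reg)),
                  ages = runif(n_sub, 20, 90),
                  sexes = rep_len(c(0L, 1L), n_sub))
  })
}

# independent product-moment coefficient (no call into the package or cor())
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# independent per-voxel t via lm(): c'beta / sqrt(c' vcov c)
lm_t_oracle <- function(y, age, sex, contrast = c(0, -1, 0)) {
  fit <- stats::lm(y ~ age + sex)
  b <- stats::coef(fit)
  v <- stats::vcov(fit)
  as.numeric(contrast %*% b) / sqrt(as.numeric(t(contrast) %*% v %*% contrast))
}

toy_atlas_12 <- function(seed = 7) {
  build_toy_atlas(c(24, 24, 24), c(2, 2, 2), n_regions = 12L, seed = seed)
}
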