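# Shared fixtures and independent oracles for the test suite. Oracles are
# coded against different machinery (lm's QR solver, stats::approx) than
# the implementation's closed forms.

# random well-conditioned harmonized set
random_hset <- function(k = 8, seed = 1, beta = 0.2, intercept = 0) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE)
  se_x <- runif(k, 0.005, 0.02)
  se_y <- runif(k, 0.005, 0.03)
  by <- intercept + beta * bx + rnorm(k, 0, se_y)
  harmonized_set(bx, se_x, by, se_y, n_x = 20000, n_y = 20000)
}

# IVW oracle: weighted least squares through the origin via lm/QR
oracle_ivw <- function(h) {
  w <- 1 / h$se_y^2
  fit <- lm(by ~ 0 + bx, data = as.data.frame(h), weights = w)
  s <- summary(fit)
  sigma <- s$sigma                      # sqrt(Q/(k-1)) for this model
  se_lm <- s$coefficients[1, 2]         # dispersion-scaled
  se_fixed <- se_lm / sigma
  list(beta = unname(coef(fit)[1]), se_fixed = se_fixed,
       se_mre = se_fixed * sqrt(max(1, sigma^2)),
       q = sigma^2 * (nrow(h) - 1))
}

# Egger oracle: weighted regression with intercept via lm/QR, dispersion
# floored at 1, t inference with k-2 df
oracle_egger <- function(h) {
  flip <- ifelse(h$bx < 0, -1, 1)
  x <- h$bx * flip
  y <- h$by * flip
  w <- 1 / h$se_y^2
  fit <- lm(y ~ x, weights = w)
  s <- summary(fit)
  adj <- max(1, s$sigma) / s$sigma
  k <- nrow(h)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_int = s$coefficients[1, 2] * adj,
       se_slope = s$coefficients[2, 2] * adj,
       p_slope = 2 * pt(-abs(coef(fit)[2] / (s$coefficients[2, 2] * adj)),
                        df = k - 2))
}

# weighted-median oracle: interpolation of the weighted ECDF midpoints via
# stats::approx
oracle_wmedian <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# small well-formed summary-statistics data.frame
toy_stats_df <- function(k = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(k)),
    chrom = "1",
    pos = seq_len(k) * 100000L,
    effect_allele = rep_len(c("A", "C", "G"), k),
    other_allele = rep_len(c("G", "T", "A"), k),
    eaf = round(runif(k, 0.05, 0.95), 4),
    beta = round(rnorm(k, 0, 0.05), 6),
    se = round(runif(k, 0.005, 0.02), 6),
    pval = round(runif(k, 0.001, 0.9), 6),
    n = 10000,
    stringsAsFactors = FALSE)
}

write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
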