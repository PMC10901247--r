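test_that("Cochran's Q arithmetic and the explicit heterogeneity rule", {
  # identical ratios: Q = 0, homogeneous
  bx <- c(0.1, 0.2, 0.4)
  h0 <- harmonized_set(bx, 0.01, 0.3 * bx, c(0.01, 0.02, 0.01))
  q0 <- cochran_q(h0)
  expect_equal(q0$q, 0)
  expect_false(q0$heterogeneous)

  # hand fixture: ratios (0.1, 0.25), weights (25, 25), fixed IVW 0.175
  # -> Q = 25*(0.075^2) + 25*(0.075^2) = 0.28125
  h <- harmonized_set(c(1, 2), 0.01, c(0.1, 0.5), c(0.2, 0.4))
  qq <- cochran_q(h)
  expect_equal(qq$q, 0.28125)
  expect_equal(qq$df, 1)
  expect_equal(qq$p, pchisq(0.28125, 1, lower.tail = FALSE))

  # boundary: Q = k-1 exactly is NOT heterogeneous (strict inequality)
  hb <- harmonized_set(c(1, 1), 0.01, c(0, 1), c(1, 1))
  qb <- cochran_q(hb, beta_ivw = 1)     # Q = (0-1)^2 + 0 = 1 = df
  expect_equal(qb$q, 1)
  expect_false(qb$heterogeneous)
  expect_true(cochran_q(hb, beta_ivw = 1.1)$heterogeneous)  # Q just above df
  expect_error(cochran_q(harmonized_set(1, 0.1, 1, 0.1)), "at least 2")
})

test_that("Q is minimized at the fixed-effects IVW estimate", {
  h <- random_hset(k = 7, seed = 12)
  b_ivw <- ivw(h, "fixed")$beta
  grid <- b_ivw + seq(-0.2, 0.2, length.out = 81)
  qs <- vapply(grid, function(b) cochran_q(h, b)$q, numeric(1))
  expect_equal(grid[which.min(qs)], b_ivw, tolerance = 0.006)
  expect_true(all(qs >= cochran_q(h, b_ivw)$q - 1e-12))
})

null_hset <- function(k, seed, beta = 0.2) {
  set.seed(seed)
  bx_true <- runif(k, 0.08, 0.3)
  se_x <- runif(k, 0.005, 0.02)
  se_y <- runif(k, 0.005, 0.02)
  harmonized_set(bx_true + rnorm(k, 0, se_x), se_x,
                 beta * bx_true + rnorm(k, 0, se_y), se_y,
                 n_x = 20000, n_y = 20000)
}

test_that("MR-PRESSO global p is valid, reproducible, and sensitive", {
  h <- null_hset(8, seed = 21)
  g1 <- presso_global(h, n_sim = 300, seed = 99)
  g2 <- presso_global(h, n_sim = 300, seed = 99)
  expect_identical(g1, g2)                      # bit-exact given seed
  expect_gt(g1$global_p, 0)                     # +1 correction
  expect_lte(g1$global_p, 1)
  expect_error(presso_global(null_hset(3, 1), seed = 1), "at least 4")

  # planted outlier: displaced 10 outcome SEs
  ho <- null_hset(10, seed = 22)
  ho_out <- ho
  ho_out$by[3] <- ho_out$by[3] + 10 * ho_out$se_y[3]
  go <- presso_global(ho_out, n_sim = 500, seed = 7)
  expect_lte(go$global_p, 0.05)
  expect_equal(names(which.min(go$outlier_p)), "snp3")
  # removing the planted outlier strictly decreases the observed RSS
  g_clean <- presso_global(harmonized_subset(ho_out, -3), n_sim = 100, seed = 7)
  expect_lt(g_clean$rss_obs, go$rss_obs)
})

test_that("MR-PRESSO global p is calibrated under its own null", {
  # rejection rate at 0.05 over 200 seeded replicates within [0.01, 0.10]
  rej <- vapply(1:200, function(s) {
    h <- null_hset(10, seed = 4000 + s)
    presso_global(h, n_sim = 199, seed = s)$global_p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("the outlier loop removes planted outliers largest-first and stops", {
  h <- null_hset(12, seed = 30)
  clean <- presso_outlier_loop(h, n_sim = 400, seed = 11)
  expect_equal(nrow(clean$removed), 0)
  expect_equal(as.data.frame(clean$cleaned), as.data.frame(h))

  h2 <- h
  h2$by[2] <- h2$by[2] + 12 * h2$se_y[2]        # larger outlier
  h2$by[7] <- h2$by[7] + 7 * h2$se_y[7]         # smaller outlier
  res <- presso_outlier_loop(h2, n_sim = 400, seed = 11)
  expect_setequal(res$removed$snp_id, c("snp2", "snp7"))
  expect_equal(res$removed$snp_id[1], "snp2")   # larger residual first
  expect_gt(res$final_global_p, 0.05)
  expect_lte(nrow(res$removed), nrow(h2) - 3)   # termination bound
})

test_that("leave-one-out flags single-SNP-driven signals", {
  h <- null_hset(9, seed = 41, beta = 0.3)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo$table), 9)
  expect_true(all(abs(loo$table$beta - loo$full$beta) <= 2 * loo$table$se))
  expect_false(loo$driven_by_single_snp)

  # one precise SNP carries all the information (the rest are consistent
  # but uninformative), so the signal collapses without it
  hs <- harmonized_set(bx = rep(0.2, 5), se_x = 0.01,
                       by = rep(0.1, 5),
                       se_y = c(0.01, 1, 1, 1, 1))
  loo2 <- leave_one_out(hs)
  expect_true(loo2$full$pval < 0.05)
  expect_true(loo2$driven_by_single_snp)

  h3 <- null_hset(3, seed = 42)
  expect_equal(nrow(leave_one_out(h3)$table), 3)
  expect_error(leave_one_out(null_hset(2, 1)), "at least 3")
})

test_that("Steiger directionality: symmetry, dominance, closed form, scaling", {
  # identical association strength on both sides: p = 1, direction FALSE
  h_eq <- harmonized_set(0.1, 0.02, 0.1, 0.02, n_x = 10000, n_y = 10000)
  st_eq <- steiger_direction(h_eq)
  expect_equal(st_eq$p, 1)
  expect_false(st_eq$direction)

  # z = 10 on the exposure versus z = 1 on the outcome
  h_dom <- harmonized_set(0.2, 0.02, 0.02, 0.02, n_x = 10000, n_y = 10000)
  expect_true(steiger_direction(h_dom)$direction)

  # hand-computed Fisher-z p for a 2-SNP fixture
  h2 <- harmonized_set(c(0.15, 0.2), 0.02, c(0.03, 0.05), 0.025,
                       n_x = 15000, n_y = 30000)
  st <- steiger_direction(h2)
  r2x <- sum((h2$bx / h2$se_x)^2 / ((h2$bx / h2$se_x)^2 + 15000 - 2))
  r2y <- sum((h2$by / h2$se_y)^2 / ((h2$by / h2$se_y)^2 + 30000 - 2))
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (15000 - 3) + 1 / (30000 - 3))
  expect_equal(st$r2_exposure, r2x)
  expect_equal(st$p, 2 * pnorm(-abs(z)))

  # invariant to rescaling both traits' betas and SEs by one constant
  h3 <- harmonized_set(3 * h2$bx, 3 * h2$se_x, 3 * h2$by, 3 * h2$se_y,
                       n_x = 15000, n_y = 30000)
  expect_equal(steiger_direction(h3)$p, st$p)
  expect_error(steiger_direction(harmonized_set(1, 0.1, 1, 0.1, n_x = 3,
                                                n_y = 10)), "greater than 3")
})

test_that("sensitivity_report assembles the applicable components", {
  rep4 <- sensitivity_report(null_hset(4, seed = 50), n_sim = 100, seed = 1)
  expect_false(is.null(rep4$q))
  expect_false(is.null(rep4$presso))
  expect_false(is.null(rep4$loo))
  expect_length(rep4$f_stats, 4)

  rep2 <- sensitivity_report(null_hset(2, seed = 51), n_sim = 100, seed = 1)
  expect_false(is.null(rep2$q))
  expect_null(rep2$presso)
  expect_null(rep2$loo)
})
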