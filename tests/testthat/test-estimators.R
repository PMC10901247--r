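test_that("Wald ratio closed forms and the delta-method option", {
  h <- harmonized_set(bx = 0.1, se_x = 0.01, by = 0.05, se_y = 0.02)
  e <- wald_ratio(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  e2 <- wald_ratio(h, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))

  h0 <- harmonized_set(bx = 0.1, se_x = 0.01, by = 0, se_y = 0.02)
  e0 <- wald_ratio(h0)
  expect_equal(e0$beta, 0)
  expect_equal(e0$pval, 1)
  hbad <- harmonized_set(bx = 0, se_x = 0.01, by = 0.05, se_y = 0.02)
  expect_error(wald_ratio(hbad), "degenerate")
})

test_that("IVW degenerate and symmetric cases", {
  # all SNPs share the exact ratio: beta = ratio, Q = 0, mre se = fixed se
  bx <- c(0.1, 0.2, 0.3)
  h <- harmonized_set(bx, 0.01, 0.25 * bx, c(0.01, 0.02, 0.015))
  e <- ivw(h)
  expect_equal(e$beta, 0.25)
  expect_equal(e$extras$q, 0)
  expect_equal(e$se, ivw(h, mode = "fixed")$se)

  h2 <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(ivw(h2)$beta, 0.3)
  expect_error(ivw(harmonized_set(1, 0.01, 0.1, 0.02)), "at least 2")
})

test_that("IVW equals the WLS-through-origin oracle on random fixtures", {
  for (s in 1:25) {
    h <- random_hset(k = sample(3:15, 1), seed = s)
    o <- oracle_ivw(h)
    expect_equal(ivw(h, "fixed")$beta, o$beta, tolerance = 1e-10)
    expect_equal(ivw(h, "fixed")$se, o$se_fixed, tolerance = 1e-10)
    expect_equal(ivw(h, "mre")$se, o$se_mre, tolerance = 1e-10)
    expect_equal(ivw(h)$extras$q, o$q, tolerance = 1e-8)
  }
})

test_that("Egger recovers exact linear and affine fits", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- harmonized_set(bx, 0.01, 0.3 * bx, c(0.01, 0.012, 0.02, 0.01, 0.015))
  e <- egger(h)
  expect_equal(e$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$extras$egger_intercept, 0, tolerance = 1e-12)

  h2 <- harmonized_set(bx, 0.01, 0.02 + 0.3 * bx, 0.01)
  e2 <- egger(h2)
  expect_equal(e2$beta, 0.3, tolerance = 1e-12)
  expect_equal(e2$extras$egger_intercept, 0.02, tolerance = 1e-12)
  expect_error(egger(harmonized_set(c(1, 2), 0.1, c(1, 2), 0.1)), "at least 3")
})

test_that("Egger matches the weighted-normal-equations oracle", {
  for (s in 1:25) {
    h <- random_hset(k = sample(4:15, 1), seed = 100 + s, intercept = 0.01)
    e <- egger(h)
    o <- oracle_egger(h)
    expect_equal(e$beta, o$slope, tolerance = 1e-10)
    expect_equal(e$se, o$se_slope, tolerance = 1e-10)
    expect_equal(e$extras$egger_intercept, o$intercept, tolerance = 1e-10)
    expect_equal(e$extras$egger_intercept_se, o$se_int, tolerance = 1e-10)
    expect_equal(e$pval, unname(o$p_slope), tolerance = 1e-10)
  }
})

test_that("weighted median reduces to the plain median and majority weight", {
  # equal weights, odd k: the sample median of the ratios
  h <- harmonized_set(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.05)
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)

  # one SNP carrying more than half the weight wins
  h2 <- harmonized_set(c(1, 1, 1), 0.01, c(0.1, 0.5, 0.9),
                       c(0.3, 0.01, 0.3))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.5)
})

test_that("weighted median matches the interpolation oracle", {
  # hand-evaluated fixture: ratios .1...5, raw weights (1,1,3,3,2);
  # cumulative midpoints (.05,.15,.35,.65,.90) -> interpolate at .5 = 0.35
  h <- harmonized_set(bx = rep(1, 5), se_x = 0.01,
                      by = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      se_y = 1 / sqrt(c(1, 1, 3, 3, 2)))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.35)

  for (s in 1:25) {
    h <- random_hset(k = sample(3:12, 1), seed = 200 + s)
    got <- weighted_median(h, n_boot = 10, seed = 1)$beta
    expect_equal(got, oracle_wmedian(h$by / h$bx, h$bx^2 / h$se_y^2),
                 tolerance = 1e-12)
  }
})

test_that("all estimators are equivariant under outcome rescaling", {
  h <- random_hset(k = 9, seed = 77)
  c0 <- 3.7
  h2 <- harmonized_set(h$bx, h$se_x, c0 * h$by, c0 * h$se_y)
  expect_equal(ivw(h2)$beta, c0 * ivw(h)$beta)
  expect_equal(ivw(h2)$se, c0 * ivw(h)$se)
  expect_equal(egger(h2)$beta, c0 * egger(h)$beta)
  expect_equal(egger(h2)$se, c0 * egger(h)$se)
  wm1 <- weighted_median(h, n_boot = 200, seed = 5)
  wm2 <- weighted_median(h2, n_boot = 200, seed = 5)
  expect_equal(wm2$beta, c0 * wm1$beta)
  expect_equal(wm2$se, c0 * wm1$se, tolerance = 1e-8)
  h1 <- harmonized_set(h$bx[1], h$se_x[1], c0 * h$by[1], c0 * h$se_y[1])
  expect_equal(wald_ratio(h1)$beta,
               c0 * wald_ratio(harmonized_subset(h, 1))$beta)
})

test_that("run_all_methods dispatches on instrument count", {
  expect_named(run_all_methods(random_hset(1, seed = 1)), "wald")
  expect_named(run_all_methods(random_hset(2, seed = 2)), "ivw")
  est <- run_all_methods(random_hset(5, seed = 3), n_boot = 50, seed = 4)
  expect_named(est, c("ivw", "egger", "weighted_median"))
  expect_true(all(vapply(est, `[[`, 1L, "n_snp") == 5L))
  expect_error(run_all_methods(random_hset(0, seed = 1)))
})
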