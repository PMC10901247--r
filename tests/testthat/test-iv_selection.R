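make_stats <- function(df) summary_stats(df, trait_id = "exp")

test_that("significance filter matches a brute-force scan with stable ordering", {
  df <- toy_stats_df(3)
  df$pval <- c(1e-7, 1e-5, 0.2)
  ss <- make_stats(df)
  expect_equal(filter_significance(ss, 5e-6), df$snp_id[1])
  df$pval <- rep(0.5, 3)
  expect_length(filter_significance(make_stats(df), 5e-6), 0)

  big <- toy_stats_df(200, seed = 9)
  big$pval <- runif(200)^3
  ss <- make_stats(big)
  got <- filter_significance(ss, 0.01)
  keep <- big$snp_id[big$pval < 0.01]
  want <- keep[order(big$pval[match(keep, big$snp_id)], keep)]
  expect_identical(got, want)
})

test_that("MAF filter is symmetric in eaf and matches brute force", {
  df <- toy_stats_df(4)
  df$eaf <- c(0.005, 0.995, 0.3, 0.011)
  ss <- make_stats(df)
  expect_equal(filter_maf(ss, df$snp_id, 0.01), df$snp_id[3:4])

  big <- toy_stats_df(100, seed = 3)
  big$eaf <- runif(100, 0, 1)
  ss <- make_stats(big)
  got <- filter_maf(ss, big$snp_id, 0.05)
  want <- big$snp_id[pmin(big$eaf, 1 - big$eaf) >= 0.05]
  expect_identical(got, want)
  big$eaf[1] <- NA
  expect_error(filter_maf(make_stats(big), big$snp_id, 0.05,
                          on_missing = "error"), "missing eaf")
})

test_that("greedy clumping follows the hand-executed rule and the window", {
  df <- toy_stats_df(3)
  df$chrom <- "2"
  df$pos <- c(100000L, 101000L, 102000L)
  df$pval <- c(1e-9, 1e-8, 1e-7)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  dimnames(r) <- list(df$snp_id, df$snp_id)
  ld <- ld_matrix(r)
  cl <- ld_clump(make_stats(df), df$snp_id, ld, clump_r2 = 0.001,
                 clump_kb = 10000)
  expect_equal(cl$kept, df$snp_id[c(1, 3)])
  expect_equal(cl$clumped_by, c(rs002 = "rs001"))

  # high r-squared but outside the window: both retained
  far <- toy_stats_df(2)
  far$chrom <- "1"
  far$pos <- c(1L, 20000001L)           # 20,000 kb apart
  r2 <- matrix(c(1, 0.95, 0.95, 1), 2,
               dimnames = list(far$snp_id, far$snp_id))
  cl2 <- ld_clump(make_stats(far), far$snp_id, ld_matrix(r2),
                  clump_r2 = 0.001, clump_kb = 10000)
  expect_setequal(cl2$kept, far$snp_id)

  # r-squared of zero at close range: both retained
  near <- toy_stats_df(2)
  near$pos <- c(1000L, 2000L)
  cl3 <- ld_clump(make_stats(near), near$snp_id,
                  ld_matrix(diag(2) |> `dimnames<-`(list(near$snp_id, near$snp_id))),
                  clump_r2 = 0.001, clump_kb = 10000)
  expect_setequal(cl3$kept, near$snp_id)
})

test_that("F statistic closed forms", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_lt(f_statistic(0.0316, 0.01), 10)  # weak instrument, excluded at 10
  # r2 form agrees with the z2 form up to the t/z distinction at large n
  expect_equal(f_statistic(0.1, 0.01, n = 1e7, form = "r2"),
               f_statistic(0.1, 0.01), tolerance = 1e-4)
})

staged_fixture <- function() {
  df <- toy_stats_df(6, seed = 5)
  df$chrom <- "3"
  df$pos <- c(1e6, 1.001e6, 5e6, 9e6, 13e6, 17e6)
  df$eaf <- c(0.3, 0.25, 0.005, 0.4, 0.2, 0.35)
  df$beta <- c(0.10, 0.08, 0.09, 0.10, 0.002, 0.11)
  df$se <- c(0.01, 0.01, 0.01, 0.01, 0.01, 0.011)
  # rs001 index; rs002 clumped by rs001; rs003 fails MAF; rs005 weak F;
  # rs006 fails significance; rs004 kept
  df$pval <- c(1e-12, 1e-10, 1e-11, 1e-9, 1e-8, 0.5)
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- 0.9
  dimnames(r) <- list(df$snp_id, df$snp_id)
  list(stats = make_stats(df), ld = ld_matrix(r))
}

test_that("select_instruments audits every stage", {
  fx <- staged_fixture()
  iv <- select_instruments(fx$stats, fx$ld,
                           selection_config(p_threshold = 5e-6))
  aud <- setNames(iv$audit$disposition, iv$audit$snp_id)
  expect_setequal(iv$snp_ids, c("rs001", "rs004"))
  expect_equal(unname(aud["rs002"]), "dropped:clumped-by:rs001")
  expect_equal(unname(aud["rs003"]), "dropped:maf")
  expect_equal(unname(aud["rs005"]), "dropped:weakF")
  expect_equal(unname(aud["rs006"]), "dropped:pvalue")
  expect_equal(sort(unique(sub(":rs[0-9]+$", "", aud))),
               c("dropped:clumped-by", "dropped:maf", "dropped:pvalue",
                 "dropped:weakF", "kept"))

  # maximally permissive thresholds retain everything
  iv2 <- select_instruments(fx$stats, fx$ld,
                            selection_config(p_threshold = 1 - 1e-12,
                                             maf_min = 0, clump_r2 = 1,
                                             f_min = 0))
  expect_setequal(iv2$snp_ids, fx$stats$snp_id)

  # empty post-significance set is fine
  iv3 <- select_instruments(fx$stats, fx$ld,
                            selection_config(p_threshold = 1e-20))
  expect_length(iv3$snp_ids, 0)
  expect_true(all(iv3$audit$disposition == "dropped:pvalue"))
})

test_that("selection is invariant to row order and monotone in thresholds", {
  sim <- simulate_pair(sim_truth(seed = 11, n_instruments = 10,
                                 n_null_snps = 40))
  cfg <- selection_config()
  iv <- select_instruments(sim$exposure, sim$ld, cfg)
  shuf <- as.data.frame(sim$exposure)[sample(nrow(sim$exposure)), ]
  ss2 <- summary_stats(shuf, trait_id = "exp")
  iv2 <- select_instruments(ss2, sim$ld, cfg)
  expect_identical(iv$snp_ids, iv2$snp_ids)

  # loosening any threshold never shrinks the retained set
  loose <- select_instruments(sim$exposure, sim$ld,
                              selection_config(p_threshold = 1e-3,
                                               maf_min = 0, clump_r2 = 0.5,
                                               f_min = 0))
  expect_true(all(iv$snp_ids %in% loose$snp_ids))

  # retained set is pairwise r2 < clump_r2 within the window
  kept <- iv$snp_ids
  if (length(kept) >= 2) {
    pos <- sim$exposure$pos[match(kept, sim$exposure$snp_id)]
    chrom <- sim$exposure$chrom[match(kept, sim$exposure$snp_id)]
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i < j && chrom[i] == chrom[j] &&
          abs(pos[i] - pos[j]) <= cfg$clump_kb * 1000) {
        expect_lt(sim$ld$r[kept[i], kept[j]]^2, cfg$clump_r2)
      }
    }
  }
})
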