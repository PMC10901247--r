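# Sensitivity analyses: Cochran's Q heterogeneity (with the explicit
# Q > k-1 OR p < 0.05 rule), the simulation-based MR-PRESSO global and
# outlier tests with iterative removal, leave-one-out IVW, the Steiger
# causal-direction test, and per-SNP F statistics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum over SNPs of w_j (ratio_j - beta)^2 with ratio_j = by_j/bx_j
#' and w_j = (se_y_j/bx_j)^-2, referred to chi-square with k-1 degrees of
#' freedom. The heterogeneity verdict uses the rule: heterogeneous when
#' Q > k-1 (strictly) or p < 0.05.
#'
#' @param h a `harmonized_set` with at least two SNPs.
#' @param beta_ivw the causal estimate at which to evaluate Q (defaults to
#'   the fixed-effects IVW estimate, which minimizes Q).
#' @return List: `q`, `df`, `p`, `heterogeneous`.
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  k <- nrow(h)
  if (k < 2) stop("cochran_q needs at least 2 SNPs", call. = FALSE)
  if (is.null(beta_ivw)) beta_ivw <- ivw(h, mode = "fixed")$beta
  ratio <- h$by / h$bx
  w <- (h$se_y / h$bx)^-2
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- k - 1
  p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  list(q = q, df = df, p = p, heterogeneous = (q > df) || (p < 0.05))
}

# Leave-one-out fixed-effects IVW slopes via sufficient statistics:
# beta_{-j} = (S1 - w_j bx_j by_j) / (S2 - w_j bx_j^2), w = 1/se_y^2.
.loo_betas <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

# Observed per-SNP weighted squared residuals against leave-one-out fits,
# the building block of both MR-PRESSO trials.
.presso_resid2 <- function(bx, by, w) {
  b_loo <- .loo_betas(bx, by, w)
  w * (by - b_loo * bx)^2
}

#' MR-PRESSO global test
#'
#' The observed residual sum of squares RSS = sum_j w_j (by_j -
#' beta_{-j} bx_j)^2 (beta_{-j} the IVW slope excluding SNP j, w = 1/se_y^2)
#' is compared with its parametric null distribution: in each of `n_sim`
#' simulations bx* ~ N(bx, se_x) and by*_j ~ N(beta_{-j} bx_j, se_y_j), and
#' RSS* is recomputed the same way. The Monte-Carlo p-value carries the +1
#' correction, so it is always in (0, 1].
#'
#' @param h a `harmonized_set` with at least four SNPs.
#' @param n_sim simulated null datasets (default 1000).
#' @param seed RNG seed (required; results are bit-reproducible given
#'   `seed` and `n_sim`).
#' @return List: `rss_obs`, `global_p`, and `outlier_p` /
#'   `outlier_p_adjusted` (per-SNP Monte-Carlo tail probabilities of each
#'   observed weighted residual, Bonferroni-adjusted by k).
#' @export
presso_global <- function(h, n_sim = 1000, seed) {
  k <- nrow(h)
  if (k < 4) stop("presso_global needs at least 4 SNPs", call. = FALSE)
  w <- 1 / h$se_y^2
  b_loo <- .loo_betas(h$bx, h$by, w)
  resid2_obs <- w * (h$by - b_loo * h$bx)^2
  rss_obs <- sum(resid2_obs)
  set.seed(seed)
  bx_star <- matrix(stats::rnorm(k * n_sim, h$bx, h$se_x), nrow = k)
  by_star <- matrix(stats::rnorm(k * n_sim, b_loo * h$bx, h$se_y), nrow = k)
  wb <- w * bx_star
  s1 <- colSums(wb * by_star)
  s2 <- colSums(wb * bx_star)
  b_loo_star <- sweep(-wb * by_star, 2, s1, "+") /
    sweep(-wb * bx_star, 2, s2, "+")
  resid2_star <- w * (by_star - b_loo_star * bx_star)^2
  rss_star <- colSums(resid2_star)
  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + rowSums(resid2_star >= resid2_obs)) / (n_sim + 1)
  list(rss_obs = rss_obs, global_p = global_p,
       resid2_obs = stats::setNames(resid2_obs, h$snp_id),
       outlier_p = stats::setNames(outlier_p, h$snp_id),
       outlier_p_adjusted = stats::setNames(pmin(1, outlier_p * k), h$snp_id))
}

#' MR-PRESSO iterative outlier removal
#'
#' While the global test rejects at `alpha` and some SNP's
#' Bonferroni-adjusted outlier p is at or below `alpha`, the SNP with the
#' smallest outlier p is removed and both tests are recomputed. The loop
#' also stops when fewer than four SNPs would remain.
#'
#' @param h a `harmonized_set` with at least four SNPs.
#' @param n_sim,seed see [presso_global()]; each iteration uses a distinct
#'   seed derived from `seed`.
#' @param alpha rejection threshold (default 0.05).
#' @return List: `cleaned` (harmonized_set), `removed` (data.frame snp_id,
#'   outlier_p in removal order), `final_global_p`.
#' @export
presso_outlier_loop <- function(h, n_sim = 1000, alpha = 0.05, seed) {
  if (nrow(h) < 4) stop("presso_outlier_loop needs at least 4 SNPs",
                        call. = FALSE)
  removed <- data.frame(snp_id = character(0), outlier_p = numeric(0),
                        stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- presso_global(h, n_sim = n_sim, seed = seed + iter)
    if (g$global_p > alpha) break
    cand <- g$outlier_p_adjusted
    if (min(cand) > alpha) break
    # smallest Monte-Carlo p first; ties (often at the 1/(n_sim+1) floor)
    # broken by the largest observed weighted residual
    worst <- names(cand)[order(unname(cand), -unname(g$resid2_obs),
                               names(cand))][1]
    removed <- rbind(removed,
                     data.frame(snp_id = worst,
                                outlier_p = unname(g$outlier_p[worst]),
                                stringsAsFactors = FALSE))
    h <- harmonized_subset(h, h$snp_id != worst)
    if (nrow(h) < 4) {
      g <- list(global_p = NA_real_)
      break
    }
  }
  list(cleaned = h, removed = removed, final_global_p = g$global_p)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each SNP excluded in turn. The result
#' is flagged as driven by a single SNP when the full-set IVW p-value is
#' below 0.05 but some leave-one-out p-value is not.
#'
#' @param h a `harmonized_set` with at least three SNPs.
#' @param ivw_mode IVW variant for the subsets (default "mre").
#' @return List: `table` (data.frame snp_id, beta, se, pval with one row
#'   per left-out SNP), `full` (the full-set IVW estimate),
#'   `driven_by_single_snp` (logical).
#' @export
leave_one_out <- function(h, ivw_mode = "mre") {
  k <- nrow(h)
  if (k < 3) stop("leave_one_out needs at least 3 SNPs", call. = FALSE)
  full <- ivw(h, mode = ivw_mode)
  rows <- lapply(seq_len(k), function(j) {
    e <- ivw(harmonized_subset(h, -j), mode = ivw_mode)
    data.frame(snp_id = h$snp_id[j], beta = e$beta, se = e$se, pval = e$pval,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  flag <- full$pval < 0.05 && any(tab$pval >= 0.05)
  list(table = tab, full = full, driven_by_single_snp = flag)
}

#' Steiger causal-direction test
#'
#' Per-SNP variance explained uses the t-statistic form
#' r2 = t^2 / (t^2 + n - 2) (no allele frequencies needed; binary traits
#' are handled on the observed log-odds scale), summed over instruments
#' for each trait. The direction is supported when the instruments explain
#' more variance in the exposure than in the outcome; the p-value compares
#' r_x = sqrt(r2_x) and r_y = sqrt(r2_y) by the two-sample Fisher z test
#' z = (atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x-3) + 1/(n_y-3)), two-sided.
#'
#' @param h a `harmonized_set`.
#' @param n_x,n_y per-trait sample sizes; default is the mean of the
#'   per-SNP sample sizes recorded in `h`.
#' @return List: `r2_exposure`, `r2_outcome`, `direction` (TRUE when
#'   exposure -> outcome is supported), `p`.
#' @export
steiger_direction <- function(h, n_x = NULL, n_y = NULL) {
  if (nrow(h) < 1) stop("empty harmonized set", call. = FALSE)
  if (is.null(n_x)) n_x <- mean(h$n_x)
  if (is.null(n_y)) n_y <- mean(h$n_y)
  if (is.na(n_x) || is.na(n_y) || n_x <= 3 || n_y <= 3) {
    stop("steiger_direction needs sample sizes greater than 3", call. = FALSE)
  }
  r2_of <- function(b, se, n) {
    t2 <- (b / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2_x <- r2_of(h$bx, h$se_x, h$n_x)
  r2_y <- r2_of(h$by, h$se_y, h$n_y)
  r_x <- sqrt(min(r2_x, 1 - 1e-12))
  r_y <- sqrt(min(r2_y, 1 - 1e-12))
  z <- (atanh(r_x) - atanh(r_y)) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(r2_exposure = r2_x, r2_outcome = r2_y,
       direction = r2_x > r2_y, p = p)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Runs every applicable sensitivity analysis given the instrument count:
#' Cochran's Q (k >= 2), MR-PRESSO global (k >= 4), leave-one-out
#' (k >= 3), Steiger directionality and per-SNP F statistics (always).
#' Components that need more SNPs than available are NULL.
#'
#' @param h a `harmonized_set`.
#' @param n_sim MR-PRESSO simulations.
#' @param seed RNG seed for MR-PRESSO.
#' @return A `sensitivity_report` list with elements `q`, `presso`, `loo`,
#'   `steiger`, `f_stats`, `k`.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1) {
  k <- nrow(h)
  rep <- list(
    k = k,
    q = if (k >= 2) cochran_q(h) else NULL,
    presso = if (k >= 4) presso_global(h, n_sim = n_sim, seed = seed) else NULL,
    loo = if (k >= 3) leave_one_out(h) else NULL,
    steiger = tryCatch(steiger_direction(h), error = function(e) NULL),
    f_stats = stats::setNames(f_statistic(h$bx, h$se_x), h$snp_id)
  )
  class(rep) <- "sensitivity_report"
  rep
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report (k = %d)\n", x$k))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran Q = %.4g (df %d, p = %.4g), heterogeneous: %s\n",
                x$q$q, x$q$df, x$q$p, x$q$heterogeneous))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.4g\n", x$presso$global_p))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("  leave-one-out driven-by-single-SNP: %s\n",
                x$loo$driven_by_single_snp))
  }
  if (!is.null(x$steiger)) {
    cat(sprintf("  Steiger: r2_x = %.4g, r2_y = %.4g, direction %s (p = %.4g)\n",
                x$steiger$r2_exposure, x$steiger$r2_outcome,
                ifelse(x$steiger$direction, "supported", "not supported"),
                x$steiger$p))
  }
  cat(sprintf("  min F = %.4g\n", min(x$f_stats)))
  invisible(x)
}

#' Serialize a sensitivity report to JSON
#' @param rep a `sensitivity_report`.
#' @param path output path; the leave-one-out table additionally goes to
#'   `<path>.loo.tsv`.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(rep, path) {
  out <- rep
  class(out) <- NULL
  if (!is.null(out$loo)) {
    loo_tab <- out$loo$table
    loo_tab$beta <- .fmt_num(loo_tab$beta)
    loo_tab$se <- .fmt_num(loo_tab$se)
    loo_tab$pval <- .fmt_num(loo_tab$pval)
    utils::write.table(loo_tab, paste0(path, ".loo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$loo <- list(driven_by_single_snp = out$loo$driven_by_single_snp,
                    full = unclass(out$loo$full))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
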