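# Causal-effect estimators for two-sample MR on harmonized summary
# statistics: Wald ratio (single SNP), inverse-variance weighted (fixed or
# multiplicative-random-effects), MR-Egger regression, weighted median.

.mr_estimate <- function(method, beta, se, pval, n_snp, extras = list()) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 n_snp = n_snp, extras = extras), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.6g, se = %.6g, p = %.4g (k = %d)\n",
              x$method, x$beta, x$se, x$pval, x$n_snp))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' beta = by/bx with the first-order delta standard error se_y/|bx|;
#' `second_order` adds the exposure-uncertainty term
#' sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4).
#'
#' @param h a `harmonized_set` with exactly one SNP.
#' @param second_order use the second-order delta-method standard error.
#' @return An `mr_estimate` with method "wald".
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  if (nrow(h) != 1) stop("wald_ratio needs exactly one SNP", call. = FALSE)
  if (h$bx == 0) stop("degenerate instrument: bx = 0", call. = FALSE)
  beta <- h$by / h$bx
  se <- if (second_order) {
    sqrt(h$se_y^2 / h$bx^2 + h$by^2 * h$se_x^2 / h$bx^4)
  } else {
    h$se_y / abs(h$bx)
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("wald", beta, se, pval, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of the outcome on the exposure effects through
#' the origin with weights 1/se_y^2. The default multiplicative
#' random-effects ("mre") variant inflates the fixed-effects standard
#' error by sqrt(max(1, Q/(k-1))) where Q is Cochran's Q at the estimate.
#'
#' @param h a `harmonized_set` with at least two SNPs.
#' @param mode "mre" (default) or "fixed".
#' @return An `mr_estimate` with method "ivw"; `extras$q`, `extras$dispersion`.
#' @export
ivw <- function(h, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(h)
  if (k < 2) stop("ivw needs at least 2 SNPs; use wald_ratio", call. = FALSE)
  w <- 1 / h$se_y^2
  s_xx <- sum(w * h$bx^2)
  beta <- sum(w * h$bx * h$by) / s_xx
  se_fixed <- sqrt(1 / s_xx)
  q <- sum(w * (h$by - beta * h$bx)^2)
  dispersion <- max(1, q / (k - 1))
  se <- if (mode == "mre") se_fixed * sqrt(dispersion) else se_fixed
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("ivw", beta, se, pval, as.integer(k),
               extras = list(mode = mode, q = q, dispersion = dispersion,
                             se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights 1/se_y^2), after re-orienting every SNP so bx >= 0
#' (Egger is orientation-dependent; a fixed convention keeps results
#' deterministic). The slope estimates the causal effect; a nonzero
#' intercept indicates directional pleiotropy. Residual dispersion
#' Q/(k-2), floored at 1, scales both variances; inference uses t with
#' k-2 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least three SNPs.
#' @return An `mr_estimate` with method "egger"; extras hold
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `dispersion`.
#' @export
egger <- function(h) {
  k <- nrow(h)
  if (k < 3) stop("egger needs at least 3 SNPs", call. = FALSE)
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  x <- h$bx * flip
  y <- h$by * flip
  w <- 1 / h$se_y^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  q <- sum(w * resid^2)
  dispersion <- max(1, q / (k - 2))
  se_slope <- sqrt(dispersion * sw / det)
  se_int <- sqrt(dispersion * swxx / det)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = k - 2)
  .mr_estimate("egger", slope, se_slope, p_slope, as.integer(k),
               extras = list(egger_intercept = intercept,
                             egger_intercept_se = se_int,
                             egger_intercept_p = p_int,
                             q = q, dispersion = dispersion))
}

# weighted-median point estimate from ratio estimates and weights
.weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  k <- length(b)
  if (0.5 >= s[k]) return(b[k])
  j <- max(which(s < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimate
#'
#' Ratio estimates by/bx are ordered and the estimate is the linear
#' interpolation of the weighted empirical distribution at probability
#' one half, with inverse-variance weights bx^2/se_y^2 (first order; set
#' `include_se_x` for the full delta-method variance). The standard error
#' is the standard deviation of the estimate over `n_boot` parametric
#' bootstrap resamples bx* ~ N(bx, se_x), by* ~ N(by, se_y). Consistent
#' when instruments carrying at least half the weight are valid.
#'
#' @param h a `harmonized_set` with at least three SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @param include_se_x use full delta-method ratio variances for weights.
#' @return An `mr_estimate` with method "weighted_median"; extras hold
#'   `n_boot` and `seed`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed, include_se_x = FALSE) {
  k <- nrow(h)
  if (k < 3) stop("weighted_median needs at least 3 SNPs", call. = FALSE)
  wm_weights <- function(bx, by, se_x, se_y) {
    if (include_se_x) {
      1 / (se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
    } else {
      bx^2 / se_y^2
    }
  }
  beta <- .weighted_median_point(h$by / h$bx,
                                 wm_weights(h$bx, h$by, h$se_x, h$se_y))
  set.seed(seed)
  bx_star <- matrix(stats::rnorm(k * n_boot, h$bx, h$se_x), nrow = k)
  by_star <- matrix(stats::rnorm(k * n_boot, h$by, h$se_y), nrow = k)
  boots <- vapply(seq_len(n_boot), function(b) {
    .weighted_median_point(by_star[, b] / bx_star[, b],
                           wm_weights(bx_star[, b], by_star[, b],
                                      h$se_x, h$se_y))
  }, numeric(1))
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("weighted_median", beta, se, pval, as.integer(k),
               extras = list(n_boot = n_boot, seed = seed))
}

#' Run the method set appropriate to the instrument count
#'
#' One SNP: Wald ratio only. Two SNPs: IVW only. Three or more: IVW,
#' MR-Egger and weighted median.
#'
#' @param h a `harmonized_set`.
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param ivw_mode "mre" or "fixed".
#' @return List of `mr_estimate`, named by method.
#' @export
run_all_methods <- function(h, n_boot = 1000, seed = 1, ivw_mode = "mre") {
  k <- nrow(h)
  if (k == 0) stop("empty harmonized set", call. = FALSE)
  if (k == 1) return(list(wald = wald_ratio(h)))
  if (k == 2) return(list(ivw = ivw(h, mode = ivw_mode)))
  list(ivw = ivw(h, mode = ivw_mode),
       egger = egger(h),
       weighted_median = weighted_median(h, n_boot = n_boot, seed = seed))
}

#' Write a list of estimates as TSV (one row per method)
#'
#' Method-specific extras are serialized to a JSON sidecar
#' `<path>.extras.json`.
#'
#' @param estimates list of `mr_estimate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  df <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, beta = .fmt_num(e$beta),
               se = .fmt_num(e$se), pval = .fmt_num(e$pval),
               n_snp = e$n_snp, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  extras <- lapply(estimates, `[[`, "extras")
  names(extras) <- vapply(estimates, `[[`, character(1), "method")
  jsonlite::write_json(extras, paste0(path, ".extras.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
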