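# Synthetic GWAS summary statistics with known causal structure:
# instruments with L-shaped strengths, optional horizontal pleiotropy
# (directional or balanced, with an optional InSIDE violation), LD blocks,
# palindromic alleles, planted outliers, and closed-form standard errors
# on the standardized scale, se = 1/sqrt(2 n maf (1 - maf)).

#' Ground-truth parameters for a synthetic exposure-outcome pair
#'
#' Defaults describe a clean, well-powered two-sample world at microbiome
#' GWAS-like scale: 30 instruments among 300 SNPs, 20,000 samples per
#' trait, causal effect 0.1, LD blocks of five SNPs at within-block
#' correlation 0.3, and roughly one SNP in ten palindromic. Instrument
#' strength is parameterized by the expected association z-score, drawn
#' from z_min + Exp(mean z_mean - z_min): an L-shaped distribution (many
#' moderate, few strong instruments) as seen in real GWAS.
#'
#' @param beta_causal true causal effect of exposure on outcome.
#' @param n_instruments SNPs with a nonzero exposure effect.
#' @param n_null_snps background SNPs with zero exposure effect.
#' @param pleiotropy_frac fraction of instruments with direct outcome
#'   effects.
#' @param pleiotropy_mean,pleiotropy_sd distribution of the direct effects
#'   (mean != 0 gives directional pleiotropy, mean = 0 balanced).
#' @param inside_violation correlation in (-1, 1) between instrument
#'   strength and pleiotropic effect (0 = InSIDE satisfied).
#' @param n_x,n_y per-trait GWAS sample sizes.
#' @param z_min,z_mean instrument-strength distribution (expected
#'   association z-score): z ~ z_min + Exp(z_mean - z_min).
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_rho within-block allelic correlation.
#' @param palindrome_frac fraction of SNPs given A/T or C/G alleles.
#' @param n_outliers instruments whose outcome effect is displaced, to
#'   plant detectable pleiotropic outliers.
#' @param outlier_shift displacement in units of the outcome standard
#'   error.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(beta_causal = 0.1, n_instruments = 30,
                      n_null_snps = 270, pleiotropy_frac = 0,
                      pleiotropy_mean = 0, pleiotropy_sd = 0,
                      inside_violation = 0, n_x = 20000, n_y = 20000,
                      z_min = 6, z_mean = 15, ld_block_size = 5,
                      ld_rho = 0.3, palindrome_frac = 0.1,
                      n_outliers = 0, outlier_shift = 10, seed = 1) {
  truth <- list(beta_causal = beta_causal, n_instruments = n_instruments,
                n_null_snps = n_null_snps, pleiotropy_frac = pleiotropy_frac,
                pleiotropy_mean = pleiotropy_mean,
                pleiotropy_sd = pleiotropy_sd,
                inside_violation = inside_violation,
                n_x = n_x, n_y = n_y, z_min = z_min, z_mean = z_mean,
                ld_block_size = ld_block_size, ld_rho = ld_rho,
                palindrome_frac = palindrome_frac,
                n_outliers = n_outliers, outlier_shift = outlier_shift,
                seed = seed)
  stopifnot(n_instruments >= 1, n_null_snps >= 0,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            abs(inside_violation) < 1,
            n_x > 3, n_y > 3, z_mean > z_min, z_min >= 0,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            palindrome_frac >= 0, palindrome_frac <= 1,
            n_outliers >= 0, n_outliers <= n_instruments)
  class(truth) <- "sim_truth"
  truth
}

# correlated standard-normal noise within consecutive LD blocks
.block_noise <- function(m, block_size, rho) {
  z <- stats::rnorm(m)
  if (block_size <= 1 || rho == 0) return(z)
  block <- (seq_len(m) - 1) %/% block_size
  shared <- stats::rnorm(max(block) + 1)[block + 1]
  sqrt(rho) * shared + sqrt(1 - rho) * z
}

# within-block compound-symmetric correlation matrix over m SNPs
.block_ld <- function(m, block_size, rho, ids) {
  r <- diag(m)
  if (block_size > 1 && rho > 0) {
    block <- (seq_len(m) - 1) %/% block_size
    same <- outer(block, block, "==")
    r[same] <- rho
    diag(r) <- 1
  }
  dimnames(r) <- list(ids, ids)
  r
}

.draw_alleles <- function(m, palindrome_frac) {
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  non_pal <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                   c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  is_pal <- stats::runif(m) < palindrome_frac
  pick <- function(pool, count) pool[sample.int(nrow(pool), count, replace = TRUE), , drop = FALSE]
  out <- matrix("", m, 2)
  out[is_pal, ] <- pick(pal_pairs, sum(is_pal))
  out[!is_pal, ] <- pick(non_pal, sum(!is_pal))
  out
}

#' Simulate a synthetic exposure-outcome summary-statistics pair
#'
#' SNPs are laid out in consecutive LD blocks (one synthetic chromosome
#' label per block, so clumping interacts only within a block).
#' Each instrument occupies the first position of its own block with joint
#' exposure effect gamma_j = z_j * se_x_j; marginal true effects are
#' R gamma (R the block LD matrix), so LD partners of an instrument carry
#' attenuated marginal effects, as in real GWAS. Outcome joint effects are
#' beta_causal * gamma + alpha with alpha the pleiotropic direct effects.
#' Observed estimates are drawn b-hat ~ N(marginal truth, se) with noise
#' correlated within blocks at the LD correlation, se =
#' 1/sqrt(2 n maf (1-maf)) on the standardized scale, and p-values from
#' the two-sided normal tail. MAF ~ Uniform(0.05, 0.5). A share of the
#' outcome records is re-coded (allele swap or strand complement) so
#' harmonization is exercised; the LD matrix returned is the generator's
#' exact block matrix.
#'
#' @param truth a [sim_truth()].
#' @return List: `exposure` and `outcome` (`summary_stats`), `ld`
#'   (`ld_matrix`), `truth` (the input, augmented with
#'   `instrument_ids`, `outlier_ids`, `gamma`, `alpha`).
#' @export
simulate_pair <- function(truth = sim_truth()) {
  set.seed(truth$seed)
  n_iv <- truth$n_instruments
  bs <- truth$ld_block_size
  # one block per instrument, then enough blocks for the null SNPs
  n_blocks <- n_iv + ceiling(truth$n_null_snps / bs)
  m <- n_blocks * bs
  ids <- sprintf("rs%05d", seq_len(m))
  block <- (seq_len(m) - 1) %/% bs
  # one synthetic chromosome label per LD block: inter-block LD is zero by
  # construction, so clumping (same-chromosome window) stays exact at any
  # panel size without overflowing integer positions
  chrom <- as.character(block + 1)
  pos <- 1000000 + ((seq_len(m) - 1) %% bs) * 2000
  maf <- stats::runif(m, 0.05, 0.5)
  eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  alleles <- .draw_alleles(m, truth$palindrome_frac)
  se_x <- 1 / sqrt(2 * truth$n_x * maf * (1 - maf))
  se_y <- 1 / sqrt(2 * truth$n_y * maf * (1 - maf))

  iv_idx <- which(block < n_iv & (seq_len(m) - 1) %% bs == 0)
  z <- truth$z_min + stats::rexp(n_iv, rate = 1 / (truth$z_mean - truth$z_min))
  gamma <- numeric(m)
  gamma[iv_idx] <- z * se_x[iv_idx] * sample(c(-1, 1), n_iv, replace = TRUE)

  # pleiotropic direct effects on the outcome, optionally correlated with
  # instrument strength (InSIDE violation)
  alpha <- numeric(m)
  n_pleio <- round(truth$pleiotropy_frac * n_iv)
  if (n_pleio > 0) {
    pl_idx <- iv_idx[sample.int(n_iv, n_pleio)]
    eps <- stats::rnorm(n_pleio)
    if (truth$inside_violation != 0) {
      g_std <- scale(abs(gamma[pl_idx]))[, 1]
      if (anyNA(g_std)) g_std <- rep(0, n_pleio)
      eps <- truth$inside_violation * g_std +
        sqrt(1 - truth$inside_violation^2) * eps
    }
    # "directional" is defined relative to the exposure-increasing allele:
    # a constant shift applied on the raw coded alleles (whose signs are
    # arbitrary) would cancel under the bx >= 0 orientation that MR-Egger
    # and the intercept test use
    alpha[pl_idx] <- sign(gamma[pl_idx]) *
      (truth$pleiotropy_mean + truth$pleiotropy_sd * eps)
  }

  r <- .block_ld(m, bs, truth$ld_rho, ids)
  gamma_marg <- drop(r %*% gamma)
  Gamma_marg <- drop(r %*% (truth$beta_causal * gamma + alpha))

  outlier_ids <- character(0)
  if (truth$n_outliers > 0) {
    out_idx <- iv_idx[sample.int(n_iv, truth$n_outliers)]
    Gamma_marg[out_idx] <- Gamma_marg[out_idx] +
      truth$outlier_shift * se_y[out_idx]
    outlier_ids <- ids[out_idx]
  }

  bx_hat <- gamma_marg + se_x * .block_noise(m, bs, truth$ld_rho)
  by_hat <- Gamma_marg + se_y * .block_noise(m, bs, truth$ld_rho)

  mk_stats <- function(bhat, se, n, trait_id, allele_mat, eafv) {
    df <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                     effect_allele = allele_mat[, 1],
                     other_allele = allele_mat[, 2],
                     eaf = eafv, beta = bhat, se = se,
                     # floor against underflow so p stays in (0, 1]
                     pval = pmax(2 * stats::pnorm(-abs(bhat / se)), 1e-300),
                     n = n, stringsAsFactors = FALSE)
    summary_stats(df, trait_id = trait_id, trait_type = "quantitative",
                  validate = FALSE)
  }
  exposure <- mk_stats(bx_hat, se_x, truth$n_x, "sim_exposure", alleles, eaf)

  # re-code a share of the outcome records: swap effect/other alleles
  # (negating beta) or report the complementary strand
  o_alleles <- alleles
  o_beta <- by_hat
  o_eaf <- eaf
  swap <- stats::runif(m) < 0.3
  o_alleles[swap, ] <- o_alleles[swap, 2:1]
  o_beta[swap] <- -o_beta[swap]
  o_eaf[swap] <- 1 - o_eaf[swap]
  flip <- stats::runif(m) < 0.3 & !is_palindromic(alleles[, 1], alleles[, 2])
  o_alleles[flip, ] <- matrix(.COMPLEMENT[o_alleles[flip, ]], ncol = 2)
  outcome <- mk_stats(o_beta, se_y, truth$n_y, "sim_outcome", o_alleles, o_eaf)

  truth$instrument_ids <- ids[iv_idx]
  truth$outlier_ids <- outlier_ids
  truth$gamma <- stats::setNames(gamma_marg, ids)
  truth$alpha <- stats::setNames(alpha, ids)
  positions <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome,
       ld = ld_matrix(r, positions = positions), truth = truth)
}

#' Simulate a bidirectional world where trait A causes trait B
#'
#' Both traits share one SNP panel. Trait A's instruments affect A
#' directly and B only through the causal path (beta from
#' `truth_forward`); trait B's own instruments (a disjoint SNP set,
#' described by `truth_reverse`) affect B directly and A only through
#' B's effect on A (`truth_reverse$beta_causal`, zero by default). The
#' Steiger-relevant variance-explained asymmetry therefore emerges from
#' the generative model.
#'
#' @param truth_forward [sim_truth()] for the A -> B direction.
#' @param truth_reverse [sim_truth()] for B's own instruments and the
#'   B -> A effect (default zero: no reverse causation).
#' @return List: `exposure` (trait A `summary_stats`), `outcome` (trait
#'   B), `ld`, `truth` (with `instrument_ids_a`, `instrument_ids_b`).
#' @export
simulate_bidirectional_world <- function(truth_forward = sim_truth(),
                                         truth_reverse = sim_truth(
                                           beta_causal = 0,
                                           seed = truth_forward$seed + 1)) {
  set.seed(truth_forward$seed)
  bs <- truth_forward$ld_block_size
  stopifnot(bs == truth_reverse$ld_block_size,
            truth_forward$ld_rho == truth_reverse$ld_rho)
  n_a <- truth_forward$n_instruments
  n_b <- truth_reverse$n_instruments
  n_blocks <- n_a + n_b +
    ceiling((truth_forward$n_null_snps + truth_reverse$n_null_snps) / bs)
  m <- n_blocks * bs
  ids <- sprintf("rs%05d", seq_len(m))
  block <- (seq_len(m) - 1) %/% bs
  # one synthetic chromosome label per LD block: inter-block LD is zero by
  # construction, so clumping (same-chromosome window) stays exact at any
  # panel size without overflowing integer positions
  chrom <- as.character(block + 1)
  pos <- 1000000 + ((seq_len(m) - 1) %% bs) * 2000
  maf <- stats::runif(m, 0.05, 0.5)
  eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  alleles <- .draw_alleles(m, truth_forward$palindrome_frac)
  se_a <- 1 / sqrt(2 * truth_forward$n_x * maf * (1 - maf))
  se_b <- 1 / sqrt(2 * truth_reverse$n_x * maf * (1 - maf))

  lead <- (seq_len(m) - 1) %% bs == 0
  idx_a <- which(block < n_a & lead)
  idx_b <- which(block >= n_a & block < n_a + n_b & lead)
  z_a <- truth_forward$z_min +
    stats::rexp(n_a, 1 / (truth_forward$z_mean - truth_forward$z_min))
  z_b <- truth_reverse$z_min +
    stats::rexp(n_b, 1 / (truth_reverse$z_mean - truth_reverse$z_min))
  delta_a <- numeric(m)  # direct effects on A
  delta_b <- numeric(m)  # direct effects on B
  delta_a[idx_a] <- z_a * se_a[idx_a] * sample(c(-1, 1), n_a, replace = TRUE)
  delta_b[idx_b] <- z_b * se_b[idx_b] * sample(c(-1, 1), n_b, replace = TRUE)

  b_ab <- truth_forward$beta_causal  # A -> B
  b_ba <- truth_reverse$beta_causal  # B -> A
  # joint per-SNP effects under simultaneous linear structural equations
  # (A = delta_a + b_ba B, B = delta_b + b_ab A)
  det <- 1 - b_ab * b_ba
  eff_a <- (delta_a + b_ba * delta_b) / det
  eff_b <- (delta_b + b_ab * delta_a) / det

  r <- .block_ld(m, bs, truth_forward$ld_rho, ids)
  a_marg <- drop(r %*% eff_a)
  b_marg <- drop(r %*% eff_b)
  a_hat <- a_marg + se_a * .block_noise(m, bs, truth_forward$ld_rho)
  b_hat <- b_marg + se_b * .block_noise(m, bs, truth_forward$ld_rho)

  mk <- function(bhat, se, n, trait_id) {
    df <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                     effect_allele = alleles[, 1], other_allele = alleles[, 2],
                     eaf = eaf, beta = bhat, se = se,
                     pval = pmax(2 * stats::pnorm(-abs(bhat / se)), 1e-300),
                     n = n, stringsAsFactors = FALSE)
    summary_stats(df, trait_id = trait_id, trait_type = "quantitative",
                  validate = FALSE)
  }
  truth <- truth_forward
  truth$instrument_ids_a <- ids[idx_a]
  truth$instrument_ids_b <- ids[idx_b]
  truth$reverse <- truth_reverse
  positions <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  list(exposure = mk(a_hat, se_a, truth_forward$n_x, "trait_A"),
       outcome = mk(b_hat, se_b, truth_reverse$n_x, "trait_B"),
       ld = ld_matrix(r, positions = positions), truth = truth)
}
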