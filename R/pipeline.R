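# Orchestration of the bidirectional screen: per-pair analysis
# (select -> harmonize -> MR-PRESSO clean -> estimate -> sensitivity ->
# verdict), the many-exposures screen against primary and verification
# outcome datasets, and the reverse direction with roles swapped.

#' Study-level configuration
#'
#' @param direction "forward", "reverse" or "both".
#' @param selection a [selection_config()].
#' @param seed master RNG seed; per-stage seeds derive from it.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulations.
#' @param ivw_mode "mre" or "fixed".
#' @param palindrome_policy "drop" or "infer" (see [harmonize()]).
#' @param presso_clean run the MR-PRESSO outlier loop before estimation
#'   when at least four instruments survive harmonization.
#' @param alpha significance level used by the verdict rule and the
#'   MR-PRESSO loop.
#' @return A `study_config` list.
#' @export
study_config <- function(direction = c("both", "forward", "reverse"),
                         selection = selection_config(), seed = 1,
                         n_boot = 1000, n_sim = 1000, ivw_mode = "mre",
                         palindrome_policy = "drop", presso_clean = TRUE,
                         alpha = 0.05) {
  direction <- match.arg(direction)
  structure(list(direction = direction, selection = selection, seed = seed,
                 n_boot = n_boot, n_sim = n_sim, ivw_mode = ivw_mode,
                 palindrome_policy = palindrome_policy,
                 presso_clean = presso_clean, alpha = alpha),
            class = "study_config")
}

.skipped_pair <- function(exposure_id, outcome_id, reason, n_initial = 0L) {
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 n_snp_initial = n_initial, n_snp_final = 0L,
                 estimates = list(), sensitivity = NULL,
                 presso_removed = character(0),
                 verdict = sprintf("skipped(%s)", reason)),
            class = "pair_result")
}

# The verdict formalizes the usual robustness narrative: a causal call
# needs a significant primary estimate (IVW, or Wald for one SNP), no
# heterogeneity by the Q rule, no directional pleiotropy by the Egger
# intercept (k >= 3), and no single SNP driving the signal.
.pair_verdict <- function(estimates, sens, alpha) {
  primary <- if (!is.null(estimates$ivw)) estimates$ivw else estimates$wald
  if (is.null(primary)) return("null")
  if (primary$pval >= alpha) return("null")
  if (!is.null(sens$q) && sens$q$heterogeneous) return("null")
  if (!is.null(estimates$egger) &&
      estimates$egger$extras$egger_intercept_p < alpha) return("null")
  if (!is.null(sens$loo) && sens$loo$driven_by_single_snp) return("null")
  if (primary$beta > 0) "causal-positive" else "causal-negative"
}

#' Analyse one exposure-outcome pair end to end
#'
#' Selects instruments from the exposure, harmonizes them against the
#' outcome, optionally removes MR-PRESSO outliers, runs the method set
#' appropriate to the instrument count, the sensitivity suite, and a
#' verdict. Pairs with no usable instruments yield a skipped result, not
#' an error.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param ld an `ld_matrix` for the exposure's candidates (NULL skips
#'   clumping).
#' @param config a [study_config()].
#' @return A `pair_result` list: exposure_id, outcome_id, n_snp_initial,
#'   n_snp_final, estimates, sensitivity, presso_removed, verdict.
#' @export
run_pair <- function(exposure, outcome, ld = NULL, config = study_config()) {
  exposure_id <- attr(exposure, "trait_id")
  outcome_id <- attr(outcome, "trait_id")
  sel <- select_instruments(exposure, ld, config$selection)
  if (length(sel$snp_ids) == 0) {
    return(.skipped_pair(exposure_id, outcome_id, "no-instruments"))
  }
  h <- tryCatch(
    harmonize(exposure, outcome, sel, policy = config$palindrome_policy),
    mr_empty_harmonization = function(e) NULL)
  if (is.null(h)) {
    return(.skipped_pair(exposure_id, outcome_id, "no-overlap",
                         length(sel$snp_ids)))
  }
  n_initial <- nrow(h)
  removed <- character(0)
  if (config$presso_clean && nrow(h) >= 4) {
    cleaned <- presso_outlier_loop(h, n_sim = config$n_sim,
                                   alpha = config$alpha,
                                   seed = config$seed)
    removed <- cleaned$removed$snp_id
    h <- cleaned$cleaned
  }
  estimates <- tryCatch(
    run_all_methods(h, n_boot = config$n_boot, seed = config$seed + 1,
                    ivw_mode = config$ivw_mode),
    error = function(e) NULL)
  if (is.null(estimates)) {
    return(.skipped_pair(exposure_id, outcome_id, "degenerate",
                         n_initial))
  }
  sens <- sensitivity_report(h, n_sim = config$n_sim, seed = config$seed + 2)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 n_snp_initial = n_initial, n_snp_final = nrow(h),
                 estimates = estimates, sensitivity = sens,
                 presso_removed = removed,
                 verdict = .pair_verdict(estimates, sens, config$alpha)),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("pair_result: %s -> %s [%s], %d -> %d SNPs\n",
              x$exposure_id, x$outcome_id, x$verdict,
              x$n_snp_initial, x$n_snp_final))
  for (e in x$estimates) print(e)
  invisible(x)
}

.primary_estimate <- function(pr) {
  if (!is.null(pr$estimates$ivw)) pr$estimates$ivw else pr$estimates$wald
}

#' Screen many exposures against one or more outcome datasets
#'
#' One `pair_result` per exposure per outcome dataset. The summary table
#' is sorted by the primary (IVW or Wald) p-value; no multiple-testing
#' correction is applied to the headline p, but Bonferroni and
#' Benjamini-Hochberg adjusted columns are reported alongside.
#'
#' @param exposures named list of `summary_stats` (for example, one per
#'   taxon).
#' @param outcomes named list of `summary_stats`; names are the dataset
#'   roles (for example primary, verification).
#' @param ld an `ld_matrix` (NULL skips clumping).
#' @param config a [study_config()].
#' @return List: `results` (pair_result list) and `summary` (data.frame).
#' @export
run_screen <- function(exposures, outcomes, ld = NULL,
                       config = study_config()) {
  if (length(exposures) == 0) stop("empty exposure list", call. = FALSE)
  if (length(outcomes) == 0) stop("empty outcome list", call. = FALSE)
  if (inherits(outcomes, "summary_stats")) outcomes <- list(primary = outcomes)
  if (is.null(names(outcomes))) {
    names(outcomes) <- paste0("outcome", seq_along(outcomes))
  }
  results <- list()
  for (role in names(outcomes)) {
    for (i in seq_along(exposures)) {
      pr <- tryCatch(
        run_pair(exposures[[i]], outcomes[[role]], ld, config),
        error = function(e) {
          .skipped_pair(attr(exposures[[i]], "trait_id"),
                        attr(outcomes[[role]], "trait_id"),
                        paste0("error:", conditionMessage(e)))
        })
      pr$outcome_role <- role
      results[[length(results) + 1]] <- pr
    }
  }
  rows <- lapply(results, function(pr) {
    est <- .primary_estimate(pr)
    data.frame(exposure_id = pr$exposure_id, outcome_id = pr$outcome_id,
               outcome_role = pr$outcome_role,
               n_snp = pr$n_snp_final,
               method = if (is.null(est)) NA_character_ else est$method,
               beta = if (is.null(est)) NA_real_ else est$beta,
               se = if (is.null(est)) NA_real_ else est$se,
               pval = if (is.null(est)) NA_real_ else est$pval,
               verdict = pr$verdict, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$p_bonferroni <- stats::p.adjust(summary$pval, method = "bonferroni")
  summary$p_bh <- stats::p.adjust(summary$pval, method = "BH")
  ord <- order(summary$pval, summary$exposure_id, summary$outcome_id)
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  list(results = results[ord], summary = summary)
}

#' Run the bidirectional screen
#'
#' Forward: each exposure against each outcome dataset. Reverse: each
#' outcome dataset, with its own instruments selected at the same
#' thresholds, against each exposure trait as outcome.
#'
#' @param exposures named list of `summary_stats`.
#' @param outcomes named list of `summary_stats` by role.
#' @param ld shared `ld_matrix` (NULL skips clumping).
#' @param config a [study_config()]; `direction` selects which screens run.
#' @return List with `forward` and `reverse` screen results (NULL when a
#'   direction is not requested).
#' @export
run_bidirectional <- function(exposures, outcomes, ld = NULL,
                              config = study_config()) {
  forward <- reverse <- NULL
  if (config$direction %in% c("both", "forward")) {
    forward <- run_screen(exposures, outcomes, ld, config)
  }
  if (config$direction %in% c("both", "reverse")) {
    reverse <- run_screen(outcomes, exposures, ld, config)
  }
  list(forward = forward, reverse = reverse)
}

#' Write a screen summary table as TSV
#' @param screen result of [run_screen()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_summary <- function(screen, path) {
  out <- screen$summary
  for (col in c("beta", "se", "pval", "p_bonferroni", "p_bh")) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a pair result to JSON
#' @param pr a `pair_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_result <- function(pr, path) {
  out <- unclass(pr)
  out$estimates <- lapply(out$estimates, unclass)
  if (!is.null(out$sensitivity)) {
    s <- unclass(out$sensitivity)
    if (!is.null(s$loo)) s$loo$full <- unclass(s$loo$full)
    out$sensitivity <- s
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
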