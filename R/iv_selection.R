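# Instrument selection: genome-wide significance, MAF floor, greedy LD
# clumping and weak-instrument (F) exclusion, with a complete per-candidate
# audit trail.

#' Instrument-selection configuration
#'
#' Defaults follow the conventional relaxed microbiome-GWAS setting:
#' p < 5e-6 (5e-8 is the strict genome-wide alternative), MAF >= 0.01,
#' clumping at r-squared < 0.001 within a 10,000 kb window, and exclusion
#' of instruments with F < 10.
#'
#' @param p_threshold significance cutoff on the exposure p-value.
#' @param maf_min minor-allele-frequency floor.
#' @param clump_r2 LD r-squared cutoff: a candidate is clumped when its
#'   r-squared with a retained index SNP is >= this value.
#' @param clump_kb clumping window, kilobases either side of the index SNP.
#' @param f_min weak-instrument floor on the per-SNP F statistic.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-6, maf_min = 0.01,
                             clump_r2 = 0.001, clump_kb = 10000, f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            maf_min >= 0, maf_min < 0.5,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, maf_min = maf_min,
                 clump_r2 = clump_r2, clump_kb = clump_kb, f_min = f_min),
            class = "selection_config")
}

#' SNPs passing the exposure significance threshold
#'
#' @param stats exposure `summary_stats`.
#' @param p_threshold keep SNPs with pval strictly below this.
#' @return Character vector of snp ids in ascending p order, ties broken
#'   lexicographically by id. May be empty.
#' @export
filter_significance <- function(stats, p_threshold) {
  if (nrow(stats) == 0) stop("empty summary statistics", call. = FALSE)
  keep <- stats$pval < p_threshold
  ids <- stats$snp_id[keep]
  ids[order(stats$pval[keep], ids)]
}

#' Minor-allele-frequency filter
#'
#' MAF is min(eaf, 1 - eaf); SNPs below `maf_min` are removed.
#'
#' @param stats `summary_stats` holding the candidates.
#' @param ids candidate snp ids.
#' @param maf_min MAF floor.
#' @param on_missing what to do with a candidate whose eaf is missing:
#'   "drop" (default) or "error".
#' @return Filtered id vector, original order preserved.
#' @export
filter_maf <- function(stats, ids, maf_min, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  idx <- match(ids, stats$snp_id)
  if (anyNA(idx)) stop("unknown snp id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  eaf <- stats$eaf[idx]
  if (anyNA(eaf) && on_missing == "error") {
    stop("missing eaf for: ", paste(ids[is.na(eaf)], collapse = ", "),
         call. = FALSE)
  }
  maf <- pmin(eaf, 1 - eaf)
  ids[!is.na(maf) & maf >= maf_min]
}

#' Greedy LD clumping
#'
#' Repeatedly retains the not-yet-clumped candidate with the smallest
#' exposure p-value (ties broken lexicographically by id) and marks as
#' clumped every remaining candidate on the same chromosome within
#' `clump_kb` kilobases whose r-squared with it is >= `clump_r2`.
#'
#' @param stats exposure `summary_stats` (supplies p-values and positions).
#' @param ids candidate snp ids.
#' @param ld an `ld_matrix` covering the candidates.
#' @param clump_r2,clump_kb see [selection_config()].
#' @param on_missing candidates absent from the LD matrix: "drop" with a
#'   warning (default) or "error".
#' @return List with `kept` (ids in selection order) and `clumped_by`
#'   (named character: clumped id -> index id that removed it) and
#'   `no_ld` (ids dropped for absence from the LD matrix).
#' @export
ld_clump <- function(stats, ids, ld, clump_r2 = 0.001, clump_kb = 10000,
                     on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  idx <- match(ids, stats$snp_id)
  if (anyNA(idx)) stop("unknown snp id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  in_ld <- ids %in% ld$snp_ids
  no_ld <- ids[!in_ld]
  if (length(no_ld) > 0) {
    if (on_missing == "error") {
      stop("candidate(s) absent from LD matrix: ",
           paste(no_ld, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(no_ld), " candidate(s) absent from LD matrix")
  }
  ids <- ids[in_ld]
  if (length(ids) == 0) return(list(kept = character(0),
                                    clumped_by = character(0), no_ld = no_ld))
  idx <- match(ids, stats$snp_id)
  pval <- stats$pval[idx]
  chrom <- stats$chrom[idx]
  pos <- stats$pos[idx]
  ord <- order(pval, ids)
  ids <- ids[ord]; chrom <- chrom[ord]; pos <- pos[ord]
  r2 <- ld$r[ids, ids, drop = FALSE]^2
  window_bp <- clump_kb * 1000
  state <- rep("open", length(ids))
  clumped_by <- character(0)
  for (i in seq_along(ids)) {
    if (state[i] != "open") next
    state[i] <- "kept"
    if (i == length(ids)) break
    j <- which(state == "open")
    hit <- j[chrom[j] == chrom[i] &
               abs(pos[j] - pos[i]) <= window_bp &
               r2[i, j] >= clump_r2]
    if (length(hit) > 0) {
      state[hit] <- "clumped"
      clumped_by[ids[hit]] <- ids[i]
    }
  }
  list(kept = ids[state == "kept"], clumped_by = clumped_by, no_ld = no_ld)
}

#' Per-SNP instrument-strength F statistic
#'
#' The squared-z form F = (beta/se)^2, standard for summary data (it needs
#' no allele frequency). An R^2-based alternative
#' F = R2 (n - 2) / (1 - R2) with R2 = t^2/(t^2 + n - 2) is available;
#' the two coincide up to the t-vs-z distinction.
#'
#' @param beta,se per-allele effect and its standard error (vectorized).
#' @param n sample size, only used by `form = "r2"`.
#' @param form "z2" (default) or "r2".
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se, n = NULL, form = c("z2", "r2")) {
  form <- match.arg(form)
  stopifnot(all(se > 0))
  t2 <- (beta / se)^2
  if (form == "z2") return(t2)
  if (is.null(n)) stop("form = 'r2' needs sample size n", call. = FALSE)
  r2 <- t2 / (t2 + n - 2)
  r2 * (n - 2) / (1 - r2)
}

#' Select instrumental variables from exposure summary statistics
#'
#' Applies, in order: significance threshold, MAF floor, greedy LD clumping
#' and weak-instrument F exclusion. Every SNP in `stats` receives exactly
#' one disposition in the audit table.
#'
#' @param stats exposure `summary_stats`.
#' @param ld an `ld_matrix`; NULL skips the clumping stage.
#' @param config a [selection_config()].
#' @return An `instrument_set`: list with `snp_ids` (retained, in clumping
#'   selection order) and `audit` (data.frame: snp_id, disposition,
#'   statistic).
#' @export
select_instruments <- function(stats, ld, config = selection_config()) {
  disposition <- stats::setNames(rep(NA_character_, nrow(stats)), stats$snp_id)
  statistic <- stats::setNames(rep(NA_real_, nrow(stats)), stats$snp_id)

  sig <- filter_significance(stats, config$p_threshold)
  out <- setdiff(stats$snp_id, sig)
  disposition[out] <- "dropped:pvalue"
  statistic[out] <- stats$pval[match(out, stats$snp_id)]

  maf_ok <- filter_maf(stats, sig, config$maf_min, on_missing = "drop")
  out <- setdiff(sig, maf_ok)
  eaf <- stats$eaf[match(out, stats$snp_id)]
  disposition[out] <- "dropped:maf"
  statistic[out] <- pmin(eaf, 1 - eaf)

  if (is.null(ld)) {
    cl <- list(kept = maf_ok, clumped_by = character(0), no_ld = character(0))
  } else {
    cl <- ld_clump(stats, maf_ok, ld, config$clump_r2, config$clump_kb)
  }
  disposition[cl$no_ld] <- "dropped:no-ld"
  if (length(cl$clumped_by) > 0) {
    disposition[names(cl$clumped_by)] <- paste0("dropped:clumped-by:",
                                                unname(cl$clumped_by))
    pair_r2 <- ld$r[cbind(names(cl$clumped_by), unname(cl$clumped_by))]^2
    statistic[names(cl$clumped_by)] <- pair_r2
  }

  idx <- match(cl$kept, stats$snp_id)
  fval <- f_statistic(stats$beta[idx], stats$se[idx])
  weak <- cl$kept[fval < config$f_min]
  disposition[weak] <- "dropped:weakF"
  statistic[cl$kept] <- fval
  kept <- cl$kept[fval >= config$f_min]
  disposition[kept] <- "kept"

  audit <- data.frame(snp_id = stats$snp_id,
                      disposition = unname(disposition[stats$snp_id]),
                      statistic = unname(statistic[stats$snp_id]),
                      stringsAsFactors = FALSE)
  structure(list(snp_ids = kept, audit = audit), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %d retained of %d candidates\n",
              length(x$snp_ids), nrow(x$audit)))
  tab <- table(sub(":.*$", "", x$audit$disposition))
  print(tab)
  invisible(x)
}

#' Write an instrument-set audit table as TSV
#' @param iv an `instrument_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instrument_set <- function(iv, path) {
  out <- iv$audit
  out$statistic <- .fmt_num(out$statistic)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
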