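# Allele harmonization of exposure and outcome summary statistics on a
# shared instrument list: same-allele matches, effect/other swaps, strand
# complements, and palindromic (A/T, C/G) SNP handling.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' Palindromic SNPs ({A,T} or {C,G}) read the same on both strands, so
#' strand cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-base alleles (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure and outcome effects to a common effect allele
#'
#' For each instrument present in both traits the outcome record is aligned
#' to the exposure's effect allele: identical coding is kept as-is; swapped
#' alleles negate the outcome beta and reflect its frequency; a strand
#' complement is complemented and re-matched; palindromic SNPs are dropped
#' under the default policy (or frequency-aligned under `policy = "infer"`,
#' dropping those with ambiguous frequency); anything else is dropped as
#' incompatible.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param instruments character vector of instrument snp ids (or an
#'   `instrument_set`).
#' @param policy palindromic-SNP policy: "drop" (default, drop all) or
#'   "infer" (align by allele frequency, dropping SNPs whose exposure or
#'   outcome frequency falls in `ambiguity_band`).
#' @param ambiguity_band inclusive eaf band treated as unresolvable under
#'   `policy = "infer"`.
#' @param strict_position also require chromosome and position agreement.
#' @return A `harmonized_set`: data.frame with columns snp_id,
#'   effect_allele, other_allele, bx, se_x, by, se_y, eaf_x, eaf_y, n_x,
#'   n_y and attributes `dropped` (named character, id -> reason),
#'   `exposure_id`, `outcome_id`, `exposure_type`, `outcome_type`.
#'   Zero retained SNPs raise an error of class `mr_empty_harmonization`.
#' @export
harmonize <- function(exposure, outcome, instruments,
                      policy = c("drop", "infer"),
                      ambiguity_band = c(0.42, 0.58),
                      strict_position = FALSE) {
  policy <- match.arg(policy)
  if (inherits(instruments, "instrument_set")) instruments <- instruments$snp_ids
  if (length(instruments) == 0) {
    stop("harmonize: empty instrument list", call. = FALSE)
  }
  ix <- match(instruments, exposure$snp_id)
  if (anyNA(ix)) stop("instrument(s) absent from exposure: ",
                      paste(instruments[is.na(ix)], collapse = ", "),
                      call. = FALSE)
  iy <- match(instruments, outcome$snp_id)

  dropped <- character(0)
  rows <- vector("list", length(instruments))
  for (i in seq_along(instruments)) {
    id <- instruments[i]
    ex <- exposure[ix[i], ]
    if (is.na(iy[i])) { dropped[id] <- "missing-in-outcome"; next }
    oy <- outcome[iy[i], ]
    if (strict_position && (ex$chrom != oy$chrom || ex$pos != oy$pos)) {
      dropped[id] <- "incompatible-alleles"; next
    }
    ea_x <- ex$effect_allele; oa_x <- ex$other_allele
    ea_y <- oy$effect_allele; oa_y <- oy$other_allele
    by <- oy$beta; eaf_y <- oy$eaf

    pal <- is_palindromic(ea_x, oa_x)
    if (pal && policy == "drop") { dropped[id] <- "palindromic"; next }

    aligned <- FALSE
    if (identical(ea_y, ea_x) && identical(oa_y, oa_x)) {
      aligned <- TRUE
    } else if (identical(ea_y, oa_x) && identical(oa_y, ea_x)) {
      by <- -by
      if (!is.na(eaf_y)) eaf_y <- 1 - eaf_y
      aligned <- TRUE
    } else if (!pal) {
      # strand flip: complement the outcome alleles and re-match
      cea <- unname(.COMPLEMENT[ea_y]); coa <- unname(.COMPLEMENT[oa_y])
      if (identical(cea, ea_x) && identical(coa, oa_x)) {
        aligned <- TRUE
      } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
        by <- -by
        if (!is.na(eaf_y)) eaf_y <- 1 - eaf_y
        aligned <- TRUE
      }
    }
    if (!aligned) { dropped[id] <- "incompatible-alleles"; next }

    if (pal && policy == "infer") {
      # alleles alone cannot resolve strand; use frequency concordance
      amb <- function(f) is.na(f) || (f >= ambiguity_band[1] && f <= ambiguity_band[2])
      if (amb(ex$eaf) || amb(eaf_y)) { dropped[id] <- "palindromic"; next }
      if ((ex$eaf - 0.5) * (eaf_y - 0.5) < 0) {
        by <- -by
        eaf_y <- 1 - eaf_y
      }
    }

    rows[[i]] <- data.frame(snp_id = id, effect_allele = ea_x,
                            other_allele = oa_x,
                            bx = ex$beta, se_x = ex$se,
                            by = by, se_y = oy$se,
                            eaf_x = ex$eaf, eaf_y = eaf_y,
                            n_x = ex$n, n_y = oy$n,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop(structure(class = c("mr_empty_harmonization", "error", "condition"),
                   list(message = "no SNPs retained after harmonization",
                        call = sys.call(-1))))
  }
  h <- do.call(rbind, rows)
  rownames(h) <- NULL
  structure(h, dropped = dropped,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            exposure_type = attr(exposure, "trait_type"),
            outcome_type = attr(outcome, "trait_type"),
            class = c("harmonized_set", "data.frame"))
}

#' Assemble a harmonized set directly from aligned vectors
#'
#' Mainly for testing and simulation studies where effects are already on a
#' common allele.
#'
#' @param bx,se_x exposure effects and standard errors.
#' @param by,se_y outcome effects and standard errors.
#' @param snp_id optional ids (default snp1..snpk).
#' @param n_x,n_y per-SNP sample sizes.
#' @param eaf_x,eaf_y optional effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(bx, se_x, by, se_y, snp_id = NULL,
                           n_x = NA_real_, n_y = NA_real_,
                           eaf_x = NA_real_, eaf_y = NA_real_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(bx)
  stopifnot(length(by) == k)
  se_x <- rep_len(se_x, k)
  se_y <- rep_len(se_y, k)
  stopifnot(all(se_x > 0), all(se_y > 0))
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(k))
  h <- data.frame(snp_id = snp_id, effect_allele = "A", other_allele = "G",
                  bx = bx, se_x = se_x, by = by, se_y = se_y,
                  eaf_x = rep_len(eaf_x, k), eaf_y = rep_len(eaf_y, k),
                  n_x = rep_len(n_x, k), n_y = rep_len(n_y, k),
                  stringsAsFactors = FALSE)
  structure(h, dropped = character(0),
            exposure_id = exposure_id, outcome_id = outcome_id,
            exposure_type = "quantitative", outcome_type = "quantitative",
            class = c("harmonized_set", "data.frame"))
}

#' Subset a harmonized set by row, keeping attributes
#' @param h a `harmonized_set`.
#' @param keep logical or integer row index.
#' @return A `harmonized_set`.
#' @export
harmonized_subset <- function(h, keep) {
  out <- as.data.frame(h)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out),
                       attributes(h)[c("dropped", "exposure_id", "outcome_id",
                                       "exposure_type", "outcome_type")])
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %s -> %s, %d SNPs (%d dropped)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x),
              length(attr(x, "dropped"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a harmonized set (and its dropped-SNP sidecar) as TSV
#' @param h a `harmonized_set`.
#' @param path output path; the sidecar goes to `<path>.dropped.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path) {
  df <- as.data.frame(h)
  for (col in c("bx", "se_x", "by", "se_y", "eaf_x", "eaf_y", "n_x", "n_y")) {
    df[[col]] <- .fmt_num(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  drp <- attr(h, "dropped")
  side <- data.frame(snp_id = names(drp), reason = unname(drp),
                     stringsAsFactors = FALSE)
  utils::write.table(side, paste0(path, ".dropped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a harmonized set written by [write_harmonized_set()]
#' @param path path to the TSV.
#' @return A `harmonized_set`.
#' @export
read_harmonized_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  side_path <- paste0(path, ".dropped.tsv")
  dropped <- character(0)
  if (file.exists(side_path)) {
    side <- utils::read.table(side_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (nrow(side) > 0) dropped <- stats::setNames(side$reason, side$snp_id)
  }
  structure(df, dropped = dropped, exposure_id = "exposure",
            outcome_id = "outcome", exposure_type = "quantitative",
            outcome_type = "quantitative",
            class = c("harmonized_set", "data.frame"))
}
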