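# Reading, validating and writing GWAS summary statistics and LD matrices.
# Formats are tab-separated text; floats are written with 10 significant
# digits so round-trips through the canonical form are value-identical.

.BASES <- c("A", "C", "G", "T")

#' Canonical summary-statistics column map
#'
#' Maps the internal field names to the column headers expected in a file.
#' The canonical dialect uses the internal names themselves.
#'
#' @return Named character vector, internal name -> file column name.
#' @export
canonical_column_map <- function() {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  stats::setNames(cols, cols)
}

#' IEU OpenGWAS-style column map
#' @return Named character vector, internal name -> file column name.
#' @export
ieu_column_map <- function() {
  c(snp_id = "SNP", chrom = "chr", pos = "position",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "samplesize")
}

#' GWAS-SSF-style column map
#' @return Named character vector, internal name -> file column name.
#' @export
gwas_ssf_column_map <- function() {
  c(snp_id = "rsid", chrom = "chromosome", pos = "base_pair_location",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
    pval = "p_value", n = "n")
}

#' Construct a summary-statistics object
#'
#' @param df data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n.
#' @param trait_id character scalar identifying the trait.
#' @param trait_type "binary" or "quantitative".
#' @param validate drop invalid rows and record a tally (default TRUE).
#' @param strict additionally require pval to agree with the two-sided
#'   normal tail of beta/se to within 1e-3.
#' @return Object of class `summary_stats`: a data.frame with attributes
#'   `trait_id`, `trait_type` and `dropped` (named integer tally of
#'   validation-drop reasons).
#' @export
summary_stats <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                          validate = TRUE, strict = FALSE) {
  trait_type <- match.arg(trait_type)
  need <- names(canonical_column_map())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("summary_stats: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need, drop = FALSE]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) df[[col]] <- as.numeric(df[[col]])

  dropped <- integer(0)
  if (validate) {
    reason <- rep(NA_character_, nrow(df))
    flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
    flag(!(df$effect_allele %in% .BASES) | !(df$other_allele %in% .BASES),
         "allele not a single base")
    flag(df$effect_allele == df$other_allele, "identical alleles")
    flag(is.na(df$beta) | is.na(df$se) | df$se <= 0, "se not positive")
    flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf out of range")
    flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval out of range")
    flag(is.na(df$n) | df$n <= 0, "n not positive")
    flag(is.na(df$pos) | df$pos < 1, "position not positive")
    if (strict) {
      expect <- 2 * stats::pnorm(-abs(df$beta / df$se))
      flag(!is.na(expect) & abs(df$pval - expect) > 1e-3,
           "pval inconsistent with beta/se")
    }
    keep <- is.na(reason)
    if (any(!keep)) dropped <- table(reason[!keep])
    dropped <- stats::setNames(as.integer(dropped), names(dropped))
    df <- df[keep, , drop = FALSE]
  }
  if (anyDuplicated(df$snp_id)) {
    stop("summary_stats: duplicate snp_id: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, trait_type = trait_type,
            dropped = dropped, class = c("summary_stats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Rows failing validation (bad alleles, non-positive se, eaf outside
#' \[0,1\], p outside (0,1\], ...) are dropped and tallied in the `dropped`
#' attribute of the result; duplicate SNP ids are an error.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named character vector mapping internal field names to
#'   file column headers; see [canonical_column_map()], [ieu_column_map()],
#'   [gwas_ssf_column_map()].
#' @param trait_id,trait_type trait metadata recorded on the result.
#' @param strict see [summary_stats()].
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, column_map = canonical_column_map(),
                               trait_id = basename(path),
                               trait_type = c("quantitative", "binary"),
                               strict = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path, call. = FALSE)
  miss <- setdiff(unname(column_map), names(raw))
  if (length(miss) > 0) {
    stop("missing mapped column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[, unname(column_map), drop = FALSE], names(column_map))
  df$eaf[df$eaf %in% c("NA", "", ".")] <- NA
  summary_stats(df, trait_id = trait_id, trait_type = trait_type,
                strict = strict)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = 10, format = "g")
  }, character(1))
  out
}

#' Write summary statistics in canonical tab-separated form
#'
#' Floats are written with 10 significant digits; reading the result back
#' reproduces the same values (round-trip identity).
#'
#' @param stats a `summary_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  df <- as.data.frame(stats)
  out <- data.frame(snp_id = df$snp_id, chrom = df$chrom, pos = df$pos,
                    effect_allele = df$effect_allele,
                    other_allele = df$other_allele,
                    eaf = .fmt_num(df$eaf), beta = .fmt_num(df$beta),
                    se = .fmt_num(df$se), pval = .fmt_num(df$pval),
                    n = .fmt_num(df$n), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  drp <- attr(x, "dropped")
  if (length(drp) > 0) {
    cat("dropped rows:", paste(sprintf("%s=%d", names(drp), drp), collapse = ", "),
        "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Construct an LD matrix object
#'
#' @param r square numeric matrix of pairwise allelic correlations with
#'   snp ids as dimnames.
#' @param positions optional data.frame with columns snp_id, chrom, pos.
#' @param tol asymmetry tolerance.
#' @return Object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, positions = NULL, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  ids <- rownames(r)
  if (is.null(ids) || is.null(colnames(r)) || !identical(ids, colnames(r))) {
    stop("LD matrix needs identical snp-id row and column names", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate snp ids in LD matrix", call. = FALSE)
  if (any(abs(r) > 1 + tol)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  if (max(abs(r - t(r))) > tol) stop("LD matrix asymmetric beyond tolerance", call. = FALSE)
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1", call. = FALSE)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(snp_ids = ids, r = r, positions = positions),
            class = "ld_matrix")
}

#' Read an LD correlation matrix from tab-separated text
#'
#' Expected layout: a header row `snp_id<TAB>id1<TAB>id2...` followed by one
#' row per SNP whose first field is the SNP id.
#'
#' @param path path to the file.
#' @param positions optional positions data.frame (snp_id, chrom, pos);
#'   clumping can also take positions from the exposure summary statistics.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, positions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           comment.char = "", quote = "")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop("LD matrix header ids do not match row ids", call. = FALSE)
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  ld_matrix(m, positions = positions)
}

#' Write an LD matrix in the format [read_ld_matrix()] reads
#' @param ld an `ld_matrix` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  m <- ld$r
  body <- apply(m, 1, function(row) paste(.fmt_num(row), collapse = "\t"))
  lines <- c(paste(c("snp_id", ld$snp_ids), collapse = "\t"),
             paste(ld$snp_ids, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d SNPs\n", length(x$snp_ids)))
  invisible(x)
}
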