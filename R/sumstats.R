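#' Default column mapping for summary-statistics files
#'
#' Maps the fields a summary-statistics table must provide onto the column
#' names used in the file. Only `chrom`, `pos`, `a1` and `a2` are mandatory;
#' a file must carry either a Z column or a p-value column together with an
#' effect-direction column.
#'
#' @param chrom,pos,a1,a2,z,p,direction Column names in the input file.
#' @return A named character vector usable as the `column_map` argument of
#'   [read_sumstats()].
#' @export
#' @examples
#' sumstat_cols(chrom = "chromosome", pos = "bp", z = "zscore")
sumstat_cols <- function(chrom = "CHR", pos = "POS", a1 = "A1", a2 = "A2",
                         z = "Z", p = "P", direction = "DIR") {
  c(chrom = chrom, pos = pos, a1 = a1, a2 = a2, z = z, p = p,
    direction = direction)
}

#' Convert a two-sided p-value to a signed Z-score
#'
#' Returns `direction * qnorm(1 - p/2)`, the signed standard-normal statistic
#' whose two-sided tail probability is `p`. p-values below the smallest
#' representable double (~1e-300) are clamped with a warning.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param direction Effect signs, +1 or -1 (recycled).
#' @return Signed Z-scores.
#' @seealso [z_to_p()] for the inverse.
#' @export
#' @examples
#' p_to_z(0.05, -1)
p_to_z <- function(p, direction = 1) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("`p` must be in (0, 1]", call. = FALSE)
  }
  if (!all(direction %in% c(-1, 1))) {
    stop("`direction` must be +1 or -1", call. = FALSE)
  }
  tiny <- 1e-300
  if (any(p < tiny)) {
    warning(sprintf("%d p-value(s) below %g clamped", sum(p < tiny), tiny))
    p <- pmax(p, tiny)
  }
  direction * qnorm(p / 2, lower.tail = FALSE)
}

#' Convert a signed Z-score to a two-sided p-value
#'
#' Returns `2 * pnorm(-|z|)`, computed on the log scale internally so that
#' extreme statistics map to positive subnormal p-values rather than zero.
#'
#' @param z Finite signed Z-scores.
#' @return Two-sided p-values in (0, 1].
#' @export
#' @examples
#' z_to_p(1.96)
z_to_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("`z` must be finite", call. = FALSE)
  }
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-delimited file with a header row into a tibble of per-variant
#' association records. Records are sorted by (chromosome, position);
#' duplicate (chromosome, position, allele pair) entries are an error. Rows
#' whose Z-score is missing are filled from the p-value and direction columns
#' via [p_to_z()] when those are present; rows where neither statistic can be
#' parsed are dropped with a message reporting the count.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param column_map Named vector from [sumstat_cols()] locating the fields
#'   in the file.
#' @return A tibble with columns `chrom` (with any "chr" prefix stripped),
#'   `pos`, `a1` (effect allele), `a2`, `z` and `p`.
#' @export
read_sumstats <- function(path, column_map = sumstat_cols()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA", "."), comment = "#")
  mandatory <- c("chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(column_map[mandatory], names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("mandatory column(s) missing from %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  has_z <- column_map[["z"]] %in% names(raw)
  has_p <- column_map[["p"]] %in% names(raw) &&
    column_map[["direction"]] %in% names(raw)
  if (!has_z && !has_p) {
    stop("file must have a Z column, or P and direction columns", call. = FALSE)
  }

  out <- tibble::tibble(
    chrom = norm_chrom(raw[[column_map[["chrom"]]]]),
    pos = as.integer(raw[[column_map[["pos"]]]]),
    a1 = toupper(raw[[column_map[["a1"]]]]),
    a2 = toupper(raw[[column_map[["a2"]]]]),
    z = if (has_z) suppressWarnings(as.numeric(raw[[column_map[["z"]]]])) else NA_real_,
    p = if (column_map[["p"]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[column_map[["p"]]]]))
    } else NA_real_,
    dir = if (column_map[["direction"]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[column_map[["direction"]]]]))
    } else NA_real_
  )

  bad_row <- is.na(out$pos) | out$pos < 1 | !(out$a1 %in% VALID_ALLELES) |
    !(out$a2 %in% VALID_ALLELES) | out$a1 == out$a2
  if (any(bad_row)) {
    message(sprintf("read_sumstats: skipped %d row(s) with invalid position or alleles",
                    sum(bad_row)))
    out <- out[!bad_row, ]
  }

  # Fill z from (p, direction) where absent, then reconcile when both given.
  fill <- is.na(out$z) & !is.na(out$p) & out$dir %in% c(-1, 1)
  if (any(fill)) out$z[fill] <- p_to_z(out$p[fill], out$dir[fill])
  both <- !is.na(out$z) & !is.na(out$p) & out$p > 0 & out$p <= 1
  if (any(both)) {
    p_implied <- z_to_p(out$z[both])
    off <- abs(p_implied - out$p[both]) > 1e-3 * pmax(out$p[both], 1e-300)
    if (any(off)) {
      warning(sprintf("%d record(s) have inconsistent z and p; trusting z", sum(off)))
    }
  }
  unusable <- is.na(out$z)
  if (any(unusable)) {
    message(sprintf("read_sumstats: skipped %d row(s) with no parseable statistic",
                    sum(unusable)))
    out <- out[!unusable, ]
  }
  out$p <- z_to_p(out$z)
  out$dir <- NULL

  resorted <- dplyr::arrange(out, .data$chrom, .data$pos)
  if (!identical(resorted$pos, out$pos) || !identical(resorted$chrom, out$chrom)) {
    warning("input not sorted by (chrom, pos); records re-sorted")
    out <- resorted
  }

  # the allele pair is unordered for duplicate detection
  key <- paste(out$chrom, out$pos, pmin(out$a1, out$a2), pmax(out$a1, out$a2))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- out[which(dup)[1], ]
    stop(sprintf("duplicate record at %s:%d (%s/%s)", first$chrom, first$pos,
                 first$a1, first$a2), call. = FALSE)
  }
  out
}

#' Write imputation results to a tab-delimited file
#'
#' Writes one row per variant with columns `chrom`, `pos`, `a1`, `a2`, `z`,
#' `p`, `r2pred` and `status` (`typed`, `imputed` or `skipped`). Variants
#' whose imputation quality fell below the reporting threshold have status
#' `skipped` and empty `z`/`p` fields. Z-scores are written with 6
#' significant digits and round-trip through [read_sumstats()].
#'
#' @param results Results tibble as produced by [impute_sumstats()] (or
#'   [tidy()] of its return value).
#' @param path Output file path.
#' @param header Optional character vector of `#`-prefixed comment lines to
#'   prepend (run parameters, panel checksum).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, header = NULL) {
  if (inherits(results, "zimpute_result")) results <- results$results
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  needed <- c("chrom", "pos", "a1", "a2", "z", "r2pred", "status")
  if (!all(needed %in% names(results))) {
    stop(sprintf("`results` must have columns %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = results$chrom,
    pos = results$pos,
    a1 = results$a1,
    a2 = results$a2,
    z = ifelse(results$status == "skipped", NA_real_,
               signif(results$z, 6)),
    p = ifelse(results$status == "skipped", NA_real_,
               signif(z_to_p(ifelse(is.na(results$z), 0, results$z)), 6)),
    r2pred = signif(results$r2pred, 6),
    status = results$status
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
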