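#' Construct a reference haplotype panel
#'
#' A `ref_panel` holds an ordered table of biallelic SNVs and a phased
#' haplotype-by-variant 0/1 allele matrix (1 = alternate allele) from which
#' linkage-disequilibrium correlations are estimated. Monomorphic sites and
#' sites below the minor-allele-frequency floor are dropped at construction,
#' so every retained column is polymorphic.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   one row per variant, in the column order of `H`.
#' @param H Integer/numeric matrix, haplotypes in rows and variants in
#'   columns, entries in \{0, 1\}.
#' @param maf_min Minor-allele-frequency floor; sites with
#'   `min(freq, 1 - freq) < maf_min` are dropped (near-monomorphic sites
#'   give unstable correlation estimates). Default 0.005.
#' @return An object of class `ref_panel`: a list with elements `variants`
#'   (tibble with an added `freq` column, the alternate-allele frequency),
#'   `H` and `n_hap`.
#' @export
ref_panel <- function(variants, H, maf_min = 0.005) {
  stopifnot(is.data.frame(variants), is.matrix(H))
  if (nrow(variants) != ncol(H)) {
    stop("`variants` rows must match `H` columns", call. = FALSE)
  }
  if (nrow(H) < 2) stop("panel needs at least 2 haplotypes", call. = FALSE)
  if (!all(H %in% c(0L, 1L))) stop("`H` entries must be 0 or 1", call. = FALSE)
  storage.mode(H) <- "integer"
  assert_scalar_number(maf_min, "maf_min", 0, 0.5)

  variants <- tibble::as_tibble(variants[, c("chrom", "pos", "ref", "alt")])
  variants$chrom <- norm_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  H <- H[, ord, drop = FALSE]

  freq <- colMeans(H)
  keep <- pmin(freq, 1 - freq) >= maf_min & freq > 0 & freq < 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("ref_panel: dropped %d monomorphic/low-MAF site(s)", n_dropped))
  }
  variants <- variants[keep, ]
  variants$freq <- freq[keep]
  if (nrow(variants) == 0) stop("no polymorphic variants retained", call. = FALSE)

  structure(
    list(variants = variants, H = H[, keep, drop = FALSE], n_hap = nrow(H)),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d haplotypes x %d variants on chromosome(s) %s\n",
              x$n_hap, nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of variants in a panel
#' @param panel A [ref_panel()].
#' @return Integer count of retained variants.
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Alternate-allele frequency of a panel variant
#'
#' @param panel A [ref_panel()].
#' @param idx Variant index (or vector of indices).
#' @return Frequencies in (0, 1), the mean of the haplotype column.
#' @export
alt_freq <- function(panel, idx) {
  stopifnot(all(idx >= 1), all(idx <= nrow(panel$variants)))
  panel$variants$freq[idx]
}

#' Load a phased reference panel from a VCF file
#'
#' Reads phased genotypes (GT with `|` separator) and expands each diploid
#' sample into two haplotypes. Indels, multiallelic records and sites with
#' missing genotypes are skipped with a message; an unphased genotype at a
#' retained biallelic SNV is an error naming the site.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region Optional `list(chrom =, start =, end =)` restricting the
#'   panel to an interval (positions inclusive).
#' @param maf_min Passed to [ref_panel()].
#' @return A [ref_panel()].
#' @export
load_vcf_panel <- function(path, region = NULL, maf_min = 0.005) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])

  snv <- ref %in% VALID_ALLELES & alt %in% VALID_ALLELES
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    message(sprintf("load_vcf_panel: skipped %d non-SNV/multiallelic record(s)", n_skip))
  }
  keep <- snv
  if (!is.null(region)) {
    keep <- keep & chrom == norm_chrom(region$chrom) &
      pos >= region$start & pos <= region$end
  }
  if (!any(keep)) stop("no biallelic SNVs retained from VCF", call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]

  has_missing <- apply(gt, 1, function(g) any(is.na(g) | grepl("\\.", g)))
  if (any(has_missing)) {
    message(sprintf("load_vcf_panel: dropped %d site(s) with missing genotypes",
                    sum(has_missing)))
    gt <- gt[!has_missing, , drop = FALSE]
    chrom <- chrom[!has_missing]; pos <- pos[!has_missing]
    ref <- ref[!has_missing]; alt <- alt[!has_missing]
    if (nrow(gt) == 0) stop("no sites left after missing-genotype filter", call. = FALSE)
  }
  unphased <- matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  if (any(unphased)) {
    i <- which(rowSums(unphased) > 0)[1]
    stop(sprintf("unphased or invalid genotype at %s:%d", chrom[i], pos[i]),
         call. = FALSE)
  }

  hap1 <- substr(gt, 1, 1)
  hap2 <- substr(gt, 3, 3)
  H <- rbind(matrix(as.integer(hap1), nrow = nrow(gt)) |> t(),
             matrix(as.integer(hap2), nrow = nrow(gt)) |> t())
  ref_panel(tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
            H, maf_min = maf_min)
}

#' Load a reference panel from IMPUTE-style hap/legend files
#'
#' The legend file is whitespace-delimited with a header
#' (`id position a0 a1`); the hap file has one row per variant and one 0/1
#' column per haplotype. `a0` is taken as the reference allele and `a1` as
#' the alternate.
#'
#' @param hap_path,legend_path Paths to the two files.
#' @param chrom Chromosome label for the variants (legend files carry none).
#' @param maf_min Passed to [ref_panel()].
#' @return A [ref_panel()].
#' @export
load_hap_legend <- function(hap_path, legend_path, chrom = "1", maf_min = 0.005) {
  for (p in c(hap_path, legend_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  legend <- utils::read.table(legend_path, header = TRUE,
                              colClasses = "character")
  needed <- c("id", "position", "a0", "a1")
  if (!all(needed %in% names(legend))) {
    stop("legend must have columns id, position, a0, a1", call. = FALSE)
  }
  hap <- as.matrix(utils::read.table(hap_path, header = FALSE))
  if (nrow(hap) != nrow(legend)) {
    stop(sprintf("hap rows (%d) do not match legend rows (%d)",
                 nrow(hap), nrow(legend)), call. = FALSE)
  }
  if (!all(hap %in% c(0, 1))) stop("hap entries must be 0 or 1", call. = FALSE)
  snv <- toupper(legend$a0) %in% VALID_ALLELES & toupper(legend$a1) %in% VALID_ALLELES
  if (any(!snv)) {
    message(sprintf("load_hap_legend: skipped %d non-SNV record(s)", sum(!snv)))
  }
  if (!any(snv)) stop("no biallelic SNVs in legend", call. = FALSE)
  ref_panel(
    tibble::tibble(chrom = chrom, pos = as.integer(legend$position[snv]),
                   ref = toupper(legend$a0[snv]), alt = toupper(legend$a1[snv])),
    t(hap[snv, , drop = FALSE]),
    maf_min = maf_min
  )
}

#' Write a panel as IMPUTE-style hap/legend files
#'
#' @param panel A [ref_panel()].
#' @param hap_path,legend_path Output paths.
#' @return `NULL`, invisibly.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  v <- panel$variants
  legend <- data.frame(id = sprintf("%s:%d", v$chrom, v$pos),
                       position = v$pos, a0 = v$ref, a1 = v$alt)
  utils::write.table(legend, legend_path, quote = FALSE, row.names = FALSE)
  utils::write.table(t(panel$H), hap_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Correlation (LD) block between two sets of panel variants
#'
#' Pearson correlation of haplotype allele indicators across the panel's
#' haplotypes — the LD correlation used both among typed variants and
#' between imputation targets and typed variants.
#'
#' @param panel A [ref_panel()].
#' @param row_ids,col_ids Variant indices (rows and columns of the block).
#' @return A `corr_block`: list with `row_ids`, `col_ids` and the matrix `R`.
#' @export
corr_block <- function(panel, row_ids, col_ids) {
  nv <- nrow(panel$variants)
  stopifnot(all(row_ids >= 1), all(row_ids <= nv),
            all(col_ids >= 1), all(col_ids <= nv))
  X <- panel$H[, row_ids, drop = FALSE]
  Y <- panel$H[, col_ids, drop = FALSE]
  if (any(col_var01(X) == 0) || any(col_var01(Y) == 0)) {
    stop("zero-variance haplotype column in corr_block (should be pre-filtered)",
         call. = FALSE)
  }
  R <- suppressWarnings(cor(X, Y))
  structure(list(row_ids = row_ids, col_ids = col_ids, R = R),
            class = "corr_block")
}

# population variance of 0/1 columns: f(1-f)
col_var01 <- function(X) {
  f <- colMeans(X)
  f * (1 - f)
}

#' Checksum identifying a panel's content
#'
#' Used to key correlation caches so a cache is never applied to a
#' different panel.
#'
#' @param panel A [ref_panel()].
#' @return A character scalar.
#' @export
panel_checksum <- function(panel) {
  digest::digest(list(panel$variants$chrom, panel$variants$pos,
                      panel$variants$ref, panel$variants$alt, panel$H),
                 algo = "xxhash64")
}

#' Pre-compute and save per-window correlation blocks
#'
#' Stores the typed-typed and target-typed LD blocks for every window of a
#' window plan, keyed by the panel checksum and the window parameters.
#' Imputing from the cache is bit-identical to imputing from the panel.
#'
#' @param panel A [ref_panel()].
#' @param plan Window plan from [plan_windows()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_corr_cache <- function(panel, plan, path) {
  blocks <- purrr::map(plan, function(w) {
    typed <- window_typed_ids(w)
    list(Stt = corr_block(panel, typed, typed),
         Sut = if (length(w$targets) > 0) corr_block(panel, w$targets, typed) else NULL)
  })
  obj <- list(
    format = "zimpute_corr_cache/1",
    checksum = panel_checksum(panel),
    pred_size = attr(plan, "pred_size"),
    flank_size = attr(plan, "flank_size"),
    blocks = blocks
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a correlation cache, verifying panel and parameters
#'
#' @param path Cache file written by [save_corr_cache()].
#' @param panel The panel the cache must have been built from.
#' @param pred_size,flank_size The window parameters of the current run.
#' @return The list of per-window correlation blocks.
#' @export
load_corr_cache <- function(path, panel, pred_size, flank_size) {
  if (!file.exists(path)) stop(sprintf("cache not found: %s", path), call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "zimpute_corr_cache/1")) {
    stop("not a zimpute correlation cache", call. = FALSE)
  }
  if (!identical(obj$checksum, panel_checksum(panel))) {
    stop("cache was built from a different panel; recompute with save_corr_cache()",
         call. = FALSE)
  }
  if (!identical(obj$pred_size, pred_size) || !identical(obj$flank_size, flank_size)) {
    stop(sprintf(paste0("cache window parameters (pred_size=%d, flank_size=%d) do not ",
                        "match this run (pred_size=%d, flank_size=%d); recompute"),
                 obj$pred_size, obj$flank_size, pred_size, flank_size), call. = FALSE)
  }
  obj$blocks
}
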