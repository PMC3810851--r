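#' Align summary statistics to a reference panel
#'
#' Matches each summary-statistic record to a panel variant by (chromosome,
#' position), reconciles the allele pair, and brings every Z-score into the
#' panel's canonical orientation: after harmonization the effect allele is
#' the panel's alternate allele. A record whose effect/other alleles equal
#' (alt, ref) keeps its sign; (ref, alt) negates it; reverse-complement
#' matches are strand-flipped first. Strand-ambiguous A/T and C/G SNPs are
#' dropped unless `keep_ambiguous = TRUE` (they then match without strand
#' resolution). Irreconcilable allele pairs are dropped with a warning,
#' never silently kept. Panel variants with no matching record become
#' imputation targets; records at positions absent from the panel are
#' ignored, since they carry no LD information.
#'
#' @param sumstats Tibble from [read_sumstats()] (columns `chrom`, `pos`,
#'   `a1`, `a2`, `z`).
#' @param panel A [ref_panel()].
#' @param keep_ambiguous Keep A/T and C/G SNPs, matching alleles as given.
#' @return A `harmonized_set`: list with `variants`, a tibble of one row per
#'   panel variant (`chrom`, `pos`, `ref`, `alt`, `freq`, `typed`, `z`,
#'   `flip`), and `counts`, the tally of each flip class. `flip` is one of
#'   `none`, `allele_swap`, `strand_flip`, `strand_flip_swap`,
#'   `dropped_ambiguous`, `dropped_mismatch`, or `NA` for untyped variants.
#' @export
harmonize <- function(sumstats, panel, keep_ambiguous = FALSE) {
  stopifnot(is.data.frame(sumstats), inherits(panel, "ref_panel"))
  v <- panel$variants
  out <- v
  out$typed <- FALSE
  out$z <- NA_real_
  out$flip <- NA_character_

  key_panel <- paste(v$chrom, v$pos)
  key_rec <- paste(norm_chrom(sumstats$chrom), sumstats$pos)
  hit <- match(key_rec, key_panel)
  n_off_panel <- sum(is.na(hit))

  for (r in which(!is.na(hit))) {
    i <- hit[r]
    a1 <- sumstats$a1[r]; a2 <- sumstats$a2[r]
    z <- sumstats$z[r]
    if (is.na(z)) next
    ref <- v$ref[i]; alt <- v$alt[i]
    ambiguous <- is_ambiguous_pair(a1, a2)
    if (ambiguous && !keep_ambiguous) {
      out$flip[i] <- "dropped_ambiguous"
      next
    }
    if (a1 == alt && a2 == ref) {
      out$typed[i] <- TRUE; out$z[i] <- z; out$flip[i] <- "none"
    } else if (a1 == ref && a2 == alt) {
      out$typed[i] <- TRUE; out$z[i] <- -z; out$flip[i] <- "allele_swap"
    } else if (!ambiguous && revcomp_allele(a1) == alt && revcomp_allele(a2) == ref) {
      out$typed[i] <- TRUE; out$z[i] <- z; out$flip[i] <- "strand_flip"
    } else if (!ambiguous && revcomp_allele(a1) == ref && revcomp_allele(a2) == alt) {
      out$typed[i] <- TRUE; out$z[i] <- -z; out$flip[i] <- "strand_flip_swap"
    } else {
      out$flip[i] <- "dropped_mismatch"
    }
  }

  counts <- table(factor(out$flip,
                         levels = c("none", "allele_swap", "strand_flip",
                                    "strand_flip_swap", "dropped_ambiguous",
                                    "dropped_mismatch")))
  counts <- c(as.list(counts), off_panel = n_off_panel,
              untyped = sum(!out$typed))
  if (counts$dropped_mismatch > 0) {
    warning(sprintf("harmonize: %d record(s) with irreconcilable alleles dropped",
                    counts$dropped_mismatch))
  }
  message(sprintf(
    "harmonize: %d typed (%d swapped, %d strand-flipped), %d untyped targets, %d dropped, %d off-panel",
    sum(out$typed), counts$allele_swap + counts$strand_flip_swap,
    counts$strand_flip + counts$strand_flip_swap,
    counts$untyped, counts$dropped_ambiguous + counts$dropped_mismatch,
    n_off_panel))

  structure(list(variants = out, counts = counts), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d panel variants: %d typed, %d targets\n",
              nrow(x$variants), sum(x$variants$typed),
              sum(!x$variants$typed)))
  invisible(x)
}

# harmonized set back to sumstats orientation (a1 = panel alt), used by
# tests for the idempotence property and by impute_all's typed passthrough
hset_typed_sumstats <- function(hset) {
  v <- hset$variants[hset$variants$typed, ]
  tibble::tibble(chrom = v$chrom, pos = v$pos, a1 = v$alt, a2 = v$ref,
                 z = v$z, p = z_to_p(v$z))
}
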