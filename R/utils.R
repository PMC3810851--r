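#' @importFrom rlang .data
#' @importFrom stats cor pnorm pt qnorm rbeta rbinom rnorm runif setNames var
#' @importFrom utils head tail
NULL

# Chromosome labels are compared after stripping any "chr"/"Chr" prefix so
# "chr22" and "22" refer to the same chromosome.
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

VALID_ALLELES <- c("A", "C", "G", "T")

revcomp_allele <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

# A/T and C/G SNPs cannot be strand-resolved from alleles alone.
is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
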