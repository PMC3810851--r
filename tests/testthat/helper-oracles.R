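# Independent oracles and fixture builders shared across test files.

# Standard-normal two-sided quantile by bisection on the error function --
# an inversion path independent of qnorm().
oracle_p_to_z <- function(p) {
  tail2 <- function(z) 1 - pracma::erf(z / sqrt(2))
  lo <- 0; hi <- 40
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (tail2(mid) > p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force conditional mean/variance by explicit full-matrix inversion of
# the joint correlation matrix: the reference the windowed solver must match.
oracle_cond_mean <- function(Sig, typed_idx, target_idx, Zt, lam = 0) {
  Stt <- Sig[typed_idx, typed_idx, drop = FALSE] + diag(lam, length(typed_idx))
  Sut <- Sig[target_idx, typed_idx, drop = FALSE]
  W <- Sut %*% solve(Stt)
  list(z = as.vector(W %*% Zt), r2pred = diag(W %*% t(Sut)))
}

# Well-conditioned random correlation matrix (Gram of Gaussians plus a
# diagonal bump, rescaled to unit diagonal).
random_corr <- function(n) {
  G <- matrix(rnorm(n * (n + 5)), ncol = n)
  A <- crossprod(G) / nrow(G) + diag(0.1, n)
  stats::cov2cor(A)
}

# Tiny deterministic panel: explicit haplotypes, no randomness.
toy_panel <- function() {
  H <- rbind(
    c(0L, 0L, 0L, 1L, 0L),
    c(0L, 1L, 0L, 1L, 1L),
    c(1L, 0L, 1L, 0L, 0L),
    c(1L, 1L, 1L, 0L, 1L),
    c(0L, 0L, 0L, 1L, 0L),
    c(1L, 1L, 1L, 0L, 1L)
  )
  suppressMessages(ref_panel(
    tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
                   ref = c("A", "C", "A", "T", "A"),
                   alt = c("G", "T", "C", "C", "G")),
    H, maf_min = 0
  ))
}

# Small simulated scene used by several end-to-end tests.
small_sim <- function(seed = 11, n_snp = 300, n_hap = 400, n_subj = 600,
                      mask_min_r = 0.8, ...) {
  cfg <- sim_config(n_hap = n_hap, n_snp = n_snp, n_subj = n_subj,
                    n_causal = 5, h2 = 0.3, mask_frac = 0.05,
                    mask_min_r = mask_min_r, seed = seed, ...)
  suppressWarnings(suppressMessages(simulate_gwas(cfg)))
}

# Minimal phased VCF fixture written to a temp file.
write_toy_vcf <- function(path, unphased_site = FALSE) {
  gt3 <- if (unphased_site) "0/1\t1|1" else "0|1\t1|1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "20\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "20\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|1",
    "20\t250\trs_indel\tCT\tC\t.\tPASS\t.\tGT\t0|0\t0|1",
    paste0("20\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t", gt3)
  )
  writeLines(lines, path)
  path
}

# Typed-only sumstats table in panel orientation (a1 = alt).
panel_sumstats <- function(panel, z) {
  v <- panel$variants
  tibble::tibble(chrom = v$chrom, pos = v$pos, a1 = v$alt, a2 = v$ref, z = z)
}
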