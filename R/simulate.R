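#' Configuration for the quantitative-trait GWAS simulator
#'
#' Bundles the parameters of the end-to-end simulation: a reference
#' haplotype panel with block-wise LD, study genotypes drawn from that
#' panel's haplotype pool (so study and reference populations are matched by
#' construction), a phenotype driven by a small set of causal variants,
#' single-variant association Z-scores, and missing-at-random masking of
#' typed variants.
#'
#' @param n_hap Reference haplotypes in the panel.
#' @param n_snp Variants simulated (a few may be dropped as monomorphic).
#' @param n_subj Study subjects.
#' @param n_causal Causal variants contributing to the phenotype.
#' @param h2 Fraction of phenotypic variance explained by the causal
#'   variants, in \[0, 1); `h2 = 0` gives a pure null phenotype.
#' @param mask_frac Fraction of panel variants masked (statistics withheld)
#'   for the imputation-accuracy experiment.
#' @param mask_min_r Optional LD floor for maskable variants: a variant may
#'   be masked only if it has |r| >= `mask_min_r` with some variant that
#'   stays typed. `NULL` masks uniformly at random.
#' @param n_founder Founder haplotypes of the mosaic generator.
#' @param ld_decay Per-site founder-switch probability of the mosaic
#'   generator; smaller values give longer shared segments.
#' @param founder_rho Autocorrelation of the latent Gaussian process from
#'   which founder alleles are thresholded; together with `freq_rho` and the
#'   defaults it yields mean adjacent-variant |r| of about 0.8.
#' @param freq_rho Autocorrelation of the latent process driving the
#'   allele-frequency series (nearby variants in strong LD have similar
#'   frequencies, as in real panels).
#' @param maf_range Range of the U-shaped allele-frequency distribution
#'   founder alleles are drawn from.
#' @param seed Random seed; every stage of the simulation derives its
#'   stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_hap = 1000, n_snp = 2000, n_subj = 2000,
                       n_causal = 10, h2 = 0.3, mask_frac = 0.05,
                       mask_min_r = NULL, n_founder = 16, ld_decay = 0.01,
                       founder_rho = 0.99, freq_rho = 0.90,
                       maf_range = c(0.01, 0.5), seed = 1) {
  stopifnot(n_hap >= 4, n_snp >= 2, n_subj >= 3, n_causal >= 0,
            n_causal <= n_snp, h2 >= 0, h2 < 1,
            mask_frac > 0, mask_frac < 1,
            n_founder >= 2, n_founder <= n_hap,
            ld_decay >= 0, ld_decay <= 1,
            founder_rho >= 0, founder_rho < 1, freq_rho >= 0, freq_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_hap = as.integer(n_hap), n_snp = as.integer(n_snp),
                 n_subj = as.integer(n_subj), n_causal = as.integer(n_causal),
                 h2 = h2, mask_frac = mask_frac, mask_min_r = mask_min_r,
                 n_founder = as.integer(n_founder), ld_decay = ld_decay,
                 founder_rho = founder_rho, freq_rho = freq_rho,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

# distinct, reproducible seed per simulation stage
stage_seed <- function(cfg, stage) {
  offsets <- c(panel = 0L, study = 500000L, mask = 1000000L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate a reference haplotype panel with block-wise LD
#'
#' Allele frequencies follow a U-shaped (Beta(0.5, 0.5)) distribution
#' rescaled to `maf_range`, made locally similar along the chromosome by a
#' latent AR(1) copula with autocorrelation `freq_rho`. Founder haplotypes
#' are thresholded from independent latent Gaussian AR(1) processes
#' (autocorrelation `founder_rho`), so each founder carries autocorrelated
#' allele runs; the remaining haplotypes are mosaics of the founders,
#' switching to a random founder with probability `ld_decay` at each site.
#' Few founders plus low switch rates give long shared segments and strong
#' block-wise LD; `ld_decay = 1` re-draws the founder at every site, which
#' leaves only weak residual correlation of order `1 / n_founder`.
#'
#' @param cfg A [sim_config()].
#' @return A [ref_panel()] on chromosome "1" with variants spaced 1 kb
#'   apart, alleles A (reference) and G (alternate).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "panel"))
  lo <- cfg$maf_range[1]; hi <- cfg$maf_range[2]
  w <- ar1_series(cfg$n_snp, cfg$freq_rho)
  freq <- lo + (hi - lo) * stats::qbeta(pnorm(w), 0.5, 0.5)
  thr <- qnorm(freq)

  founders <- matrix(0L, nrow = cfg$n_founder, ncol = cfg$n_snp)
  for (k in seq_len(cfg$n_founder)) {
    founders[k, ] <- as.integer(ar1_series(cfg$n_snp, cfg$founder_rho) < thr)
  }
  n_mosaic <- cfg$n_hap - cfg$n_founder
  H <- matrix(0L, nrow = cfg$n_hap, ncol = cfg$n_snp)
  H[seq_len(cfg$n_founder), ] <- founders
  for (h in seq_len(n_mosaic)) {
    switch_here <- runif(cfg$n_snp) < cfg$ld_decay
    switch_here[1] <- TRUE
    src <- sample.int(cfg$n_founder, sum(switch_here), replace = TRUE)
    source_at <- src[cumsum(switch_here)]
    H[cfg$n_founder + h, ] <- founders[cbind(source_at, seq_len(cfg$n_snp))]
  }
  ref_panel(
    tibble::tibble(chrom = "1", pos = seq_len(cfg$n_snp) * 1000L,
                   ref = "A", alt = "G"),
    H, maf_min = 0.005
  )
}

# stationary standard-normal AR(1) path of length n
ar1_series <- function(n, rho) {
  if (rho == 0) return(rnorm(n))
  innov <- rnorm(n - 1) * sqrt(1 - rho^2)
  as.numeric(stats::filter(c(rnorm(1), innov), rho, method = "recursive"))
}

#' Simulate study genotypes and a quantitative phenotype
#'
#' Each subject's genotype is the sum of two haplotypes drawn uniformly
#' (with replacement) from the panel pool, so the study sample matches the
#' reference population exactly. The phenotype is a linear combination of
#' dosages at `n_causal` randomly chosen causal variants plus Gaussian
#' noise, with effect sizes rescaled so the causal variants explain `h2` of
#' the phenotypic variance.
#'
#' @param panel A [ref_panel()] from [simulate_panel()].
#' @param cfg The [sim_config()].
#' @return A list with `G` (subject-by-variant dosage matrix), `y`
#'   (phenotype), `beta` (per-variant effects, zero off the causal set) and
#'   `causal_idx`.
#' @export
simulate_study <- function(panel, cfg) {
  stopifnot(inherits(panel, "ref_panel"), inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "study"))
  nv <- n_variants(panel)
  i1 <- sample.int(panel$n_hap, cfg$n_subj, replace = TRUE)
  i2 <- sample.int(panel$n_hap, cfg$n_subj, replace = TRUE)
  G <- panel$H[i1, , drop = FALSE] + panel$H[i2, , drop = FALSE]

  beta <- numeric(nv)
  causal_idx <- integer(0)
  if (cfg$n_causal > 0 && cfg$h2 > 0) {
    causal_idx <- sort(sample.int(nv, min(cfg$n_causal, nv)))
    b <- rnorm(length(causal_idx))
    gc <- as.vector(G[, causal_idx, drop = FALSE] %*% b)
    s2g <- var(gc)
    if (s2g > 0) {
      # scale genetic values to variance h2, noise to 1 - h2
      b <- b * sqrt(cfg$h2 / s2g)
      beta[causal_idx] <- b
      gc <- gc * sqrt(cfg$h2 / s2g)
      y <- gc + rnorm(cfg$n_subj, sd = sqrt(1 - cfg$h2))
    } else {
      y <- rnorm(cfg$n_subj)
    }
  } else {
    y <- rnorm(cfg$n_subj)
  }
  list(G = G, y = y, beta = beta, causal_idx = causal_idx)
}

#' Single-variant association Z-scores for a quantitative trait
#'
#' For each variant, the Wald statistic of the simple linear regression of
#' phenotype on dosage: `t_j = r_j sqrt((n-2)/(1-r_j^2))` with `r_j` the
#' sample correlation, mapped through the t-to-normal quantile
#' correspondence to an exactly standard-normal null statistic. The sign
#' follows the alternate-allele effect direction. Variants with zero dosage
#' variance get `NA` with a warning.
#'
#' @param G Subject-by-variant dosage matrix.
#' @param y Phenotype vector.
#' @return A numeric vector of signed Z-scores, one per variant.
#' @export
gwas_z <- function(G, y) {
  n <- nrow(G)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (length(y) != n) stop("phenotype length must match genotype rows", call. = FALSE)
  f <- colMeans(G)
  v <- colMeans(G^2) - f^2
  bad <- v <= 0
  z <- rep(NA_real_, ncol(G))
  if (any(bad)) {
    warning(sprintf("gwas_z: %d zero-variance variant(s) flagged NA", sum(bad)))
  }
  ok <- which(!bad)
  if (length(ok) > 0) {
    r <- as.vector(suppressWarnings(cor(G[, ok, drop = FALSE], y)))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    zval <- qnorm(pt(abs(tval), df = n - 2, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
    z[ok] <- sign(tval) * zval
  }
  z
}

# max |r| partners within a local band of the panel, as index pairs
local_ld_pairs <- function(panel, threshold, band = 50) {
  H <- panel$H
  nv <- ncol(H)
  f <- colMeans(H)
  s <- sqrt(f * (1 - f))
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (k in seq_len(min(band, nv - 1))) {
    i <- seq_len(nv - k)
    exy <- colMeans(H[, i, drop = FALSE] * H[, i + k, drop = FALSE])
    r <- (exy - f[i] * f[i + k]) / (s[i] * s[i + k])
    hit <- which(abs(r) >= threshold)
    pairs_i <- c(pairs_i, i[hit])
    pairs_j <- c(pairs_j, i[hit] + k)
  }
  list(i = pairs_i, j = pairs_j)
}

#' Mask variants and package a simulation replicate
#'
#' Withholds the Z-scores of a masked variant set — these become the
#' imputation targets — and returns the observed (typed-only) summary
#' statistics together with the held-out truth. Masking is either uniform
#' at random (`mask_min_r = NULL`) or restricted to variants with a strong
#' LD partner (|r| >= `mask_min_r` within a 50-variant band) that stays
#' typed, the regime in which LD carries enough information to impute well.
#' A `mask_targets` integer vector in `cfg` (extra field) masks exactly
#' those variant indices instead.
#'
#' @param z_all Z-score vector aligned with `panel$variants` (from
#'   [gwas_z()]).
#' @param panel The [ref_panel()].
#' @param cfg The [sim_config()].
#' @return A `sim_result`: list with `panel`, `true_z` (tibble of all
#'   scoreable variants), `observed` (summary-statistics tibble of typed
#'   variants only, effect allele = panel alt), `masked` (held-out truth at
#'   masked variants) and `masked_idx`.
#' @export
mask_and_package <- function(z_all, panel, cfg) {
  stopifnot(inherits(panel, "ref_panel"), inherits(cfg, "sim_config"))
  nv <- n_variants(panel)
  stopifnot(length(z_all) == nv)
  set.seed(stage_seed(cfg, "mask"))
  scoreable <- which(is.finite(z_all))
  n_mask <- round(cfg$mask_frac * nv)

  if (!is.null(cfg$mask_targets)) {
    masked <- intersect(as.integer(cfg$mask_targets), scoreable)
  } else if (is.null(cfg$mask_min_r)) {
    masked <- sample(scoreable, min(n_mask, length(scoreable) - 1L))
  } else {
    prs <- local_ld_pairs(panel, cfg$mask_min_r)
    partners <- split(c(prs$j, prs$i), c(prs$i, prs$j))
    candidates <- intersect(as.integer(names(partners)), scoreable)
    if (length(candidates) == 0) {
      stop("no variant has an LD partner at or above mask_min_r", call. = FALSE)
    }
    candidates <- sample(candidates)
    is_masked <- rep(FALSE, nv)
    taken <- 0L
    for (i in candidates) {
      if (taken >= n_mask) break
      p_i <- partners[[as.character(i)]]
      if (all(is_masked[p_i])) next
      # masking i must not strip an already-masked variant of its last
      # retained partner
      robbed <- FALSE
      for (j in p_i[is_masked[p_i]]) {
        p_j <- partners[[as.character(j)]]
        if (!any(!is_masked[p_j] & p_j != i)) { robbed <- TRUE; break }
      }
      if (robbed) next
      is_masked[i] <- TRUE
      taken <- taken + 1L
    }
    masked <- which(is_masked)
    if (taken < n_mask) {
      warning(sprintf("only %d of %d requested maskable variants found", taken, n_mask))
    }
  }
  if (length(setdiff(scoreable, masked)) == 0) {
    stop("mask would remove all typed variants", call. = FALSE)
  }

  v <- panel$variants
  truth <- tibble::tibble(chrom = v$chrom[scoreable], pos = v$pos[scoreable],
                          a1 = v$alt[scoreable], a2 = v$ref[scoreable],
                          z = z_all[scoreable])
  typed_idx <- setdiff(scoreable, masked)
  observed <- tibble::tibble(chrom = v$chrom[typed_idx], pos = v$pos[typed_idx],
                             a1 = v$alt[typed_idx], a2 = v$ref[typed_idx],
                             z = z_all[typed_idx], p = z_to_p(z_all[typed_idx]))
  held_out <- tibble::tibble(chrom = v$chrom[masked], pos = v$pos[masked],
                             a1 = v$alt[masked], a2 = v$ref[masked],
                             z = z_all[masked])
  structure(list(panel = panel, true_z = truth, observed = observed,
                 masked = held_out, masked_idx = masked),
            class = "sim_result")
}

#' Run one full simulation replicate
#'
#' Panel, study, association scan and masking in sequence, all driven by
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_result` (see [mask_and_package()]) with the study
#'   attached as attribute `"study"`.
#' @export
simulate_gwas <- function(cfg) {
  panel <- simulate_panel(cfg)
  study <- simulate_study(panel, cfg)
  z <- suppressWarnings(gwas_z(study$G, study$y))
  out <- mask_and_package(z, panel, cfg)
  attr(out, "study") <- study[c("beta", "causal_idx")]
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d variants: %d typed, %d masked\n",
              nrow(x$true_z), nrow(x$observed), nrow(x$masked)))
  invisible(x)
}

#' Score imputed against true Z-scores
#'
#' The accuracy metric of the imputation experiment: the squared Pearson
#' correlation between imputed and true (full-data) Z-scores across masked
#' variants, plus a per-variant error table. Note that squared correlation
#' is invariant to affine shifts, so it measures tracking, not bias.
#'
#' @param imputed A `zimpute_result` or its results tibble; only rows with
#'   status `imputed` are scored.
#' @param truth Tibble with columns `chrom`, `pos`, `z` holding the
#'   held-out true Z-scores (e.g. `sim$masked`).
#' @return A `zimpute_accuracy`: list with `r2`, `n`, and `table` (per-SNP
#'   imputed, true and absolute error). Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
evaluate_accuracy <- function(imputed, truth) {
  if (inherits(imputed, "zimpute_result")) imputed <- imputed$results
  stopifnot(is.data.frame(imputed), is.data.frame(truth))
  imp <- imputed[imputed$status %in% "imputed", c("chrom", "pos", "z", "r2pred")]
  tr <- tibble::tibble(chrom = norm_chrom(truth$chrom), pos = truth$pos,
                       z_true = truth$z)
  tab <- dplyr::inner_join(imp, tr, by = c("chrom", "pos"))
  if (nrow(tab) < 2) {
    stop("need at least 2 scored variants to compute a correlation", call. = FALSE)
  }
  tab$abs_err <- abs(tab$z - tab$z_true)
  structure(list(r2 = cor(tab$z, tab$z_true)^2, n = nrow(tab),
                 table = tibble::as_tibble(tab)),
            class = "zimpute_accuracy")
}

#' @export
print.zimpute_accuracy <- function(x, ...) {
  cat(sprintf("<zimpute_accuracy> r2 = %.4f over %d variants (mean |error| %.3f)\n",
              x$r2, x$n, mean(x$table$abs_err)))
  invisible(x)
}

#' @rdname evaluate_accuracy
#' @param x A `zimpute_accuracy`.
#' @param ... Unused.
#' @method tidy zimpute_accuracy
#' @export
tidy.zimpute_accuracy <- function(x, ...) x$table

#' @rdname evaluate_accuracy
#' @method glance zimpute_accuracy
#' @export
glance.zimpute_accuracy <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n = x$n, mean_abs_err = mean(x$table$abs_err),
                 max_abs_err = max(x$table$abs_err))
}

#' @rdname evaluate_accuracy
#' @param object A `zimpute_accuracy`.
#' @method autoplot zimpute_accuracy
#' @export
autoplot.zimpute_accuracy <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$z_true, y = .data$z)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$r2pred), alpha = 0.8) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "true Z-score", y = "imputed Z-score", color = "r2pred",
                  title = sprintf("imputed vs true Z (r2 = %.3f)", object$r2)) +
    ggplot2::theme_minimal()
}

#' Pooled imputation-accuracy experiment over replicates
#'
#' Repeats the simulate-mask-impute-score cycle `n_rep` times with
#' replicate `r` seeded at `seed + r`, pools imputed/true Z pairs over all
#' replicates, and returns the pooled squared correlation together with
#' per-replicate values.
#'
#' @param cfg Base [sim_config()]; its seed is overridden per replicate.
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param ... Passed to [impute_sumstats()] (window sizes, `lam`, ...).
#' @return A `zimpute_accuracy` over the pooled pairs, with a
#'   `per_replicate` tibble attached as a list element.
#' @export
run_accuracy_experiment <- function(cfg, n_rep = 25, seed = 1, ...) {
  tabs <- purrr::map(seq_len(n_rep), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(seed + r)
    sim <- simulate_gwas(cfg_r)
    fit <- suppressMessages(impute_sumstats(sim$observed, sim$panel, ...))
    acc <- evaluate_accuracy(fit, sim$masked)
    dplyr::mutate(acc$table, replicate = r)
  })
  pooled <- dplyr::bind_rows(tabs)
  out <- structure(list(r2 = cor(pooled$z, pooled$z_true)^2, n = nrow(pooled),
                        table = pooled),
                   class = "zimpute_accuracy")
  out$per_replicate <- pooled |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(r2 = cor(.data$z, .data$z_true)^2, n = dplyr::n(),
                     .groups = "drop")
  out
}
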