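mk_hset <- function(pos_typed, pos_untyped, chrom = "1") {
  pos <- sort(c(pos_typed, pos_untyped))
  typed <- pos %in% pos_typed
  variants <- tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G",
                             freq = 0.5, typed = typed,
                             z = ifelse(typed, 1, NA_real_),
                             flip = ifelse(typed, "none", NA_character_))
  structure(list(variants = variants, counts = list()),
            class = "harmonized_set")
}

test_that("plan_windows partitions typed runs, truncates flanks, and covers targets exactly once", {
  # 10 typed and 3 untyped interleaved
  hset <- mk_hset(pos_typed = (1:10) * 100L,
                  pos_untyped = c(150L, 450L, 850L))
  plan <- plan_windows(hset, pred_size = 5, flank_size = 2)
  expect_length(plan, 2L)
  w1 <- plan[[1]]; w2 <- plan[[2]]
  expect_length(w1$core, 5L)
  expect_length(w1$flank_left, 0L)   # chromosome start
  expect_length(w1$flank_right, 2L)
  expect_length(w2$flank_left, 2L)
  expect_length(w2$flank_right, 0L)  # chromosome end
  # targets at 150 and 450 fall before the second window's first core SNP (600)
  v <- hset$variants
  expect_equal(sort(v$pos[w1$targets]), c(150L, 450L))
  expect_equal(v$pos[w2$targets], 850L)

  # an untyped variant upstream of all typed ones goes to the first window
  hset2 <- mk_hset(pos_typed = (2:11) * 100L, pos_untyped = 50L)
  plan2 <- plan_windows(hset2, pred_size = 5, flank_size = 2)
  expect_equal(hset2$variants$pos[plan2[[1]]$targets], 50L)

  # pred_size >= number of typed SNPs: one window, empty flanks
  plan3 <- plan_windows(hset, pred_size = 50, flank_size = 2)
  expect_length(plan3, 1L)
  expect_length(plan3[[1]]$core, 10L)
  expect_length(plan3[[1]]$flank_left, 0L)
  expect_length(plan3[[1]]$flank_right, 0L)

  expect_error(plan_windows(mk_hset(integer(0), c(100L, 200L))),
               "nothing to condition on")

  # property: every untyped variant lands in exactly one window
  for (seed in 1:10) {
    set.seed(seed)
    pos <- sort(sample.int(10000L, 60))
    typed_pos <- sort(sample(pos, 35))
    h <- mk_hset(typed_pos, setdiff(pos, typed_pos))
    p <- plan_windows(h, pred_size = sample(3:10, 1), flank_size = sample(0:5, 1))
    tgt <- unlist(lapply(p, `[[`, "targets"))
    expect_equal(sort(tgt), which(!h$variants$typed))
    expect_equal(sort(unlist(lapply(p, `[[`, "core"))), which(h$variants$typed))
  }
})

test_that("impute_window reproduces the analytic fixtures exactly", {
  # perfect proxy: unit-vector LD row returns the proxy's statistic
  Stt <- diag(3)
  res <- impute_window(c(1.1, -0.4, 2.2), Stt, matrix(c(0, 1, 0), 1), lam = 0)
  expect_equal(res$z, -0.4)
  expect_equal(res$r2pred, 1)

  # no LD with any typed SNP: null mean, zero information
  res0 <- impute_window(c(1.1, -0.4, 2.2), Stt, matrix(0, 1, 3), lam = 0)
  expect_equal(res0$z, 0)
  expect_equal(res0$r2pred, 0)

  # 2-typed worked example, verified against the 2x2 adjugate inverse:
  # inv = [[1,-.5],[-.5,1]]/0.75; W = (0.8, 0); Zu = 2.4; r2pred = 0.64
  res2 <- impute_window(c(3, 1), matrix(c(1, .5, .5, 1), 2),
                        matrix(c(0.8, 0.4), 1), lam = 0)
  expect_equal(res2$z, 2.4, tolerance = 1e-12)
  expect_equal(res2$r2pred, 0.64, tolerance = 1e-12)
})

test_that("impute_window validates inputs and flags singular systems", {
  expect_error(impute_window(c(1, 2), diag(3), matrix(0, 1, 3)), "square")
  expect_error(impute_window(c(1, 2), diag(2), matrix(0, 1, 3)), "column")
  expect_error(impute_window(c(1, 2), diag(2), matrix(0, 1, 2), lam = -1), ">= 0")
  singular <- matrix(c(1, 1, 1, 1), 2)
  expect_error(impute_window(c(1, 1), singular, matrix(c(1, 1), 1), lam = 0),
               "lam")
  # the same system solves with ridge
  res <- impute_window(c(1, 1), singular, matrix(c(1, 1), 1), lam = 1e-3)
  expect_true(is.finite(res$z))
})

test_that("impute_window matches the full-inversion oracle on random instances", {
  set.seed(42)
  for (i in 1:100) {
    n_typed <- sample(3:12, 1)
    n_tgt <- sample(1:3, 1)
    n <- n_typed + n_tgt
    Sig <- random_corr(n)
    typed_idx <- sort(sample.int(n, n_typed))
    target_idx <- setdiff(seq_len(n), typed_idx)
    Zt <- rnorm(n_typed)
    want <- oracle_cond_mean(Sig, typed_idx, target_idx, Zt, lam = 0)
    got <- impute_window(Zt, Sig[typed_idx, typed_idx],
                         Sig[target_idx, typed_idx, drop = FALSE], lam = 0)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$r2pred, unname(want$r2pred), tolerance = 1e-10)
  }
})

test_that("r2pred is monotone in added predictors at lam = 0 and shrinks under ridge", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    Sig <- random_corr(n)
    # target is variant n; grow the predictor set one typed variant at a time
    r2_prev <- 0
    for (k in 2:(n - 1)) {
      typed_idx <- seq_len(k)
      r2 <- oracle_cond_mean(Sig, typed_idx, n, rnorm(k), lam = 0)$r2pred
      expect_gte(r2 + 1e-12, r2_prev)
      r2_prev <- r2
    }
    expect_lte(r2_prev, 1 + 1e-8)

    # ridge strictly reduces r2pred for a target with nonzero LD row
    typed_idx <- seq_len(n - 1)
    Zt <- rnorm(n - 1)
    r2_0 <- impute_window(Zt, Sig[typed_idx, typed_idx],
                          Sig[n, typed_idx, drop = FALSE], lam = 0)$r2pred
    r2_l <- impute_window(Zt, Sig[typed_idx, typed_idx],
                          Sig[n, typed_idx, drop = FALSE], lam = 0.05)$r2pred
    expect_lt(r2_l, r2_0)
  }
})

test_that("impute_all passes typed variants through and nails perfect proxies", {
  # all variants typed: output equals input
  sim <- small_sim(seed = 8, n_snp = 60, n_hap = 200, n_subj = 300,
                   mask_min_r = NULL)
  full_obs <- sim$true_z
  hset <- suppressMessages(harmonize(full_obs, sim$panel))
  out <- suppressMessages(impute_all(hset, sim$panel, pred_size = 20, flank_size = 10))
  expect_true(all(out$status == "typed"))
  expect_equal(out$z, hset$variants$z)
  expect_true(all(out$r2pred == 1))

  # a target duplicating a typed variant's haplotype column is imputed to its z
  H <- matrix(rbinom(400 * 3, 1, 0.4), 400, 3)
  H <- cbind(H, H[, 2]) # variant 4 duplicates variant 2
  panel <- suppressMessages(ref_panel(
    tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                   ref = "A", alt = "G"), H, maf_min = 0))
  ss <- panel_sumstats(panel, z = c(0.3, 1.8, -0.6, NA))[1:3, ]
  fit <- suppressMessages(impute_sumstats(ss, panel, pred_size = 10,
                                          flank_size = 10, lam = 0))
  imp <- fit$results[fit$results$status == "imputed", ]
  expect_equal(imp$z, 1.8, tolerance = 1e-10)
  expect_equal(imp$r2pred, 1, tolerance = 1e-10)
})

test_that("windowed imputation agrees with the one-shot full-matrix conditional mean", {
  sim <- small_sim(seed = 9, n_snp = 150, n_hap = 300, n_subj = 400)
  hset <- suppressMessages(harmonize(sim$observed, sim$panel))
  v <- hset$variants
  typed_idx <- which(v$typed)
  target_idx <- which(!v$typed)
  Sig <- corr_block(sim$panel, seq_len(nrow(v)), seq_len(nrow(v)))$R
  want <- oracle_cond_mean(Sig, typed_idx, target_idx, v$z[typed_idx], lam = 1e-3)

  # single window spanning everything
  one <- suppressMessages(impute_all(hset, sim$panel, pred_size = length(typed_idx),
                                     flank_size = 0, lam = 1e-3, min_r2pred = 0))
  expect_equal(one$z[target_idx], want$z, tolerance = 1e-10)
  expect_equal(one$r2pred[target_idx], unname(want$r2pred), tolerance = 1e-10)

  # many windows whose extended regions still span all typed variants
  split <- suppressMessages(impute_all(hset, sim$panel, pred_size = 25,
                                       flank_size = length(typed_idx), lam = 1e-3,
                                       min_r2pred = 0))
  expect_equal(split$z[target_idx], want$z, tolerance = 1e-10)
})

test_that("imputation quality gates reporting and collinear windows are pruned", {
  sim <- small_sim(seed = 10, n_snp = 150, n_hap = 300, n_subj = 400,
                   mask_min_r = NULL)
  fit <- suppressMessages(impute_sumstats(sim$observed, sim$panel,
                                          pred_size = 50, flank_size = 50,
                                          min_r2pred = 0.9))
  res <- fit$results[!is.na(fit$results$n_typed_used), ]
  expect_true(all(res$status[res$r2pred < 0.9] == "skipped"))
  expect_true(all(is.na(fit$results$z[fit$results$status == "skipped"])))
  expect_true(all(res$status[res$r2pred >= 0.9] == "imputed"))

  # duplicated typed columns make Stt singular at lam = 0; pruning rescues it
  H <- matrix(rbinom(200 * 4, 1, 0.5), 200, 4)
  H[, 2] <- H[, 1]
  panel <- suppressMessages(ref_panel(
    tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                   ref = "A", alt = "G"), H, maf_min = 0))
  ss <- panel_sumstats(panel, z = c(1.2, 1.2, 0.4, NA))[1:3, ]
  hset <- suppressMessages(harmonize(ss, panel))
  expect_message(
    out <- impute_all(hset, panel, pred_size = 10, flank_size = 0, lam = 0,
                      min_r2pred = 0),
    "pruned")
  expect_equal(out$status[4], "imputed")
  expect_true(is.finite(out$z[4]))
})
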