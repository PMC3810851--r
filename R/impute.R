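#' Partition a harmonized variant sequence into imputation windows
#'
#' Typed variants on each chromosome are split into consecutive cores of
#' `pred_size` (the prediction window; the final core may be shorter), and
#' each core is extended by up to `flank_size` adjacent typed variants on
#' either side (the extended window), truncated at chromosome ends. Every
#' untyped variant is assigned to exactly one window by a half-open rule on
#' position: it belongs to the window whose first core variant's position is
#' the largest not exceeding its own; untyped variants upstream of all typed
#' variants go to the first window, downstream of all to the last.
#'
#' @param hset A `harmonized_set` from [harmonize()].
#' @param pred_size Number of typed variants per prediction-window core.
#' @param flank_size Number of typed variants in each side region of the
#'   extended window.
#' @return A list of windows (class `window_plan`), each a list with
#'   `chrom`, `core`, `flank_left`, `flank_right` and `targets`, all indices
#'   into the panel's variant table.
#' @export
plan_windows <- function(hset, pred_size = 100, flank_size = 250) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (pred_size < 1) stop("`pred_size` must be >= 1", call. = FALSE)
  if (flank_size < 0) stop("`flank_size` must be >= 0", call. = FALSE)
  v <- hset$variants
  plan <- list()
  for (ch in unique(v$chrom)) {
    on_ch <- which(v$chrom == ch)
    typed <- on_ch[v$typed[on_ch]]
    untyped <- on_ch[!v$typed[on_ch]]
    if (length(typed) == 0) {
      stop(sprintf("chromosome %s has no typed variants: nothing to condition on", ch),
           call. = FALSE)
    }
    m <- length(typed)
    n_win <- ceiling(m / pred_size)
    starts_i <- seq(1L, by = pred_size, length.out = n_win)
    ends_i <- pmin(starts_i + pred_size - 1L, m)
    # half-open assignment on the position of each window's first core variant
    start_pos <- v$pos[typed[starts_i]]
    w_of <- findInterval(v$pos[untyped], start_pos)
    w_of[w_of == 0L] <- 1L
    wins <- purrr::map(seq_len(n_win), function(w) {
      core <- typed[starts_i[w]:ends_i[w]]
      left_pool <- if (starts_i[w] > 1) typed[1:(starts_i[w] - 1L)] else integer(0)
      right_pool <- if (ends_i[w] < m) typed[(ends_i[w] + 1L):m] else integer(0)
      list(
        chrom = ch,
        core = core,
        flank_left = tail(left_pool, flank_size),
        flank_right = head(right_pool, flank_size),
        targets = untyped[w_of == w]
      )
    })
    plan <- c(plan, wins)
  }
  structure(plan, class = "window_plan",
            pred_size = as.integer(pred_size),
            flank_size = as.integer(flank_size))
}

window_typed_ids <- function(w) c(w$flank_left, w$core, w$flank_right)

#' Impute untyped Z-scores in one window by the conditional-mean formula
#'
#' For jointly standard-normal statistics under the null with LD correlation
#' blocks `Stt` (typed-typed) and `Sut` (target-typed), the conditional
#' expectation of the untyped statistics given the typed ones is
#' `Zu = Sut (Stt + lam I)^-1 Zt`, and the null variance of each imputed
#' statistic — its imputation quality `r2pred` — is the corresponding
#' diagonal of `Sut (Stt + lam I)^-1 Sut'`. The solve uses a Cholesky
#' factorization of the (ridge-stabilized) typed block, never an explicit
#' inverse.
#'
#' @param Zt Numeric vector of typed Z-scores.
#' @param Stt Typed-typed correlation matrix (or a `corr_block`).
#' @param Sut Target-by-typed correlation matrix (or a `corr_block`).
#' @param lam Ridge parameter added to the diagonal of `Stt`; `lam = 0`
#'   requires `Stt` to be numerically positive definite.
#' @return A list with `z` (imputed Z-scores) and `r2pred`.
#' @export
#' @examples
#' Stt <- matrix(c(1, 0.5, 0.5, 1), 2)
#' impute_window(c(3, 1), Stt, matrix(c(0.8, 0.4), 1), lam = 0)
impute_window <- function(Zt, Stt, Sut, lam = 0) {
  if (inherits(Stt, "corr_block")) Stt <- Stt$R
  if (inherits(Sut, "corr_block")) Sut <- Sut$R
  if (is.null(dim(Sut))) Sut <- matrix(Sut, nrow = 1)
  n <- length(Zt)
  if (!is.matrix(Stt) || nrow(Stt) != n || ncol(Stt) != n) {
    stop("`Stt` must be square with dimension length(Zt)", call. = FALSE)
  }
  if (ncol(Sut) != n) {
    stop("`Sut` must have one column per typed variant", call. = FALSE)
  }
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (nrow(Sut) == 0) return(list(z = numeric(0), r2pred = numeric(0)))

  A <- Stt + diag(lam, n)
  cf <- tryCatch(chol(A), error = function(e) NULL)
  # diag(U)^2 bounds the smallest eigenvalue of A from above
  if (is.null(cf) || min(diag(cf))^2 < 1e-10) {
    stop(paste0("typed-typed correlation block is numerically singular; ",
                "set lam > 0 or prune collinear variants"), call. = FALSE)
  }
  alpha <- backsolve(cf, forwardsolve(t(cf), Zt))
  zu <- as.vector(Sut %*% alpha)
  B <- forwardsolve(t(cf), t(Sut))
  r2 <- colSums(B^2)
  list(z = zu, r2pred = unname(r2))
}

# drop one member of each typed pair with |r| > 0.999 (keep the first, i.e.
# lower-position, variant); returns indices into `typed` to keep
prune_collinear <- function(R, threshold = 0.999) {
  n <- nrow(R)
  keep <- rep(TRUE, n)
  for (j in seq_len(n)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(n) > j & abs(R[j, ]) > threshold)
    keep[later] <- FALSE
  }
  which(keep)
}

#' Impute Z-scores at all untyped panel variants
#'
#' Runs the full window scheme: plans prediction/extended windows over the
#' harmonized set, estimates the LD blocks from the panel (or takes them
#' from a pre-computed cache), and imputes each window's targets with
#' [impute_window()]. Typed variants pass through with status `typed` and
#' `r2pred = 1`; targets whose quality falls below `min_r2pred` are reported
#' with status `skipped` and no Z-score. If a window's typed block fails the
#' positive-definiteness check, one member of each near-collinear typed pair
#' (|r| > 0.999) is pruned and the window is retried.
#'
#' @param hset A `harmonized_set` from [harmonize()].
#' @param panel The [ref_panel()] the set was harmonized against.
#' @param pred_size,flank_size Window sizes, in numbers of typed variants
#'   (see [plan_windows()]).
#' @param lam Ridge parameter on the correlation scale.
#' @param min_r2pred Reporting threshold on imputation quality.
#' @param cache Optional path to a correlation cache from
#'   [save_corr_cache()].
#' @param rescale Also report `z_rescaled = z / sqrt(r2pred)` for imputed
#'   variants (the variance-standardized convention).
#' @return A tibble with one row per panel variant: `chrom`, `pos`, `a1`
#'   (effect allele = panel alt), `a2`, `z`, `p`, `r2pred`, `n_typed_used`,
#'   `status`, and optionally `z_rescaled`.
#' @export
impute_all <- function(hset, panel, pred_size = 100, flank_size = 250,
                       lam = 1e-3, min_r2pred = 0.3, cache = NULL,
                       rescale = FALSE) {
  stopifnot(inherits(hset, "harmonized_set"), inherits(panel, "ref_panel"))
  assert_scalar_number(lam, "lam", lower = 0)
  assert_scalar_number(min_r2pred, "min_r2pred", 0, 1)
  plan <- plan_windows(hset, pred_size = pred_size, flank_size = flank_size)
  blocks <- if (!is.null(cache)) {
    load_corr_cache(cache, panel, as.integer(pred_size), as.integer(flank_size))
  }
  v <- hset$variants

  target_rows <- purrr::map(seq_along(plan), function(wi) {
    w <- plan[[wi]]
    if (length(w$targets) == 0) return(NULL)
    typed <- window_typed_ids(w)
    if (is.null(blocks)) {
      Stt <- corr_block(panel, typed, typed)$R
      Sut <- corr_block(panel, w$targets, typed)$R
    } else {
      Stt <- blocks[[wi]]$Stt$R
      Sut <- blocks[[wi]]$Sut$R
    }
    Zt <- v$z[typed]
    res <- tryCatch(
      impute_window(Zt, Stt, Sut, lam = lam),
      error = function(e) {
        keep <- prune_collinear(Stt)
        if (length(keep) == length(typed)) stop(e)
        message(sprintf(
          "impute_all: pruned %d collinear typed variant(s) in window %d",
          length(typed) - length(keep), wi))
        impute_window(Zt[keep], Stt[keep, keep, drop = FALSE],
                      Sut[, keep, drop = FALSE], lam = lam)
      })
    tibble::tibble(idx = w$targets, z = res$z, r2pred = res$r2pred,
                   n_typed_used = length(typed))
  })
  imp <- dplyr::bind_rows(target_rows)

  out <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, a1 = v$alt, a2 = v$ref,
    z = v$z, r2pred = NA_real_, n_typed_used = NA_integer_,
    status = ifelse(v$typed, "typed", "skipped")
  )
  out$r2pred[v$typed] <- 1
  if (nrow(imp) > 0) {
    ok <- imp$r2pred >= min_r2pred
    out$z[imp$idx] <- ifelse(ok, imp$z, NA_real_)
    out$r2pred[imp$idx] <- imp$r2pred
    out$n_typed_used[imp$idx] <- imp$n_typed_used
    out$status[imp$idx] <- ifelse(ok, "imputed", "skipped")
  }
  out$p <- ifelse(is.na(out$z), NA_real_, z_to_p(ifelse(is.na(out$z), 0, out$z)))
  if (rescale) {
    out$z_rescaled <- ifelse(out$status == "imputed" & out$r2pred > 0,
                             out$z / sqrt(out$r2pred), out$z)
  }
  cols <- c("chrom", "pos", "a1", "a2", "z", "p", "r2pred", "n_typed_used",
            "status", if (rescale) "z_rescaled")
  out[, cols]
}

#' Impute summary statistics against a reference panel
#'
#' The front door of the package: takes a summary-statistics table and a
#' reference panel, harmonizes alleles, runs the windowed conditional-mean
#' imputation, and returns a fitted-result object with [generics::tidy()],
#' [generics::glance()] and [ggplot2::autoplot()] methods.
#'
#' @inheritParams impute_all
#' @param sumstats Tibble from [read_sumstats()], or any data frame with
#'   columns `chrom`, `pos`, `a1`, `a2`, `z`.
#' @param keep_ambiguous Passed to [harmonize()].
#' @return A `zimpute_result`: list with `results` (the [impute_all()]
#'   tibble), `harmonization` (flip-class counts), and `params`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_hap = 200, n_snp = 150, n_subj = 300, seed = 7)
#' sim <- simulate_gwas(cfg)
#' fit <- impute_sumstats(sim$observed, sim$panel, pred_size = 50, flank_size = 50)
#' generics::glance(fit)
#' }
impute_sumstats <- function(sumstats, panel, pred_size = 100, flank_size = 250,
                            lam = 1e-3, min_r2pred = 0.3,
                            keep_ambiguous = FALSE, cache = NULL,
                            rescale = FALSE) {
  hset <- harmonize(sumstats, panel, keep_ambiguous = keep_ambiguous)
  results <- impute_all(hset, panel, pred_size = pred_size,
                        flank_size = flank_size, lam = lam,
                        min_r2pred = min_r2pred, cache = cache,
                        rescale = rescale)
  structure(
    list(results = results, harmonization = hset$counts,
         params = list(pred_size = pred_size, flank_size = flank_size,
                       lam = lam, min_r2pred = min_r2pred,
                       keep_ambiguous = keep_ambiguous, rescale = rescale),
         panel_checksum = panel_checksum(panel)),
    class = "zimpute_result"
  )
}

#' @export
print.zimpute_result <- function(x, ...) {
  n_of <- function(s) sum(x$results$status == s)
  cat(sprintf("<zimpute_result> %d variants: %d typed, %d imputed, %d skipped\n",
              nrow(x$results), n_of("typed"), n_of("imputed"), n_of("skipped")))
  imp <- x$results[x$results$status == "imputed", ]
  if (nrow(imp) > 0) {
    cat(sprintf("  imputation quality r2pred: median %.3f [IQR %.3f-%.3f]\n",
                stats::median(imp$r2pred),
                stats::quantile(imp$r2pred, 0.25),
                stats::quantile(imp$r2pred, 0.75)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname impute_sumstats
#' @param x A `zimpute_result`.
#' @param ... Unused.
#' @method tidy zimpute_result
#' @export
tidy.zimpute_result <- function(x, ...) x$results

#' @rdname impute_sumstats
#' @method glance zimpute_result
#' @export
glance.zimpute_result <- function(x, ...) {
  imp <- x$results[x$results$status == "imputed", ]
  tibble::tibble(
    n_variants = nrow(x$results),
    n_typed = sum(x$results$status == "typed"),
    n_imputed = nrow(imp),
    n_skipped = sum(x$results$status == "skipped"),
    mean_r2pred = if (nrow(imp) > 0) mean(imp$r2pred) else NA_real_,
    median_r2pred = if (nrow(imp) > 0) stats::median(imp$r2pred) else NA_real_
  )
}

#' Plot an imputation result
#'
#' `type = "r2pred"` draws the distribution of imputation quality across
#' imputed variants; `type = "manhattan"` draws -log10(p) along the
#' chromosome, coloring typed and imputed variants.
#'
#' @param object A `zimpute_result`.
#' @param type One of `"r2pred"`, `"manhattan"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zimpute_result <- function(object, type = c("r2pred", "manhattan"), ...) {
  type <- match.arg(type)
  res <- object$results
  if (type == "r2pred") {
    dat <- res[res$status == "imputed", ]
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$r2pred)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
      ggplot2::labs(x = "imputation quality (r2pred)", y = "variants") +
      ggplot2::theme_minimal()
  } else {
    dat <- res[res$status != "skipped", ]
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                      color = .data$status)) +
      ggplot2::geom_point(size = 0.7, alpha = 0.7) +
      ggplot2::facet_wrap(~chrom, scales = "free_x") +
      ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
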