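#' One-class SAM d statistic
#'
#' Relative difference score of a gene's replicate log ratios:
#' `d = mean(x) / (sd(x)/sqrt(n) + s0)`. The sign carries the direction; the
#' fudge constant `s0` stabilizes the score for low-variance genes. At
#' `s0 = 0` the score equals the one-sample t statistic.
#'
#' @param values Numeric vector of replicate log2 ratios (>= 2 values).
#' @param s0 Fudge constant, >= 0.
#' @return The d score.
#' @export
sam_d_statistic <- function(values, s0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("d statistic needs at least 2 replicate values", call. = FALSE)
  }
  mean(values) / (stats::sd(values) / sqrt(length(values)) + s0)
}

# Row-wise means, scatters (sd/sqrt(n)) and d over a genes x replicates
# matrix with missing values.
sam_row_stats <- function(x, s0 = 0) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  sq <- rowSums(x^2, na.rm = TRUE)
  sdev <- sqrt(pmax(sq - n * m^2, 0) / pmax(n - 1, 1))
  s <- sdev / sqrt(n)
  list(n = n, mean = m, s = s, d = m / (s + s0))
}

#' Choose the SAM fudge constant s0
#'
#' Tusher-style search: candidate values are percentiles of the per-gene
#' scatters `s`; for each candidate the coefficient of variation of the d
#' scores is evaluated across s-quantile windows, and the candidate
#' minimizing it is chosen. Without the gene means (needed to form d) the
#' documented fallback `median(s)` is returned.
#'
#' @param per_gene_sds Per-gene scatter values `s_i = sd_i / sqrt(n_i)`
#'   (>= 10 genes).
#' @param means Optional per-gene means (same length). `NULL` triggers the
#'   median fallback.
#' @param alphas Candidate percentiles scanned (default 0, 0.05, ..., 1).
#' @return The chosen s0 (>= 0).
#' @export
choose_s0 <- function(per_gene_sds, means = NULL,
                      alphas = seq(0, 1, by = 0.05)) {
  s <- per_gene_sds
  keep <- is.finite(s)
  s <- s[keep]
  if (length(s) < 10L) stop("choose_s0 needs at least 10 genes", call. = FALSE)
  if (max(s) - min(s) < .Machine$double.eps * max(abs(s), 1)) {
    return(s[1L])  # degenerate: all scatters equal
  }
  if (is.null(means)) {
    return(stats::median(s))
  }
  m <- means[keep]
  n_windows <- if (length(s) >= 1000L) 100L else 10L
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows, labels = FALSE)
  cv <- vapply(alphas, function(a) {
    s0 <- stats::quantile(s, a, names = FALSE)
    d <- m / (s + s0)
    mads <- tapply(d, win, stats::mad)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  stats::quantile(s, alphas[which.min(cv)], names = FALSE)
}

#' Fit one-class SAM with a sign-flip permutation null
#'
#' Computes the observed d scores and the permutation-expected order
#' statistics. The null flips the signs of the replicate columns jointly
#' across genes: exhaustively (all `2^n` patterns, 64 for six replicates)
#' when `n <= max_exhaustive`, otherwise `n_random` random patterns drawn
#' from a fixed seed. Genes with fewer than `min_usable` usable values are
#' excluded and reported.
#'
#' @param x Numeric matrix, genes x replicates, of log2 ratios (`NA`
#'   allowed); rownames are gene ids.
#' @param s0 Fudge constant; `NULL` (default) chooses it via [choose_s0()].
#' @param max_exhaustive Largest replicate count for exhaustive sign
#'   flips (default 10).
#' @param n_random Random flip patterns beyond that (default 1000).
#' @param min_usable Evaluability floor on usable replicates (default 4).
#' @param seed Seed for the random-flip branch.
#' @return A `sam_fit` list: `d` (named, sorted ascending), `s`, `s0`,
#'   `d_expected` (expected order statistics), `d_perm` (permuted sorted d,
#'   genes x permutations), `n_permutations`, `excluded` (gene ids).
#' @export
sam_fit <- function(x, s0 = NULL, max_exhaustive = 10, n_random = 1000,
                    min_usable = 4, seed = 1L) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  usable <- rowSums(!is.na(x))
  excluded <- rownames(x)[usable < min_usable]
  x <- x[usable >= min_usable, , drop = FALSE]
  if (nrow(x) < 10L) stop("SAM needs at least 10 evaluable genes", call. = FALSE)
  obs <- sam_row_stats(x)
  if (is.null(s0)) s0 <- choose_s0(obs$s, obs$mean)
  d <- obs$mean / (obs$s + s0)
  names(d) <- rownames(x)

  n_rep <- ncol(x)
  if (n_rep <= max_exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_rep)))
  } else {
    set.seed(derive_seed(seed, "sam_flips"))
    flips <- matrix(sample(c(-1, 1), n_random * n_rep, replace = TRUE),
                    nrow = n_random)
  }
  d_perm <- apply(flips, 1L, function(eps) {
    st <- sam_row_stats(sweep(x, 2L, eps, `*`), s0 = s0)
    sort(st$d)
  })
  ord <- order(d)
  structure(list(d = d[ord],
                 s = stats::setNames(obs$s, rownames(x))[ord],
                 s0 = s0,
                 d_expected = rowMeans(d_perm),
                 d_perm = d_perm,
                 n_permutations = nrow(flips),
                 excluded = excluded),
            class = "sam_fit")
}

#' Call genes and estimate the FDR at a significance threshold delta
#'
#' Observed d scores (sorted) are compared with the permutation-expected
#' order statistics. On the positive side the cut point is the smallest
#' non-negative d whose excess over its expected value reaches `delta`; all
#' genes at or above it are called up (symmetrically below for down calls).
#' At `delta = 0` the band is vacuous and every evaluated gene is called.
#' False calls are counted per permutation as permuted d beyond the cut
#' points; the FDR estimate is the median false-call count over permutations
#' divided by the number of observed calls (the 90th-percentile variant is
#' reported alongside).
#'
#' @param fit A `sam_fit` from [sam_fit()].
#' @param delta Threshold, >= 0.
#' @return A `sam_result` list: `delta`, `s0`, `called` (data frame gene,
#'   d, s, direction), `cutup`, `cutlow`, `estimated_fdr`, `fdr_90`,
#'   `n_called`, `n_permutations`, `no_calls` flag, `excluded`.
#' @export
sam_call <- function(fit, delta) {
  stopifnot(inherits(fit, "sam_fit"), delta >= 0)
  d <- fit$d
  diff <- d - fit$d_expected
  if (delta == 0) {
    cutup <- -Inf
    cutlow <- Inf
    called_up <- d >= 0
    called_down <- d < 0
  } else {
    up_cand <- d >= 0 & diff >= delta
    down_cand <- d <= 0 & diff <= -delta
    cutup <- if (any(up_cand)) min(d[up_cand]) else Inf
    cutlow <- if (any(down_cand)) max(d[down_cand]) else -Inf
    called_up <- d >= cutup
    called_down <- d <= cutlow
  }
  called <- data.frame(
    gene_id = names(d)[called_up | called_down],
    d = unname(d[called_up | called_down]),
    s = unname(fit$s[called_up | called_down]),
    direction = c("down", "up")[(d[called_up | called_down] >= 0) + 1L],
    stringsAsFactors = FALSE
  )
  n_called <- nrow(called)
  false_per_perm <- colSums(fit$d_perm >= cutup | fit$d_perm <= cutlow)
  if (n_called == 0L) {
    est <- 0
    f90 <- 0
  } else {
    est <- stats::median(false_per_perm) / n_called
    f90 <- stats::quantile(false_per_perm, 0.9, names = FALSE) / n_called
  }
  structure(list(delta = delta, s0 = fit$s0, called = called,
                 cutup = cutup, cutlow = cutlow,
                 estimated_fdr = est, fdr_90 = f90,
                 n_called = n_called,
                 n_permutations = fit$n_permutations,
                 no_calls = n_called == 0L,
                 excluded = fit$excluded),
            class = "sam_result")
}

#' One-class SAM with permutation FDR at a given delta
#'
#' Convenience wrapper: [sam_fit()] followed by [sam_call()].
#'
#' @inheritParams sam_fit
#' @param delta Significance threshold, >= 0.
#' @return A `sam_result` (see [sam_call()]).
#' @export
sam_permutation_fdr <- function(x, delta, s0 = NULL, max_exhaustive = 10,
                                n_random = 1000, min_usable = 4, seed = 1L) {
  fit <- sam_fit(x, s0 = s0, max_exhaustive = max_exhaustive,
                 n_random = n_random, min_usable = min_usable, seed = seed)
  sam_call(fit, delta)
}

#' Choose delta for a target false positive rate
#'
#' Scans a grid of thresholds and returns the smallest delta whose estimated
#' FDR is at or below `target_fdr`. If none qualifies, the largest scanned
#' delta is returned with `achieved = FALSE`.
#'
#' @param fit A `sam_fit`, or a genes x replicates matrix (then fitted with
#'   defaults).
#' @param target_fdr Desired false positive rate, in (0, 1]; default 0.05.
#' @param grid_size Number of thresholds scanned (default 101, from 0 to the
#'   largest observed-vs-expected excess).
#' @return List with `delta`, `estimated_fdr`, `n_called`, `achieved` and the
#'   scanned `table` (delta, fdr, calls).
#' @export
choose_delta <- function(fit, target_fdr = 0.05, grid_size = 101) {
  if (!inherits(fit, "sam_fit")) fit <- sam_fit(fit)
  stopifnot(target_fdr > 0, target_fdr <= 1)
  dmax <- max(abs(fit$d - fit$d_expected))
  grid <- seq(0, dmax * 1.001, length.out = grid_size)
  scan <- lapply(grid, function(dl) {
    r <- sam_call(fit, dl)
    data.frame(delta = dl, estimated_fdr = r$estimated_fdr,
               n_called = r$n_called)
  })
  tab <- do.call(rbind, scan)
  ok <- which(tab$estimated_fdr <= target_fdr)
  if (length(ok)) {
    i <- ok[1L]
    list(delta = tab$delta[i], estimated_fdr = tab$estimated_fdr[i],
         n_called = tab$n_called[i], achieved = TRUE, table = tab)
  } else {
    i <- nrow(tab)
    warning("no scanned delta reaches the target FDR; returning the largest")
    list(delta = tab$delta[i], estimated_fdr = tab$estimated_fdr[i],
         n_called = tab$n_called[i], achieved = FALSE, table = tab)
  }
}
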