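#' Calibrate the fold-change threshold from self-self ratios
#'
#' The spread of linear ratios in a self-self hybridization measures pure
#' technical noise. The up-regulation threshold is set two standard
#' deviations above unity, `1 + 2 * sigma` (approximately a 95% confidence
#' band for no change), and the down threshold is its reciprocal rounded to
#' two decimals. With the calibrated sigma of 0.25 this yields the 1.5 /
#' 0.67 criterion.
#'
#' @param self_self_ratios Numeric vector of linear ratios (>= 2 values).
#' @return A `calibration_result` list with `sigma`, `up_threshold`,
#'   `down_threshold`.
#' @export
calibrate_fold_threshold <- function(self_self_ratios) {
  ratios <- self_self_ratios[is.finite(self_self_ratios)]
  if (length(ratios) < 2L) {
    stop("calibration error: need at least 2 self-self ratios", call. = FALSE)
  }
  sigma <- stats::sd(ratios)
  fold_thresholds(sigma)
}

#' Fold-change thresholds from a known ratio SD
#'
#' @param sigma SD of self-self linear ratios.
#' @return A `calibration_result` list.
#' @export
fold_thresholds <- function(sigma) {
  stopifnot(sigma >= 0)
  up <- 1 + 2 * sigma
  structure(list(sigma = sigma,
                 up_threshold = up,
                 down_threshold = round(1 / up, 2)),
            class = "calibration_result")
}

#' Reconcile a dye-swap pair into one replicate ratio
#'
#' A channel-specific dye bias enters the forward and swapped log ratios with
#' opposite sign; averaging the sign-reconciled log ratios cancels it. The
#' replicate's linear ratio is `2^((forward_M - swapped_M) / 2)`. If only one
#' orientation passed QC its single measurement is used; if neither, the
#' replicate is missing (`NA`).
#'
#' @param forward_m,swapped_m Normalized log2 ratios (`NA` where the
#'   measurement is unusable). Vectorized over features.
#' @return Linear test/reference ratios.
#' @export
reconcile_dye_swap <- function(forward_m, swapped_m) {
  both <- !is.na(forward_m) & !is.na(swapped_m)
  only_f <- !is.na(forward_m) & is.na(swapped_m)
  only_s <- is.na(forward_m) & !is.na(swapped_m)
  out <- rep(NA_real_, length(forward_m))
  out[both] <- 2^((forward_m[both] - swapped_m[both]) / 2)
  out[only_f] <- 2^forward_m[only_f]
  out[only_s] <- 2^(-swapped_m[only_s])
  out
}

#' Call differential expression by replicate consensus
#'
#' A gene is called up if at least `min_support` of its usable replicate
#' ratios exceed the calibrated up threshold, down if at least `min_support`
#' fall below the down threshold; otherwise the call is `"none"`. Mixed
#' directions never combine into a call. Mean, SD and SEM are computed over
#' all usable ratios. A gene with fewer than `min_support` usable replicates
#' is non-evaluable (`NA` direction), distinct from a definite `"none"`.
#'
#' @param ratios Numeric vector of linear replicate ratios (`NA` = missing).
#' @param calibration A `calibration_result` (see [calibrate_fold_threshold()]).
#' @param min_support Minimum number of concordant datasets; default
#'   [default_min_support()] of the replicate count.
#' @return A one-row data frame: `direction`, `mean_fold_change`, `sd`,
#'   `sem`, `support_count`, `usable_count`, `evaluable`.
#' @export
call_de_foldchange <- function(ratios, calibration,
                               min_support = default_min_support(length(ratios))) {
  usable <- ratios[!is.na(ratios)]
  n <- length(usable)
  n_up <- sum(usable > calibration$up_threshold)
  n_down <- sum(usable < calibration$down_threshold)
  if (n < min_support) {
    return(data.frame(direction = NA_character_, mean_fold_change = NA_real_,
                      sd = NA_real_, sem = NA_real_, support_count = NA_integer_,
                      usable_count = n, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  }
  # passes must share one direction: any opposite-direction pass voids the call
  direction <- if (n_up >= min_support && n_down == 0L) "up"
               else if (n_down >= min_support && n_up == 0L) "down"
               else "none"
  s <- stats::sd(usable)
  data.frame(direction = direction,
             mean_fold_change = mean(usable),
             sd = s,
             sem = s / sqrt(n),
             support_count = max(n_up, n_down),
             usable_count = n,
             evaluable = TRUE,
             stringsAsFactors = FALSE)
}

#' Consensus support required for a replicate count
#'
#' The printed rule is 5 of 6 datasets; for other replicate counts it scales
#' as `ceiling(5/6 * n)`.
#'
#' @param n_replicates Number of replicate datasets.
#' @return Integer count.
#' @export
default_min_support <- function(n_replicates = 6) {
  as.integer(ceiling(5 / 6 * n_replicates))
}

#' Consensus fold-change calls for a ratio matrix
#'
#' Vectorized [call_de_foldchange()] over the genes of one comparison.
#'
#' @param ratio_matrix Numeric matrix, genes x replicates, of linear ratios
#'   with `NA` for missing replicates; rownames are gene ids.
#' @param calibration A `calibration_result`.
#' @param min_support Consensus count (default from the column count).
#' @return Data frame with one row per gene (`gene_id`, `direction`,
#'   `mean_fold_change`, `sd`, `sem`, `support_count`, `usable_count`,
#'   `evaluable`).
#' @export
call_de_table <- function(ratio_matrix, calibration,
                          min_support = default_min_support(ncol(ratio_matrix))) {
  stopifnot(is.matrix(ratio_matrix), !is.null(rownames(ratio_matrix)))
  usable <- !is.na(ratio_matrix)
  n <- rowSums(usable)
  n_up <- rowSums(ratio_matrix > calibration$up_threshold, na.rm = TRUE)
  n_down <- rowSums(ratio_matrix < calibration$down_threshold, na.rm = TRUE)
  mean_fc <- rowMeans(ratio_matrix, na.rm = TRUE)
  sq <- rowSums(ratio_matrix^2, na.rm = TRUE)
  sds <- sqrt(pmax(sq - n * mean_fc^2, 0) / pmax(n - 1, 1))
  sds[n < 2] <- NA_real_
  evaluable <- n >= min_support
  direction <- rep("none", nrow(ratio_matrix))
  direction[n_up >= min_support & n_down == 0L] <- "up"
  direction[n_down >= min_support & n_up == 0L] <- "down"
  direction[!evaluable] <- NA_character_
  data.frame(gene_id = rownames(ratio_matrix),
             direction = direction,
             mean_fold_change = ifelse(n > 0, mean_fc, NA_real_),
             sd = sds,
             sem = sds / sqrt(n),
             support_count = ifelse(evaluable, pmax(n_up, n_down), NA_integer_),
             usable_count = n,
             evaluable = evaluable,
             stringsAsFactors = FALSE, row.names = NULL)
}
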