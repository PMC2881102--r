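#' QC policy for a single hybridization
#'
#' Encodes the stringency filters applied before any ratio analysis: flagged
#' features are always removed; a feature must reach `min_intensity` in
#' either (or both, depending on `channel_rule`) of the red and green
#' channels; and the whole array is rejected unless its normalization factor
#' (ratio of the channel medians) lies inside `norm_factor_window` (closed
#' interval).
#'
#' @param min_intensity Minimum absolute hybridization intensity (default 200).
#' @param norm_factor_window Closed acceptance interval for the
#'   median-ratio normalization factor (default `c(0.8, 1.2)`).
#' @param channel_rule `"either"` (default: one channel at `min_intensity`
#'   suffices) or `"both"`.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_intensity = 200, norm_factor_window = c(0.8, 1.2),
                      channel_rule = c("either", "both")) {
  channel_rule <- match.arg(channel_rule)
  if (min_intensity < 0) stop("min_intensity must be >= 0", call. = FALSE)
  if (length(norm_factor_window) != 2L ||
      norm_factor_window[1L] > norm_factor_window[2L]) {
    stop("norm_factor_window must be an interval c(lower, upper)", call. = FALSE)
  }
  structure(list(min_intensity = min_intensity,
                 norm_factor_window = norm_factor_window,
                 channel_rule = channel_rule),
            class = "qc_policy")
}

#' Normalization factor of an array
#'
#' Ratio of the median red (F635) to median green (F532) intensity over
#' unflagged features. Arrays whose factor falls outside the policy window
#' are rejected as poorly balanced hybridizations.
#'
#' @param array A [two_color_array()].
#' @return The dimensionless median ratio.
#' @export
compute_normalization_factor <- function(array) {
  stopifnot(inherits(array, "two_color_array"))
  ok <- array$features$flag == 0L
  if (!any(ok)) stop("QC error: all features flagged", call. = FALSE)
  stats::median(array$features$f635[ok]) / stats::median(array$features$f532[ok])
}

#' Apply the stringency filters to one array
#'
#' Removes all flagged features, then applies the minimum-intensity rule,
#' and evaluates array-level acceptance from the normalization factor.
#' Rejection is a reported state, not an error.
#'
#' @param array A [two_color_array()].
#' @param policy A [qc_policy()].
#' @return List with fields `passed` (logical per feature of the input
#'   array), `accepted` (array-level), `norm_factor`, `n_flagged`,
#'   `n_low_intensity`, `n_retained`.
#' @export
apply_qc_filters <- function(array, policy = qc_policy()) {
  stopifnot(inherits(array, "two_color_array"), inherits(policy, "qc_policy"))
  f <- array$features
  unflagged <- f$flag == 0L
  bright <- if (policy$channel_rule == "either") {
    f$f635 >= policy$min_intensity | f$f532 >= policy$min_intensity
  } else {
    f$f635 >= policy$min_intensity & f$f532 >= policy$min_intensity
  }
  passed <- unflagged & bright
  nf <- compute_normalization_factor(array)
  accepted <- nf >= policy$norm_factor_window[1L] &&
    nf <= policy$norm_factor_window[2L]
  list(passed = passed,
       accepted = accepted,
       norm_factor = nf,
       n_flagged = sum(!unflagged),
       n_low_intensity = sum(unflagged & !bright),
       n_retained = sum(passed))
}

#' M/A values of an array
#'
#' Per-feature `M = log2(F635 / F532)` and `A = (log2 F635 + log2 F532) / 2`.
#' `M` is oriented red-over-green regardless of dye orientation; dye-swap
#' reconciliation handles the sign. Features that failed QC get `NA`.
#'
#' @param array A [two_color_array()].
#' @param passed Logical vector marking QC-passed features (default: all).
#' @return A `normalized_ratios` list with `feature_id`, `m`, `a`,
#'   `passed_qc` and a `normalized` flag.
#' @export
ma_values <- function(array, passed = rep(TRUE, nrow(array$features))) {
  f <- array$features
  m <- a <- rep(NA_real_, nrow(f))
  ok <- passed & f$f635 > 0 & f$f532 > 0
  m[ok] <- log2(f$f635[ok] / f$f532[ok])
  a[ok] <- (log2(f$f635[ok]) + log2(f$f532[ok])) / 2
  structure(list(feature_id = f$feature_id, m = m, a = a, passed_qc = ok,
                 normalized = FALSE),
            class = "normalized_ratios")
}

#' Loess (MA) normalization
#'
#' Removes the intensity-dependent trend of the log ratios: `M` is replaced
#' by the residual of a robust degree-1 local regression of `M` on `A`
#' (tricube weights, robustness iterations), leaving `A` and the feature
#' order untouched. Only QC-passed features enter the fit or are normalized.
#'
#' @param ratios A `normalized_ratios` object from [ma_values()].
#' @param span Loess span as a fraction of the data (default 0.4, a
#'   conventional MA-normalization setting).
#' @param iterations Robustness iterations of the fit (default 3).
#' @return The input with `m` detrended and `normalized = TRUE`.
#' @export
loess_normalize <- function(ratios, span = 0.4, iterations = 3) {
  stopifnot(inherits(ratios, "normalized_ratios"))
  ok <- ratios$passed_qc & is.finite(ratios$m) & is.finite(ratios$a)
  n <- sum(ok)
  if (n < max(10, ceiling(span * n))) {
    stop("normalization error: too few passed features (", n, ")", call. = FALSE)
  }
  fit <- stats::lowess(ratios$a[ok], ratios$m[ok], f = span, iter = iterations)
  # lowess returns values sorted by A; map fitted values back to input order
  trend <- numeric(n)
  trend[order(ratios$a[ok])] <- fit$y
  out <- ratios
  out$m[ok] <- ratios$m[ok] - trend
  out$normalized <- TRUE
  out
}

#' QC and normalize one array
#'
#' Convenience wrapper running [apply_qc_filters()], [ma_values()] and
#' [loess_normalize()]; the pipeline's per-array stage.
#'
#' @param array A [two_color_array()].
#' @param policy A [qc_policy()].
#' @param span,iterations Passed to [loess_normalize()].
#' @return List with `ratios` (normalized), `qc` (filter report) and
#'   `accepted`.
#' @export
normalize_array <- function(array, policy = qc_policy(), span = 0.4,
                            iterations = 3) {
  qc <- apply_qc_filters(array, policy)
  ratios <- loess_normalize(ma_values(array, qc$passed), span = span,
                            iterations = iterations)
  list(ratios = ratios, qc = qc, accepted = qc$accepted)
}
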