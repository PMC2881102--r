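#' Relative expression of one biological sample by comparative CT
#'
#' Technical replicates are averaged on the Ct scale within each experiment,
#' experiment means are averaged, and the expression of the target relative
#' to the reference gene (GAPDH) from the same sample is
#' `efficiency^(mean Ct_reference - mean Ct_target)` (efficiency 2 assumes
#' perfect doubling per cycle).
#'
#' @param ct_target,ct_reference Numeric Ct vectors of the technical
#'   replicates (`NA` allowed).
#' @param experiment Optional experiment index per measurement (same length);
#'   default treats all measurements as one experiment.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return The normalized expression ratio.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     experiment = rep(1L, length(ct_target)),
                                     efficiency = 2) {
  if (all(is.na(ct_reference))) {
    stop("sample excluded: missing reference Ct", call. = FALSE)
  }
  if (all(is.na(ct_target))) {
    stop("sample excluded: missing target Ct", call. = FALSE)
  }
  per_exp <- function(ct) {
    m <- tapply(ct, experiment, mean, na.rm = TRUE)
    mean(m[is.finite(m)])
  }
  efficiency^(per_exp(ct_reference) - per_exp(ct_target))
}

#' Per-sample relative expression table from a Ct table
#'
#' Applies [qpcr_relative_expression()] to every biological sample of a Ct
#' table in the layout of [generate_qpcr_table()].
#'
#' @param ct_table Data frame with columns `sample_id`, `group`,
#'   `experiment`, `ct_target`, `ct_reference`.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return Data frame `sample_id`, `group`, `expression`.
#' @export
qpcr_sample_expression <- function(ct_table, efficiency = 2) {
  samples <- unique(ct_table[, c("sample_id", "group")])
  samples$expression <- vapply(samples$sample_id, function(s) {
    rows <- ct_table[ct_table$sample_id == s, ]
    qpcr_relative_expression(rows$ct_target, rows$ct_reference,
                             rows$experiment, efficiency)
  }, numeric(1))
  rownames(samples) <- NULL
  samples
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test with an exact two-sided p value obtained by full
#' enumeration of all `choose(n1 + n2, n1)` group labelings when the
#' combined sample size is at most `exact_limit` (ties handled by mid-ranks
#' within the enumeration), and by a normal approximation with tie
#' correction and continuity correction beyond that.
#'
#' The statistic is `U = sum over pairs of [x > y] + 0.5 [x == y]` for
#' group 1 vs group 2; the two-sided p value is the probability, under
#' random labeling, of a U at least as extreme in either tail.
#'
#' @param group1,group2 Non-empty numeric vectors.
#' @param exact_limit Largest combined n for exact enumeration (default 14).
#' @return List with `u`, `p_value` and `method` (`"exact"` or
#'   `"normal_approximation"`).
#' @export
mann_whitney_exact <- function(group1, group2, exact_limit = 14) {
  x <- group1[!is.na(group1)]
  y <- group2[!is.na(group2)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty group", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)   # mid-ranks for ties
  u_from_idx <- function(idx1) {
    sum(r[idx1]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_from_idx(seq_len(n1))
  if (n1 + n2 <= exact_limit) {
    labelings <- utils::combn(n1 + n2, n1)
    u_all <- apply(labelings, 2L, u_from_idx)
    u_low <- min(u_obs, n1 * n2 - u_obs)
    eps <- 1e-9
    p <- (sum(u_all <= u_low + eps) + sum(u_all >= n1 * n2 - u_low - eps)) /
      ncol(labelings)
    list(u = u_obs, p_value = min(p, 1), method = "exact")
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    list(u = u_obs, p_value = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal_approximation")
  }
}

#' Group comparison of qPCR expression with exact Mann-Whitney tests
#'
#' Computes per-sample normalized expression and tests a pair of groups, the
#' per-gene report of the validation assay.
#'
#' @param ct_table Ct table (see [generate_qpcr_table()]).
#' @param groups Character vector of two group labels to compare.
#' @param efficiency Amplification factor per cycle.
#' @return Data frame with group means, `u` and `p_value`.
#' @export
qpcr_compare_groups <- function(ct_table, groups, efficiency = 2) {
  stopifnot(length(groups) == 2L)
  expr <- qpcr_sample_expression(ct_table, efficiency)
  g1 <- expr$expression[expr$group == groups[1L]]
  g2 <- expr$expression[expr$group == groups[2L]]
  test <- mann_whitney_exact(g1, g2)
  data.frame(group1 = groups[1L], group2 = groups[2L],
             mean1 = mean(g1), mean2 = mean(g2),
             ratio = mean(g1) / mean(g2),
             u = test$u, p_value = test$p_value, method = test$method,
             stringsAsFactors = FALSE)
}

#' ChIP-qPCR fold enrichment over input by comparative CT
#'
#' The input Ct is first adjusted for the fraction of chromatin reserved as
#' input (`ct_input - log2(input_fraction)`, on the cycle scale); the n-fold
#' enrichment of antibody-bound chromatin over input is then
#' `2^-(ct_ip - adjusted input Ct)`.
#'
#' @param ct_ip Ct of the immunoprecipitated chromatin.
#' @param ct_input Ct of the input chromatin.
#' @param input_fraction Fraction of chromatin reserved as input, in (0, 1].
#' @return The fold enrichment.
#' @export
chip_fold_enrichment <- function(ct_ip, ct_input, input_fraction = 1) {
  if (any(input_fraction <= 0)) stop("input_fraction must be > 0", call. = FALSE)
  if (any(input_fraction > 1)) stop("input_fraction must be <= 1", call. = FALSE)
  2^(-(ct_ip - (ct_input - log2(input_fraction))))
}

#' Fit a first-order rate constant to a kinetics trace
#'
#' The decay of absorbance toward the plateau is log-linearized,
#' `ln(A(t) - a_inf)`, and the rate constant is the negated slope of its
#' least-squares regression on time, divided by the protein amount
#' (rate/minute/mg protein). Points at or below the plateau are dropped, as
#' are near-plateau points below `min_amplitude_frac` of the initial
#' amplitude, where the log transform amplifies noise. If the plateau is not
#' supplied it is estimated as the mean of the trailing 10% of the trace.
#'
#' @param trace Data frame with columns `time` (minutes) and `absorbance`.
#' @param a_inf Plateau absorbance; `NULL` to estimate from the trace tail.
#' @param protein_mg Protein amount in mg (default 1).
#' @param min_amplitude_frac Fraction of the initial amplitude below which
#'   points are excluded from the fit (default 0.02, about 5.6 half-lives).
#' @return List with `k` (per minute per mg), `a_inf`, `a_inf_estimated`,
#'   `n_points` used.
#' @export
fit_first_order_rate <- function(trace, a_inf = NULL, protein_mg = 1,
                                 min_amplitude_frac = 0.02) {
  stopifnot(all(c("time", "absorbance") %in% names(trace)), protein_mg > 0)
  estimated <- is.null(a_inf)
  if (estimated) {
    tail_n <- max(1L, ceiling(nrow(trace) * 0.1))
    a_inf <- mean(utils::tail(trace$absorbance, tail_n))
  }
  amplitude <- max(trace$absorbance) - a_inf
  keep <- trace$absorbance - a_inf > min_amplitude_frac * amplitude
  if (sum(keep) < 3L) {
    stop("fit error: fewer than 3 points above the plateau", call. = FALSE)
  }
  fit <- stats::lm(log(absorbance - a_inf) ~ time, data = trace[keep, ])
  list(k = -unname(stats::coef(fit)[2L]) / protein_mg,
       a_inf = a_inf,
       a_inf_estimated = estimated,
       n_points = sum(keep))
}

#' Cytochrome c oxidase activity normalized to citrate synthase
#'
#' Citrate synthase activity proxies mitochondrial content; the COX/CS ratio
#' removes between-sample variation in mitochondrial numbers.
#'
#' @param cox_k COX first-order rate constant (per minute per mg protein).
#' @param cs_activity Citrate synthase specific activity (nmol/min/mg), > 0.
#' @return The dimensionless ratio `cox_k / cs_activity`.
#' @export
cox_cs_ratio <- function(cox_k, cs_activity) {
  if (any(cs_activity <= 0)) stop("cs_activity must be > 0", call. = FALSE)
  cox_k / cs_activity
}
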