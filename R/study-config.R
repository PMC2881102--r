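#' Comparison labels of the four-arm regional study design
#'
#' The design crosses disease status (RTT vs control, CON) with brain region
#' (frontal cortex, fc; occipital cortex, oc) into four co-hybridization
#' comparisons:
#'
#' * `RTTfc_vs_CONfc` (a): disease frontal cortex vs control frontal cortex,
#' * `RTTfc_vs_RTToc` (b): disease frontal cortex vs disease occipital cortex,
#' * `RTToc_vs_CONoc` (d): disease occipital cortex vs control occipital cortex,
#' * `CONfc_vs_CONoc` (c): control frontal vs control occipital cortex.
#'
#' Genes exclusive to the disease frontal cortex are those called in (a) and
#' (b) but not in (c); (d) is reported but does not enter the subtraction.
#'
#' @return Character vector of the four comparison labels.
#' @export
comparison_labels <- function() {
  c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc", "RTToc_vs_CONoc", "CONfc_vs_CONoc")
}

#' Describe a planted differential-expression effect
#'
#' @param gene_id Feature identifier the effect is planted on.
#' @param comparisons_affected Character vector, subset of
#'   [comparison_labels()], naming the comparisons in which the test sample
#'   carries the effect.
#' @param fold_change Linear test/reference ratio, > 0. Values > 1 are
#'   up-regulation in the test sample, < 1 down-regulation.
#' @return A `planted_effect` list with fields `gene_id`,
#'   `comparisons_affected`, `fold_change` and derived `direction`.
#' @export
planted_effect <- function(gene_id, comparisons_affected, fold_change) {
  if (!is.numeric(fold_change) || length(fold_change) != 1L || fold_change <= 0) {
    stop("invalid configuration field 'fold_change': must be a single ratio > 0",
         call. = FALSE)
  }
  bad <- setdiff(comparisons_affected, comparison_labels())
  if (length(bad)) {
    stop("invalid configuration field 'comparisons_affected': unknown label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(gene_id = as.character(gene_id),
         comparisons_affected = comparisons_affected,
         fold_change = fold_change,
         direction = if (fold_change > 1) "up" else "down"),
    class = "planted_effect"
  )
}

#' Default planted effects emulating the study's ground truth
#'
#' Plants three kinds of signal: frontal-cortex-exclusive disease effects
#' (present in `RTTfc_vs_CONfc` and `RTTfc_vs_RTToc`, absent from the control
#' regional comparison), normal regional differences shared by disease and
#' control brains (present in both frontal-vs-occipital comparisons), and a
#' handful of individual-variation effects confined to the occipital
#' comparison. Frontal-exclusive effects are planted at 2-fold in both
#' directions.
#'
#' @param n_exclusive_up,n_exclusive_down Numbers of frontal-exclusive genes
#'   planted up (fold 2) and down (fold 0.5).
#' @param n_regional Number of normal regional-difference genes (fold 2,
#'   planted in `RTTfc_vs_RTToc` and `CONfc_vs_CONoc`).
#' @param n_occipital Number of individual-variation genes confined to
#'   `RTToc_vs_CONoc`.
#' @param fold Linear fold change used for up-regulated plants (down plants
#'   use `1/fold`).
#' @return List of [planted_effect()] objects.
#' @export
default_planted_effects <- function(n_exclusive_up = 60, n_exclusive_down = 40,
                                    n_regional = 30, n_occipital = 10,
                                    fold = 2) {
  idx <- 0L
  nxt <- function(n) {
    out <- sprintf("EST%05d", idx + seq_len(n))
    idx <<- idx + n
    out
  }
  effects <- c(
    lapply(nxt(n_exclusive_up), planted_effect,
           comparisons_affected = c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc"),
           fold_change = fold),
    lapply(nxt(n_exclusive_down), planted_effect,
           comparisons_affected = c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc"),
           fold_change = 1 / fold),
    lapply(nxt(n_regional), planted_effect,
           comparisons_affected = c("RTTfc_vs_RTToc", "CONfc_vs_CONoc"),
           fold_change = fold),
    lapply(nxt(n_occipital), planted_effect,
           comparisons_affected = "RTToc_vs_CONoc",
           fold_change = fold)
  )
  effects
}

#' Configure a synthetic regional microarray study
#'
#' Defines the complete study structure: platform size, replication, dye
#' swapping, the calibration noise level, the baseline intensity model, QC
#' flag rate and the planted ground truth.
#'
#' @param n_features Features per array (spotted ESTs); default 19008, the
#'   platform scale of the emulated study.
#' @param n_replicates_per_comparison Replicate co-hybridizations per
#'   comparison set; default 6.
#' @param dye_swap If `TRUE` (default) every replicate is hybridized twice
#'   with the cyanine dye assignment reversed.
#' @param comparison_sets The four comparison labels; fixed to
#'   [comparison_labels()].
#' @param self_self_ratio_sd Standard deviation of per-feature linear ratios
#'   in a self-self hybridization; default 0.25. This single number sets the
#'   per-channel noise of every generated array.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal baseline intensity
#'   distribution of the features (defaults 11 and 1.2, i.e. median intensity
#'   2048 with a realistic dynamic range for a spotted array scanned at
#'   16 bits).
#' @param flag_rate Fraction of features flagged bad per array, in `[0, 1)`;
#'   default 0.02.
#' @param planted_effects List of [planted_effect()]; defaults to
#'   [default_planted_effects()].
#' @param seed Master integer seed; every array derives its own substream
#'   deterministically from it.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_features = 19008,
                         n_replicates_per_comparison = 6,
                         dye_swap = TRUE,
                         comparison_sets = comparison_labels(),
                         self_self_ratio_sd = 0.25,
                         baseline_log2_mean = 11,
                         baseline_log2_sd = 1.2,
                         flag_rate = 0.02,
                         planted_effects = default_planted_effects(),
                         seed = 1L) {
  cfg <- structure(
    list(n_features = as.integer(n_features),
         n_replicates_per_comparison = as.integer(n_replicates_per_comparison),
         dye_swap = isTRUE(dye_swap),
         comparison_sets = comparison_sets,
         self_self_ratio_sd = self_self_ratio_sd,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         flag_rate = flag_rate,
         planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid configuration field '%s': %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_features) || cfg$n_features <= 0L) {
    fail("n_features", "must be a positive count")
  }
  if (is.na(cfg$n_replicates_per_comparison) ||
      cfg$n_replicates_per_comparison <= 0L) {
    fail("n_replicates_per_comparison", "must be a positive count")
  }
  if (!setequal(cfg$comparison_sets, comparison_labels()) ||
      length(cfg$comparison_sets) != 4L) {
    fail("comparison_sets", "must be exactly the four study comparison labels")
  }
  if (!is.numeric(cfg$self_self_ratio_sd) || cfg$self_self_ratio_sd < 0) {
    fail("self_self_ratio_sd", "must be >= 0")
  }
  if (!is.numeric(cfg$flag_rate) || cfg$flag_rate < 0 || cfg$flag_rate >= 1) {
    fail("flag_rate", "must lie in [0, 1)")
  }
  if (!is.numeric(cfg$baseline_log2_sd) || cfg$baseline_log2_sd < 0) {
    fail("baseline_log2_sd", "must be >= 0")
  }
  if (!all(vapply(cfg$planted_effects, inherits, logical(1), "planted_effect"))) {
    fail("planted_effects", "must be a list of planted_effect objects")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

# Per-channel log2 noise SD reproducing a target SD of self-self linear
# ratios. If each channel carries independent N(0, sc^2) log2 noise, the
# log2 self-self ratio is N(0, 2 sc^2) and the linear ratio is lognormal;
# solving var = (e^v - 1) e^v = sd^2 for v = (natural-log SD)^2 gives the
# exact calibration.
channel_log2_sd <- function(self_self_ratio_sd) {
  s <- self_self_ratio_sd
  if (s == 0) return(0)
  u <- (1 + sqrt(1 + 4 * s^2)) / 2   # e^v
  sigma_ln <- sqrt(log(u))           # natural-log SD of the ratio
  sigma_log2 <- sigma_ln / log(2)
  sigma_log2 / sqrt(2)
}

# Deterministic substream seed from a master seed and a string tag; keeps
# results reproducible per array irrespective of generation order.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 1009 + h) %% 2147483587) + 1L
}
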