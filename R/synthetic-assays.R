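#' Generate a synthetic qRT-PCR Ct table
#'
#' Emulates the validation-assay design: four sample groups (disease and
#' control, frontal and occipital cortex), `n_per_group` biological samples
#' per group, each measured in triplicate within an experiment across
#' `n_experiments` independent experiments. Target and reference (GAPDH) Ct
#' values carry additive Gaussian noise; planted group effects are encoded as
#' shifts of the target Ct (a 2-fold up-regulation is a -1 cycle shift).
#'
#' @param groups Group labels; default the study's four groups.
#' @param n_per_group Biological samples per group (default 6).
#' @param gene_effects Named numeric vector of planted log2 fold changes per
#'   group (e.g. `c("RTT-FC" = 1)` plants a 2-fold up-regulation in the
#'   disease frontal cortex). Unnamed groups are unshifted.
#' @param n_experiments Independent experiments (default 3).
#' @param n_technical Technical replicates per experiment (default 3).
#' @param ct_target_base,ct_reference_base Mean Ct of the target and the
#'   reference gene in an unshifted sample (defaults 24 and 18 cycles).
#' @param biological_sd Between-sample SD of the target Ct (cycles; default
#'   0.25).
#' @param technical_sd Within-sample measurement SD of every Ct (cycles;
#'   default 0.15).
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `group`, `experiment`,
#'   `tech_rep`, `ct_target`, `ct_reference`.
#' @export
generate_qpcr_table <- function(groups = c("RTT-FC", "RTT-OC", "CTL-FC", "CTL-OC"),
                                n_per_group = 6, gene_effects = numeric(0),
                                n_experiments = 3, n_technical = 3,
                                ct_target_base = 24, ct_reference_base = 18,
                                biological_sd = 0.25, technical_sd = 0.15,
                                seed = 1L) {
  stopifnot(n_per_group >= 1)
  set.seed(derive_seed(seed, "qpcr"))
  rows <- list()
  for (g in groups) {
    shift <- if (g %in% names(gene_effects)) -gene_effects[[g]] else 0
    for (s in seq_len(n_per_group)) {
      sample_id <- sprintf("%s_%02d", g, s)
      # per-sample true Ct values (biology varies between samples, not
      # between technical replicates)
      true_target <- ct_target_base + shift + stats::rnorm(1, 0, biological_sd)
      true_ref <- ct_reference_base + stats::rnorm(1, 0, biological_sd / 2)
      for (e in seq_len(n_experiments)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, group = g, experiment = e,
          tech_rep = seq_len(n_technical),
          ct_target = true_target + stats::rnorm(n_technical, 0, technical_sd),
          ct_reference = true_ref + stats::rnorm(n_technical, 0, technical_sd),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a first-order enzyme kinetics trace
#'
#' Absorbance-vs-time trace of a first-order decay, as in a cytochrome c
#' oxidase assay following the oxidation of reduced cytochrome c at 550 nm:
#' `A(t) = a_inf + (a0 - a_inf) * exp(-k t) + noise`.
#'
#' @param k First-order rate constant (per minute), >= 0.
#' @param a0 Initial absorbance; must exceed `a_inf`.
#' @param a_inf Plateau absorbance at complete oxidation.
#' @param noise_sd SD of additive Gaussian absorbance noise (default 0).
#' @param times Strictly increasing time points in minutes.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data frame with columns `time` and `absorbance`.
#' @export
generate_kinetics_trace <- function(k, a0, a_inf, noise_sd = 0,
                                    times = seq(0, 3, by = 0.1), seed = 1L) {
  if (k < 0) stop("invalid trace: rate constant k must be >= 0", call. = FALSE)
  if (a0 <= a_inf) stop("invalid trace: a0 must exceed a_inf", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("invalid trace: times must be strictly increasing", call. = FALSE)
  }
  a <- a_inf + (a0 - a_inf) * exp(-k * times)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "kinetics"))
    a <- a + stats::rnorm(length(times), 0, noise_sd)
  }
  data.frame(time = times, absorbance = a)
}
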