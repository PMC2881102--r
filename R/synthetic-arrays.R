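#' Generate a complete synthetic regional microarray study
#'
#' Emulates the full study design: for each of the four comparison sets,
#' `n_replicates_per_comparison` replicate co-hybridizations, each repeated
#' with the dye assignment reversed (when `dye_swap`). Per-feature baseline
#' intensities are log2-normal and shared across the whole study; each
#' channel of each array carries independent multiplicative noise whose scale
#' is calibrated so that a self-self hybridization's linear ratios have
#' standard deviation `self_self_ratio_sd`. Planted effects multiply the test
#' sample's expression on the linear scale in the comparisons they affect.
#' Features are flagged bad uniformly at random at `flag_rate` per array.
#'
#' @param config A [study_config()].
#' @return List with components:
#'   * `arrays`: nested list `arrays[[comparison]][[replicate]]` with
#'     elements `forward` and (if `dye_swap`) `swapped`, each a
#'     [two_color_array()];
#'   * `truth`: a `synthetic_truth` object (see [synthetic_truth()]).
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  ids <- feature_ids(config)
  baseline <- baseline_intensities(config, ids)
  sc <- channel_log2_sd(config$self_self_ratio_sd)
  truth <- synthetic_truth(config)

  arrays <- lapply(config$comparison_sets, function(cmp) {
    fold <- rep(1, config$n_features)
    planted <- truth$log_ratio[[cmp]]
    if (length(planted)) {
      fold[match(names(planted), ids)] <- 2^planted
    }
    lapply(seq_len(config$n_replicates_per_comparison), function(rep_i) {
      pair <- list(
        forward = simulate_array(config, ids, baseline, fold, sc,
                                 cmp, rep_i, "forward")
      )
      if (config$dye_swap) {
        pair$swapped <- simulate_array(config, ids, baseline, fold, sc,
                                       cmp, rep_i, "swapped")
      }
      pair
    })
  })
  names(arrays) <- config$comparison_sets
  list(arrays = arrays, truth = truth)
}

# One hybridization: test profile = baseline * fold, reference = baseline;
# forward arrays carry the test sample in the red (F635) channel.
simulate_array <- function(config, ids, baseline, fold, sc,
                           comparison, replicate, orientation) {
  set.seed(derive_seed(config$seed,
                       paste(comparison, replicate, orientation, sep = "/")))
  n <- config$n_features
  test <- baseline * fold * 2^stats::rnorm(n, 0, sc)
  ref <- baseline * 2^stats::rnorm(n, 0, sc)
  flag <- ifelse(stats::runif(n) < config$flag_rate, -50L, 0L)
  labels <- strsplit(comparison, "_vs_")[[1L]]
  if (orientation == "forward") {
    two_color_array(ids, f635 = test, f532 = ref, flag = flag,
                    test_label = labels[1L], reference_label = labels[2L],
                    dye_orientation = "forward")
  } else {
    two_color_array(ids, f635 = ref, f532 = test, flag = flag,
                    test_label = labels[1L], reference_label = labels[2L],
                    dye_orientation = "swapped")
  }
}

feature_ids <- function(config) sprintf("EST%05d", seq_len(config$n_features))

baseline_intensities <- function(config, ids) {
  set.seed(derive_seed(config$seed, "baseline"))
  b <- 2^stats::rnorm(config$n_features, config$baseline_log2_mean,
                      config$baseline_log2_sd)
  names(b) <- ids
  b
}

#' Planted ground truth of a synthetic study
#'
#' Registry of the planted effects: per-comparison maps from gene to planted
#' log2 ratio, and the derived list of frontal-cortex-exclusive genes (those
#' planted in `RTTfc_vs_CONfc` and `RTTfc_vs_RTToc` but not in
#' `CONfc_vs_CONoc`). The exclusive list is the parameter-recovery oracle for
#' the subtractive pipeline.
#'
#' @param config A [study_config()].
#' @return A `synthetic_truth` list with fields `log_ratio` (named list of
#'   named numeric vectors, one per comparison), `frontal_exclusive`
#'   (character vector) and `direction` (named, for the exclusive genes).
#' @export
synthetic_truth <- function(config) {
  log_ratio <- stats::setNames(
    lapply(config$comparison_sets, function(cmp) {
      hits <- Filter(function(e) cmp %in% e$comparisons_affected,
                     config$planted_effects)
      stats::setNames(vapply(hits, function(e) log2(e$fold_change), numeric(1)),
                      vapply(hits, function(e) e$gene_id, character(1)))
    }),
    config$comparison_sets
  )
  excl <- setdiff(
    intersect(names(log_ratio$RTTfc_vs_CONfc), names(log_ratio$RTTfc_vs_RTToc)),
    names(log_ratio$CONfc_vs_CONoc)
  )
  dir <- ifelse(log_ratio$RTTfc_vs_CONfc[excl] > 0, "up", "down")
  structure(list(log_ratio = log_ratio,
                 frontal_exclusive = excl,
                 direction = stats::setNames(dir, excl)),
            class = "synthetic_truth")
}

#' Generate a self-self hybridization
#'
#' Both channels measure the same RNA: per-feature intensities share one
#' expression profile and differ only by the per-channel noise, so the linear
#' ratios are centered at 1 with standard deviation approximately
#' `self_self_ratio_sd`. Used to calibrate the fold-change threshold.
#'
#' @param config A [study_config()].
#' @return A [two_color_array()] labeled `self/self`.
#' @export
generate_self_self <- function(config) {
  validate_study_config(config)
  ids <- feature_ids(config)
  baseline <- baseline_intensities(config, ids)
  sc <- channel_log2_sd(config$self_self_ratio_sd)
  set.seed(derive_seed(config$seed, "self_self"))
  n <- config$n_features
  f635 <- baseline * 2^stats::rnorm(n, 0, sc)
  f532 <- baseline * 2^stats::rnorm(n, 0, sc)
  flag <- ifelse(stats::runif(n) < config$flag_rate, -50L, 0L)
  two_color_array(ids, f635, f532, flag,
                  test_label = "self", reference_label = "self",
                  dye_orientation = "forward")
}
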