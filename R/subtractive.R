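#' Overlap of fold-change and SAM calls
#'
#' Genes called by both analysis arms of one comparison, with agreeing
#' direction. Direction conflicts are excluded: a gene called up by one arm
#' and down by the other supports no interpretable regional statement.
#'
#' @param fc Named character vector gene -> direction (`"up"`/`"down"`) from
#'   the fold-change arm.
#' @param sam Named character vector gene -> direction from the SAM arm.
#' @return Named character vector gene -> direction for the overlap set.
#' @export
overlap_calls <- function(fc, sam) {
  common <- intersect(names(fc), names(sam))
  agree <- common[fc[common] == sam[common]]
  fc[agree]
}

#' Frontal-cortex-exclusive genes by subtractive logic
#'
#' A gene is exclusive to the disease frontal cortex when it is called in
#' both the disease-vs-control frontal comparison (a) and the
#' frontal-vs-occipital comparison within disease (b), but not in the
#' control regional comparison (c): `(a` \eqn{\cap} `b) \ c`. Normal regional
#' expression differences appear in (c) and are subtracted away.
#'
#' @param set_a,set_b Named direction vectors (gene -> `"up"`/`"down"`) of
#'   comparisons (a) `RTTfc_vs_CONfc` and (b) `RTTfc_vs_RTToc`, typically
#'   from [overlap_calls()].
#' @param set_c Named direction vector (or bare gene ids) of comparison (c)
#'   `CONfc_vs_CONoc`.
#' @return An `exclusive_list`: data frame `gene_id`, `direction` (from set
#'   a), `in_a`, `in_b`, `in_c` provenance columns.
#' @export
exclusive_frontal <- function(set_a, set_b, set_c) {
  genes_c <- if (is.null(names(set_c))) as.character(set_c) else names(set_c)
  keep <- setdiff(intersect(names(set_a), names(set_b)), genes_c)
  structure(
    data.frame(gene_id = keep,
               direction = unname(set_a[keep]),
               in_a = rep(TRUE, length(keep)),
               in_b = rep(TRUE, length(keep)),
               in_c = rep(FALSE, length(keep)),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("exclusive_list", "data.frame")
  )
}

# Direction vector (gene -> up/down) from a fold-change call table.
fc_directions <- function(calls) {
  hit <- calls$evaluable & calls$direction %in% c("up", "down")
  stats::setNames(calls$direction[hit], calls$gene_id[hit])
}

# Direction vector from a sam_result.
sam_directions <- function(result) {
  stats::setNames(result$called$direction, result$called$gene_id)
}

#' Build the replicate ratio matrix of one comparison
#'
#' Runs QC and loess normalization on every array of the comparison, drops
#' arrays rejected by the normalization-factor window, and reconciles each
#' dye-swap pair into one replicate linear ratio per feature.
#'
#' @param replicates List of replicate pairs (`forward`/`swapped` arrays),
#'   i.e. one element of `generate_study()$arrays`.
#' @param policy A [qc_policy()].
#' @param span,iterations Loess settings (see [loess_normalize()]).
#' @return List with `ratios` (genes x replicates matrix of linear ratios),
#'   `n_rejected_arrays` and `log` (character lines).
#' @export
comparison_ratio_sets <- function(replicates, policy = qc_policy(),
                                  span = 0.4, iterations = 3) {
  log <- character(0)
  n_rejected <- 0L
  cols <- lapply(seq_along(replicates), function(i) {
    pair <- replicates[[i]]
    get_m <- function(array, which) {
      if (is.null(array)) return(NULL)
      norm <- normalize_array(array, policy, span = span, iterations = iterations)
      if (!norm$accepted) {
        n_rejected <<- n_rejected + 1L
        log <<- c(log, sprintf(
          "replicate %d %s array rejected: normalization factor %.3f outside window",
          i, which, norm$qc$norm_factor))
        return(NULL)
      }
      log <<- c(log, sprintf(
        "replicate %d %s: factor %.3f, flagged %d, low-intensity %d, retained %d",
        i, which, norm$qc$norm_factor, norm$qc$n_flagged,
        norm$qc$n_low_intensity, norm$qc$n_retained))
      stats::setNames(norm$ratios$m, norm$ratios$feature_id)
    }
    fwd <- get_m(pair$forward, "forward")
    swp <- get_m(pair$swapped, "swapped")
    ids <- names(if (!is.null(fwd)) fwd else swp)
    if (is.null(ids)) return(NULL)
    f <- if (is.null(fwd)) rep(NA_real_, length(ids)) else fwd
    s <- if (is.null(swp)) rep(NA_real_, length(ids)) else swp[ids]
    stats::setNames(reconcile_dye_swap(f, s), ids)
  })
  keep <- !vapply(cols, is.null, logical(1))
  if (!any(keep)) stop("no usable replicate in comparison", call. = FALSE)
  ids <- names(cols[keep][[1L]])
  mat <- vapply(cols[keep], function(v) unname(v[ids]),
                numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, NULL))
  list(ratios = mat, n_rejected_arrays = n_rejected, log = log)
}

#' Run the full region-subtractive differential-expression pipeline
#'
#' End to end: calibrate the fold-change thresholds from a self-self
#' hybridization, then for every comparison set run QC, loess normalization,
#' dye-swap reconciliation, the consensus fold-change caller and one-class
#' SAM (delta chosen for `target_fdr`), intersect the two arms, and apply
#' the four-comparison subtractive logic. The fourth comparison
#' (`RTToc_vs_CONoc`) is computed and reported but does not enter the
#' exclusivity formula; it reflects mostly individual variation in the
#' spared region.
#'
#' @param config A [study_config()]; the synthetic study and the self-self
#'   calibration array are generated from it unless `arrays`/`self_self` are
#'   supplied.
#' @param arrays Optional pre-built study arrays in the
#'   `generate_study()$arrays` layout.
#' @param self_self Optional pre-built self-self [two_color_array()].
#' @param policy A [qc_policy()].
#' @param target_fdr SAM false positive rate target (default 0.05).
#' @param min_support Consensus count (default [default_min_support()]).
#' @param span,iterations Loess settings.
#' @return A `subtractive_run` list: `calibration`, `comparisons` (per
#'   comparison: `n_passed_cutoff`, `fc_calls` table, `sam` result, `delta`
#'   info, `fc_called`, `sam_called`, `overlap` direction vectors, counts),
#'   `exclusive` (an `exclusive_list`), `summary` (Table-shaped counts data
#'   frame) and `log`.
#' @export
run_pipeline <- function(config, arrays = NULL, self_self = NULL,
                         policy = qc_policy(), target_fdr = 0.05,
                         min_support = default_min_support(config$n_replicates_per_comparison),
                         span = 0.4, iterations = 3) {
  validate_study_config(config)
  log <- character(0)
  if (is.null(arrays)) {
    study <- generate_study(config)
    arrays <- study$arrays
    log <- c(log, "synthetic study generated from config")
  }
  missing_cmp <- setdiff(comparison_labels(), names(arrays))
  if (length(missing_cmp)) {
    stop("configuration error: missing comparison set(s) ",
         paste(missing_cmp, collapse = ", "), call. = FALSE)
  }
  if (is.null(self_self)) self_self <- generate_self_self(config)

  ss_norm <- normalize_array(self_self, policy, span = span,
                             iterations = iterations)
  calibration <- calibrate_fold_threshold(2^ss_norm$ratios$m)
  log <- c(log, sprintf(
    "self-self calibration: sigma %.4f, thresholds %.3f / %.3f",
    calibration$sigma, calibration$up_threshold, calibration$down_threshold))

  comparisons <- lapply(comparison_labels(), function(cmp) {
    rs <- comparison_ratio_sets(arrays[[cmp]], policy, span = span,
                                iterations = iterations)
    log <<- c(log, paste0("[", cmp, "] ", rs$log))
    fc_calls <- call_de_table(rs$ratios, calibration, min_support = min_support)
    fit <- sam_fit(log2(rs$ratios))
    delta_info <- choose_delta(fit, target_fdr = target_fdr)
    sam_result <- sam_call(fit, delta_info$delta)
    fc_called <- fc_directions(fc_calls)
    sam_called <- sam_directions(sam_result)
    ov <- overlap_calls(fc_called, sam_called)
    log <<- c(log, sprintf(
      "[%s] passed cut-off %d; fold-change %d, SAM %d (delta %.3f, est. FDR %.4f), overlap %d",
      cmp, sum(fc_calls$evaluable), length(fc_called), length(sam_called),
      delta_info$delta, sam_result$estimated_fdr, length(ov)))
    list(comparison = cmp,
         n_passed_cutoff = sum(fc_calls$evaluable),
         n_rejected_arrays = rs$n_rejected_arrays,
         fc_calls = fc_calls,
         sam = sam_result,
         delta = delta_info$delta,
         delta_achieved = delta_info$achieved,
         fc_called = fc_called,
         sam_called = sam_called,
         overlap = ov)
  })
  names(comparisons) <- comparison_labels()

  exclusive <- exclusive_frontal(comparisons$RTTfc_vs_CONfc$overlap,
                                 comparisons$RTTfc_vs_RTToc$overlap,
                                 comparisons$CONfc_vs_CONoc$overlap)
  summary <- data.frame(
    comparison = comparison_labels(),
    n_passed_cutoff = vapply(comparisons, function(x) x$n_passed_cutoff, integer(1)),
    fold_change = vapply(comparisons, function(x) length(x$fc_called), integer(1)),
    sam = vapply(comparisons, function(x) length(x$sam_called), integer(1)),
    overlap = vapply(comparisons, function(x) length(x$overlap), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(calibration = calibration,
                 comparisons = comparisons,
                 exclusive = exclusive,
                 summary = summary,
                 config = config,
                 log = log),
            class = "subtractive_run")
}

#' @export
print.subtractive_run <- function(x, ...) {
  cat("Region-subtractive differential-expression run\n")
  cat(sprintf("  thresholds: >%.3f / <%.2f (sigma %.4f)\n",
              x$calibration$up_threshold, x$calibration$down_threshold,
              x$calibration$sigma))
  print(x$summary, row.names = FALSE)
  cat(sprintf("  frontal-cortex-exclusive genes: %d\n", nrow(x$exclusive)))
  invisible(x)
}
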