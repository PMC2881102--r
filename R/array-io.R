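#' Construct a two-color array object
#'
#' Container for one co-hybridization: per-feature intensities of the red
#' (F635) and green (F532) channels plus an integer QC flag (0 = good,
#' negative = flagged by the scanner software).
#'
#' @param feature_id Character vector of unique feature identifiers.
#' @param f635,f532 Non-negative channel intensities (arbitrary units).
#' @param flag Integer QC flags; default all 0.
#' @param test_label,reference_label Sample identifiers of the test and
#'   reference RNA.
#' @param dye_orientation `"forward"` (test labeled in the red channel) or
#'   `"swapped"`.
#' @return A `two_color_array` object.
#' @export
two_color_array <- function(feature_id, f635, f532,
                            flag = rep(0L, length(feature_id)),
                            test_label = "test", reference_label = "reference",
                            dye_orientation = c("forward", "swapped")) {
  dye_orientation <- match.arg(dye_orientation)
  feature_id <- as.character(feature_id)
  if (length(feature_id) == 0L) stop("array must contain at least one feature", call. = FALSE)
  if (anyDuplicated(feature_id)) {
    stop("duplicate feature_id within array: ",
         feature_id[duplicated(feature_id)][1L], call. = FALSE)
  }
  if (any(!nzchar(feature_id))) stop("feature_id must be non-empty", call. = FALSE)
  if (any(f635 < 0) || any(f532 < 0)) {
    stop("negative intensity at row ",
         which(f635 < 0 | f532 < 0)[1L], call. = FALSE)
  }
  structure(
    list(features = data.frame(feature_id = feature_id,
                               f635 = as.numeric(f635),
                               f532 = as.numeric(f532),
                               flag = as.integer(flag),
                               stringsAsFactors = FALSE),
         test_label = test_label,
         reference_label = reference_label,
         dye_orientation = dye_orientation),
    class = "two_color_array"
  )
}

#' @export
print.two_color_array <- function(x, ...) {
  cat(sprintf("two_color_array: %d features, %s vs %s (%s)\n",
              nrow(x$features), x$test_label, x$reference_label,
              x$dye_orientation))
  cat(sprintf("  flagged: %d; median F635 %.0f, median F532 %.0f\n",
              sum(x$features$flag != 0L),
              stats::median(x$features$f635),
              stats::median(x$features$f532)))
  invisible(x)
}

# Accepted column spellings (GPR convention and plain channel names).
.gpr_columns <- list(
  feature_id = c("ID", "Name", "feature_id"),
  f635 = c("F635 Median", "F635 Mean", "F635"),
  f532 = c("F532 Median", "F532 Mean", "F532"),
  flag = c("Flags", "Flag", "flag")
)

#' Read a GenePix-result-style two-channel intensity table
#'
#' Reads a tab-delimited text file with one row per spotted feature and
#' columns for the feature identifier, the red (F635) and green (F532)
#' channel intensities and an integer QC flag. Both the GPR spellings
#' (`"F635 Median"`, `"F532 Median"`, `"Flags"`) and plain names (`"F635"`,
#' `"F532"`) are accepted. Lines starting with `#` are ignored. Rows are kept
#' in file order; flagged rows are read, not filtered (filtering is a later
#' pipeline stage).
#'
#' @param path Path to the file.
#' @param test_label,reference_label,dye_orientation Array metadata (not
#'   stored in the file body).
#' @return A [two_color_array()].
#' @export
read_gpr <- function(path, test_label = "test", reference_label = "reference",
                     dye_orientation = "forward") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  pick <- function(role) {
    hit <- intersect(.gpr_columns[[role]], names(tab))
    if (!length(hit)) {
      stop(sprintf("format error: missing column for '%s' (accepted: %s)",
                   role, paste(.gpr_columns[[role]], collapse = ", ")),
           call. = FALSE)
    }
    tab[[hit[1L]]]
  }
  f635 <- as.numeric(pick("f635"))
  f532 <- as.numeric(pick("f532"))
  bad <- which(f635 < 0 | f532 < 0)
  if (length(bad)) {
    stop("validation error: negative intensity at row ", bad[1L], call. = FALSE)
  }
  flag <- if (any(.gpr_columns$flag %in% names(tab))) as.integer(pick("flag"))
          else rep(0L, nrow(tab))
  two_color_array(pick("feature_id"), f635, f532, flag,
                  test_label = test_label, reference_label = reference_label,
                  dye_orientation = dye_orientation)
}

#' Write a two-color array as a GPR-like tab-delimited file
#'
#' Columns are `ID`, `F635 Median`, `F532 Median`, `Flags`; a `#` comment
#' header records the sample labels and dye orientation. [read_gpr()] is the
#' exact inverse.
#'
#' @param array A [two_color_array()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(array, path) {
  stopifnot(inherits(array, "two_color_array"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# test=%s reference=%s dye_orientation=%s",
                     array$test_label, array$reference_label,
                     array$dye_orientation), con)
  out <- array$features
  names(out) <- c("ID", "F635 Median", "F532 Median", "Flags")
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-to-gene annotation table
#'
#' Two-column tab-delimited file: feature identifier, gene symbol. Several
#' spotted ESTs commonly map to one gene symbol (many-to-one).
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping feature_id to symbol.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("format error: annotation needs two columns", call. = FALSE)
  ann <- as.character(tab[[2L]])
  names(ann) <- as.character(tab[[1L]])
  if (anyDuplicated(names(ann))) {
    stop("annotation maps a feature_id to more than one symbol", call. = FALSE)
  }
  ann
}

#' Group feature identifiers by gene symbol
#'
#' Features present in the annotation are grouped under their symbol;
#' unannotated features form singleton groups under their own identifier.
#'
#' @param ids Character vector of feature identifiers.
#' @param annotation Named character vector (feature_id -> symbol), e.g. from
#'   [read_annotation()]. May be empty, in which case the grouping is the
#'   identity.
#' @return Named list of character vectors; names are symbols (or feature ids
#'   for unannotated features).
#' @export
map_to_genes <- function(ids, annotation = character(0)) {
  ids <- as.character(ids)
  key <- ifelse(ids %in% names(annotation), unname(annotation[ids]), ids)
  split(ids, factor(key, levels = unique(key)))
}
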