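# The samples x features container used throughout the pipeline.

#' Construct a feature table
#'
#' A feature table holds a numeric samples-by-features matrix together with a
#' binary group label (control/case) and optional per-sample subgroup
#' annotations (e.g. Gleason-score or PSA strata for the cases).
#'
#' @param values numeric matrix, samples in rows, features in columns; must
#'   have unique row and column names
#' @param group factor or character of length `nrow(values)` with exactly the
#'   levels control and case (first level = control)
#' @param subgroups optional data.frame of per-sample labels
#' @return an object of class `feature_table`
#' @export
feature_table <- function(values, group, subgroups = NULL) {
  stop_if_not(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  stop_if_not(!anyDuplicated(rownames(values)), "duplicate sample ids")
  stop_if_not(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "features must have unique names")
  group <- as.factor(group)
  stop_if_not(length(group) == nrow(values),
              "group must have one label per sample")
  stop_if_not(nlevels(droplevels(group)) <= 2L,
              "group must be binary (control/case)")
  if (!is.null(subgroups)) {
    stop_if_not(is.data.frame(subgroups) && nrow(subgroups) == nrow(values),
                "subgroups must be a data.frame with one row per sample")
  }
  structure(
    list(values = values, group = group, subgroups = subgroups),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group),
                                 tabulate(x$group, nlevels(x$group))),
                         collapse = ", "), "\n")
  if (!is.null(x$subgroups))
    cat("  subgroup annotations:", paste(names(x$subgroups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

# Accept either a feature_table or a bare matrix in the preprocessing verbs.
ft_values <- function(t) {
  if (inherits(t, "feature_table")) t$values else as.matrix(t)
}

ft_rewrap <- function(t, values) {
  if (inherits(t, "feature_table")) {
    t$values <- values
    t
  } else {
    values
  }
}

#' Write a feature table to CSV
#'
#' Writes a `sample_id` and `group` column followed by one column per feature.
#'
#' @param t a feature_table
#' @param path output file
#' @export
write_feature_table <- function(t, path) {
  df <- data.frame(sample_id = rownames(t$values),
                   group = as.character(t$group),
                   t$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the layout written by [write_feature_table()]: `sample_id`,
#' `group`, then numeric feature columns.
#'
#' @param path input CSV
#' @return a feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not(all(c("sample_id", "group") %in% names(df)),
              "feature table CSV needs 'sample_id' and 'group' columns")
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE])
  stop_if_not(is.numeric(vals), "non-numeric feature values in %s", path)
  rownames(vals) <- df$sample_id
  feature_table(vals, df$group)
}
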