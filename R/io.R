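#' Read a rectangular data table for subset selection
#'
#' Reads a CSV or TSV file with a header row, verifies that the outcome
#' column exists, that column labels are unique, and that every cell is a
#' non-missing number -- offending cells are reported with their row and
#' column so the file can be fixed rather than silently coerced.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @param outcome Name of the outcome column (checked, not removed).
#' @return A tibble with all columns numeric.
#' @export
read_dataset <- function(path, outcome) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (anyDuplicated(names(raw)))
    abort(sprintf("duplicate column labels in %s: %s", path,
                  paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", ")))
  if (!outcome %in% names(raw))
    abort(sprintf("outcome column '%s' not found in %s (columns: %s)",
                  outcome, path, paste(names(raw), collapse = ", ")))
  out <- raw
  for (j in names(raw)) {
    v <- raw[[j]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad)) {
      what <- if (is.na(v[bad[1]])) "missing value" else
        sprintf("non-numeric value '%s'", v[bad[1]])
      abort(sprintf("%s in column '%s', row %d of %s", what, j, bad[1], path))
    }
    out[[j]] <- num
  }
  tibble::as_tibble(out)
}

#' Write a report tibble as TSV
#'
#' Numeric columns are printed with 3 decimals (full precision is available
#' from the returned objects themselves); `NA` cells are left blank, matching
#' the convention that variables excluded from a selected model have no
#' post-selection Wald p-value.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, digits = 3) {
  fmt <- as.data.frame(x)
  for (j in names(fmt)) {
    if (is.numeric(fmt[[j]])) {
      v <- ifelse(is.na(fmt[[j]]), "", formatC(fmt[[j]], digits = digits,
                                               format = "f"))
      fmt[[j]] <- v
    }
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a variable-group specification
#'
#' YAML file mapping group names to lists of column labels, e.g.
#' `size: [Weight, Height]`. Groups must be non-empty and disjoint.
#'
#' @param path Path to the YAML file.
#' @return A named list of character vectors.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) abort(sprintf("group file not found: %s", path))
  g <- yaml::read_yaml(path)
  if (!is.list(g) || is.null(names(g)) || any(names(g) == ""))
    abort("group file must map group names to lists of column labels.")
  lapply(g, as.character)
}
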