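#' Read a deletion table
#'
#' Reads a TSV or CSV file with one row per deletion.  The header must
#' contain `id`, `bp5` and `bp3` (5' and 3' breakpoint coordinates, 1-based
#' on the circular genome); any extra columns are kept as group labels
#' usable with [filter_by_group()].
#'
#' Breakpoints are stored exactly as given.  All published human mtDNA
#' deletions satisfy `bp5 < bp3` in reference-sequence linearisation, so
#' rows violating it are accepted with a warning rather than rejected.
#'
#' @param path Path to a TSV (default) or CSV (by `.csv` extension) file.
#' @param L Optional genome length; when given, coordinates are range-checked
#'   against it.
#' @return A tibble of validated deletion records.
#' @export
read_deletions <- function(path, L = NULL) {
  if (!file.exists(path)) abort(paste0("Deletion table not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_deletions(df, L = L)
}

#' Validate a deletion table
#'
#' @param deletions Data frame with columns `id`, `bp5`, `bp3` (extra
#'   columns are group labels).
#' @param L Optional genome length for range checking.
#' @return The validated tibble (with `id` as character).
#' @export
validate_deletions <- function(deletions, L = NULL) {
  df <- as_tibble(deletions)
  need <- c("id", "bp5", "bp3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Deletion table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort("Deletion table has no rows.")
  df$id <- as.character(df$id)
  bad_rows <- function(flag, what) {
    if (any(flag)) {
      abort(sprintf("Invalid deletion rows (%s): %s", what,
                    paste(which(flag), collapse = ", ")))
    }
  }
  num_ok <- function(x) is.numeric(x) & !is.na(x) & x == floor(x)
  bad_rows(!num_ok(df$bp5) | !num_ok(df$bp3), "non-integer breakpoint")
  bad_rows(df$bp5 < 1 | df$bp3 < 1, "coordinate below 1")
  if (!is.null(L)) bad_rows(df$bp5 > L | df$bp3 > L, paste0("coordinate above L = ", L))
  bad_rows(df$bp5 == df$bp3, "bp5 equals bp3")
  dup <- duplicated(df$id)
  if (any(dup)) {
    abort(paste0("Duplicate deletion ids: ",
                 paste(unique(df$id[dup]), collapse = ", ")))
  }
  if (any(df$bp5 > df$bp3)) {
    warn(sprintf("%d deletion(s) have bp5 > bp3; records kept as given.",
                 sum(df$bp5 > df$bp3)))
  }
  df
}

#' Unique breakpoints for one deletion end
#'
#' Deduplicates the 5' or 3' breakpoint coordinates of a deletion set.
#' Idempotent and order-independent.
#'
#' @param deletions A deletion tibble (see [read_deletions()]).
#' @param end `"five_prime"`/`"5p"` or `"three_prime"`/`"3p"`.
#' @return A tibble with a single sorted `position` column; the chosen end
#'   is stored in the `"end"` attribute and the count is `nrow()`.
#' @export
unique_breakpoints <- function(deletions, end = c("five_prime", "three_prime", "5p", "3p")) {
  end <- match.arg(end)
  end <- c(five_prime = "five_prime", three_prime = "three_prime",
           `5p` = "five_prime", `3p` = "three_prime")[[end]]
  if (nrow(deletions) == 0L) abort("Deletion set is empty.")
  col <- if (end == "five_prime") "bp5" else "bp3"
  out <- tibble(position = sort(unique(as.numeric(deletions[[col]]))))
  attr(out, "end") <- end
  out
}

#' Filter deletions by a group label
#'
#' @param deletions A deletion tibble.
#' @param label Name of a group column (any column other than
#'   `id`/`bp5`/`bp3`).
#' @param value Value to keep.
#' @return The subset of rows with `deletions[[label]] == value`, input
#'   order preserved.
#' @export
filter_by_group <- function(deletions, label, value) {
  if (!label %in% names(deletions)) {
    abort(paste0("Unknown group label: ", label))
  }
  deletions[!is.na(deletions[[label]]) & deletions[[label]] == value, , drop = FALSE]
}
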