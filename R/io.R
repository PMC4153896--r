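#' Read and write motif sets as TSV
#'
#' Motif tables are plain TSV with one row per element; any columns are
#' preserved, and `midpoint` is required on read.  The motif name, genome id
#' and genome length ride along as header comment lines so a round trip
#' restores the full motif set.
#'
#' @param motifs A [new_motif_set()] tibble.
#' @param path Output (or input) path.
#' @return `write_motif_tsv()` returns `path` invisibly; `read_motif_tsv()`
#'   returns a motif set.
#' @export
write_motif_tsv <- function(motifs, path) {
  meta <- sprintf("# motif_name=%s genome_id=%s L=%s",
                  attr(motifs, "motif_name") %||% "motifs",
                  attr(motifs, "genome_id") %||% "NA",
                  attr(motifs, "L") %||% "NA")
  df <- as_tibble(motifs)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  writeLines(meta, path)
  suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' @rdname write_motif_tsv
#' @export
read_motif_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("Motif file not found: ", path))
  first <- readLines(path, n = 1L)
  meta <- c(motif_name = NA_character_, genome_id = NA_character_, L = NA_character_)
  if (startsWith(first, "#")) {
    for (kv in strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% names(meta)) meta[parts[1]] <- parts[2]
    }
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"midpoint" %in% names(df)) abort("Motif TSV must have a `midpoint` column.")
  new_motif_set(df, name = meta[["motif_name"]], genome_id = meta[["genome_id"]],
                L = suppressWarnings(as.numeric(meta[["L"]])))
}

#' Export motif midpoints as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' an element `[start, end]` becomes `start - 1, end`, and each midpoint is
#' additionally written as a point interval (`floor(mid) - 1, floor(mid)`)
#' when `what = "midpoints"`.
#'
#' @param motifs A [new_motif_set()] tibble.
#' @param path Output path.
#' @param what `"elements"` (intervals) or `"midpoints"` (point intervals).
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(motifs, path, what = c("elements", "midpoints")) {
  what <- match.arg(what)
  chrom <- attr(motifs, "genome_id") %||% "genome"
  name <- attr(motifs, "motif_name") %||% "motif"
  df <- as_tibble(motifs)
  bed <- if (what == "midpoints" || !all(c("start", "span") %in% names(df))) {
    tibble(chrom = chrom,
           start = floor(df$midpoint) - 1,
           end = floor(df$midpoint),
           name = paste0(name, "_", seq_len(nrow(df))))
  } else {
    # elements wrapping the origin extend past L rather than splitting
    tibble(chrom = chrom,
           start = df$start - 1,
           end = df$start - 1 + df$span,
           name = paste0(name, "_", seq_len(nrow(df))))
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
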