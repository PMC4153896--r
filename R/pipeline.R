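#' Motif set specifications for the association suite
#'
#' A motif spec tells [run_association_suite()] how to obtain one motif
#' midpoint set: with a built-in scanner, or from externally computed
#' midpoints (for example stem-loop/cruciform midpoints predicted by a
#' folding program, which this package deliberately does not reimplement).
#'
#' @param min_run Minimum G-run length for the QFP scanners (2 or 3).
#' @param k,repeat_class Parameters for [find_repeats()].
#' @param midpoints Numeric vector of midpoint positions, or a path to a
#'   TSV file with a `midpoint` column.
#' @param paired For repeat specs: also run the paired-repeat both-ends
#'   test.
#' @return A motif spec list.
#' @name motif_spec
NULL

#' @rdname motif_spec
#' @export
qfp_spec <- function(min_run = 2L) {
  list(type = "intrastrand_qfp", min_run = as.integer(min_run))
}

#' @rdname motif_spec
#' @export
ddi_qfp_spec <- function(min_run = 2L) {
  list(type = "ddi_qfp", min_run = as.integer(min_run))
}

#' @rdname motif_spec
#' @export
repeat_spec <- function(k = 11L, repeat_class = "direct", paired = TRUE) {
  list(type = "repeats", k = as.integer(k), repeat_class = repeat_class,
       paired = isTRUE(paired))
}

#' @rdname motif_spec
#' @export
midpoint_spec <- function(midpoints) {
  list(type = "midpoints", midpoints = midpoints)
}

# Materialise one motif spec into (motif_set tibble or midpoint vector,
# optional pair table).
.build_motif_set <- function(spec, genome) {
  switch(spec$type,
    intrastrand_qfp = {
      ms <- find_intrastrand_qfp(genome, min_run = spec$min_run)
      list(set = ms, pairs = NULL)
    },
    ddi_qfp = {
      intra <- find_intrastrand_qfp(genome, min_run = spec$min_run)
      list(set = find_ddi_qfp(genome, min_run = spec$min_run, intra), pairs = NULL)
    },
    repeats = {
      units <- find_repeats(genome, k = spec$k, repeat_class = spec$repeat_class)
      pairs <- if (isTRUE(spec$paired)) enumerate_repeat_pairs(units) else NULL
      list(set = units, pairs = pairs)
    },
    midpoints = {
      mids <- spec$midpoints
      if (is.character(mids) && length(mids) == 1L) {
        df <- readr::read_tsv(mids, show_col_types = FALSE, progress = FALSE)
        if (!"midpoint" %in% names(df)) {
          abort("External midpoint file must have a `midpoint` column.")
        }
        mids <- as.numeric(df$midpoint)
      }
      list(set = new_motif_set(tibble(midpoint = as.numeric(mids)),
                               name = "external", genome_id = genome$id,
                               L = genome$length),
           pairs = NULL)
    },
    abort(paste0("Unknown motif spec type: ", spec$type))
  )
}

.stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

.mda_rows <- function(motif_name, mids, deletions, L, d_max) {
  ends <- c(five_prime = "bp5", three_prime = "bp3")
  purrr::imap(ends, function(col, end) {
    bps <- sort(unique(as.numeric(deletions[[col]])))
    dirs <- list(
      bp_to_motif = list(from = bps, to = mids,
                         label = "from_breakpoints_to_motifs"),
      motif_to_bp = list(from = mids, to = bps,
                         label = "from_motifs_to_breakpoints")
    )
    purrr::imap(dirs, function(d, dname) {
      res <- mda(d$from, d$to, L, direction = d$label)
      row <- tidy(res)
      row <- dplyr::mutate(row,
        motif = motif_name, end = end, .before = 1L)
      row$stars <- .stars(row$p_value)
      curve <- enrichment_curve(d$from, d$to, L, d_max = d_max,
                                direction = d$label)
      list(row = row, curve = curve,
           curve_name = paste(motif_name, end, dname, sep = "."))
    })
  })
}

#' Run the full motif-breakpoint association suite
#'
#' For every motif set, breakpoint end (5'/3') and direction (breakpoints to
#' motifs and motifs to breakpoints), runs Minimal Distance Analysis with
#' exhaustive rotational controls and builds the per-distance enrichment
#' curve; runs the both-ends proximity test for every motif set (and its
#' paired-repeat variant for repeat specs); optionally reruns the MDA table
#' on clinically defined subgroups.  Everything is exhaustive, so a rerun
#' with identical inputs is byte-identical.
#'
#' @param genome A [circular_genome()].
#' @param deletions A deletion tibble (see [read_deletions()]).
#' @param motif_specs Named list of motif specs (see [qfp_spec()] and
#'   friends).
#' @param d_max Largest enrichment-curve threshold (nt).
#' @param both_ends_d Both-ends distance threshold (nt).
#' @param subgroups Optional named list of `list(label =, value =)` filters;
#'   the MDA table is recomputed on each subgroup.
#' @param output_dir Optional directory; when given, TSV tables and a JSON
#'   manifest are written there via [write_association_report()].
#' @return A list of class `association_report` with elements `mda_table`
#'   (one row per motif x end x direction, with significance stars at
#'   0.05/0.01/0.001 and exact p-values), `enrichment_curves` (named list),
#'   `both_ends` (tibble), `subgroup_tables` (named list of MDA tables),
#'   `motif_sets` (named list) and `manifest`.
#' @export
run_association_suite <- function(genome, deletions, motif_specs,
                                  d_max = 50, both_ends_d = 10,
                                  subgroups = NULL, output_dir = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  deletions <- validate_deletions(deletions, L = genome$length)
  if (is.null(names(motif_specs)) || any(names(motif_specs) == "")) {
    abort("`motif_specs` must be a fully named list.")
  }
  L <- genome$length

  built <- purrr::imap(motif_specs, function(spec, nm) {
    tryCatch(.build_motif_set(spec, genome),
             error = function(e) abort(sprintf(
               "Motif stage failed for spec '%s': %s", nm, conditionMessage(e))))
  })

  mda_rows <- list(); curves <- list(); both <- list()
  for (nm in names(built)) {
    mids <- motif_midpoints(built[[nm]]$set)
    if (length(mids) == 0L) {
      warn(sprintf("Motif set '%s' is empty; association rows skipped.", nm))
      next
    }
    cells <- .mda_rows(nm, mids, deletions, L, d_max)
    for (endcell in cells) {
      for (cell in endcell) {
        mda_rows[[length(mda_rows) + 1L]] <- cell$row
        curves[[cell$curve_name]] <- cell$curve
      }
    }
    be <- both_ends_enrichment(deletions, mids, L, D = both_ends_d)
    both[[paste0(nm, ".single")]] <- dplyr::mutate(tidy(be), motif = nm, .before = 1L)
    if (!is.null(built[[nm]]$pairs) && nrow(built[[nm]]$pairs) > 0L) {
      bp <- paired_repeat_both_ends(deletions, built[[nm]]$pairs, L, D = both_ends_d)
      both[[paste0(nm, ".paired")]] <- dplyr::mutate(tidy(bp), motif = nm, .before = 1L)
    }
  }
  mda_table <- dplyr::bind_rows(mda_rows)
  both_ends <- dplyr::bind_rows(both)

  subgroup_tables <- list()
  for (gname in names(subgroups %||% list())) {
    flt <- subgroups[[gname]]
    sub <- filter_by_group(deletions, flt$label, flt$value)
    if (nrow(sub) == 0L) {
      warn(sprintf("Subgroup '%s' selects no deletions; skipped.", gname))
      next
    }
    rows <- list()
    for (nm in names(built)) {
      mids <- motif_midpoints(built[[nm]]$set)
      if (length(mids) == 0L) next
      cells <- .mda_rows(nm, mids, sub, L, d_max)
      for (endcell in cells) for (cell in endcell) {
        rows[[length(rows) + 1L]] <- cell$row
      }
    }
    subgroup_tables[[gname]] <- dplyr::bind_rows(rows)
  }

  report <- structure(
    list(
      mda_table = mda_table,
      enrichment_curves = curves,
      both_ends = both_ends,
      subgroup_tables = subgroup_tables,
      motif_sets = purrr::map(built, "set"),
      manifest = list(
        genome_id = genome$id,
        L = L,
        n_rotations = L - 1L,
        n_deletions = nrow(deletions),
        n_unique_bp5 = length(unique(deletions$bp5)),
        n_unique_bp3 = length(unique(deletions$bp3)),
        motif_specs = motif_specs,
        motif_counts = purrr::map_int(built, ~ nrow(.x$set)),
        d_max = d_max,
        both_ends_d = both_ends_d,
        binomial_conventions = c("at_least_K", "paper_literal"),
        package_version = as.character(utils::packageVersion("mitoqfp")),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "association_report"
  )
  if (!is.null(output_dir)) write_association_report(report, output_dir)
  report
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> %s (L = %s), %d deletions\n",
              x$manifest$genome_id, format(x$manifest$L, big.mark = ","),
              x$manifest$n_deletions))
  cat("MDA table (means rounded to nearest integer):\n")
  tbl <- dplyr::mutate(x$mda_table,
    actual_mean = round(.data$actual_mean),
    control_mean = round(.data$control_mean))
  print(dplyr::select(tbl, "motif", "end", "direction",
                      "actual_mean", "control_mean", "p_value", "stars"))
  invisible(x)
}

#' Write an association report to disk
#'
#' Writes `mda_table.tsv`, `both_ends.tsv`, one TSV per enrichment curve
#' and per subgroup table, and `manifest.json`.  Given identical inputs the
#' TSVs are byte-identical across reruns (only the manifest carries a
#' timestamp).
#'
#' @param report An `association_report` from [run_association_suite()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_association_report <- function(report, dir) {
  stopifnot(inherits(report, "association_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$mda_table, file.path(dir, "mda_table.tsv"))
  readr::write_tsv(report$both_ends, file.path(dir, "both_ends.tsv"))
  for (nm in names(report$enrichment_curves)) {
    readr::write_tsv(as_tibble(report$enrichment_curves[[nm]]),
                     file.path(dir, paste0("enrichment.", nm, ".tsv")))
  }
  for (nm in names(report$subgroup_tables)) {
    readr::write_tsv(report$subgroup_tables[[nm]],
                     file.path(dir, paste0("mda_subgroup.", nm, ".tsv")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Motif count excess over composition-matched shuffled genomes
#'
#' Counts motifs in the genome, then in `n_shuffles` random permutations of
#' its bases (identical nucleotide content and strand asymmetry), and
#' reports the empirical upper-tail p-value
#' `(1 + #\{null >= actual\}) / (n_shuffles + 1)`.
#'
#' @param genome A [circular_genome()].
#' @param motif_spec A motif spec (see [qfp_spec()]).
#' @param n_shuffles Number of shuffled genomes (>= 1).
#' @param seed Integer seed; shuffle `i` uses `seed + i`.
#' @return A one-row tibble with `actual`, `null_mean`, `null_sd`,
#'   `p_value`, `n_shuffles`.
#' @export
summarize_motif_count_excess <- function(genome, motif_spec, n_shuffles, seed = 1L) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1.")
  count_in <- function(g) nrow(.build_motif_set(motif_spec, g)$set)
  actual <- count_in(genome)
  null_counts <- vapply(seq_len(n_shuffles), function(i) {
    count_in(shuffle_genome(genome, seed = seed + i))
  }, numeric(1))
  tibble(
    actual = actual,
    null_mean = mean(null_counts),
    null_sd = sd(null_counts),
    p_value = (1 + sum(null_counts >= actual)) / (n_shuffles + 1),
    n_shuffles = n_shuffles
  )
}
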