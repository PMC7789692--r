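#' Write a dataset to a tab-separated slice file
#'
#' Serializes the 3D grid as `|Z|` slice blocks in context order, each
#' preceded by a header line `# context <k>` (0-based context index). Within
#' a block, rows are observations and columns are features, tab-separated;
#' missing cells are written as empty fields. Real values are printed with
#' 17 significant digits so that [read_dataset()] round-trips exactly.
#'
#' @param dataset a [tg_dataset] (or a bare 3D array).
#' @param path_stem output path stem; the file is `<stem>_data.tsv`.
#' @return The path of the written file, invisibly.
#' @export
write_dataset <- function(dataset, path_stem) {
  values <- if (inherits(dataset, "tg_dataset")) dataset$values else dataset
  dims <- dim(values)
  fmt <- function(v) {
    out <- if (is.numeric(v)) sprintf("%.17g", v) else v
    out[is.na(v)] <- ""
    out
  }
  path <- paste0(path_stem, "_data.tsv")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(dims[3])) {
    writeLines(sprintf("# context %d", k - 1L), con)
    slice <- matrix(fmt(values[, , k]), nrow = dims[1])
    writeLines(apply(slice, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dataset slice file back into a 3D array
#'
#' Inverse of [write_dataset()]: parses the `# context <k>` blocks and
#' reassembles the `(observation, feature, context)` array. Empty fields
#' become `NA`.
#'
#' @param path path to a `<stem>_data.tsv` file.
#' @param symbolic force values to stay character (symbolic alphabets whose
#'   symbols look numeric would otherwise be converted).
#' @return A 3D array, numeric when every non-missing field parses as a
#'   number (unless `symbolic = TRUE`).
#' @export
read_dataset <- function(path, symbolic = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^# context ", lines)
  if (length(hdr) == 0) stop("not a dataset slice file: ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  slices <- lapply(seq_along(hdr), function(b) {
    body <- lines[(hdr[b] + 1L):ends[b]]
    do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  })
  nr <- nrow(slices[[1]]); nc <- ncol(slices[[1]])
  vals <- unlist(slices, use.names = FALSE)
  vals[vals == ""] <- NA
  if (!symbolic) {
    num <- suppressWarnings(as.numeric(vals))
    if (all(is.na(num) == is.na(vals))) vals <- num
  }
  array(vals, dim = c(nr, nc, length(slices)))
}

#' Write the triclustering solution (ground truth)
#'
#' Emits the solution in two renderings: `<stem>_trics.json`, the
#' machine-readable ground truth (indices 0-based; schema shipped at
#' `inst/schema/solution.schema.json`), and `<stem>_trics.txt`, a
#' human-readable report of the same content: number of planted
#' triclusters, dataset coverage, global missing/noise/error percentages,
#' and, per tricluster, its size, location, per-dimension patterns, plaid
#' coherency and planted degradation percentages.
#'
#' @param report a [solution_report()] (a `tg_dataset` is also accepted).
#' @param path_stem output path stem.
#' @return Character vector of the two written paths, invisibly.
#' @export
write_solution <- function(report, path_stem) {
  if (inherits(report, "tg_dataset")) report <- solution_report(report)
  json_path <- paste0(path_stem, "_trics.json")
  txt_path <- paste0(path_stem, "_trics.txt")
  payload <- list(
    n_triclusters = report$n_triclusters,
    dataset_dims = report$dataset_dims,
    alphabet_kind = report$alphabet_kind,
    coverage = report$coverage,
    missing_pct = report$missing_pct,
    noise_pct = report$noise_pct,
    error_pct = report$error_pct,
    overlap_groups = lapply(report$overlap_groups, function(g)
      list(members = g$members - 1L,
           edges = lapply(g$edges, function(e) e - 1L))),
    triclusters = lapply(report$triclusters, function(t)
      list(id = t$id - 1L, dims = t$dims, n_cells = t$n_cells,
           rows = t$rows - 1L, cols = t$cols - 1L, ctxs = t$ctxs - 1L,
           patterns = unname(t$patterns), profile = t$profile,
           plaid = t$plaid, missing_pct = t$missing_pct,
           noise_pct = t$noise_pct, error_pct = t$error_pct)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(format_solution(report), txt_path)
  invisible(c(json_path, txt_path))
}

# Human-readable rendering of a solution report (0-based indices, matching
# the JSON file).
format_solution <- function(report) {
  out <- c(
    sprintf("Triclustering solution: %d planted tricluster(s)", report$n_triclusters),
    sprintf("Dataset: %s", paste(report$dataset_dims, collapse = " x ")),
    sprintf("Coverage: %.4f", report$coverage),
    sprintf("Missing: %.2f%%  Noise: %.2f%%  Errors: %.2f%%",
            report$missing_pct, report$noise_pct, report$error_pct),
    "")
  for (t in report$triclusters) {
    out <- c(out,
      sprintf("Tricluster #%d: %s (%d cells)", t$id - 1L,
              paste(t$dims, collapse = " x "), t$n_cells),
      sprintf("  rows: %s", paste(t$rows - 1L, collapse = " ")),
      sprintf("  cols: %s", paste(t$cols - 1L, collapse = " ")),
      sprintf("  ctxs: %s", paste(t$ctxs - 1L, collapse = " ")),
      sprintf("  patterns: (%s)%s", paste(t$patterns, collapse = ", "),
              if (any(t$patterns == "OrderPreserving"))
                paste0(" profile=", t$profile) else ""),
      sprintf("  plaid: %s", t$plaid),
      sprintf("  missing: %.2f%%  noise: %.2f%%  errors: %.2f%%",
              t$missing_pct, t$noise_pct, t$error_pct),
      "")
  }
  out
}

#' Generate a dataset and write all output files
#'
#' Convenience wrapper used by the command-line interface: generates the
#' dataset and writes `<stem>_data.tsv`, `<stem>_trics.json` and
#' `<stem>_trics.txt`.
#'
#' @param config a [tg_config()].
#' @param path_stem output path stem.
#' @param seed integer seed.
#' @return The generated `tg_dataset`, invisibly.
#' @export
generate_and_write <- function(config, path_stem, seed = NULL) {
  dataset <- generate_dataset(config, seed = seed)
  write_dataset(dataset, path_stem)
  write_solution(solution_report(dataset), path_stem)
  invisible(dataset)
}
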