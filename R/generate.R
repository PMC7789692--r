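#' Generate a three-way dataset with a planted triclustering solution
#'
#' Runs the full pipeline: plan overlap groups, sample tricluster sizes,
#' place index sets, synthesize each tricluster's coherent values, draw the
#' background, stamp triclusters over it (composing overlap regions under
#' the configured plaid assumption), and inject missing values, noise and
#' errors. The result carries the ground truth: every planted tricluster
#' with its location, pattern triple, compact value representation and
#' per-tricluster quality counts.
#'
#' @param config a [tg_config()] (possibly from [load_config()] or
#'   [load_preset()]).
#' @param seed integer seed; identical (config, seed) pairs produce
#'   identical datasets.
#' @return An object of class `tg_dataset`: a list with `dims`, `alphabet`,
#'   `background`, `values` (3D array, `NA` = missing), `triclusters`,
#'   `plan` (overlap groups) and `quality` (degraded cell bookkeeping).
#' @examples
#' cfg <- tg_config(
#'   dims = c(30, 10, 4),
#'   alphabet = tg_alphabet("real", min = 0, max = 100),
#'   structure = tg_structure(2, size_dist("uniform", 4, 6),
#'                            size_dist("uniform", 3, 4),
#'                            size_dist("uniform", 2, 2)))
#' d <- generate_dataset(cfg, seed = 7)
#' d
#' @export
generate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- config$dims
  alphabet <- config$alphabet
  n <- config$structure$n_triclusters

  plan <- plan_overlap_groups(n, config$overlap)
  sizes <- sample_sizes(config$structure, dims)
  placements <- place_triclusters(sizes, dims, config$structure$contiguity,
                                  plan, config$overlap)

  triples <- config$patterns
  triclusters <- list()
  for (m in seq_len(n)) {
    if (is.null(placements[[m]])) next
    tr <- triples[[sample.int(length(triples), 1)]]
    pl <- placements[[m]]
    triclusters[[length(triclusters) + 1L]] <-
      build_tricluster(m, pl$rows, pl$cols, pl$ctxs, tr, alphabet,
                       plaid = config$overlap$plaid, background = config$background)
  }

  values <- generate_background(dims, alphabet, config$background)
  values <- stamp_triclusters(values, triclusters, dims, alphabet,
                              config$overlap$plaid)

  dataset <- structure(list(dims = dims, alphabet = alphabet,
                            background = config$background, values = values,
                            triclusters = triclusters, plan = plan,
                            quality = list(background = list(missing = integer(0),
                                                             noise = integer(0),
                                                             error = integer(0)),
                                           triclusters = list()),
                            config = config),
                       class = "tg_dataset")

  q <- config$quality
  if (q$bg_missing + q$bg_noise + q$bg_errors > 0)
    dataset <- inject_background(dataset, q)
  if (q$tric_missing + q$tric_noise + q$tric_errors > 0)
    for (t in dataset$triclusters) dataset <- inject_tricluster(t, dataset, q)
  dataset
}

# Write every tricluster's clean block into the value grid. Cells covered by
# a single tricluster take its value; cells shared by several are composed
# under the plaid assumption ("none" keeps the last-generated tricluster's
# value) and clamped into the alphabet.
stamp_triclusters <- function(values, triclusters, dims, alphabet, plaid) {
  if (length(triclusters) == 0) return(values)
  cell_list <- lapply(triclusters, tricluster_cells, dims = dims)
  # id order ensures the `none` plaid keeps the last-generated value
  for (i in seq_along(triclusters))
    values[cell_list[[i]]] <- as.vector(tricluster_block(triclusters[[i]]))
  if (plaid %in% c("additive", "multiplicative", "interpoled")) {
    idx_all <- unlist(cell_list, use.names = FALSE)
    dup <- unique(idx_all[duplicated(idx_all)])
    if (length(dup)) {
      val_all <- unlist(lapply(triclusters,
                               function(t) as.vector(tricluster_block(t))),
                        use.names = FALSE)
      sel <- idx_all %in% dup
      composed <- tapply(val_all[sel], idx_all[sel], function(v)
        compose_plaid(v, plaid))
      ids <- as.integer(names(composed))
      values[ids] <- alphabet_clamp(alphabet, as.numeric(composed))
    }
  }
  values
}

#' @export
print.tg_dataset <- function(x, ...) {
  cat(sprintf("<three-way dataset> %d x %d x %d (%s), %d planted triclusters\n",
              x$dims[1], x$dims[2], x$dims[3], x$alphabet$kind,
              length(x$triclusters)))
  rep <- solution_report(x)
  cat(sprintf("  coverage %.4f | missing %.2f%% | noise %.2f%% | errors %.2f%%\n",
              rep$coverage, rep$missing_pct, rep$noise_pct, rep$error_pct))
  invisible(x)
}

#' Build the triclustering solution report
#'
#' Summarizes the ground truth of a generated dataset: per tricluster its
#' size, location, per-dimension patterns, plaid coherency and the
#' percentage of missing/noisy/error cells planted in it; at dataset level
#' the number of triclusters, the coverage (fraction of cells belonging to
#' at least one tricluster) and the global degradation percentages.
#'
#' @param dataset a [tg_dataset] from [generate_dataset()].
#' @return A list of class `tg_solution`.
#' @export
solution_report <- function(dataset) {
  dims <- dataset$dims
  n_cells <- prod(dims)
  cov_cells <- covered_cells(dataset$triclusters, dims)
  qb <- dataset$quality$background
  qt <- dataset$quality$triclusters
  tot <- function(kind) {
    length(qb[[kind]]) +
      sum(vapply(qt, function(s) length(s[[kind]]), integer(1)))
  }
  trics <- lapply(dataset$triclusters, function(t) {
    size <- tricluster_size(t)
    list(id = t$id,
         dims = c(length(t$rows), length(t$cols), length(t$ctxs)),
         n_cells = size,
         rows = t$rows, cols = t$cols, ctxs = t$ctxs,
         patterns = c(row = t$triple$row, col = t$triple$col,
                      ctx = t$triple$ctx),
         profile = t$triple$profile,
         plaid = t$plaid,
         missing_pct = 100 * t$quality[["missing"]] / size,
         noise_pct = 100 * t$quality[["noise"]] / size,
         error_pct = 100 * t$quality[["error"]] / size)
  })
  groups <- lapply(dataset$plan$groups, function(g) {
    adj <- attr(g, "graph")
    list(members = as.integer(g),
         edges = if (!is.null(adj) && any(adj > 0)) {
           e <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
           lapply(seq_len(nrow(e)), function(r)
             c(g[e[r, 1]], g[e[r, 2]]))
         } else list())
  })
  structure(list(n_triclusters = length(dataset$triclusters),
                 dataset_dims = dims,
                 alphabet_kind = dataset$alphabet$kind,
                 coverage = length(cov_cells) / n_cells,
                 missing_pct = 100 * tot("missing") / n_cells,
                 noise_pct = 100 * tot("noise") / n_cells,
                 error_pct = 100 * tot("error") / n_cells,
                 overlap_groups = groups,
                 triclusters = trics),
            class = "tg_solution")
}

#' @export
print.tg_solution <- function(x, ...) {
  cat(format_solution(x), sep = "\n")
  invisible(x)
}
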