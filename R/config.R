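#' Assemble and validate a generator configuration
#'
#' Bundles everything one generation run needs: dataset dimensions,
#' alphabet, background distribution, tricluster structure, the pool of
#' admissible pattern triples, overlap settings and quality settings.
#' Validation is eager: inadmissible pattern triples, backgrounds
#' incompatible with the alphabet, numeric plaids on symbolic alphabets and
#' over-budget quality demands are all rejected here, naming the offending
#' field.
#'
#' @param dims dataset dimensions `c(n_obs, n_feat, n_ctx)`.
#' @param alphabet a [tg_alphabet()].
#' @param background a [tg_background()] (default uniform).
#' @param structure a [tg_structure()].
#' @param patterns pattern pool: `"all"` (every admissible triple for the
#'   dataset type), a character vector of families (e.g.
#'   `c("order_preserving", "constant")`), or a list of [pattern_triple()]s
#'   / 3-element character vectors.
#' @param overlap a [tg_overlap()] (default: no overlap).
#' @param quality a [tg_quality()] (default: clean data).
#' @return An object of class `tg_config`.
#' @export
tg_config <- function(dims, alphabet, background = tg_background("uniform"),
                      structure, patterns = "all",
                      overlap = tg_overlap("no_overlap"),
                      quality = tg_quality()) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1))
    stop("`dims` must be three positive integers")
  if (!inherits(alphabet, "tg_alphabet")) stop("`alphabet` must be a tg_alphabet")
  if (!inherits(structure, "tg_structure")) stop("`structure` must be a tg_structure")
  check_background(background, alphabet)
  dtype <- if (alphabet$kind == "symbolic") "symbolic" else "numeric"
  if (dtype == "symbolic" &&
      overlap$plaid %in% c("additive", "multiplicative", "interpoled"))
    stop("`overlap$plaid`: symbolic alphabets only admit the `none` plaid coherency")
  if ((alphabet$kind %in% c("integer", "symbolic")) &&
      quality$noise_deviation != round(quality$noise_deviation))
    stop("`quality$noise_deviation` must be an integer for integer/symbolic alphabets")
  triples <- resolve_patterns(patterns, dtype)
  base::structure(list(dims = dims, alphabet = alphabet, background = background,
                       structure = structure, patterns = triples,
                       overlap = overlap, quality = quality,
                       dataset_type = dtype),
                  class = "tg_config")
}

#' @export
print.tg_config <- function(x, ...) {
  cat(sprintf("<generator config> %d x %d x %d %s, %d triclusters, %d pattern triples, plaid=%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$alphabet$kind,
              x$structure$n_triclusters, length(x$patterns), x$overlap$plaid))
  invisible(x)
}

# Turn a patterns declaration into a validated list of pattern triples.
resolve_patterns <- function(patterns, dataset_type) {
  if (is.character(patterns) && length(patterns) == 1 && patterns == "all")
    return(admissible_triples(dataset_type))
  if (is.character(patterns))
    return(must_be_nonempty(admissible_triples(dataset_type, families = patterns),
                            patterns))
  stopifnot(is.list(patterns))
  triples <- lapply(patterns, function(p) {
    if (inherits(p, "tg_triple")) p
    else if (is.character(p) && length(p) >= 3)
      pattern_triple(p[1], p[2], p[3],
                     profile = if (length(p) >= 4) p[4] else "random")
    else stop("`patterns` entries must be pattern triples or 3-element character vectors")
  })
  for (tr in triples) {
    v <- validate_triple(tr, dataset_type)
    if (!v$ok) stop("`patterns`: inadmissible triple (", tr$row, ", ", tr$col,
                    ", ", tr$ctx, "): ", v$violation)
  }
  triples
}

must_be_nonempty <- function(triples, families) {
  if (length(triples) == 0)
    stop("`patterns`: no admissible triple in families ",
         paste(families, collapse = ", "))
  triples
}

#' Load a generator configuration from a YAML or JSON file
#'
#' Missing optional sections get defaults (uniform background, no overlap,
#' clean quality, all admissible patterns). See the package vignette for the
#' config schema; the essential fields are `dataset` (`type`, `dims`,
#' `alphabet`, `background`), `triclusters` (`number`, `size`, `contiguity`,
#' `patterns`), `overlap` and `quality`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [tg_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  config_from_list(raw)
}

# Build a tg_config from a plain nested list (parsed YAML/JSON).
config_from_list <- function(raw) {
  ds <- raw$dataset
  if (is.null(ds)) stop("config: missing `dataset` section")
  if (is.null(ds$dims) || length(ds$dims) != 3)
    stop("config: `dataset$dims` must be three integers")
  type <- tolower(ds$type %||% "real")
  al <- ds$alphabet
  alphabet <- switch(type,
    real = tg_alphabet("real", min = al$min, max = al$max),
    integer = tg_alphabet("integer", min = al$min, max = al$max),
    binary = tg_alphabet("integer", min = 0, max = 1),
    symbolic = tg_alphabet("symbolic",
                           symbols = if (!is.null(al$symbols)) as.character(al$symbols),
                           size = al$size),
    stop("config: unknown `dataset$type`: ", type))
  bgl <- ds$background
  background <- if (is.null(bgl)) tg_background("uniform")
  else tg_background(bgl$family %||% "uniform", mean = bgl$mean,
                     stdev = bgl$stdev, probabilities = bgl$probabilities)

  tc <- raw$triclusters
  if (is.null(tc) || is.null(tc$number))
    stop("config: missing `triclusters$number`")
  sd_of <- function(s, what) {
    if (is.null(s)) stop("config: missing `triclusters$size$", what, "`")
    if ((s$dist %||% "uniform") == "uniform")
      size_dist("uniform", s$min, s$max)
    else size_dist("normal", mean = s$mean, stdev = s$stdev)
  }
  struct <- tg_structure(tc$number,
                         sd_of(tc$size$rows, "rows"),
                         sd_of(tc$size$cols, "cols"),
                         sd_of(tc$size$ctxs, "ctxs"),
                         contiguity = tc$contiguity %||% "none")
  patterns <- tc$patterns %||% "all"
  if (is.list(patterns)) patterns <- lapply(patterns, unlist)

  ov <- raw$overlap
  overlap <- if (is.null(ov)) tg_overlap("no_overlap")
  else tg_overlap(ov$plaid %||% "no_overlap",
                  pct_triclusters = ov$pct_triclusters %||% 0,
                  max_group_size = ov$max_group_size %||% 0,
                  pct_elements = ov$pct_elements %||% 0,
                  pct_rows = ov$pct_rows %||% 100,
                  pct_cols = ov$pct_cols %||% 100,
                  pct_ctxs = ov$pct_ctxs %||% 100)

  qu <- raw$quality
  quality <- if (is.null(qu)) tg_quality()
  else tg_quality(bg_missing = qu$background$missing %||% 0,
                  bg_noise = qu$background$noise %||% 0,
                  bg_errors = qu$background$errors %||% 0,
                  tric_missing = qu$triclusters$missing %||% 0,
                  tric_noise = qu$triclusters$noise %||% 0,
                  tric_errors = qu$triclusters$errors %||% 0,
                  noise_deviation = qu$noise_deviation %||% 0)

  tg_config(dims = ds$dims, alphabet = alphabet, background = background,
            structure = struct, patterns = patterns, overlap = overlap,
            quality = quality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
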