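#' Define the value alphabet of a dataset
#'
#' An alphabet is the admissible value set of a three-way dataset: an ordered
#' list of symbols for symbolic data, or a bounded range for numeric data.
#' For symbolic alphabets the order in which symbols are given defines the
#' total order used by order-preserving patterns and by the rank distance of
#' the quality injector.
#'
#' @param kind one of `"symbolic"`, `"integer"`, `"real"`.
#' @param symbols character vector of unique symbols (symbolic only). If
#'   `NULL` and `size` is given, a default alphabet `"1"`, `"2"`, ... is built.
#' @param size number of default symbols to create (symbolic only, ignored
#'   when `symbols` is given).
#' @param min,max numeric bounds (numeric kinds only), `min < max`.
#' @return An object of class `tg_alphabet`.
#' @examples
#' tg_alphabet("real", min = -10, max = 30)
#' tg_alphabet("symbolic", symbols = c("a", "b", "c"))
#' tg_alphabet("symbolic", size = 5)
#' @export
tg_alphabet <- function(kind = c("real", "integer", "symbolic"),
                        symbols = NULL, size = NULL, min = NULL, max = NULL) {
  kind <- match.arg(kind)
  if (kind == "symbolic") {
    if (is.null(symbols)) {
      if (is.null(size)) stop("symbolic alphabet needs `symbols` or `size`")
      symbols <- as.character(seq_len(size))
    }
    symbols <- as.character(symbols)
    if (length(symbols) == 0L) stop("symbolic alphabet must be non-empty")
    if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
    obj <- list(kind = kind, symbols = symbols)
  } else {
    if (is.null(min) || is.null(max)) stop("numeric alphabet needs `min` and `max`")
    min <- as.numeric(min); max <- as.numeric(max)
    if (!(min < max)) stop("alphabet requires min < max")
    if (kind == "integer" && (min != round(min) || max != round(max)))
      stop("integer alphabet bounds must be integers")
    obj <- list(kind = kind, min = min, max = max)
  }
  structure(obj, class = "tg_alphabet")
}

#' @export
print.tg_alphabet <- function(x, ...) {
  if (x$kind == "symbolic") {
    cat("<alphabet> symbolic:", paste(x$symbols, collapse = " "), "\n")
  } else {
    cat(sprintf("<alphabet> %s: [%g, %g]\n", x$kind, x$min, x$max))
  }
  invisible(x)
}

is_numeric_alphabet <- function(a) a$kind %in% c("real", "integer")

#' Number of distinct alphabet elements
#'
#' Infinite (`Inf`) for real-valued alphabets.
#' @param a a [tg_alphabet()].
#' @return integer count, or `Inf`.
#' @export
alphabet_size <- function(a) {
  switch(a$kind,
         symbolic = length(a$symbols),
         integer  = as.integer(a$max - a$min + 1),
         real     = Inf)
}

# Enumerable elements (symbolic ranks are returned as the symbols themselves).
alphabet_elements <- function(a) {
  switch(a$kind,
         symbolic = a$symbols,
         integer  = seq(a$min, a$max),
         stop("real alphabets are not enumerable"))
}

# Check a vector of (non-missing) values against the alphabet.
alphabet_contains <- function(a, values) {
  values <- values[!is.na(values)]
  if (a$kind == "symbolic") return(all(values %in% a$symbols))
  if (a$kind == "integer" && any(values != round(values))) return(FALSE)
  all(values >= a$min & values <= a$max)
}

# Clamp numeric values into the alphabet range (integers also rounded).
alphabet_clamp <- function(a, values) {
  stopifnot(is_numeric_alphabet(a))
  if (a$kind == "integer") values <- round(values)
  pmin(pmax(values, a$min), a$max)
}

# Rank of symbolic values in alphabet order (1-based).
symbol_rank <- function(a, values) match(values, a$symbols)

#' Describe a background distribution
#'
#' The background is the set of cells belonging to no tricluster. Four
#' families are available: `uniform` (each alphabet element equiprobable, or
#' continuous uniform for real alphabets), `normal` (Gaussian draws mapped
#' into the alphabet), `discrete` (user probabilities per element; symbolic or
#' integer alphabets only) and `missing` (a null background, every cell
#' missing).
#'
#' @param family one of `"uniform"`, `"normal"`, `"discrete"`, `"missing"`.
#' @param mean,stdev Gaussian parameters (`normal` family).
#' @param probabilities numeric vector of per-element probabilities summing to
#'   1 (`discrete` family); its length must equal the alphabet size.
#' @return An object of class `tg_background`.
#' @examples
#' tg_background("normal", mean = 14, stdev = 7)
#' tg_background("discrete", probabilities = c(0.7, 0.3))
#' @export
tg_background <- function(family = c("uniform", "normal", "discrete", "missing"),
                          mean = NULL, stdev = NULL, probabilities = NULL) {
  family <- match.arg(family)
  if (family == "normal") {
    if (is.null(mean) || is.null(stdev)) stop("normal background needs `mean` and `stdev`")
    if (stdev < 0) stop("`stdev` must be non-negative")
  }
  if (family == "discrete") {
    if (is.null(probabilities)) stop("discrete background needs `probabilities`")
    if (abs(sum(probabilities) - 1) > 1e-9)
      stop("discrete background probabilities must sum to 1")
    if (any(probabilities < 0)) stop("probabilities must be non-negative")
  }
  structure(list(family = family, mean = mean, stdev = stdev,
                 probabilities = probabilities),
            class = "tg_background")
}

# Validate a background spec against an alphabet; returns invisibly or stops.
check_background <- function(spec, alphabet) {
  if (spec$family == "discrete") {
    if (alphabet$kind == "real")
      stop("discrete backgrounds are only available for symbolic or integer alphabets")
    if (length(spec$probabilities) != alphabet_size(alphabet))
      stop("discrete background needs one probability per alphabet element")
  }
  invisible(spec)
}

# Expected value of the background distribution, on the value scale for
# numeric alphabets and on the rank scale for symbolic ones. Used by the
# error injector to pick the alphabet extreme farther from the expectation.
background_expected <- function(spec, alphabet) {
  mid <- if (alphabet$kind == "symbolic") {
    (1 + length(alphabet$symbols)) / 2
  } else {
    (alphabet$min + alphabet$max) / 2
  }
  switch(spec$family,
         uniform  = mid,
         missing  = mid,
         normal   = spec$mean,
         discrete = {
           vals <- if (alphabet$kind == "symbolic")
             seq_along(alphabet$symbols) else alphabet_elements(alphabet)
           sum(spec$probabilities * vals)
         })
}
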