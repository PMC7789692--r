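#' Quality (degradation) configuration
#'
#' Background percentages are exact: `floor(|B| * pct / 100)` cells are
#' degraded. Tricluster percentages are maxima: each planted tricluster
#' receives a uniform random count in `[0, floor(|t| * pct / 100)]`.
#' `noise_deviation` is the distance boundary separating noise (within) from
#' errors (beyond): absolute difference for numeric alphabets, rank distance
#' in alphabet order for symbolic ones.
#'
#' @param bg_missing,bg_noise,bg_errors exact background percentages, 0-100.
#' @param tric_missing,tric_noise,tric_errors maximum tricluster
#'   percentages, 0-100.
#' @param noise_deviation non-negative distance threshold (integer for
#'   integer/symbolic alphabets).
#' @return An object of class `tg_quality`.
#' @export
tg_quality <- function(bg_missing = 0, bg_noise = 0, bg_errors = 0,
                       tric_missing = 0, tric_noise = 0, tric_errors = 0,
                       noise_deviation = 0) {
  pct <- c(bg_missing, bg_noise, bg_errors, tric_missing, tric_noise, tric_errors)
  if (any(pct < 0 | pct > 100)) stop("quality percentages must lie in [0, 100]")
  if (bg_missing + bg_noise + bg_errors > 100)
    stop("background missing + noise + errors must not exceed 100%")
  if (tric_missing + tric_noise + tric_errors > 100)
    stop("tricluster missing + noise + errors must not exceed 100%")
  if (noise_deviation < 0) stop("noise_deviation must be non-negative")
  structure(list(bg_missing = bg_missing, bg_noise = bg_noise,
                 bg_errors = bg_errors, tric_missing = tric_missing,
                 tric_noise = tric_noise, tric_errors = tric_errors,
                 noise_deviation = noise_deviation),
            class = "tg_quality")
}

#' Perturb a value into a noisy one
#'
#' Replaces `value` by a different value at distance at most
#' `n_deviation`, chosen uniformly from the admissible set: for symbolic and
#' integer alphabets the alphabet elements within rank/absolute distance
#' `n_deviation` (excluding the original), for real alphabets a uniform draw
#' on `[value - n_deviation, value + n_deviation]` clamped into the alphabet
#' range. If no admissible replacement exists the value is returned
#' unchanged with a warning.
#'
#' @param value the original (non-missing) value.
#' @param alphabet a [tg_alphabet()].
#' @param n_deviation positive distance bound.
#' @return The perturbed value.
#' @examples
#' set.seed(1)
#' a <- tg_alphabet("integer", min = 0, max = 9)
#' perturb_noise(5, a, 2)  # one of 3, 4, 6, 7
#' @export
perturb_noise <- function(value, alphabet, n_deviation) {
  stopifnot(all(!is.na(value)))
  perturb_noise_vec(value, alphabet, n_deviation)
}

# Vectorized noise perturbation; `values` may be any length.
perturb_noise_vec <- function(values, alphabet, n_deviation) {
  n <- length(values)
  if (n == 0) return(values)
  if (alphabet$kind == "real") {
    if (n_deviation <= 0) {
      warning("no admissible noisy replacement; value left unchanged")
      return(values)
    }
    out <- alphabet_clamp(alphabet,
                          values + stats::runif(n, -n_deviation, n_deviation))
    # boundary clamps can land back on the original; redraw those few
    for (i in 1:100) {
      eq <- which(out == values)
      if (!length(eq)) break
      out[eq] <- alphabet_clamp(alphabet,
        values[eq] + stats::runif(length(eq), -n_deviation, n_deviation))
    }
    return(out)
  }
  # integer / symbolic: uniform draw over the rank window [-Nd, Nd] \ {0}
  # clipped to the alphabet ends
  pos <- if (alphabet$kind == "symbolic") symbol_rank(alphabet, values)
         else values
  pmin_ <- if (alphabet$kind == "symbolic") 1 else alphabet$min
  pmax_ <- if (alphabet$kind == "symbolic") length(alphabet$symbols)
           else alphabet$max
  lo <- pmax(-n_deviation, pmin_ - pos)
  hi <- pmin(n_deviation, pmax_ - pos)
  cnt <- hi - lo                       # window size minus the excluded 0
  none <- cnt <= 0
  if (any(none)) warning("no admissible noisy replacement; value left unchanged")
  off <- lo + floor(stats::runif(n) * pmax(cnt, 1))
  off <- ifelse(off >= 0, off + 1, off)
  off[none] <- 0
  newpos <- pos + off
  if (alphabet$kind == "symbolic") alphabet$symbols[newpos] else newpos
}

#' Replace a value by an error
#'
#' Background scope: the error is the alphabet extreme (minimum or maximum)
#' farther from the expected value of the background distribution.
#' Tricluster scope: a uniform draw from the alphabet values at distance
#' greater than `n_deviation` from the original (beyond the noise band); if
#' that set is empty, the alphabet extreme farther from the original.
#'
#' @param value the original (non-missing) value.
#' @param alphabet a [tg_alphabet()].
#' @param n_deviation noise/error distance boundary.
#' @param scope `"background"` or `"tricluster"`.
#' @param background_spec the dataset's [tg_background()] (background scope).
#' @return The error value.
#' @examples
#' set.seed(1)
#' a <- tg_alphabet("integer", min = 0, max = 9)
#' make_error(5, a, 2, scope = "tricluster")  # one of 0, 1, 2, 8, 9
#' @export
make_error <- function(value, alphabet, n_deviation,
                       scope = c("background", "tricluster"),
                       background_spec = NULL) {
  scope <- match.arg(scope)
  make_error_vec(value, alphabet, n_deviation, scope, background_spec)
}

# Vectorized error generation over any number of original values.
make_error_vec <- function(values, alphabet, n_deviation,
                           scope = c("background", "tricluster"),
                           background_spec = NULL) {
  scope <- match.arg(scope)
  n <- length(values)
  if (n == 0) return(values)
  symbolic <- alphabet$kind == "symbolic"
  ext <- if (symbolic) alphabet$symbols[c(1L, length(alphabet$symbols))]
         else c(alphabet$min, alphabet$max)
  ext_pos <- if (symbolic) c(1, length(alphabet$symbols))
             else c(alphabet$min, alphabet$max)
  farther_from <- function(ref) {
    # per-element farther extreme, random tie-break
    d1 <- abs(ext_pos[1] - ref); d2 <- abs(ext_pos[2] - ref)
    pick2 <- ifelse(d1 == d2, stats::runif(length(ref)) < 0.5, d2 > d1)
    ifelse(pick2, ext[2], ext[1])
  }
  if (scope == "background") {
    if (is.null(background_spec)) background_spec <- tg_background("uniform")
    ref <- background_expected(background_spec, alphabet)
    e <- rep(farther_from(ref), n)
    # never hand back the original value: flip to the other extreme
    hit <- !is.na(values) & e == values
    e[hit] <- ifelse(e[hit] == ext[1], ext[2], ext[1])
    return(e)
  }
  pos <- if (symbolic) symbol_rank(alphabet, values) else values
  if (alphabet$kind == "real") {
    lo_len <- pmax(0, (values - n_deviation) - alphabet$min)
    hi_len <- pmax(0, alphabet$max - (values + n_deviation))
    tot <- lo_len + hi_len
    u <- stats::runif(n) * tot
    out <- ifelse(u < lo_len, alphabet$min + u,
                  values + n_deviation + (u - lo_len))
    empty <- tot <= 0
    out[empty] <- farther_from(pos[empty])
    return(out)
  }
  pmin_ <- if (symbolic) 1 else alphabet$min
  pmax_ <- if (symbolic) length(alphabet$symbols) else alphabet$max
  cnt_lo <- pmax(0, (pos - n_deviation - 1) - pmin_ + 1)
  cnt_hi <- pmax(0, pmax_ - (pos + n_deviation + 1) + 1)
  tot <- cnt_lo + cnt_hi
  k <- floor(stats::runif(n) * pmax(tot, 1))
  newpos <- ifelse(k < cnt_lo, pmin_ + k, pos + n_deviation + 1 + (k - cnt_lo))
  empty <- tot <= 0
  if (symbolic) {
    out <- alphabet$symbols[newpos]
    out[empty] <- farther_from(pos[empty])
  } else {
    out <- newpos
    out[empty] <- farther_from(pos[empty])
  }
  out
}

# Sample `counts` disjoint cell-id sets from `pool` (already shuffled draw).
split_cells <- function(pool, counts) {
  chosen <- pool[sample.int(length(pool), sum(counts))]
  split(chosen, rep(seq_along(counts), counts))
}

#' Inject missing values, noise and errors into the background
#'
#' Degrades exactly `floor(|B| * pct / 100)` background cells per category
#' (cells covered by no tricluster), the three target sets being disjoint
#' and sampled uniformly without replacement.
#'
#' @param dataset a generated [tg_dataset] (see [generate_dataset()]).
#' @param cfg a [tg_quality()].
#' @return The mutated dataset, with the degraded cell ids recorded in
#'   `dataset$quality$background`.
#' @export
inject_background <- function(dataset, cfg) {
  dims <- dataset$dims
  bg <- setdiff(seq_len(prod(dims)), covered_cells(dataset$triclusters, dims))
  nb <- length(bg)
  counts <- floor(nb * c(cfg$bg_missing, cfg$bg_noise, cfg$bg_errors) / 100)
  if (sum(counts) > nb)
    stop("background quality demand exceeds the number of background cells")
  if (sum(counts) == 0) return(dataset)
  sets <- split_cells(bg, counts)
  miss <- if (counts[1]) sets[["1"]] else integer(0)
  noise <- if (counts[2]) sets[["2"]] else integer(0)
  err <- if (counts[3]) sets[["3"]] else integer(0)
  dataset$values[miss] <- NA
  nz <- noise[!is.na(dataset$values[noise])]
  dataset$values[nz] <- perturb_noise_vec(dataset$values[nz], dataset$alphabet,
                                          cfg$noise_deviation)
  ez <- err[!is.na(dataset$values[err])]
  dataset$values[ez] <- make_error_vec(dataset$values[ez], dataset$alphabet,
                                       cfg$noise_deviation, "background",
                                       dataset$background)
  dataset$quality$background <- list(missing = miss, noise = noise, error = err)
  dataset
}

#' Inject missing values, noise and errors into one planted tricluster
#'
#' Unlike the background (exact counts), tricluster percentages are maxima:
#' the number of degraded cells per category is drawn uniformly from
#' `[0, floor(|t| * pct / 100)]`, cells sampled without replacement within
#' the block and disjoint from previously degraded cells.
#'
#' @param t a planted [tg_tricluster()] belonging to `dataset`.
#' @param dataset a generated [tg_dataset].
#' @param cfg a [tg_quality()].
#' @return The mutated dataset; counts are recorded in the tricluster's
#'   `quality` field and cell ids under `dataset$quality$triclusters`.
#' @export
inject_tricluster <- function(t, dataset, cfg) {
  size <- tricluster_size(t)
  maxima <- floor(size * c(cfg$tric_missing, cfg$tric_noise, cfg$tric_errors) / 100)
  counts <- vapply(maxima, function(mx) sample.int(mx + 1L, 1) - 1L, integer(1))
  cells <- tricluster_cells(t, dataset$dims)
  taken <- unlist(dataset$quality$background, use.names = FALSE)
  taken <- c(taken, unlist(dataset$quality$triclusters, use.names = FALSE))
  avail <- setdiff(cells, taken)
  if (sum(counts) > length(avail)) {
    # overlap with already-degraded cells: scale the draw down gracefully
    while (sum(counts) > length(avail)) {
      d <- which.max(counts)
      counts[d] <- counts[d] - 1L
    }
  }
  miss <- noise <- err <- integer(0)
  if (sum(counts) > 0) {
    sets <- split_cells(avail, counts)
    miss <- if (counts[1]) sets[["1"]] else integer(0)
    noise <- if (counts[2]) sets[["2"]] else integer(0)
    err <- if (counts[3]) sets[["3"]] else integer(0)
    dataset$values[miss] <- NA
    nz <- noise[!is.na(dataset$values[noise])]
    dataset$values[nz] <- perturb_noise_vec(dataset$values[nz], dataset$alphabet,
                                            cfg$noise_deviation)
    ez <- err[!is.na(dataset$values[err])]
    dataset$values[ez] <- make_error_vec(dataset$values[ez], dataset$alphabet,
                                         cfg$noise_deviation, "tricluster")
  }
  id <- as.character(t$id)
  dataset$quality$triclusters[[id]] <-
    list(missing = miss, noise = noise, error = err)
  ti <- which(vapply(dataset$triclusters, function(x) x$id == t$id, logical(1)))
  dataset$triclusters[[ti]]$quality <-
    c(missing = length(miss), noise = length(noise), error = length(err))
  dataset
}
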