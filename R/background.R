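#' Fill a dataset with background values
#'
#' Draws one value per cell from the configured background distribution.
#' Triclusters are stamped over this grid afterwards, so the background is
#' what remains visible outside every planted subspace.
#'
#' Gaussian draws on bounded alphabets are clamped into `[min, max]`; integer
#' alphabets round to the nearest integer; symbolic alphabets interpret the
#' Gaussian on the symbol-rank scale (clamped to `[1, n]` and rounded), so
#' the nominal center of the distribution is preserved.
#'
#' Uses R's global RNG stream; call `set.seed()` for reproducibility.
#'
#' @param dims dataset dimensions `c(n_obs, n_feat, n_ctx)`.
#' @param alphabet a [tg_alphabet()].
#' @param spec a [tg_background()] admissible for the alphabet.
#' @return A 3D array (`numeric` or `character` depending on the alphabet)
#'   with `NA` marking missing cells.
#' @examples
#' set.seed(1)
#' g <- generate_background(c(10, 10, 3), tg_alphabet("real", min = -10, max = 30),
#'                          tg_background("normal", mean = 14, stdev = 7))
#' range(g)
#' @export
generate_background <- function(dims, alphabet, spec) {
  check_background(spec, alphabet)
  n <- prod(dims)
  vals <- switch(spec$family,
    missing = if (alphabet$kind == "symbolic") rep(NA_character_, n) else rep(NA_real_, n),
    uniform = switch(alphabet$kind,
      real     = stats::runif(n, alphabet$min, alphabet$max),
      integer  = sample(alphabet_elements(alphabet), n, replace = TRUE),
      symbolic = sample(alphabet$symbols, n, replace = TRUE)),
    discrete = sample(alphabet_elements(alphabet), n, replace = TRUE,
                      prob = spec$probabilities),
    normal = {
      z <- stats::rnorm(n, spec$mean, spec$stdev)
      if (alphabet$kind == "symbolic") {
        ranks <- round(pmin(pmax(z, 1), length(alphabet$symbols)))
        alphabet$symbols[ranks]
      } else {
        alphabet_clamp(alphabet, z)
      }
    })
  array(vals, dim = dims)
}
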