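PATTERNS <- c("OrderPreserving", "Constant", "Additive", "Multiplicative", "None")

normalize_pattern <- function(p) {
  key <- gsub("[ _-]", "", tolower(p))
  idx <- match(key, c("orderpreserving", "constant", "additive",
                      "multiplicative", "none"))
  if (is.na(idx)) stop("unknown pattern: ", p)
  PATTERNS[idx]
}

#' Construct a pattern triple
#'
#' A pattern triple assigns one coherence pattern to each dimension of a
#' tricluster: `(P_row, P_col, P_ctx)` with patterns among
#' `OrderPreserving`, `Constant`, `Additive`, `Multiplicative` and `None`
#' (no coherence on that dimension). When the order-preserving pattern sits
#' on the context dimension, a temporal profile selects the shared ordering:
#' monotonically `increasing`, `decreasing`, or `random`.
#'
#' @param row,col,ctx pattern names (case and separators are ignored).
#' @param profile temporal profile for order-preserving contexts.
#' @return An object of class `tg_triple`.
#' @export
pattern_triple <- function(row, col, ctx,
                           profile = c("random", "increasing", "decreasing")) {
  profile <- match.arg(profile)
  structure(list(row = normalize_pattern(row), col = normalize_pattern(col),
                 ctx = normalize_pattern(ctx), profile = profile),
            class = "tg_triple")
}

#' @export
print.tg_triple <- function(x, ...) {
  cat(sprintf("<triple> (%s, %s, %s)\n", x$row, x$col, x$ctx))
  invisible(x)
}

#' Check a pattern triple against the dataset type
#'
#' Admissibility rules: at least one dimension must carry coherence; the
#' order-preserving pattern occupies exactly one dimension and forces `None`
#' on the other two; additive and multiplicative patterns never mix with each
#' other, with `None`, or with order-preserving; symbolic datasets admit no
#' additive or multiplicative pattern. These rules yield 24 admissible
#' triples for numeric datasets and 10 for symbolic ones.
#'
#' @param triple a [pattern_triple()].
#' @param dataset_type `"numeric"` or `"symbolic"`.
#' @return A list with elements `ok` (logical) and, when inadmissible,
#'   `violation` (character description of the broken rule). Never raises for
#'   mere inadmissibility.
#' @examples
#' validate_triple(pattern_triple("OrderPreserving", "None", "None"), "symbolic")
#' validate_triple(pattern_triple("Additive", "Additive", "Constant"), "symbolic")
#' @export
validate_triple <- function(triple, dataset_type = c("numeric", "symbolic")) {
  dataset_type <- match.arg(dataset_type)
  p <- c(triple$row, triple$col, triple$ctx)
  bad <- function(msg) list(ok = FALSE, violation = msg)
  if (all(p == "None"))
    return(bad("at least one dimension must carry a coherence pattern"))
  n_op <- sum(p == "OrderPreserving")
  if (n_op > 0) {
    if (n_op > 1)
      return(bad("the order-preserving pattern can only be attributed to a single dimension"))
    if (!all(p[p != "OrderPreserving"] == "None"))
      return(bad("order-preserving triples require None on the other two dimensions"))
    return(list(ok = TRUE))
  }
  has_a <- "Additive" %in% p; has_m <- "Multiplicative" %in% p
  if (has_a && has_m)
    return(bad("additive and multiplicative patterns cannot be combined"))
  if ((has_a || has_m) && "None" %in% p)
    return(bad("the None pattern can only be used in order-preserving or constant triples"))
  if ((has_a || has_m) && dataset_type == "symbolic")
    return(bad("symbolic datasets do not admit additive or multiplicative patterns"))
  list(ok = TRUE)
}

#' Enumerate admissible pattern triples
#'
#' @param dataset_type `"numeric"` or `"symbolic"`.
#' @param families optional subset of pattern families to keep:
#'   any of `"order_preserving"`, `"constant"`, `"additive"`,
#'   `"multiplicative"` (a triple's family is its strongest pattern).
#' @return List of admissible [pattern_triple()]s.
#' @export
admissible_triples <- function(dataset_type = c("numeric", "symbolic"),
                               families = NULL) {
  dataset_type <- match.arg(dataset_type)
  grid <- expand.grid(row = PATTERNS, col = PATTERNS, ctx = PATTERNS,
                      stringsAsFactors = FALSE)
  triples <- lapply(seq_len(nrow(grid)), function(r)
    pattern_triple(grid$row[r], grid$col[r], grid$ctx[r]))
  keep <- vapply(triples, function(tr) validate_triple(tr, dataset_type)$ok,
                 logical(1))
  triples <- triples[keep]
  if (!is.null(families)) {
    families <- vapply(families, function(f)
      normalize_pattern(if (gsub("[ _-]", "", tolower(f)) == "orderpreserving")
        "OrderPreserving" else f), character(1))
    triples <- Filter(function(tr) triple_family(tr) %in% families, triples)
  }
  triples
}

# The family of a triple: its strongest pattern.
triple_family <- function(triple) {
  p <- c(triple$row, triple$col, triple$ctx)
  if ("OrderPreserving" %in% p) return("OrderPreserving")
  if ("Multiplicative" %in% p) return("Multiplicative")
  if ("Additive" %in% p) return("Additive")
  "Constant"
}

#' Synthesize seed and factors for a numeric tricluster
#'
#' Draws a seed `c` and per-dimension factor vectors such that every
#' reconstructed cell value stays inside the alphabet range. Constant
#' dimensions get the neutral factor (0 for the additive model, 1 for the
#' multiplicative model); `None` dimensions of constant-family triples get
#' free random offsets. After sampling, the block extremes are computed in
#' closed form (the models are separable) and the factors are shrunk toward
#' the neutral element until the block fits the alphabet; if no
#' non-degenerate assignment fits, all factors collapse to the neutral value
#' with a warning.
#'
#' @param triple an admissible non-order-preserving [pattern_triple()].
#' @param dims block dimensions `c(|I|, |J|, |K|)`.
#' @param alphabet a numeric [tg_alphabet()].
#' @return List with `model` (`"additive"` or `"multiplicative"`), `seed`,
#'   and `row_factors`, `col_factors`, `ctx_factors`.
#' @export
build_numeric <- function(triple, dims, alphabet) {
  stopifnot(is_numeric_alphabet(alphabet))
  p <- c(triple$row, triple$col, triple$ctx)
  if ("OrderPreserving" %in% p)
    stop("order-preserving triples store explicit values; use build_order_preserving()")
  model <- if ("Multiplicative" %in% p) "multiplicative" else "additive"
  lo <- alphabet$min; hi <- alphabet$max; range <- hi - lo
  int <- alphabet$kind == "integer"

  draw_seed <- function() {
    a <- lo + range / 4; b <- hi - range / 4
    if (int) {
      cand <- seq(ceiling(a), floor(b))
      if (length(cand) == 0) cand <- alphabet_elements(alphabet)
      cand[sample.int(length(cand), 1)]
    } else stats::runif(1, a, b)
  }
  seed <- draw_seed()

  if (model == "additive") {
    amp <- range / (2 * max(dims))
    mk <- function(pat, n) {
      f <- if (pat == "Constant") rep(0, n) else stats::runif(n, -amp, amp)
      if (int) round(f) else f
    }
    fac <- Map(mk, p, dims)
    for (iter in 1:60) {
      blo <- seed + sum(vapply(fac, min, 0))
      bhi <- seed + sum(vapply(fac, max, 0))
      if (blo >= lo && bhi <= hi) break
      fac <- lapply(fac, function(f) if (int) round(f / 2) else f / 2)
    }
    blo <- seed + sum(vapply(fac, min, 0)); bhi <- seed + sum(vapply(fac, max, 0))
    if (blo < lo || bhi > hi) {
      warning("alphabet too narrow for additive factors; using constant factors")
      fac <- lapply(dims, function(n) rep(0, n))
    }
  } else {
    # keep |c| away from 0 so the factor cap is finite
    if (!int && abs(seed) < range / 100) seed <- sign(seed + (seed == 0)) * range / 100
    if (int && seed == 0) seed <- if (hi >= 1) 1 else -1
    bound <- if (seed >= 0) hi else abs(lo)
    cap <- max(1, (bound / abs(seed))^(1 / 3))
    mk <- function(pat, n) {
      f <- if (pat == "Constant") rep(1, n) else stats::runif(n, 1, cap)
      if (int) pmax(1, round(f)) else f
    }
    fac <- Map(mk, p, dims)
    for (iter in 1:60) {
      pmax_ <- prod(vapply(fac, max, 0)); pmin_ <- prod(vapply(fac, min, 0))
      ext <- seed * c(pmin_, pmax_)
      if (min(ext) >= lo && max(ext) <= hi) break
      fac <- lapply(fac, function(f) {
        f <- 1 + (f - 1) * 0.5
        if (int) pmax(1, round(f)) else f
      })
    }
    ext <- seed * c(prod(vapply(fac, min, 0)), prod(vapply(fac, max, 0)))
    if (min(ext) < lo || max(ext) > hi) {
      warning("alphabet too narrow for multiplicative factors; using constant factors")
      fac <- lapply(dims, function(n) rep(1, n))
      if (seed < lo || seed > hi) seed <- alphabet_clamp(alphabet, seed)
    }
  }
  list(model = model, seed = seed,
       row_factors = fac[[1]], col_factors = fac[[2]], ctx_factors = fac[[3]])
}

#' Synthesize the template / context seeds of a symbolic tricluster
#'
#' A constant context pattern yields a single `|I| x |J|` template repeated
#' across every context; a `None` context pattern yields one independent seed
#' per context. Within a seed, `Constant` dimensions hold their symbol fixed
#' while `None` dimensions are filled with independent uniform draws from the
#' alphabet.
#'
#' @param triple an admissible symbolic, non-order-preserving triple.
#' @param dims block dimensions `c(|I|, |J|, |K|)`.
#' @param alphabet a symbolic [tg_alphabet()].
#' @return List with `template` (matrix or `NULL`) and `context_seeds`
#'   (list of matrices or `NULL`).
#' @export
build_symbolic <- function(triple, dims, alphabet) {
  stopifnot(alphabet$kind == "symbolic")
  p <- c(triple$row, triple$col, triple$ctx)
  if (any(p %in% c("Additive", "Multiplicative", "OrderPreserving")))
    stop("symbolic builder handles constant-family triples only")
  # free (None) dimensions index independent draws; constant dimensions collapse
  free <- ifelse(p == "None", dims, 1L)
  draws <- array(sample(alphabet$symbols, prod(free), replace = TRUE), dim = free)
  at <- function(i, j, k) draws[min(i, free[1]), min(j, free[2]), min(k, free[3])]
  seed_for <- function(k) {
    outer(seq_len(dims[1]), seq_len(dims[2]),
          Vectorize(function(i, j) at(i, j, k)))
  }
  if (triple$ctx == "Constant") {
    list(template = seed_for(1L), context_seeds = NULL)
  } else {
    list(template = NULL, context_seeds = lapply(seq_len(dims[3]), seed_for))
  }
}

#' Synthesize an order-preserving tricluster block
#'
#' Order-preserving coherence fixes a single permutation of one dimension
#' such that, along every fiber of that dimension, the values read in
#' permutation order are non-decreasing; the ordering is shared by the whole
#' block (in particular it is maintained across contexts). Values are drawn
#' fiber-wise from the background distribution restricted to the alphabet
#' (uniform over the alphabet when the background is the null/missing
#' family), then sorted and laid out under the permutation.
#'
#' @param dims block dimensions `c(|I|, |J|, |K|)`.
#' @param op_dimension dimension carrying the ordering: `"rows"`, `"cols"`
#'   or `"ctxs"`.
#' @param temporal_profile `"increasing"` (identity permutation),
#'   `"decreasing"` (reversal) or `"random"` (uniform over permutations).
#' @param alphabet a [tg_alphabet()].
#' @param background optional [tg_background()] used as the value source.
#' @return List with `block` (`|I| x |J| x |K|` array) and `perm` (the
#'   ordering permutation).
#' @export
build_order_preserving <- function(dims, op_dimension = c("rows", "cols", "ctxs"),
                                   temporal_profile = c("random", "increasing",
                                                        "decreasing"),
                                   alphabet, background = NULL) {
  op_dimension <- match.arg(op_dimension)
  temporal_profile <- match.arg(temporal_profile)
  d <- match(op_dimension, c("rows", "cols", "ctxs"))
  n <- dims[d]
  perm <- switch(temporal_profile,
                 increasing = seq_len(n),
                 decreasing = rev(seq_len(n)),
                 random = sample.int(n))
  n_fib <- prod(dims[-d])
  draws <- draw_from_background(n * n_fib, alphabet, background)
  if (alphabet$kind == "symbolic") {
    ranks <- matrix(symbol_rank(alphabet, draws), nrow = n)
    sorted <- apply(ranks, 2, sort)
    m <- matrix(NA_integer_, nrow = n, ncol = n_fib)
    m[perm, ] <- sorted
    vals <- alphabet$symbols[m]
  } else {
    sorted <- apply(matrix(draws, nrow = n), 2, sort)
    m <- matrix(NA_real_, nrow = n, ncol = n_fib)
    m[perm, ] <- sorted
    vals <- m
  }
  # op dimension is currently first; rotate back into (rows, cols, ctxs)
  md <- c(d, setdiff(1:3, d))
  block <- aperm(array(vals, dim = dims[md]), order(md))
  list(block = block, perm = perm)
}

# n draws from the background distribution restricted to the alphabet;
# falls back to uniform draws when the background carries no values.
draw_from_background <- function(n, alphabet, background = NULL) {
  if (is.null(background) || background$family == "missing")
    background <- tg_background("uniform")
  as.vector(generate_background(c(n, 1, 1), alphabet, background))
}

# Build a complete tricluster from placed index sets and a triple.
build_tricluster <- function(id, rows, cols, ctxs, triple, alphabet,
                             plaid = "none", background = NULL) {
  dims <- c(length(rows), length(cols), length(ctxs))
  p <- c(triple$row, triple$col, triple$ctx)
  if ("OrderPreserving" %in% p) {
    opd <- c("rows", "cols", "ctxs")[match("OrderPreserving", p)]
    prof <- if (opd == "ctxs") triple$profile else "random"
    built <- build_order_preserving(dims, opd, prof, alphabet, background)
    return(tg_tricluster(id, rows, cols, ctxs, triple, "order_preserving",
                         block = built$block, perm = built$perm, plaid = plaid))
  }
  if (alphabet$kind == "symbolic") {
    built <- build_symbolic(triple, dims, alphabet)
    return(tg_tricluster(id, rows, cols, ctxs, triple, "symbolic",
                         template = built$template,
                         context_seeds = built$context_seeds, plaid = plaid))
  }
  built <- build_numeric(triple, dims, alphabet)
  tg_tricluster(id, rows, cols, ctxs, triple, built$model, seed = built$seed,
                row_factors = built$row_factors, col_factors = built$col_factors,
                ctx_factors = built$ctx_factors, plaid = plaid)
}
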