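#' Construct a planted tricluster specification
#'
#' A tricluster is a subspace (I, J, K) of the dataset whose cells satisfy a
#' declared coherence. Numeric triclusters are stored compactly as a seed
#' plus per-dimension factors (additive or multiplicative model); symbolic
#' triclusters as a template seed matrix repeated across contexts, or one
#' seed per context; order-preserving triclusters store their values
#' explicitly together with the shared ordering permutation, because the
#' seed-and-factor form cannot express an ordering constraint.
#'
#' @param id integer identifier (generation order; relevant for the `none`
#'   plaid rule, which keeps the last-generated tricluster's value).
#' @param rows,cols,ctxs sorted 1-based index vectors into the dataset.
#' @param triple a [pattern_triple()].
#' @param model one of `"additive"`, `"multiplicative"`, `"symbolic"`,
#'   `"order_preserving"`.
#' @param seed numeric seed `c` (numeric models).
#' @param row_factors,col_factors,ctx_factors per-dimension factor vectors
#'   (numeric models; lengths `|I|`, `|J|`, `|K|`).
#' @param template `|I| x |J|` character matrix (symbolic, constant context
#'   pattern).
#' @param context_seeds list of `|K|` character matrices (symbolic, `none`
#'   context pattern).
#' @param block explicit `|I| x |J| x |K|` value array (order-preserving).
#' @param perm ordering permutation of the order-preserving dimension.
#' @param plaid plaid coherency of this tricluster's overlap regions.
#' @return An object of class `tg_tricluster`.
#' @seealso [reconstruct_cell()], [tricluster_block()]
#' @export
tg_tricluster <- function(id, rows, cols, ctxs, triple, model,
                          seed = NULL, row_factors = NULL, col_factors = NULL,
                          ctx_factors = NULL, template = NULL,
                          context_seeds = NULL, block = NULL, perm = NULL,
                          plaid = "none") {
  stopifnot(length(rows) >= 1, length(cols) >= 1, length(ctxs) >= 1)
  structure(list(id = id,
                 rows = as.integer(sort(rows)),
                 cols = as.integer(sort(cols)),
                 ctxs = as.integer(sort(ctxs)),
                 triple = triple, model = model, seed = seed,
                 row_factors = row_factors, col_factors = col_factors,
                 ctx_factors = ctx_factors, template = template,
                 context_seeds = context_seeds, block = block, perm = perm,
                 plaid = plaid,
                 quality = c(missing = 0L, noise = 0L, error = 0L)),
            class = "tg_tricluster")
}

#' @export
print.tg_tricluster <- function(x, ...) {
  cat(sprintf("<tricluster #%d> %dx%dx%d (%s,%s,%s) model=%s plaid=%s\n",
              x$id, length(x$rows), length(x$cols), length(x$ctxs),
              x$triple$row, x$triple$col, x$triple$ctx, x$model, x$plaid))
  invisible(x)
}

# Cell count of a tricluster block.
tricluster_size <- function(t) {
  length(t$rows) * length(t$cols) * length(t$ctxs)
}

#' Reconstruct the clean value of one tricluster cell
#'
#' Evaluates the tricluster's coherence model at local indices `(i, j, k)`
#' (1-based positions within the block): `c + alpha_i + beta_j + gamma_k` for
#' the additive model, `c * alpha_i * beta_j * gamma_k` for the
#' multiplicative model, and a template / context-seed lookup for symbolic
#' triclusters. Order-preserving triclusters store their values explicitly
#' and are not reconstructible from factors; asking for one is an error.
#'
#' @param t a [tg_tricluster()].
#' @param i,j,k local 1-based indices into the block.
#' @return The clean (pre-quality-injection) cell value.
#' @examples
#' t <- tg_tricluster(1, 1:3, 1:3, 1:3,
#'   pattern_triple("Constant", "Additive", "Additive"), "additive",
#'   seed = 1, row_factors = c(0, 0, 0), col_factors = c(1, 2, 3),
#'   ctx_factors = c(2, -1, 6))
#' reconstruct_cell(t, 1, 2, 1)  # 1 + 0 + 2 + 2 = 5
#' @export
reconstruct_cell <- function(t, i, j, k) {
  ni <- length(t$rows); nj <- length(t$cols); nk <- length(t$ctxs)
  if (i < 1 || i > ni || j < 1 || j > nj || k < 1 || k > nk)
    stop("local index out of range for tricluster block")
  switch(t$model,
    additive = t$seed + t$row_factors[i] + t$col_factors[j] + t$ctx_factors[k],
    multiplicative = t$seed * t$row_factors[i] * t$col_factors[j] * t$ctx_factors[k],
    symbolic = if (!is.null(t$template)) t$template[i, j] else t$context_seeds[[k]][i, j],
    order_preserving = stop("order-preserving triclusters store values explicitly; ",
                            "reconstruction from factors is unsupported"))
}

# Full clean value block of a tricluster, as an |I| x |J| x |K| array.
# Vectorized equivalent of reconstruct_cell over all local cells.
tricluster_block <- function(t) {
  ni <- length(t$rows); nj <- length(t$cols); nk <- length(t$ctxs)
  switch(t$model,
    additive = {
      b <- outer(outer(t$row_factors, t$col_factors, `+`), t$ctx_factors, `+`)
      t$seed + b
    },
    multiplicative = {
      t$seed * outer(outer(t$row_factors, t$col_factors, `*`), t$ctx_factors, `*`)
    },
    symbolic = {
      if (!is.null(t$template)) {
        array(rep(t$template, nk), dim = c(ni, nj, nk))
      } else {
        arr <- array(NA_character_, dim = c(ni, nj, nk))
        for (k in seq_len(nk)) arr[, , k] <- t$context_seeds[[k]]
        arr
      }
    },
    order_preserving = t$block)
}

# Linear (1-based) dataset cell ids of a tricluster's block, given dataset dims.
tricluster_cells <- function(t, dims) {
  cell_ids(t$rows, t$cols, t$ctxs, dims)
}

# Linear ids for the Cartesian product I x J x K under dims (nx, ny, nz).
cell_ids <- function(rows, cols, ctxs, dims) {
  nx <- dims[1]; ny <- dims[2]
  ij <- outer(rows, (cols - 1L) * nx, `+`)
  as.integer(outer(ij, (ctxs - 1L) * nx * ny, `+`))
}

#' Cells covered by a set of triclusters
#'
#' Union of the Cartesian products I x J x K of every tricluster, as linear
#' 1-based cell ids into the dataset array. Coverage and background-size
#' accounting are both derived from this set.
#'
#' @param ts list of [tg_tricluster()] objects.
#' @param dims dataset dimensions `c(n_obs, n_feat, n_ctx)`.
#' @return Sorted integer vector of distinct covered cell ids.
#' @export
covered_cells <- function(ts, dims) {
  if (length(ts) == 0L) return(integer(0))
  ids <- unlist(lapply(ts, tricluster_cells, dims = dims), use.names = FALSE)
  sort(unique(ids))
}
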