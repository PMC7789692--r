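test_that("triple admissibility matches the brute-force rule oracle", {
  pats <- c("OrderPreserving", "Constant", "Additive", "Multiplicative", "None")
  grid <- expand.grid(row = pats, col = pats, ctx = pats,
                      stringsAsFactors = FALSE)
  for (type in c("numeric", "symbolic")) {
    got <- vapply(seq_len(nrow(grid)), function(r)
      validate_triple(pattern_triple(grid$row[r], grid$col[r], grid$ctx[r]),
                      type)$ok, logical(1))
    want <- vapply(seq_len(nrow(grid)), function(r)
      oracle_admissible(grid$row[r], grid$col[r], grid$ctx[r], type),
      logical(1))
    expect_identical(got, want, label = type)
  }
  expect_length(admissible_triples("numeric"), 24)
  expect_length(admissible_triples("symbolic"), 10)
})

test_that("specific rule violations are named, not raised", {
  v <- validate_triple(pattern_triple("Additive", "Additive", "Constant"),
                       "symbolic")
  expect_false(v$ok)
  expect_match(v$violation, "symbolic")
  v <- validate_triple(pattern_triple("Additive", "Multiplicative", "Constant"),
                       "numeric")
  expect_false(v$ok)
  expect_match(v$violation, "cannot be combined")
  v <- validate_triple(pattern_triple("OrderPreserving", "Constant", "None"),
                       "numeric")
  expect_false(v$ok)
  expect_match(v$violation, "None on the other two")
  expect_true(validate_triple(pattern_triple("OrderPreserving", "None", "None"),
                              "symbolic")$ok)
})

test_that("numeric builder keeps every block value inside the alphabet", {
  set.seed(10)
  a <- tg_alphabet("real", min = 0, max = 100)
  for (rep in 1:20) {
    triple <- pattern_triple("Multiplicative", "Multiplicative",
                             "Multiplicative")
    b <- build_numeric(triple, c(3, 4, 2), a)
    t <- tg_tricluster(1, 1:3, 1:4, 1:2, triple, b$model, seed = b$seed,
                       row_factors = b$row_factors, col_factors = b$col_factors,
                       ctx_factors = b$ctx_factors)
    blk <- tricgen:::tricluster_block(t)
    expect_true(max(blk) <= 100 && min(blk) >= 0)
  }
  ai <- tg_alphabet("integer", min = 0, max = 100)
  for (rep in 1:20) {
    triple <- pattern_triple("Additive", "Additive", "Constant")
    b <- build_numeric(triple, c(4, 3, 3), ai)
    t <- tg_tricluster(1, 1:4, 1:3, 1:3, triple, b$model, seed = b$seed,
                       row_factors = b$row_factors, col_factors = b$col_factors,
                       ctx_factors = b$ctx_factors)
    blk <- tricgen:::tricluster_block(t)
    expect_true(all(blk == round(blk)))
    expect_true(max(blk) <= 100 && min(blk) >= 0)
  }
})

test_that("constant dimensions carry the neutral factor", {
  set.seed(11)
  b <- build_numeric(pattern_triple("Constant", "Additive", "Additive"),
                     c(3, 3, 3), real_alphabet())
  expect_identical(b$row_factors, rep(0, 3))
  b <- build_numeric(pattern_triple("Constant", "Multiplicative", "Constant"),
                     c(2, 3, 4), real_alphabet(0, 100))
  expect_identical(b$row_factors, rep(1, 2))
  expect_identical(b$ctx_factors, rep(1, 4))
  b <- build_numeric(pattern_triple("Constant", "Constant", "Constant"),
                     c(2, 2, 2), real_alphabet())
  t <- tg_tricluster(1, 1:2, 1:2, 1:2, pattern_triple("Constant", "Constant",
                                                      "Constant"),
                     b$model, seed = b$seed, row_factors = b$row_factors,
                     col_factors = b$col_factors, ctx_factors = b$ctx_factors)
  expect_true(all(tricgen:::tricluster_block(t) == b$seed))
})

test_that("symbolic builder honors constant and free dimensions", {
  set.seed(12)
  a <- abc_alphabet()
  # fully constant: one symbol fills the block
  b <- build_symbolic(pattern_triple("Constant", "Constant", "Constant"),
                      c(3, 3, 2), a)
  expect_length(unique(as.vector(b$template)), 1)
  # rows free, cols and ctxs constant: each row holds one symbol
  b <- build_symbolic(pattern_triple("None", "Constant", "Constant"),
                      c(3, 4, 2), a)
  expect_null(b$context_seeds)
  for (r in 1:3) expect_length(unique(b$template[r, ]), 1)
  # contexts free: one seed per context, each internally constant
  b <- build_symbolic(pattern_triple("Constant", "Constant", "None"),
                      c(2, 2, 2), a)
  expect_null(b$template)
  expect_length(b$context_seeds, 2)
  for (s in b$context_seeds) expect_length(unique(as.vector(s)), 1)
})

test_that("order-preserving blocks share one permutation across all fibers", {
  set.seed(13)
  # increasing profile on contexts uses the identity permutation
  b <- build_order_preserving(c(3, 2, 4), "ctxs", "increasing",
                              real_alphabet())
  expect_identical(b$perm, 1:4)
  for (i in 1:3) for (j in 1:2)
    expect_true(!is.unsorted(b$block[i, j, ]))
  b <- build_order_preserving(c(3, 2, 4), "ctxs", "decreasing",
                              real_alphabet())
  expect_identical(b$perm, 4:1)
  for (i in 1:3) for (j in 1:2)
    expect_true(!is.unsorted(rev(b$block[i, j, ])))
  # random permutation on columns: every (row, ctx) fiber is sorted under it
  for (rep in 1:10) {
    b <- build_order_preserving(c(3, 4, 2), "cols", "random", digit_alphabet())
    for (i in 1:3) for (k in 1:2)
      expect_true(!is.unsorted(b$block[i, b$perm, k]))
  }
  # symbolic order-preserving uses the alphabet order
  b <- build_order_preserving(c(2, 3, 2), "cols", "random", abc_alphabet())
  rk <- function(v) match(v, letters)
  for (i in 1:2) for (k in 1:2)
    expect_true(!is.unsorted(rk(b$block[i, b$perm, k])))
})

test_that("singleton order-preserving dimensions are valid degenerate cases", {
  set.seed(14)
  b <- build_order_preserving(c(1, 3, 1), "cols", "random", digit_alphabet())
  expect_true(!is.unsorted(b$block[1, b$perm, 1]))
  b <- build_order_preserving(c(2, 2, 1), "ctxs", "random", real_alphabet())
  expect_identical(b$perm, 1L)
})

test_that("every admissible triple yields an exactly coherent tricluster", {
  set.seed(15)
  check_coherence <- function(t, alphabet) {
    blk <- tricgen:::tricluster_block(t)
    p <- c(t$triple$row, t$triple$col, t$triple$ctx)
    if (t$model %in% c("additive", "multiplicative")) {
      for (rep in 1:5) {
        i <- sample(dim(blk)[1], 1); j <- sample(dim(blk)[2], 1)
        k <- sample(dim(blk)[3], 1)
        expect_equal(blk[i, j, k], reconstruct_cell(t, i, j, k))
      }
    }
    if (t$model == "order_preserving") {
      d <- match("OrderPreserving", p)
      perm <- t$perm
      fib <- function(v) if (alphabet$kind == "symbolic")
        match(v, alphabet$symbols) else v
      idx <- expand.grid(a = seq_len(dim(blk)[setdiff(1:3, d)[1]]),
                         b = seq_len(dim(blk)[setdiff(1:3, d)[2]]))
      for (r in seq_len(nrow(idx))) {
        v <- switch(d,
                    blk[perm, idx$a[r], idx$b[r]],
                    blk[idx$a[r], perm, idx$b[r]],
                    blk[idx$a[r], idx$b[r], perm])
        expect_true(!is.unsorted(fib(v)))
      }
    } else {
      # constancy along every Constant dimension
      for (d in which(p == "Constant")) {
        m <- apply(blk, setdiff(1:3, d), function(v) length(unique(v)))
        expect_true(all(m == 1))
      }
    }
    expect_true(tricgen:::alphabet_contains(alphabet, blk))
  }
  for (alphabet in list(real_alphabet(), digit_alphabet(), abc_alphabet())) {
    type <- if (alphabet$kind == "symbolic") "symbolic" else "numeric"
    for (triple in admissible_triples(type)) {
      for (rep in 1:3) {
        dims <- c(sample(2:4, 1), sample(2:4, 1), sample(2:4, 1))
        t <- tricgen:::build_tricluster(1, seq_len(dims[1]), seq_len(dims[2]),
                                        seq_len(dims[3]), triple, alphabet)
        check_coherence(t, alphabet)
      }
    }
  }
})
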