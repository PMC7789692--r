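test_that("clean planted blocks match their compact representation exactly", {
  set.seed(60)
  d <- generate_dataset(small_config(3, dims = c(40, 15, 6)), seed = 60)
  for (t in d$triclusters) {
    blk <- tricgen:::tricluster_block(t)
    cells <- tricgen:::tricluster_cells(t, d$dims)
    expect_equal(d$values[cells], as.vector(blk))
    if (t$model %in% c("additive", "multiplicative")) {
      i <- sample(length(t$rows), 1); j <- sample(length(t$cols), 1)
      k <- sample(length(t$ctxs), 1)
      expect_equal(d$values[t$rows[i], t$cols[j], t$ctxs[k]],
                   reconstruct_cell(t, i, j, k))
    }
  }
})

test_that("overlap cells equal the plaid composition of their contributions", {
  set.seed(61)
  for (plaid in c("additive", "multiplicative", "interpoled")) {
    cfg <- small_config(4, dims = c(50, 20, 6),
                        alphabet = real_alphabet(-1000, 1000),
                        overlap = tg_overlap(plaid, pct_triclusters = 100,
                                             max_group_size = 2,
                                             pct_elements = 50))
    d <- generate_dataset(cfg, seed = 61)
    cells <- lapply(d$triclusters, tricgen:::tricluster_cells, dims = d$dims)
    blocks <- lapply(d$triclusters, function(t)
      as.vector(tricgen:::tricluster_block(t)))
    all_cells <- unlist(cells)
    dup <- unique(all_cells[duplicated(all_cells)])
    expect_gt(length(dup), 0)
    for (cell in dup) {
      contrib <- numeric(0)
      for (ti in seq_along(cells)) {
        pos <- match(cell, cells[[ti]])
        if (!is.na(pos)) contrib <- c(contrib, blocks[[ti]][pos])
      }
      want <- compose_plaid(contrib, plaid)
      want <- min(max(want, -1000), 1000)
      expect_equal(d$values[cell], want)
    }
  }
})

test_that("`none` plaid keeps the last-generated tricluster's value", {
  set.seed(62)
  cfg <- small_config(4, dims = c(50, 20, 6),
                      overlap = tg_overlap("none", pct_triclusters = 100,
                                           max_group_size = 2,
                                           pct_elements = 50))
  d <- generate_dataset(cfg, seed = 62)
  cells <- lapply(d$triclusters, tricgen:::tricluster_cells, dims = d$dims)
  all_cells <- unlist(cells)
  dup <- unique(all_cells[duplicated(all_cells)])
  for (cell in dup) {
    holders <- which(vapply(cells, function(cc) cell %in% cc, logical(1)))
    last <- max(holders)
    pos <- match(cell, cells[[last]])
    expect_equal(d$values[cell],
                 as.vector(tricgen:::tricluster_block(d$triclusters[[last]]))[pos])
  }
})

test_that("the full pipeline is deterministic given (config, seed)", {
  cfg <- small_config(3, overlap = tg_overlap("additive",
                                              pct_triclusters = 100,
                                              max_group_size = 2,
                                              pct_elements = 40),
                      quality = tg_quality(bg_missing = 5, bg_noise = 10,
                                           bg_errors = 2, tric_missing = 10,
                                           tric_noise = 10,
                                           noise_deviation = 3))
  s1 <- tempfile(); s2 <- tempfile()
  d1 <- generate_dataset(cfg, seed = 77)
  write_dataset(d1, s1); write_solution(solution_report(d1), s1)
  d2 <- generate_dataset(cfg, seed = 77)
  write_dataset(d2, s2); write_solution(solution_report(d2), s2)
  for (suffix in c("_data.tsv", "_trics.json", "_trics.txt"))
    expect_identical(readLines(paste0(s1, suffix)),
                     readLines(paste0(s2, suffix)))
  d3 <- generate_dataset(cfg, seed = 78)
  expect_false(identical(d1$values, d3$values))
})

test_that("generated values always stay within the alphabet", {
  set.seed(63)
  for (cfg in list(
    small_config(3, alphabet = digit_alphabet(),
                 quality = tg_quality(bg_noise = 20, bg_errors = 10,
                                      noise_deviation = 2)),
    small_config(3, alphabet = abc_alphabet(),
                 patterns = c("constant", "order_preserving"),
                 quality = tg_quality(bg_noise = 10, bg_errors = 10,
                                      tric_noise = 20, noise_deviation = 1)),
    small_config(3, alphabet = real_alphabet(0, 1),
                 quality = tg_quality(bg_noise = 10, noise_deviation = 0.1)))) {
    d <- generate_dataset(cfg, seed = 64)
    expect_true(tricgen:::alphabet_contains(d$alphabet, d$values))
  }
})

test_that("quality injection never touches cells outside its scope", {
  set.seed(65)
  cfg <- quality_example_config(bg_missing = 20, bg_noise = 10, bg_errors = 5)
  cfg$quality$tric_missing <- 30
  d <- generate_dataset(cfg, seed = 65)
  covered <- covered_cells(d$triclusters, d$dims)
  qb <- d$quality$background
  expect_length(intersect(unlist(qb), covered), 0)
  qt <- unlist(d$quality$triclusters)
  expect_true(all(qt %in% covered))
})
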