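test_that("sampled sizes respect their distribution bounds", {
  set.seed(30)
  cfg <- tg_structure(50, size_dist("uniform", 30, 50),
                      size_dist("uniform", 5, 10), size_dist("uniform", 2, 4))
  s <- sample_sizes(cfg, c(1000, 100, 10))
  expect_true(all(s[, "rows"] >= 30 & s[, "rows"] <= 50))
  expect_true(all(s[, "cols"] >= 5 & s[, "cols"] <= 10))
  expect_true(all(s[, "ctxs"] >= 2 & s[, "ctxs"] <= 4))

  # degenerate distributions always return their fixed value
  cfg2 <- tg_structure(20, size_dist("uniform", 4, 4),
                       size_dist("uniform", 4, 4), size_dist("uniform", 8, 8))
  s2 <- sample_sizes(cfg2, c(28, 20, 365))
  expect_true(all(s2[, "rows"] == 4 & s2[, "cols"] == 4 & s2[, "ctxs"] == 8))

  cfg3 <- tg_structure(20, size_dist("normal", mean = 5, stdev = 0),
                       size_dist("normal", mean = 5, stdev = 0),
                       size_dist("normal", mean = 5, stdev = 0))
  expect_true(all(sample_sizes(cfg3, c(50, 50, 50)) == 5))
})

test_that("sizes are clipped to the dataset and bad supports rejected", {
  set.seed(31)
  cfg <- tg_structure(10, size_dist("normal", mean = 100, stdev = 50),
                      size_dist("uniform", 1, 3), size_dist("uniform", 1, 3))
  s <- sample_sizes(cfg, c(20, 5, 5))
  expect_true(all(s[, "rows"] >= 1 & s[, "rows"] <= 20))
  bad <- tg_structure(5, size_dist("uniform", 30, 50),
                      size_dist("uniform", 1, 2), size_dist("uniform", 1, 2))
  expect_error(sample_sizes(bad, c(10, 5, 5)), "outside")
})

test_that("placed index sets are sorted, duplicate-free and within bounds", {
  set.seed(32)
  sizes <- sample_sizes(tg_structure(6, size_dist("uniform", 3, 6),
                                     size_dist("uniform", 2, 4),
                                     size_dist("uniform", 2, 3)),
                        c(40, 15, 8))
  pl <- place_triclusters(sizes, c(40, 15, 8))
  for (p in pl) {
    for (d in 1:3) {
      expect_false(is.unsorted(p[[d]], strictly = TRUE))
      expect_true(all(p[[d]] >= 1))
    }
    expect_true(all(p$rows <= 40) && all(p$cols <= 15) && all(p$ctxs <= 8))
  }
})

test_that("no-overlap placement conserves cell counts (disjoint union)", {
  set.seed(33)
  dims <- c(40, 15, 8)
  sizes <- sample_sizes(tg_structure(5, size_dist("uniform", 3, 6),
                                     size_dist("uniform", 2, 4),
                                     size_dist("uniform", 2, 3)), dims)
  pl <- place_triclusters(sizes, dims)
  all_cells <- unlist(lapply(pl, function(p)
    enumerate_cells(p$rows, p$cols, p$ctxs, dims)))
  expect_identical(anyDuplicated(all_cells), 0L)
  expect_length(all_cells, sum(apply(sizes, 1, prod)))
})

test_that("contiguous contexts form a run with a uniform start", {
  set.seed(34)
  starts <- integer(0)
  sizes <- matrix(c(3L, 2L, 4L), 1, dimnames = list(NULL, c("rows", "cols", "ctxs")))
  for (rep in 1:300) {
    pl <- place_triclusters(sizes, c(20, 10, 10), contiguity = "contexts")
    k <- pl[[1]]$ctxs
    expect_length(k, 4)
    expect_identical(max(k) - min(k) + 1L, 4L)  # a run
    starts <- c(starts, min(k))
  }
  # start index ranges over every feasible position 1..(10 - 4 + 1)
  expect_identical(sort(unique(starts)), 1:7)
})

test_that("designated pairs share between one cell and their quota", {
  set.seed(35)
  dims <- c(30, 30, 30)
  sizes <- matrix(c(2L, 2L, 2L, 3L, 3L, 3L), 2, byrow = TRUE,
                  dimnames = list(NULL, c("rows", "cols", "ctxs")))
  cfg <- tg_overlap("additive", pct_triclusters = 100, max_group_size = 2,
                    pct_elements = 50)
  for (rep in 1:50) {
    plan <- plan_overlap_groups(2, cfg)
    pl <- place_triclusters(sizes, dims, plan = plan, overlap_cfg = cfg)
    shared <- length(intersect(
      enumerate_cells(pl[[1]]$rows, pl[[1]]$cols, pl[[1]]$ctxs, dims),
      enumerate_cells(pl[[2]]$rows, pl[[2]]$cols, pl[[2]]$ctxs, dims)))
    expect_gte(shared, 1)
    expect_lte(shared, 4)  # floor(0.5 * 8)
  }
})

test_that("per-dimension caps bound every overlapping pair", {
  set.seed(36)
  dims <- c(60, 40, 20)
  cfg <- tg_overlap("additive", pct_triclusters = 100, max_group_size = 3,
                    pct_elements = 80, pct_rows = 50, pct_cols = 50,
                    pct_ctxs = 50)
  sizes <- sample_sizes(tg_structure(6, size_dist("uniform", 4, 6),
                                     size_dist("uniform", 4, 6),
                                     size_dist("uniform", 2, 4)), dims)
  plan <- plan_overlap_groups(6, cfg)
  pl <- suppressWarnings(
    place_triclusters(sizes, dims, plan = plan, overlap_cfg = cfg))
  placed <- which(!vapply(pl, is.null, logical(1)))
  for (i in placed) for (j in placed[placed < i]) {
    for (d in 1:3) {
      sh <- length(intersect(pl[[i]][[d]], pl[[j]][[d]]))
      expect_lte(sh, floor(0.5 * min(sizes[i, d], sizes[j, d])))
    }
  }
})

test_that("infeasible placements degrade to a warning, not an error", {
  set.seed(37)
  # 5 disjoint 3x3x3 triclusters cannot fit in a 4x4x4 dataset
  sizes <- matrix(3L, 5, 3, dimnames = list(NULL, c("rows", "cols", "ctxs")))
  expect_warning(
    pl <- place_triclusters(sizes, c(4, 4, 4), max_attempts = 20),
    "maximal placed set")
  expect_lt(sum(!vapply(pl, is.null, logical(1))), 5)
})
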