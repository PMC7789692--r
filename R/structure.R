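#' Size distribution for one tricluster dimension
#'
#' @param dist `"uniform"` or `"normal"`.
#' @param min,max uniform bounds (inclusive).
#' @param mean,stdev normal parameters.
#' @return An object of class `tg_sizedist`.
#' @examples
#' size_dist("uniform", 30, 50)
#' size_dist("normal", mean = 5, stdev = 0)
#' @export
size_dist <- function(dist = c("uniform", "normal"), min = NULL, max = NULL,
                      mean = NULL, stdev = NULL) {
  dist <- match.arg(dist)
  if (dist == "uniform") {
    if (is.null(min) || is.null(max)) stop("uniform size needs `min` and `max`")
    if (min > max) stop("uniform size needs min <= max")
  } else {
    if (is.null(mean) || is.null(stdev)) stop("normal size needs `mean` and `stdev`")
    if (stdev < 0) stop("`stdev` must be non-negative")
  }
  structure(list(dist = dist, min = min, max = max, mean = mean, stdev = stdev),
            class = "tg_sizedist")
}

#' Tricluster structure configuration
#'
#' @param n_triclusters number of triclusters to plant.
#' @param rows,cols,ctxs a [size_dist()] per dimension.
#' @param contiguity `"none"`, `"features"` or `"contexts"`: a contiguous
#'   dimension's index set is a run of consecutive indices (time-series-like
#'   data).
#' @return An object of class `tg_structure`.
#' @export
tg_structure <- function(n_triclusters, rows, cols, ctxs,
                         contiguity = c("none", "features", "contexts")) {
  contiguity <- match.arg(contiguity)
  stopifnot(n_triclusters >= 1)
  structure(list(n_triclusters = n_triclusters, rows = rows, cols = cols,
                 ctxs = ctxs, contiguity = contiguity),
            class = "tg_structure")
}

#' Sample tricluster sizes
#'
#' Draws one `(|I|, |J|, |K|)` triple per requested tricluster from the
#' per-dimension size distributions, rounds to integers (half-to-even) and
#' clips to `[1, dimension length]`.
#'
#' @param cfg a [tg_structure()].
#' @param dataset_dims dataset dimensions `c(n_obs, n_feat, n_ctx)`.
#' @return Integer matrix with `n_triclusters` rows and columns
#'   `rows`, `cols`, `ctxs`.
#' @export
sample_sizes <- function(cfg, dataset_dims) {
  dists <- list(cfg$rows, cfg$cols, cfg$ctxs)
  n <- cfg$n_triclusters
  out <- vapply(1:3, function(d) {
    sd_ <- dists[[d]]; dim_len <- dataset_dims[d]
    if (sd_$dist == "uniform") {
      if (sd_$min > dim_len || sd_$max < 1)
        stop("size distribution support lies outside [1, dimension length]")
      s <- round(stats::runif(n, sd_$min, sd_$max))
    } else {
      s <- round(stats::rnorm(n, sd_$mean, sd_$stdev))
    }
    pmin(pmax(s, 1), dim_len)
  }, numeric(n))
  out <- matrix(as.integer(out), nrow = n,
                dimnames = list(NULL, c("rows", "cols", "ctxs")))
  out
}

# Pick a per-dimension shared-count vector for an overlapping pair, under the
# per-dimension caps and the pairwise element quota; NULL when infeasible.
choose_shared_counts <- function(len_m, len_p, caps_pct, quota) {
  cap <- pmin(floor(caps_pct / 100 * pmin(len_m, len_p)), pmin(len_m, len_p))
  if (any(cap < 1) || quota < 1) return(NULL)
  s <- vapply(cap, function(cc) sample.int(cc, 1), integer(1))
  while (prod(s) > quota) {
    big <- which(s > 1L)
    if (!length(big)) return(NULL)
    d <- big[sample.int(length(big), 1)]
    s[d] <- s[d] - 1L
  }
  s
}

#' Place triclusters in the dataset
#'
#' Assigns index sets (I, J, K) to every tricluster, honoring the overlap
#' plan: triclusters are placed in overlap-group order; the first member of
#' a group samples its index sets independently, later members copy a random
#' sub-block of an already-placed group partner (sized to respect the
#' pairwise element quota and the per-dimension caps) and sample their
#' remaining indices fresh. Candidates colliding with triclusters they are
#' not designated to overlap are rejected and resampled, up to
#' `max_attempts` per tricluster; on exhaustion the tricluster is dropped
#' with a warning and the maximal placed set is returned.
#'
#' @param sizes matrix from [sample_sizes()].
#' @param dataset_dims dataset dimensions `c(n_obs, n_feat, n_ctx)`.
#' @param contiguity `"none"`, `"features"` or `"contexts"`.
#' @param plan overlap plan from [plan_overlap_groups()].
#' @param overlap_cfg a [tg_overlap()].
#' @param max_attempts placement retries per tricluster (rejection sampling
#'   against unintended collisions).
#' @return List of per-tricluster placements (`list(rows, cols, ctxs)`), with
#'   `NULL` entries for triclusters that could not be placed.
#' @export
place_triclusters <- function(sizes, dataset_dims,
                              contiguity = c("none", "features", "contexts"),
                              plan = NULL, overlap_cfg = NULL,
                              max_attempts = 3000) {
  contiguity <- match.arg(contiguity)
  n <- nrow(sizes)
  if (is.null(plan)) plan <- list(groups = list(), singletons = seq_len(n))
  if (is.null(overlap_cfg)) overlap_cfg <- tg_overlap("no_overlap")
  caps_pct <- c(overlap_cfg$pct_rows, overlap_cfg$pct_cols, overlap_cfg$pct_ctxs)
  contig <- c(FALSE, contiguity == "features", contiguity == "contexts")
  placements <- vector("list", n)

  cells_of <- function(m) prod(sizes[m, ])
  quota <- function(a, b)
    max_shared_elements(cells_of(a), cells_of(b), overlap_cfg$pct_elements)

  # shared-index counts of a candidate against a placed tricluster
  dim_shared <- function(cand, q) {
    vapply(1:3, function(d)
      length(intersect(cand[[d]], placements[[q]][[d]])), integer(1))
  }

  verify <- function(cand, m, partners) {
    placed <- which(!vapply(placements, is.null, logical(1)))
    for (q in setdiff(placed, m)) {
      sh <- dim_shared(cand, q)
      cells <- prod(sh)
      if (q %in% partners) {
        if (cells < 1 || cells > quota(m, q)) return(FALSE)
        cap <- floor(caps_pct / 100 * pmin(sizes[m, ], sizes[q, ]))
        if (any(sh > cap)) return(FALSE)
      } else if (cells > 0) {
        return(FALSE)
      }
    }
    TRUE
  }

  # contexts already claimed (in both row and col) by triclusters the
  # candidate is not designated to overlap: picking them would collide
  blocked_ctxs <- function(cand, m, partners) {
    placed <- which(!vapply(placements, is.null, logical(1)))
    blocked <- integer(0)
    for (q in setdiff(placed, c(m, partners))) {
      if (length(intersect(cand[[1]], placements[[q]][[1]])) &&
          length(intersect(cand[[2]], placements[[q]][[2]])))
        blocked <- c(blocked, placements[[q]][[3]])
    }
    unique(blocked)
  }

  make_candidate <- function(m, partners) {
    len_m <- sizes[m, ]
    copied <- list(integer(0), integer(0), integer(0))
    for (p in partners) {
      s <- choose_shared_counts(len_m, sizes[p, ], caps_pct, quota(m, p))
      if (is.null(s)) return(NULL)
      for (d in 1:3) {
        if (contig[d]) next
        pool <- placements[[p]][[d]]
        # prefer indices exclusive to this partner so the realized sharing
        # with the other partners stays close to the chosen counts
        others <- unlist(lapply(setdiff(partners, p),
                                function(o) placements[[o]][[d]]))
        excl <- setdiff(pool, c(copied[[d]], others))
        take <- if (length(excl) >= s[d]) {
          excl[sample.int(length(excl), s[d])]
        } else {
          pool[sample.int(length(pool), s[d])]
        }
        copied[[d]] <- union(copied[[d]], take)
      }
    }
    cand <- vector("list", 3)
    for (d in 1:3) {
      dim_len <- dataset_dims[d]; len <- len_m[d]
      avoid <- if (d == 3) blocked_ctxs(cand, m, partners) else integer(0)
      if (contig[d]) {
        ok <- !(seq_len(dim_len) %in% avoid)
        starts <- which(vapply(seq_len(dim_len - len + 1L), function(s)
          all(ok[s:(s + len - 1L)]), logical(1)))
        # keep only run positions whose overlap with every placed partner
        # satisfies the pairwise quota and the per-dimension cap
        for (p in partners) {
          prun <- placements[[p]][[d]]
          sh_other <- prod(vapply(seq_len(d - 1L), function(dd)
            length(intersect(cand[[dd]], placements[[p]][[dd]])), integer(1)))
          capd <- floor(caps_pct[d] / 100 * min(len, length(prun)))
          qmax <- quota(m, p)
          starts <- Filter(function(s) {
            o <- length(intersect(seq.int(s, s + len - 1L), prun))
            o >= 1 && o <= capd && sh_other * o >= 1 && sh_other * o <= qmax
          }, starts)
        }
        if (!length(starts)) return(NULL)
        start <- starts[sample.int(length(starts), 1)]
        cand[[d]] <- seq.int(start, start + len - 1L)
      } else {
        need <- len - length(copied[[d]])
        if (need < 0) return(NULL)
        # keep realized per-dimension sharing at exactly the chosen counts:
        # the fresh remainder avoids every partner's index set
        p_idx <- unlist(lapply(partners, function(p) placements[[p]][[d]]))
        pool <- setdiff(seq_len(dim_len), c(copied[[d]], p_idx, avoid))
        if (length(pool) < need) return(NULL)
        cand[[d]] <- sort(c(copied[[d]], pool[sample.int(length(pool), need)]))
      }
    }
    names(cand) <- c("rows", "cols", "ctxs")
    cand
  }

  try_place <- function(m, partners) {
    # partners whose quota is zero cannot legally share a cell; drop them
    partners <- partners[vapply(partners, function(p) quota(m, p) >= 1,
                                logical(1))]
    for (a in seq_len(max_attempts)) {
      cand <- make_candidate(m, partners)
      if (!is.null(cand) && verify(cand, m, partners)) return(cand)
    }
    NULL
  }

  for (g in plan$groups) {
    adj <- attr(g, "graph")
    for (gi in seq_along(g)) {
      m <- g[gi]
      nb <- g[which(adj[gi, ] > 0)]
      partners <- nb[!vapply(placements[nb], is.null, logical(1))]
      placements[m] <- list(try_place(m, partners))
    }
  }
  for (m in plan$singletons) placements[m] <- list(try_place(m, integer(0)))

  n_placed <- sum(!vapply(placements, is.null, logical(1)))
  if (n_placed < n)
    warning(sprintf("placed %d of %d requested triclusters; returning the maximal placed set",
                    n_placed, n))
  placements
}
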