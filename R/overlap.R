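#' Overlap configuration
#'
#' Controls how planted triclusters may share cells and how values in shared
#' regions are composed. `pct_triclusters` marks the fraction of triclusters
#' allowed to overlap; `max_group_size` (`k`) splits them into groups inside
#' which an interaction graph (pairwise up to k-wise) is drawn;
#' `pct_elements` caps shared cells per overlapping pair at that fraction of
#' the smaller tricluster; `pct_rows`/`pct_cols`/`pct_ctxs` cap the shared
#' indices per dimension (default 100, no restriction).
#'
#' @param plaid plaid coherency of overlap regions: `"additive"`,
#'   `"multiplicative"`, `"interpoled"`, `"none"` (last-generated tricluster
#'   wins) or `"no_overlap"` (overlap disabled).
#' @param pct_triclusters percentage of triclusters that overlap, 0-100.
#' @param max_group_size maximum number of triclusters overlapping
#'   simultaneously (k >= 2 whenever `pct_triclusters > 0`).
#' @param pct_elements maximum percentage of shared elements, 0-100.
#' @param pct_rows,pct_cols,pct_ctxs per-dimension sharing caps, 0-100.
#' @return An object of class `tg_overlap`.
#' @export
tg_overlap <- function(plaid = c("no_overlap", "none", "additive",
                                 "multiplicative", "interpoled"),
                       pct_triclusters = 0, max_group_size = 0,
                       pct_elements = 0, pct_rows = 100, pct_cols = 100,
                       pct_ctxs = 100) {
  plaid <- match.arg(plaid)
  pct <- c(pct_triclusters, pct_elements, pct_rows, pct_cols, pct_ctxs)
  if (any(pct < 0 | pct > 100)) stop("overlap percentages must lie in [0, 100]")
  if (plaid == "no_overlap") pct_triclusters <- 0
  if (pct_triclusters > 0 && max_group_size < 2)
    stop("overlapping requires max_group_size >= 2")
  structure(list(plaid = plaid, pct_triclusters = pct_triclusters,
                 max_group_size = max_group_size, pct_elements = pct_elements,
                 pct_rows = pct_rows, pct_cols = pct_cols, pct_ctxs = pct_ctxs),
            class = "tg_overlap")
}

#' Partition triclusters into overlap groups
#'
#' Marks `floor(n * pct_triclusters / 100)` triclusters as overlapping and
#' splits them into `floor(. / k)` groups of size `k`; a remainder of one
#' becomes a singleton (it cannot overlap), a larger remainder forms a final
#' smaller group. Within each group an interaction graph is drawn uniformly
#' among connected graphs on the group's members, ranging from pairwise-only
#' chains to the complete (k-wise) graph.
#'
#' @param n_triclusters number of triclusters to plant.
#' @param cfg a [tg_overlap()].
#' @return List with `groups` (list of integer member vectors, each with its
#'   adjacency matrix in attribute `"graph"`) and `singletons` (integer
#'   vector of non-overlapping tricluster indices).
#' @examples
#' set.seed(1)
#' p <- plan_overlap_groups(10, tg_overlap("additive", pct_triclusters = 100,
#'                                         max_group_size = 3, pct_elements = 50))
#' lengths(p$groups); p$singletons
#' @export
plan_overlap_groups <- function(n_triclusters, cfg) {
  stopifnot(n_triclusters >= 1)
  n_over <- floor(n_triclusters * cfg$pct_triclusters / 100)
  if (cfg$plaid == "no_overlap" || n_over < 2) {
    return(list(groups = list(), singletons = seq_len(n_triclusters)))
  }
  k <- cfg$max_group_size
  overlapping <- sort(sample.int(n_triclusters, n_over))
  n_groups <- floor(n_over / k)
  sizes <- rep(k, n_groups)
  rem <- n_over - n_groups * k
  if (rem >= 2) sizes <- c(sizes, rem)
  groups <- list()
  pos <- 1L
  for (s in sizes) {
    members <- overlapping[pos:(pos + s - 1L)]
    attr(members, "graph") <- sample_connected_graph(s)
    groups[[length(groups) + 1L]] <- members
    pos <- pos + s
  }
  grouped <- unlist(lapply(groups, as.integer))
  list(groups = groups,
       singletons = setdiff(seq_len(n_triclusters), grouped))
}

# Uniform draw among connected labeled graphs on n nodes, by rejection.
sample_connected_graph <- function(n) {
  if (n == 1) return(matrix(0L, 1, 1))
  repeat {
    adj <- matrix(0L, n, n)
    e <- sample(0:1, n * (n - 1) / 2, replace = TRUE)
    adj[upper.tri(adj)] <- e
    adj <- adj + t(adj)
    if (graph_connected(adj)) return(adj)
  }
}

graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(adj[frontier, , drop = FALSE] > 0, arr.ind = TRUE)[, 2]
    nxt <- unique(nxt[!seen[nxt]])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Maximum shared elements between two overlapping triclusters
#'
#' The sharing quota of a pair is `floor(pct_elements / 100 * min(size_a,
#' size_b))`: the cap applies to the smaller tricluster.
#'
#' @param size_a,size_b cell counts of the two triclusters.
#' @param pct_elements maximum percentage of overlapping elements, 0-100.
#' @return Integer quota of shareable cells.
#' @examples
#' max_shared_elements(8, 27, 50)  # 4
#' @export
max_shared_elements <- function(size_a, size_b, pct_elements) {
  stopifnot(size_a >= 1, size_b >= 1)
  as.integer(floor(pct_elements / 100 * min(size_a, size_b)))
}

#' Compose overlapping tricluster contributions under a plaid assumption
#'
#' In a cell shared by several triclusters the dataset value is a function
#' of the individual contributions: their sum (additive plaid), their
#' product (multiplicative), their average (interpoled), or simply the value
#' of the last-generated tricluster (`none`). The base term `c` defaults to
#' 0 since each contribution already carries its own seed.
#'
#' @param contributions values of the cell in each containing tricluster,
#'   ordered by generation (tricluster id).
#' @param plaid one of `"additive"`, `"multiplicative"`, `"interpoled"`,
#'   `"none"`.
#' @param base base term added to the composed value (numeric plaids).
#' @return The composed cell value.
#' @examples
#' compose_plaid(c(2, 3), "additive")    # 5
#' compose_plaid(c(2, 4), "interpoled")  # 3
#' compose_plaid(c(2, 9), "none")        # 9
#' @export
compose_plaid <- function(contributions,
                          plaid = c("none", "additive", "multiplicative",
                                    "interpoled"),
                          base = 0) {
  plaid <- match.arg(plaid)
  stopifnot(length(contributions) >= 1)
  if (plaid != "none" && !is.numeric(contributions))
    stop("symbolic alphabets only admit the `none` plaid coherency")
  switch(plaid,
         none = contributions[[length(contributions)]],
         additive = base + sum(contributions),
         multiplicative = base + prod(contributions),
         interpoled = base + sum(contributions) / length(contributions))
}
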