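# Benchmark preset configurations. Four families:
#   real/dataset1..5  - mimics of five published real-world three-way datasets
#   base/R|S|B|C      - clean 1000x100x10 datasets, one per data type
#   scal/S1|S2|S3     - scalability series (1e7, 1e8, 1e9 cells)
#   overlap/low|high, quality/higher|lower - stress variants of base/R
#   rich/R|S|B|C      - all properties combined
#   pattern/<T>-<family> - base datasets restricted to one pattern family

u <- function(a, b) size_dist("uniform", a, b)

base_alphabets <- function(type) {
  switch(type,
         R = tg_alphabet("real", min = -100, max = 100),
         S = tg_alphabet("symbolic", symbols = as.character(1:5)),
         B = tg_alphabet("integer", min = 0, max = 1),
         C = tg_alphabet("integer", min = 0, max = 100))
}

base_backgrounds <- function(type) {
  switch(type,
         R = tg_background("normal", mean = 0, stdev = 30),
         S = tg_background("discrete",
                           probabilities = c(0.1, 0.15, 0.3, 0.3, 0.15)),
         B = tg_background("uniform"),
         C = tg_background("uniform"))
}

base_patterns <- function(type) {
  switch(type,
         R = "all",
         S = c("order_preserving", "constant"),
         B = "constant",
         C = "all")
}

base_config <- function(type, dims = c(1000, 100, 10), n_trics = 12,
                        ctx_size = u(2, 4), patterns = base_patterns(type),
                        overlap = tg_overlap("no_overlap"),
                        quality = tg_quality()) {
  tg_config(dims = dims,
            alphabet = base_alphabets(type),
            background = base_backgrounds(type),
            structure = tg_structure(n_trics, u(30, 50), u(5, 10), ctx_size,
                                     contiguity = if (type == "C") "contexts"
                                                  else "none"),
            patterns = patterns, overlap = overlap, quality = quality)
}

real_presets <- list(
  dataset1 = function() tg_config(
    dims = c(7679, 13, 14),
    alphabet = tg_alphabet("real", min = 0, max = 500),
    background = tg_background("uniform"),
    structure = tg_structure(7, u(80, 400), u(2, 4), u(3, 13))),
  dataset2 = function() tg_config(
    dims = c(3200, 30, 28),
    alphabet = tg_alphabet("real", min = 5, max = 1000),
    background = tg_background("normal", mean = 500, stdev = 150),
    structure = tg_structure(10, u(100, 500), u(10, 20), u(5, 15)),
    overlap = tg_overlap("additive", pct_triclusters = 40, max_group_size = 2,
                         pct_elements = 50),
    quality = tg_quality(bg_missing = 20, bg_noise = 10, bg_errors = 10,
                         tric_missing = 10, tric_noise = 15, tric_errors = 5,
                         noise_deviation = 2)),
  dataset3 = function() tg_config(
    dims = c(20, 494, 94),
    alphabet = tg_alphabet("real", min = -5, max = 5),
    background = tg_background("uniform"),
    structure = tg_structure(5, u(5, 15), u(50, 200), u(15, 50)),
    overlap = tg_overlap("additive", pct_triclusters = 100, max_group_size = 3,
                         pct_elements = 40),
    quality = tg_quality(bg_noise = 20, bg_errors = 15, tric_noise = 10,
                         tric_errors = 5, noise_deviation = 1)),
  dataset4 = function() tg_config(
    dims = c(51, 924, 2844),
    alphabet = tg_alphabet("integer", min = 0, max = 1),
    background = tg_background("discrete", probabilities = c(0.7, 0.3)),
    structure = tg_structure(7000, u(5, 8), u(20, 70), u(100, 400)),
    patterns = "constant",
    overlap = tg_overlap("none", pct_triclusters = 80, max_group_size = 3000,
                         pct_elements = 70, pct_cols = 80, pct_ctxs = 80)),
  dataset5 = function() tg_config(
    dims = c(28, 20, 365),
    alphabet = tg_alphabet("real", min = -10, max = 30),
    background = tg_background("normal", mean = 14, stdev = 7),
    structure = tg_structure(128, u(4, 4), u(4, 4), u(8, 8)),
    quality = tg_quality(bg_missing = 15, bg_noise = 20, bg_errors = 5,
                         tric_missing = 5, tric_noise = 10, tric_errors = 2,
                         noise_deviation = 1)))

#' Load a benchmark preset configuration
#'
#' Ships the configurations of the published benchmark suites:
#' `real/dataset1`..`real/dataset5` (mimics of five real-world three-way
#' datasets: yeast gene expression, stock ratios, fMRI, bookmarking triples,
#' daily temperatures), `base/R|S|B|C` (clean real-valued, symbolic, binary
#' and integer-contiguous base datasets), `scal/S1|S2|S3` (scalability
#' series with 1e7 to 1e9 cells), `overlap/low`, `overlap/high`,
#' `quality/higher`, `quality/lower`, `rich/R|S|B|C` (all properties
#' combined) and `pattern/<T>-<family>` suites (e.g. `pattern/R-additive`).
#'
#' @param name preset name, e.g. `"base/R"`.
#' @return A [tg_config()].
#' @seealso [preset_names()]
#' @export
load_preset <- function(name) {
  f <- preset_registry()[[name]]
  if (is.null(f))
    stop("unknown preset: ", name, " (see preset_names())")
  f()
}

#' List the available preset names
#' @return Character vector of names accepted by [load_preset()].
#' @export
preset_names <- function() names(preset_registry())

preset_registry <- function() {
  reg <- list()
  for (nm in names(real_presets)) reg[[paste0("real/", nm)]] <- real_presets[[nm]]
  for (tp in c("R", "S", "B", "C"))
    reg[[paste0("base/", tp)]] <- local({
      tp0 <- tp; function() base_config(tp0)
    })
  scal <- list(S1 = list(dims = c(1000, 100, 100), n = 120),
               S2 = list(dims = c(10000, 100, 100), n = 1200),
               S3 = list(dims = c(10000, 1000, 100), n = 12000))
  for (nm in names(scal))
    reg[[paste0("scal/", nm)]] <- local({
      s <- scal[[nm]]
      function() base_config("R", dims = s$dims, n_trics = s$n)
    })
  reg[["overlap/low"]] <- function() base_config("R",
    overlap = tg_overlap("additive", pct_triclusters = 30, max_group_size = 2,
                         pct_elements = 30, pct_cols = 70, pct_ctxs = 70))
  reg[["overlap/high"]] <- function() base_config("R",
    overlap = tg_overlap("additive", pct_triclusters = 75, max_group_size = 3,
                         pct_elements = 70))
  reg[["quality/higher"]] <- function() base_config("R",
    quality = tg_quality(bg_missing = 2, bg_noise = 10, bg_errors = 5,
                         tric_missing = 2, tric_noise = 10, tric_errors = 5,
                         noise_deviation = 1))
  reg[["quality/lower"]] <- function() base_config("R",
    quality = tg_quality(bg_missing = 10, bg_noise = 30, bg_errors = 15,
                         tric_missing = 5, tric_noise = 20, tric_errors = 8,
                         noise_deviation = 3))
  rich_overlap <- list(
    R = tg_overlap("additive", pct_triclusters = 50, max_group_size = 3,
                   pct_elements = 60),
    S = tg_overlap("none", pct_triclusters = 40, max_group_size = 2,
                   pct_elements = 50),
    B = tg_overlap("none", pct_triclusters = 60, max_group_size = 3,
                   pct_elements = 80),
    C = tg_overlap("multiplicative", pct_triclusters = 60, max_group_size = 4,
                   pct_elements = 70))
  rich_ndev <- c(R = 2, S = 1, B = 1, C = 2)
  for (tp in c("R", "S", "B", "C"))
    reg[[paste0("rich/", tp)]] <- local({
      tp0 <- tp
      function() base_config(tp0, dims = c(1000, 100, 100), n_trics = 30,
        ctx_size = u(3, 5), overlap = rich_overlap[[tp0]],
        quality = tg_quality(bg_missing = 2, bg_noise = 10,
                             bg_errors = if (tp0 == "B") 0 else 5,
                             tric_missing = 2, tric_noise = 10,
                             tric_errors = if (tp0 == "B") 0 else 5,
                             noise_deviation = rich_ndev[[tp0]]))
    })
  fams <- list(R = c("constant", "additive", "multiplicative", "order_preserving"),
               S = c("constant", "order_preserving"),
               B = "constant",
               C = c("constant", "additive", "multiplicative", "order_preserving"))
  for (tp in names(fams))
    for (fm in fams[[tp]])
      reg[[paste0("pattern/", tp, "-", fm)]] <- local({
        tp0 <- tp; fm0 <- fm
        function() base_config(tp0, patterns = fm0)
      })
  reg
}
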