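# Small reusable configuration builders for the test suite.

digit_alphabet <- function() tg_alphabet("integer", min = 0, max = 9)

real_alphabet <- function(min = -100, max = 100)
  tg_alphabet("real", min = min, max = max)

abc_alphabet <- function(n = 5) tg_alphabet("symbolic", symbols = letters[seq_len(n)])

# a small clean numeric config with n disjoint triclusters
small_config <- function(n = 2, dims = c(30, 12, 5), patterns = "all",
                         alphabet = real_alphabet(),
                         background = tg_background("uniform"),
                         overlap = tg_overlap("no_overlap"),
                         quality = tg_quality()) {
  tg_config(dims = dims, alphabet = alphabet, background = background,
            structure = tg_structure(n, size_dist("uniform", 3, 5),
                                     size_dist("uniform", 3, 4),
                                     size_dist("uniform", 2, 3)),
            patterns = patterns, overlap = overlap, quality = quality)
}

# the quality worked example: 10x10x10 dataset, one 4x5x5 (100-cell)
# tricluster, so |B| = 900
quality_example_config <- function(bg_missing = 50, bg_noise = 30,
                                   bg_errors = 10, noise_deviation = 2) {
  tg_config(dims = c(10, 10, 10), alphabet = digit_alphabet(),
            structure = tg_structure(1, size_dist("uniform", 4, 4),
                                     size_dist("uniform", 5, 5),
                                     size_dist("uniform", 5, 5)),
            patterns = "constant",
            quality = tg_quality(bg_missing = bg_missing, bg_noise = bg_noise,
                                 bg_errors = bg_errors,
                                 noise_deviation = noise_deviation))
}

# brute-force cell enumeration for a tricluster spec skeleton
enumerate_cells <- function(rows, cols, ctxs, dims) {
  g <- expand.grid(i = rows, j = cols, k = ctxs)
  sort(g$i + (g$j - 1) * dims[1] + (g$k - 1) * dims[1] * dims[2])
}

# independent admissibility oracle: explicit construction of the allowed
# triple set (order-preserving forms; constant/None forms; additive and
# multiplicative forms for numeric data)
oracle_admissible <- function(row, col, ctx, type) {
  p <- c(row, col, ctx)
  op_forms <- (sum(p == "OrderPreserving") == 1 && sum(p == "None") == 2)
  cn_forms <- all(p %in% c("Constant", "None")) && any(p == "Constant")
  ac_forms <- all(p %in% c("Additive", "Constant")) && any(p == "Additive")
  mc_forms <- all(p %in% c("Multiplicative", "Constant")) &&
    any(p == "Multiplicative")
  if (type == "symbolic") op_forms || cn_forms
  else op_forms || cn_forms || ac_forms || mc_forms
}
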