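# shared fixtures built in code

# write a size file in the given dialect and return its path
write_size_file <- function(lines, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Lorenz points taken directly from a model curve on a uniform grid, for
# parameter-recovery tests of the comparator models
curve_points <- function(model, params, n = 150L) {
  x <- seq_len(n) / n
  f <- switch(model,
              proposed = function(x) lorenz_proposed(x, params),
              scs = function(x) lorenz_scs(x, params),
              s = function(x) lorenz_s(x, params))
  structure(list(x = x, y = f(x), n = n, total = 1,
                 includes_origin = TRUE, label = model),
            class = "lorenz_points")
}

# small multistart budget for speed where the optimum is easy
quick_config <- function(model, n_starts = 32L, seed = 20230323L) {
  fit_config(model, n_starts = n_starts, seed = seed)
}
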