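# Shared fixtures: everything is generated in code at test time.

small_grid <- c(16L, 16L)

small_phantom_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = small_grid,
                   roi_layout = default_roi_layout(small_grid))
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# single start is enough for well-initialized noiseless checks
quick_fit_config <- function(...) fit_config(multistart = 1L, ...)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
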