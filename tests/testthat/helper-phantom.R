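# Shared phantom builders: the default spec reproduces the consensus STEAM
# systolic study conditions (MD 1.03e-3 mm^2/s, FA 0.47, HA +50 -> -50,
# E2A 62 deg, 12 directions at b 50/450, noiseless).

default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom()
    cache
  }
})

# a small, fast phantom for registration / IO tests
small_spec <- function(...) {
  phantom_spec(matrix_size = 32, r_endo = 6, r_epi = 11, ...)
}

fitted_eigensystem <- function(ph) {
  eigendecompose(fit_tensor(ph$stack, ph$geom$mask))
}

expect_all_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected), na.rm = TRUE), tol)
}
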