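# Comparison against a printed table value: the printed inputs are rounded
# means, so recomputed derived columns can differ by more than half a unit of
# the last printed digit. Tolerance = half the printed resolution plus 2 % of
# the value (propagated input rounding).
expect_printed <- function(object, printed, decimals) {
  tol <- 0.5 * 10^(-decimals) + 0.02 * abs(printed)
  expect_lt(abs(object - printed), tol)
}

# A small, fast synthetic configuration for tests that only need structure.
quick_config <- function(...) {
  simulation_config(sample_interval = 0.1, t_end = 25, ...)
}
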