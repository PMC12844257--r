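# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture_pool <- function() {
  if (is.null(.fixtures$pool)) .fixtures$pool <- smiles_pool()
  .fixtures$pool
}

fixture_blocks <- function() {
  if (is.null(.fixtures$blocks))
    .fixtures$blocks <- gen_building_blocks(10, 8, 10, seed = 2024)
  .fixtures$blocks
}

# noiseless two-state melt curve on the standard 25-95 degC grid
sigmoid_curve <- function(tm = 55, base = 0.1, amp = 1, slope = 1,
                          grid = seq(25, 95, by = 0.5)) {
  base + amp / (1 + exp((tm - grid) / slope))
}
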