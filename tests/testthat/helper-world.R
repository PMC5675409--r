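# Shared small synthetic worlds, built once per test run.

tiny_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- make_world(world_config(seed = 42,
                                                  grid_shape = c(8, 8),
                                                  n_years = 5))
    w
  }
})

noiseless_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- make_world(world_config(seed = 7,
                                                  grid_shape = c(10, 10),
                                                  n_years = 6,
                                                  noise_sd = 0,
                                                  npp_temp_coupling = 0))
    w
  }
})

# per-pixel yearly series helper: stack (one layer per year) -> vector
pixel_series <- function(stack, row, col) stack$values[row, col, ]
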