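# Shared fixtures, built once per test run and cached in-process.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 64x64 study conditions used for the main training experiments.
small_synth_config <- function(seed = 11L)
  synthetic_config(height = 64, width = 64, nerve_radius_range = c(6, 12),
                   seed = seed)

fixture_dataset200 <- function()
  fixture("ds200", function() generate_dataset(200, small_synth_config()))

# The tiny RFF-U-net trained on the 200-image dataset (30 epochs).
fixture_unet_fit <- function()
  fixture("unet_fit", function() {
    mc <- model_config("unet", input_size = c(64, 64), depth = 2,
                       base_filters = 8, use_rff = TRUE, Q_factor = 16,
                       epochs = 30, batch_size = 32, learning_rate = 1e-3,
                       optimizer_seed = 7)
    seg_fit(fixture_dataset200(), mc)
  })

# A very small trained model + dataset for interface-level tests.
fixture_tiny <- function()
  fixture("tiny", function() {
    cfg <- synthetic_config(height = 32, width = 32,
                            nerve_radius_range = c(5, 9), seed = 5)
    ds <- generate_dataset(20, cfg)
    mc <- model_config("unet", input_size = c(32, 32), depth = 1,
                       base_filters = 4, use_rff = TRUE, Q_factor = 8,
                       epochs = 6, batch_size = 8, optimizer_seed = 3)
    list(fit = seg_fit(ds, mc), ds = ds, config = mc)
  })
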