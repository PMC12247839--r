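# Shared expensive fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_phantom <- function(seed = 101)
  fixture(paste0("phantom_", seed),
          function() generate_phantom(phantom_spec(seed = seed)))

default_pipeline_run <- function(seed = 101)
  fixture(paste0("run_", seed), function() {
    ph <- default_phantom(seed)
    run_pipeline(ph$volume)
  })

# sparse phantom (extra background) used for the deep-learning tests; the
# default layout is densely packed, so extra empty space keeps the joint
# fraction well below one half and the IoU criterion discriminative
dl_phantom_tiles <- function(seed, edge = 32L)
  fixture(sprintf("dl_tiles_%d_%d", seed, edge), function() {
    ph <- generate_phantom(phantom_spec(seed = seed,
                                        shape = c(64, 150, 100)))
    jt <- derive_joint_truth(ph$truth, 5L)
    extract_training_tiles(ph$volume, jt, n_tiles = 3L, edge = edge)
  })
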