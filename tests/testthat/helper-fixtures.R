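# Shared fixtures.  Everything is generated in code; the heavier objects
# (a strongly cued dataset and a small trained CNN) are built once per test
# run and memoised in this environment.

fixture_env <- new.env(parent = emptyenv())

# strongly cued world: appearance pinned near the extremes, default gains
strong_mix <- function() {
  class_mix(a_range = list(mirror = c(0.9, 1), glass = c(0, 0.1),
                           amb_mirror = c(0.3, 0.7),
                           amb_glass = c(0.3, 0.7)))
}

# gradient-dominant cue world for the interpretability analyses: the
# vertical asymmetry carries the spatial signature; the small luminance
# offset makes the task solvable for the translation-invariant GAP head
gradient_gains <- function() {
  cue_gains(gradient = 0.5, contrast = 0, saturation = 0, luminance = 0.1)
}

strong_dataset <- function(n_per_class = 40L, seed = 11L) {
  key <- sprintf("strong_%d_%d", n_per_class, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_dataset(n_per_class, strong_mix(),
                                           master_seed = seed)
  }
  fixture_env[[key]]
}

# a small CNN trained once on gradient-cued data, with a GAP head, reused
# by the CAM / robustness / inversion tests
trained_gap_cnn <- function(seed = 21L) {
  key <- sprintf("gapcnn_%d", seed)
  if (is.null(fixture_env[[key]])) {
    ds <- generate_dataset(40L, strong_mix(), master_seed = seed,
                           gains = gradient_gains())
    x <- stack_images(ds$images)
    fac <- cnn_factory(cnn_spec(depth = 2L, filters_base = 8L,
                                gap_head = TRUE, dropout_rate = 0),
                       max_epochs = 6L)
    model <- fac(x, ds$manifest$class_label, seed = seed)
    fixture_env[[key]] <- list(model = model, ds = ds, x = x)
  }
  fixture_env[[key]]
}

# flatten-head twin of trained_gap_cnn: spatially sensitive, used for the
# inversion analyses (a GAP head is translation invariant and cannot show
# an inversion effect)
trained_flat_cnn <- function(seed = 21L) {
  key <- sprintf("flatcnn_%d", seed)
  if (is.null(fixture_env[[key]])) {
    ds <- generate_dataset(40L, strong_mix(), master_seed = seed,
                           gains = gradient_gains())
    x <- stack_images(ds$images)
    fac <- cnn_factory(cnn_spec(depth = 2L, filters_base = 8L,
                                dropout_rate = 0), max_epochs = 6L)
    model <- fac(x, ds$manifest$class_label, seed = seed)
    fixture_env[[key]] <- list(model = model, ds = ds, x = x)
  }
  fixture_env[[key]]
}
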