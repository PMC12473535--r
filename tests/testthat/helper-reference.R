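# The desk-scale reference study shared by the training, comparison and
# acceptance tests: 20 single-instance training crops, 8 held-out crops,
# and one model trained once per test run (memoized).

ref_crop_config <- function(seed) {
  scene_config(image_height = 96L, image_width = 96L, n_instances = 1L,
               body_length_range_mm = c(45, 80), mm_per_px = 1,
               body_width_px_range = c(5, 11), curvature_range = c(0.05, 0.3),
               seed = seed)
}

ref_crop <- function(seed) generate_scene(ref_crop_config(seed))

ref_segmenter <- function() segmenter_params(min_area_frac = 2e-3)

ref_train_config <- function() {
  train_config(epochs = 30L, lr = 0.05, momentum = 0.9,
               lr_milestones = c(20L, 27L), batch_size = 2L, seed = 7L)
}

.ref_cache <- new.env(parent = emptyenv())

get_reference_model <- function() {
  if (is.null(.ref_cache$model)) {
    ds <- centerline_dataset(lapply(1:20, ref_crop), masks = "detected",
                             segmenter = ref_segmenter())
    .ref_cache$model <- train_centerline_model(ds, model_config(),
                                               ref_train_config())
  }
  .ref_cache$model
}

get_heldout_samples <- function() {
  if (is.null(.ref_cache$heldout)) {
    .ref_cache$heldout <- centerline_dataset(lapply(101:108, ref_crop),
                                             masks = "detected",
                                             segmenter = ref_segmenter())
  }
  .ref_cache$heldout
}
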