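# Shared phantom builders for the tests. All fixtures are generated in
# code at test time; nothing is read from disk.

desk_phantom <- function(seed, n_slices, image_size = 160, crop = 128) {
  p <- synth_params(
    image_size = image_size, n_slices = n_slices, n_fascicles = 5,
    merge_split_rate = 0, artifact_density = 0.3, seed = seed
  )
  preprocess_stack(generate_stack(p, nerve_id = paste0("nerve", seed)),
                   crop_size = crop, sigma = 1)
}

# a hand-built stack of `n` tiny slices of which `n_border` have the
# epineurium touching the frame edge
border_test_stack <- function(n, n_border, S = 24) {
  interior <- matrix(FALSE, S, S); interior[8:16, 8:16] <- TRUE
  touching <- matrix(FALSE, S, S); touching[1:9, 8:16] <- TRUE
  fasc <- matrix(FALSE, S, S); fasc[10:12, 10:12] <- TRUE
  fasc_b <- matrix(FALSE, S, S); fasc_b[4:6, 10:12] <- TRUE
  img <- matrix(5000L, S, S)
  border_at <- seq_len(n_border)  # first n_border slices touch the frame
  nerve_stack(
    "border_case",
    slices = rep(list(img), n),
    fascicle_masks = lapply(seq_len(n), function(i) {
      if (i %in% border_at) fasc_b else fasc
    }),
    epineurium_masks = lapply(seq_len(n), function(i) {
      if (i %in% border_at) touching else interior
    })
  )
}
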