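# The desk-scale study conditions: a 2,000-sample synthetic closure corpus,
# an 0.8/0.1/0.1 split, and a 50-epoch CPU training run.  Trained once and
# shared by the end-to-end tests (training dominates the suite's runtime).

.run_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.run_cache$run)) return(.run_cache$run)
  dataset <- generate_dataset(2000, seed = 20240101)
  split <- split_dataset(2000, c(0.8, 0.1, 0.1), seed = 7)
  model <- train_cae(dataset, split, cae_config(seed = 42, epochs = 50))
  .run_cache$run <- list(dataset = dataset, split = split, model = model)
  .run_cache$run
}

valve_textures <- function(valve) {
  tex <- array(NA_real_, c(3, dim(valve$leaflets[[1]]$control)))
  for (k in 1:3) tex[k, , , ] <- valve$leaflets[[k]]$control
  tex
}
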