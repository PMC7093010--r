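# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Small rendered dataset: 4 plants x 6 timepoints at 64 px.
tiny_dataset <- function() {
  if (is.null(fixture_env$tiny))
    fixture_env$tiny <- generate_dataset(4, 6, canvas_size = 64, seed = 42)
  fixture_env$tiny
}

# A dataset record skeleton without rendered pixels, for label-mask logic.
fake_dataset <- function(n_plants = 3, n_timepoints = 8) {
  images <- list()
  rows <- list()
  for (p in seq_len(n_plants)) {
    pid <- sprintf("plant_%02d", p)
    for (t in seq_len(n_timepoints)) {
      images[[length(images) + 1L]] <-
        list(pixels = NULL, plant_mask = NULL, plant_id = pid, timepoint = t,
             leaf_count = 2L + t %/% 2L, pla = 0.05 + 0.01 * t,
             genotype = p %% 2L, has_count = TRUE, has_pla = TRUE,
             has_genotype = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(image = sprintf("%s_t%02d.png", pid, t), plant_id = pid,
                   timepoint = t, leaf_count = 2L + t %/% 2L,
                   pla = 0.05 + 0.01 * t, genotype = p %% 2L)
    }
  }
  structure(list(images = images, annotations = do.call(rbind, rows)),
            class = "rosette_dataset")
}

# Small trained multitask model at 64 px for occlusion/prediction tests.
tiny_fit <- function() {
  if (is.null(fixture_env$fit)) {
    ds <- tiny_dataset()
    pids <- unique(ds$annotations$plant_id)
    tr <- subset_plants(ds, pids[1:3])
    va <- subset_plants(ds, pids[4])
    set.seed(11)
    m <- build_model(model_config(input_size = 64))
    fixture_env$fit <- train_model(
      m, tr, va, loss_config(),
      train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 5,
                   early_stop_patience = 5, seed = 11))
  }
  fixture_env$fit
}
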