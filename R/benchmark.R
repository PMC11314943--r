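#' High-SNR simulation preset
#'
#' The low-noise benchmark condition used for posture-recovery checks:
#' reduced channel noise and clutter relative to [sim_params()] defaults,
#' everything else unchanged.
#'
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params`.
#' @export
high_snr_params <- function(...) {
  sim_params(noise_sigma = 0.002, clutter_amp = 0.2, ...)
}

#' Synthetic posture-recovery benchmark
#'
#' The package's end-to-end self-check: simulate a high-SNR cohort on the
#' full eight-radar bench, build echo-map view stacks, train the compact
#' multiview network on the coarse (4-class) task with a subject-wise
#' 55:15-proportioned split, and score held-out subjects. The same stacks
#' are then used to compare the full 8-radar ensemble against the minimal
#' 2-radar pair (central side + central head) over several training seeds.
#'
#' Problem sizes default to 20 subjects x 9 postures x 1 blanket x 1 trial
#' (180 samples), 20 training epochs for the main model and 12 for the
#' ensemble comparison — small enough to run on one CPU in a few minutes
#' while leaving a clear accuracy signal.
#'
#' @param seed Root seed for data generation, splitting and training.
#' @param n_subjects Cohort size.
#' @param epochs Training epochs for the main held-out model.
#' @param ablation_epochs Epochs per ensemble-comparison training.
#' @param n_seeds Training seeds for the 8-vs-2 radar comparison.
#' @param input_size Model input side length.
#' @param verbose Print progress to stderr?
#' @return List: `holdout_accuracy`, `n_test`, `acc_8radar` and
#'   `acc_2radar` (vectors over seeds), `history` (main-model tibble),
#'   `n_samples`.
#' @export
run_posture_benchmark <- function(seed = 1L, n_subjects = 20L,
                                  epochs = 20L, ablation_epochs = 12L,
                                  n_seeds = 3L, input_size = 32L,
                                  verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  placement <- default_placement()
  grid <- grid_spec()
  say("simulating ", n_subjects, "-subject cohort")
  ds <- generate_dataset(n_subjects, blankets = "thin", trials = 1,
                         placement = placement,
                         params = high_snr_params(), seed = seed)
  say("building view stacks for ", nrow(ds$manifest), " samples")
  sv <- stack_views_array(ds$samples, placement, grid,
                          input_size = input_size)
  y <- coarse_map(ds$manifest$posture)
  split <- subject_split(ds$manifest$subject_id, seed = seed)
  tr <- ds$manifest$subject_id %in% split$train
  te <- ds$manifest$subject_id %in% split$test

  say("training main model (", epochs, " epochs)")
  spec <- model_spec(n_views = 8L, n_classes = 4L, input_size = input_size)
  model <- build_model(spec, seed = seed)
  model <- train_mvcnn(model, sv$x[tr, , , , drop = FALSE], y[tr],
                       train_config(epochs = epochs, seed = seed))
  ev <- evaluate_model(model, sv$x[te, , , , drop = FALSE], y[te])

  v22 <- match(c("HC", "S3"), sv$radar_ids)
  acc8 <- acc2 <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- as.integer(seed + 100L * k)
    say("ensemble comparison, seed ", sk)
    m8 <- build_model(spec, seed = sk)
    m8 <- train_mvcnn(m8, sv$x[tr, , , , drop = FALSE], y[tr],
                      train_config(epochs = ablation_epochs, seed = sk))
    acc8[k] <- evaluate_model(m8, sv$x[te, , , , drop = FALSE],
                              y[te])$accuracy
    sp2 <- model_spec(n_views = 2L, n_classes = 4L,
                      input_size = input_size)
    x2 <- sv$x[, v22, , , drop = FALSE]
    m2 <- build_model(sp2, seed = sk)
    m2 <- train_mvcnn(m2, x2[tr, , , , drop = FALSE], y[tr],
                      train_config(epochs = ablation_epochs, seed = sk))
    acc2[k] <- evaluate_model(m2, x2[te, , , , drop = FALSE],
                              y[te])$accuracy
  }
  list(holdout_accuracy = ev$accuracy, n_test = ev$n,
       acc_8radar = acc8, acc_2radar = acc2,
       history = model$history, n_samples = nrow(ds$manifest))
}
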