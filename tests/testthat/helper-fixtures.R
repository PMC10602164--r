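# Fixture builders shared across test files. All data are generated in code;
# sizes are desk-scale so the whole suite runs in minutes on one CPU.

# Two well-separated embedding clusters: the "easy" regime where the
# similarity pipeline must succeed.
separable_survey <- function(seed, n_per_class = 60, dim = 32,
                             separation = 2.5, noise_sd = 0.25, ...) {
  generate_survey(synthetic_config(n_per_class = n_per_class, dim = dim,
                                   separation = separation,
                                   noise_sd = noise_sd, seed = seed, ...))
}

# Zero separation: embeddings carry no class signal at all (the null).
null_survey <- function(seed, n_per_class = 150, dim = 32) {
  generate_survey(synthetic_config(n_per_class = n_per_class, dim = dim,
                                   separation = 0, noise_sd = 0.25,
                                   seed = seed))
}

# Small network configuration for tests; protocol hyperparameters (Adam 1e-4,
# batch 32, 50 epochs, patience 3, 20% validation) are left at their defaults.
test_model_config <- function(dim = 32, seed = 1, hidden = c(64L, 16L), ...) {
  model_config(input_dim = dim, hidden_sizes = hidden, seed = seed, ...)
}

# One full pass: balance, split, augment, train, classify, evaluate.
# With shuffle_labels = TRUE the class labels are permuted before training
# and metrics are computed against the original labels.
fit_pipeline_once <- function(sv, seed, train_per_class,
                              shuffle_labels = FALSE) {
  rec <- sv$records
  truth <- rec$label
  if (shuffle_labels) {
    rec$label <- withr::with_seed(seed + 5000L, sample(rec$label))
  }
  bal <- balance_downsample(rec, seed = seed)
  split <- split_train_test(bal, train_per_class = train_per_class,
                            seed = seed)
  ts <- build_training_set(split, sv$store, seed = seed)
  model <- train_model(ts, test_model_config(dim = ncol(ts$features),
                                             seed = seed))
  preds <- classify_test_set(split, model, sv$store)
  if (shuffle_labels) {
    preds$true_label <- truth[match(preds$record_id, sv$records$record_id)]
  }
  met <- confusion_metrics(preds$true_label, preds$predicted)
  met$auc <- binary_auc(met$sensitivity, met$specificity)
  list(split = split, train_set = ts, model = model, preds = preds,
       metrics = met)
}

# Minimal labeled record table (no PCL-5 columns) for split/balance tests.
toy_records <- function(labels, words = 40L) {
  n <- length(labels)
  data.frame(
    record_id = sprintf("T%03d", seq_len(n)),
    text = rep(paste(rep("word", words), collapse = " "), n),
    label = as.integer(labels),
    word_count = rep(as.integer(words), n),
    stringsAsFactors = FALSE
  )
}

# A similarity model with all-zero weights: predicts exactly 0.5 everywhere.
constant_model <- function(dim) {
  cfg <- model_config(input_dim = dim, hidden_sizes = c(4L, 2L))
  par <- list(
    W = list(matrix(0, dim, 4), matrix(0, 4, 2), matrix(0, 2, 1)),
    b = list(rep(0, 4), rep(0, 2), 0)
  )
  structure(list(config = cfg, par = par,
                 history = data.frame(epoch = 1L, train_loss = log(2),
                                      val_loss = log(2)),
                 stopped_epoch = 1L, best_epoch = 1L, val_indices = integer()),
            class = "similarity_model")
}
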