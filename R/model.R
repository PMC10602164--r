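# Feedforward similarity network over Hadamard pair features.
#
# Architecture: input (backend dim) -> dense ReLU layers (default 400, 50)
# -> single sigmoid output. Trained with mini-batch Adam on binary
# cross-entropy, a stratified validation holdout, and early stopping with
# best-weight restoration. Implemented directly in base R matrix algebra.

#' Training configuration for the similarity network
#'
#' Defaults mirror the study protocol: 400- and 50-unit ReLU hidden layers,
#' sigmoid output, Adam at learning rate 1e-4, batch size 32, at most 50
#' epochs, early stopping after 3 epochs without validation-loss improvement,
#' and a 20% validation holdout.
#'
#' @param input_dim Feature dimension (the embedding backend's dim).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive non-improving epochs before stopping.
#' @param validation_fraction Fraction of examples held out for validation.
#' @param improvement_tol Minimum validation-loss decrease counted as
#'   improvement (guards against float noise).
#' @param seed Integer seed controlling initialization, the validation split
#'   and batch shuffling.
#' @return A `model_config` object.
#' @export
model_config <- function(input_dim = 1536L, hidden_sizes = c(400L, 50L),
                         learning_rate = 1e-4, batch_size = 32L,
                         max_epochs = 50L, patience = 3L,
                         validation_fraction = 0.2, improvement_tol = 1e-6,
                         seed = 1L) {
  stopifnot(input_dim >= 1, all(hidden_sizes >= 1), learning_rate >= 0,
            batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience < max_epochs,
            validation_fraction > 0, validation_fraction < 1,
            improvement_tol >= 0)
  structure(
    list(input_dim = as.integer(input_dim),
         hidden_sizes = as.integer(hidden_sizes),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience),
         validation_fraction = validation_fraction,
         improvement_tol = improvement_tol,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# --- internal network primitives ------------------------------------------

nn_init <- function(input_dim, hidden_sizes) {
  sizes <- c(input_dim, hidden_sizes, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # fan-in-scaled (He) normal initialization, suited to ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

nn_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% par$W[[l]]
    Zl <- Zl + matrix(par$b[[l]], nrow(Zl), ncol(Zl), byrow = TRUE)
    Z[[l]] <- Zl
    A[[l + 1L]] <- if (l < L) pmax(Zl, 0) else stats::plogis(Zl)
  }
  list(A = A, Z = Z, p = A[[L + 1L]][, 1L])
}

bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

nn_grad <- function(par, X, y) {
  fw <- nn_forward(par, X)
  L <- length(par$W)
  m <- nrow(X)
  dW <- vector("list", L)
  db <- vector("list", L)
  # sigmoid + BCE: dL/dZ_L = (p - y) / m
  delta <- matrix((fw$p - y) / m, ncol = 1L)
  for (l in seq(L, 1L)) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$W[[l]])) * (fw$Z[[l - 1L]] > 0)
  }
  list(dW = dW, db = db)
}

adam_init <- function(par) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  }
  list(mW = lapply(par$W, zeros), vW = lapply(par$W, zeros),
       mb = lapply(par$b, zeros), vb = lapply(par$b, zeros))
}

adam_step <- function(par, gr, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(par$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * gr$dW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * gr$dW[[l]]^2
    par$W[[l]] <- par$W[[l]] - lr * (st$mW[[l]] / c1) /
      (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * gr$db[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * gr$db[[l]]^2
    par$b[[l]] <- par$b[[l]] - lr * (st$mb[[l]] / c1) /
      (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(par = par, st = st)
}

extract_training_data <- function(pairs) {
  if (is.list(pairs) && !is.null(pairs$features)) {
    labels <- pairs$labels %||% pairs$pairs$label
    if (is.null(labels)) stop("no labels found in training set object")
    list(X = as.matrix(pairs$features), y = as.numeric(labels))
  } else {
    stop("pairs must be a training-set object with $features and labels ",
         "(see build_training_set)")
  }
}

# --- training --------------------------------------------------------------

#' Train the similarity network
#'
#' Fits the feedforward network on labeled Hadamard pair features. A
#' stratified `validation_fraction` holdout monitors binary cross-entropy;
#' training stops after `patience` consecutive epochs without improvement
#' (by more than `improvement_tol`) or at `max_epochs`, restoring the
#' best-epoch weights. Fully reproducible from `config$seed`.
#'
#' @param pairs Training-set object from [build_training_set()], or any list
#'   with `$features` (matrix) and `$labels` (0/1 vector).
#' @param config A [model_config()].
#' @return A `similarity_model`: config, weights, per-epoch loss history,
#'   `stopped_epoch` and `best_epoch`.
#' @export
train_model <- function(pairs, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  dat <- extract_training_data(pairs)
  X <- dat$X
  y <- dat$y
  if (ncol(X) != config$input_dim) {
    stop("feature dimension (", ncol(X), ") does not match config input_dim (",
         config$input_dim, ")")
  }
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(unique(y)) < 2L) {
    stop("training set must contain both labels (similar and dissimilar)")
  }

  withr::with_seed(config$seed, {
    n <- nrow(X)
    n_val <- round(config$validation_fraction * n)
    if (n_val < 1L || n - n_val < 1L) {
      stop("validation_fraction leaves too few examples (n = ", n, ")")
    }
    idx1 <- which(y == 1)
    idx0 <- which(y == 0)
    n_val1 <- min(max(round(config$validation_fraction * length(idx1)), 0L),
                  length(idx1))
    n_val0 <- min(max(n_val - n_val1, 0L), length(idx0))
    val_idx <- c(if (n_val1 > 0L) sample(idx1, n_val1),
                 if (n_val0 > 0L) sample(idx0, n_val0))
    tr_idx <- setdiff(seq_len(n), val_idx)
    X_tr <- X[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
    X_val <- X[val_idx, , drop = FALSE]; y_val <- y[val_idx]

    par <- nn_init(config$input_dim, config$hidden_sizes)
    st <- adam_init(par)
    best_loss <- Inf
    best_par <- par
    best_epoch <- 0L
    wait <- 0L
    t_step <- 0L
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    stopped_epoch <- config$max_epochs

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(nrow(X_tr))
      batch_of <- ceiling(seq_along(ord) / config$batch_size)
      for (bi in split(ord, batch_of)) {
        t_step <- t_step + 1L
        gr <- nn_grad(par, X_tr[bi, , drop = FALSE], y_tr[bi])
        upd <- adam_step(par, gr, st, config$learning_rate, t_step)
        par <- upd$par
        st <- upd$st
      }
      train_loss <- bce_loss(nn_forward(par, X_tr)$p, y_tr)
      val_loss <- bce_loss(nn_forward(par, X_val)$p, y_val)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (val_loss < best_loss - config$improvement_tol) {
        best_loss <- val_loss
        best_par <- par
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }

    structure(
      list(config = config, par = best_par, history = history,
           stopped_epoch = stopped_epoch,
           best_epoch = if (best_epoch > 0L) best_epoch else stopped_epoch,
           val_indices = sort(val_idx)),
      class = "similarity_model"
    )
  })
}

#' @export
print.similarity_model <- function(x, ...) {
  cat("similarity_model: ", x$config$input_dim, " -> ",
      paste(x$config$hidden_sizes, collapse = " -> "), " -> 1\n",
      "  trained ", x$stopped_epoch, " epoch(s); best epoch ", x$best_epoch,
      " (val loss ", signif(x$history$val_loss[x$best_epoch], 4), ")\n",
      sep = "")
  invisible(x)
}

#' Predict pair similarity
#'
#' Applies the trained network to one or more Hadamard feature vectors.
#'
#' @param model A `similarity_model`.
#' @param z Numeric vector of length `input_dim`, or a matrix with that many
#'   columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_similarity <- function(model, z) {
  stopifnot(inherits(model, "similarity_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != model$config$input_dim) {
    stop("feature length (", ncol(z), ") does not match model input_dim (",
         model$config$input_dim, ")")
  }
  as.numeric(nn_forward(model$par, z)$p)
}

model_format_version <- "cbscreen-model-v1"

#' Save a trained model to a directory
#'
#' Writes a format marker, the configuration (DCF text), the training history
#' (TSV) and the weights. [load_model()] restores an object whose predictions
#' agree exactly.
#'
#' @param model A `similarity_model`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "similarity_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(model_format_version, file.path(path, "FORMAT"))
  cfg <- model$config
  cfg$hidden_sizes <- paste(cfg$hidden_sizes, collapse = ",")
  write.dcf(as.data.frame(unclass(cfg)), file.path(path, "config.dcf"))
  utils::write.table(model$history, file.path(path, "history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  saveRDS(list(par = model$par, stopped_epoch = model$stopped_epoch,
               best_epoch = model$best_epoch, val_indices = model$val_indices),
          file.path(path, "weights.rds"))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model directory.
#' @return A `similarity_model`.
#' @export
load_model <- function(path) {
  fmt_file <- file.path(path, "FORMAT")
  if (!file.exists(fmt_file)) stop("not a model directory: ", path)
  fmt <- readLines(fmt_file, n = 1L)
  if (!identical(fmt, model_format_version)) {
    stop("model format mismatch: file is '", fmt, "', this package reads '",
         model_format_version, "'")
  }
  cfg_raw <- as.list(as.data.frame(read.dcf(file.path(path, "config.dcf")),
                                   stringsAsFactors = FALSE))
  config <- model_config(
    input_dim = as.integer(cfg_raw$input_dim),
    hidden_sizes = as.integer(strsplit(cfg_raw$hidden_sizes, ",")[[1L]]),
    learning_rate = as.numeric(cfg_raw$learning_rate),
    batch_size = as.integer(cfg_raw$batch_size),
    max_epochs = as.integer(cfg_raw$max_epochs),
    patience = as.integer(cfg_raw$patience),
    validation_fraction = as.numeric(cfg_raw$validation_fraction),
    improvement_tol = as.numeric(cfg_raw$improvement_tol),
    seed = as.integer(cfg_raw$seed)
  )
  blob <- tryCatch(readRDS(file.path(path, "weights.rds")), error = function(e) {
    stop("corrupted or unreadable weights in ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (nrow(blob$par$W[[1L]]) != config$input_dim) {
    stop("saved weights expect input_dim ", nrow(blob$par$W[[1L]]),
         " but config declares ", config$input_dim)
  }
  history <- utils::read.table(file.path(path, "history.tsv"), sep = "\t",
                               header = TRUE)
  structure(
    list(config = config, par = blob$par, history = history,
         stopped_epoch = blob$stopped_epoch, best_epoch = blob$best_epoch,
         val_indices = blob$val_indices),
    class = "similarity_model"
  )
}
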