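#' Configuration of the backpropagation pixel classifier
#'
#' One hidden layer, logistic activations in hidden and output layers,
#' gradient descent with momentum on min-max-scaled band DNs.  The
#' training rate must stay in \[0.01, 0.05\] (the band within which this
#' classifier is well behaved on scaled 11-bit imagery) unless
#' `allow_any_rate` is set.
#'
#' @param learning_rate training rate (default 0.02).
#' @param momentum momentum term in \[0, 1) (default 0.8).
#' @param n_hidden_units hidden-layer width (default 16).
#' @param max_epochs epoch cap (default 3000).
#' @param rms_stop stop when output RMS error drops below this (0.01).
#' @param seed RNG seed for weight initialization.
#' @param allow_any_rate permit learning rates outside \[0.01, 0.05\].
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(learning_rate = 0.02, momentum = 0.8,
                       n_hidden_units = 16, max_epochs = 3000,
                       rms_stop = 0.01, seed = 1L,
                       allow_any_rate = FALSE) {
  if (!allow_any_rate &&
      (learning_rate < 0.01 || learning_rate > 0.05)) {
    stop("learning_rate outside [0.01, 0.05]; set allow_any_rate = TRUE ",
         "to override")
  }
  stopifnot(momentum >= 0, momentum < 1, n_hidden_units >= 1,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 n_hidden_units = as.integer(n_hidden_units),
                 max_epochs = as.integer(max_epochs), rms_stop = rms_stop,
                 seed = as.integer(seed)), class = "ann_config")
}

#' Split a multimodal class into spectral subclasses
#'
#' When one nominal class occupies several distinct regions of feature
#' space, pixel classifiers train better on subclasses.  Gaussian
#' mixtures with 1..`max_k` components are fitted to the class's sample
#' DNs and the component count is selected by BIC; samples are relabeled
#' `<class>.1`, `<class>.2`, ... when k > 1.  Subclasses collapse back to
#' the parent class at prediction time (see [classify_pixels()]).
#'
#' @param raster the raster samples were drawn from.
#' @param samples labeled [point_set()].
#' @param class_name the class to examine.
#' @param max_k maximum number of mixture components.
#' @param min_n minimum samples per class (a class with fewer than
#'   `2 * min_n` samples is returned unchanged with a warning).
#' @return The relabeled [point_set()].
#' @export
subclass_split <- function(raster, samples, class_name, max_k = 3,
                           min_n = 5) {
  idx <- which(samples$class == class_name)
  if (length(idx) < 2 * min_n) {
    warning("too few samples in ", class_name, " for subclass analysis")
    return(samples)
  }
  rw <- map_to_row(raster, samples$y[idx])
  cl <- map_to_col(raster, samples$x[idx])
  X <- vapply(seq_len(n_bands(raster)),
              function(k) raster$bands[, , k][cbind(rw, cl)],
              numeric(length(idx)))
  mclustBIC <- mclust::mclustBIC  # Mclust() looks this up in the caller
  fit <- tryCatch(
    mclust::Mclust(X, G = seq_len(max_k), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G <= 1) return(samples)
  samples$class[idx] <- paste0(class_name, ".", fit$classification)
  samples
}

#' Train the pixel classifier
#'
#' Full-batch backpropagation with momentum on one-hot targets; inputs
#' are per-band min-max scaled to \[0, 1\] from the training split.
#' Training stops when the output RMS error falls below
#' `config$rms_stop` or at `config$max_epochs`.  Deterministic given
#' `config$seed`.
#'
#' @param raster an [mb_raster()].
#' @param samples a [point_set()] with `class` and `split`
#'   (train/test) columns and at least two classes.
#' @param config an [ann_config()].
#' @param parent_map optional named character vector mapping subclass ->
#'   parent class (subclass labels of the form `parent.k` are handled
#'   automatically).
#' @return A list of class `ann_model`: weight matrices `W1`, `W2`,
#'   scaling, `classes`, `parent_map`, `converged`, `train_log`
#'   (epoch/RMS), and `test_report` with per-class held-out accuracy.
#' @export
train_ann <- function(raster, samples, config = ann_config(),
                      parent_map = NULL) {
  stopifnot(inherits(raster, "mb_raster"), !is.null(samples$split))
  classes <- sort(unique(samples$class))
  if (length(classes) < 2) stop("need at least two classes to train")
  rw <- map_to_row(raster, samples$y)
  cl <- map_to_col(raster, samples$x)
  nb <- n_bands(raster)
  X <- vapply(seq_len(nb), function(k) raster$bands[, , k][cbind(rw, cl)],
              numeric(length(rw)))
  X <- matrix(X, ncol = nb)
  tr <- samples$split == "train"
  lo <- apply(X[tr, , drop = FALSE], 2, min)
  hi <- apply(X[tr, , drop = FALSE], 2, max)
  hi <- ifelse(hi > lo, hi, lo + 1)
  Xs <- sweep(sweep(X, 2, lo), 2, hi - lo, "/")
  Y <- outer(samples$class, classes, "==") * 1

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  nh <- config$n_hidden_units; nk <- length(classes)
  W1 <- matrix(runif((nb + 1) * nh, -0.5, 0.5), nb + 1, nh) / sqrt(nb + 1)
  W2 <- matrix(runif((nh + 1) * nk, -0.5, 0.5), nh + 1, nk) / sqrt(nh + 1)
  V1 <- W1 * 0; V2 <- W2 * 0
  sigm <- function(z) 1 / (1 + exp(-z))
  Xtr <- cbind(1, Xs[tr, , drop = FALSE]); Ytr <- Y[tr, , drop = FALSE]
  n <- nrow(Xtr)
  log_ep <- integer(0); log_rms <- numeric(0)
  rms <- Inf; epoch <- 0
  while (epoch < config$max_epochs && rms > config$rms_stop) {
    epoch <- epoch + 1
    H <- sigm(Xtr %*% W1)
    Hb <- cbind(1, H)
    O <- sigm(Hb %*% W2)
    E <- O - Ytr
    rms <- sqrt(mean(E^2))
    dO <- E  # cross-entropy delta for logistic outputs
    dH <- (dO %*% t(W2[-1, , drop = FALSE])) * H * (1 - H)
    g2 <- crossprod(Hb, dO) / n
    g1 <- crossprod(Xtr, dH) / n
    V2 <- config$momentum * V2 - config$learning_rate * g2
    V1 <- config$momentum * V1 - config$learning_rate * g1
    W2 <- W2 + V2; W1 <- W1 + V1
    if (epoch %% 50 == 0 || epoch == 1) {
      log_ep <- c(log_ep, epoch); log_rms <- c(log_rms, rms)
    }
  }
  converged <- rms <= config$rms_stop
  if (is.null(parent_map)) {
    parent_map <- setNames(sub("\\.[0-9]+$", "", classes), classes)
  }
  model <- structure(list(W1 = W1, W2 = W2, scale_lo = lo, scale_hi = hi,
                          classes = classes, parent_map = parent_map,
                          config = config, converged = converged,
                          train_log = data.frame(epoch = log_ep,
                                                 rms = log_rms)),
                     class = "ann_model")
  te <- samples$split == "test"
  test_report <- NULL
  if (any(te)) {
    pred <- predict_classes(model, X[te, , drop = FALSE])
    truth <- parent_map[samples$class[te]]
    acc <- tapply(pred == truth, truth, mean)
    test_report <- data.frame(class = names(acc),
                              accuracy = as.numeric(acc),
                              n = as.integer(table(truth)[names(acc)]))
    attr(test_report, "overall") <- mean(pred == truth)
  }
  model$test_report <- test_report
  model
}

#' Save or load a trained pixel classifier
#'
#' Models are stored as versioned JSON: weight matrices, input scaling,
#' class table and configuration.
#'
#' @param model an `ann_model`.
#' @param path file path (`.json`).
#' @return `read_ann_model()` returns the `ann_model`.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  payload <- list(format = "herdspot-ann", version = 1L,
                  W1 = model$W1, W2 = model$W2,
                  scale_lo = model$scale_lo, scale_hi = model$scale_hi,
                  classes = model$classes,
                  parent_map = as.list(model$parent_map),
                  config = unclass(model$config),
                  converged = model$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "herdspot-ann")) stop("not a model file: ", path)
  structure(list(W1 = j$W1, W2 = j$W2, scale_lo = j$scale_lo,
                 scale_hi = j$scale_hi, classes = j$classes,
                 parent_map = unlist(j$parent_map),
                 config = structure(j$config, class = "ann_config"),
                 converged = j$converged, train_log = NULL,
                 test_report = NULL),
            class = "ann_model")
}

predict_activations <- function(model, X) {
  sigm <- function(z) 1 / (1 + exp(-z))
  Xs <- sweep(sweep(X, 2, model$scale_lo), 2,
              model$scale_hi - model$scale_lo, "/")
  H <- sigm(cbind(1, Xs) %*% model$W1)
  sigm(cbind(1, H) %*% model$W2)
}

predict_classes <- function(model, X, animal_class = NULL, margin = 0) {
  O <- predict_activations(model, X)
  if (!is.null(animal_class)) {
    is_an <- model$parent_map[model$classes] == animal_class
    if (any(is_an)) O[, is_an] <- O[, is_an] + margin
  }
  k <- max.col(O, ties.method = "first")
  unname(model$parent_map[model$classes[k]])
}

#' Classify every pixel of a raster
#'
#' Applies a trained [train_ann()] model per pixel (argmax over output
#' activations) and collapses subclasses to their parent classes.  To
#' favor recall of animal candidates — the pixel stage is deliberately
#' permissive, leaving false positives for the object stage to remove —
#' an activation margin can be added to the animal class, and the animal
#' class wins exact ties.
#'
#' @param raster an [mb_raster()] with the band count the model was
#'   trained on.
#' @param model an `ann_model`.
#' @param animal_class parent class favored by `margin` (default
#'   `"animal"`; set `NULL` to disable).
#' @param margin activation bonus for the animal class (default 0).
#' @return A [class_raster()].
#' @export
classify_pixels <- function(raster, model, animal_class = "animal",
                            margin = 0) {
  stopifnot(inherits(model, "ann_model"))
  d <- dim(raster$bands)
  if (d[3] != nrow(model$W1) - 1) stop("band count does not match model")
  X <- matrix(raster$bands, ncol = d[3])
  ## tie-break toward animal: add a hair below numeric resolution of ties
  eps <- if (!is.null(animal_class)) margin + 1e-12 else 0
  pred <- predict_classes(model, X, animal_class, eps)
  parents <- sort(unique(unname(model$parent_map)))
  tab <- setNames(seq_along(parents), parents)
  class_raster(matrix(tab[pred], d[1], d[2]), tab,
               cell_size_m = raster$cell_size_m, origin = raster$origin)
}
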