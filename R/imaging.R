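#' Class-balanced frame capture rates
#'
#' Classes with more video material are sampled at proportionally lower
#' rates so the expected number of extracted frames per class is equal. The
#' largest rate is scaled to 1.
#'
#' @param class_video_counts positive integer counts of videos (trials) per
#'   class, in class order
#' @return numeric sampling rates in (0, 1], same order
#' @export
balance_capture_rates <- function(class_video_counts) {
  counts <- as.numeric(class_video_counts)
  if (any(counts < 1)) stop("every class needs at least one video")
  rate <- (1 / counts) / max(1 / counts)
  rate
}

#' Image-branch model configuration
#'
#' @param backbone `"small_cnn"` (default) or `"inception_resnet_v2"`; the
#'   latter requires an external implementation and is not bundled
#' @param resolution square input side; 299 matches the Inception input
#'   contract, smaller values suit the CPU backbone
#' @param train_fraction trial-level training fraction (default 2/3)
#' @param epochs training epochs (default 8)
#' @param batch_size minibatch size (default 32)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed integer seed
#' @return an `image_model_config` list
#' @export
image_model_config <- function(backbone = c("small_cnn", "inception_resnet_v2"),
                               resolution = 299, train_fraction = 2 / 3,
                               epochs = 8, batch_size = 32, lr = 1e-3,
                               seed = 1) {
  backbone <- match.arg(backbone)
  stopifnot(resolution >= 8, epochs >= 1)
  structure(list(backbone = backbone, resolution = resolution,
                 fc_layers = 3L, out_nodes = 3L,
                 train_fraction = train_fraction, epochs = epochs,
                 batch_size = batch_size, lr = lr, seed = seed),
            class = "image_model_config")
}

read_frame_file <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    jpeg::readJPEG(path)
  } else {
    stop("unsupported frame format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Extract class-balanced frames from trial frame directories
#'
#' Each trial directory is scanned for PNG/JPEG files in filename order and
#' subsampled deterministically at its class rate by keeping every
#' `round(1/rate)`-th frame. Frames are resized to `resolution` by bilinear
#' interpolation.
#'
#' @param frame_dirs named character vector: `trial_id -> directory`
#' @param labels skill labels aligned with `frame_dirs`
#' @param rates per-class sampling rates named by class (see
#'   [balance_capture_rates()]); default all 1
#' @param resolution output side length (default 299)
#' @return a `frame_set`: list with `frames` (n, r, r, 3 array), `trial_id`
#'   and `label` vectors aligned to frames, and `resolution`
#' @export
extract_frames <- function(frame_dirs, labels, rates = NULL,
                           resolution = 299) {
  labels <- as.character(labels)
  stopifnot(length(frame_dirs) == length(labels))
  if (is.null(rates)) {
    rates <- rep(1, length(unique(labels)))
    names(rates) <- unique(labels)
  }
  imgs <- list(); ids <- character(0); labs <- character(0)
  for (i in seq_along(frame_dirs)) {
    files <- sort(list.files(frame_dirs[i],
                             pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frames for trial ", names(frame_dirs)[i])
    stride <- max(1L, round(1 / rates[[labels[i]]]))
    files <- files[seq(1, length(files), by = stride)]
    for (f in files) {
      img <- tryCatch(read_frame_file(f), error = function(e) {
        warning("skipping unreadable frame ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      imgs[[length(imgs) + 1]] <- resize_bilinear(img, resolution)
      ids <- c(ids, names(frame_dirs)[i])
      labs <- c(labs, labels[i])
    }
  }
  if (length(imgs) == 0) stop("no readable frames found")
  arr <- array(0, c(length(imgs), resolution, resolution, 3))
  for (k in seq_along(imgs)) arr[k, , , ] <- imgs[[k]]
  structure(list(frames = arr, trial_id = ids, label = labs,
                 resolution = resolution),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames (%dx%dx3) from %d trials\n",
              dim(x$frames)[1], x$resolution, x$resolution,
              length(unique(x$trial_id))))
  invisible(x)
}

#' Train the image-branch classifier
#'
#' Splits trials (never frames) into train/test at `train_fraction`,
#' stratified by class, and fits the configured backbone on the training
#' frames. The per-epoch training loss is recorded in the returned model.
#'
#' @param frameset a `frame_set` from [extract_frames()]
#' @param config an [image_model_config()]
#' @param train_trials optional explicit vector of training trial ids (used
#'   by the pipeline so both branches share one split); when `NULL` a
#'   stratified trial-level split is drawn from the config seed
#' @return an `image_model`: fitted network, `losses`, `train_trials`,
#'   `test_trials`, `classes`
#' @export
train_image_classifier <- function(frameset, config = image_model_config(),
                                   train_trials = NULL) {
  stopifnot(inherits(frameset, "frame_set"))
  if (config$backbone == "inception_resnet_v2") {
    stop("inception_resnet_v2 backbone requires an external implementation ",
         "and pretrained weights; none is bundled. Use backbone = 'small_cnn'.")
  }
  trial_label <- tapply(frameset$label, frameset$trial_id,
                        function(l) l[1])
  classes <- canonical_classes(trial_label)
  if (length(classes) < 2) stop("need at least 2 classes of trials")
  if (any(table(as.character(trial_label)) < 2)) {
    stop("every class needs at least 2 trials for a trial-level split")
  }
  trials <- names(trial_label)
  if (is.null(train_trials)) {
    sp <- stratified_split(as.character(trial_label), config$train_fraction,
                           derive_seed(config$seed, "imgsplit"))
    train_trials <- trials[sp$train]
  } else {
    train_trials <- intersect(trials, train_trials)
  }
  test_trials <- setdiff(trials, train_trials)
  in_train <- frameset$trial_id %in% train_trials
  if (frameset$resolution != config$resolution) {
    stop("frame_set resolution (", frameset$resolution,
         ") differs from config resolution (", config$resolution, ")")
  }
  Y <- one_hot(frameset$label[in_train], classes)
  net <- train_small_cnn(frameset$frames[in_train, , , , drop = FALSE], Y,
                         epochs = config$epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = derive_seed(config$seed, "cnn"))
  structure(list(net = net, classes = classes, losses = net$losses,
                 train_trials = train_trials, test_trials = test_trials,
                 resolution = frameset$resolution, config = config),
            class = "image_model")
}

#' @export
print.image_model <- function(x, ...) {
  cat(sprintf("<image_model> small_cnn @ %dpx, %d train / %d test trials, final loss %.4f\n",
              x$resolution, length(x$train_trials), length(x$test_trials),
              x$losses[length(x$losses)]))
  invisible(x)
}

#' Per-frame class probabilities
#'
#' @param model an `image_model`
#' @param frames (n, r, r, 3) array at the model resolution
#' @return n-by-K probability matrix
#' @export
predict_frame_probs <- function(model, frames) {
  dm <- dim(frames)
  if (dm[2] != model$resolution || dm[3] != model$resolution) {
    stop("frames must be ", model$resolution, "x", model$resolution)
  }
  pr <- predict_small_cnn(model$net, frames)
  colnames(pr) <- model$classes
  pr
}

#' Aggregate frame probabilities into one trial prediction
#'
#' The trial probability vector is the arithmetic mean of its frame
#' probability vectors; the label is the argmax (ties resolved to the
#' lower-ordered class).
#'
#' @param frame_probs matrix of frame probabilities (rows = frames)
#' @param classes class names in column order (default the matrix colnames)
#' @param trial_id id to attach (default "trial")
#' @return one-row `classifier_outcome`
#' @export
aggregate_trial_prediction <- function(frame_probs, classes = NULL,
                                       trial_id = "trial") {
  frame_probs <- as.matrix(frame_probs)
  if (nrow(frame_probs) == 0) stop("no frames to aggregate")
  if (is.null(classes)) classes <- colnames(frame_probs)
  p <- colMeans(frame_probs)
  classifier_outcome(trial_id, matrix(p, 1), classes)
}

#' Trial-level image predictions for a frame set
#'
#' @param model an `image_model`
#' @param frameset a `frame_set`
#' @param trials optional subset of trial ids (default all in the set)
#' @return `classifier_outcome` with one row per trial
#' @export
predict_image_trials <- function(model, frameset, trials = NULL) {
  if (is.null(trials)) trials <- unique(frameset$trial_id)
  pr <- predict_frame_probs(model,
                            frameset$frames[frameset$trial_id %in% trials, , , ,
                                            drop = FALSE])
  ids <- frameset$trial_id[frameset$trial_id %in% trials]
  rows <- lapply(unique(ids), function(tid) {
    aggregate_trial_prediction(pr[ids == tid, , drop = FALSE],
                               model$classes, tid)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("classifier_outcome", "data.frame")
  out
}
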