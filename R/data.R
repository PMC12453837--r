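# Synthetic labelled-image generation, image-folder loading, and dataset
# split protocols.
#
# The generator emulates multi-class medical-image folders with
# class-dependent parametric textures: each class has its own oriented
# stripe frequency, blob count, base intensity and colour tint, plus i.i.d.
# Gaussian pixel noise. The class signal is strong by construction (the
# class-conditional mean intensity separates classes by >= 5 noise standard
# deviations at the defaults), so a classifier that learns anything at all
# can be detected quickly. An optional per-class count vector reproduces
# long-tailed label distributions such as the 6075:...:115 skin-lesion
# imbalance.

#' Synthetic dataset specification
#'
#' @param num_classes Number of classes (>= 2).
#' @param images_per_class Scalar or per-class integer vector.
#' @param image_size Square image side in pixels.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param texture_params Optional data frame with one row per class and
#'   columns `stripe_freq`, `stripe_angle`, `blob_count`, `base`; defaults
#'   to an evenly spread, pairwise-distinct schedule.
#' @param seed Integer seed; fully determines the dataset.
#' @return An object of class `hemf_synth_spec`.
#' @export
synthetic_spec <- function(num_classes, images_per_class = 32L,
                           image_size = 64L, noise_sd = 0.05,
                           texture_params = NULL, seed = 1L) {
  if (num_classes < 2L) hemf_stop_validation("need at least two classes")
  if (length(images_per_class) == 1L)
    images_per_class <- rep(as.integer(images_per_class), num_classes)
  if (length(images_per_class) != num_classes || any(images_per_class < 1L))
    hemf_stop_validation("images_per_class must be positive, one per class")
  if (is.null(texture_params)) {
    K <- num_classes
    texture_params <- data.frame(
      stripe_freq = 3 + 2 * (seq_len(K) - 1L),
      stripe_angle = pi * (seq_len(K) - 1L) / K,
      blob_count = seq_len(K),
      base = 0.35 + 0.3 * (seq_len(K) - 1L) / max(1L, K - 1L)
    )
  }
  if (nrow(texture_params) != num_classes)
    hemf_stop_validation("texture_params needs one row per class")
  if (anyDuplicated(texture_params))
    hemf_stop_validation("class texture parameters must be pairwise distinct")
  structure(list(
    num_classes = as.integer(num_classes),
    images_per_class = as.integer(images_per_class),
    image_size = as.integer(image_size),
    noise_sd = noise_sd,
    texture_params = texture_params,
    seed = as.integer(seed)
  ), class = "hemf_synth_spec")
}

#' Generate a synthetic labelled image set
#'
#' Deterministic given the spec's seed. Images are RGB in [0, 1] with a
#' class-dependent oriented stripe pattern, Gaussian blobs, a base
#' intensity offset, a colour tint, and additive pixel noise.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `images` ([n, 3, S, S] array in [0,1]), `labels`
#'   (0-based integers) and `class_names`.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "hemf_synth_spec"))
  S <- spec$image_size
  n <- sum(spec$images_per_class)
  K <- spec$num_classes
  withr::with_seed(spec$seed, {
    images <- array(0, dim = c(n, 3L, S, S))
    labels <- integer(n)
    grid <- (seq_len(S) - 0.5) / S
    gx <- matrix(grid, S, S, byrow = TRUE)   # x varies along width (dim 4)
    gy <- matrix(grid, S, S)                 # y varies along height (dim 3)
    i <- 0L
    for (k in seq_len(K)) {
      tp <- spec$texture_params[k, ]
      tint <- 0.08 * sin(2 * pi * (k - 1) / K + 2 * pi * (0:2) / 3)
      for (j in seq_len(spec$images_per_class[k])) {
        i <- i + 1L
        labels[i] <- k - 1L
        phase <- stats::runif(1, 0, 2 * pi)
        pat <- tp$base + 0.18 * sin(2 * pi * tp$stripe_freq *
                                      (gx * cos(tp$stripe_angle) +
                                       gy * sin(tp$stripe_angle)) + phase)
        for (b in seq_len(tp$blob_count)) {
          cx <- stats::runif(1); cy <- stats::runif(1)
          pat <- pat + 0.15 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * 0.08^2))
        }
        for (ch in 1:3) {
          img <- pat + tint[ch] +
            stats::rnorm(S * S, 0, spec$noise_sd)
          images[i, ch, , ] <- pmin(pmax(img, 0), 1)
        }
      }
    }
    list(images = images, labels = labels,
         class_names = sprintf("class_%02d", seq_len(K) - 1L))
  })
}

#' Normalize images by fixed per-channel constants
#' @param images Array [n, C, S, S] in [0, 1].
#' @param mean,sd Normalization constants (defaults 0.5, 0.5).
#' @return Normalized array.
#' @export
normalize_images <- function(images, mean = 0.5, sd = 0.5) (images - mean) / sd

#' Write an image set to a class-subdirectory folder of PNGs
#' @param dataset List with `images`, `labels`, `class_names` (as produced
#'   by [generate_synthetic_dataset()]); images in [0, 1].
#' @param path Output directory (created if needed).
#' @return Invisibly, `path`.
#' @export
write_image_folder <- function(dataset, path) {
  for (cn in dataset$class_names)
    dir.create(file.path(path, cn), recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(dataset$class_names))
  for (i in seq_along(dataset$labels)) {
    k <- dataset$labels[i] + 1L
    counter[k] <- counter[k] + 1L
    img <- aperm(dataset$images[i, , , ], c(2L, 3L, 1L))  # H, W, C
    png::writePNG(img, file.path(path, dataset$class_names[k],
                                 sprintf("img_%04d.png", counter[k])))
  }
  invisible(path)
}

# Bilinear resampling of an H x W x C array to size x size (pixel-center
# alignment, edge clamping).
bilinear_resize <- function(img, size) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  if (H == size && W == size) return(img)
  map <- function(n_in) {
    src <- (seq_len(size) - 0.5) * n_in / size - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    list(lo = lo + 1, hi = pmin(lo + 1, n_in - 1) + 1, w = src - lo)
  }
  my <- map(H); mx <- map(W)
  out <- array(0, dim = c(size, size, d[3L]))
  wy <- matrix(my$w, size, size)
  wx <- matrix(mx$w, size, size, byrow = TRUE)
  for (c in seq_len(d[3L])) {
    p <- img[, , c]
    out[, , c] <-
      p[cbind(rep(my$lo, size), rep(mx$lo, each = size))] * (1 - wy) * (1 - wx) +
      p[cbind(rep(my$hi, size), rep(mx$lo, each = size))] * wy * (1 - wx) +
      p[cbind(rep(my$lo, size), rep(mx$hi, each = size))] * (1 - wy) * wx +
      p[cbind(rep(my$hi, size), rep(mx$hi, each = size))] * wy * wx
  }
  out
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    tryCatch(png::readPNG(path), error = function(e)
      hemf_stop_validation(sprintf("cannot read image '%s': %s", path,
                                   conditionMessage(e))))
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      hemf_stop_validation(sprintf(
        "reading '%s' requires the EBImage package", path))
    a <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                  error = function(e)
                    hemf_stop_validation(sprintf("cannot read image '%s': %s",
                                                 path, conditionMessage(e))))
    if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  } else {
    hemf_stop_validation(sprintf("unsupported image format: '%s'", path))
  }
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  img
}

#' Load a class-subdirectory image folder
#'
#' Reads one subdirectory per class (PNG/JPEG), resizes every image
#' bilinearly to `image_size` x `image_size`, scales pixels to [0, 1] and
#' normalizes by fixed constants. Class names are the subdirectory names,
#' sorted lexicographically, mapped to label ids 0, 1, ...
#'
#' @param path Folder with one subdirectory per class.
#' @param image_size Target square resolution.
#' @param normalize Apply `(x - mean) / sd`?
#' @param mean,sd Normalization constants (defaults 0.5, 0.5).
#' @return List with `images` ([n, 3, S, S]), `labels` (0-based),
#'   `class_names`, `files`.
#' @export
load_image_folder <- function(path, image_size = 224L, normalize = TRUE,
                              mean = 0.5, sd = 0.5) {
  if (!dir.exists(path)) hemf_stop_validation(sprintf("no such folder: '%s'", path))
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (length(dirs) == 0L)
    hemf_stop_validation(sprintf("'%s' has no class subdirectories", path))
  class_names <- basename(dirs)
  imgs <- list(); labels <- integer(0); files <- character(0)
  for (k in seq_along(dirs)) {
    fs <- sort(list.files(dirs[k], pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (length(fs) == 0L)
      hemf_stop_validation(sprintf("class directory '%s' is empty", dirs[k]))
    for (f in fs) {
      imgs[[length(imgs) + 1L]] <- bilinear_resize(read_one_image(f), image_size)
      labels <- c(labels, k - 1L)
      files <- c(files, f)
    }
  }
  n <- length(imgs)
  images <- array(0, dim = c(n, 3L, image_size, image_size))
  for (i in seq_len(n)) images[i, , , ] <- aperm(imgs[[i]], c(3L, 1L, 2L))
  if (normalize) images <- normalize_images(images, mean, sd)
  list(images = images, labels = labels, class_names = class_names,
       files = files)
}

#' Stratified dataset split protocols
#'
#' `holdout_70_30`: stratified 70% train(+validation) / 30% test.
#' `kfold2`: two stratified folds, each used once as the test set.
#' `three_way_60_15_25`: stratified 60% train / 15% validation / 25% test.
#' Index sets are disjoint, exhaustive and deterministic given the seed.
#'
#' @param y Integer class labels (length n >= 10).
#' @param protocol One of `"holdout_70_30"`, `"kfold2"`,
#'   `"three_way_60_15_25"`.
#' @param seed Integer seed.
#' @return Named list of index vectors (`train`/`test`,
#'   `fold1`/`fold2`, or `train`/`val`/`test`).
#' @export
make_splits <- function(y, protocol = c("holdout_70_30", "kfold2",
                                        "three_way_60_15_25"),
                        seed = 1L) {
  protocol <- match.arg(protocol)
  n <- length(y)
  if (n < 10L) hemf_stop_validation("need at least 10 samples to split")
  classes <- sort(unique(y))
  if (protocol == "kfold2" && any(table(y) < 2L))
    hemf_stop_validation("every class needs at least as many samples as folds")
  withr::with_seed(seed, {
    per_class <- lapply(classes, function(k) sample(which(y == k)))
    take <- function(fracs) {
      parts <- lapply(seq_along(fracs), function(i) integer(0))
      alloc <- numeric(length(fracs))
      done <- 0L
      for (idx in per_class) {
        nc <- length(idx)
        done <- done + nc
        sizes <- floor(fracs * nc)
        rem <- nc - sum(sizes)
        if (rem > 0L) {
          # largest remainder first; ties go to the split lagging most
          # behind its overall target, so totals match the protocol exactly
          deficit <- fracs * done - (alloc + sizes)
          extra <- order(fracs * nc - sizes, deficit,
                         decreasing = TRUE)[seq_len(rem)]
          sizes[extra] <- sizes[extra] + 1L
        }
        alloc <- alloc + sizes
        off <- 0L
        for (i in seq_along(sizes)) {
          parts[[i]] <- c(parts[[i]], idx[off + seq_len(sizes[i])])
          off <- off + sizes[i]
        }
      }
      lapply(parts, sort)
    }
    switch(protocol,
      holdout_70_30 = {
        p <- take(c(0.7, 0.3)); list(train = p[[1L]], test = p[[2L]])
      },
      kfold2 = {
        p <- take(c(0.5, 0.5)); list(fold1 = p[[1L]], fold2 = p[[2L]])
      },
      three_way_60_15_25 = {
        p <- take(c(0.6, 0.15, 0.25))
        list(train = p[[1L]], val = p[[2L]], test = p[[3L]])
      })
  })
}
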