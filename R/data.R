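#' Canonical pathology names
#'
#' The 14 finding labels of the NIH chest-radiograph dataset, in the
#' conventional order, and the 5-observation competition subset of the
#' Stanford dataset.
#'
#' @return A character vector of class names.
#' @export
chestxray14_classes <- function() {
  c("Atelectasis", "Cardiomegaly", "Effusion", "Infiltration", "Mass",
    "Nodule", "Pneumonia", "Pneumothorax", "Consolidation", "Edema",
    "Emphysema", "Fibrosis", "Pleural_Thickening", "Hernia")
}

#' @rdname chestxray14_classes
#' @export
chexpert_classes5 <- function() {
  c("Atelectasis", "Cardiomegaly", "Consolidation", "Edema",
    "Pleural Effusion")
}

new_dataset <- function(index, labels, class_names) {
  rownames(labels) <- index$image
  structure(list(index = index, labels = labels, class_names = class_names),
            class = "hrcc_dataset")
}

#' @export
print.hrcc_dataset <- function(x, ...) {
  cat("<hrcc_dataset>", nrow(x$index), "images,",
      length(x$class_names), "classes,",
      sum(x$labels), "positive labels\n")
  invisible(x)
}

#' Read labels in the pipe-separated (NIH) dialect
#'
#' One row per image with a findings column holding pipe-separated
#' label names; `"No Finding"` maps to an all-zero row. Image files are
#' checked against `image_dir` when given: missing files are skipped
#' with a warning (or an error in strict mode).
#'
#' @param csv_path Path to the label CSV. The image column is matched by
#'   name (`Image Index` or `image`) and the findings column by
#'   `Finding Labels`/`findings`/`labels`; otherwise the first two
#'   columns are used.
#' @param image_dir Optional directory holding the image files.
#' @param class_names Label vocabulary (defaults to the 14 canonical
#'   names); unknown label strings are an error.
#' @param strict Error (rather than warn and skip) on missing images.
#' @return An `hrcc_dataset`: a list with an `index` tibble
#'   (`image`, `path`, `patient_id`, `findings`), the `(n, N)` 0/1
#'   `labels` matrix and `class_names`.
#' @export
read_chestxray14_labels <- function(csv_path, image_dir = NULL,
                                    class_names = chestxray14_classes(),
                                    strict = FALSE) {
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  img_col <- intersect(c("Image Index", "image", "Image"), names(df))[1]
  lab_col <- intersect(c("Finding Labels", "findings", "labels"), names(df))[1]
  if (is.na(img_col)) img_col <- names(df)[1]
  if (is.na(lab_col)) lab_col <- names(df)[2]
  images <- as.character(df[[img_col]])
  if (anyDuplicated(images)) {
    stop("duplicate image names in ", csv_path, call. = FALSE)
  }
  findings <- as.character(df[[lab_col]])
  keep <- rep(TRUE, length(images))
  paths <- if (!is.null(image_dir)) file.path(image_dir, images) else
    rep(NA_character_, length(images))
  if (!is.null(image_dir)) {
    missing <- !file.exists(paths)
    if (any(missing)) {
      msg <- paste0(sum(missing), " image file(s) missing under ", image_dir)
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; skipping", call. = FALSE)
      keep <- !missing
    }
  }
  images <- images[keep]; findings <- findings[keep]; paths <- paths[keep]
  labels <- matrix(0L, length(images), length(class_names),
                   dimnames = list(NULL, class_names))
  for (i in seq_along(findings)) {
    parts <- trimws(strsplit(findings[i], "|", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts) & parts != "No Finding"]
    unknown <- setdiff(parts, class_names)
    if (length(unknown)) {
      stop("unknown label string(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    labels[i, parts] <- 1L
  }
  patient <- ifelse(grepl("^\\d+_\\d+", images),
                    sub("_.*$", "", images), NA_character_)
  index <- tibble::tibble(image = images, path = paths,
                          patient_id = patient, findings = findings)
  new_dataset(index, labels, class_names)
}

#' Read labels in the per-observation (CheXpert) dialect
#'
#' One column per observation with values 1 (positive), 0 (negative),
#' -1 (uncertain) or blank (unmentioned). Uncertain labels are resolved
#' by a policy: `"zeros"` maps -1 to 0, `"ones"` maps -1 to 1; blanks
#' are always 0.
#'
#' @param csv_path Path to the label CSV; a `Path` (or first) column
#'   identifies the image.
#' @param policy Uncertainty policy, `"zeros"` or `"ones"`.
#' @param classes Observation columns to keep; defaults to every
#'   observation column found, or use [chexpert_classes5()] for the
#'   five-pathology subset.
#' @return An `hrcc_dataset` (see [read_chestxray14_labels()]).
#' @export
read_chexpert_labels <- function(csv_path, policy = c("zeros", "ones"),
                                 classes = NULL) {
  if (is.character(policy) && length(policy) == 1 &&
      !policy %in% c("zeros", "ones")) {
    stop("unknown uncertainty policy: ", policy, call. = FALSE)
  }
  policy <- match.arg(policy)
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  img_col <- intersect(c("Path", "path", "image"), names(df))[1]
  if (is.na(img_col)) img_col <- names(df)[1]
  meta_cols <- c(img_col, "Sex", "Age", "Frontal/Lateral", "AP/PA")
  if (is.null(classes)) classes <- setdiff(names(df), meta_cols)
  missing_cols <- setdiff(classes, names(df))
  if (length(missing_cols)) {
    stop("observation column(s) not in CSV: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  images <- as.character(df[[img_col]])
  labels <- matrix(0L, nrow(df), length(classes),
                   dimnames = list(NULL, classes))
  for (j in seq_along(classes)) {
    v <- suppressWarnings(as.numeric(df[[classes[j]]]))
    v[is.na(v)] <- 0
    v[v == -1] <- if (policy == "ones") 1 else 0
    labels[, j] <- as.integer(v)
  }
  patient <- ifelse(grepl("patient\\d+", images),
                    sub(".*?(patient\\d+).*", "\\1", images), NA_character_)
  index <- tibble::tibble(image = images, path = images,
                          patient_id = patient,
                          findings = NA_character_)
  new_dataset(index, labels, classes)
}

#' Random train/test/validation split
#'
#' Randomly partitions a dataset in the given ratios (default 7:2:1).
#' When patient identifiers are present (and `by_patient` is `TRUE`),
#' whole patients are assigned to one part so no subject straddles the
#' split.
#'
#' @param dataset An `hrcc_dataset`.
#' @param ratios Positive ratios summing to 1, named `train`, `test`,
#'   `val`.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param by_patient Group by `patient_id` where available?
#' @return A named list of three `hrcc_dataset`s.
#' @export
split_dataset <- function(dataset,
                          ratios = c(train = 0.7, test = 0.2, val = 0.1),
                          seed = 1L, by_patient = TRUE) {
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be positive and sum to 1", call. = FALSE)
  }
  n <- nrow(dataset$index)
  if (n < length(ratios)) stop("fewer records than splits", call. = FALSE)
  groups <- if (by_patient && !all(is.na(dataset$index$patient_id))) {
    ifelse(is.na(dataset$index$patient_id),
           paste0(".img", seq_len(n)), dataset$index$patient_id)
  } else {
    as.character(seq_len(n))
  }
  ug <- unique(groups)
  perm <- with_seed(seed, sample(ug))
  sizes <- vapply(perm, function(g) sum(groups == g), numeric(1))
  cum <- cumsum(sizes) / n
  part <- cut(cum, breaks = c(0, cumsum(ratios)[-length(ratios)] + 1e-12, 1),
              labels = names(ratios), include.lowest = TRUE)
  assign_part <- setNames(as.character(part), perm)
  out <- lapply(names(ratios), function(p) {
    idx <- which(assign_part[groups] == p)
    new_dataset(dataset$index[idx, , drop = FALSE],
                dataset$labels[idx, , drop = FALSE],
                dataset$class_names)
  })
  names(out) <- names(ratios)
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable bilinear resampling used for preprocessing and heatmaps.
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  interp_axis <- function(n_in, n_out) {
    # align pixel centers
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L)
    if (n_in == 1) lo <- rep(1, n_out)
    w <- pos - lo
    list(lo = as.integer(lo), hi = as.integer(pmin(lo + 1L, n_in)), w = w)
  }
  ay <- interp_axis(d[1], out_h)
  ax <- interp_axis(d[2], out_w)
  apply_plane <- function(m) {
    rows <- m[ay$lo, , drop = FALSE] * (1 - ay$w) + m[ay$hi, , drop = FALSE] * ay$w
    rows[, ax$lo, drop = FALSE] * rep(1 - ax$w, each = out_h) +
      rows[, ax$hi, drop = FALSE] * rep(ax$w, each = out_h)
  }
  if (length(d) == 2) apply_plane(img)
  else {
    out <- array(0, c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- apply_plane(img[, , c])
    out
  }
}

#' Preprocess a radiograph for the network
#'
#' Resizes to `resize_to` pixels square, replicates grayscale to three
#' channels, crops to `out_size` (randomly in training mode, centrally
#' otherwise), flips horizontally with probability 0.5 in training
#' mode, and normalizes: pixel values are scaled to the 0-255
#' convention, rescaled to `[0, 1]` and standardized per channel.
#'
#' @param image A `(h, w)` grayscale matrix or `(h, w, 3)` array, on
#'   any nonnegative scale (0-1 or 0-255).
#' @param train_mode Random crop and flip instead of the deterministic
#'   center crop?
#' @param resize_to Intermediate square size (default 256).
#' @param out_size Final crop size (default 224).
#' @param mean,std Per-channel normalization constants (defaults are
#'   the standard three-channel natural-image statistics).
#' @return A `(out_size, out_size, 3)` numeric array.
#' @export
preprocess <- function(image, train_mode = FALSE, resize_to = 256L,
                       out_size = 224L,
                       mean = c(0.485, 0.456, 0.406),
                       std = c(0.229, 0.224, 0.225)) {
  if (is.character(image)) {
    if (!file.exists(image)) {
      stop("cannot read image file: ", image, call. = FALSE)
    }
    image <- png::readPNG(image)
    if (length(dim(image)) == 3) image <- image[, , 1]
  }
  d <- dim(image)
  if (is.null(d) || length(d) > 3) stop("not an image array", call. = FALSE)
  if (max(image) > 1.5) image <- image / 255      # to [0, 1]
  img <- if (length(d) == 2) bilinear_resize(image, resize_to, resize_to)
         else bilinear_resize(image, resize_to, resize_to)[, , 1:3]
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), c(resize_to, resize_to, 3))
  }
  margin <- resize_to - out_size
  if (margin < 0) stop("out_size larger than resize_to", call. = FALSE)
  if (train_mode) {
    oy <- sample.int(margin + 1L, 1L) - 1L
    ox <- sample.int(margin + 1L, 1L) - 1L
  } else {
    oy <- ox <- margin %/% 2L
  }
  img <- img[oy + seq_len(out_size), ox + seq_len(out_size), , drop = FALSE]
  if (train_mode && runif(1) < 0.5) {
    img <- img[, rev(seq_len(out_size)), , drop = FALSE]
  }
  for (c in 1:3) img[, , c] <- (img[, , c] - mean[c]) / std[c]
  img
}
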