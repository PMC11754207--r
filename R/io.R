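# File formats and run configuration.
#
# Coordinate convention used across the package: matrices are indexed
# (row, col) = (v-down, u-right) with the origin at the top-left; PNG
# files are written so that a round-trip through disk is bit-exact for
# class-id grids (8-bit, ignore = 255), binary masks (8-bit 0/255) and
# segment ids (16-bit).

#' Read an RGB image / label mask pair
#'
#' Loads a PNG image and its single-channel class-id label, validating
#' that the shapes agree and every label value is a known class id or
#' the ignore value.  Errors name the offending file.
#'
#' @param image_path Path to the RGB (or RGBA; alpha dropped) PNG.
#' @param label_path Path to the single-channel 8-bit label PNG.
#' @param n_classes Number of classes (valid ids `0..n_classes-1`).
#' @param ignore_value Reserved ignore label (default 255).
#' @return List with `image` (`U x V x 3` array, values `[0, 255]`) and
#'   `label` (integer matrix).
#' @export
read_image_pair <- function(image_path, label_path, n_classes,
                            ignore_value = 255L) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  if (!file.exists(label_path)) stop("label file not found: ", label_path)
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L)
    stop("expected an RGB image, got single-channel: ", image_path)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L)
    stop("expected 3 channels in image: ", image_path)
  img <- img * 255

  lab <- png::readPNG(label_path)
  if (length(dim(lab)) != 2L)
    stop("label must be single-channel, got multi-channel: ", label_path)
  lab <- matrix(as.integer(round(lab * 255)), nrow(lab), ncol(lab))
  if (!identical(dim(lab), dim(img)[1:2]))
    stop(sprintf("shape mismatch between %s (%dx%d) and %s (%dx%d)",
                 image_path, dim(img)[1], dim(img)[2],
                 label_path, nrow(lab), ncol(lab)))
  known <- c(0:(n_classes - 1L), ignore_value)
  bad <- setdiff(unique(as.vector(lab)), known)
  if (length(bad))
    stop(sprintf("unknown class id(s) %s in label file %s",
                 paste(bad, collapse = ", "), label_path))
  if (all(lab == ignore_value))
    warning("label file contains only the ignore value: ", label_path)
  list(image = img, label = lab)
}

#' Write a class-id grid as an 8-bit PNG
#'
#' @param label Integer matrix with values in `0..255`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_label_png <- function(label, path) {
  if (any(label < 0) || any(label > 255))
    stop("label values must fit 8 bits (0..255)")
  png::writePNG(label / 255, path)
  invisible(path)
}

#' Read a class-id grid written by [write_label_png]
#'
#' @param path PNG path.
#' @return Integer matrix.
#' @export
read_label_png <- function(path) {
  lab <- png::readPNG(path)
  if (length(dim(lab)) != 2L)
    stop("label must be single-channel: ", path)
  matrix(as.integer(round(lab * 255)), nrow(lab), ncol(lab))
}

#' Write a binary mask as a black/white PNG
#'
#' Foreground pixels are written as 255, background as 0 (single
#' channel), the usual query-mask visualization.
#'
#' @param mask Logical matrix or [foreground_mask].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "foreground_mask")) mask <- mask$mask
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path.
#' @return Logical matrix (`TRUE` where the pixel is > 127).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) != 2L) stop("mask must be single-channel: ", path)
  m > 0.5
}

#' Write a superpixel map as a 16-bit grayscale TIFF
#'
#' Segment ids (1..m) are stored in a single 16-bit channel for
#' inspection and exact round-tripping.
#'
#' @param spmap A [superpixel_map].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_segments_tiff <- function(spmap, path) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (spmap$m > 65535L) stop("more than 65535 segments")
  tiff::writeTIFF(spmap$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a superpixel map written by [write_segments_tiff]
#'
#' @param path TIFF path.
#' @return A [superpixel_map].
#' @export
read_segments_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) != 2L) stop("segment map must be single-channel: ", path)
  superpixel_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

# keys accepted in a YAML run configuration
RUN_CONFIG_KEYS <- c("image_dir", "label_dir", "output_dir", "n_classes",
                     "init_count", "b", "steps", "T", "n_segments", "mode",
                     "q_fraction", "foreground_mode", "background_class",
                     "ignore_value", "compactness", "bald_mode", "seed")

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (they usually indicate a typo in a tunable
#' name) and all directory paths are checked before a run starts.
#'
#' @param path YAML file with [al_config] fields plus `image_dir`,
#'   `label_dir`, `output_dir`, `n_classes`.
#' @return List with `cfg` (an [al_config]) and `paths`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in c("image_dir", "label_dir")) {
    if (is.null(raw[[key]])) stop("missing required key: ", key)
    if (!dir.exists(raw[[key]]))
      stop(sprintf("%s does not exist: %s", key, raw[[key]]))
  }
  if (is.null(raw$n_classes)) stop("missing required key: n_classes")
  cfg_args <- raw[intersect(names(raw), names(formals(al_config)))]
  list(cfg = do.call(al_config, cfg_args),
       paths = list(image_dir = raw$image_dir, label_dir = raw$label_dir,
                    output_dir = raw$output_dir),
       n_classes = as.integer(raw$n_classes))
}

read_manifest <- function(path) {
  if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    list(steps = list())
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write one step's query masks and partial labels, updating the manifest
#'
#' Writes, per selected image, the query mask (black/white PNG) and the
#' partial label (8-bit PNG, ignore = 255) under `out_dir`, and inserts
#' or replaces the step's entry in `manifest.json` atomically, so
#' re-running a completed step is idempotent.
#'
#' @param step_record List with at least `step`, `selected`, `queried`,
#'   `totals` (as produced by [al_step] in `state$record`).
#' @param masks Named list of logical query masks (names = image ids).
#' @param labels Named list of partial-label matrices (same names).
#' @param out_dir Output directory (created if missing).
#' @return The manifest entry for the step, invisibly.
#' @export
write_outputs <- function(step_record, masks, labels, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- step_record$step
  files <- character(0)
  for (nm in names(masks)) {
    mp <- file.path(out_dir, sprintf("step%03d_%s_mask.png", step, nm))
    lp <- file.path(out_dir, sprintf("step%03d_%s_label.png", step, nm))
    write_mask_png(masks[[nm]], mp)
    write_label_png(labels[[nm]], lp)
    files <- c(files, mp, lp)
  }
  entry <- list(step = step,
                selected = as.list(step_record$selected),
                queried = as.list(step_record$queried),
                totals = as.list(step_record$totals),
                files = as.list(basename(files)))
  mpath <- file.path(out_dir, "manifest.json")
  man <- read_manifest(mpath)
  existing <- vapply(man$steps, function(s) identical(s$step, step),
                     logical(1))
  if (any(existing)) man$steps[[which(existing)[1]]] <- entry
  else man$steps[[length(man$steps) + 1L]] <- entry
  write_json_atomic(man, mpath)
  invisible(entry)
}

#' Write a machine-readable run manifest
#'
#' Serializes an [run_active_learning] result — configuration echo,
#' per-step records (labeled images, budget, mIoU) and the raw ledger
#' counts — as JSON.  The manifest alone suffices to re-plot the
#' mIoU-versus-labeled-images and average-percent-labeled-superpixels
#' curves of a run.
#'
#' @param run An `al_run` object.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(run, path) {
  stopifnot(inherits(run, "al_run"))
  cfg <- run$cfg
  cfg$q_fraction <- if (is.null(cfg$q_fraction)) NA else cfg$q_fraction
  write_json_atomic(
    list(config = unclass(cfg),
         records = run$records,
         ledger = list(labeled = run$ledger$labeled,
                       total = run$ledger$total,
                       images = run$ledger$images,
                       avg_labeled_fraction = labeled_fraction(run$ledger))),
    path)
}
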