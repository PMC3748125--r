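# File formats.  Label volumes and cue maps travel as HDF5 datasets
# (rhdf5; default dataset names "labels" and "probabilities",
# channels-last), 16-bit grayscale PNG (2D labels with ids <= 65535), or
# plain CSV matrices (2D).  Axis order is (z,)y,x; R indexing (1-based).

.io_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         h5 = , hdf5 = "h5",
         png = "png",
         csv = "csv",
         stop(sprintf("cannot infer format from extension '.%s'", ext),
              call. = FALSE))
}

.need <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop(sprintf("package '%s' is required for this format", pkg), call. = FALSE)
  }
}

#' Write / read a label volume
#'
#' @param x label volume (2D or 3D integer array).
#' @param path output file; the extension selects the format unless
#'   `format` is given (`"h5"`, `"png"`, `"csv"`).
#' @param format `"auto"` (default), `"h5"`, `"png"` (2D, ids <= 65535) or
#'   `"csv"` (2D).
#' @param dataset HDF5 dataset name (default `"labels"`).
#' @return `path`, invisibly (writer); a label volume (reader).
#' @export
write_labels <- function(x, path, format = "auto", dataset = "labels") {
  x <- validate_label_volume(x, require_nonzero = FALSE)
  fmt <- .io_format(path, format)
  if (fmt == "h5") {
    .need("rhdf5")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x, path, dataset)
    rhdf5::h5closeAll()
  } else if (fmt == "png") {
    .need("png")
    if (length(dim(x)) != 2L) stop("PNG labels are 2D-only", call. = FALSE)
    if (max(x) > 65535L) stop("PNG labels support ids up to 65535", call. = FALSE)
    # ids encoded exactly: high byte in R, low byte in G
    img <- array(0, dim = c(dim(x), 3L))
    img[, , 1L] <- (x %/% 256L) / 255
    img[, , 2L] <- (x %% 256L) / 255
    png::writePNG(img, path)
  } else if (fmt == "csv") {
    if (length(dim(x)) != 2L) stop("CSV labels are 2D-only", call. = FALSE)
    utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else stop(sprintf("unknown format '%s'", fmt), call. = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, format = "auto", dataset = "labels") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  fmt <- .io_format(path, format)
  x <- if (fmt == "h5") {
    .need("rhdf5")
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5read(path, dataset)
  } else if (fmt == "png") {
    .need("png")
    img <- png::readPNG(path)
    round(img[, , 1L] * 255) * 256 + round(img[, , 2L] * 255)
  } else if (fmt == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else stop(sprintf("unknown format '%s'", fmt), call. = FALSE)
  dimnames(x) <- NULL
  validate_label_volume(array(as.integer(round(x)), dim = dim(x)),
                        require_nonzero = FALSE)
}

#' Write / read cue maps
#'
#' Cues are stored as float32 with channels last: an HDF5 dataset of shape
#' `c(shape, n_channels)` (default name `"probabilities"`), or one CSV per
#' channel (`<stem>_ch<k>.csv`, 2D only).
#'
#' @param cues list of numeric arrays in `[0, 1]` of identical shape.
#' @param path file path (HDF5) or stem (CSV).
#' @inheritParams write_labels
#' @return `path` invisibly (writer); list of numeric arrays (reader).
#' @export
write_cues <- function(cues, path, format = "auto", dataset = "probabilities") {
  stopifnot(is.list(cues), length(cues) > 0L)
  d <- dim(cues[[1L]])
  fmt <- if (format == "auto" && !grepl("\\.", basename(path))) "csv"
         else .io_format(path, format)
  if (fmt == "h5") {
    .need("rhdf5")
    if (file.exists(path)) unlink(path)
    arr <- array(unlist(cues), dim = c(d, length(cues)))
    rhdf5::h5createFile(path)
    rhdf5::h5createDataset(path, dataset, dims = dim(arr), H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(arr, path, dataset)
    rhdf5::h5closeAll()
  } else if (fmt == "csv") {
    if (length(d) != 2L) stop("CSV cues are 2D-only", call. = FALSE)
    stem <- sub("\\.csv$", "", path)
    for (k in seq_along(cues)) {
      utils::write.table(signif(cues[[k]], 8L), sprintf("%s_ch%d.csv", stem, k),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  } else stop(sprintf("unsupported cue format '%s'", fmt), call. = FALSE)
  invisible(path)
}

#' @rdname write_cues
#' @export
read_cues <- function(path, format = "auto", dataset = "probabilities") {
  fmt <- if (format == "auto" && !grepl("\\.", basename(path))) "csv"
         else .io_format(path, format)
  if (fmt == "h5") {
    .need("rhdf5")
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    arr <- rhdf5::h5read(path, dataset)
    d <- dim(arr)
    nd <- length(d)
    lapply(seq_len(d[nd]), function(k) {
      idx <- c(rep(list(quote(expr = )), nd - 1L), list(k))
      array(do.call(`[`, c(list(arr), idx)), dim = d[-nd])
    })
  } else if (fmt == "csv") {
    stem <- sub("\\.csv$", "", path)
    files <- Sys.glob(sprintf("%s_ch*.csv", stem))
    if (length(files) == 0L) stop(sprintf("no cue files match %s_ch*.csv", stem),
                                  call. = FALSE)
    ord <- order(as.integer(sub(".*_ch(\\d+)\\.csv$", "\\1", files)))
    lapply(files[ord], function(f) {
      as.matrix(utils::read.table(f, sep = ",", header = FALSE)) |>
        unname() |> as.matrix()
    })
  } else stop(sprintf("unsupported cue format '%s'", fmt), call. = FALSE)
}

# ---- run configuration ----------------------------------------------------

.config_keys <- c("superpixels", "cues", "gold", "candidate", "output_dir",
                  "epochs", "thresholds", "threshold", "seed", "label_source",
                  "boundary_mode", "init_policy", "model", "log_level",
                  "features", "classifier", "dataset_labels", "dataset_cues",
                  "phantom")
.feature_keys <- c("bins", "n_quantiles", "use_moments", "use_jsd",
                   "use_midlevel_2d", "channels")
.classifier_keys <- c("type", "n_bags", "sample_fraction", "lambda", "alpha")
.phantom_keys <- c("shape", "n_segments", "geometry", "blur_sigma", "noise_sd",
                   "superpixel_spacing", "n_texture_cues", "seed")

#' Read a run configuration
#'
#' One YAML file drives the command-line pipeline.  Unknown keys are errors
#' (typo protection); the effective configuration of a run is always
#' written next to its outputs.
#'
#' @param path YAML file.
#' @return a named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check(names(cfg), .config_keys, "config")
  if (!is.null(cfg$features)) check(names(cfg$features), .feature_keys, "[features]")
  if (!is.null(cfg$classifier)) check(names(cfg$classifier), .classifier_keys, "[classifier]")
  if (!is.null(cfg$phantom)) check(names(cfg$phantom), .phantom_keys, "[phantom]")
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a `"run_config"`.
#' @export
config_feature_config <- function(cfg) {
  do.call(feature_config, cfg$features %||% list())
}

#' @rdname read_run_config
#' @export
config_classifier_spec <- function(cfg) {
  do.call(classifier_spec, cfg$classifier %||% list())
}

#' @rdname read_run_config
#' @export
config_phantom_spec <- function(cfg) {
  p <- cfg$phantom %||% list()
  if (!is.null(p$shape)) p$shape <- as.integer(unlist(p$shape))
  do.call(phantom_spec, p)
}
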