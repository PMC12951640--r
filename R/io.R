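# NIfTI input/output and run configuration. Volumes are expected to be
# co-registered and skull-stripped on a common grid; on load each image is
# reoriented to the canonical axis convention (X sagittal-, Y coronal-,
# Z axial-normal, i.e. RAS) when its header carries an orientation.

.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  # images written without a qform/sform (e.g. bare arrays) cannot be
  # reoriented; they are taken to already follow the canonical convention
  suppressWarnings(tryCatch(RNifti::orientation(img) <- "RAS",
                            error = function(e) NULL))
  a <- as.array(img)
  if (length(dim(a)) > 3L) dim(a) <- dim(a)[1:3]
  attr(a, "pixdim") <- tryCatch(RNifti::pixdim(img)[1:3],
                                error = function(e) c(1, 1, 1))
  a
}

#' Read a multicontrast volume from NIfTI files
#'
#' Missing contrasts are specified by omission (or `NA` paths); they are
#' zero-filled with their presence flag cleared. All present contrasts must
#' share one grid.
#'
#' @param paths named character vector or list; names among
#'   `r paste(contrast_names(), collapse = ", ")`.
#' @return an [mc_volume()].
#' @export
read_mc_volume <- function(paths) {
  cn <- contrast_names()
  if (is.null(names(paths)) || !all(names(paths) %in% cn))
    stop("paths must be named with contrast names: ", paste(cn, collapse = ", "))
  arrays <- list(); spacing <- NULL; shape <- NULL
  for (nm in cn) {
    p <- paths[[nm]]
    if (is.null(p) || is.na(p)) { arrays[[nm]] <- NULL; next }
    if (!file.exists(p)) stop("missing file: ", p)
    a <- .read_nifti_array(p)
    if (is.null(shape)) {
      shape <- dim(a); spacing <- attr(a, "pixdim")
    } else if (!identical(dim(a), shape)) {
      stop("inconsistent grids across contrasts: ", nm)
    }
    arrays[[nm]] <- a
  }
  if (is.null(shape)) stop("at least one contrast path is required")
  data <- array(0, dim = c(shape, 4L))
  present <- rep(FALSE, 4L)
  for (ci in seq_along(cn)) {
    if (!is.null(arrays[[cn[ci]]])) {
      data[, , , ci] <- arrays[[cn[ci]]]
      present[ci] <- any(arrays[[cn[ci]]] != 0)
    }
  }
  mc_volume(data, present = present, spacing = as.numeric(spacing))
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file.
#' @return integer 3D array with values in {0, 1}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  a <- .read_nifti_array(path)
  if (!all(a %in% c(0, 1)))
    stop("mask is not binary: ", path)
  array(as.integer(a), dim = dim(a))
}

#' Write a 3D array to NIfTI
#'
#' Masks and confidence maps are written with an integer datatype so that
#' the confidence map's integrality survives serialization.
#'
#' @param a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(a, path, spacing = c(1, 1, 1)) {
  datatype <- if (is.integer(a) || all(a == round(a))) "int16" else "float"
  img <- RNifti::asNifti(a * 1, internal = FALSE)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a phantom subject to a directory
#'
#' Writes the four contrasts, the truth and the two rater masks as NIfTI,
#' plus a JSON manifest with the generating configuration.
#'
#' @param subject a [generate_phantom()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cn <- contrast_names()
  for (ci in 1:4)
    write_nifti(subject$vol$data[, , , ci],
                file.path(dir, paste0(cn[ci], ".nii.gz")))
  write_nifti(subject$truth, file.path(dir, "truth.nii.gz"))
  write_nifti(subject$rater1, file.path(dir, "rater1.nii.gz"))
  write_nifti(subject$rater2, file.path(dir, "rater2.nii.gz"))
  cfg <- subject$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom cohort directory
#'
#' Reads subject subdirectories written by [write_phantom()] (contrasts +
#' truth + rater masks) back into the in-memory cohort layout used by
#' [train_backbone()].
#'
#' @param dir cohort directory containing one subdirectory per subject.
#' @param val_fraction held-out fraction (last subjects).
#' @return a cohort list with `subjects`, `train`, `val`.
#' @export
read_phantom_dir <- function(dir, val_fraction = 0.2) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subdirs) == 0L) stop("no subject directories under ", dir)
  cn <- contrast_names()
  subjects <- lapply(subdirs, function(sd) {
    paths <- file.path(sd, paste0(cn, ".nii.gz"))
    names(paths) <- cn
    paths <- paths[file.exists(paths)]
    list(vol = read_mc_volume(as.list(paths)),
         truth = read_mask(file.path(sd, "truth.nii.gz")),
         rater1 = read_mask(file.path(sd, "rater1.nii.gz")),
         rater2 = read_mask(file.path(sd, "rater2.nii.gz")))
  })
  n <- length(subjects)
  n_val <- min(n - 1L, max(0L, round(val_fraction * n)))
  val <- if (n_val >= 1L) seq.int(n - n_val + 1L, n) else integer(0)
  list(subjects = subjects, train = setdiff(seq_len(n), val), val = val)
}

#' Run configuration
#'
#' Bundles the backbone, training and fusion settings with a master seed;
#' round-trips through YAML.
#'
#' @param backbone a [backbone_config()].
#' @param train a [train_config()].
#' @param fusion a [fusion_params()] (defaults tau1 = 16, tau2 = 7).
#' @param connectivity lesion-metric connectivity.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(backbone = backbone_config(preset = "tiny"),
                       train = train_config(preset = "tiny"),
                       fusion = fusion_params(), connectivity = 26L,
                       seed = 1L) {
  structure(list(backbone = backbone, train = train, fusion = fusion,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(backbone, path) {
  cfg <- backbone  # a run_config
  stopifnot(inherits(cfg, "run_config"))
  plain <- rapply(unclass(cfg), function(x) x, how = "list")
  plain <- lapply(plain, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bk <- do.call(backbone_config,
                y$backbone[c("levels", "channels", "norm_mode", "in_channels",
                             "eps", "momentum")])
  tr <- do.call(train_config,
                y$train[c("lr", "batch_size", "epochs", "iters_per_epoch",
                          "elastic_affine_prob", "warp_sd", "seed")])
  fu <- fusion_params(y$fusion$tau1, y$fusion$tau2)
  run_config(bk, tr, fu, connectivity = y$connectivity %||% 26L,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, package version and MD5 hashes of the
#' input files, sufficient to reproduce a run.
#'
#' @param path output JSON path.
#' @param config any configuration list.
#' @param seed the seed used.
#' @param inputs character vector of input file paths (hashed).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(config = rapply(unclass(config), identity, how = "list"),
         seed = seed,
         package_version = as.character(utils::packageVersion("mstta")),
         input_md5 = hashes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
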