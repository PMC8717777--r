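# Dataset I/O: NIfTI volumes, PNG masks and JSON manifests.
#
# Storage conventions (documented contract):
#   * one NIfTI file per case with modality channels on the 4th axis,
#     i.e. an (H, W, 1, C) volume; masks are 2D uint8 NIfTI or 8-bit PNG;
#   * in memory images are (channel, row, column) arrays, 0/1 matrices for
#     masks, row-major (row, column) indexing;
#   * `manifest.json` records case_id, relative image/mask paths, role,
#     spacing and the generating seed; relative paths resolve against the
#     manifest's directory.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Write an image or mask volume to NIfTI (or a mask to PNG)
#'
#' A C x H x W array is stored as an (H, W, 1, C) NIfTI volume with channels
#' on the 4th axis; an H x W matrix is stored as a 2D volume (uint8 NIfTI for
#' binary masks, or 8-bit grey PNG when the extension is `.png`). The
#' isotropic spacing is written into the NIfTI header. Overwriting an
#' existing file succeeds with a warning.
#'
#' @param values C x H x W numeric array or H x W matrix.
#' @param spacing_mm isotropic pixel spacing in millimetres.
#' @param path destination; `.nii`, `.nii.gz` or (masks only) `.png`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, spacing_mm, path) {
  stopifnot(all(is.finite(values)), spacing_mm > 0)
  if (!dir.exists(dirname(path))) {
    stop("cannot write '", path, "': directory does not exist")
  }
  if (file.exists(path)) {
    warning("overwriting existing file: ", path, call. = FALSE)
  }
  if (grepl("\\.png$", path)) {
    if (!is.matrix(values)) stop("PNG output is supported for 2D masks only")
    png::writePNG(values, path)
    return(invisible(path))
  }
  if (!is_nifti_path(path)) stop("unsupported extension for: ", path)
  if (is.matrix(values)) {
    arr <- values
    attr(arr, "pixdim") <- rep(spacing_mm, 2)
    datatype <- if (all(values %in% c(0, 1))) "uint8" else "float"
  } else if (length(dim(values)) == 3) {
    C <- dim(values)[1]
    arr <- aperm(values, c(2, 3, 1))           # (H, W, C)
    dim(arr) <- c(dim(arr)[1], dim(arr)[2], 1, C)
    attr(arr, "pixdim") <- c(spacing_mm, spacing_mm, spacing_mm, 1)
    datatype <- "float"
  } else {
    stop("values must be a C x H x W array or an H x W matrix")
  }
  RNifti::writeNifti(arr, path, datatype = datatype)
  invisible(path)
}

#' Read a multi-modal slice from NIfTI or PNG
#'
#' NIfTI volumes written by [write_volume()] — (H, W, 1, C) with channels on
#' the 4th axis — come back as C x H x W arrays; plain 2D/3D volumes are also
#' accepted. Spacing is taken from the NIfTI header; PNG files carry no
#' spacing, so `spacing_mm` (default 1) is used.
#'
#' @param path a readable `.nii`, `.nii.gz` or `.png` file.
#' @param spacing_mm fallback spacing for formats without a header (PNG).
#' @param case_id optional id attached to the returned slice.
#' @return A `multimodal_slice`.
#' @export
read_volume <- function(path, spacing_mm = 1, case_id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (grepl("\\.png$", path)) {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3) v <- aperm(v, c(3, 1, 2)) else dim(v) <- c(1, dim(v))
    return(new_multimodal_slice(v, spacing_mm,
                                case_id %||% sub("\\.png$", "", basename(path))))
  }
  if (!is_nifti_path(path)) stop("unsupported extension for: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  d <- dim(img)
  arr <- as.array(img)
  values <- if (length(d) == 4) {
    aperm(array(arr[, , 1, ], c(d[1], d[2], d[4])), c(3, 1, 2))
  } else if (length(d) == 3) {
    aperm(arr, c(3, 1, 2))
  } else {
    array(arr, c(1, d))
  }
  new_multimodal_slice(values, sp,
                       case_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Read a binary label mask, validating its domain
#'
#' @param path `.nii`, `.nii.gz` or `.png` mask file.
#' @return H x W 0/1 matrix with the header spacing as attribute
#'   `spacing_mm` (PNG: 1).
#' @export
read_mask <- function(path) {
  slice <- read_volume(path)
  v <- slice$values
  if (dim(v)[1] != 1) stop("mask file '", path, "' has multiple channels")
  m <- matrix(v[1, , ], dim(v)[2], dim(v)[3])
  if (!all(m %in% c(0, 1))) {
    bad <- unique(m[!(m %in% c(0, 1))])
    stop("mask file '", path, "' is not binary; found value(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(m, spacing_mm = slice$spacing_mm)
}

#' Write a phantom dataset to disk (NIfTI volumes + manifest.json)
#'
#' @param records list of `sample_record`s (see [generate_dataset()]).
#' @param dir output directory, created if needed.
#' @param config optional `phantom_config` echoed into the manifest.
#' @return Path to the written `manifest.json`.
#' @export
write_dataset <- function(records, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(records, function(r) {
    img_rel <- paste0(r$case_id, "_img.nii.gz")
    write_volume(r$image$values, r$spacing_mm, file.path(dir, img_rel))
    mask_rel <- NA_character_
    if (!is.null(r$mask)) {
      mask_rel <- paste0(r$case_id, "_mask.nii.gz")
      write_volume(r$mask, r$spacing_mm, file.path(dir, mask_rel))
    }
    list(case_id = r$case_id, image = img_rel, mask = mask_rel,
         role = r$role, spacing_mm = r$spacing_mm)
  })
  write_manifest(entries, file.path(dir, "manifest.json"), config = config)
}

#' Write a dataset manifest as JSON
#'
#' @param entries list of per-case entries (`case_id`, `image`, `mask`,
#'   `role`, `spacing_mm`); paths may be relative to the manifest directory
#'   or absolute.
#' @param path output `manifest.json` path.
#' @param config optional configuration echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path, config = NULL) {
  ids <- vapply(entries, function(e) e$case_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate case_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  payload <- list(records = entries)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a dataset manifest
#'
#' Relative paths are resolved against the manifest's directory; absolute
#' paths pass through untouched. Duplicate case ids or missing referenced
#' files are errors.
#'
#' @param path `manifest.json` path.
#' @param check_files verify that every referenced file exists.
#' @return List with `records` (entries with resolved paths) and `config`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NA_character_)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  records <- lapply(payload$records, function(e) {
    e$image <- resolve(e$image)
    e$mask <- resolve(e$mask %||% NA_character_)
    e$role <- e$role %||% NA_character_
    e
  })
  ids <- vapply(records, function(e) e$case_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate case_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (check_files) {
    paths <- unlist(lapply(records, function(e) c(e$image, e$mask)))
    paths <- paths[!is.na(paths)]
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("manifest references missing file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  list(records = records, config = payload$config)
}

#' Load a dataset written by [write_dataset()] back into sample records
#'
#' @param manifest_path path to `manifest.json`.
#' @return List of `sample_record`s.
#' @export
read_dataset <- function(manifest_path) {
  mf <- read_manifest(manifest_path)
  lapply(mf$records, function(e) {
    img <- read_volume(e$image, case_id = e$case_id)
    mask <- if (!is.na(e$mask)) unclass(read_mask(e$mask)) else NULL
    if (!is.null(mask)) attr(mask, "spacing_mm") <- NULL
    structure(list(case_id = e$case_id, image = img, mask = mask,
                   role = e$role, spacing_mm = img$spacing_mm),
              class = "sample_record")
  })
}
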