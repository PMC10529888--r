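default_label_map <- c(background = 0L, remnant = 1L, resected = 2L,
                       lesion = 3L, vessel = 4L)

#' Construct a segmentation label mask
#'
#' @param labels 3-D integer array of voxel labels.
#' @param spacing Voxel spacing in mm per axis (3 positive values).
#' @param label_map Named integer vector mapping roles to label values;
#'   defaults to background 0, remnant 1, resected 2, lesion 3, vessel 4.
#' @return A `liver_mask`: the label array with `spacing` and
#'   `label_map` attributes.
#' @export
liver_mask <- function(labels, spacing, label_map = default_label_map) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort("`labels` must be a 3-D array.")
  }
  check_number(spacing, "spacing", min = .Machine$double.eps, allow_vector = TRUE)
  if (length(spacing) != 3) abort("`spacing` must have 3 values.")
  if (is.null(names(label_map)) || any(names(label_map) == "")) {
    abort("`label_map` must be fully named.")
  }
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), as.integer(label_map))
  if (length(bad) > 0) {
    abort(paste0("Labels not declared in `label_map`: ",
                 paste(bad, collapse = ", "), "."))
  }
  structure(labels, spacing = as.double(spacing),
            label_map = setNames(as.integer(label_map), names(label_map)),
            class = "liver_mask")
}

#' Volume of selected roles in a segmentation mask
#'
#' Counts voxels whose label belongs to the requested roles and converts
#' to mL via the voxel volume. Lesion and vessel voxels are separate
#' roles and are therefore never counted toward functional liver volume
#' unless explicitly requested.
#'
#' @param mask A [liver_mask()].
#' @param roles Character vector of roles from the mask's `label_map`.
#' @return Volume in mL.
#' @examples
#' m <- generate_phantom_mask(c(24, 24, 24), c(5, 5, 5), 500, 100)
#' mask_volume(m, c("remnant", "resected"))
#' @export
mask_volume <- function(mask, roles = c("remnant", "resected")) {
  if (!inherits(mask, "liver_mask")) abort("`mask` must be a liver_mask.")
  label_map <- attr(mask, "label_map")
  unknown <- setdiff(roles, names(label_map))
  if (length(unknown) > 0) {
    abort(paste0("Unknown roles: ", paste(unknown, collapse = ", "),
                 ". Declared roles: ", paste(names(label_map), collapse = ", "), "."))
  }
  wanted <- label_map[roles]
  count <- sum(unclass(mask) %in% wanted)
  count * prod(attr(mask, "spacing")) / 1000
}

#' Liver, resection and remnant volumes of a mask
#'
#' Functional liver volume is the remnant plus resected labels (lesions
#' and vessels excluded); the remnant volume is their difference:
#' `rLV = LV - resection volume`.
#'
#' @param mask A [liver_mask()].
#' @return One-row tibble with `lv_ml`, `resected_ml`, `rlv_ml`.
#' @export
volume_set <- function(mask) {
  lv <- mask_volume(mask, c("remnant", "resected"))
  resected <- mask_volume(mask, "resected")
  tibble::tibble(lv_ml = lv, resected_ml = resected, rlv_ml = lv - resected)
}

#' Read / write segmentation masks as NIfTI
#'
#' Label volumes are stored as integer NIfTI with the voxel spacing in
#' the header `pixdim`.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param label_map Role-to-label mapping, defaulting to the package
#'   convention (see [liver_mask()]).
#' @return `read_mask_nifti()` returns a [liver_mask()];
#'   `write_mask_nifti()` returns `path` invisibly.
#' @export
read_mask_nifti <- function(path, label_map = default_label_map) {
  img <- RNifti::readNifti(path)
  liver_mask(array(as.integer(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3],
             label_map = label_map)
}

#' @rdname read_mask_nifti
#' @param mask A [liver_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  if (!inherits(mask, "liver_mask")) abort("`mask` must be a liver_mask.")
  img <- RNifti::asNifti(unclass(mask))
  RNifti::pixdim(img) <- attr(mask, "spacing")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
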