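# Readers/writers and preprocessing: NIfTI case volumes, PNG slice export,
# CSV manifests, slice extraction and intensity normalization.

#' Construct a multi-modal case volume
#'
#' @param t2w,dwi,adc 3-D arrays (slices x H x W) sharing one shape.
#' @param mask Optional binary 3-D array of the same shape.
#' @param spacing Optional voxel spacing.
#' @param case_id Identifier.
#' @return An object of class `case_volume`.
#' @export
case_volume <- function(t2w, dwi, adc, mask = NULL, spacing = NULL,
                        case_id = "case") {
  stopifnot(length(dim(t2w)) == 3L, identical(dim(t2w), dim(dwi)),
            identical(dim(t2w), dim(adc)))
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(t2w)))
  structure(list(t2w = t2w, dwi = dwi, adc = adc, mask = mask,
                 spacing = spacing, case_id = case_id),
            class = "case_volume")
}

#' Read a multi-modal NIfTI case
#'
#' Loads the three modality volumes (and optional mask), verifying that
#' all files share dimensions and affine (within `tol`); mismatches are
#' rejected with an error naming the offending file.
#'
#' @param paths Named list/vector with `t2w`, `dwi`, `adc` and optionally
#'   `mask` NIfTI file paths.
#' @param case_id Identifier (defaults to the t2w file name).
#' @param tol Affine comparison tolerance.
#' @return A [case_volume()] (axial slice index first).
#' @export
read_case <- function(paths, case_id = NULL, tol = 1e-4) {
  need <- c("t2w", "dwi", "adc")
  if (!all(need %in% names(paths))) {
    stop("missing modality path(s): ",
         paste(setdiff(need, names(paths)), collapse = ", "), call. = FALSE)
  }
  imgs <- lapply(paths[intersect(c(need, "mask"), names(paths))],
                 RNifti::readNifti)
  ref <- imgs$t2w
  for (nm in names(imgs)) {
    if (!identical(dim(imgs[[nm]]), dim(ref))) {
      stop("geometry mismatch: dimensions of '", paths[[nm]],
           "' differ from '", paths$t2w, "'", call. = FALSE)
    }
    if (max(abs(RNifti::xform(imgs[[nm]]) - RNifti::xform(ref))) > tol) {
      stop("geometry mismatch: affine of '", paths[[nm]],
           "' differs from '", paths$t2w, "'", call. = FALSE)
    }
  }
  to_sfirst <- function(a) aperm(array(a, dim(a)), c(3, 1, 2))
  case_volume(
    t2w = to_sfirst(imgs$t2w), dwi = to_sfirst(imgs$dwi),
    adc = to_sfirst(imgs$adc),
    mask = if (!is.null(imgs$mask)) to_sfirst(imgs$mask) else NULL,
    spacing = RNifti::pixdim(ref),
    case_id = case_id %||% sub("\\.nii(\\.gz)?$", "",
                               basename(paths[["t2w"]]))
  )
}

#' Write a case volume to NIfTI files
#'
#' @param vol A [case_volume()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_case <- function(vol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  to_hwS <- function(a) aperm(a, c(2, 3, 1))
  out <- c()
  for (nm in c("t2w", "dwi", "adc", "mask")) {
    if (is.null(vol[[nm]])) next
    path <- file.path(dir, paste0(vol$case_id, "_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(to_hwS(vol[[nm]])), path)
    out[nm] <- path
  }
  invisible(out)
}

#' Split a case volume into per-slice modality triples
#'
#' One [modality_triple()] per axial index, order preserved.
#'
#' @param vol A [case_volume()].
#' @return A list of [modality_triple()].
#' @export
split_to_slices <- function(vol) {
  stopifnot(inherits(vol, "case_volume"))
  lapply(seq_len(dim(vol$t2w)[1]), function(k) {
    modality_triple(vol$t2w[k, , ], vol$dwi[k, , ], vol$adc[k, , ],
                    mask = if (!is.null(vol$mask))
                      as_binary_mask(vol$mask[k, , ]) else NULL,
                    spacing = vol$spacing[2:3],
                    case_id = vol$case_id, slice_index = k)
  })
}

# Percentile normalization of one modality image to [0, 1].
normalize_percentile <- function(x, lower = 0.005, upper = 0.995) {
  q <- stats::quantile(x, c(lower, upper), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant-intensity slice normalized to zeros")
    return(matrix(0, nrow(x), ncol(x)))
  }
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Preprocess a slice triple for the model
#'
#' Normalizes each modality per slice to `[0, 1]` by 0.5-99.5 percentile
#' clipping (robust to MRI intensity outliers), then resizes images with
#' bilinear interpolation and the mask with nearest-neighbour (so it stays
#' binary) to the model's input size.
#'
#' @param triple A [modality_triple()].
#' @param target_size Output side in pixels (e.g. `config$input_size`).
#' @return A resized, normalized [modality_triple()].
#' @export
preprocess <- function(triple, target_size) {
  stopifnot(target_size > 0)
  rs <- function(x, filt) {
    if (nrow(x) == target_size && ncol(x) == target_size) return(x)
    matrix(EBImage::resize(x, w = target_size, h = target_size,
                           filter = filt), target_size, target_size)
  }
  modality_triple(
    rs(normalize_percentile(triple$t2w), "bilinear"),
    rs(normalize_percentile(triple$dwi), "bilinear"),
    rs(normalize_percentile(triple$adc), "bilinear"),
    mask = if (is.null(triple$mask)) NULL else
      as_binary_mask(rs(triple$mask, "none")),
    spacing = triple$spacing, case_id = triple$case_id,
    slice_index = triple$slice_index
  )
}

#' Write a phantom dataset as PNG slices with a CSV manifest
#'
#' Each slice is written as three 8-bit grayscale PNGs plus a mask PNG;
#' `manifest.csv` records case, slice, split and file paths.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_phantom_png <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map2(dataset$slices, seq_along(dataset$slices),
                      function(tr, i) {
    stem <- sprintf("%s_s%03d", tr$case_id, tr$slice_index)
    paths <- c(t2w = file.path(dir, paste0(stem, "_t2w.png")),
               dwi = file.path(dir, paste0(stem, "_dwi.png")),
               adc = file.path(dir, paste0(stem, "_adc.png")),
               mask = file.path(dir, paste0(stem, "_mask.png")))
    png::writePNG(tr$t2w, paths["t2w"])
    png::writePNG(tr$dwi, paths["dwi"])
    png::writePNG(tr$adc, paths["adc"])
    png::writePNG(tr$mask + 0, paths["mask"])
    tibble::tibble(case_id = tr$case_id, slice_index = tr$slice_index,
                   split = dataset$manifest$split[i],
                   t2w = paths["t2w"], dwi = paths["dwi"],
                   adc = paths["adc"], mask = paths["mask"])
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one phantom slice triple back from PNG files
#'
#' @param row One row of the manifest written by [write_phantom_png()].
#' @return A [modality_triple()].
#' @export
read_phantom_png <- function(row) {
  modality_triple(png::readPNG(row$t2w), png::readPNG(row$dwi),
                  png::readPNG(row$adc),
                  mask = as_binary_mask(round(png::readPNG(row$mask))),
                  case_id = row$case_id, slice_index = row$slice_index)
}
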