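#' Specification of a synthetic multi-modal MRI phantom slice
#'
#' Describes the geometry and intensity model of the synthetic phantom used
#' throughout the package: a bright prostate gland on a dark background, with
#' elliptical lesions that are strongly hypointense on ADC, hyperintense on
#' DWI and subtly hypointense on T2W -- the contrast semantics of clinical
#' prostate MRI, where low ADC reflects the high cellular density of tumours.
#'
#' @param image_size Pixels per side of the square slice.
#' @param gland_radius_frac Gland radius as a fraction of `image_size`.
#' @param n_lesions Number of lesions per slice (>= 0).
#' @param lesion_radius_range Min/max lesion semi-major axis in pixels.
#' @param axis_ratio_range Min/max minor/major axis ratio of lesion ellipses.
#' @param contrast Named list of lesion-vs-gland intensity offsets per
#'   modality (`t2w` subtle negative, `dwi` positive, `adc` strong negative).
#' @param gland_mean Gland intensity in normalized units.
#' @param background Background intensity in normalized units.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         gland_radius_frac = 0.38,
                         n_lesions = 1L,
                         lesion_radius_range = c(6, 14),
                         axis_ratio_range = c(0.6, 1.0),
                         contrast = list(t2w = -0.10, dwi = 0.30, adc = -0.35),
                         gland_mean = 0.55,
                         background = 0.15,
                         noise_sigma = 0.05,
                         seed = 1L) {
  stopifnot(
    image_size >= 16, gland_radius_frac > 0, gland_radius_frac < 0.5,
    n_lesions >= 0, length(lesion_radius_range) == 2L,
    all(lesion_radius_range > 0),
    lesion_radius_range[1] <= lesion_radius_range[2],
    max(lesion_radius_range) < gland_radius_frac * image_size,
    length(axis_ratio_range) == 2L, all(axis_ratio_range > 0),
    all(axis_ratio_range <= 1), noise_sigma >= 0,
    all(c("t2w", "dwi", "adc") %in% names(contrast)),
    contrast$adc < 0, contrast$dwi > 0, contrast$t2w < 0
  )
  structure(
    list(image_size = as.integer(image_size),
         gland_radius_frac = gland_radius_frac,
         n_lesions = as.integer(n_lesions),
         lesion_radius_range = lesion_radius_range,
         axis_ratio_range = axis_ratio_range,
         contrast = contrast,
         gland_mean = gland_mean,
         background = background,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Construct an aligned multi-modality slice triple
#'
#' Container for one registered T2W/DWI/ADC slice set with an optional
#' binary lesion mask and pixel spacing.  All three channels (and the mask,
#' when present) must share identical dimensions.
#'
#' @param t2w,dwi,adc 2-D numeric matrices of identical dimensions.
#' @param mask Optional binary matrix (values in \{0, 1\}).
#' @param spacing Optional (row, col) pixel spacing in mm.
#' @param case_id,slice_index Identifiers.
#' @return An object of class `modality_triple`.
#' @export
modality_triple <- function(t2w, dwi, adc, mask = NULL, spacing = NULL,
                            case_id = "case", slice_index = 1L) {
  stopifnot(is.matrix(t2w), is.matrix(dwi), is.matrix(adc),
            identical(dim(t2w), dim(dwi)), identical(dim(t2w), dim(adc)))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(t2w)), all(mask %in% c(0L, 1L)))
    mask <- as_binary_mask(mask)
  }
  structure(
    list(t2w = t2w, dwi = dwi, adc = adc, mask = mask, spacing = spacing,
         case_id = case_id, slice_index = as.integer(slice_index)),
    class = "modality_triple"
  )
}

# Rasterize one ellipse into a logical matrix; pixel-centre inclusion test.
rasterize_ellipse <- function(n, cy, cx, r_major, r_minor, theta) {
  ys <- rep(seq_len(n), times = n) - cy
  xs <- rep(seq_len(n), each = n) - cx
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  matrix((u / r_major)^2 + (v / r_minor)^2 <= 1, n, n)
}

# Shared implementation so that all slices of one case can share a gland
# centre while the public generate_slice() remains self-contained.
generate_slice_impl <- function(spec, gland_center = NULL,
                                case_id = "case001", slice_index = 1L) {
  n <- spec$image_size
  gr <- spec$gland_radius_frac * n
  cc <- (n + 1) / 2
  if (is.null(gland_center)) {
    gland_center <- cc + stats::runif(2, -0.03, 0.03) * n
  }
  ys <- rep(seq_len(n), times = n) - gland_center[1]
  xs <- rep(seq_len(n), each = n) - gland_center[2]
  gland <- matrix(sqrt(ys^2 + xs^2) <= gr, n, n)

  mask <- matrix(FALSE, n, n)
  if (spec$n_lesions > 0) {
    for (i in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        r_major <- stats::runif(1, spec$lesion_radius_range[1],
                                spec$lesion_radius_range[2])
        ratio <- stats::runif(1, spec$axis_ratio_range[1],
                              spec$axis_ratio_range[2])
        theta <- stats::runif(1, 0, pi)
        # centre such that the whole ellipse stays inside the gland
        max_d <- gr - r_major
        if (max_d <= 0) next
        ang <- stats::runif(1, 0, 2 * pi)
        d <- sqrt(stats::runif(1)) * max_d
        cy <- gland_center[1] + d * sin(ang)
        cx <- gland_center[2] + d * cos(ang)
        les <- rasterize_ellipse(n, cy, cx, r_major, r_major * ratio, theta)
        if (sum(les) > 0) {
          mask <- mask | les
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("lesion placement failed after 100 retries; ",
             "lesion radii too large for the gland", call. = FALSE)
      }
    }
  }

  base <- matrix(spec$background, n, n)
  base[gland] <- spec$gland_mean
  imgs <- lapply(c(t2w = "t2w", dwi = "dwi", adc = "adc"), function(mod) {
    im <- base
    im[mask] <- spec$gland_mean + spec$contrast[[mod]]
    if (spec$noise_sigma > 0) {
      im <- im + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    }
    pmin(pmax(im, 0), 1)
  })

  modality_triple(imgs$t2w, imgs$dwi, imgs$adc,
                  mask = as_binary_mask(mask * 1L),
                  spacing = c(0.5, 0.5),
                  case_id = case_id, slice_index = slice_index)
}

#' Generate one synthetic multi-modal phantom slice
#'
#' Draws gland geometry, lesion ellipses and noise from the RNG seeded with
#' `spec$seed`, so the same spec always yields bit-identical arrays.  The
#' ground-truth mask marks exactly the union of the rasterized lesion
#' ellipses.
#'
#' @param spec A [phantom_spec()].
#' @param case_id,slice_index Identifiers stored in the triple.
#' @return A [modality_triple()] with ground-truth mask.
#' @export
#' @examples
#' tr <- generate_slice(phantom_spec(n_lesions = 1, seed = 7))
#' mean(tr$adc[tr$mask == 1]) < mean(tr$adc[tr$mask == 0])
generate_slice <- function(spec, case_id = "case001", slice_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed,
                   generate_slice_impl(spec, NULL, case_id, slice_index))
}

# 7:1:2 split sizes by proportional rounding; every split must be non-empty.
split_sizes <- function(n_cases) {
  n_test <- round(0.2 * n_cases)
  n_val <- round(0.1 * n_cases)
  n_train <- n_cases - n_val - n_test
  if (n_val < 1 || n_test < 1 || n_train < 1) {
    stop("n_cases = ", n_cases,
         " is too small to populate all of train/val/test (7:1:2 by case)",
         call. = FALSE)
  }
  c(train = n_train, val = n_val, test = n_test)
}

#' Generate a phantom dataset with case-level 7:1:2 splits
#'
#' Cases (not slices) are partitioned into train/validation/test at the 7:1:2
#' ratio used for model development, so all slices of one case always land in
#' the same split.  Slices within a case share a gland centre.
#'
#' @param spec A [phantom_spec()]; its `seed` drives all randomness.
#' @param n_cases Number of cases (>= 10 so each split is non-empty).
#' @param slices_per_case Slices generated per case.
#' @return An object of class `phantom_dataset`: a list with `slices`
#'   (list of [modality_triple()]), `manifest` (tibble with `case_id`,
#'   `slice_index`, `split`) and the `spec`.
#' @export
generate_dataset <- function(spec, n_cases, slices_per_case = 10L) {
  stopifnot(inherits(spec, "phantom_spec"), n_cases >= 3, slices_per_case >= 1)
  sizes <- split_sizes(n_cases)
  withr::with_seed(spec$seed, {
    split <- sample(rep(names(sizes), sizes))
    case_ids <- sprintf("case%03d", seq_len(n_cases))
    slices <- vector("list", n_cases * slices_per_case)
    rows <- vector("list", n_cases * slices_per_case)
    k <- 0L
    for (ci in seq_len(n_cases)) {
      n <- spec$image_size
      center <- (n + 1) / 2 + stats::runif(2, -0.03, 0.03) * n
      for (si in seq_len(slices_per_case)) {
        k <- k + 1L
        slices[[k]] <- generate_slice_impl(spec, center, case_ids[ci], si)
        rows[[k]] <- tibble::tibble(case_id = case_ids[ci], slice_index = si,
                                    split = split[ci])
      }
    }
    structure(list(slices = slices,
                   manifest = dplyr::bind_rows(rows),
                   spec = spec),
              class = "phantom_dataset")
  })
}

#' Subset the slices of a phantom dataset by split
#'
#' @param dataset A `phantom_dataset`.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return A list of [modality_triple()].
#' @export
dataset_split <- function(dataset, split = c("train", "val", "test")) {
  split <- match.arg(split)
  keep <- dataset$manifest$split == split
  dataset$slices[keep]
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset> ", length(x$slices), " slices, ",
      dplyr::n_distinct(x$manifest$case_id), " cases (",
      paste(table(x$manifest$split)[c("train", "val", "test")],
            collapse = "/"),
      " slices train/val/test)\n", sep = "")
  invisible(x)
}
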