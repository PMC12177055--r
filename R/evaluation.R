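# Segmentation metrics and statistics: per-image and dataset-global Dice,
# Wilcoxon signed-rank comparison with Benjamini-Hochberg correction.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  When both masks are empty the DSC is defined
#' as 1 by default (a correct "no lesion" call scores perfectly); set
#' `both_empty` to change the convention.
#'
#' @param a,b Binary matrices of identical shape.
#' @param both_empty Value returned when both masks are empty (default 1).
#' @return A number in `[0, 1]`.
#' @export
dsc_pair <- function(a, b, both_empty = 1.0) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch", call. = FALSE)
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(both_empty)
  2 * sum(a == 1L & b == 1L) / s
}

#' Per-image evaluation record
#'
#' Computes per-image DSC together with the TP/FP/FN pixel counts that feed
#' the dataset-global DSC.
#'
#' @param pred,truth Binary matrices.
#' @param case_id,slice_index,method Identifiers.
#' @return A one-row tibble (`case_id`, `slice_index`, `method`, `dsc`,
#'   `tp`, `fp`, `fn`).
#' @export
eval_record <- function(pred, truth, case_id = "case", slice_index = 1L,
                        method = "model") {
  cnt <- global_dsc_counts(as_binary_mask(pred), as_binary_mask(truth))
  tibble::tibble(case_id = case_id, slice_index = as.integer(slice_index),
                 method = method, dsc = dsc_pair(pred, truth),
                 tp = as.numeric(cnt["tp"]), fp = as.numeric(cnt["fp"]),
                 fn = as.numeric(cnt["fn"]))
}

#' Dataset-global Dice similarity coefficient
#'
#' Pools pixel counts over all images of a dataset:
#' `2 * sum(TP) / (2 * sum(TP) + sum(FP) + sum(FN))`.  This is the headline
#' metric; it deliberately differs from the mean of per-image DSCs (large
#' lesions weigh more).
#'
#' @param records A tibble of [eval_record()] rows for one method.
#' @return A number in `[0, 1]`.
#' @export
dsc_global <- function(records) {
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  num <- 2 * sum(records$tp)
  den <- num + sum(records$fp) + sum(records$fn)
  if (den == 0) return(1)
  num / den
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on per-image metric values of two methods.  Zero
#' differences are dropped (the Wilcoxon convention); if all differences
#' are zero the p-value is defined as 1.  The exact distribution is used
#' for n <= 25 non-zero differences (falling back to the normal
#' approximation when ties make the exact test unavailable), otherwise the
#' normal approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5).
#' @return A list with `statistic`, `p_value`, `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(statistic = NA_real_, p_value = 1.0, n = 0L))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = nz <= 25,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = as.integer(nz))
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up BH adjustment (monotone, capped at 1) controlling the false
#' discovery rate at level `q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble with `p`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, significant = adj <= q)
}

#' Pairwise method comparison on per-image DSC
#'
#' Runs the paired Wilcoxon signed-rank test for every pair of methods on
#' identical image sets and applies the Benjamini-Hochberg correction
#' across all pairs.
#'
#' @param records A tibble with columns `method`, `case_id`, `slice_index`
#'   and `dsc` (e.g. bound [eval_record()] rows for several methods).
#' @param q FDR level for the significance flags.
#' @return A tibble of class `sf_comparison`: `method_a`, `method_b`, `n`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_methods <- function(records, q = 0.05) {
  stopifnot(all(c("method", "case_id", "slice_index", "dsc") %in%
                  names(records)))
  methods <- sort(unique(records$method))
  if (length(methods) < 2) stop("need at least two methods", call. = FALSE)
  wide <- records |>
    dplyr::mutate(image = paste(.data$case_id, .data$slice_index,
                                sep = ":")) |>
    dplyr::select("image", "method", "dsc") |>
    tidyr::pivot_wider(names_from = "method", values_from = "dsc")
  if (anyNA(wide[methods])) {
    stop("methods were not evaluated on identical image sets",
         call. = FALSE)
  }
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    wt <- wilcoxon_signed_rank(wide[[pr[1]]], wide[[pr[2]]])
    tibble::tibble(method_a = pr[1], method_b = pr[2], n = nrow(wide),
                   statistic = wt$statistic, p_value = wt$p_value)
  })
  adj <- bh_adjust(res$p_value, q)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$significant
  class(res) <- c("sf_comparison", class(res))
  res
}

#' Evaluate a trained model on a set of slices
#'
#' Segments each slice with the requested prompting mode and returns one
#' [eval_record()] row per slice.
#'
#' @param model A trained `sf_model`.
#' @param slices List of [modality_triple()] with ground-truth masks.
#' @param prompts `"none"` (prompt-free), `"gt"` (unperturbed ground-truth
#'   boxes) or `"auto"` (PGM-generated boxes).
#' @param method Label stored in the records (defaults to the prompt mode).
#' @return A tibble of evaluation records; pass to [dsc_global()] or
#'   [compare_methods()].
#' @export
evaluate_model <- function(model, slices,
                           prompts = c("none", "gt", "auto"),
                           method = NULL) {
  prompts <- match.arg(prompts)
  method <- method %||% prompts
  purrr::map_dfr(slices, function(tr) {
    seg <- segment_slice(model, tr, prompts = prompts)
    eval_record(seg$mask, tr$mask, tr$case_id, tr$slice_index, method)
  })
}
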