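# Prompt generation module (PGM): coarse prompt-free segmentation,
# morphological post-processing with per-lesion splitting, minimum
# enclosing rectangles with outward expansion, and iterative box
# refinement.  The PGM is segmentation-only: no detection network.

#' Construct a lesion mask object
#'
#' @param mask Binary matrix.
#' @param prob Optional probability map (`mask` must equal `prob >= 0.5`).
#' @param components Optional list of disjoint single-lesion binary masks
#'   whose union equals `mask`.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, prob = NULL, components = NULL) {
  mask <- as_binary_mask(mask)
  if (!is.null(prob)) stopifnot(identical(dim(prob), dim(mask)))
  structure(list(prob = prob, mask = mask, components = components),
            class = "lesion_mask")
}

#' Coarse prompt-free segmentation of a slice
#'
#' Runs the prompt-free branch (frozen backbone + prompt-free fusion
#' module, decoder without prompt feature) and thresholds the probability
#' map at 0.5.  The probability map is returned at input resolution
#' (nearest-neighbour upsampled from the decoder grid).
#'
#' @param triple A [modality_triple()].
#' @param model An `sf_model` with a trained prompt-free MFM.
#' @return A [lesion_mask()] with `prob` and `mask`.
#' @export
coarse_segment <- function(triple, model) {
  stopifnot(inherits(model, "sf_model"))
  cfg <- model$config
  if (nrow(triple$t2w) != cfg$input_size) {
    stop("slice size does not match the model's input size; ",
         "preprocess first", call. = FALSE)
  }
  res <- forward_slice(model, triple, "mfm_pf")
  prob <- upsample_nearest(res$prob, cfg$input_size %/% nrow(res$prob))
  lesion_mask(threshold_mask(prob), prob = prob)
}

#' Morphological post-processing and per-lesion splitting
#'
#' Applies a morphological open-close with a 3x3 square structuring element
#' (removes isolated specks and fills pinholes), then a closing with a disk
#' of radius `merge_radius` to merge adjacent connected areas, drops
#' components smaller than `min_area` pixels, and splits the result into
#' single-component masks (8-connectivity).
#'
#' @param mask Binary matrix.
#' @param open_size Side of the square open-close element (default 3).
#' @param merge_radius Disk radius in pixels for the merging closing.
#' @param min_area Minimum surviving component area in pixels; default
#'   `10 * (n / 128)^2` for an `n`-pixel image side.
#' @param connectivity 8 (default) or 4.
#' @return A [lesion_mask()] with `mask` (union of surviving components)
#'   and `components`.
#' @export
postprocess <- function(mask, open_size = 3L, merge_radius = 2L,
                        min_area = NULL, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  min_area <- min_area %||% (10 * (nrow(mask) / 128)^2)
  if (sum(mask) > 0) {
    kern <- EBImage::makeBrush(open_size, "box")
    m <- EBImage::closing(EBImage::opening(mask, kern), kern)
    if (merge_radius > 0) {
      disc <- EBImage::makeBrush(2L * merge_radius + 1L, "disc")
      m <- EBImage::closing(m, disc)
    }
    m <- as_binary_mask(matrix(as.numeric(m), nrow(mask), ncol(mask)))
  } else {
    m <- mask
  }
  lab <- label_components(m, connectivity)
  comps <- list()
  keep <- matrix(0L, nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      cm <- as_binary_mask((lab == k) * 1L)
      if (sum(cm) >= min_area) {
        comps[[length(comps) + 1L]] <- cm
        keep <- keep | cm
      }
    }
  }
  lesion_mask(as_binary_mask(keep * 1L), components = comps)
}

#' Minimum enclosing rectangle of a mask, expanded outward
#'
#' The tight axis-aligned box (0-based, half-open) is grown by
#' `expand_frac` of its width/height -- half on each side -- rounded
#' outward (floor on the min corner, ceiling on the max corner) and clamped
#' to the image bounds.  The expanded box always contains the tight box.
#'
#' @param m Non-empty binary matrix (single connected component in the
#'   intended use).
#' @param expand_frac Total outward expansion as a fraction of box size
#'   (0.15 for initial boxes, 0.10 during refinement).
#' @return A [bbox()].
#' @export
box_from_mask <- function(m, expand_frac = 0.15) {
  m <- as_binary_mask(m)
  if (sum(m) == 0) stop("cannot compute a bounding box of an empty mask",
                        call. = FALSE)
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  y_min <- min(rows) - 1; y_max <- max(rows)
  x_min <- min(cols) - 1; x_max <- max(cols)
  dx <- expand_frac * (x_max - x_min) / 2
  dy <- expand_frac * (y_max - y_min) / 2
  bbox(max(floor(x_min - dx), 0), max(floor(y_min - dy), 0),
       min(ceiling(x_max + dx), ncol(m)), min(ceiling(y_max + dy), nrow(m)))
}

#' Iterative refinement of a box prompt
#'
#' Starting from the initial single-lesion mask `m0`, computes its
#' enclosing box expanded by `init_expand`, then repeats: encode the box,
#' decode a probability map from the fused embedding, threshold at 0.5,
#' and recompute the box expanded by `iter_expand` -- until the DSC between
#' consecutive masks reaches `dsc_stop` (the first comparison is against
#' `m0`), the decoded mask collapses to empty (the previous mask is
#' returned, not converged), or `max_iter` is reached.
#'
#' @param f_prime Fused embedding (passed through to `decoder`; any type
#'   the supplied decoder accepts).
#' @param m0 Non-empty initial binary mask.
#' @param prompt_encoder Function `(bbox) -> prompt feature`.
#' @param decoder Function `(f_prime, f_p) -> probability map` at the
#'   resolution of `m0`.
#' @param max_iter Safety cap on iterations (default 10).
#' @param dsc_stop Consecutive-mask DSC stopping threshold (default 0.95).
#' @param init_expand,iter_expand Box expansion fractions (0.15 / 0.10).
#' @return A list with `mask` (the final mask) and `trace` (class
#'   `refinement_trace`: boxes, masks, consecutive DSC values, iteration
#'   count, convergence flag).
#' @export
refine_box <- function(f_prime, m0, prompt_encoder, decoder,
                       max_iter = 10L, dsc_stop = 0.95,
                       init_expand = 0.15, iter_expand = 0.10) {
  m0 <- as_binary_mask(m0)
  if (sum(m0) == 0) stop("initial mask must be non-empty", call. = FALSE)
  b <- box_from_mask(m0, init_expand)
  boxes <- list(b)
  masks <- list(m0)
  dscs <- numeric(0)
  m_prev <- m0
  converged <- FALSE
  iterations <- 0L
  for (i in seq_len(max_iter)) {
    iterations <- i
    f_p <- prompt_encoder(b)
    prob <- decoder(f_prime, f_p)
    m_i <- as_binary_mask((prob >= 0.5) * 1L)
    if (sum(m_i) == 0) {          # degenerate collapse: keep previous mask
      iterations <- i - 1L
      m_i <- m_prev
      break
    }
    d <- dsc_pair(m_prev, m_i)
    dscs <- c(dscs, d)
    masks <- c(masks, list(m_i))
    if (d >= dsc_stop) {
      converged <- TRUE
      m_prev <- m_i
      break
    }
    b <- box_from_mask(m_i, iter_expand)
    boxes <- c(boxes, list(b))
    m_prev <- m_i
  }
  trace <- structure(list(boxes = boxes, masks = masks,
                          dsc_consecutive = dscs, iterations = iterations,
                          converged = converged),
                     class = "refinement_trace")
  list(mask = m_prev, trace = trace)
}

#' Generate bounding-box prompts for a slice
#'
#' The three PGM steps: (1) coarse prompt-free segmentation, (2)
#' morphological post-processing and per-lesion splitting, (3) iterative
#' box refinement per component (using the decoder with the fused
#' embedding of the prompt-guided fusion module when trained, otherwise the
#' prompt-free one).  An empty coarse mask yields zero boxes -- the
#' "no lesion" outcome.
#'
#' @param triple A [modality_triple()].
#' @param model An `sf_model`.
#' @param refine Run the iterative refinement (default TRUE)?
#' @param max_iter Refinement iteration cap.
#' @return A list of [bbox()] (possibly empty), with the refinement traces
#'   attached as attribute `"traces"`.
#' @export
generate_prompts <- function(triple, model, refine = TRUE, max_iter = 10L) {
  cfg <- model$config
  coarse <- coarse_segment(triple, model)
  post <- postprocess(coarse$mask)
  if (length(post$components) == 0) {
    return(structure(list(), traces = list()))
  }
  emb <- embed_triple(model, triple)
  which <- if ("mfm_pf" %in% model$frozen) "mfm_g" else "mfm_pf"
  fused <- mfm_fwd(emb$all, emb$t, emb$d, emb$a, model$params[[which]],
                   cfg)$out
  penc <- function(b) prompt_forward(b, model$params$prompt, cfg)$out
  dec <- function(f_prime, f_p) {
    prob <- decoder_forward(f_prime, f_p, model$params$decoder, cfg)$prob
    upsample_nearest(prob, cfg$input_size %/% nrow(prob))
  }
  boxes <- list()
  traces <- list()
  for (comp in post$components) {
    if (refine) {
      r <- refine_box(fused, comp, penc, dec, max_iter = max_iter)
      boxes[[length(boxes) + 1L]] <- box_from_mask(r$mask, 0.10)
      traces[[length(traces) + 1L]] <- r$trace
    } else {
      boxes[[length(boxes) + 1L]] <- box_from_mask(comp, 0.15)
    }
  }
  structure(boxes, traces = traces)
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat("<refinement_trace> ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "not converged",
      if (length(x$dsc_consecutive))
        paste0(" (last consecutive DSC ",
               signif(utils::tail(x$dsc_consecutive, 1), 4), ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Export a refinement trace as JSON
#'
#' @param trace A `refinement_trace`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
trace_to_json <- function(trace, path) {
  jsonlite::write_json(
    list(iterations = trace$iterations, converged = trace$converged,
         dsc_consecutive = trace$dsc_consecutive,
         boxes = lapply(trace$boxes, function(b) as.list(unclass(b)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
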