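#' Segment one slice with the full pipeline
#'
#' Prompt modes: `"none"` decodes the prompt-free branch; `"gt"` uses
#' unperturbed tight boxes around each ground-truth lesion component;
#' `"auto"` generates boxes with the prompt generation module
#' ([generate_prompts()]).  With box prompts, each box is decoded through
#' the prompt-guided branch and the per-box masks are unioned; zero boxes
#' yield an empty segmentation ("no lesion").
#'
#' @param model A trained `sf_model`.
#' @param triple A [modality_triple()] matching the model's input size.
#' @param prompts `"auto"`, `"gt"` or `"none"`.
#' @param boxes Optional explicit list of [bbox()] (overrides `prompts`).
#' @return A list of class `sf_segmentation`: `mask` (binary, input
#'   resolution), `prob` (pixelwise max probability over decoded prompts),
#'   `boxes` (list of boxes used).
#' @export
segment_slice <- function(model, triple, prompts = c("auto", "gt", "none"),
                          boxes = NULL) {
  prompts <- match.arg(prompts)
  cfg <- model$config
  n <- cfg$input_size
  up <- function(p) upsample_nearest(p, n %/% nrow(p))

  if (is.null(boxes) && prompts == "none") {
    res <- forward_slice(model, triple, "mfm_pf")
    prob <- up(res$prob)
    return(structure(list(mask = threshold_mask(prob), prob = prob,
                          boxes = list()),
                     class = "sf_segmentation"))
  }

  if (is.null(boxes)) {
    boxes <- if (prompts == "gt") {
      if (is.null(triple$mask)) stop("ground-truth boxes need a mask",
                                     call. = FALSE)
      lab <- label_components(triple$mask)
      lapply(seq_len(max(lab, 0L)),
             function(k) tight_box((lab == k) * 1L))
    } else {
      generate_prompts(triple, model)
    }
  }

  if (length(boxes) == 0) {
    empty <- matrix(0L, n, n)
    return(structure(list(mask = as_binary_mask(empty),
                          prob = matrix(0, n, n), boxes = list()),
                     class = "sf_segmentation"))
  }

  emb <- embed_triple(model, triple)
  fus <- mfm_fwd(emb$all, emb$t, emb$d, emb$a, model$params$mfm_g, cfg)
  prob <- matrix(0, n, n)
  for (b in boxes) {
    validate_bbox(b, n)
    fp <- prompt_forward(b, model$params$prompt, cfg)$out
    p <- up(decoder_forward(fus$out, fp, model$params$decoder, cfg)$prob)
    prob <- pmax(prob, p)
  }
  structure(list(mask = threshold_mask(prob), prob = prob, boxes = boxes),
            class = "sf_segmentation")
}

#' @export
print.sf_segmentation <- function(x, ...) {
  cat("<sf_segmentation> ", sum(x$mask), " foreground px, ",
      length(x$boxes), " box prompt(s)\n", sep = "")
  invisible(x)
}
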