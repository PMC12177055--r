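#' Run the complete phantom study pipeline
#'
#' The package's end-to-end experiment at desk scale: generate a phantom
#' dataset with case-level 7:1:2 splits, pre-train and freeze the stand-in
#' backbone on the training split, train the prompt-free fusion module,
#' freeze it and train the prompt-guided module (tiny preset, at most 10
#' epochs per phase), then evaluate validation global DSC under the three
#' prompting modes: prompt-free, unperturbed ground-truth boxes, and
#' automatically generated boxes (PGM).
#'
#' @param seed Integer seed driving every random component.
#' @param n_cases,slices_per_case Dataset size (defaults: 20 cases x 10
#'   slices = 200 slices).
#' @param pretrain_epochs Backbone pre-training epochs.
#' @param config A [train_config()] for the two fusion phases.
#' @param eval_split Split evaluated (default `"val"`).
#' @return A list of class `sf_study`: `model`, `dataset`, `fits` (the two
#'   `sf_fit`s), `records` (per-image evaluation records of the three
#'   modes) and `metrics` (tibble of global DSC per prompting mode).
#' @export
phantom_study <- function(seed = 1L, n_cases = 20L, slices_per_case = 10L,
                          pretrain_epochs = 48L,
                          config = train_config("tiny", seed = seed),
                          eval_split = "val") {
  spec <- phantom_spec(seed = seed)
  dataset <- generate_dataset(spec, n_cases, slices_per_case)
  model <- model_init(backbone_config("tiny"), seed = seed)
  model <- pretrain_backbone(model, dataset_split(dataset, "train"),
                             epochs = pretrain_epochs, seed = seed)
  fit_pf <- train_promptfree(dataset, model, config)
  fit_g <- train_guided(dataset, fit_pf, config)
  model <- fit_g$model
  slices <- dataset_split(dataset, eval_split)
  records <- dplyr::bind_rows(
    evaluate_model(model, slices, "none", method = "prompt_free"),
    evaluate_model(model, slices, "gt", method = "gt_boxes"),
    evaluate_model(model, slices, "auto", method = "pgm_boxes")
  )
  metrics <- records |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(~tibble::tibble(global_dsc = dsc_global(.x))) |>
    dplyr::ungroup()
  structure(list(model = model, dataset = dataset,
                 fits = list(prompt_free = fit_pf, prompt_guided = fit_g),
                 records = records, metrics = metrics, seed = seed),
            class = "sf_study")
}

#' @export
print.sf_study <- function(x, ...) {
  cat("<sf_study> seed ", x$seed, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}
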