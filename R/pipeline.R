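#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage configuration of the
#' simulate/ingest -> scalogram -> balance -> split -> train -> evaluate
#' pipeline. Balancing follows one of three modes: `"pooled"` oversamples
#' the whole dataset to `target_count` per class and then splits (this
#' reproduces a 4,000-fragment corpus splitting 3,200/400/400 from the
#' reference class counts); `"safe"` splits first and oversamples the
#' training partition only, so no synthetic fragment can leak information
#' about validation/test members; `"off"` trains on the imbalanced data as
#' is.
#'
#' @param counts Named per-class fragment counts to simulate (defaults to
#'   the reference corpus composition: 97 VFL, 240 VF, 72 VTTdP, 169
#'   VTHR), or `NULL` when `input_dir` is given.
#' @param input_dir Optional directory of fragments (layout of
#'   [write_fragments()]) used instead of simulation.
#' @param synth A [synth_config()].
#' @param balance_mode `"pooled"`, `"safe"` or `"off"`.
#' @param target_count SMOTE per-class target (1,000 balances the
#'   reference corpus).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param scales,sigma,image_size,colormap Scalogram settings (see
#'   [fragments_to_scalograms()]).
#' @param split A [split_spec()].
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param explain_top Explain this many test images per run (0 disables).
#' @param seed Master seed; stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts = c(C1 = 97, C2 = 240, C3 = 72, C4 = 169),
                       input_dir = NULL,
                       synth = synth_config(),
                       balance_mode = c("pooled", "safe", "off"),
                       target_count = 1000,
                       k_neighbors = 5,
                       scales = scale_grid(),
                       sigma = 1,
                       image_size = 64,
                       colormap = "jet",
                       split = split_spec(),
                       model = model_config(input_size = image_size),
                       train = train_config(),
                       explain_top = 0,
                       seed = 1L) {
  structure(
    list(counts = counts, input_dir = input_dir, synth = synth,
         balance_mode = match.arg(balance_mode),
         target_count = target_count, k_neighbors = k_neighbors,
         scales = scales, sigma = sigma, image_size = image_size,
         colormap = colormap, split = split, model = model, train = train,
         explain_top = explain_top, seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Executes simulate/ingest -> balance -> scalogram -> split -> train ->
#' evaluate (optionally -> explain), writing into `out_dir`: the fragment
#' manifest (`labels.csv` columns plus the partition of each fragment),
#' per-epoch history (`history.csv`), the evaluation report
#' (`metrics.json`), the resolved configuration (`config.yaml`, including
#' every derived stage seed) and, if requested, explanation weights
#' (`explanations.json`). A failing stage aborts with the stage name;
#' artifacts written before the failure are retained.
#'
#' @param cfg A [run_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with `fit`, `report`, `manifest`, `counts`
#'   and the output paths.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("shockscale_run_")) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(synth = cfg$seed, smote = cfg$seed + 1L,
                split = cfg$seed + 2L, init = cfg$seed + 3L,
                train = cfg$seed + 4L)

  frags <- stage("ingest", {
    if (!is.null(cfg$input_dir)) {
      if (!dir.exists(cfg$input_dir)) {
        stop("input directory not found: ", cfg$input_dir)
      }
      read_fragments(cfg$input_dir)
    } else {
      sc <- cfg$synth
      sc$seed <- seeds$synth
      generate_dataset(cfg$counts, sc)
    }
  })
  message("ingest: ", nrow(frags), " fragments (seed ", seeds$synth, ")")

  sp <- cfg$split
  sp$seed <- seeds$split

  to_imgs <- function(f) {
    fragments_to_scalograms(f, scales = cfg$scales, sigma = cfg$sigma,
                            size = cfg$image_size, colormap = cfg$colormap)
  }

  if (cfg$balance_mode == "pooled") {
    frags <- stage("balance", smote_resample(frags, cfg$target_count,
                                             cfg$k_neighbors, seeds$smote))
    imgs <- stage("scalogram", to_imgs(frags))
    parts <- stage("split", split_dataset(imgs, sp))
  } else if (cfg$balance_mode == "safe") {
    fparts <- stage("split", split_dataset(frags, sp))
    fparts$train <- stage("balance", smote_resample(
      fparts$train, cfg$target_count, cfg$k_neighbors, seeds$smote))
    parts <- stage("scalogram", purrr::map(fparts, to_imgs))
    frags <- dplyr::bind_rows(fparts)
  } else {
    imgs <- stage("scalogram", to_imgs(frags))
    parts <- stage("split", split_dataset(imgs, sp))
  }
  message("split: ", paste(names(parts), purrr::map_int(parts, nrow),
                           collapse = " ", sep = "="))

  manifest <- dplyr::bind_rows(purrr::imap(parts, function(p, nm) {
    tibble::tibble(id = p$id, label = p$label,
                   synthetic = if ("synthetic" %in% names(p)) p$synthetic
                               else FALSE,
                   partition = nm)
  }))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  fit <- stage("train", {
    model <- build_model(cfg$model, seed = seeds$init)
    tc <- cfg$train
    tc$seed <- seeds$train
    train_model(model, parts$train, parts$val, tc)
  })
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  report <- stage("evaluate", evaluate_model(fit, parts$test))
  jsonlite::write_json(
    list(confusion = report$confusion, metrics = report$metrics,
         macro = report$macro, auc = as.list(report$auc)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )

  if (cfg$explain_top > 0) {
    ex <- stage("explain", {
      idx <- seq_len(min(cfg$explain_top, nrow(parts$test)))
      purrr::map(idx, function(i) {
        e <- explain_prediction(parts$test$image[[i]], fit,
                                parts$test$label[i],
                                block = max(8, cfg$image_size %/% 8),
                                n = 200, seed = cfg$seed + i)
        list(id = parts$test$id[i], class = parts$test$label[i],
             weight = e$weight)
      })
    })
    jsonlite::write_json(ex, file.path(out_dir, "explanations.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  resolved <- cfg
  resolved$scales <- as.numeric(cfg$scales)
  resolved$seeds <- seeds
  yaml::write_yaml(purrr::map(unclass(resolved), function(x) {
    if (is.list(x)) unclass(x) else x
  }), file.path(out_dir, "config.yaml"))

  invisible(list(fit = fit, report = report, manifest = manifest,
                 counts = class_counts(frags), dir = out_dir))
}
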