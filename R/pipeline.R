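## Online annotation: liver segmentation -> tumor segmentation on the
## liver-masked input -> post-processing -> instance split -> partition ->
## per-tumor measuring, location and recognition -> JSON report.

#' Pipeline configuration
#'
#' Bundles the models and rules the online annotation needs. Any model may
#' be a trained `hep_segnet` or an [oracle_segnet()] stand-in; the
#' recognizer may be `NULL` to disable the recognition stage (the
#' characteristic bits are then reported as `NA`).
#'
#' @param liver_model,tumor_model segmentation networks.
#' @param partition_ensemble a `hep_partition_ensemble` or list of 8
#'   oracle networks (or `NULL` to skip location).
#' @param recognizer a `hep_multilabel_model` or `NULL`.
#' @param size_regression a [size_regression()].
#' @param postprocess a [postprocess_config()].
#' @param location_rule a [location_rule()].
#' @param liver_threshold,tumor_threshold probability cuts (default 0.5).
#' @param radiomics a [radiomics_config()].
#' @param verbose log stage progress.
#' @export
pipeline_config <- function(liver_model, tumor_model,
                            partition_ensemble = NULL, recognizer = NULL,
                            size_regression = hepannot::size_regression(),
                            postprocess = postprocess_config(),
                            location_rule = hepannot::location_rule(),
                            liver_threshold = 0.5, tumor_threshold = 0.5,
                            radiomics = radiomics_config(),
                            verbose = FALSE) {
  structure(list(liver_model = liver_model, tumor_model = tumor_model,
                 partition_ensemble = partition_ensemble,
                 recognizer = recognizer,
                 size_regression = size_regression,
                 postprocess = postprocess, location_rule = location_rule,
                 liver_threshold = liver_threshold,
                 tumor_threshold = tumor_threshold,
                 radiomics = radiomics, verbose = verbose),
            class = "hep_pipeline_config")
}

model_id <- function(m) {
  if (is.null(m)) "none"
  else if (inherits(m, "hep_oracle_net")) m$id
  else if (inherits(m, "hep_segnet")) sprintf("%s-%dD", m$arch, m$dims)
  else if (inherits(m, "hep_partition_ensemble"))
    sprintf("multi8-%dD", m$dims)
  else if (inherits(m, "hep_multilabel_model"))
    sprintf("%s+%s", m$base, m$selector)
  else class(m)[1]
}

stage_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Annotate a CT volume end-to-end
#'
#' Runs the online stages in order: liver segmentation (threshold 0.5),
#' tumor segmentation on the liver-masked volume, tri-planar morphological
#' post-processing with the plane vote, 26-connected instance split, the
#' eight-model liver partition, and per-tumor size regression, location
#' rule and radiomics recognition. Returns one annotation per tumor
#' instance (an empty list when no tumor is found).
#'
#' @param x a `hep_volume`, path to a NIfTI file, or phantom case.
#' @param cfg a [pipeline_config()].
#' @param report_path optional path for the JSON report.
#' @return list of [annotation()] records, with the intermediate masks
#'   attached as attributes `liver`, `tumor_mask` and `segments`.
#' @export
annotate <- function(x, cfg, report_path = NULL) {
  v <- if (is.character(x)) read_volume(x)
       else if (inherits(x, "hep_phantom")) x$volume
       else x
  stopifnot(inherits(v, "hep_volume"))
  prov <- list(liver = model_id(cfg$liver_model),
               tumor = model_id(cfg$tumor_model),
               partition = model_id(cfg$partition_ensemble),
               recognition = model_id(cfg$recognizer),
               measuring = sprintf("linear(a=%.4f,b=%.4f)",
                                   cfg$size_regression$a,
                                   cfg$size_regression$b))

  stage_log(cfg, "liver segmentation (%s)", prov$liver)
  liver_prob <- predict_segnet(cfg$liver_model, v)
  liver <- mask(liver_prob >= cfg$liver_threshold, v$spacing)
  if (sum(liver$data) == 0) stopf("no liver found")

  stage_log(cfg, "tumor segmentation (%s)", prov$tumor)
  tumor_in <- array(scale_intensity(v$data) * liver$data,
                    c(dim(v$data), 1))
  tumor_prob <- predict_segnet(cfg$tumor_model, tumor_in, liver = liver)
  initial <- mask((tumor_prob >= cfg$tumor_threshold) & liver$data != 0,
                  v$spacing)

  stage_log(cfg, "post-processing (vote threshold %d)",
            cfg$postprocess$vote_threshold)
  cleaned <- postprocess_tumor(initial, cfg$postprocess)

  comps <- label_components(cleaned$data, connectivity = 26)
  n_tumors <- max(comps)
  stage_log(cfg, "%d tumor instance(s)", n_tumors)

  segs <- NULL
  if (!is.null(cfg$partition_ensemble)) {
    stage_log(cfg, "liver partition (%s)", prov$partition)
    segs <- partition(cfg$partition_ensemble, v, liver)
  }

  anns <- list()
  if (n_tumors > 0) {
    for (t in seq_len(n_tumors)) {
      tm <- mask(comps == t, v$spacing)
      len <- longest_diameter(tm, cfg$size_regression$length_mode)
      sz <- size_cm(len, cfg$size_regression)
      if (sz < 0) {
        warning(sprintf("tumor %d: predicted size %.3f cm clamped to 0",
                        t, sz))
        sz <- 0
      }
      locs <- if (is.null(segs)) integer(0)
              else locate(tm, segs, cfg$location_rule)
      chars <- rep(NA_integer_, 11)
      if (!is.null(cfg$recognizer)) {
        feats <- extract_features(v, tm, cfg$radiomics)
        chars <- predict_labels(cfg$recognizer, feats)
      }
      anns[[t]] <- annotation(t, sz, locs, chars, provenance = prov)
    }
  }
  if (!is.null(report_path)) write_report(anns, report_path)
  attr(anns, "liver") <- liver
  attr(anns, "tumor_mask") <- cleaned
  attr(anns, "segments") <- segs
  anns
}

#' Evaluate predictions against ground truth
#'
#' Compares per-case segmentation masks, partition label maps, sizes,
#' locations and characteristic labels, emitting the stage metrics as a
#' data.frame (one row per metric).
#'
#' @param pred,truth lists with optional named elements per case:
#'   `liver`, `tumor`, `segments` (masks/label maps), `sizes` (numeric),
#'   `locations` (list of sets), `labels` (binary matrix).
#' @return data.frame with columns `stage`, `metric`, `value`.
#' @export
evaluate_cases <- function(pred, truth) {
  if (length(pred) != length(truth))
    stopf("evaluate_cases: unmatched case lists (%d vs %d)",
          length(pred), length(truth))
  rows <- list()
  add <- function(stage, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, metric = metric,
                                            value = value)
  for (what in c("liver", "tumor")) {
    ds <- unlist(Map(function(p, y) {
      if (is.null(p[[what]]) || is.null(y[[what]])) return(NULL)
      dice(p[[what]], y[[what]])
    }, pred, truth))
    if (length(ds)) add(what, "dice", mean(ds))
  }
  seg_d <- list()
  for (i in seq_along(pred)) {
    if (is.null(pred[[i]]$segments) || is.null(truth[[i]]$segments)) next
    for (k in 1:8)
      seg_d[[length(seg_d) + 1]] <-
        data.frame(k = k, d = dice(pred[[i]]$segments$data == k,
                                   truth[[i]]$segments$data == k))
  }
  if (length(seg_d)) {
    sd_ <- do.call(rbind, seg_d)
    for (k in 1:8)
      add("partition", sprintf("dice_segment_%d", k),
          mean(sd_$d[sd_$k == k]))
  }
  szp <- unlist(lapply(pred, `[[`, "sizes"))
  szt <- unlist(lapply(truth, `[[`, "sizes"))
  if (length(szp) && length(szp) == length(szt)) {
    mr <- mae_rmse(szp, szt)
    add("measuring", "mae_cm", mr$mae)
    add("measuring", "rmse_cm", mr$rmse)
  }
  locp <- do.call(c, lapply(pred, `[[`, "locations"))
  loct <- do.call(c, lapply(truth, `[[`, "locations"))
  if (length(locp) && length(locp) == length(loct)) {
    la <- location_accuracy(locp, loct)
    for (m in names(la)) add("location", m, la[[m]])
  }
  labp <- do.call(rbind, lapply(pred, `[[`, "labels"))
  labt <- do.call(rbind, lapply(truth, `[[`, "labels"))
  if (!is.null(labp)) {
    ml <- eval_multilabel(labp, labt)
    for (m in names(ml)) add("recognition", m, ml[[m]])
  }
  do.call(rbind, rows)
}

#' Deterministic k-fold assignment
#'
#' @param n number of cases.
#' @param folds number of folds (2 or 5 in the evaluation protocols).
#' @param seed RNG seed; a fixed seed reproduces the assignment.
#' @export
fold_assignment <- function(n, folds, seed = 1) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Write a phantom cohort to disk (NIfTI + CSV of truths)
#'
#' @param cases list of phantom cases.
#' @param dir output directory (created if missing).
#' @export
export_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    id <- sprintf("case%03d", i)
    write_volume(cs$volume, file.path(dir, paste0(id, "_ct.nii.gz")))
    write_mask(cs$liver, file.path(dir, paste0(id, "_liver.nii.gz")))
    write_labelmap(cs$segments,
                   file.path(dir, paste0(id, "_segments.nii.gz")))
    for (t in seq_along(cs$tumors))
      write_mask(cs$tumors[[t]],
                 file.path(dir, sprintf("%s_tumor%02d.nii.gz", id, t)))
    if (length(cs$tumors))
      truth[[length(truth) + 1]] <- data.frame(
        case = id, tumor = seq_along(cs$tumors),
        size_cm = cs$true_size_cm, cs$labels)
  }
  if (length(truth))
    utils::write.csv(do.call(rbind, truth),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Save / load the scalar pipeline settings as YAML
#'
#' Persists the size-regression coefficients, post-process settings and
#' location rule (the non-model part of a [pipeline_config()]) so a
#' calibration can be carried between sessions.
#'
#' @param cfg a `hep_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_yaml <- function(cfg, path) {
  yaml::write_yaml(list(
    size_regression = list(a = cfg$size_regression$a,
                           b = cfg$size_regression$b,
                           length_mode = cfg$size_regression$length_mode),
    postprocess = list(vote_threshold = cfg$postprocess$vote_threshold,
                       struct_radius = cfg$postprocess$struct_radius,
                       order = as.list(cfg$postprocess$order)),
    location_rule = list(threshold = cfg$location_rule$threshold),
    thresholds = list(liver = cfg$liver_threshold,
                      tumor = cfg$tumor_threshold)), path)
  invisible(path)
}

#' @rdname write_pipeline_yaml
#' @param liver_model,tumor_model,partition_ensemble,recognizer models to
#'   attach to the loaded settings.
#' @export
read_pipeline_yaml <- function(path, liver_model = NULL, tumor_model = NULL,
                               partition_ensemble = NULL, recognizer = NULL) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    liver_model = liver_model, tumor_model = tumor_model,
    partition_ensemble = partition_ensemble, recognizer = recognizer,
    size_regression = size_regression(a = y$size_regression$a,
                                      b = y$size_regression$b,
                                      length_mode = y$size_regression$length_mode),
    postprocess = postprocess_config(y$postprocess$vote_threshold,
                                     y$postprocess$struct_radius,
                                     unlist(y$postprocess$order)),
    location_rule = location_rule(y$location_rule$threshold),
    liver_threshold = y$thresholds$liver,
    tumor_threshold = y$thresholds$tumor)
}
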