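#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Serialisable to YAML
#' with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param channel_map named integer vector mapping channel names to TIFF
#'   page indices (passed to [read_stack()]); `NULL` uses sidecar
#'   metadata or the default page order CFP, GFP, RFP, DAPI.
#' @param segmentation a [seg_params()].
#' @param mask_paths optional character vector (one per input, `NA`
#'   allowed) of manual mask files; where given, automatic segmentation
#'   is skipped.
#' @param mode profile construction, `"periphery"` or `"centroid"`.
#' @param w band width in pixels.
#' @param error cohort error band, `"sem"` or `"sd"`.
#' @param out_dir directory for result files; `NULL` keeps results
#'   in memory only.
#' @param seed integer seed for any stochastic step.
#' @return a `lam_config` list.
#' @export
pipeline_config <- function(channel_map = NULL,
                            segmentation = seg_params(),
                            mask_paths = NULL,
                            mode = "periphery",
                            w = 5,
                            error = "sem",
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(w >= 1)
  structure(list(channel_map = channel_map, segmentation = segmentation,
                 mask_paths = mask_paths, mode = mode, w = w,
                 error = error, out_dir = out_dir, seed = as.integer(seed)),
            class = "lam_config")
}

#' @rdname pipeline_config
#' @param config a `lam_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$segmentation <- unclass(x$segmentation)
  if (!is.null(x$channel_map)) x$channel_map <- as.list(x$channel_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  seg <- do.call(seg_params, x$segmentation %||% list())
  cm <- x$channel_map
  if (!is.null(cm)) cm <- unlist(cm)
  pipeline_config(channel_map = cm, segmentation = seg,
                  mask_paths = x$mask_paths,
                  mode = x$mode %||% "periphery", w = x$w %||% 5,
                  error = x$error %||% "sem", out_dir = x$out_dir,
                  seed = x$seed %||% 1L)
}

#' Run the full lamination analysis over a set of aggregates
#'
#' For each input image: segment (or load a manual mask), profile,
#' normalise, compute ECDF curves and the lamination score. Then average
#' profiles per group and, if exactly two groups are present, compare
#' their scores with a two-tailed Mann-Whitney test. A failure on one
#' aggregate is recorded and the run continues with the rest.
#'
#' @param inputs character vector of TIFF paths, or a list of
#'   [image_stack()] objects (named or not).
#' @param config a [pipeline_config()].
#' @param groups optional character/factor of group labels, one per
#'   input.
#' @return a `lam_run` list: `scores` (tibble, one row per succeeded
#'   aggregate: `id`, `group`, per-channel areas, `score`,
#'   `mask_provenance`), `profiles` and `ecdfs` (named lists),
#'   `mean_profiles` (per group, when n >= 2), `test` (`lam_mwtest` or
#'   `NULL`), `errors` (named character), `config`. If `out_dir` is set,
#'   masks (PNG), profiles (CSV), scores (JSON) and a run log are written
#'   there.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), groups = NULL) {
  if (length(inputs) < 1) stop("need at least one input")
  ids <- names(inputs) %||% rep(NA_character_, length(inputs))
  if (is.character(inputs) && all(is.na(ids)))
    ids <- tools::file_path_sans_ext(basename(inputs))
  ids[is.na(ids) | ids == ""] <- paste0("aggregate_", which(is.na(ids) | ids == ""))
  ids <- make.unique(ids)
  if (!is.null(groups) && length(groups) != length(inputs))
    stop("groups must have one label per input")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  scores <- list(); nprofiles <- list(); ecdfs <- list(); errors <- character()
  for (i in seq_along(inputs)) {
    id <- ids[i]
    res <- tryCatch({
      stack <- if (is.character(inputs)) read_stack(inputs[i], config$channel_map)
               else inputs[[i]]
      manual <- config$mask_paths[i]
      mask <- if (!is.null(config$mask_paths) && !is.na(manual) && nzchar(manual))
        load_mask(manual, expected_dims = dim(stack[[1]]))
      else segment_aggregate(stack$DAPI, config$segmentation)
      prof <- radial_profile(stack, mask, w = config$w, mode = config$mode)
      chans <- intersect(c("CFP", "GFP", "RFP"), names(stack))
      np <- normalize_profile(prof, channels = chans)
      ec <- profile_ecdf(np)
      areas <- area_beneath(ec)
      sc <- tibble::as_tibble(as.list(stats::setNames(areas$area,
                                                      paste0("area_", areas$channel))))
      sc$score <- sc$area_CFP - sc$area_GFP
      sc$mask_provenance <- mask_provenance(mask)
      if (!is.null(out_dir)) {
        write_mask(mask, file.path(out_dir, paste0(id, "_mask.png")))
        write.csv(prof, file.path(out_dir, paste0(id, "_profile.csv")),
                  row.names = FALSE)
        jsonlite::write_json(c(as.list(sc), list(w = config$w, mode = config$mode)),
                             file.path(out_dir, paste0(id, "_score.json")),
                             auto_unbox = TRUE, digits = NA)
      }
      list(np = np, ec = ec, sc = sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
    } else {
      nprofiles[[id]] <- res$np
      ecdfs[[id]] <- res$ec
      scores[[id]] <- dplyr::mutate(res$sc, id = id,
                                    group = if (is.null(groups)) NA_character_
                                            else as.character(groups[i]),
                                    .before = 1)
    }
  }
  scores <- dplyr::bind_rows(scores)
  mean_profiles <- NULL
  if (nrow(scores) > 0) {
    grp_of <- scores$group
    split_ids <- split(scores$id, if (all(is.na(grp_of))) rep("all", nrow(scores)) else grp_of)
    mean_profiles <- purrr::map(split_ids, function(gids) {
      if (length(gids) < 2) return(NULL)
      average_profiles(nprofiles[gids], error = config$error)
    })
  }
  test <- NULL
  gl <- unique(stats::na.omit(scores$group))
  if (length(gl) == 2) {
    test <- mann_whitney(scores$score[scores$group == gl[1]],
                         scores$score[scores$group == gl[2]])
  }
  if (!is.null(out_dir)) {
    log <- c(paste("laminatr", as.character(utils::packageVersion("laminatr"))),
             paste("R", getRversion()),
             paste("date", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             paste("mode", config$mode), paste("w", config$w),
             paste("seed", config$seed),
             paste("inputs", length(inputs)), paste("failed", length(errors)))
    writeLines(log, file.path(out_dir, "run_log.txt"))
    if (nrow(scores) > 0)
      write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    if (!is.null(test))
      jsonlite::write_json(as.list(tidy(test)), file.path(out_dir, "test.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  structure(list(scores = scores, profiles = nprofiles, ecdfs = ecdfs,
                 mean_profiles = mean_profiles, test = test,
                 errors = errors, config = config),
            class = "lam_run")
}

#' @export
print.lam_run <- function(x, ...) {
  cat(sprintf("<lamination run> %d aggregate(s) scored, %d failed\n",
              nrow(x$scores), length(x$errors)))
  if (nrow(x$scores) > 0)
    cat(sprintf("  mean score: %.2f ru\n", mean(x$scores$score)))
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}
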