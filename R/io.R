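#' Plain-text serialization
#'
#' All on-disk formats are plain text: CSV for numeric arrays, JSON for
#' metadata, YAML for configurations — readable from any language and stable
#' across platforms.
#'
#' @name fusionesi-io
NULL

#' Write / read a source space
#'
#' A directory with `positions.csv`, `triangles.csv`, `orientations.csv` and
#' `meta.json`.
#'
#' @param space A `source_space`.
#' @param path Directory path (created if needed).
#' @return `write_source_space()` returns `path` invisibly;
#'   `read_source_space()` returns a `source_space`.
#' @export
write_source_space <- function(space, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(space$positions),
                   file.path(path, "positions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(space$triangles),
                   file.path(path, "triangles.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(space$orientations),
                   file.path(path, "orientations.csv"), row.names = FALSE)
  jsonlite::write_json(list(radius_m = space$radius_m),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_source_space
#' @export
read_source_space <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  structure(
    list(
      positions = as.matrix(utils::read.csv(file.path(path, "positions.csv"))),
      triangles = as.matrix(utils::read.csv(file.path(path, "triangles.csv"))),
      orientations = as.matrix(utils::read.csv(file.path(path, "orientations.csv"))),
      radius_m = meta$radius_m
    ),
    class = "source_space"
  )
}

#' Write / read a leadfield
#'
#' `L.csv` (channels x sources, full precision) plus `meta.json` with the
#' modality tag.
#'
#' @param lf A `leadfield`.
#' @param path Directory path.
#' @return `write_leadfield()` returns `path` invisibly; `read_leadfield()`
#'   returns a `leadfield` (without the generating space/sensors).
#' @export
write_leadfield <- function(lf, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format(as.data.frame(lf$L), digits = 17),
                   file.path(path, "L.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(modality = lf$modality, channels = nrow(lf$L),
                            sources = ncol(lf$L)),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  L <- as.matrix(utils::read.csv(file.path(path, "L.csv")))
  dimnames(L) <- NULL
  if (!is.null(meta$channels) &&
      (nrow(L) != meta$channels || ncol(L) != meta$sources)) {
    stop(sprintf("leadfield shape %dx%d disagrees with metadata %dx%d",
                 nrow(L), ncol(L), meta$channels, meta$sources))
  }
  new_leadfield(L, meta$modality)
}

#' Load an externally computed forward model pair
#'
#' Reproduction path for a realistic head model: reads EEG and MEG leadfields
#' exported as CSV (one directory each, as written by [write_leadfield()])
#' and optionally checks the expected channel/source counts. The reference
#' BEM forward model this path targets has 59 EEG channels, 102 MEG
#' magnetometers and 1984 cortical sources.
#'
#' @param eeg_path,meg_path Leadfield directories.
#' @param expect_shapes Verify the canonical 59 x 1984 / 102 x 1984 shapes?
#' @return List with `lf_eeg` and `lf_meg`.
#' @export
load_external_forward <- function(eeg_path, meg_path, expect_shapes = TRUE) {
  lf_eeg <- read_leadfield(eeg_path)
  lf_meg <- read_leadfield(meg_path)
  if (expect_shapes) {
    if (!all(dim(lf_eeg$L) == c(59, 1984))) {
      stop(sprintf("EEG leadfield is %dx%d, expected 59x1984",
                   nrow(lf_eeg$L), ncol(lf_eeg$L)))
    }
    if (!all(dim(lf_meg$L) == c(102, 1984))) {
      stop(sprintf("MEG leadfield is %dx%d, expected 102x1984",
                   nrow(lf_meg$L), ncol(lf_meg$L)))
    }
  }
  list(lf_eeg = lf_eeg, lf_meg = lf_meg)
}

#' Write / read a sample set
#'
#' A directory with `meta.json` (config + seed), `samples.csv` (per-sample
#' metadata), `patches.csv` (patch membership), and per-array CSVs `s.csv`,
#' `x_eeg.csv`, `x_meg.csv`, `y_eeg.csv`, `y_meg.csv`. The head model is not
#' serialized; it is rebuilt from the stored config on read, which is exact
#' because generation is seed-deterministic.
#'
#' @param set A `sample_set`.
#' @param path Directory path.
#' @return `write_sample_set()` returns `path` invisibly;
#'   `read_sample_set()` a `sample_set`.
#' @export
write_sample_set <- function(set, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(set$config)
  jsonlite::write_json(cfg, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(set$meta, file.path(path, "samples.csv"), row.names = FALSE)
  wr <- function(m, f) {
    utils::write.csv(format(as.data.frame(m), digits = 17),
                     file.path(path, f), row.names = FALSE, quote = FALSE)
  }
  wr(set$s, "s.csv"); wr(set$x_eeg, "x_eeg.csv"); wr(set$x_meg, "x_meg.csv")
  wr(set$y_eeg, "y_eeg.csv"); wr(set$y_meg, "y_meg.csv")
  patches <- dplyr::bind_rows(lapply(seq_along(set$patches), function(i) {
    p <- set$patches[[i]]
    cbind(sample = i, p$members,
          centers = paste(p$centers, collapse = ";"), amplitude = p$amplitude)
  }))
  utils::write.csv(patches, file.path(path, "patches.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  cfg <- do.call(sim_config, meta)
  head <- build_head_model(cfg)
  rd <- function(f) {
    m <- as.matrix(utils::read.csv(file.path(path, f)))
    dimnames(m) <- NULL
    m
  }
  samples <- tibble::as_tibble(utils::read.csv(file.path(path, "samples.csv"),
                                               stringsAsFactors = FALSE))
  ptab <- utils::read.csv(file.path(path, "patches.csv"), stringsAsFactors = FALSE)
  patches <- lapply(split(ptab, ptab$sample), function(g) {
    new_source_patch(
      tibble::tibble(region = as.integer(g$region), ring = as.integer(g$ring),
                     intensity = g$intensity),
      centers = as.integer(strsplit(as.character(g$centers[1]), ";")[[1]]),
      lns = max(g$ring), amplitude = g$amplitude[1]
    )
  })
  patches <- patches[order(as.integer(names(patches)))]
  structure(
    list(config = cfg, head = head, s = rd("s.csv"),
         x_eeg = rd("x_eeg.csv"), x_meg = rd("x_meg.csv"),
         y_eeg = rd("y_eeg.csv"), y_meg = rd("y_meg.csv"),
         patches = unname(patches), meta = samples),
    class = "sample_set"
  )
}

#' Save / load a fitted fusion model
#'
#' Single-file checkpoint: the architecture descriptor is stored as a JSON
#' string alongside the parameter list.
#'
#' @param fit A `fusion_fit` (or bare `fusion_model`).
#' @param path File path (`.rds`).
#' @return `write_fusion_model()` returns `path` invisibly;
#'   `read_fusion_model()` the saved object.
#' @export
write_fusion_model <- function(fit, path) {
  model <- if (inherits(fit, "fusion_fit")) fit$model else fit
  payload <- list(
    descriptor_json = jsonlite::toJSON(unclass(model$descriptor), auto_unbox = TRUE),
    params = model$params,
    history = if (inherits(fit, "fusion_fit")) fit$history else NULL,
    loss = if (inherits(fit, "fusion_fit")) {
      list(alpha = fit$loss_cfg$alpha, rho = fit$loss_cfg$rho,
           tau = fit$loss_cfg$tau)
    } else NULL
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_fusion_model
#' @export
read_fusion_model <- function(path) {
  payload <- readRDS(path)
  dj <- jsonlite::fromJSON(payload$descriptor_json)
  d <- fusion_descriptor(grid = dj$grid, n_out = dj$n_out,
                         conv_filters = dj$conv_filters, kernel = dj$kernel,
                         dilation = dj$dilation, reduction = dj$reduction,
                         fc_hidden = dj$fc_hidden)
  model <- fusion_model(d, seed = 1L)
  model$params <- payload$params
  model
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}
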