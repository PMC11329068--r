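#' Extended source patches
#'
#' An extended source is a patch of co-activated mesh regions: a center plus
#' concentric rings of graph neighbors. The number of rings is the "level of
#' neighborhoods" (LNs); activation decays with ring order as 100%, 85%, 70%
#' and 55% of the central amplitude for rings 0-3.
#'
#' @param space A `source_space` (or anything [build_mesh_graph()] accepts).
#' @param center 1-based region index of the patch center.
#' @param lns Level of neighborhoods, in 0:3.
#' @param amplitude Central amplitude (arbitrary units, default 1).
#' @param graph Optional precomputed mesh graph (saves rebuilding in loops).
#' @return A `source_patch`: tibble `members` (columns `region`, `ring`,
#'   `intensity`) plus fields `centers`, `lns`, `amplitude`.
#' @export
grow_patch <- function(space, center, lns, amplitude = 1, graph = NULL) {
  if (!lns %in% 0:3) stop("`lns` must be 0, 1, 2 or 3")
  if (is.null(graph)) graph <- build_mesh_graph(space)
  n <- igraph::vcount(graph)
  if (center < 1 || center > n) stop(sprintf("`center` %s out of range 1..%d", center, n))

  fractions <- ring_intensities()
  rings <- hop_rings(graph, center, lns)
  members <- dplyr::bind_rows(lapply(seq_along(rings), function(k) {
    tibble::tibble(region = as.integer(rings[[k]]), ring = k - 1L,
                   intensity = fractions[k])
  }))
  new_source_patch(members, centers = center, lns = lns, amplitude = amplitude)
}

ring_intensities <- function() c(1.0, 0.85, 0.70, 0.55)

new_source_patch <- function(members, centers, lns, amplitude) {
  stopifnot(!anyDuplicated(members$region))
  structure(
    list(members = members, centers = as.integer(centers), lns = as.integer(lns),
         amplitude = amplitude),
    class = "source_patch"
  )
}

#' @export
print.source_patch <- function(x, ...) {
  cat(sprintf("<source_patch> %d center(s), LNs=%d, %d regions\n",
              length(x$centers), x$lns, nrow(x$members)))
  invisible(x)
}

#' Sample a multi-source patch configuration
#'
#' Draws `ns` patch centers with pairwise geodesic separation of at least
#' `min_separation` mm, grows an LNs-patch around each, and merges them.
#' Regions claimed by more than one patch keep the maximum intensity.
#'
#' @inheritParams grow_patch
#' @param ns Number of simultaneous sources (>= 1).
#' @param seed Integer seed; placement is deterministic given the seed.
#' @param min_separation Minimum pairwise center distance in mm. Default
#'   `NULL` uses 2 * (lns + 1) mesh hops converted via the mean edge length,
#'   enough to keep patches from merging.
#' @param D Optional precomputed geodesic matrix.
#' @param max_tries Resampling budget before giving up.
#' @return A `source_patch` with `ns` centers.
#' @export
sample_multi_patch <- function(space, ns, lns, seed, min_separation = NULL,
                               amplitude = 1, graph = NULL, D = NULL,
                               max_tries = 200L) {
  if (ns < 1) stop("`ns` must be >= 1")
  if (is.null(graph)) graph <- build_mesh_graph(space)
  if (is.null(D)) D <- geodesic_all_pairs(graph)
  n <- nrow(D)
  if (is.null(min_separation)) {
    mean_edge <- mean(igraph::E(graph)$weight)
    min_separation <- 2 * (lns + 1) * mean_edge
  }

  centers <- withr_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      cand <- sample.int(n, ns)
      ok <- ns == 1 ||
        min(D[cand, cand][upper.tri(diag(ns))]) >= min_separation
      if (ok) {
        found <- cand
        break
      }
    }
    found
  })
  if (is.null(centers)) {
    stop(sprintf("could not place %d patch centers >= %.1f mm apart in %d tries",
                 ns, min_separation, max_tries))
  }

  patches <- lapply(centers, function(ctr) grow_patch(space, ctr, lns, amplitude, graph))
  members <- dplyr::bind_rows(lapply(patches, function(p) p$members))
  members <- members |>
    dplyr::group_by(.data$region) |>
    dplyr::slice_max(.data$intensity, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$region)
  new_source_patch(members, centers = centers, lns = lns, amplitude = amplitude)
}

#' Expand a patch into a dense source amplitude vector
#'
#' @param patch A `source_patch`.
#' @param n_regions Total number of regions N.
#' @return Length-N nonnegative vector; `amplitude * intensity` at patch
#'   members, 0 elsewhere.
#' @export
patch_to_source_vector <- function(patch, n_regions) {
  if (nrow(patch$members) > 0 && max(patch$members$region) > n_regions) {
    stop("patch member index exceeds `n_regions`")
  }
  s <- numeric(n_regions)
  s[patch$members$region] <- patch$amplitude * patch$members$intensity
  s
}

#' Simulation configuration
#'
#' Bundles everything the dataset builder needs. Defaults are the desk-scale
#' study conditions: a 162-dipole icosphere with randomly oriented dipoles,
#' 32 EEG + 64 MEG sensors, extended sources with LNs = 3 at 30 dB SNR,
#' 120 train / 20 test centers and several noise realizations per center.
#'
#' @param subdivisions,radius_m Icosphere geometry (see
#'   [make_icosphere_source_space()]).
#' @param orientation Dipole orientation model (`"random"` keeps MEG
#'   informative in the spherical conductor).
#' @param n_eeg,n_meg Channel counts.
#' @param eeg_radius_m,meg_radius_m Sensor shell radii (meters).
#' @param lns Levels of neighborhoods to simulate (vector, values in 0:3).
#' @param snr_db SNR levels in dB (vector).
#' @param ns Number of simultaneous sources per sample.
#' @param n_train,n_test Numbers of distinct patch-center regions for the
#'   train and test splits (disjoint by construction).
#' @param val_fraction Fraction of training samples held out for validation
#'   (split 70/30 by default).
#' @param reps_per_center Independent noise realizations per
#'   (center, LNs, SNR) cell.
#' @param grid_size Topographic encoding resolution (see [grid_encoding()]).
#' @param seed Master seed; everything downstream derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(subdivisions = 2, radius_m = 0.08,
                       orientation = "random",
                       n_eeg = 32, n_meg = 64,
                       eeg_radius_m = 0.10, meg_radius_m = 0.12,
                       lns = 3, snr_db = 30, ns = 1,
                       n_train = 120, n_test = 20, val_fraction = 0.3,
                       reps_per_center = 4, grid_size = c(16, 16),
                       seed = 1L) {
  cfg <- list(
    subdivisions = subdivisions, radius_m = radius_m, orientation = orientation,
    n_eeg = n_eeg, n_meg = n_meg,
    eeg_radius_m = eeg_radius_m, meg_radius_m = meg_radius_m,
    lns = lns, snr_db = snr_db, ns = ns,
    n_train = n_train, n_test = n_test, val_fraction = val_fraction,
    reps_per_center = reps_per_center, grid_size = grid_size,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Build a full head model from a simulation configuration
#'
#' @param config A [sim_config()].
#' @return List with `space`, `graph`, `D` (geodesics, mm), `sensors_eeg`,
#'   `sensors_meg`, `lf_eeg`, `lf_meg`, `enc_eeg`, `enc_meg`.
#' @export
build_head_model <- function(config) {
  space <- make_icosphere_source_space(
    config$subdivisions, config$radius_m,
    orientation = config$orientation,
    orientation_seed = config$seed + 1000L
  )
  graph <- build_mesh_graph(space)
  D <- geodesic_all_pairs(graph)
  sensors_eeg <- fibonacci_sensors(config$n_eeg, config$eeg_radius_m, "eeg")
  sensors_meg <- fibonacci_sensors(config$n_meg, config$meg_radius_m, "meg")
  lf_eeg <- eeg_leadfield(space, sensors_eeg)
  lf_meg <- meg_leadfield(space, sensors_meg)
  enc_eeg <- grid_encoding(sensors_eeg$positions, config$grid_size)
  enc_meg <- grid_encoding(sensors_meg$positions, config$grid_size)
  list(space = space, graph = graph, D = D,
       sensors_eeg = sensors_eeg, sensors_meg = sensors_meg,
       lf_eeg = lf_eeg, lf_meg = lf_meg,
       enc_eeg = enc_eeg, enc_meg = enc_meg)
}

#' Generate train / validation / test sample sets
#'
#' Draws disjoint train and test center regions, grows a patch per
#' (center, LNs, SNR, repetition) cell, projects it through both leadfields,
#' adds SNR-controlled noise independently per modality, z-scores each
#' modality across channels, and encodes the topographies on the input grid.
#' The train pool is further split into train/validation by sample. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param head Optional precomputed [build_head_model()] output.
#' @return A `sample_set`: list with `config`, `head`, matrices `s`
#'   (samples x N), `x_eeg`, `x_meg` (samples x grid cells), `y_eeg`, `y_meg`
#'   (samples x channels, noisy, unstandardized) and a `meta` tibble
#'   (`sample`, `split`, `center`, `lns`, `snr_db`, `ns`, `rep`).
#' @export
build_dataset <- function(config, head = NULL) {
  if (is.null(head)) head <- build_head_model(config)
  N <- nrow(head$space$positions)
  if (config$n_train + config$n_test > N) {
    stop(sprintf("n_train + n_test = %d exceeds the %d regions available",
                 config$n_train + config$n_test, N))
  }

  picks <- withr_seed(config$seed, sample.int(N, config$n_train + config$n_test))
  train_centers <- picks[seq_len(config$n_train)]
  test_centers <- picks[config$n_train + seq_len(config$n_test)]

  cells <- tidyr::expand_grid(
    center = c(train_centers, test_centers),
    lns = config$lns, snr_db = config$snr_db,
    rep = seq_len(config$reps_per_center)
  )
  cells$split <- ifelse(cells$center %in% train_centers, "train", "test")

  n_samp <- nrow(cells)
  G <- prod(config$grid_size)
  s <- matrix(0, n_samp, N)
  x_eeg <- matrix(0, n_samp, G)
  x_meg <- matrix(0, n_samp, G)
  y_eeg <- matrix(0, n_samp, config$n_eeg)
  y_meg <- matrix(0, n_samp, config$n_meg)

  patch_cache <- new.env(hash = TRUE)
  patches <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    ci <- cells$center[i]; li <- cells$lns[i]
    key <- paste(ci, li, config$ns)
    patch <- patch_cache[[key]]
    if (is.null(patch)) {
      patch <- if (config$ns == 1) {
        grow_patch(head$space, ci, li, graph = head$graph)
      } else {
        sample_multi_patch(head$space, config$ns, li,
                           seed = config$seed + 7L * ci + li,
                           graph = head$graph, D = head$D)
      }
      patch_cache[[key]] <- patch
    }
    patches[[i]] <- patch
    si <- patch_to_source_vector(patch, N)
    ye <- add_noise_at_snr(project_forward(head$lf_eeg, si), cells$snr_db[i],
                           seed = config$seed + 2L * i)
    ym <- add_noise_at_snr(project_forward(head$lf_meg, si), cells$snr_db[i],
                           seed = config$seed + 2L * i + 1L)
    s[i, ] <- si
    y_eeg[i, ] <- ye
    y_meg[i, ] <- ym
    x_eeg[i, ] <- encode_topography(standardize_channels(ye[, 1]), head$enc_eeg)$values
    x_meg[i, ] <- encode_topography(standardize_channels(ym[, 1]), head$enc_meg)$values
  }

  # hold out a validation fraction of the training samples (70/30 default)
  train_idx <- which(cells$split == "train")
  n_val <- floor(length(train_idx) * config$val_fraction)
  val_pick <- withr_seed(config$seed + 99L, sample(train_idx, n_val))
  cells$split[val_pick] <- "val"
  cells$sample <- seq_len(n_samp)
  cells$ns <- config$ns

  structure(
    list(config = config, head = head, s = s,
         x_eeg = x_eeg, x_meg = x_meg, y_eeg = y_eeg, y_meg = y_meg,
         patches = patches,
         meta = tibble::as_tibble(cells[, c("sample", "split", "center", "lns",
                                            "snr_db", "ns", "rep")])),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  tab <- table(x$meta$split)
  cat(sprintf("<sample_set> %d samples (%s), N=%d regions\n",
              nrow(x$s),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$s)))
  invisible(x)
}

#' Z-score a channel vector
#'
#' Per-sample standardization across channels, so EEG (volts) and MEG (tesla)
#' enter the network on comparable scales. A zero-variance vector maps to all
#' zeros.
#' @param y Channel vector.
#' @return Standardized vector.
#' @export
standardize_channels <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) return(y * 0)
  (y - mean(y)) / s
}

#' Subset a sample set by split
#'
#' @param set A `sample_set`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List with `s`, `x_eeg`, `x_meg`, `meta` restricted to the split.
#' @export
split_samples <- function(set, split) {
  idx <- which(set$meta$split == split)
  list(s = set$s[idx, , drop = FALSE],
       x_eeg = set$x_eeg[idx, , drop = FALSE],
       x_meg = set$x_meg[idx, , drop = FALSE],
       y_eeg = set$y_eeg[idx, , drop = FALSE],
       y_meg = set$y_meg[idx, , drop = FALSE],
       patches = set$patches[idx],
       meta = set$meta[idx, ])
}
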