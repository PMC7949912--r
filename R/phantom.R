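#' Default multi-site table for phantom cohorts
#'
#' Four acquisition sites with different age distributions (young student
#' samples through older clinical samples) and small per-site intensity
#' offsets, mimicking the age-heterogeneous multi-center cohorts typical of
#' brain-age studies.
#'
#' @return A tibble with columns `site_id`, `age_mean`, `age_sd`,
#'   `intensity_offset`, `proportion`.
#' @export
default_site_table <- function() {
  tibble::tibble(
    site_id = 1:4,
    age_mean = c(25, 35, 50, 65),
    age_sd = c(8, 8, 8, 8),
    intensity_offset = c(0, 0.02, 0.04, 0.06),
    proportion = rep(0.25, 4)
  )
}

#' Specify a synthetic aging-brain phantom cohort
#'
#' A phantom is a pair of concentric-ellipsoid tissue maps (white-matter core,
#' gray-matter shell, central ventricle-like cavity) whose geometry encodes a
#' known chronological age: the GM shell thins with age at `atrophy_rate` and
#' the cavity radius grows at `ventricle_growth_rate`. The age-driven
#' deformation is tapered to zero over `informativeness_taper` of each axis
#' extent, so slices near the volume edge carry little age signal and
#' downstream per-slice error profiles rise toward the edges.
#'
#' @param n_subjects Number of subjects.
#' @param volume_shape Integer vector of 3 voxel dimensions.
#' @param age_range Two-element numeric, minimum and maximum age in years.
#' @param site_table Data frame with columns `site_id`, `age_mean`, `age_sd`,
#'   `intensity_offset`, `proportion` (proportions sum to 1). Ages are sampled
#'   per site from a truncated normal, so sites differ in age distribution.
#' @param sex_ratio Fraction of female subjects in `[0, 1]`.
#' @param atrophy_rate GM fractional thickness loss per year (1/year).
#' @param ventricle_growth_rate Cavity radius increase per year (voxels/year).
#' @param informativeness_taper Fraction of each axis extent (in `[0, 0.5)`)
#'   over which the age signal fades to zero toward the volume edge.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 240,
                         volume_shape = c(61, 73, 61),
                         age_range = c(18, 90),
                         site_table = default_site_table(),
                         sex_ratio = 0.5,
                         atrophy_rate = 0.006,
                         ventricle_growth_rate = 0.12,
                         informativeness_taper = 0.35,
                         noise_sd = 0.04,
                         seed = 7L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape <= 0)) {
    abort("`volume_shape` must be 3 positive integers.")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("`age_range` must satisfy min < max.")
  }
  site_table <- tibble::as_tibble(site_table)
  need <- c("site_id", "age_mean", "age_sd", "intensity_offset", "proportion")
  if (nrow(site_table) == 0) abort("`site_table` must have at least one site.")
  if (!all(need %in% names(site_table))) {
    abort(paste0("`site_table` needs columns: ", paste(need, collapse = ", ")))
  }
  if (abs(sum(site_table$proportion) - 1) > 1e-9) {
    abort("site proportions must sum to 1.")
  }
  if (atrophy_rate < 0) abort("`atrophy_rate` must be >= 0.")
  if (informativeness_taper < 0 || informativeness_taper >= 0.5) {
    abort("`informativeness_taper` must be in [0, 0.5).")
  }
  if (sex_ratio < 0 || sex_ratio > 1) abort("`sex_ratio` must be in [0, 1].")
  structure(
    list(
      n_subjects = as.integer(n_subjects), volume_shape = volume_shape,
      age_range = as.numeric(age_range), site_table = site_table,
      sex_ratio = sex_ratio, atrophy_rate = atrophy_rate,
      ventricle_growth_rate = ventricle_growth_rate,
      informativeness_taper = informativeness_taper,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$n_subjects, " subjects, shape ",
    paste(x$volume_shape, collapse = "x"), ", ages [",
    x$age_range[1], ", ", x$age_range[2], "], ",
    nrow(x$site_table), " sites, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# truncated-normal sample by rejection; falls back to clamping for extreme
# means so generation always terminates
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  for (it in 1:50) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (!length(need)) return(out)
  }
  out[need] <- pmin(pmax(rnorm(length(need), mean, sd), lo), hi)
  out
}

# per-axis edge-taper weight: 0 at the first/last voxel, rising to 1 over
# `taper` of the axis extent. Cubic ramp: the weight stays near zero for a
# good part of the taper band, so the attenuated region is not erased by
# the downstream corner crop (which removes about 20% per side).
taper_weight_1d <- function(n, taper) {
  if (taper <= 0) return(rep(1, n))
  idx <- seq_len(n) - 1
  edge_dist <- pmin(idx, n - 1 - idx)
  pmin(1, edge_dist / (taper * n))^3
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Render a single phantom volume for a given age
#'
#' Deterministic geometry given `age`; the caller supplies (or seeds) the
#' additive noise so nuisance randomness can be held fixed across ages, which
#' is how the monotone-atrophy property is verified.
#'
#' @param spec A [phantom_spec()].
#' @param age Chronological age in years.
#' @param intensity_offset Additive per-site offset applied to both channels.
#' @param noise Optional list with `gm` and `wm` arrays of `volume_shape`
#'   matching additive noise; if `NULL`, noise is drawn from the current RNG.
#' @param participant_id Identifier stored in the returned volume.
#' @return A [segmented_volume()] with `gm` and `wm` channels.
#' @export
phantom_volume <- function(spec, age, intensity_offset = 0, noise = NULL,
                           participant_id = "phantom") {
  shp <- spec$volume_shape
  half <- (shp - 1) / 2
  mean_half <- mean(half)
  a_ref <- mean(spec$age_range)

  # normalized centered coordinates per axis, and edge-taper ramps
  ax <- lapply(1:3, function(d) (seq_len(shp[d]) - 1 - half[d]) / half[d])
  tw <- lapply(1:3, function(d) taper_weight_1d(shp[d], spec$informativeness_taper))

  # voxel-wise radius and taper weight via outer products (kept as vectors)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- sqrt(r2)
  w <- outer(outer(tw[[1]], tw[[2]]), tw[[3]])

  # local effective age: tapered toward the cohort reference age at the edges
  a_loc <- a_ref + w * (age - a_ref)

  r_out <- 0.92
  th0 <- 0.28
  thick <- th0 * pmax(0.05, 1 - spec$atrophy_rate * (a_loc - spec$age_range[1]))
  r_in <- r_out - thick
  rv <- (2 + spec$ventricle_growth_rate * (a_loc - spec$age_range[1])) / mean_half

  wsoft <- 0.8 / mean_half # soft tissue boundary, ~0.8 voxels
  # saturate the tissue plateau at 1 so the volume-wise intensity maximum is
  # age-independent: min-max scaling must not leak age into edge slices
  gm <- pmin(1, 1.25 * logistic((r - r_in) / wsoft) * logistic((r_out - r) / wsoft))
  wm <- pmin(1, 1.25 * logistic((r_in - r) / wsoft) * logistic((r - rv) / wsoft))

  if (is.null(noise)) {
    noise <- list(
      gm = array(rnorm(prod(shp), 0, spec$noise_sd), shp),
      wm = array(rnorm(prod(shp), 0, spec$noise_sd), shp)
    )
  }
  gm <- pmin(pmax(gm + noise$gm, 0), 1) + intensity_offset
  wm <- pmin(pmax(wm + noise$wm, 0), 1) + intensity_offset
  dim(gm) <- shp
  dim(wm) <- shp
  segmented_volume(participant_id, gm, wm)
}

#' Generate a synthetic segmented-brain cohort
#'
#' Draws ages per site (truncated normal within `age_range`), sexes, and site
#' assignments, then renders one phantom volume per subject. Identical seeds
#' give bit-identical cohorts.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volumes` (list of [segmented_volume()]) and `records`
#'   (tibble with `participant_id`, `age`, `sex`, `site`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    st <- spec$site_table
    site_idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$proportion)
    age <- numeric(n)
    for (k in seq_len(nrow(st))) {
      sel <- site_idx == k
      if (any(sel)) {
        age[sel] <- rtruncnorm(
          sum(sel), st$age_mean[k], st$age_sd[k],
          spec$age_range[1], spec$age_range[2]
        )
      }
    }
    sex <- ifelse(runif(n) < spec$sex_ratio, "F", "M")
    ids <- sprintf("sub-%03d", seq_len(n))
    records <- tibble::tibble(
      participant_id = ids, age = age, sex = sex,
      site = st$site_id[site_idx]
    )
    volumes <- lapply(seq_len(n), function(i) {
      phantom_volume(spec, age[i],
        intensity_offset = st$intensity_offset[site_idx[i]],
        participant_id = ids[i]
      )
    })
    list(volumes = volumes, records = records)
  })
}

#' Write a cohort to disk as NIfTI + participants TSV
#'
#' One gzipped NIfTI file per subject per tissue channel plus a
#' `participants.tsv` with columns `participant_id`, `age`, `sex`, `site`.
#'
#' @param volumes List of [segmented_volume()].
#' @param records Participants tibble, same length and order.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a manifest tibble of written paths.
#' @export
write_cohort <- function(volumes, records, out_dir) {
  if (length(volumes) != nrow(records)) {
    abort("`volumes` and `records` lengths differ.")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", out_dir))
  }
  rows <- purrr::map2(volumes, seq_along(volumes), function(v, i) {
    gm_path <- file.path(out_dir, paste0(v$participant_id, "_gm.nii.gz"))
    wm_path <- file.path(out_dir, paste0(v$participant_id, "_wm.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(v$gm), gm_path)
    RNifti::writeNifti(RNifti::asNifti(v$wm), wm_path)
    tibble::tibble(
      participant_id = v$participant_id, gm = gm_path, wm = wm_path
    )
  })
  manifest <- dplyr::bind_rows(rows)
  tsv <- file.path(out_dir, "participants.tsv")
  readr::write_tsv(records, tsv)
  manifest$participants_tsv <- tsv
  invisible(manifest)
}

#' Read a participants table
#'
#' @param path Path to a tab-separated participants file with header
#'   `participant_id`, `age`, `sex`, `site`.
#' @return A tibble.
#' @export
read_participants <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      site = readr::col_integer()
    )
  )
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `*_gm.nii.gz`, `*_wm.nii.gz` and
#'   `participants.tsv`.
#' @return A list with `volumes` and `records`, as [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  records <- read_participants(file.path(dir, "participants.tsv"))
  volumes <- lapply(records$participant_id, function(id) {
    load_volume(
      file.path(dir, paste0(id, "_gm.nii.gz")),
      file.path(dir, paste0(id, "_wm.nii.gz")),
      participant_id = id
    )
  })
  list(volumes = volumes, records = records)
}
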