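#' Tissue class labels of the digital thorax phantom
#'
#' Fixed enumeration used in every label map the generator produces.
#' `active_border` is the one-voxel shell of lung parenchyma adjacent to a
#' lesion: it looks like normal parenchyma on MRI but carries the highest
#' PET tracer density among the lung classes, emulating active collagen
#' synthesis at the rim of lesions.
#'
#' @return named integer vector of class ids.
#' @export
tissue_labels <- function() {
  c(background = 0L, muscle_organ = 1L, lung_parenchyma = 2L, vessel = 3L,
    edema = 4L, fibrotic_tissue = 5L, active_border = 6L)
}

#' Default tissue signal and uptake properties
#'
#' Per-class proton density (arbitrary units), effective transverse
#' relaxation time T2* (ms), and relative PET tracer density. The MRI
#' values realise the contrast the dual-echo analysis relies on: fluid-like
#' classes (vessel, edema, muscle) have T2* much longer than the long echo
#' time and stay bright at both echoes; fibrotic tissue has T2* between the
#' two echo times and fades at the long echo; aerated parenchyma has both
#' low proton density and very short T2*. The active border carries
#' parenchyma-like MRI properties (it is invisible on MRI) but the highest
#' relative tracer density of the lung classes.
#'
#' @return tibble with columns `class`, `label`, `proton_density`,
#'   `t2_star_ms`, `pet_uptake`.
#' @export
tissue_properties <- function() {
  tibble::tibble(
    class = names(tissue_labels()),
    label = unname(tissue_labels()),
    proton_density = c(0, 80, 15, 100, 95, 70, 15),
    t2_star_ms     = c(1, 8, 0.5, 20, 15, 0.7, 0.5),
    pet_uptake     = c(0, 0.5, 0.2, 1.0, 1.5, 2.0, 8.0))
}

#' Longitudinal disease trajectory of the bleomycin phantom
#'
#' Target lesion-compartment volumes per imaging day. The defaults follow
#' the characteristic course of intratracheal bleomycin injury: an
#' inflammatory edema burden peaking at day 7, and a fibrotic tissue burden
#' building up to a day-28 peak, both shaped as gamma-like curves
#' `A * (t/m)^k * exp(k * (1 - t/m))` with mode `m`. Day 0 volumes are 0.
#' The border-uptake curve scales the relative tracer density of the
#' active-border class per day, emulating intensifying collagen synthesis
#' at the lesion rim over the four weeks.
#'
#' @param days integer imaging days; must include 0.
#' @param edema_peak_mm3 edema volume (mm^3) at its day-7 peak.
#' @param tissue_peak_mm3 fibrotic-tissue volume (mm^3) at its day-28 peak.
#' @param edema_mode,tissue_mode day of each peak.
#' @param border_uptake relative border tracer density multiplier per day
#'   (recycled); day-0 entries are irrelevant (no lesions, hence no border).
#' @param seed integer seed fixing the lesion geometry of the series.
#' @return object of class `trajectory_spec` with per-day target volumes.
#' @examples
#' tr <- trajectory_spec()
#' tr$days[which.max(tr$edema_mm3)]   # 7
#' tr$days[which.max(tr$tissue_mm3)]  # 28
#' @export
trajectory_spec <- function(days = c(0L, 7L, 14L, 21L, 28L),
                            edema_peak_mm3 = 800,
                            tissue_peak_mm3 = 500,
                            edema_mode = 7, tissue_mode = 28,
                            border_uptake = c(0, 1, 1.25, 1.5, 1.75),
                            seed = 1L) {
  days <- as.integer(days)
  if (!0L %in% days) stop("trajectory days must include day 0 (baseline)")
  gamma_curve <- function(t, peak, mode, k) {
    ifelse(t <= 0, 0, peak * (t / mode)^k * exp(k * (1 - t / mode)))
  }
  out <- structure(list(
    days = days,
    edema_mm3 = gamma_curve(days, edema_peak_mm3, edema_mode, k = 2),
    tissue_mm3 = gamma_curve(days, tissue_peak_mm3, tissue_mode, k = 3),
    border_uptake = rep_len(border_uptake, length(days)),
    seed = as.integer(seed)), class = "trajectory_spec")
  stopifnot(all(out$edema_mm3 >= 0), all(out$tissue_mm3 >= 0))
  out
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("<trajectory_spec>\n")
  print(data.frame(day = x$days, edema_mm3 = round(x$edema_mm3, 1),
                   tissue_mm3 = round(x$tissue_mm3, 1),
                   border_uptake = x$border_uptake))
  invisible(x)
}

#' Default grids of the phantom
#'
#' `default_mri_grid()` is the desk-scale simulation frame (96^3 voxels at
#' 0.6 mm, 57.6 mm field of view); `full_mri_grid()` matches the in-plane
#' acquisition geometry (58 mm field of view on a 192 matrix, ~0.302 mm).
#' `default_pet_grid()` is 0.4 mm isotropic and slightly over-covers the
#' MRI extent so that resampling onto it conserves activity.
#' @return a [grid_spec()].
#' @export
default_mri_grid <- function() grid_spec(c(96L, 96L, 96L), 0.6, 0)

#' @rdname default_mri_grid
#' @export
full_mri_grid <- function()
  grid_spec(c(192L, 192L, 96L), c(58 / 192, 58 / 192, 0.6), 0)

#' @rdname default_mri_grid
#' @param mri_grid MRI grid whose extent the PET grid must cover.
#' @export
default_pet_grid <- function(mri_grid = default_mri_grid()) {
  ext <- mri_grid$shape * mri_grid$spacing
  n <- as.integer(ceiling(ext / 0.4)) + 2L
  grid_spec(n, 0.4, origin = -0.4)
}

# world coordinates (mm) of voxel centres as three arrays
coord_arrays <- function(grid) {
  list(x = array(rep(axis_centres(grid, 1), times = prod(grid$shape[2:3])),
                 grid$shape),
       y = array(rep(rep(axis_centres(grid, 2), each = grid$shape[1]),
                     times = grid$shape[3]), grid$shape),
       z = array(rep(axis_centres(grid, 3), each = prod(grid$shape[1:2])),
                 grid$shape))
}

ellipsoid_mask <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

#' Generate a rat-thorax tissue label map for one imaging day
#'
#' Builds an ellipsoidal body with two lung fields, a small set of
#' intrapulmonary vessels, and patchy lesions whose edema and fibrotic
#' voxel counts match the trajectory's target volumes for the requested day
#' to within half a voxel volume. Lesion geometry (blob centres, radii,
#' vessels) is derived from the trajectory seed only, so maps for different
#' days of one series are spatially consistent: lesions grow and shrink in
#' place rather than jumping around. The edema component occupies the blob
#' cores and the fibrotic component the surrounding rim, emulating fibrotic
#' streaks forming around resolving inflammation. The `active_border` class
#' is the one-voxel shell (6-connectivity) of lung parenchyma adjacent to
#' any lesion voxel.
#'
#' @param grid [grid_spec()] of the map.
#' @param trajectory [trajectory_spec()].
#' @param day one of `trajectory$days`.
#' @param seed integer; together with grid, trajectory and day fully
#'   determines the map.
#' @return object of class `label_map`: list with `grid`, `labels` (integer
#'   3-D array), `day`, `seed`.
#' @export
make_label_map <- function(grid = default_mri_grid(),
                           trajectory = trajectory_spec(),
                           day = 0L, seed = trajectory$seed) {
  if (!day %in% trajectory$days)
    stop(sprintf("day %s not in trajectory; valid days: %s", day,
                 paste(trajectory$days, collapse = ", ")))
  i_day <- match(day, trajectory$days)
  vv <- voxel_volume(grid)
  n_edema <- round(trajectory$edema_mm3[i_day] / vv)
  n_tissue <- round(trajectory$tissue_mm3[i_day] / vv)

  set.seed(seed)
  co <- coord_arrays(grid)
  ext <- grid$shape * grid$spacing
  centre <- grid$origin + ext / 2
  labels <- array(tissue_labels()[["background"]], grid$shape)
  body <- ellipsoid_mask(co, centre, semi = 0.45 * ext)
  labels[body] <- tissue_labels()[["muscle_organ"]]
  lung_semi <- c(0.17, 0.19, 0.30) * ext
  lungs <- vector("list", 2)
  for (s in 1:2) {
    c_l <- centre + c((-1)^s * 0.21 * ext[1], -0.02 * ext[2], 0)
    lungs[[s]] <- ellipsoid_mask(co, c_l, lung_semi)
  }
  lung <- lungs[[1]] | lungs[[2]]
  labels[lung] <- tissue_labels()[["lung_parenchyma"]]

  # vessels: 1-3 finite cylinders per lung, fully inside the lung field
  vessel <- array(FALSE, grid$shape)
  for (s in 1:2) {
    c_l <- centre + c((-1)^s * 0.21 * ext[1], -0.02 * ext[2], 0)
    for (v in seq_len(sample(1:3, 1))) {
      dir <- rnorm(3); dir[3] <- dir[3] * 3  # roughly cranio-caudal
      dir <- dir / sqrt(sum(dir^2))
      len <- stats::runif(1, 0.5, 0.8) * lung_semi[3]
      rad <- stats::runif(1, 0.7, 1.1)
      # distance of voxel centres to the segment through c_l along dir
      px <- co$x - c_l[1]; py <- co$y - c_l[2]; pz <- co$z - c_l[3]
      t_par <- px * dir[1] + py * dir[2] + pz * dir[3]
      t_cl <- pmin(pmax(t_par, -len), len)
      d2 <- (px - t_cl * dir[1])^2 + (py - t_cl * dir[2])^2 +
        (pz - t_cl * dir[3])^2
      vessel <- vessel | (d2 <= rad^2 & lungs[[s]])
    }
  }
  labels[vessel] <- tissue_labels()[["vessel"]]

  eligible <- lung & !vessel
  n_lesion <- n_edema + n_tissue
  if (n_lesion > sum(eligible))
    stop(sprintf(
      "lesion target volume (%.0f mm^3) exceeds the available lung volume (%.0f mm^3)",
      n_lesion * vv, sum(eligible) * vv))
  if (n_lesion > 0) {
    # lesion geometry from the trajectory seed, so the blob layout is
    # shared across days of a series
    geo <- get(".Random.seed", envir = .GlobalEnv)
    set.seed(trajectory$seed)
    idx_el <- which(eligible)
    k <- sample(4:8, 1)
    ctr_idx <- sample(idx_el, k)
    radii <- stats::runif(k, 0.6, 1.6)
    score <- array(Inf, grid$shape)
    for (j in seq_len(k)) {
      cx <- co$x[ctr_idx[j]]; cy <- co$y[ctr_idx[j]]; cz <- co$z[ctr_idx[j]]
      dj <- sqrt((co$x[idx_el] - cx)^2 + (co$y[idx_el] - cy)^2 +
                   (co$z[idx_el] - cz)^2) / radii[j]
      score[idx_el] <- pmin(score[idx_el], dj)
    }
    score[idx_el] <- score[idx_el] + stats::runif(length(idx_el), 0, 0.4)
    assign(".Random.seed", geo, envir = .GlobalEnv)
    ord <- idx_el[order(score[idx_el])]
    if (n_edema > 0) labels[ord[seq_len(n_edema)]] <- tissue_labels()[["edema"]]
    if (n_tissue > 0)
      labels[ord[n_edema + seq_len(n_tissue)]] <- tissue_labels()[["fibrotic_tissue"]]
    lesion <- array(labels %in% tissue_labels()[c("edema", "fibrotic_tissue")],
                    grid$shape)
    parenchyma <- labels == tissue_labels()[["lung_parenchyma"]]
    border <- adjacent_to(parenchyma, lesion)
    labels[border] <- tissue_labels()[["active_border"]]
  }
  structure(list(grid = grid, labels = labels, day = as.integer(day),
                 seed = as.integer(seed)), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> day %d, seed %d\n", x$day, x$seed))
  counts <- table(factor(x$labels, levels = tissue_labels(),
                         labels = names(tissue_labels())))
  print(round(counts * voxel_volume(x$grid), 1))
  cat("(volumes in mm^3)\n")
  invisible(x)
}

#' Boolean mask of one or more phantom classes
#' @param map a `label_map`.
#' @param classes character vector of class names (see [tissue_labels()]).
#' @return logical array.
#' @export
class_mask <- function(map, classes) {
  ids <- tissue_labels()[classes]
  if (anyNA(ids)) stop("unknown tissue class: ",
                       paste(classes[is.na(ids)], collapse = ", "))
  array(map$labels %in% ids, dim(map$labels))
}

# The lung region as the analysis defines it: everything inside the lung
# fields, i.e. parenchyma, vessels, lesions and the active border.
lung_region_mask <- function(map)
  class_mask(map, c("lung_parenchyma", "vessel", "edema", "fibrotic_tissue",
                    "active_border"))

#' Simulate one UTE echo image from a label map
#'
#' Noise-free signal per voxel is the mono-exponential
#' `proton_density * exp(-TE / T2*)` of the voxel's tissue class.
#' Magnitude (Rician) noise is then applied:
#' `sqrt((s + sigma*N1)^2 + (sigma*N2)^2)` with independent standard
#' normal N1, N2, the magnitude-image noise model of complex-Gaussian MRI
#' data. With `noise_sigma = 0` the exact exponential model is returned.
#'
#' @param map a `label_map`.
#' @param props property table as from [tissue_properties()].
#' @param te_ms echo time in ms (> 0).
#' @param noise_sigma Rician noise scale in signal units (>= 0).
#' @param seed integer RNG seed.
#' @return numeric 3-D array of magnitude signal.
#' @export
simulate_echo <- function(map, props = tissue_properties(), te_ms,
                          noise_sigma = 0, seed = 1L) {
  stopifnot(te_ms > 0, noise_sigma >= 0)
  present <- sort(unique(as.integer(map$labels)))
  if (!all(present %in% props$label))
    stop("label map contains class ids without properties: ",
         paste(setdiff(present, props$label), collapse = ", "))
  lut <- numeric(max(props$label) + 1L)
  lut[props$label + 1L] <- props$proton_density * exp(-te_ms / props$t2_star_ms)
  s <- array(lut[as.integer(map$labels) + 1L], dim(map$labels))
  if (noise_sigma > 0) {
    set.seed(seed)
    n <- length(s)
    s <- sqrt((s + noise_sigma * rnorm(n))^2 + (noise_sigma * rnorm(n))^2)
    dim(s) <- dim(map$labels)
  }
  s
}

#' Simulate both UTE echoes
#'
#' @inheritParams simulate_echo
#' @param te_short_ms,te_long_ms the two echo times (ms); defaults 0.324
#'   and 1.0.
#' @return object of class `echo_pair`: `grid`, `te_short_ms`, `te_long_ms`,
#'   and arrays `short`, `long`.
#' @export
simulate_echo_pair <- function(map, props = tissue_properties(),
                               te_short_ms = 0.324, te_long_ms = 1.0,
                               noise_sigma = 0, seed = 1L) {
  structure(list(
    grid = map$grid, te_short_ms = te_short_ms, te_long_ms = te_long_ms,
    short = simulate_echo(map, props, te_short_ms, noise_sigma, seed),
    long = simulate_echo(map, props, te_long_ms, noise_sigma, seed + 1L)),
    class = "echo_pair")
}

#' Rician noise scale for a target signal-to-noise ratio
#'
#' SNR is referenced to the brightest tissue signal of the property table
#' (the vessel blood pool at proton density 100 by default), so `snr = 20`
#' corresponds to `sigma = 5` signal units.
#' @param snr desired ratio (> 0).
#' @param props property table.
#' @return noise sigma in signal units.
#' @export
noise_sigma_for_snr <- function(snr, props = tissue_properties()) {
  stopifnot(snr > 0)
  max(props$proton_density) / snr
}

#' Simulate a collagen-PET acquisition from a label map
#'
#' Each tissue class is assigned a relative tracer density
#' (`props$pet_uptake`, with the active border highest among lung classes).
#' Densities are converted to absolute concentration by calibrating against
#' a healthy-lung reference: the scale is chosen so that a lesion-free lung
#' of the same geometry would hold `lung_dose_fraction` of the injected
#' dose. Lesions and the active border therefore add uptake on top of that
#' reference, so diseased phantoms carry a larger lung dose fraction than
#' controls, as seen in bleomycin-challenged animals. The concentration map
#' is resampled onto the PET grid by exact volume-weighted averaging,
#' blurred with the scanner point-spread function, and Poisson-perturbed.
#'
#' @param map a `label_map`.
#' @param props property table; `pet_uptake` column is used.
#' @param pet_grid target [grid_spec()]; must cover the label-map extent.
#' @param psf_fwhm_mm Gaussian point-spread FWHM in mm (>= 0).
#' @param injected_dose_mbq injected activity (MBq, > 0).
#' @param lung_dose_fraction fraction of the dose a healthy lung of this
#'   geometry would contain (calibration reference).
#' @param count_scale detected counts per MBq of voxel activity; governs
#'   Poisson noise. `Inf` (default) disables counting noise.
#' @param border_uptake_scale multiplier on the active-border tracer
#'   density (the trajectory's `border_uptake` for the day).
#' @param delay_minutes injection-to-scan delay (min).
#' @param half_life_hours nuclide half-life; default 12.7 h (Cu-64).
#' @param seed integer RNG seed (Poisson stage).
#' @return object of class `pet_volume`: `grid`, `activity` (MBq/mL),
#'   `injected_dose_mbq`, `delay_minutes`, `half_life_hours`.
#' @export
simulate_pet <- function(map, props = tissue_properties(),
                         pet_grid = default_pet_grid(map$grid),
                         psf_fwhm_mm = 1.0, injected_dose_mbq = 35,
                         lung_dose_fraction = 0.01, count_scale = Inf,
                         border_uptake_scale = 1, delay_minutes = 60,
                         half_life_hours = 12.7, seed = 1L) {
  stopifnot(psf_fwhm_mm >= 0, injected_dose_mbq > 0, count_scale > 0,
            lung_dose_fraction > 0)
  lut <- numeric(max(props$label) + 1L)
  lut[props$label + 1L] <- props$pet_uptake
  lut[tissue_labels()[["active_border"]] + 1L] <-
    lut[tissue_labels()[["active_border"]] + 1L] * border_uptake_scale
  rel <- array(lut[as.integer(map$labels) + 1L], dim(map$labels))

  # healthy-lung reference: lesion and border voxels replaced by parenchyma
  ref_lut <- lut
  ref_lut[tissue_labels()[c("edema", "fibrotic_tissue", "active_border")] + 1L] <-
    lut[tissue_labels()[["lung_parenchyma"]] + 1L]
  ref <- array(ref_lut[as.integer(map$labels) + 1L], dim(map$labels))
  lung <- lung_region_mask(map)
  if (!any(lung)) stop("phantom has no lung region")
  vv_ml <- voxel_volume(map$grid) / 1000
  ref_total <- sum(ref[lung]) * vv_ml          # relative units * mL
  if (ref_total <= 0) {
    # degenerate property tables (e.g. tracer confined to one lesion
    # class) have no healthy-lung reference; calibrate on the actual map
    ref_total <- sum(rel[lung]) * vv_ml
  }
  if (ref_total <= 0) stop("property table assigns no lung activity")
  scale <- lung_dose_fraction * injected_dose_mbq / ref_total
  conc <- rel * scale                          # MBq/mL on the label grid

  conc <- resample_volume(conc, map$grid, pet_grid, require_cover = TRUE)
  conc <- gaussian_blur(conc, pet_grid, psf_fwhm_mm)
  if (is.finite(count_scale)) {
    set.seed(seed)
    vox_ml <- voxel_volume(pet_grid) / 1000
    lambda <- pmax(conc, 0) * vox_ml * count_scale
    counts <- rpois(length(lambda), lambda)
    conc <- array(counts / (vox_ml * count_scale), pet_grid$shape)
  }
  structure(list(grid = pet_grid, activity = conc,
                 injected_dose_mbq = injected_dose_mbq,
                 delay_minutes = delay_minutes,
                 half_life_hours = half_life_hours),
            class = "pet_volume")
}

#' Simulate a full longitudinal imaging series
#'
#' One co-registered (label map, dual-echo MRI, PET) triplet per trajectory
#' day, plus a ground-truth table of true compartment volumes and true
#' (noise-free, unblurred) compartment activities and percent injected
#' dose. All stages are seeded deterministically from the trajectory seed.
#'
#' @param trajectory [trajectory_spec()].
#' @param grid MRI/label grid.
#' @param pet_grid PET grid.
#' @param props property table.
#' @param snr MRI signal-to-noise ratio (see [noise_sigma_for_snr()]);
#'   `Inf` for noise-free echoes.
#' @param psf_fwhm_mm,count_scale,injected_dose_mbq,lung_dose_fraction
#'   passed to [simulate_pet()]. The default dose is drawn once per series
#'   from 35 +/- 5 MBq.
#' @param simulate_pet_volumes set FALSE to skip the PET stage (MRI-only
#'   series are faster).
#' @return list with `days` (list of per-day lists: `day`, `map`, `echoes`,
#'   `pet`) and `truth` (tibble of per-day ground truth).
#' @export
make_series <- function(trajectory = trajectory_spec(),
                        grid = default_mri_grid(),
                        pet_grid = default_pet_grid(grid),
                        props = tissue_properties(),
                        snr = 20, psf_fwhm_mm = 1.0, count_scale = 1e7,
                        injected_dose_mbq = NULL, lung_dose_fraction = 0.01,
                        simulate_pet_volumes = TRUE) {
  sigma <- if (is.finite(snr)) noise_sigma_for_snr(snr, props) else 0
  if (is.null(injected_dose_mbq)) {
    set.seed(derive_seed(trajectory$seed, "dose"))
    injected_dose_mbq <- stats::runif(1, 30, 40)
  }
  vv <- voxel_volume(grid)
  vv_ml <- vv / 1000
  days <- vector("list", length(trajectory$days))
  truth <- vector("list", length(trajectory$days))
  for (i in seq_along(trajectory$days)) {
    d <- trajectory$days[i]
    map <- make_label_map(grid, trajectory, d, seed = trajectory$seed)
    echoes <- simulate_echo_pair(map, props, noise_sigma = sigma,
                                 seed = derive_seed(trajectory$seed, "mri", d))
    pet <- NULL
    lut <- numeric(max(props$label) + 1L)
    lut[props$label + 1L] <- props$pet_uptake
    lut[tissue_labels()[["active_border"]] + 1L] <-
      lut[tissue_labels()[["active_border"]] + 1L] * trajectory$border_uptake[i]
    ref_lut <- lut
    ref_lut[tissue_labels()[c("edema", "fibrotic_tissue", "active_border")] + 1L] <-
      lut[tissue_labels()[["lung_parenchyma"]] + 1L]
    lung <- lung_region_mask(map)
    ref_total <- sum(array(ref_lut[as.integer(map$labels) + 1L],
                           dim(map$labels))[lung]) * vv_ml
    scale <- lung_dose_fraction * injected_dose_mbq / ref_total
    if (simulate_pet_volumes) {
      pet <- simulate_pet(map, props, pet_grid, psf_fwhm_mm,
                          injected_dose_mbq, lung_dose_fraction, count_scale,
                          border_uptake_scale = trajectory$border_uptake[i],
                          seed = derive_seed(trajectory$seed, "pet", d))
    }
    cls <- function(cl) sum(class_mask(map, cl))
    act <- function(cl) {
      ids <- tissue_labels()[cl]
      sum(lut[as.integer(map$labels[map$labels %in% ids]) + 1L]) * vv_ml * scale
    }
    truth[[i]] <- tibble::tibble(
      day = d,
      lung_volume_ml = sum(lung) * vv_ml,
      edema_mm3 = cls("edema") * vv,
      tissue_mm3 = cls("fibrotic_tissue") * vv,
      border_mm3 = cls("active_border") * vv,
      vessel_mm3 = cls("vessel") * vv,
      lung_activity_mbq = act(c("lung_parenchyma", "vessel", "edema",
                                "fibrotic_tissue", "active_border")),
      edema_activity_mbq = act("edema"),
      tissue_activity_mbq = act("fibrotic_tissue"),
      border_activity_mbq = act("active_border"),
      injected_dose_mbq = injected_dose_mbq)
    days[[i]] <- list(day = d, map = map, echoes = echoes, pet = pet)
  }
  truth <- dplyr::bind_rows(truth)
  truth$lung_percent_id <- 100 * truth$lung_activity_mbq / truth$injected_dose_mbq
  list(days = days, truth = truth)
}

#' Derive a child RNG seed from a parent seed and stage tags
#'
#' Stable small-integer derivation so that every stage of a pipeline run is
#' individually reproducible from the single top-level seed.
#' @param seed parent integer seed.
#' @param ... stage tags (characters or numbers).
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tags)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}
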