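#' Seeded synthetic cohorts with planted group differences
#'
#' The generator emulates the structure of a neoadjuvant-chemotherapy
#' cohort: per patient, a tile-resolution tissue-segmentation label map
#' over {excluded, tumor, stroma, necrosis, iTIL, sTIL}, clinical
#' covariates (ER/PR status and percentage, HER2/CEP17 ratio) and the
#' outcome pair (pCR, residual infiltration size). Group differences are
#' planted on the stromal-lymphocyte morphology — patients achieving pCR
#' carry more and larger sTIL components — and optionally on PR
#' positivity, so every downstream stage can be validated against known
#' ground truth.
#'
#' @name synthetic_data
NULL

#' Cohort generation configuration
#'
#' @param n_patients Number of patients (>= 2).
#' @param pcr_fraction Proportion achieving pathological complete response;
#'   when strictly inside (0, 1) both outcome groups are guaranteed
#'   non-empty. Default 36/85, the pCR rate of a typical HER2+ training
#'   cohort.
#' @param grid_height,grid_width Tile-grid dimensions; default 48 x 48,
#'   the scale of a core-needle-biopsy slide at tile resolution.
#' @param effect_size Standardized mean shift planted on sTIL component
#'   count and component area between outcome groups; default 1.5.
#' @param clinical_effect Log-odds shift of PR positivity for the pCR
#'   group; default 1.
#' @param seed Integer random seed; the same config and seed reproduce the
#'   cohort bit for bit.
#' @param ris_scale Median residual infiltration size (cm) for non-pCR
#'   patients; default 1.35 cm.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 85L, pcr_fraction = 36 / 85,
                          grid_height = 48L, grid_width = 48L,
                          effect_size = 1.5, clinical_effect = 1,
                          seed = 1L, ris_scale = 1.35) {
  if (n_patients < 2L) stop("n_patients must be at least 2")
  if (pcr_fraction < 0 || pcr_fraction > 1)
    stop("pcr_fraction must lie in [0, 1]")
  if (grid_height < 8L || grid_width < 8L)
    stop("grid dimensions must be positive (at least 8 tiles)")
  if (ris_scale <= 0) stop("ris_scale must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 pcr_fraction = pcr_fraction,
                 grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 effect_size = effect_size,
                 clinical_effect = clinical_effect,
                 seed = as.integer(seed),
                 ris_scale = ris_scale),
            class = "cohort_config")
}

#' Planted distribution parameters of the generator
#'
#' The morphology planted on sTILs, with `effect_size` acting as the
#' slide-level standardized shift of each planted descriptor: per slide
#' the component count is drawn from
#' `round(N(count_mean + pcr * effect_size * count_sd, count_sd))`, a
#' slide-level area location from
#' `N(area_mean + pcr * effect_size * area_sd_between, area_sd_between)`,
#' and each component's target area (tiles) around that location with
#' within-slide spread `area_sd_within`. Layout
#' fractions: `excluded` of the whole grid, then `tumor_of_tissue` of the
#' remaining cells seed the tumor branch (tumor + necrosis + iTIL) and the
#' rest the stromal branch (stroma + sTIL).
#'
#' @return Named list of constants used by [generate_cohort()].
#' @export
planted_params <- function() {
  list(count_mean = 8, count_sd = 2,
       area_mean = 8, area_sd_between = 1.5, area_sd_within = 2,
       excluded_fraction = 0.08, tumor_of_tissue = 0.40,
       itil_count_mean = 3, itil_count_sd = 1, itil_area = 6,
       necrosis_blobs = 2, necrosis_area = 10,
       er_rate = 0.8, pr_base_logodds = stats::qlogis(0.6),
       her2_log_median = log(3.1), her2_log_sd = 0.45,
       ris_log_sd = 0.6, ris_burden_rho = 0.4)
}

# smoothed Gaussian random field via row/column band-kernel smoothing
smooth_field <- function(h, w, scale = 4) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-(d / scale)^2 / 2)
    k / rowSums(k)
  }
  band(h) %*% matrix(stats::rnorm(h * w), h, w) %*% t(band(w))
}

dilate8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    rt <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    ct <- max(1, 1 - dc):min(w, w - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

# grow a 4-connected blob of (up to) `target` cells inside `allowed`
grow_blob <- function(allowed, target) {
  h <- nrow(allowed); w <- ncol(allowed)
  starts <- which(allowed)
  if (length(starts) == 0L || target < 1L) return(integer(0L))
  start <- if (length(starts) == 1L) starts else sample(starts, 1L)
  cells <- start
  in_set <- logical(h * w); in_set[start] <- TRUE
  frontier <- integer(0L)
  add_nbrs <- function(idx, frontier) {
    r <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    for (k in 1:4) {
      rr <- r + c(-1L, 1L, 0L, 0L)[k]; ccn <- cc + c(0L, 0L, -1L, 1L)[k]
      if (rr >= 1L && rr <= h && ccn >= 1L && ccn <= w) {
        j <- (ccn - 1L) * h + rr
        if (allowed[j] && !in_set[j]) frontier <- c(frontier, j)
      }
    }
    frontier
  }
  frontier <- add_nbrs(start, frontier)
  while (length(cells) < target && length(frontier) > 0L) {
    pick <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    frontier <- frontier[frontier != pick]
    if (in_set[pick]) next
    in_set[pick] <- TRUE
    cells <- c(cells, pick)
    frontier <- add_nbrs(pick, frontier)
  }
  cells
}

# place `k` mutually non-adjacent blobs with given target areas inside
# `region`; returns a logical mask of the placed cells
place_blobs <- function(region, k, targets) {
  placed <- matrix(FALSE, nrow(region), ncol(region))
  if (k < 1L) return(placed)
  for (i in seq_len(k)) {
    allowed <- region & !dilate8(placed)
    cells <- grow_blob(allowed, targets[i])
    if (length(cells) == 0L) next
    placed[cells] <- TRUE
  }
  placed
}

generate_ts_labels <- function(config, pcr) {
  pp <- planted_params()
  h <- config$grid_height; w <- config$grid_width
  # blank / artifact regions to be excluded by preprocessing
  ef <- smooth_field(h, w, scale = 5)
  excluded <- ef > stats::quantile(ef, 1 - pp$excluded_fraction)
  # tumor nests vs stroma from an independent blob process
  tf <- smooth_field(h, w, scale = 5)
  tissue_vals <- tf[!excluded]
  tumor <- !excluded &
    tf > stats::quantile(tissue_vals, 1 - pp$tumor_of_tissue)
  stroma <- !excluded & !tumor
  lab <- matrix(2L, h, w)
  lab[tumor] <- 1L
  lab[excluded] <- 0L
  # necrosis inside tumor (no group effect); mimics iTILs morphologically
  nec <- place_blobs(tumor, pp$necrosis_blobs,
                     rep(pp$necrosis_area, pp$necrosis_blobs))
  lab[nec] <- 3L
  # iTILs inside remaining tumor (no group effect)
  k_i <- max(0L, round(stats::rnorm(1, pp$itil_count_mean, pp$itil_count_sd)))
  itil <- place_blobs(tumor & !nec, k_i, rep(pp$itil_area, max(k_i, 1L)))
  lab[itil] <- 4L
  # sTILs inside stroma: planted group difference in count and area
  shift <- if (pcr) config$effect_size else 0
  k_s <- max(0L, round(stats::rnorm(1, pp$count_mean + shift * pp$count_sd,
                                    pp$count_sd)))
  area_loc <- stats::rnorm(1, pp$area_mean + shift * pp$area_sd_between,
                           pp$area_sd_between)
  areas <- pmax(3L, round(stats::rnorm(max(k_s, 1L), area_loc,
                                       pp$area_sd_within)))
  stil <- place_blobs(stroma, k_s, areas)
  lab[stil] <- 5L
  list(labels = lab, k_stil = k_s, stil_cells = sum(stil))
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return List of `synthetic_patient` objects (fields `patient_id`, `ts`,
#'   `er`, `er_pct`, `pr`, `pr_pct`, `her2_cep17`, `pcr`, `ris_cm`), with
#'   the config attached as attribute `config`. Patients achieving pCR have
#'   `ris_cm = 0`; for the rest, RIS is lognormal with median `ris_scale`,
#'   negatively coupled to the planted sTIL burden.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  pp <- planted_params()
  n <- config$n_patients
  withr::with_seed(config$seed, {
    n_pcr <- round(n * config$pcr_fraction)
    if (config$pcr_fraction > 0 && config$pcr_fraction < 1)
      n_pcr <- min(max(n_pcr, 1L), n - 1L)
    pcr <- sample(rep(c(1L, 0L), c(n_pcr, n - n_pcr)))
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- sprintf("P%03d", i)
      g <- generate_ts_labels(config, pcr[i] == 1L)
      er <- stats::rbinom(1, 1, pp$er_rate)
      pr <- stats::rbinom(1, 1, stats::plogis(
        pp$pr_base_logodds + config$clinical_effect * pcr[i]))
      er_pct <- if (er == 1L) stats::runif(1, 10, 100) else 0
      pr_pct <- if (pr == 1L) stats::runif(1, 10, 100) else 0
      her2 <- exp(stats::rnorm(1, pp$her2_log_median, pp$her2_log_sd))
      if (pcr[i] == 1L) {
        ris <- 0
      } else {
        z_burden <- (g$k_stil - pp$count_mean) / pp$count_sd
        z <- -pp$ris_burden_rho * z_burden +
          sqrt(1 - pp$ris_burden_rho^2) * stats::rnorm(1)
        ris <- config$ris_scale * exp(pp$ris_log_sd * z)
      }
      patients[[i]] <- structure(
        list(patient_id = pid,
             ts = ts_image(g$labels, pid),
             er = er, er_pct = er_pct, pr = pr, pr_pct = pr_pct,
             her2_cep17 = her2, pcr = pcr[i], ris_cm = ris,
             planted_k_stil = g$k_stil),
        class = "synthetic_patient")
    }
  })
  structure(patients, config = config, class = "synthetic_cohort")
}

#' Clinical table of a cohort
#'
#' @param patients A cohort from [generate_cohort()] or [read_cohort()].
#' @return Data frame with columns `patient_id`, `er`, `er_pct`, `pr`,
#'   `pr_pct`, `her2_cep17`, `pcr`, `ris_cm`.
#' @export
clinical_table <- function(patients) {
  data.frame(
    patient_id = vapply(patients, function(p) p$patient_id, ""),
    er = vapply(patients, function(p) p$er, 0),
    er_pct = vapply(patients, function(p) p$er_pct, 0),
    pr = vapply(patients, function(p) p$pr, 0),
    pr_pct = vapply(patients, function(p) p$pr_pct, 0),
    her2_cep17 = vapply(patients, function(p) p$her2_cep17, 0),
    pcr = vapply(patients, function(p) p$pcr, 0),
    ris_cm = vapply(patients, function(p) p$ris_cm, 0),
    stringsAsFactors = FALSE)
}

#' Render a synthetic RGB slide from a TS-image
#'
#' Each tile becomes a square of `tile_size` pixels whose mean color
#' encodes the compartment: tumor-branch tiles are dark in the green
#' channel, necrotic tiles have a red-over-blue excess, lymphocyte tiles a
#' blue-over-red excess, and excluded tiles are near-white background.
#' [reference_classifiers()] inverts this encoding, so the classification
#' cascade can reconstruct the label grid exactly.
#'
#' @param ts A `ts_image`.
#' @param tile_size Rendered tile side in pixels; default 8 (kept small for
#'   test-scale slides; real slides use 175).
#' @param noise_sd Per-pixel Gaussian noise, 8-bit scale; default 4.
#' @return Numeric array `height x width x 3` in `[0, 1]`.
#' @export
render_slide <- function(ts, tile_size = 8L, noise_sd = 4) {
  stopifnot(inherits(ts, "ts_image"))
  cols <- rbind(excluded = c(245, 245, 245),
                tumor = c(140, 70, 140),
                stroma = c(190, 105, 170),
                necrosis = c(100, 70, 40),
                itil = c(110, 70, 170),
                stil = c(160, 105, 205))
  h <- nrow(ts$labels); w <- ncol(ts$labels)
  img <- array(0, c(h * tile_size, w * tile_size, 3L))
  for (ch in 1:3) {
    base <- matrix(cols[ts$labels + 1L, ch], h, w)
    up <- base[rep(seq_len(h), each = tile_size),
               rep(seq_len(w), each = tile_size)]
    img[, , ch] <- up + stats::rnorm(length(up), 0, noise_sd)
  }
  pmin(pmax(img / 255, 0), 1)
}

#' Simulate a feature-level cohort for selection benchmarking
#'
#' Draws a patients-by-features Gaussian matrix in which a known subset of
#' columns carries a standardized mean shift between outcome groups; used
#' to measure LASSO recovery of planted informative features.
#'
#' @param n Number of patients.
#' @param n_features Total features; default 51 (46 morphological + 5
#'   clinical).
#' @param n_informative Number of planted informative features; default 3.
#' @param effect Standardized mean shift; default 1.5.
#' @param pcr_fraction Class-1 proportion; default 0.5.
#' @param seed Random seed.
#' @return List with `x` (matrix with named columns), `y` (0/1 vector),
#'   `informative` (column names of the planted features).
#' @export
simulate_feature_cohort <- function(n = 200L, n_features = 51L,
                                    n_informative = 3L, effect = 1.5,
                                    pcr_fraction = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    n1 <- round(n * pcr_fraction)
    y <- sample(rep(c(1L, 0L), c(n1, n - n1)))
    x <- matrix(stats::rnorm(n * n_features), n, n_features)
    colnames(x) <- sprintf("f%02d", seq_len(n_features))
    informative <- colnames(x)[seq_len(n_informative)]
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
      effect * y
    list(x = x, y = y, informative = informative)
  })
}

#' Write a cohort to disk / read it back
#'
#' Writes one grayscale label-grid PNG (plus JSON sidecar) per patient, a
#' clinical CSV (`clinical.csv`) and a JSON manifest (`manifest.json`)
#' echoing the generating configuration. The writer is deterministic:
#' writing the same cohort twice produces byte-identical files.
#'
#' @param patients Cohort list.
#' @param directory Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(patients, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  files <- character(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    files[i] <- paste0(p$patient_id, ".png")
    write_ts_image(p$ts, file.path(directory, files[i]))
  }
  utils::write.csv(clinical_table(patients),
                   file.path(directory, "clinical.csv"), row.names = FALSE)
  config <- attr(patients, "config")
  manifest <- list(
    n_patients = length(patients),
    label_codes = as.list(ts_codes()),
    ts_images = as.list(files),
    clinical = "clinical.csv")
  if (!is.null(config)) manifest$config <- unclass(config)
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mpath)
  clin <- utils::read.csv(file.path(directory, manifest$clinical),
                          stringsAsFactors = FALSE)
  patients <- vector("list", nrow(clin))
  for (i in seq_len(nrow(clin))) {
    ts <- read_ts_image(file.path(directory, manifest$ts_images[[i]]))
    patients[[i]] <- structure(
      c(list(patient_id = clin$patient_id[i], ts = ts),
        as.list(clin[i, c("er", "er_pct", "pr", "pr_pct", "her2_cep17",
                          "pcr", "ris_cm")])),
      class = "synthetic_patient")
  }
  cfg <- manifest$config
  if (!is.null(cfg)) cfg <- do.call(cohort_config, cfg)
  structure(patients, config = cfg, class = "synthetic_cohort")
}
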