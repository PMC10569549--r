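#' @useDynLib hivemorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rlnorm runif
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Species presets for cohort simulation
#'
#' Mean neuropil volumes and coefficients of variation used by the cohort
#' sampler. The honeybee preset uses the published summary volumes of
#' N = 110 forager honey bee brains (AL 0.0284, MB 0.134, CX 0.0033,
#' ME 0.146, LO 0.045, OTH 0.166 mm^3, with their standard deviations).
#' The bumblebee preset is a stylized variant with the same central volumes
#' but 1.6x the coefficients of variation, reflecting the substantially
#' larger inter-individual variability reported for bumblebee workers
#' (44-85% neuropil volume variation versus 29-52% in honey bee foragers).
#'
#' @param species `"honeybee"` or `"bumblebee"`.
#' @return list with named numeric vectors `means` (mm^3) and `cv`.
#' @export
species_preset <- function(species = c("honeybee", "bumblebee")) {
  species <- match.arg(species)
  means <- c(AL = 0.0284, MB = 0.134, CX = 0.0033,
             ME = 0.146, LO = 0.045, OTH = 0.166)
  sds <- c(AL = 0.0033, MB = 0.011, CX = 0.0004,
           ME = 0.011, LO = 0.004, OTH = 0.019)
  cv <- sds / means
  if (species == "bumblebee") cv <- cv * 1.6
  list(species = species, means = means, cv = cv)
}

#' Hive plans matching the two study designs
#'
#' `honeybee_hive_plan()`: 110 specimens in 9 hives from two apiary
#' populations (population A: 6 hives with 9/11/18/19/17/16 bees;
#' population B: 3 hives with 6/11/3 bees).
#' `bumblebee_hive_plan()`: 77 specimens in 4 commercial colonies
#' (18/20/21/18), a single population.
#'
#' @return data.frame with columns `hive`, `population`, `n`.
#' @export
honeybee_hive_plan <- function() {
  data.frame(
    hive = paste0("H", 1:9),
    population = c(rep("A", 6), rep("B", 3)),
    n = c(9L, 11L, 18L, 19L, 17L, 16L, 6L, 11L, 3L),
    stringsAsFactors = FALSE
  )
}

#' @rdname honeybee_hive_plan
#' @export
bumblebee_hive_plan <- function() {
  data.frame(
    hive = paste0("H", 1:4),
    population = "A",
    n = c(18L, 20L, 21L, 18L),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic phantom generator
#'
#' Controls both the statistical cohort draw (volumes, hive effects,
#' lateralization) and the voxel rendering (geometry, contrast, noise).
#'
#' Volumes are drawn lognormally: each specimen's neuropil volume is the
#' preset mean times a shared within-hive lognormal multiplier
#' (log-sd `hive_sigma`) times an individual lognormal deviate whose
#' coefficient of variation is `neuropil_cv`. Paired neuropils are split
#' into left and right sides through the log left/right ratio
#' `log(L/R) ~ Normal(log(1 - delta), lateral_noise_cv^2)`, so `delta` is
#' the expected fractional left deficit.
#'
#' @param grid_shape voxels per axis (z, y, x); default desk grid 96^3.
#' @param spacing_mm isotropic voxel edge (mm); default 0.0054 as in the
#'   source micro-CT protocol. At desk grid sizes the rendered volumes are
#'   proportionally rescaled so the structures fit the grid.
#' @param neuropil_means named vector, target mean volume (mm^3) per neuropil.
#' @param neuropil_cv named vector, marginal coefficient of variation per
#'   neuropil (the shared size factor is subtracted internally, so these are
#'   the CVs a large cohort exhibits per neuropil).
#' @param size_cv coefficient of variation of a per-specimen lognormal size
#'   factor shared by all neuropils. It induces the positive inter-neuropil
#'   correlations and near-isometric part-whole scaling seen in real
#'   cohorts; the default 0.06 reproduces a total-brain CV of about 7%
#'   under the honeybee preset.
#' @param lateral_delta named vector of fractional left deficits for paired
#'   neuropils (names among AL, MB, ME, LO, or OL which expands to ME and LO).
#' @param lateral_noise_cv s.d. of the per-specimen log left/right ratio.
#' @param hive_sigma log-sd of the hive-level lognormal volume multiplier.
#' @param p_merge_mb probability that the two mushroom-body masses touch
#'   across the midline (as happens in real segmentations).
#' @param tissue_gray named vector of mean intensities, one per label plus
#'   `background`.
#' @param noise_sd additive Gaussian intensity noise s.d.
#' @param blur_sigma Gaussian smoothing of rendered intensities (voxels).
#' @param fill_fraction fraction of grid voxels occupied by the brain.
#' @param seed integer RNG seed.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96, 96, 96),
                           spacing_mm = 0.0054,
                           neuropil_means = species_preset("honeybee")$means,
                           neuropil_cv = species_preset("honeybee")$cv,
                           size_cv = 0.06,
                           lateral_delta = c(AL = 0, MB = 0, ME = 0, LO = 0),
                           lateral_noise_cv = 0.03,
                           hive_sigma = 0.02,
                           p_merge_mb = 0.2,
                           tissue_gray = c(background = 50, AL = 110, MB = 130,
                                           CX = 150, ME = 170, LO = 190,
                                           OTH = 210),
                           noise_sd = 8,
                           blur_sigma = 0.7,
                           fill_fraction = 0.22,
                           seed = 1L) {
  nps <- c("AL", "MB", "CX", "ME", "LO", "OTH")
  if (!all(nps %in% names(neuropil_means)))
    stop("phantom_params: neuropil_means must name all of ",
         paste(nps, collapse = ", "))
  if (!all(nps %in% names(neuropil_cv)))
    stop("phantom_params: neuropil_cv must name all neuropils")
  if (any(neuropil_cv < 0)) stop("phantom_params: all CVs must be >= 0")
  if (size_cv < 0) stop("phantom_params: size_cv must be >= 0")
  if (lateral_noise_cv < 0) stop("phantom_params: lateral_noise_cv must be >= 0")
  if (hive_sigma < 0) stop("phantom_params: hive_sigma must be >= 0")
  ld <- c(AL = 0, MB = 0, ME = 0, LO = 0)
  if (length(lateral_delta)) {
    if (is.null(names(lateral_delta)))
      stop("phantom_params: lateral_delta must be named")
    if ("OL" %in% names(lateral_delta)) {
      ld[c("ME", "LO")] <- lateral_delta[["OL"]]
      lateral_delta <- lateral_delta[names(lateral_delta) != "OL"]
    }
    ld[names(lateral_delta)] <- lateral_delta
  }
  if (any(ld < 0 | ld >= 1))
    stop("phantom_params: lateral deficits must satisfy 0 <= delta < 1")
  if (p_merge_mb < 0 || p_merge_mb > 1)
    stop("phantom_params: p_merge_mb must be in [0, 1]")
  if (!all(c("background", nps) %in% names(tissue_gray)))
    stop("phantom_params: tissue_gray must name background and all neuropils")
  structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         neuropil_means = neuropil_means[nps], neuropil_cv = neuropil_cv[nps],
         size_cv = size_cv, lateral_delta = ld, lateral_noise_cv = lateral_noise_cv,
         hive_sigma = hive_sigma, p_merge_mb = p_merge_mb,
         tissue_gray = tissue_gray, noise_sd = noise_sd,
         blur_sigma = blur_sigma, fill_fraction = fill_fraction,
         seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Draw a synthetic specimen cohort
#'
#' Samples per-specimen neuropil volumes (and left/right splits of paired
#' neuropils) with the hive/population structure given by `hive_plan`,
#' without rendering any voxel data. Reproducible given the seed.
#'
#' @param params a [phantom_params()] object.
#' @param n_specimens total number of specimens; must equal `sum(hive_plan$n)`.
#' @param hive_plan data.frame with columns `hive`, `population`, `n`
#'   (see [honeybee_hive_plan()]), or a named integer vector hive -> count
#'   (single population "A").
#' @param species species tag recorded in the cohort.
#' @param seed optional seed overriding `params$seed`.
#' @return A `cohort_spec` data.frame, one row per specimen, with absolute
#'   volumes per neuropil, left/right volumes for paired neuropils, the
#'   drawn mushroom-body merge indicator, and the derived total.
#' @export
sample_cohort <- function(params, n_specimens = NULL, hive_plan = NULL,
                          species = "honeybee", seed = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  if (is.null(hive_plan)) hive_plan <- honeybee_hive_plan()
  if (!is.data.frame(hive_plan)) {
    if (is.null(names(hive_plan)) || length(hive_plan) == 0)
      stop("sample_cohort: hive_plan must be non-empty and named")
    hive_plan <- data.frame(hive = names(hive_plan), population = "A",
                            n = as.integer(hive_plan),
                            stringsAsFactors = FALSE)
  }
  if (nrow(hive_plan) == 0 || sum(hive_plan$n) == 0)
    stop("sample_cohort: hive_plan is empty")
  if (is.null(n_specimens)) n_specimens <- sum(hive_plan$n)
  if (n_specimens != sum(hive_plan$n))
    stop("sample_cohort: n_specimens (", n_specimens,
         ") must equal sum of hive_plan counts (", sum(hive_plan$n), ")")
  if (is.null(seed)) seed <- params$seed
  nps <- names(params$neuropil_means)
  paired <- c("AL", "MB", "ME", "LO")

  with_seed(seed, {
    hive_mult <- exp(rnorm(nrow(hive_plan), -params$hive_sigma^2 / 2,
                           params$hive_sigma))
    names(hive_mult) <- hive_plan$hive
    # log-scale variance split: shared specimen size factor + residual noise,
    # keeping each neuropil's marginal CV at the requested value
    sig_tot <- sqrt(log(1 + params$neuropil_cv^2))
    sig_sz <- sqrt(log(1 + params$size_cv^2))
    sig_res <- sqrt(pmax(sig_tot^2 - sig_sz^2, 0))
    sig_shared <- pmin(sig_tot, sig_sz)   # capped when a CV is below size_cv
    rows <- vector("list", n_specimens)
    idx <- 1L
    for (h in seq_len(nrow(hive_plan))) {
      for (b in seq_len(hive_plan$n[h])) {
        z_size <- rnorm(1)
        vols <- params$neuropil_means * hive_mult[h] *
          exp(sig_shared * z_size - sig_shared^2 / 2) *
          exp(rnorm(length(nps), -sig_res^2 / 2, sig_res))
        names(vols) <- nps
        rec <- list(specimen = sprintf("%s_%03d", species, idx),
                    species = species,
                    population = hive_plan$population[h],
                    hive = hive_plan$hive[h])
        for (r in nps) rec[[r]] <- unname(vols[r])
        for (r in paired) {
          delta <- params$lateral_delta[[r]]
          lr <- exp(rnorm(1, log(1 - delta), params$lateral_noise_cv))
          rec[[paste0(r, "_left")]] <- unname(vols[r] * lr / (1 + lr))
          rec[[paste0(r, "_right")]] <- unname(vols[r] / (1 + lr))
        }
        rec$merge_mb <- runif(1) < params$p_merge_mb
        rec$total <- sum(vols)
        rows[[idx]] <- rec
        idx <- idx + 1L
      }
    }
    cohort <- do.call(rbind, lapply(rows, as.data.frame,
                                    stringsAsFactors = FALSE))
    attr(cohort, "params") <- params
    class(cohort) <- c("cohort_spec", class(cohort))
    cohort
  })
}

# --- rendering ---------------------------------------------------------------

# Anatomically inspired layout on the normalized (z, y, x) grid in [0, 1]:
# paired AL anterior (low y), paired MB dorsal (high z) flanking the midline,
# CX small and central, ME/LO lateral, OTH a central mass. `ratio` gives the
# per-axis semi-axis multipliers of each ellipsoid.
phantom_layout <- function() {
  L <- list(
    list(name = "OTH", side = NA, center = c(0.46, 0.60, 0.50), ratio = c(0.85, 0.80, 1.35)),
    list(name = "AL", side = "left", center = c(0.36, 0.18, 0.34), ratio = c(1, 1, 1)),
    list(name = "AL", side = "right", center = c(0.36, 0.18, 0.66), ratio = c(1, 1, 1)),
    list(name = "MB", side = "left", center = c(0.76, 0.42, 0.36), ratio = c(0.8, 0.95, 1)),
    list(name = "MB", side = "right", center = c(0.76, 0.42, 0.64), ratio = c(0.8, 0.95, 1)),
    list(name = "CX", side = NA, center = c(0.70, 0.70, 0.50), ratio = c(1, 1, 1)),
    list(name = "ME", side = "left", center = c(0.50, 0.55, 0.135), ratio = c(1.45, 1.05, 0.62)),
    list(name = "ME", side = "right", center = c(0.50, 0.55, 0.865), ratio = c(1.45, 1.05, 0.62)),
    list(name = "LO", side = "left", center = c(0.50, 0.52, 0.315), ratio = c(1.15, 0.9, 0.55)),
    list(name = "LO", side = "right", center = c(0.50, 0.52, 0.685), ratio = c(1.15, 0.9, 0.55))
  )
  L
}

# Separable Gaussian blur with reflect padding; sigma in voxels.
gauss_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  blur_axis1 <- function(a) {
    n <- dim(a)[1]
    idx <- outer(seq_len(n), -rad:rad, `+`)
    idx[idx < 1] <- 1 - idx[idx < 1]            # reflect, edge duplicated
    idx[idx > n] <- 2 * n + 1 - idx[idx > n]
    K <- matrix(0, n, n)
    for (j in seq_along(k)) K[cbind(seq_len(n), idx[, j])] <-
        K[cbind(seq_len(n), idx[, j])] + k[j]
    array(K %*% matrix(a, n), dim(a))
  }
  arr <- blur_axis1(arr)
  arr <- aperm(blur_axis1(aperm(arr, c(2, 1, 3))), c(2, 1, 3))
  arr <- aperm(blur_axis1(aperm(arr, c(3, 2, 1))), c(3, 2, 1))
  arr
}

#' Render one specimen as an image/label phantom pair
#'
#' Rasterizes six neuropil classes as smooth ellipsoidal bodies in
#' anatomically inspired positions, scaled so that the relative volumes of
#' the structures match the specimen's drawn volumes and the brain fills
#' `fill_fraction` of the grid. The label volume is the exact rasterization;
#' the image is a tissue-intensity lookup followed by Gaussian blur and
#' additive Gaussian noise. Rasterization quantizes the targets, so the
#' voxel-true achieved volumes are returned alongside.
#'
#' @param spec one row of a [sample_cohort()] result (a data.frame row).
#' @param params a [phantom_params()] object.
#' @param seed optional RNG seed for the intensity noise (defaults to
#'   `params$seed` combined with the specimen index).
#' @return list with elements `image` ([volume3d()]), `labels`
#'   ([label_volume()]), `achieved` (named voxel-true volumes, mm^3),
#'   `sides` (achieved left/right voxel counts per paired neuropil) and
#'   `merged_mb` (whether the MB was rendered merged).
#' @export
render_phantom <- function(spec, params, seed = NULL) {
  stopifnot(inherits(params, "phantom_params"), nrow(spec) == 1)
  g <- params$grid_shape
  nvox <- prod(g)
  spacing <- params$spacing_mm
  nps <- c("AL", "MB", "CX", "ME", "LO", "OTH")
  lab_ids <- c(AL = 1L, MB = 2L, CX = 3L, ME = 4L, LO = 5L, OTH = 6L)

  # voxel budget and per-structure voxel targets (relative volumes preserved)
  budget <- params$fill_fraction * nvox
  tot <- sum(vapply(nps, function(r) spec[[r]], numeric(1)))

  layout <- phantom_layout()
  merged <- isTRUE(spec$merge_mb)
  targets <- vapply(layout, function(st) {
    v <- if (is.na(st$side)) spec[[st$name]]
         else spec[[paste0(st$name, "_", st$side)]]
    v / tot * budget
  }, numeric(1))

  render_once <- function(n_targets) {
    lab <- integer(nvox)
    inst <- integer(nvox)
    bestF <- rep(Inf, nvox)
    for (s_i in seq_along(layout)) {
      st <- layout[[s_i]]
      r_name <- st$name
      rad <- (3 * n_targets[s_i] / (4 * pi * prod(st$ratio)))^(1 / 3)
      center <- st$center * (g - 1) + 1
      if (r_name == "MB" && merged) {
        # pull both bodies to the midline so that they just overlap
        mid_x <- (g[3] + 1) / 2
        off <- 0.85 * rad * st$ratio[3]
        center[3] <- if (st$side == "left") mid_x - off else mid_x + off
      }
      semi <- rad * st$ratio
      lo <- pmax(1, floor(center - semi))
      hi <- pmin(g, ceiling(center + semi))
      if (any(center - semi < 0.5) || any(center + semi > g + 0.5)) {
        if (!(r_name == "MB" && merged))
          stop("render_phantom: structure ", r_name,
               if (!is.na(st$side)) paste0(" (", st$side, ")") else "",
               " overflows the grid; increase grid_shape or lower fill_fraction")
      }
      zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
      fz <- ((zi - center[1]) / semi[1])^2
      fy <- ((yi - center[2]) / semi[2])^2
      fx <- ((xi - center[3]) / semi[3])^2
      F <- outer(outer(fz, fy, `+`), fx, `+`)
      sel <- which(F <= 1)
      if (!length(sel)) next
      # linear indices of the bbox voxels within the full grid
      box_idx <- as.vector(
        outer(outer(zi, (yi - 1) * g[1], `+`), (xi - 1) * g[1] * g[2], `+`))
      sel_idx <- box_idx[sel]
      better <- F[sel] < bestF[sel_idx]
      upd <- sel_idx[better]
      lab[upd] <- lab_ids[[r_name]]
      inst[upd] <- s_i
      bestF[upd] <- F[sel][better]
    }
    list(lab = lab, inst = inst)
  }

  # two-pass calibration: where adjacent ellipsoids contest voxels, inflate
  # the losing structure's target so achieved counts track the draws
  r1 <- render_once(targets)
  got <- tabulate(r1$inst, nbins = length(layout))
  corr <- ifelse(got > 0, pmin(2, targets / pmax(got, 1)), 1)
  r2 <- render_once(targets * corr)
  lab <- r2$lab; inst <- r2$inst

  inst_counts <- tabulate(inst, nbins = length(layout))
  achieved <- vapply(nps, function(r) {
    sum(inst_counts[vapply(layout, function(st) st$name == r, logical(1))])
  }, numeric(1)) * spacing^3
  sides <- list()
  for (r in c("AL", "MB", "ME", "LO")) {
    li <- which(vapply(layout, function(st)
      st$name == r && identical(st$side, "left"), logical(1)))
    ri <- which(vapply(layout, function(st)
      st$name == r && identical(st$side, "right"), logical(1)))
    sides[[r]] <- c(left = inst_counts[li], right = inst_counts[ri])
  }

  dim(lab) <- g
  img <- params$tissue_gray[["background"]] + numeric(nvox)
  for (r in nps) img[lab == lab_ids[[r]]] <- params$tissue_gray[[r]]
  dim(img) <- g
  img <- gauss_blur3(img, params$blur_sigma)
  if (params$noise_sd > 0) {
    if (is.null(seed)) seed <- params$seed + 104729L
    img <- with_seed(seed, img + array(rnorm(nvox, 0, params$noise_sd), g))
  }

  list(image = volume3d(img, spacing),
       labels = label_volume(lab, neuropil_labels(), spacing),
       achieved = achieved, sides = sides, merged_mb = merged)
}

#' Flatten a cohort into the specimen table layout
#'
#' One row per specimen with grouping metadata, absolute and relative
#' neuropil volumes (relative volumes in % of total brain volume over
#' AL, MB, OL, CX, OTH), left/right columns for paired neuropils, the
#' derived optic lobe volume OL = ME + LO and total brain volume.
#'
#' @param cohort a `cohort_spec` from [sample_cohort()], or any data.frame
#'   with the same volume columns.
#' @param path optional CSV output path.
#' @return A `specimen_table` data.frame (invisibly written to `path` if given).
#' @export
cohort_to_table <- function(cohort, path = NULL) {
  if (nrow(cohort) == 0) stop("cohort_to_table: cohort is empty")
  t <- data.frame(
    specimen = cohort$specimen, species = cohort$species,
    population = cohort$population, hive = cohort$hive,
    stringsAsFactors = FALSE
  )
  for (r in c("AL", "MB", "CX", "ME", "LO", "OTH")) t[[r]] <- cohort[[r]]
  t$OL <- t$ME + t$LO
  t$total <- t$AL + t$MB + t$CX + t$ME + t$LO + t$OTH
  for (r in c("AL", "MB", "ME", "LO")) {
    t[[paste0(r, "_left")]] <- cohort[[paste0(r, "_left")]]
    t[[paste0(r, "_right")]] <- cohort[[paste0(r, "_right")]]
  }
  t$OL_left <- t$ME_left + t$LO_left
  t$OL_right <- t$ME_right + t$LO_right
  t$mb_separable <- if ("mb_separable" %in% names(cohort)) cohort$mb_separable
                    else !cohort$merge_mb
  for (r in c("AL", "MB", "OL", "CX", "OTH"))
    t[[paste0(r, "_rel")]] <- 100 * t[[r]] / t$total
  class(t) <- c("specimen_table", class(t))
  if (!is.null(path)) {
    utils::write.csv(t, path, row.names = FALSE)
    return(invisible(t))
  }
  t
}
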