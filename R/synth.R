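# Synthetic phantom cohorts with known ground truth. Regional dynamics
# are generated as stationary AR(1) processes: with phi = exp(-b), the
# theoretical autocorrelation at lag k is exactly exp(-b k), so the
# exponential ACF model is well-specified on unfiltered phantoms (a = 1).
#
# Decay-rate scales. The conditioning pipeline (detrend + 0.01-0.1 Hz
# zero-phase band-pass at 200 volumes, TR = 2 s) imprints its own
# autocorrelation on every series: fitted decay rates are compressed
# towards a band of roughly 0.38-0.79 regardless of the generative AR(1)
# rate. Reference cluster statistics are reported on that observed scale,
# so the generator lets regional rates be specified either on the
# observed scale (default; mapped to generative AR(1) rates through a
# frozen monotone calibration table computed once from the conditioning
# pipeline at the default acquisition) or directly on the generative
# scale (for unfiltered recovery studies).

# Calibration table: expected fitted b after the default conditioning
# (detrend + band-pass, measurement noise SD 0.2, n = 200, TR = 2 s) as a
# function of the generative AR(1) rate; 2000 simulated series per knot.
.b_calibration <- list(
  b_gen = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80,
            0.90, 1.00, 1.20, 1.40, 1.70, 2.00, 2.50, 3.00, 4.00, 6.00),
  b_obs = cummax(c(0.3791, 0.3985, 0.4284, 0.4569, 0.5131, 0.5643, 0.6025,
                   0.6403, 0.6671, 0.6866, 0.7040, 0.7193, 0.7423, 0.7526,
                   0.7674, 0.7774, 0.7835, 0.7876, 0.7877, 0.7878)))

#' Expected observed decay rate for a generative AR(1) rate
#'
#' Monotone spline through the generator's calibration table: the mean
#' fitted decay rate after the default conditioning (detrend + 0.01-0.1 Hz
#' zero-phase band-pass, 200 volumes at TR = 2 s) of an AR(1) series with
#' generative rate `b_gen`.
#'
#' @param b_gen generative decay rate(s), in `[0.05, 6]`
#' @return expected observed (fitted) decay rate(s)
#' @export
b_generative_to_observed <- function(b_gen) {
  f <- stats::splinefun(.b_calibration$b_gen, .b_calibration$b_obs,
                        method = "hyman")
  f(pmin(pmax(b_gen, 0.05), 6))
}

#' Generative AR(1) rate realising a target observed decay rate
#'
#' Inverse of [b_generative_to_observed()]. Targets are censored into the
#' attainable observed band `[0.40, 0.775]`: the conditioning pipeline
#' bounds the decay rates it can produce.
#'
#' @param b_obs target observed decay rate(s)
#' @return generative AR(1) rate(s)
#' @export
b_observed_to_generative <- function(b_obs) {
  f <- stats::splinefun(.b_calibration$b_obs, .b_calibration$b_gen,
                        method = "hyman")
  f(pmin(pmax(b_obs, 0.40), 0.775))
}

#' Stationary AR(1) series with a prescribed ACF decay rate
#'
#' `x_t = phi x_(t-1) + e_t` with `phi = exp(-b)` and innovation variance
#' `1 - phi^2`, so the marginal variance is 1 and the theoretical
#' autocorrelation at lag k is `exp(-b k)`.
#'
#' @param b decay rate per sample (> 0)
#' @param n series length (>= 9)
#' @param seed optional integer seed (consumes the global RNG if `NULL`)
#' @return numeric vector of length `n`
#' @export
ar1_for_b <- function(b, n, seed = NULL) {
  if (!is.finite(b) || b <= 0) stop_acf("ar1_for_b: b must be > 0")
  if (n < 9) stop_acf("ar1_for_b: n must be at least 9")
  if (!is.null(seed)) set.seed(seed)
  drop(.ar1_matrix(b, n, 1L))
}

# nv independent stationary AR(1) columns at a common rate.
.ar1_matrix <- function(b, n, nv) {
  phi <- exp(-b)
  isd <- sqrt(1 - phi^2)
  X <- matrix(0, n, nv)
  X[1, ] <- rnorm(nv)
  E <- matrix(rnorm((n - 1) * nv, sd = isd), n - 1, nv)
  for (t in 2:n) X[t, ] <- phi * X[t - 1, ] + E[t - 1, ]
  X
}

#' Pair of series with a prescribed population correlation
#'
#' `a = z`; `b = r z + sqrt(1 - r^2) w` with `z`, `w` independent
#' unit-variance white noise, so the population correlation is exactly
#' `r_target`.
#'
#' @param r_target target correlation, `|r_target| < 1`
#' @param n series length
#' @param seed optional integer seed
#' @return list with components `a` and `b`
#' @export
make_connected_pair <- function(r_target, n, seed = NULL) {
  if (!is.finite(r_target) || abs(r_target) >= 1)
    stop_acf("make_connected_pair: |r_target| must be < 1")
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n)
  w <- rnorm(n)
  list(a = z, b = r_target * z + sqrt(1 - r_target^2) * w)
}

# Sphere of voxels around a centre (voxel units, anisotropic radii).
.sphere_mask <- function(dm, centre, radius) {
  i <- slice.index(array(0, dm), 1)
  j <- slice.index(array(0, dm), 2)
  k <- slice.index(array(0, dm), 3)
  ((i - centre[1]) / radius[1])^2 + ((j - centre[2]) / radius[2])^2 +
    ((k - centre[3]) / radius[3])^2 <= 1
}

#' Phantom-cohort specification
#'
#' The generative description of a two-group resting-state cohort on a
#' small voxel grid. Defaults emulate a 19-versus-19 comparison of
#' 200-volume TR = 2 s acquisitions in which the focal region's observed
#' decay rate is lowered in patients (control 0.71 +/- 0.09 versus
#' patient 0.57 +/- 0.05 across subjects, on the observed scale) against
#' a background shared by the two groups, with white-matter/CSF confound
#' signals, slow random-walk head motion, planted inter-regional
#' correlations (a locally increased and a long-range decreased edge in
#' patients), and clinical covariates linked to connectivity through a
#' Gaussian copula.
#'
#' Geometry: an ellipsoidal "brain" inside a `grid_shape` box with six
#' spherical grey-matter regions (region 1, ~150 voxels, is the focal
#' region; the others hold ~60 voxels), and separate WM and CSF blocks
#' used only as nuisance sources. Voxel size is 3 x 3 x 4 mm.
#'
#' Voxel signal model: a voxel in region r is
#' `sqrt(w) S_r + sqrt(1-w) V_i + sigma eps`, where `S_r` is one
#' region-wide AR(1) realization (it carries the planted inter-regional
#' edges), `V_i` is the voxel's own independent AR(1) realization at the
#' same subject-level rate, `w = shared_fraction`, and `sigma` is
#' `measurement_noise_sd`. Background voxels are fully voxel-independent
#' (`w = 0`).
#'
#' @param grid_shape 3D grid dimensions
#' @param n_per_group subjects per group
#' @param n_volumes volumes per subject
#' @param tr repetition time in seconds
#' @param focal_b named list: `control = c(mean, sd)`, `patient = c(mean,
#'   sd)` of the focal region's subject-level decay rate, on `b_scale`
#' @param region_b `c(mean, sd)` for the non-focal regions (shared
#'   between groups)
#' @param background_b `c(mean, sd)` for unlabeled brain tissue
#' @param b_scale `"observed"` (default; rates are post-conditioning
#'   targets, mapped through [b_observed_to_generative()]) or
#'   `"generative"` (rates are AR(1) rates used directly)
#' @param region_b_overrides optional named list `region index ->
#'   c(mean, sd)` replacing `region_b` for specific regions (both groups)
#' @param shared_fraction variance fraction of the region-wide signal in
#'   region voxels
#' @param measurement_noise_sd SD of i.i.d. voxel noise added to the unit
#'   variance regional signal
#' @param confound_amplitude scale of the WM/CSF/motion-linked signal
#'   mixed into brain voxels
#' @param connectivity_edges data.frame with columns `region_a`,
#'   `region_b`, `r_control`, `r_patient`, `subject_sd` (subject-level SD
#'   of the Fisher-z edge strength)
#' @param covariate_links data.frame with columns `covariate` (`duration`
#'   or `lm_dr`), `edge` (row index into `connectivity_edges`), `rho`
#'   (target population correlation with the patient's realized edge
#'   Fisher z)
#' @param master_seed integer seed from which all subject seeds are
#'   derived
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 16),
                         n_per_group = 19,
                         n_volumes = 200,
                         tr = 2,
                         focal_b = list(control = c(0.71, 0.09),
                                        patient = c(0.57, 0.05)),
                         region_b = c(0.66, 0.05),
                         background_b = c(0.70, 0.05),
                         b_scale = c("observed", "generative"),
                         region_b_overrides = NULL,
                         shared_fraction = 0.3,
                         measurement_noise_sd = 0.2,
                         confound_amplitude = 0.4,
                         connectivity_edges = data.frame(
                           region_a = c(1, 1),
                           region_b = c(2, 5),
                           r_control = c(0.25, 0.45),
                           r_patient = c(0.55, 0.15),
                           subject_sd = c(0.12, 0.12)),
                         covariate_links = data.frame(
                           covariate = c("duration", "lm_dr"),
                           edge = c(2, 1),
                           rho = c(0.6, -0.5)),
                         master_seed = 20151221) {
  b_scale <- match.arg(b_scale)
  if (n_volumes < 9) stop_acf("phantom_spec: n_volumes must be >= 9")
  stopifnot(focal_b$control[1] > 0, focal_b$patient[1] > 0,
            region_b[1] > 0, background_b[1] > 0,
            shared_fraction >= 0, shared_fraction < 1)
  if (nrow(connectivity_edges) &&
      any(abs(c(connectivity_edges$r_control, connectivity_edges$r_patient)) >= 1))
    stop_acf("phantom_spec: edge target |r| must be < 1")

  dm <- grid_shape
  centre <- (dm + 1) / 2
  brain <- .sphere_mask(dm, centre, c(0.42, 0.42, 0.42) * dm)
  rc <- rbind(
    centre + c(-0.22, 0.10, -0.12) * dm,   # 1: focal
    centre + c(-0.18, -0.18, 0.08) * dm,   # 2: near the focal region
    centre + c(0.20, 0.15, -0.10) * dm,
    centre + c(0.18, -0.15, 0.12) * dm,
    centre + c(0.02, 0.24, 0.10) * dm,     # 5: distant from region 1
    centre + c(0.00, -0.05, -0.22) * dm)
  radii <- rbind(c(3.6, 3.6, 2.8),          # focal: ~150 voxels
                 matrix(rep(c(2.6, 2.6, 2.1), 5), 5, 3, byrow = TRUE))
  labels <- array(0L, dm)
  for (r in seq_len(nrow(rc))) {
    sm <- .sphere_mask(dm, rc[r, ], radii[r, ]) & brain
    labels[sm & labels == 0L] <- r
  }
  wm <- array(FALSE, dm)
  wm[1:3, 1:3, ] <- TRUE
  csf <- array(FALSE, dm)
  csf[(dm[1] - 2):dm[1], 1:3, ] <- TRUE
  wm <- wm & !brain
  csf <- csf & !brain
  if (any(table(labels[labels > 0]) < 27))
    stop_acf("phantom_spec: a region has fewer than 27 voxels; enlarge the grid")

  affine <- rbind(c(3, 0, 0, -3 * centre[1]),
                  c(0, 3, 0, -3 * centre[2]),
                  c(0, 0, 4, -4 * centre[3]),
                  c(0, 0, 0, 1))
  structure(list(
    grid_shape = dm, n_per_group = n_per_group, n_volumes = n_volumes,
    tr = tr, focal_b = focal_b, region_b = region_b,
    background_b = background_b, b_scale = b_scale,
    region_b_overrides = region_b_overrides,
    shared_fraction = shared_fraction,
    measurement_noise_sd = measurement_noise_sd,
    confound_amplitude = confound_amplitude,
    connectivity_edges = connectivity_edges,
    covariate_links = covariate_links,
    master_seed = as.integer(master_seed),
    region_labels = labels, brain_mask = brain, wm_mask = wm,
    csf_mask = csf, affine = affine,
    n_regions = nrow(rc)), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, %d + %d subjects, %d volumes at TR = %g s, %d regions (%s-scale rates)\n",
              paste(x$grid_shape, collapse = "x"), x$n_per_group,
              x$n_per_group, x$n_volumes, x$tr, x$n_regions, x$b_scale))
  invisible(x)
}

# Draw per-region subject decay rates (on the spec's scale) and convert
# to generative AR(1) rates.
.draw_subject_b <- function(spec, group) {
  fb <- if (group == "patient") spec$focal_b$patient else spec$focal_b$control
  means <- c(spec$background_b[1], fb[1],
             rep(spec$region_b[1], max(spec$n_regions - 1, 0)))
  sds <- c(spec$background_b[2], fb[2],
           rep(spec$region_b[2], max(spec$n_regions - 1, 0)))
  if (!is.null(spec$region_b_overrides)) {
    for (nm in names(spec$region_b_overrides)) {
      r <- as.integer(nm)
      means[r + 1L] <- spec$region_b_overrides[[nm]][1]
      sds[r + 1L] <- spec$region_b_overrides[[nm]][2]
    }
  }
  drawn <- pmax(rnorm(length(means), means, sds), 0.05)
  gen <- if (spec$b_scale == "observed") b_observed_to_generative(drawn)
  else drawn
  names(drawn) <- names(gen) <-
    c("background", paste0("region", seq_len(spec$n_regions)))
  list(drawn = drawn, generative = gen)
}

#' Generate one phantom subject
#'
#' Implements the voxel signal model described in [phantom_spec()]:
#' per-voxel independent AR(1) realizations mixed with one region-wide
#' realization (which carries the planted inter-regional edges) plus
#' measurement noise. Slow random-walk motion traces are generated, and
#' WM/CSF confound signals are written into the tissue blocks and leaked
#' into brain voxels at `confound_amplitude`.
#'
#' @param spec a [phantom_spec()]
#' @param group `"patient"` or `"control"`
#' @param subject_seed integer seed (see [derive_seed()])
#' @return list: `bold` ([bold_image()]), `motion` (T x 6 matrix), `truth`
#'   (drawn rates on both scales, drawn and realized edge correlations)
#' @export
make_subject <- function(spec, group, subject_seed) {
  group <- match.arg(group, c("patient", "control"))
  set.seed(subject_seed)
  dm <- spec$grid_shape
  nt <- spec$n_volumes
  bb <- .draw_subject_b(spec, group)
  b_gen <- bb$generative

  edges <- spec$connectivity_edges
  r_drawn <- numeric(0)
  if (nrow(edges)) {
    r_grp <- if (group == "patient") edges$r_patient else edges$r_control
    r_drawn <- tanh(rnorm(nrow(edges), atanh(r_grp), edges$subject_sd))
  }

  # region-wide signals; planted edges mix the source region's signal in
  sig <- matrix(0, nt, spec$n_regions + 1L)  # col 1 = background
  sig[, 1] <- drop(.ar1_matrix(b_gen["background"], nt, 1L))
  for (r in seq_len(spec$n_regions)) {
    own <- drop(.ar1_matrix(b_gen[paste0("region", r)], nt, 1L))
    mixed <- own
    if (nrow(edges)) {
      ei <- which(edges$region_b == r)
      if (length(ei)) {
        ei <- ei[1]
        src <- sig[, edges$region_a[ei] + 1L]
        rr <- r_drawn[ei]
        mixed <- rr * src + sqrt(1 - rr^2) * own
      }
    }
    sig[, r + 1L] <- mixed
  }

  wm_sig <- drop(.ar1_matrix(0.5, nt, 1L))
  csf_sig <- drop(.ar1_matrix(0.4, nt, 1L))
  motion <- cbind(
    vapply(1:3, function(j) cumsum(rnorm(nt, 0, 0.02)), numeric(nt)),
    vapply(1:3, function(j) cumsum(rnorm(nt, 0, 5e-4)), numeric(nt)))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mot_sig <- as.numeric(scale(rms_displacement(motion)$per_volume))

  flat <- matrix(0, prod(dm), nt)
  ca <- spec$confound_amplitude
  conf <- ca * (0.3 * wm_sig + 0.3 * csf_sig + 0.2 * mot_sig)
  sigma <- spec$measurement_noise_sd
  w <- spec$shared_fraction
  fill_region <- function(idx, shared, b_region, w_use) {
    nv <- length(idx)
    if (!nv) return()
    V <- .ar1_matrix(b_region, nt, nv)
    S <- if (w_use > 0) sqrt(w_use) * matrix(shared, nt, nv) else 0
    noise <- matrix(rnorm(nv * nt, sd = sigma), nt, nv)
    flat[idx, ] <<- t(S + sqrt(1 - w_use) * V + noise +
                        matrix(conf, nt, nv))
  }
  fill_region(which(spec$brain_mask & spec$region_labels == 0L),
              sig[, 1], b_gen["background"], 0)
  for (r in seq_len(spec$n_regions))
    fill_region(which(spec$region_labels == r), sig[, r + 1L],
                b_gen[paste0("region", r)], w)
  wm_idx <- which(spec$wm_mask)
  flat[wm_idx, ] <- t(matrix(wm_sig, nt, length(wm_idx)) +
                        matrix(rnorm(length(wm_idx) * nt, sd = 0.1),
                               nt, length(wm_idx)))
  csf_idx <- which(spec$csf_mask)
  flat[csf_idx, ] <- t(matrix(csf_sig, nt, length(csf_idx)) +
                         matrix(rnorm(length(csf_idx) * nt, sd = 0.1),
                                nt, length(csf_idx)))
  arr <- array(flat, c(dm, nt))

  realized_z <- numeric(0)
  if (nrow(edges)) {
    realized_z <- vapply(seq_len(nrow(edges)), function(e) {
      atanh(cor(sig[, edges$region_a[e] + 1L], sig[, edges$region_b[e] + 1L]))
    }, numeric(1))
  }
  list(bold = bold_image(arr, spec$affine, spec$tr),
       motion = structure(motion, class = c("motion_params", "matrix", "array")),
       truth = list(group = group, b_drawn = bb$drawn,
                    b_generative = b_gen, b_scale = spec$b_scale,
                    r_drawn = r_drawn, edge_z_realized = realized_z,
                    seed = subject_seed))
}

#' Generate a full phantom cohort
#'
#' `n_per_group` controls and patients, bit-exactly reproducible from
#' `(spec, master_seed)`: subject seeds come from [derive_seed()].
#' Clinical covariates for patients are drawn by a Gaussian copula
#' against each subject's realized edge Fisher z (standardized within the
#' patient group), so the planted covariate-connectivity correlation
#' survives into the estimable quantities. Duration is in years; `lm_dr`
#' is an integer verbal-memory score. Both are missing for controls.
#'
#' @param spec a [phantom_spec()]
#' @return object of class `cohort_data`: `subjects` (list of
#'   [make_subject()] outputs with ids), `table` (cohort covariate
#'   data.frame), `masks`, `affine`, and the ground-truth `ledger`
#' @export
make_cohort <- function(spec) {
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("sub%02d", seq_along(groups))
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- make_subject(spec, groups[i], derive_seed(spec$master_seed, i))
    s$id <- ids[i]
    subjects[[i]] <- s
  }

  set.seed(derive_seed(spec$master_seed, 10007L))
  n <- length(ids)
  age <- round(pmin(pmax(rnorm(n, 40, 13), 18), 70))
  sex <- rep(rep(c("M", "F"), length.out = spec$n_per_group), 2)

  pat <- which(groups == "patient")
  duration <- rep(NA_real_, n)
  lm_dr <- rep(NA_real_, n)
  links <- spec$covariate_links
  edge_z <- do.call(rbind, lapply(subjects[pat],
                                  function(s) s$truth$edge_z_realized))
  if (!is.null(links) && nrow(links) && length(edge_z)) {
    for (li in seq_len(nrow(links))) {
      e <- links$edge[li]
      rho <- links$rho[li]
      u <- as.numeric(scale(edge_z[, e]))
      latent <- rho * u + sqrt(1 - rho^2) * rnorm(length(pat))
      p <- pnorm(as.numeric(scale(latent)))
      p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
      if (links$covariate[li] == "duration") {
        duration[pat] <- round(qgamma(p, shape = 4, scale = 3.5), 1)
      } else if (links$covariate[li] == "lm_dr") {
        lm_dr[pat] <- pmax(0, round(qnorm(p, 12, 4)))
      }
    }
  }

  tab <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                    duration = duration, lm_dr = lm_dr,
                    stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")

  ledger <- list(
    master_seed = spec$master_seed,
    b_scale = spec$b_scale,
    subjects = lapply(subjects, function(s) c(list(id = s$id), s$truth)),
    focal_region = 1L,
    edges = spec$connectivity_edges,
    covariate_links = spec$covariate_links)

  structure(list(subjects = subjects, table = tab,
                 masks = list(brain = spec$brain_mask, wm = spec$wm_mask,
                              csf = spec$csf_mask,
                              region_labels = spec$region_labels,
                              analysis = spec$brain_mask & !spec$wm_mask &
                                !spec$csf_mask),
                 affine = spec$affine, spec = spec, ledger = ledger),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d subjects (%d patients), %s grid\n",
              length(x$subjects), sum(x$table$group == "patient"),
              paste(dim(x$masks$brain), collapse = "x")))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Produces the same on-disk layout real data would use: per-subject 4D
#' NIfTI images and motion text files, mask NIfTIs, the cohort CSV, and a
#' ground-truth JSON ledger.
#'
#' @param cohort a [make_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_bold(s$bold, file.path(dir, paste0("bold_", s$id, ".nii.gz")),
               datatype = "float")
    write_motion(s$motion, file.path(dir, paste0("motion_", s$id, ".txt")))
  }
  aff <- cohort$affine
  write_mask(cohort$masks$brain, aff, file.path(dir, "mask_brain.nii.gz"))
  write_mask(cohort$masks$wm, aff, file.path(dir, "mask_wm.nii.gz"))
  write_mask(cohort$masks$csf, aff, file.path(dir, "mask_csf.nii.gz"))
  write_mask(cohort$masks$analysis, aff, file.path(dir, "mask_analysis.nii.gz"))
  lbl <- cohort$masks$region_labels
  img <- RNifti::asNifti(array(as.numeric(lbl), dim = dim(lbl)))
  RNifti::pixdim(img) <- sqrt(colSums(aff[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, file.path(dir, "region_labels.nii.gz"),
                     datatype = "int16")
  write_cohort_table(cohort$table, file.path(dir, "cohort.csv"))
  jsonlite::write_json(cohort$ledger, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
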