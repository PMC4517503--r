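#' Reader profile for the multi-reader simulator
#'
#' Encodes a simulated expert's systematic contouring habit: a constant
#' signed radial offset per surface (positive = outward; real readers are
#' consistently tighter or looser than their peers depending on their lab's
#' protocol), smooth zero-mean angular noise mimicking hand contouring, and a
#' probability of omitting the most apical or most basal slice, where real
#' disagreement concentrates. Sensitivity/specificity are emergent properties
#' of these offsets, not set directly.
#'
#' @param reader_id reader label.
#' @param endo_bias_mm,epi_bias_mm signed radial offsets in mm.
#' @param noise_sd_mm SD (RMS over angle) of the smooth angular noise, mm.
#' @param slice_skip_prob probability in \\[0, 1) of omitting an end slice
#'   (applied independently to the apical and basal end, per frame).
#' @return an object of class `reader_profile`.
#' @export
reader_profile <- function(reader_id, endo_bias_mm = 0, epi_bias_mm = 0,
                           noise_sd_mm = 0, slice_skip_prob = 0) {
  stopifnot(noise_sd_mm >= 0, slice_skip_prob >= 0, slice_skip_prob < 1)
  structure(
    list(reader_id = as.character(reader_id), endo_bias_mm = endo_bias_mm,
         epi_bias_mm = epi_bias_mm, noise_sd_mm = noise_sd_mm,
         slice_skip_prob = slice_skip_prob),
    class = "reader_profile"
  )
}

#' Default panel of simulated readers
#'
#' Seven profiles with zero-mean endocardial biases spanning -2..+2 mm and
#' epicardial biases of the opposite sign pattern (readers who draw tight
#' endocardial contours tend to draw generous epicardial ones and vice
#' versa), 1 mm smooth noise, and an 8% chance of dropping an end slice.
#' At typical LV perimeters a 1 mm radial offset moves EDV by roughly
#' 10-16 ml, so the +-2 mm spread produces volume biases of a few tens of ml
#' across a cohort — the magnitude observed between real core laboratories.
#'
#' @param n number of readers (default 7).
#' @param noise_sd_mm,slice_skip_prob shared noise/omission settings.
#' @return list of [reader_profile]s named R1..Rn.
#' @export
default_reader_profiles <- function(n = 7L, noise_sd_mm = 1.0,
                                    slice_skip_prob = 0.08) {
  stopifnot(n >= 2L)
  endo <- if (n == 7L) c(-2, -1.2, -0.5, 0, 0.5, 1.2, 2) else
    seq(-2, 2, length.out = n)
  endo <- endo - mean(endo)
  epi <- -0.7 * endo
  lapply(seq_len(n), function(i) {
    reader_profile(paste0("R", i), endo_bias_mm = endo[i],
                   epi_bias_mm = epi[i], noise_sd_mm = noise_sd_mm,
                   slice_skip_prob = slice_skip_prob)
  })
}

phantom_phenotypes <- c("healthy", "dilated", "hypertrophic")

# Smooth angular perturbation: low-order cosine series with random phases,
# normalized to unit RMS over angle. Zero mean over the circle by
# construction. Returns an evaluator so the same draw can be applied to the
# endocardial and epicardial vertex grids of one slice.
smooth_angular_noise <- function(n_harmonics = 3L) {
  g <- stats::rnorm(n_harmonics)
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  rms <- sqrt(sum(g^2) / 2)
  function(theta) {
    delta <- rep(0, length(theta))
    if (rms < 1e-12) return(delta)
    for (m in seq_len(n_harmonics)) {
      delta <- delta + g[m] * cos(m * theta + phi[m])
    }
    delta / rms
  }
}

#' Generate a ground-truth LV phantom
#'
#' Builds one case's true contour stack: per-slice smooth closed curves whose
#' radii follow a truncated half-ellipsoid apex-to-base profile with mild
#' angular irregularity, an epicardial surface offset outward by a constant
#' wall thickness, and an end-systolic endocardium contracted radially with
#' slightly stronger contraction toward the apex. Phenotype sets the scale:
#' `"healthy"` (normal cavity, EF in the 50-70% range), `"dilated"` (large
#' cavity, reduced EF — the infarct/heart-failure end of the spectrum),
#' `"hypertrophic"` (normal cavity, thick wall, high mass). The cohort
#' defaults put EDV roughly in the 100-380 ml range and mass in the
#' 70-195 g range seen across real pathologies.
#'
#' The phantom also records a 20-frame mid-slice cavity-area curve with a
#' known end-systolic frame, for exercising ES-frame selection.
#'
#' @param phenotype one of `"healthy"`, `"dilated"`, `"hypertrophic"`.
#' @param geometry optional [slice_geometry]; when `NULL` one is drawn from
#'   realistic ranges (10-15 slices, thickness 8 or 10 mm with contiguous
#'   spacing, pixel 1.1-2.1 mm, 200 mm field of view).
#' @param seed integer seed; the phantom is deterministic given
#'   (phenotype, geometry, seed).
#' @param case_id case label.
#' @param n_points vertices per contour (default 60).
#' @return object of class `true_phantom`: list with `case_id`, `phenotype`,
#'   `geometry`, `truth` (a [contour_set], `source_id = "truth"`),
#'   `lv_function` (truth [compute_lv_function()]), `es_frame`,
#'   `mid_slice_areas_mm2`, `center_mm`, `params`.
#' @export
generate_phantom <- function(phenotype = phantom_phenotypes, geometry = NULL,
                             seed = 1L, case_id = "case1", n_points = 60L) {
  phenotype <- match.arg(phenotype)
  with_seed(seed, {
    if (is.null(geometry)) {
      px <- round(stats::runif(1, 1.1, 2.1), 2)
      slt <- sample(c(8, 10), 1L)
      # thinner slices need more of them for the same apex-to-base coverage
      nsl <- if (slt == 10) sample(10:11, 1L) else sample(11:14, 1L)
      npix <- as.integer(ceiling(200 / px))
      geometry <- slice_geometry(px, slt, slt, npix, npix, nsl)
    }
    g <- geometry
    pars <- switch(phenotype,
      healthy = list(r_endo = stats::runif(1, 25, 29),
                     wall = stats::runif(1, 5.5, 7.5),
                     es_ratio = stats::runif(1, 0.58, 0.66)),
      dilated = list(r_endo = stats::runif(1, 32, 40),
                     wall = stats::runif(1, 6, 7.5),
                     es_ratio = stats::runif(1, 0.85, 0.95)),
      hypertrophic = list(r_endo = stats::runif(1, 22, 25),
                          wall = stats::runif(1, 9.5, 12),
                          es_ratio = stats::runif(1, 0.55, 0.62))
    )
    if (pars$wall <= 0) stop("infeasible geometry: non-positive wall thickness")
    fov <- c(g$n_cols * g$pixel_size_mm[1L], g$n_rows * g$pixel_size_mm[2L])
    center <- fov / 2 + stats::runif(2, -4, 4)
    S <- g$n_slices
    d <- g$slice_spacing_mm
    L <- 0.95 * S * d                      # endocardial long-axis length
    z <- (seq_len(S) - 0.5) * d            # slice centers, apex at z = 0
    u <- pmin(z, L) / L
    r_prof <- pars$r_endo * sqrt(pmax(1 - (1 - u)^2, 0))
    r_prof <- pmax(r_prof, 3)              # keep the apical cap contourable
    es_scale <- pars$es_ratio * (1 - 0.05 * (1 - u))
    # case-level angular irregularity shared by all slices and surfaces
    a_m <- stats::runif(2, 0, 0.03)
    phi_m <- stats::runif(2, 0, 2 * pi)
    theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
    shape <- 1 + a_m[1L] * cos(2 * theta + phi_m[1L]) +
      a_m[2L] * cos(3 * theta + phi_m[2L])
    ring <- function(r) {
      cbind(center[1L] + r * shape * cos(theta),
            center[2L] + r * shape * sin(theta))
    }
    truth <- contour_set(case_id, "truth", g)
    for (i in seq_len(S)) {
      s0 <- i - 1L
      truth <- set_contour(truth, lv_contour(ring(r_prof[i]), "endo", "ED",
                                             s0, check = FALSE))
      truth <- set_contour(truth, lv_contour(ring(r_prof[i] + pars$wall),
                                             "epi", "ED", s0, check = FALSE))
      r_es <- max(r_prof[i] * es_scale[i], 1.5)
      truth <- set_contour(truth, lv_contour(ring(r_es), "endo", "ES",
                                             s0, check = FALSE))
    }
    mid <- S %/% 2L
    n_frames <- 20L
    es_frame <- sample(7:9, 1L)
    f <- seq_len(n_frames) - 1L
    gcurve <- exp(-((f - es_frame) / 3.2)^2)
    a_ed <- polygon_area_mm2(get_contour(truth, "ED", mid, "endo"))
    a_es <- polygon_area_mm2(get_contour(truth, "ES", mid, "endo"))
    mid_areas <- a_ed - (a_ed - a_es) * gcurve
    structure(
      list(case_id = as.character(case_id), phenotype = phenotype,
           geometry = g, truth = truth,
           lv_function = compute_lv_function(truth),
           es_frame = es_frame, mid_slice_areas_mm2 = mid_areas,
           center_mm = center, params = pars),
      class = "true_phantom"
    )
  })
}

#' Simulate one reader's contour set from a phantom
#'
#' Displaces every true contour radially about its centroid by the reader's
#' surface bias plus smooth zero-mean angular noise (a low-order cosine
#' perturbation, so the polygon stays simple/star-shaped), and drops end
#' slices with the profile's omission probability. Deterministic given
#' (phantom, profile, seed). When a noise draw breaks endo/epi nesting on an
#' ED slice the noise is redrawn, up to 10 attempts.
#'
#' @param phantom a `true_phantom` from [generate_phantom()].
#' @param profile a [reader_profile].
#' @param seed integer seed.
#' @return a [contour_set] with `source_id = profile$reader_id`.
#' @export
simulate_reader <- function(phantom, profile, seed = 1L) {
  stopifnot(inherits(phantom, "true_phantom"), inherits(profile, "reader_profile"))
  truth <- phantom$truth
  g <- phantom$geometry
  wall_min <- phantom$params$wall * (1 - 2 * 0.03 * 2)  # worst-case irregularity
  if (profile$endo_bias_mm - profile$epi_bias_mm >= wall_min - 1) {
    stop("reader profile infeasible: biased endocardium would reach the ",
         "biased epicardium (reader ", profile$reader_id, ")")
  }
  with_seed(seed, {
    out <- contour_set(phantom$case_id, profile$reader_id, g)
    keys <- contour_keys(truth)
    slice_range <- range(keys$slice_index)
    # The two surfaces of one slice share most of their angular noise (a
    # hand tracing drifts coherently), with a smaller independent component;
    # the shared part cancels in the wall and keeps nesting robust.
    displace <- function(ct, bias, shared, private) {
      if (bias == 0 && profile$noise_sd_mm == 0) return(ct$points)
      cen <- polygon_centroid(ct)
      dx <- ct$points[, 1L] - cen[1L]
      dy <- ct$points[, 2L] - cen[2L]
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      noise <- profile$noise_sd_mm * (0.8 * shared(th) + 0.6 * private(th))
      r_new <- pmax(r + bias + noise, 1)
      cbind(cen[1L] + r_new * cos(th), cen[2L] + r_new * sin(th))
    }
    for (frame in c("ED", "ES")) {
      fkeys <- keys[keys$frame == frame, , drop = FALSE]
      if (!nrow(fkeys)) next
      drop_apex <- stats::runif(1) < profile$slice_skip_prob
      drop_base <- stats::runif(1) < profile$slice_skip_prob
      for (sl in sort(unique(fkeys$slice_index))) {
        if ((drop_apex && sl == slice_range[1L]) ||
            (drop_base && sl == slice_range[2L])) next
        endo_t <- get_contour(truth, frame, sl, "endo")
        epi_t <- get_contour(truth, frame, sl, "epi")
        for (attempt in seq_len(10L)) {
          shared <- smooth_angular_noise()
          endo_pts <- if (!is.null(endo_t)) {
            displace(endo_t, profile$endo_bias_mm, shared,
                     smooth_angular_noise())
          }
          epi_pts <- if (!is.null(epi_t)) {
            displace(epi_t, profile$epi_bias_mm, shared,
                     smooth_angular_noise())
          }
          if (is.null(endo_pts) || is.null(epi_pts)) break
          # vertices share the angular grid, so nesting is a radial check
          r_en <- sqrt(rowSums((endo_pts - rep(polygon_centroid(endo_t),
                                               each = nrow(endo_pts)))^2))
          r_ep <- sqrt(rowSums((epi_pts - rep(polygon_centroid(epi_t),
                                              each = nrow(epi_pts)))^2))
          if (all(r_en < r_ep - 0.2)) break
          if (attempt == 10L) {
            stop("could not keep endocardium inside epicardium after 10 noise ",
                 "draws (case ", phantom$case_id, ", reader ",
                 profile$reader_id, ", frame ", frame, ", slice ", sl, ")")
          }
        }
        if (!is.null(endo_pts)) {
          out <- set_contour(out, lv_contour(endo_pts, "endo", frame, sl,
                                             check = FALSE))
        }
        if (!is.null(epi_pts)) {
          out <- set_contour(out, lv_contour(epi_pts, "epi", frame, sl,
                                             check = FALSE))
        }
      }
    }
    out
  })
}

#' Cohort configuration
#'
#' Defaults reproduce the shape of a multi-center consensus study: 15 cases
#' read by 7 readers, a phenotype mix of 5 healthy / 8 dilated-spectrum /
#' 2 hypertrophic, and the default reader panel.
#'
#' @param n_cases number of cases (default 15).
#' @param n_readers number of readers (default 7; >= 2).
#' @param seed master seed; all per-case and per-reader seeds derive from it.
#' @param phenotype_mix named integer vector over
#'   healthy/dilated/hypertrophic; recycled or truncated to `n_cases`.
#' @param profiles list of [reader_profile]s (default
#'   [default_reader_profiles()]).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 15L, n_readers = 7L, seed = 1L,
                          phenotype_mix = c(healthy = 5L, dilated = 8L,
                                            hypertrophic = 2L),
                          profiles = NULL) {
  stopifnot(n_cases >= 1L, n_readers >= 2L)
  if (is.null(profiles)) profiles <- default_reader_profiles(n_readers)
  stopifnot(length(profiles) == n_readers)
  phen <- rep(rep(names(phenotype_mix), phenotype_mix), length.out = n_cases)
  structure(
    list(n_cases = as.integer(n_cases), n_readers = as.integer(n_readers),
         seed = as.integer(seed), phenotypes = phen, profiles = profiles),
    class = "cohort_config"
  )
}

#' Simulate a full multi-reader cohort
#'
#' Applies [generate_phantom()] and [simulate_reader()] over the case x
#' reader grid. Every seed is derived deterministically from the config seed
#' and recorded in the manifest, so the cohort is fully reproducible.
#'
#' @param config a [cohort_config].
#' @return list of class `lv_cohort`: `truths` (named list of phantoms),
#'   `readers` (per case, a named list of reader [contour_set]s), `profiles`,
#'   `manifest` (data.frame of every seed used), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  truths <- list()
  readers <- list()
  manifest <- list()
  for (ci in seq_len(config$n_cases)) {
    case_id <- sprintf("case%02d", ci)
    cseed <- derive_seed(config$seed, ci, 0L)
    ph <- generate_phantom(config$phenotypes[ci], seed = cseed,
                           case_id = case_id)
    truths[[case_id]] <- ph
    manifest[[length(manifest) + 1L]] <- data.frame(
      case_id = case_id, source_id = "truth", seed = cseed,
      stringsAsFactors = FALSE)
    rsets <- list()
    for (ri in seq_len(config$n_readers)) {
      prof <- config$profiles[[ri]]
      rseed <- derive_seed(config$seed, ci, ri)
      rsets[[prof$reader_id]] <- simulate_reader(ph, prof, seed = rseed)
      manifest[[length(manifest) + 1L]] <- data.frame(
        case_id = case_id, source_id = prof$reader_id, seed = rseed,
        stringsAsFactors = FALSE)
    }
    readers[[case_id]] <- rsets
  }
  structure(
    list(truths = truths, readers = readers, profiles = config$profiles,
         manifest = do.call(rbind, manifest), config = config),
    class = "lv_cohort"
  )
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat("<lv_cohort>", length(x$truths), "cases x", x$config$n_readers,
      "readers (seed", x$config$seed, ")\n")
  invisible(x)
}
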