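#' Simulation scenarios
#'
#' A scenario bundles a scanner geometry, a phantom, a source and the
#' physics model.  The four NEMA set-ups are available as presets.
#'
#' @param geom a [build_scanner()] geometry (or a design preset name)
#' @param phantom a [phantom_model()]
#' @param source a `source_model`
#' @param physics a [physics_model()]; defaults to the source's emission
#'   mode with standard parameters
#' @return object of class `pet_scenario`
#' @export
scenario <- function(geom, phantom, source, physics = NULL) {
  if (is.character(geom)) geom <- build_scanner(scanner_config(geom))
  stopifnot(inherits(geom, "scanner_geometry"),
            inherits(phantom, "phantom_model"),
            inherits(source, "source_model"))
  if (is.null(physics)) {
    physics <- physics_model(
      if (source$mode == "f18") "f18" else "back_to_back")
  }
  structure(list(geometry = geom, phantom = phantom, source = source,
                 physics = physics),
            class = "pet_scenario")
}

#' @describeIn scenario NEMA sensitivity set-up: centred (or 100 mm offset)
#'   70 cm back-to-back line source, no phantom.
#' @param design `"design_a"` or `"design_b"` (or a geometry)
#' @param radial_offset mm
#' @export
scenario_sensitivity <- function(design = "design_a", radial_offset = 0,
                                 physics = NULL) {
  s <- make_sensitivity_source(radial_offset)
  scenario(design, s$phantom, s$source, physics)
}

#' @describeIn scenario NEMA count-rate set-up: scatter phantom with the
#'   F-18 line at 45 mm offset.
#' @param activity_concentration kBq/mL
#' @export
scenario_scatter <- function(design = "design_a", activity_concentration,
                             physics = NULL) {
  s <- make_scatter_phantom(activity_concentration)
  scenario(design, s$phantom, s$source, physics)
}

#' @describeIn scenario NEMA spatial-resolution set-up: F-18 point source in
#'   the glass capillary at `position`.
#' @param position length-3 mm
#' @param capillary logical
#' @export
scenario_point <- function(design = "design_a", position,
                           capillary = TRUE, physics = NULL) {
  s <- make_point_source(position, capillary = capillary)
  scenario(design, s$phantom, s$source, physics)
}

#' @describeIn scenario NEMA image-quality set-up: body phantom with six hot
#'   spheres at `sbr` : 1 against a 5.3 kBq/mL background.
#' @param sbr sphere-to-background ratio
#' @param background_concentration kBq/mL
#' @export
scenario_iq <- function(design = "design_a", sbr = 4,
                        background_concentration = 5.3, physics = NULL) {
  s <- make_iq_phantom(sbr, background_concentration)
  scenario(design, s$phantom, s$source, physics)
}

# deterministic midpoint-lattice estimate of the effective (priority-aware)
# volume of every primitive, mm^3
effective_region_volumes <- function(phantom, n_axis = 64L) {
  np <- n_primitives(phantom)
  if (np == 0L) return(numeric(0))
  bb <- primitive_bboxes(phantom)
  vols <- numeric(np)
  for (i in seq_len(np)) {
    lo <- bb[i, c(1, 3, 5)]
    hi <- bb[i, c(2, 4, 6)]
    step <- (hi - lo) / n_axis
    ax <- lapply(1:3, function(j) lo[j] + (seq_len(n_axis) - 0.5) * step[j])
    pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    idx <- point_in_phantom(phantom, pts)
    vols[i] <- prod(hi - lo) * mean(idx == i)
  }
  vols
}

source_activity_bq <- function(scn) {
  src <- scn$source
  if (src$kind != "volume") return(src$activity_bq)
  act <- scn$phantom$primitives$activity
  vols <- effective_region_volumes(scn$phantom)
  sum(act * vols)  # kBq/mL x mm^3 == Bq
}

source_list <- function(scn) {
  src <- scn$source
  if (src$kind == "line") {
    list(kind = 0L, p0 = src$p0, p1 = src$p1)
  } else if (src$kind == "point") {
    list(kind = 1L, p0 = src$p0)
  } else {
    p <- scn$phantom$primitives
    hot <- which(p$activity > 0)
    if (!length(hot)) stop("volume source has no active region")
    vols <- effective_region_volumes(scn$phantom)
    regions <- cbind(as.matrix(p[hot, c("shape", paste0("p", 1:7))]), hot)
    list(kind = 2L, regions = regions, weights = p$activity[hot] * vols[hot])
  }
}

#' Run an end-to-end singles simulation
#'
#' Samples decays as a homogeneous Poisson process at the source activity,
#' emits annihilation photon pairs (exactly back-to-back at 511 keV, or
#' F-18 mode with positron range and acolinearity), transports them through
#' the phantom and records crystal interactions as time-stamped singles
#' with full ground-truth lineage (decay id, phantom scatter count).
#'
#' Exactly one of `duration` and `n_decays` must be given; the other is
#' derived from the source activity so that absolute rates (and hence dead
#' time and randoms) are physical.
#'
#' @param scn a [scenario()]
#' @param duration acquisition time in seconds
#' @param n_decays number of decays to simulate
#' @param seed RNG seed (all randomness flows through R's RNG)
#' @param max_decays guard against accidental huge runs
#' @return object of class `pet_singles`: a list with `singles` (a
#'   time-ordered data.table), `tallies` (photon bookkeeping), `duration_s`,
#'   `activity_bq`, the scenario and the seed
#' @export
run_simulation <- function(scn, duration = NULL, n_decays = NULL,
                           seed = NULL, max_decays = 5e7) {
  stopifnot(inherits(scn, "pet_scenario"))
  if (!is.null(seed)) set.seed(seed)
  activity <- source_activity_bq(scn)
  if (is.null(n_decays) == is.null(duration)) {
    stop("give exactly one of duration or n_decays")
  }
  if (is.null(n_decays)) {
    stopifnot(duration > 0)
    expected <- activity * duration
    if (expected > max_decays) {
      stop(sprintf(
        "duration x activity = %.3g decays exceeds the event budget (%.3g); raise max_decays deliberately",
        expected, max_decays))
    }
    n_decays <- rpois(1, expected)
  } else {
    if (n_decays > max_decays) {
      stop("n_decays exceeds the event budget; raise max_decays deliberately")
    }
    duration <- if (activity > 0) n_decays / activity else 0
  }
  out <- simulate_singles_cpp(
    geom_list(scn$geometry), phantom_matrix(scn$phantom),
    phantom_aux(scn$phantom), source_list(scn),
    as.numeric(n_decays), duration * 1e9, scn$physics)
  tallies <- out$tallies
  out$tallies <- NULL
  singles <- setDT(out)  # in place: no copy of the event columns
  setorder(singles, t_ns)
  structure(
    list(singles = singles, tallies = tallies, duration_s = duration,
         activity_bq = activity, n_decays = n_decays, seed = seed,
         scenario = scn),
    class = "pet_singles")
}

#' @export
print.pet_singles <- function(x, ...) {
  cat(sprintf(
    "pet_singles: %d singles from %.4g decays over %.4g s (activity %.4g Bq)\n",
    nrow(x$singles), x$n_decays, x$duration_s, x$activity_bq))
  invisible(x)
}

# ---------------------------------------------------------------------------
# unit-level surfaces of the engine steps (the fused C++ run uses the same
# inline routines)

#' Sample a decay stream
#'
#' Homogeneous Poisson process at the source activity over `duration`
#' seconds; positions uniform on the source region (for volume sources the
#' containing phantom must be given for priority-aware rejection sampling).
#'
#' @param source a `source_model`
#' @param duration seconds
#' @param seed RNG seed
#' @param phantom required for volume sources
#' @param activity_bq override the source activity
#' @return data.table: `decay_id`, `t_ns` (non-decreasing), `x`, `y`, `z`
#' @export
sample_decays <- function(source, duration, seed = NULL, phantom = NULL,
                          activity_bq = NULL) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(activity_bq)) {
    activity_bq <- if (source$kind == "volume") {
      stopifnot(!is.null(phantom))
      sum(phantom$primitives$activity * effective_region_volumes(phantom))
    } else {
      source$activity_bq
    }
  }
  n <- rpois(1, activity_bq * duration)
  t_ns <- sort(runif(n, 0, duration * 1e9))
  pos <- if (n == 0) {
    matrix(0, 0, 3)
  } else if (source$kind == "line") {
    u <- runif(n)
    cbind(source$p0[1] + u * (source$p1[1] - source$p0[1]),
          source$p0[2] + u * (source$p1[2] - source$p0[2]),
          source$p0[3] + u * (source$p1[3] - source$p0[3]))
  } else if (source$kind == "point") {
    matrix(source$p0, n, 3, byrow = TRUE)
  } else {
    sample_volume_positions(phantom, n)
  }
  data.table(decay_id = seq_len(n), t_ns = t_ns,
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

sample_volume_positions <- function(phantom, n) {
  p <- phantom$primitives
  hot <- which(p$activity > 0)
  vols <- effective_region_volumes(phantom)
  w <- p$activity[hot] * vols[hot]
  reg <- sample(hot, n, replace = TRUE, prob = w)
  pos <- matrix(NA_real_, n, 3)
  bb <- primitive_bboxes(phantom)
  for (i in hot) {
    k <- which(reg == i)
    if (!length(k)) next
    got <- 0L
    while (got < length(k)) {
      m <- (length(k) - got) * 3L + 16L
      cand <- cbind(runif(m, bb[i, 1], bb[i, 2]), runif(m, bb[i, 3], bb[i, 4]),
                    runif(m, bb[i, 5], bb[i, 6]))
      ok <- which(point_in_phantom(phantom, cand) == i)
      take <- head(ok, length(k) - got)
      if (length(take)) {
        pos[k[(got + 1):(got + length(take))], ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
  }
  pos
}

#' Emit annihilation photon direction pairs
#'
#' Isotropic first photon; in back-to-back mode the second is the exact
#' antipode, in F-18 mode it deviates from 180 degrees by a half-normal
#' angle with the configured FWHM (acolinearity).
#'
#' @param n number of pairs
#' @param physics a [physics_model()]
#' @param seed RNG seed
#' @return list of two n x 3 unit-vector matrices `d1`, `d2`
#' @export
emit_pairs <- function(n, physics = physics_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  emit_pairs_cpp(n, physics)
}

#' Transport photons through a phantom
#'
#' Woodcock (delta) tracking with photoelectric absorption and
#' Klein-Nishina Compton scattering; terminates below the energy cutoff.
#'
#' @param pos,dir n x 3 start positions and unit directions
#' @param energy keV (defaults to 511)
#' @param phantom a [phantom_model()]
#' @param energy_cutoff keV
#' @param seed RNG seed
#' @return list: end `pos`, `dir`, `energy`, cumulative `path` (mm),
#'   `n_scatters`, `escaped` (1/0)
#' @export
transport_photons <- function(pos, dir, energy = 511, phantom,
                              energy_cutoff = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- rbind_point(pos); dir <- rbind_point(dir)
  if (length(energy) == 1L) energy <- rep(energy, nrow(pos))
  transport_photons_cpp(pos, dir, energy, phantom_matrix(phantom),
                        phantom_aux(phantom), energy_cutoff)
}

#' Detect escaped photons in the crystal slabs
#'
#' Finds the first slab along each ray, samples the interaction depth from
#' the LYSO attenuation along the chord (miss if none), deposits the full
#' energy with probability `p_full` or a Compton-escape deposit otherwise,
#' blurs the deposit with the sqrt-scaled energy resolution and timestamps
#' the single with time-of-flight plus Gaussian jitter.
#'
#' @param pos,dir n x 3 escape positions and unit directions
#' @param energy photon energies (keV)
#' @param path0 path already travelled since the decay (mm)
#' @param tdecay_ns decay times (ns)
#' @param geom scanner geometry
#' @param physics a [physics_model()]
#' @param seed RNG seed
#' @return list with `module` (0 = not detected), interaction `point`,
#'   `energy_dep`, `energy_meas`, `t_ns` and `fate` (1 detected, 2 missed
#'   geometry, 3 crossed a slab without interacting)
#' @export
detect_in_crystal <- function(pos, dir, energy = 511, path0 = 0,
                              tdecay_ns = 0, geom,
                              physics = physics_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- rbind_point(pos); dir <- rbind_point(dir)
  n <- nrow(pos)
  if (length(energy) == 1L) energy <- rep(energy, n)
  if (length(path0) == 1L) path0 <- rep(path0, n)
  if (length(tdecay_ns) == 1L) tdecay_ns <- rep(tdecay_ns, n)
  detect_photons_cpp(pos, dir, energy, path0, tdecay_ns,
                     geom_list(geom), physics)
}
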