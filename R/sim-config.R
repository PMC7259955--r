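#' Simulation configuration for the two-state SPT generator
#'
#' Builds and validates the generative parameters of the two-state diffusion
#' model: a fraction `f_bound` of molecules is chromatin-bound for its whole
#' observed lifetime and diffuses slowly (`d_bound`); the remainder diffuses
#' fast (`d_free`) and, in addition, moves axially until it leaves the
#' detection slab of thickness `dz`, which terminates its track. Observed
#' positions carry independent Gaussian localization error per axis.
#'
#' @param n_molecules number of molecules to simulate.
#' @param f_bound fraction of molecules in the bound state, in `[0, 1]`.
#' @param d_bound diffusion coefficient of bound molecules, um^2/s.
#' @param d_free diffusion coefficient of free molecules, um^2/s.
#' @param sigma_loc localization error SD per axis, um.
#' @param dt frame interval, seconds (default 0.010, i.e. 10 ms).
#' @param dz axial detection range (slab thickness), um.
#' @param bleach_prob per-frame photobleaching probability in `[0, 1)`.
#'   Track lifetimes are geometric with this rate.
#' @param roi lateral field size, um; initial x/y positions are uniform in a
#'   `roi` x `roi` square (lateral motion itself is unbounded).
#' @param pixel_size camera pixel size, um (default 0.107).
#' @param min_track_len minimum number of frames for a track to be kept.
#' @param n_frames movie length in frames; molecules appear at staggered
#'   start frames within the movie when `stagger_starts` is `TRUE` and tracks
#'   are truncated at the last frame.
#' @param stagger_starts logical; if `FALSE` every molecule starts at frame 1
#'   (useful for deterministic toy cases).
#' @param seed integer seed driving all randomness of a simulation.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [condition_preset()] for configurations matching named
#'   experimental conditions, [simulate_trajectories()].
#' @export
sim_config <- function(n_molecules = 5000,
                       f_bound = 0.5,
                       d_bound = 0.03,
                       d_free = 1.0,
                       sigma_loc = 0.03,
                       dt = 0.010,
                       dz = 0.65,
                       bleach_prob = 0.1,
                       roi = 2.0,
                       pixel_size = 0.107,
                       min_track_len = 3,
                       n_frames = 2000,
                       stagger_starts = TRUE,
                       seed = NULL) {
  check_number(n_molecules, "n_molecules", lower = 1, integer = TRUE)
  check_number(f_bound, "f_bound", lower = 0, upper = 1)
  check_number(d_bound, "d_bound", lower = 0)
  check_number(d_free, "d_free", lower = 0)
  check_number(sigma_loc, "sigma_loc", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(dz, "dz", lower = 0, strict_lower = TRUE)
  check_number(bleach_prob, "bleach_prob", lower = 0, upper = 1)
  if (bleach_prob >= 1) stop_field("bleach_prob", "must be < 1")
  check_number(roi, "roi", lower = 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(min_track_len, "min_track_len", lower = 2, integer = TRUE)
  check_number(n_frames, "n_frames", lower = 2, integer = TRUE)
  if (!is.logical(stagger_starts) || length(stagger_starts) != 1L ||
      is.na(stagger_starts)) {
    stop_field("stagger_starts", "must be TRUE or FALSE")
  }
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)

  structure(
    list(
      n_molecules = as.integer(n_molecules),
      f_bound = f_bound,
      d_bound = d_bound,
      d_free = d_free,
      sigma_loc = sigma_loc,
      dt = dt,
      dz = dz,
      bleach_prob = bleach_prob,
      roi = roi,
      pixel_size = pixel_size,
      min_track_len = as.integer(min_track_len),
      n_frames = as.integer(n_frames),
      stagger_starts = stagger_starts,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-state SPT simulation config\n")
  cat(sprintf("  molecules: %d  f_bound: %.3f\n", x$n_molecules, x$f_bound))
  cat(sprintf("  D_bound: %g um^2/s  D_free: %g um^2/s\n", x$d_bound, x$d_free))
  cat(sprintf("  sigma_loc: %g um  dt: %g s  dz: %g um\n",
              x$sigma_loc, x$dt, x$dz))
  cat(sprintf("  bleach_prob: %g/frame  min_track_len: %d  n_frames: %d\n",
              x$bleach_prob, x$min_track_len, x$n_frames))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Condition table: chromatin-bound fractions and diffusion coefficients
# reported for each strain/perturbation, used as generative ground truth.
# dz reflects the dye used for that condition (0.65 um JF646, 0.60 um JF552).
.preset_table <- function() {
  list(
    h2az_wt       = list(f_bound = 0.82, d_bound = 0.03, d_free = 1.18, dz = 0.65),
    h2b_wt        = list(f_bound = 0.76, d_bound = 0.03, d_free = 1.29, dz = 0.65),
    swr1_wt       = list(f_bound = 0.47, d_bound = 0.03, d_free = 1.00, dz = 0.65),
    swr1_swc2del  = list(f_bound = 0.21, d_bound = 0.03, d_free = 1.00, dz = 0.65),
    swc5_norap    = list(f_bound = 0.79, d_bound = 0.03, d_free = 1.18, dz = 0.60),
    swc5_aa       = list(f_bound = 0.49, d_bound = 0.03, d_free = 1.18, dz = 0.60),
    swc5_rpb1_aa  = list(f_bound = 0.66, d_bound = 0.03, d_free = 1.18, dz = 0.60),
    swc5_kin28_aa = list(f_bound = 0.65, d_bound = 0.03, d_free = 1.18, dz = 0.60)
  )
}

#' Simulation presets for named experimental conditions
#'
#' Returns a [sim_config()] whose bound fraction and diffusion coefficients
#' equal the values reported for a named condition of the underlying
#' live-yeast SPT study, so that closed-loop parameter-recovery runs can use
#' them as generative ground truth.
#'
#' Available presets:
#' \describe{
#'   \item{`h2az_wt`}{H2A.Z-Halo, wild type: 82\% bound, free D 1.18 um^2/s.}
#'   \item{`h2b_wt`}{Halo-H2B, wild type: 76\% bound, free D 1.29 um^2/s.}
#'   \item{`swr1_wt`}{Swr1-Halo, wild type: 47\% bound.}
#'   \item{`swr1_swc2del`}{Swr1-Halo in the swc2 deletion: 21\% bound.}
#'   \item{`swc5_norap`}{H2A.Z-Halo in the Swc5 anchor-away strain without
#'     rapamycin: 79\% bound.}
#'   \item{`swc5_aa`}{H2A.Z-Halo after Swc5 anchor-away: 49\% bound.}
#'   \item{`swc5_rpb1_aa`}{H2A.Z-Halo after Swc5+Rpb1 double anchor-away:
#'     66\% bound.}
#'   \item{`swc5_kin28_aa`}{H2A.Z-Halo after Swc5+Kin28 double anchor-away:
#'     65\% bound.}
#' }
#' Bound-state D is 0.03 um^2/s throughout (reported average for chromatin-
#' bound histones). The Swr1 free-state D is not reported; 1.0 um^2/s is used
#' (a ~1 MDa complex, somewhat slower than free histone dimers). `dz` follows
#' the dye used per condition: 0.65 um (JF646) for the wild-type/Swr1 panels,
#' 0.60 um (JF552) for the anchor-away panels.
#'
#' @param name preset name (see Details).
#' @param ... overrides passed on to [sim_config()] (e.g. `n_molecules`,
#'   `seed`).
#' @return A `sim_config` object.
#' @export
condition_preset <- function(name, ...) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      !(name %in% names(tab))) {
    stop(sprintf(
      "unknown condition preset %s; valid names: %s",
      if (is.character(name) && length(name) == 1L) dQuote(name) else "<non-string>",
      paste(names(tab), collapse = ", ")
    ), call. = FALSE)
  }
  p <- tab[[name]]
  cfg <- sim_config(f_bound = p$f_bound, d_bound = p$d_bound,
                    d_free = p$d_free, dz = p$dz, ...)
  cfg$condition <- name
  cfg
}
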