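#' Time-lapse configuration for synthetic recordings
#'
#' Dynamics of a synthetic time-lapse: per-interval Markovian polarity
#' inversions (the dominant cluster switching poles), cell divisions at
#' midcell with old/new pole bookkeeping, and rigid-body positional drift.
#' Defaults emulate a strain with stable polarity and an old-pole
#' preference after division (inversion probability 0.12 per 10-min
#' interval, 64% of daughters starting with the dominant cluster at the
#' old pole).
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Minutes between frames.
#' @param inversion_prob Per-interval probability that the dominant pole
#'   switches.
#' @param division_prob Per-interval probability of division per cell.
#' @param old_pole_bias_prob Probability that a daughter's dominant cluster
#'   starts at its old (inherited) pole.
#' @param drift_sd Rigid translation per frame (px, per axis).
#' @return An object of class `timelapse_config`.
#' @export
timelapse_config <- function(n_frames = 12, frame_interval = 10,
                             inversion_prob = 0.12, division_prob = 0.02,
                             old_pole_bias_prob = 0.64, drift_sd = 1) {
  probs <- c(inversion_prob, division_prob, old_pole_bias_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_frames < 2) abort("n_frames must be at least 2")
  structure(as.list(environment()), class = "timelapse_config")
}

#' Generate a synthetic time-lapse with lineage and inversion truth
#'
#' Evolves a snapshot scene over time: the dominant-pole identity of each
#' cell follows a Bernoulli switch per interval, cells divide at midcell
#' (each daughter inheriting one old pole), and whole cells drift. Ground
#' truth records every inversion and division. Frames are rendered as
#' images only when `render = TRUE`; the truth table alone suffices for
#' tracking benchmarks.
#'
#' @param scene A [scene_config()].
#' @param dyn A [timelapse_config()].
#' @param render Logical; render per-frame images and label masks.
#' @param seed Integer seed (falls back to `scene$rng_seed`).
#' @return An object of class `polarity_timelapse`: list with `truth` (one
#'   row per cell per frame: cell_id, frame, pole coordinates, p1/p2/total
#'   truth, old_pole, parent_id, inverted_this_frame), `frames` (list of
#'   images or NULL), `masks` (list of label matrices or NULL) and the two
#'   configs.
#' @export
#' @examples
#' tl <- generate_timelapse(scene_config(n_cells = 4), timelapse_config(),
#'                          seed = 1)
#' head(tl$truth)
generate_timelapse <- function(scene, dyn, render = FALSE, seed = NULL) {
  stopifnot(inherits(scene, "scene_config"), inherits(dyn, "timelapse_config"))
  seed <- seed %||% scene$rng_seed
  with_seed(seed, {
    cells <- place_cells(scene)
    n0 <- length(cells)
    fr <- draw_cell_fractions(n0, scene)
    state <- lapply(seq_len(n0), function(i) {
      list(id = i, pole1 = cells[[i]]$pole1, pole2 = cells[[i]]$pole2,
           p_hi = fr[i, "p1"], p_lo = fr[i, "p2"],
           dom_pole = sample(1:2, 1),
           total = max(rnorm(1, scene$total_intensity_mean,
                             scene$total_intensity_sd),
                       scene$total_intensity_mean / 10),
           old_pole = NA_integer_, parent = NA_integer_)
    })
    next_id <- as.integer(n0 + 1L)
    rows <- list()
    frames <- list()
    mask_stack <- list()
    W <- scene$image_width; H <- scene$image_height
    for (f in seq_len(dyn$n_frames)) {
      inverted <- setNames(logical(length(state)),
                           vapply(state, `[[`, integer(1), "id"))
      if (f > 1) {
        # drift, inversion, division
        new_state <- list()
        for (cell in state) {
          shift <- rnorm(2, 0, dyn$drift_sd)
          cell$pole1 <- pmin(pmax(cell$pole1 + shift, 1), c(W, H))
          cell$pole2 <- pmin(pmax(cell$pole2 + shift, 1), c(W, H))
          if (runif(1) < dyn$inversion_prob) {
            cell$dom_pole <- 3L - cell$dom_pole
            inverted[as.character(cell$id)] <- TRUE
          }
          len <- sqrt(sum((cell$pole2 - cell$pole1)^2))
          if (runif(1) < dyn$division_prob && len > 4 * scene$cell_width) {
            mid <- (cell$pole1 + cell$pole2) / 2
            u <- (cell$pole2 - cell$pole1) / len
            gap <- scene$cell_width / 2
            for (k in 1:2) {
              outer_pole <- if (k == 1) cell$pole1 else cell$pole2
              inner_pole <- if (k == 1) mid - gap * u else mid + gap * u
              dom_at_old <- runif(1) < dyn$old_pole_bias_prob
              d <- list(id = next_id,
                        pole1 = outer_pole, pole2 = inner_pole,
                        p_hi = cell$p_hi, p_lo = cell$p_lo,
                        dom_pole = if (dom_at_old) 1L else 2L,
                        total = cell$total / 2,
                        old_pole = 1L, parent = cell$id)
              next_id <- next_id + 1L
              new_state[[length(new_state) + 1]] <- d
              inverted[as.character(d$id)] <- FALSE
            }
          } else {
            new_state[[length(new_state) + 1]] <- cell
          }
        }
        state <- new_state
      }
      truth_f <- dplyr::bind_rows(lapply(state, function(cell) {
        p1f <- if (cell$dom_pole == 1) cell$p_hi else cell$p_lo
        tibble(cell_id = cell$id, frame = f,
               pole1_x = cell$pole1[1], pole1_y = cell$pole1[2],
               pole2_x = cell$pole2[1], pole2_y = cell$pole2[2],
               p1_true = p1f, p2_true = cell$p_hi + cell$p_lo - p1f,
               total_true = cell$total,
               old_pole = cell$old_pole, parent_id = cell$parent,
               inverted_this_frame = unname(inverted[as.character(cell$id)]))
      }))
      rows[[f]] <- truth_f
      if (render) {
        geom <- lapply(state, function(cell)
          list(pixels = capsule_pixels(cell$pole1, cell$pole2,
                                       scene$cell_width, W, H)))
        rendered <- render_scene(scene, geom, truth_f)
        frames[[f]] <- rendered$image
        mask_stack[[f]] <- rendered$masks
      }
    }
    structure(list(truth = dplyr::bind_rows(rows),
                   frames = if (render) frames else NULL,
                   masks = if (render) mask_stack else NULL,
                   scene = scene, dyn = dyn),
              class = "polarity_timelapse")
  })
}

#' Induction-series configuration
#'
#' Emulates gradual induction of a fluorescent reporter: total cellular
#' fluorescence concentration rises linearly in time, and the polar
#' fractions follow a saturating law whose shape encodes cooperativity. For
#' `hill_coefficient = 1` (non-cooperative binding) the polar fraction is
#' constant, independent of concentration -- the null signature. For
#' `hill_coefficient > 1` the fraction at each pole rises with concentration
#' as `capacity * c^(h-1) / (c^(h-1) + half_saturation^(h-1))`.
#'
#' @param conc_max Maximal fluorescence concentration reached (intensity per
#'   area unit).
#' @param n_timepoints Number of time points.
#' @param hill_coefficient Cooperativity exponent (>= 1).
#' @param half_saturation Concentration of half-maximal polar fraction.
#' @param capacity_frac Limiting total polar fraction (both poles), in
#'   `(0, 1]`.
#' @param asymmetry_ratio Ratio of pole-1 to pole-2 capacity.
#' @return An object of class `induction_config`.
#' @export
induction_config <- function(conc_max = 100, n_timepoints = 24,
                             hill_coefficient = 2, half_saturation = 30,
                             capacity_frac = 0.4, asymmetry_ratio = 3) {
  if (hill_coefficient < 1) abort("hill_coefficient must be >= 1")
  if (capacity_frac <= 0 || capacity_frac > 1)
    abort("capacity_frac must lie in (0, 1]")
  structure(as.list(environment()), class = "induction_config")
}

induction_fraction <- function(conc, cap, h, k_half) {
  out <- numeric(length(conc))
  pos <- conc > 0
  out[pos] <- if (h == 1) {
    cap
  } else {
    cap * conc[pos]^(h - 1) / (conc[pos]^(h - 1) + k_half^(h - 1))
  }
  out
}

#' Generate a synthetic induction series
#'
#' @param config An [induction_config()].
#' @param per_cell If `TRUE`, emit noisy per-cell observations
#'   (`n_cells_per_time` cells per time point with concentration jitter,
#'   fraction noise and a cell area), suitable for [analyze_induction()].
#'   Otherwise returns the deterministic curve.
#' @param n_cells_per_time,conc_cv,frac_noise_sd,area_mean Per-cell
#'   observation settings.
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `concentration`, `p1_frac`,
#'   `p2_frac`, plus `cell_id`, `area`, `total_fluorescence`, `P1`, `P2`
#'   when `per_cell = TRUE`.
#' @export
#' @examples
#' generate_induction_series(induction_config(hill_coefficient = 1))
generate_induction_series <- function(config, per_cell = FALSE,
                                      n_cells_per_time = 8, conc_cv = 0.25,
                                      frac_noise_sd = 0.01, area_mean = 600,
                                      seed = NULL) {
  stopifnot(inherits(config, "induction_config"))
  times <- seq_len(config$n_timepoints)
  conc <- config$conc_max * times / config$n_timepoints
  cap1 <- config$capacity_frac * config$asymmetry_ratio /
    (1 + config$asymmetry_ratio)
  cap2 <- config$capacity_frac / (1 + config$asymmetry_ratio)
  h <- config$hill_coefficient
  k <- config$half_saturation
  curve <- tibble(time = times, concentration = conc,
                  p1_frac = induction_fraction(conc, cap1, h, k),
                  p2_frac = induction_fraction(conc, cap2, h, k))
  if (any(curve$p1_frac + curve$p2_frac > 1))
    abort("polar fractions exceed 1; reduce capacity_frac")
  if (!per_cell) return(curve)
  with_seed(seed, {
    cells <- tidyr::expand_grid(time = times,
                                rep = seq_len(n_cells_per_time))
    cells$cell_id <- seq_len(nrow(cells))
    cells$concentration <- config$conc_max * cells$time /
      config$n_timepoints * exp(rnorm(nrow(cells), 0, conc_cv))
    cells$area <- pmax(rnorm(nrow(cells), area_mean, area_mean / 8), 50)
    cells$total_fluorescence <- cells$concentration * cells$area
    cells$P1 <- pmax(induction_fraction(cells$concentration, cap1, h, k) +
                       rnorm(nrow(cells), 0, frac_noise_sd), 0)
    cells$P2 <- pmax(induction_fraction(cells$concentration, cap2, h, k) +
                       rnorm(nrow(cells), 0, frac_noise_sd), 0)
    if (any(cells$P1 + cells$P2 > 1)) abort("polar fractions exceed 1")
    dplyr::select(cells, "cell_id", "time", "concentration", "area",
                  "total_fluorescence", "P1", "P2")
  })
}

#' Sample per-cell polar fractions for a strain
#'
#' Draws `(P1, P2)` pairs from a bivariate normal with mean
#' `(m (1 + omega) / 2, m (1 - omega) / 2)` truncated by rejection to the
#' physical simplex `P1 >= 0, P2 >= 0, P1 + P2 <= 1`, emulating the
#' single-cell scatter of snapshot quantification.
#'
#' @param mean_total Target mean total polar fraction `m` in `[0, 1]`.
#' @param omega Target mean asymmetry in `[-1, 1]`.
#' @param covariance 2x2 positive semidefinite covariance matrix (a scalar
#'   is expanded to `diag(x, 2)`).
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return A tibble with columns `P1`, `P2`.
#' @export
#' @examples
#' s <- generate_strain_sample(0.212, 0.5, diag(0.03^2, 2), 1000, seed = 1)
#' colMeans(s)
generate_strain_sample <- function(mean_total, omega, covariance, n,
                                   seed = NULL) {
  if (mean_total < 0 || mean_total > 1) abort("mean_total must be in [0, 1]")
  if (abs(omega) > 1) abort("omega must be in [-1, 1]")
  if (length(covariance) == 1) covariance <- diag(covariance, 2)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) abort("covariance must be positive semidefinite")
  mu <- c(mean_total * (1 + omega) / 2, mean_total * (1 - omega) / 2)
  if (mu[1] < 0 || mu[2] < 0 || sum(mu) > 1)
    abort("implied pole means lie outside the simplex")
  with_seed(seed, {
    out <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(out) < n) {
      m <- max(n * 2, 100)
      draw <- MASS::mvrnorm(m, mu, covariance)
      keep <- draw[, 1] >= 0 & draw[, 2] >= 0 & rowSums(draw) <= 1
      out <- rbind(out, draw[keep, , drop = FALSE])
      tries <- tries + 1
      if (tries > 1000) abort("rejection sampling failed; check covariance")
    }
    tibble(P1 = out[seq_len(n), 1], P2 = out[seq_len(n), 2])
  })
}
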