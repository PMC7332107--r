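#' Scene configuration for synthetic fluorescence snapshots
#'
#' Describes a synthetic wide-field fluorescence image of rod-shaped cells
#' with polar protein clusters. Cells are rendered as capsules (a rectangle
#' with semicircular caps) of realistic aspect ratio (about 70 x 11 px,
#' roughly a 4.5 um x 0.7 um cell at 65 nm/px); each cell carries a diffuse
#' cytoplasmic signal plus two polar clusters rendered as isotropic 2-D
#' Gaussians centred 2 px inside the pole tips. Noise is Poisson shot noise
#' on the expected photon count plus Gaussian read noise.
#'
#' @param image_width,image_height Image size in pixels.
#' @param n_cells Number of cells to place (without mask overlap).
#' @param cell_length_mean,cell_length_sd Tip-to-tip cell length (px).
#' @param cell_width Cell width (px).
#' @param background_level Mean background intensity (counts).
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param shot_noise Logical; add Poisson noise on the expected intensity.
#' @param cluster_sigma Standard deviation of the polar cluster Gaussian (px).
#' @param total_intensity_mean,total_intensity_sd Integrated fluorescence per
#'   cell (counts).
#' @param mean_total,omega_mean,frac_sd Parameters of the truncated bivariate
#'   normal from which per-cell polar fractions (p1, p2) are drawn when no
#'   explicit truth is supplied (defaults emulate a RomR-like reporter).
#' @param stray_fraction,stray_intensity A minority of out-of-mask pixels
#'   carries extra intensity (out-of-focus debris and stray fluorescence),
#'   reproducing the bimodal out-of-cell intensity distribution of real
#'   images that the mixture-model background estimator assumes.
#' @param rng_seed Integer seed.
#' @return An object of class `scene_config` (a list).
#' @seealso [generate_snapshot_scene()], [generate_timelapse()]
#' @export
scene_config <- function(image_width = 512, image_height = 512,
                         n_cells = 20,
                         cell_length_mean = 70, cell_length_sd = 7,
                         cell_width = 11,
                         background_level = 100, read_noise_sd = 5,
                         shot_noise = TRUE, cluster_sigma = 1,
                         total_intensity_mean = 20000,
                         total_intensity_sd = 2000,
                         mean_total = 0.212, omega_mean = 0.5,
                         frac_sd = 0.03,
                         stray_fraction = 0.05, stray_intensity = 60,
                         rng_seed = NULL) {
  cfg <- as.list(environment())
  if (image_width <= 0 || image_height <= 0 || n_cells < 0)
    abort("image dimensions must be positive and n_cells >= 0")
  if (cluster_sigma <= 0) abort("cluster_sigma must be positive")
  structure(cfg, class = "scene_config")
}

# Pixels of a capsule with tip-to-tip endpoints p1, p2 (x, y) and width w.
# Returns an integer matrix with columns row, col (1-based).
capsule_pixels <- function(p1, p2, w, width, height) {
  r <- w / 2
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  c1 <- p1 + r * u
  c2 <- p2 - r * u
  xmin <- max(1L, floor(min(p1[1], p2[1]) - r)); xmax <- min(width,  ceiling(max(p1[1], p2[1]) + r))
  ymin <- max(1L, floor(min(p1[2], p2[2]) - r)); ymax <- min(height, ceiling(max(p1[2], p2[2]) + r))
  if (xmin > xmax || ymin > ymax) return(cbind(row = integer(0), col = integer(0)))
  gx <- xmin:xmax
  gy <- ymin:ymax
  px <- rep(gx, each = length(gy))
  py <- rep(gy, times = length(gx))
  # distance from each pixel centre to the segment c1-c2
  vx <- c2[1] - c1[1]; vy <- c2[2] - c1[2]
  L2 <- vx^2 + vy^2
  t <- if (L2 > 0) pmin(1, pmax(0, ((px - c1[1]) * vx + (py - c1[2]) * vy) / L2)) else 0
  dx <- px - (c1[1] + t * vx)
  dy <- py - (c1[2] + t * vy)
  keep <- dx^2 + dy^2 <= r^2
  cbind(row = py[keep], col = px[keep])
}

# Draw (p1, p2) polar fractions for cells from the truncated bivariate
# normal used by generate_strain_sample, sorted so p1 >= p2.
draw_cell_fractions <- function(n, cfg) {
  if (n == 0) return(cbind(p1 = numeric(0), p2 = numeric(0)))
  s <- generate_strain_sample(cfg$mean_total, cfg$omega_mean,
                              covariance = diag(cfg$frac_sd^2, 2), n = n)
  cbind(p1 = pmax(s$P1, s$P2), p2 = pmin(s$P1, s$P2))
}

# Place n capsules uniformly at random without mask overlap (1-px clearance).
# Returns a list of per-cell geometry or aborts after bounded retries.
place_cells <- function(cfg, lengths = NULL, max_tries = 200) {
  W <- cfg$image_width; H <- cfg$image_height
  occupied <- matrix(FALSE, H, W)
  cells <- list()
  n <- cfg$n_cells
  if (is.null(lengths))
    lengths <- pmax(cfg$cell_width * 2,
                    rnorm(n, cfg$cell_length_mean, cfg$cell_length_sd))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      len <- lengths[i]
      ang <- runif(1, 0, pi)
      margin <- len / 2 + cfg$cell_width
      if (W - margin <= margin || H - margin <= margin)
        abort("image too small for the requested cell size")
      ctr <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
      half <- (len / 2) * c(cos(ang), sin(ang))
      p1 <- ctr - half; p2 <- ctr + half
      px <- capsule_pixels(p1, p2, cfg$cell_width, W, H)
      if (nrow(px) == 0) next
      # 1-px dilated clearance against existing masks
      rr <- pmin(pmax(rep(px[, 1], 3) + rep(c(-1L, 0L, 1L), each = nrow(px)), 1L), H)
      cc <- pmin(pmax(rep(px[, 2], 3) + rep(c(-1L, 0L, 1L), each = nrow(px)), 1L), W)
      if (any(occupied[cbind(rr, cc)])) next
      occupied[px] <- TRUE
      cells[[i]] <- list(pole1 = p1, pole2 = p2, length = len, pixels = px)
      placed <- TRUE
      break
    }
    if (!placed)
      abort(sprintf("failed to place cell %d of %d without overlap", i, n))
  }
  cells
}

# Discretized isotropic Gaussian of unit mass centred at (x, y), added onto
# image `im` scaled by `mass`.
add_gaussian <- function(im, x, y, sigma, mass) {
  H <- nrow(im); W <- ncol(im)
  r <- ceiling(4 * sigma) + 1
  cols <- max(1L, floor(x - r)):min(W, ceiling(x + r))
  rows <- max(1L, floor(y - r)):min(H, ceiling(y + r))
  gx <- exp(-(cols - x)^2 / (2 * sigma^2))
  gy <- exp(-(rows - y)^2 / (2 * sigma^2))
  patch <- outer(gy, gx)
  patch <- patch / sum(patch) * mass
  im[rows, cols] <- im[rows, cols] + patch
  im
}

render_scene <- function(cfg, cells, truth) {
  H <- cfg$image_height; W <- cfg$image_width
  img <- matrix(cfg$background_level, H, W)
  labels <- matrix(0L, H, W)
  for (i in seq_along(cells)) {
    px <- cells[[i]]$pixels
    labels[px] <- i
    diffuse <- truth$total_true[i] * (1 - truth$p1_true[i] - truth$p2_true[i])
    img[px] <- img[px] + diffuse / nrow(px)
    for (k in 1:2) {
      p <- c(truth[[paste0("pole", k, "_x")]][i],
             truth[[paste0("pole", k, "_y")]][i])
      other <- c(truth[[paste0("pole", 3 - k, "_x")]][i],
                 truth[[paste0("pole", 3 - k, "_y")]][i])
      u <- (other - p) / sqrt(sum((other - p)^2))
      ctr <- p + 2 * u  # cluster centre 2 px inside the pole tip
      mass <- truth$total_true[i] * truth[[paste0("p", k, "_true")]][i]
      if (mass > 0) img <- add_gaussian(img, ctr[1], ctr[2],
                                        cfg$cluster_sigma, mass)
    }
  }
  if (cfg$stray_fraction > 0 && cfg$stray_intensity > 0) {
    bg_px <- which(labels == 0L)
    n_stray <- round(cfg$stray_fraction * length(bg_px))
    if (n_stray > 0) {
      stray <- sample(bg_px, n_stray)
      img[stray] <- img[stray] + cfg$stray_intensity
    }
  }
  if (isTRUE(cfg$shot_noise))
    img <- matrix(rpois(length(img), pmax(img, 0)), H, W)
  if (cfg$read_noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, cfg$read_noise_sd), H, W)
  list(image = img, masks = labels)
}

#' Generate a synthetic snapshot scene with known ground truth
#'
#' Places non-overlapping capsule-shaped cells, draws per-cell polar
#' fractions, renders diffuse plus polar-cluster fluorescence with optional
#' shot and read noise, and returns the image, the 16-bit-style integer
#' label mask (background 0) and the ground-truth table.
#'
#' @param config A [scene_config()].
#' @param truth Optional ground-truth tibble overriding the generated one
#'   (columns as in the returned `truth`); geometry is still placed randomly
#'   unless pole coordinates are supplied for every cell.
#' @return An object of class `polarity_scene`: a list with elements `image`
#'   (numeric matrix), `masks` (integer label matrix), `truth` (tibble with
#'   cell_id, pole coordinates, p1/p2/total truth, old_pole, parent_id) and
#'   `config`.
#' @export
#' @examples
#' sc <- generate_snapshot_scene(scene_config(n_cells = 3, rng_seed = 1))
#' sc$truth
generate_snapshot_scene <- function(config, truth = NULL) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    cells <- place_cells(config)
    n <- length(cells)
    if (is.null(truth)) {
      fr <- draw_cell_fractions(n, config)
      totals <- if (n > 0)
        pmax(rnorm(n, config$total_intensity_mean, config$total_intensity_sd),
             config$total_intensity_mean / 10) else numeric(0)
      truth <- tibble(
        cell_id = seq_len(n),
        pole1_x = vapply(cells, function(c) c$pole1[1], numeric(1)),
        pole1_y = vapply(cells, function(c) c$pole1[2], numeric(1)),
        pole2_x = vapply(cells, function(c) c$pole2[1], numeric(1)),
        pole2_y = vapply(cells, function(c) c$pole2[2], numeric(1)),
        p1_true = fr[, "p1"], p2_true = fr[, "p2"],
        total_true = totals,
        old_pole = NA_integer_, parent_id = NA_integer_)
    }
    if (any(truth$p1_true + truth$p2_true > 1))
      abort("planted fractions exceed 1")
    rendered <- render_scene(config, cells, truth)
    structure(list(image = rendered$image, masks = rendered$masks,
                   truth = truth, config = config),
              class = "polarity_scene")
  })
}
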