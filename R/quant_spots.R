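# 8-connected components among a set of pixels given as a (row, col) matrix.
# Returns a list of index vectors into the input rows.
connected_components8 <- function(px) {
  n <- nrow(px)
  if (n == 0) return(list())
  key <- paste(px[, 1], px[, 2])
  lookup <- setNames(seq_len(n), key)
  seen <- logical(n)
  comps <- list()
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i
    seen[i] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, j)
      nb_keys <- paste(px[j, 1] + off$dr, px[j, 2] + off$dc)
      nb <- lookup[nb_keys]
      nb <- nb[!is.na(nb)]
      nb <- nb[!seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

pixel_key <- function(px, nrow_img) (px[, 2] - 1) * nrow_img + px[, 1]

#' Detect a polar spot in a search region
#'
#' Thresholds the filtered image at `threshold_sds` standard deviations
#' above the mean of the reference pixels (cell mask minus both polar
#' search regions), groups supra-threshold pixels inside the region by
#' 8-connectivity, and calls a spot when at least one group has
#' `min_spot_pixels` members; the largest group is the spot.
#'
#' @param filtered LoG-filtered image (or raw background-subtracted image
#'   when `config$threshold_on == "raw"`; must match the config choice).
#' @param region Pixel matrix (row, col) of the search disc.
#' @param mask A [cell_mask()].
#' @param regions_both List with `region1`, `region2` (both search discs).
#' @param config A [filter_config()].
#' @return `NULL` when no spot is found, else a list of class `polar_spot`
#'   with `pixels` (row, col matrix), `n_pixels` and `threshold`.
#' @export
detect_polar_spot <- function(filtered, region, mask, regions_both, config) {
  H <- nrow(filtered)
  mask_keys <- pixel_key(mask$pixels, H)
  excl <- unique(c(pixel_key(regions_both$region1, H),
                   pixel_key(regions_both$region2, H)))
  ref_keys <- setdiff(mask_keys, excl)
  if (length(ref_keys) == 0)
    abort("empty reference pixel set for thresholding")
  ref <- filtered[ref_keys]
  thr <- mean(ref) + config$threshold_sds * sd(ref)
  cand <- region[filtered[region] > thr, , drop = FALSE]
  if (nrow(cand) < config$min_spot_pixels) return(NULL)
  comps <- connected_components8(cand)
  sizes <- lengths(comps)
  if (max(sizes) < config$min_spot_pixels) return(NULL)
  best <- comps[[which.max(sizes)]]
  structure(list(pixels = cand[best, , drop = FALSE],
                 n_pixels = length(best), threshold = thr),
            class = "polar_spot")
}

#' Quantify polar fluorescence of one cell
#'
#' Computes the total background-subtracted fluorescence inside the cell
#' mask, detects polar spots in the LoG-filtered image within the two polar
#' search regions, and integrates the *unfiltered* background-subtracted
#' intensities over each spot's pixels. `P1`/`P2` are the larger/smaller
#' polar fraction and the asymmetry is `omega = (P1 - P2)/(P1 + P2)`
#' (0 when no clusters are detected).
#'
#' @param image Raw image matrix.
#' @param labels Integer label matrix.
#' @param cell_id Label of the cell.
#' @param background Background level (see [estimate_background()]).
#' @param config A [filter_config()].
#' @param frame Optional frame index carried into the record.
#' @return One-row tibble: `cell_id`, `frame`, `total_fluorescence`,
#'   `p_pole1`, `p_pole2` (fractions in geometric pole order), `P1`, `P2`,
#'   `omega`, `n_spots`, `area`, `pole1_x/y`, `pole2_x/y`, `valid`,
#'   `capped`.
#' @export
quantify_cell <- function(image, labels, cell_id, background,
                          config = filter_config(), frame = NA_integer_) {
  mask <- cell_mask(labels, cell_id)
  bgsub <- image - background
  total <- sum(bgsub[mask$pixels])
  regions <- polar_search_regions(mask, config, dim(image))

  # filter a crop around the cell for speed; zero padding is unaffected
  pad <- ceiling(config$search_radius + config$anchor_segment +
                   config$kernel_size)
  rr <- range(mask$pixels[, 1]); cc <- range(mask$pixels[, 2])
  r0 <- max(1L, rr[1] - pad); r1 <- min(nrow(image), rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(ncol(image), cc[2] + pad)
  crop <- bgsub[r0:r1, c0:c1, drop = FALSE]
  crop_labels <- labels[r0:r1, c0:c1, drop = FALSE]
  filt_crop <- filter_cell_image(crop, crop_labels, cell_id, config)
  filtered <- matrix(-Inf, nrow(image), ncol(image))
  filtered[r0:r1, c0:c1] <- filt_crop

  score_img <- if (config$threshold_on == "filtered") filtered else {
    tmp <- bgsub
    tmp[labels != 0 & labels != cell_id] <- 0
    tmp
  }
  polar <- numeric(2)
  n_spots <- 0L
  for (k in 1:2) {
    region <- if (k == 1) regions$region1 else regions$region2
    spot <- detect_polar_spot(score_img, region, mask, regions, config)
    if (!is.null(spot)) {
      intensity <- sum(bgsub[spot$pixels])
      if (intensity >= config$min_spot_intensity) {
        polar[k] <- intensity
        n_spots <- n_spots + 1L
      }
    }
  }
  valid <- total > 0
  p <- if (valid) polar / total else c(0, 0)
  capped <- FALSE
  if (sum(p) > 1) {
    p <- p / sum(p)
    capped <- TRUE
  }
  P1 <- max(p); P2 <- min(p)
  tibble(cell_id = cell_id, frame = frame,
         total_fluorescence = total,
         p_pole1 = p[1], p_pole2 = p[2],
         P1 = P1, P2 = P2,
         omega = polar_asymmetry(P1, P2),
         n_spots = n_spots, area = mask$area,
         pole1_x = mask$poles[1, 1], pole1_y = mask$poles[1, 2],
         pole2_x = mask$poles[2, 1], pole2_y = mask$poles[2, 2],
         valid = valid, capped = capped)
}

#' Quantify every cell in a scene
#'
#' Estimates the background once from out-of-mask pixels, then runs
#' [quantify_cell()] for each labelled cell.
#'
#' @param image Raw image matrix (or a `polarity_scene`, whose image and
#'   masks are used).
#' @param labels Integer label matrix (ignored when `image` is a scene).
#' @param config A [filter_config()].
#' @param frame Optional frame index.
#' @return A tibble of per-cell records (see [quantify_cell()]).
#' @export
#' @examples
#' sc <- generate_snapshot_scene(scene_config(n_cells = 2, rng_seed = 1))
#' quantify_scene(sc)
quantify_scene <- function(image, labels = NULL, config = filter_config(),
                           frame = NA_integer_) {
  if (inherits(image, "polarity_scene")) {
    labels <- image$masks
    image <- image$image
  }
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0) return(tibble())
  bg <- estimate_background(image, labels)
  dplyr::bind_rows(lapply(ids, function(id)
    quantify_cell(image, labels, id, bg, config, frame)))
}
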