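#' Cell mask geometry: centerline and poles
#'
#' Builds the geometric description of a cell from its label-mask pixels:
#' an ordered centerline resampled into 1-px segments from pole to pole,
#' and the two pole coordinates (the extreme centerline points). The
#' centerline is obtained by projecting mask pixels onto the principal axis
#' and averaging the transverse position within 1-px bins, which is exact
#' for straight rods and adequate for gently curved ones.
#'
#' @param labels Integer label matrix (background 0).
#' @param cell_id Label of the cell.
#' @return An object of class `cell_mask`: list with `cell_id`, `pixels`
#'   (n x 2 matrix of row, col), `centerline` (m x 2 matrix of x, y
#'   coordinates ordered pole 1 to pole 2), `poles` (2 x 2 matrix, rows =
#'   poles, cols = x, y) and `area`.
#' @export
cell_mask <- function(labels, cell_id) {
  idx <- which(labels == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 0) abort(sprintf("no pixels with label %s", cell_id))
  xy <- cbind(x = idx[, 2], y = idx[, 1])  # x = col, y = row
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(cxy) / nrow(cxy), symmetric = TRUE)
  u <- ev$vectors[, 1]
  t <- cxy %*% u          # position along the major axis
  s <- cxy %*% ev$vectors[, 2]  # transverse offset
  breaks <- seq(floor(min(t)), ceiling(max(t)), by = 1)
  if (length(breaks) < 3) breaks <- c(min(t) - 0.5, max(t) + 0.5)
  bin <- cut(t, breaks, include.lowest = TRUE)
  t_mid <- tapply(t, bin, mean)
  s_mid <- tapply(s, bin, mean)
  keep <- !is.na(t_mid)
  line <- cbind(ctr[1] + t_mid[keep] * u[1] + s_mid[keep] * ev$vectors[1, 2],
                ctr[2] + t_mid[keep] * u[2] + s_mid[keep] * ev$vectors[2, 2])
  colnames(line) <- c("x", "y")
  rownames(line) <- NULL
  # deterministic orientation: pole 1 has the smaller x (then y) coordinate
  a <- line[1, ]; b <- line[nrow(line), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
    line <- line[rev(seq_len(nrow(line))), , drop = FALSE]
  structure(list(cell_id = cell_id, pixels = idx, centerline = line,
                 poles = line[c(1, nrow(line)), , drop = FALSE],
                 area = nrow(idx)),
            class = "cell_mask")
}

disc_pixels <- function(center, radius, width, height) {
  cols <- max(1L, floor(center[1] - radius)):min(width, ceiling(center[1] + radius))
  rows <- max(1L, floor(center[2] - radius)):min(height, ceiling(center[2] + radius))
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  keep <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
  cbind(row = py[keep], col = px[keep])
}

#' Polar search regions
#'
#' Circular search regions of radius `search_radius` px at each pole,
#' centred on the `anchor_segment`-th centerline segment from the
#' corresponding pole. The discs may extend outside the cell mask (polar
#' clusters often do) and are clipped to the image bounds.
#'
#' @param mask A [cell_mask()].
#' @param config A [filter_config()].
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return List with `region1`, `region2` (pixel matrices of row, col) and
#'   `centers` (2 x 2 matrix of x, y).
#' @export
polar_search_regions <- function(mask, config = filter_config(),
                                 dim) {
  line <- mask$centerline
  m <- nrow(line)
  a <- config$anchor_segment
  if (m < 2 * a) abort("centerline too short for the requested anchor segment")
  centers <- rbind(line[a, ], line[m - a + 1, ])
  list(region1 = disc_pixels(centers[1, ], config$search_radius,
                             dim[2], dim[1]),
       region2 = disc_pixels(centers[2, ], config$search_radius,
                             dim[2], dim[1]),
       centers = centers)
}
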