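# Shared fixtures and a lazily-computed, cached full fit used by the
# acceptance suite (the fit is expensive; criteria share one).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

acceptance_fit <- function() {
  cached("fit", fit_hierarchical(strain_means(), n_starts = 50, seed = 1,
                                 polish_maxit = 2000))
}

# A straight horizontal capsule cell in an otherwise empty label image.
straight_cell_labels <- function(length = 70, width = 11,
                                 H = 120, W = 160, id = 1L) {
  labels <- matrix(0L, H, W)
  p1 <- c(30, H / 2)
  p2 <- c(30 + length, H / 2)
  px <- mxpolarity:::capsule_pixels(p1, p2, width, W, H)
  labels[px] <- id
  list(labels = labels, p1 = p1, p2 = p2)
}

# Minimal tracks tibble with the polarity_tracks layout.
make_tracks <- function(df) {
  out <- tibble::as_tibble(df)
  defaults <- list(parent_id = NA_integer_, cell_id = out$track_id,
                   poleA_x = 0, poleA_y = 0, poleB_x = 10, poleB_y = 0,
                   old_pole = NA_character_)
  for (nm in names(defaults))
    if (is.null(out[[nm]])) out[[nm]] <- defaults[[nm]]
  structure(out, class = c("polarity_tracks", class(out)),
            config = tracking_config())
}

# Brute-force quadrant oracle for the 2-D KS D statistic (points on the
# dividing lines split evenly), independent of the C implementation.
brute_ks2d_d <- function(a, b) {
  quad_frac <- function(px, x0, y0) {
    wx <- ifelse(px[, 1] > x0, 1, ifelse(px[, 1] == x0, 0.5, 0))
    wy <- ifelse(px[, 2] > y0, 1, ifelse(px[, 2] == y0, 0.5, 0))
    c(mean(wx * wy), mean((1 - wx) * wy),
      mean((1 - wx) * (1 - wy)), mean(wx * (1 - wy)))
  }
  d_anchor <- function(anchors) {
    max(vapply(seq_len(nrow(anchors)), function(i) {
      max(abs(quad_frac(a, anchors[i, 1], anchors[i, 2]) -
                quad_frac(b, anchors[i, 1], anchors[i, 2])))
    }, numeric(1)))
  }
  (d_anchor(a) + d_anchor(b)) / 2
}
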