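#' Tracking configuration
#'
#' @param link_distance_threshold Maximum summed pole-to-pole distance (px)
#'   for a same-cell call between consecutive frames (single-pole distance
#'   for a daughter call).
#' @param min_move_fraction Minimum displacement, as a fraction of cell
#'   length, for a frame pair to count as movement when assigning
#'   leading/lagging poles.
#' @param frame_interval Minutes between frames.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(link_distance_threshold = 40,
                            min_move_fraction = 0.10,
                            frame_interval = 10) {
  if (link_distance_threshold <= 0) abort("threshold must be positive")
  if (min_move_fraction <= 0 || min_move_fraction >= 1)
    abort("min_move_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "tracking_config")
}

# Optimal pairing of the two pole coordinates of a current cell against a
# previous cell: returns the summed distance, the single best pole-to-pole
# distance, and whether the pairing is crossed (cur pole1 <-> prev pole2).
pole_pairing <- function(cur, prev) {
  d11 <- sqrt((cur$pole1_x - prev$pole1_x)^2 + (cur$pole1_y - prev$pole1_y)^2)
  d22 <- sqrt((cur$pole2_x - prev$pole2_x)^2 + (cur$pole2_y - prev$pole2_y)^2)
  d12 <- sqrt((cur$pole1_x - prev$pole2_x)^2 + (cur$pole1_y - prev$pole2_y)^2)
  d21 <- sqrt((cur$pole2_x - prev$pole1_x)^2 + (cur$pole2_y - prev$pole1_y)^2)
  straight <- d11 + d22
  crossed <- d12 + d21
  list(total = min(straight, crossed),
       crossed = crossed < straight,
       single = min(d11, d22, d12, d21),
       single_cur_pole = c(1L, 2L, 1L, 2L)[which.min(c(d11, d22, d12, d21))])
}

#' Link cell masks between two frames
#'
#' For each cell in the current frame, finds the closest cell of the
#' previous frame by summed pole-to-pole distance under the optimal pole
#' pairing. A summed distance below the threshold is a same-cell call (at
#' most one per previous cell; conflicts are resolved by distance, ties by
#' the lower cell id). Otherwise, if a single pole matches within the
#' threshold, the cell is called a daughter of that previous cell and the
#' matching pole is labelled "old", the opposite pole "new". Otherwise the
#' cell is new, with no pole identity.
#'
#' @param prev,cur Tibbles with columns `cell_id`, `pole1_x`, `pole1_y`,
#'   `pole2_x`, `pole2_y` (one row per cell in that frame).
#' @param config A [tracking_config()].
#' @return `cur` with added columns `link` (`"same"`, `"daughter"`,
#'   `"new"`), `prev_id`, `swap` (current pole 1 corresponds to previous
#'   pole 2) and `old_pole` (1, 2 or NA; geometric pole index).
#' @export
link_frames <- function(prev, cur, config = tracking_config()) {
  thr <- config$link_distance_threshold
  n <- nrow(cur)
  out <- dplyr::mutate(cur, link = "new", prev_id = NA_integer_,
                       swap = FALSE, old_pole = NA_integer_)
  if (nrow(prev) == 0 || n == 0) return(out)
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(prev))) {
      pr <- pole_pairing(cur[i, ], prev[j, ])
      pairs[[length(pairs) + 1]] <-
        list(i = i, j = j, total = pr$total, crossed = pr$crossed,
             single = pr$single, single_pole = pr$single_cur_pole)
    }
  }
  totals <- vapply(pairs, `[[`, numeric(1), "total")
  ids <- vapply(pairs, function(p) cur$cell_id[p$i], numeric(1))
  ord <- order(totals, ids)
  used_prev <- logical(nrow(prev))
  assigned <- logical(n)
  for (k in ord) {
    p <- pairs[[k]]
    if (p$total >= thr || assigned[p$i] || used_prev[p$j]) next
    assigned[p$i] <- TRUE
    used_prev[p$j] <- TRUE
    out$link[p$i] <- "same"
    out$prev_id[p$i] <- prev$cell_id[p$j]
    out$swap[p$i] <- p$crossed
  }
  # daughter calls for unassigned cells with one matching pole
  singles <- vapply(pairs, `[[`, numeric(1), "single")
  ord2 <- order(singles, ids)
  for (k in ord2) {
    p <- pairs[[k]]
    if (assigned[p$i] || p$single >= thr) next
    assigned[p$i] <- TRUE
    out$link[p$i] <- "daughter"
    out$prev_id[p$i] <- prev$cell_id[p$j]
    out$old_pole[p$i] <- p$single_pole
  }
  out
}

#' Track cells across a time-lapse
#'
#' Links frames sequentially with [link_frames()], maintaining stable pole
#' labels per track: pole A is the pole with the higher polar fraction in
#' the track's first frame, pole B the other. Daughter tracks record their
#' parent and which stable label is the old (inherited) pole.
#'
#' @param geometry Tibble with one row per cell per frame: `frame`,
#'   `cell_id`, `pole1_x`, `pole1_y`, `pole2_x`, `pole2_y`, `p_pole1`,
#'   `p_pole2` (polar fractions in geometric pole order). The `truth` table
#'   of [generate_timelapse()] has this layout (columns `p1_true`,
#'   `p2_true` are accepted as fractions).
#' @param config A [tracking_config()].
#' @return A tibble of class `polarity_tracks`: `track_id`, `parent_id`,
#'   `frame`, `poleA_x/y`, `poleB_x/y`, `P_A`, `P_B`, `old_pole` (`"A"`,
#'   `"B"` or NA), plus `cell_id` (the per-frame label).
#' @export
track_cells <- function(geometry, config = tracking_config()) {
  geom <- as_tibble(geometry)
  if ("p1_true" %in% names(geom) && !"p_pole1" %in% names(geom))
    geom <- dplyr::rename(geom, p_pole1 = "p1_true", p_pole2 = "p2_true")
  frames <- sort(unique(geom$frame))
  next_track <- 1L
  # per active cell label: track id, whether geometric pole1 is pole A,
  # parent, old pole label
  active <- list()
  rows <- list()
  prev <- NULL
  prev_frame <- NA_integer_
  for (f in frames) {
    cur <- geom[geom$frame == f, ]
    # only strictly consecutive frames are linked; a longer gap starts new
    # tracks (merge_gap_tracks() reconnects single-frame gaps afterwards)
    linked <- if (is.null(prev) || f != prev_frame + 1) {
      dplyr::mutate(cur, link = "new", prev_id = NA_integer_, swap = FALSE,
                    old_pole = NA_integer_)
    } else {
      link_frames(prev, cur, config)
    }
    new_active <- list()
    for (i in seq_len(nrow(linked))) {
      row <- linked[i, ]
      key <- as.character(row$cell_id)
      if (row$link == "same" && !is.null(active[[as.character(row$prev_id)]])) {
        st <- active[[as.character(row$prev_id)]]
        if (row$swap) st$pole1_is_A <- !st$pole1_is_A
      } else {
        pole1_is_A <- row$p_pole1 >= row$p_pole2
        st <- list(track_id = next_track,
                   parent_id = if (row$link == "daughter") {
                     pst <- active[[as.character(row$prev_id)]]
                     if (!is.null(pst)) pst$track_id else NA_integer_
                   } else NA_integer_,
                   pole1_is_A = pole1_is_A,
                   old_pole = if (row$link == "daughter" &&
                                  !is.na(row$old_pole)) {
                     if ((row$old_pole == 1) == pole1_is_A) "A" else "B"
                   } else NA_character_)
        next_track <- next_track + 1L
      }
      new_active[[key]] <- st
      a <- if (st$pole1_is_A) 1 else 2
      b <- 3 - a
      rows[[length(rows) + 1]] <- tibble(
        track_id = st$track_id, parent_id = st$parent_id %||% NA_integer_,
        frame = f, cell_id = row$cell_id,
        poleA_x = row[[paste0("pole", a, "_x")]],
        poleA_y = row[[paste0("pole", a, "_y")]],
        poleB_x = row[[paste0("pole", b, "_x")]],
        poleB_y = row[[paste0("pole", b, "_y")]],
        P_A = row[[paste0("p_pole", a)]],
        P_B = row[[paste0("p_pole", b)]],
        old_pole = st$old_pole)
    }
    active <- new_active
    prev <- cur
    prev_frame <- f
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("polarity_tracks", class(out)),
            config = config)
}

#' Merge tracks separated by a single missing frame
#'
#' Two tracks, one ending at frame `k - 1` and the other starting at frame
#' `k + 1`, whose poles align within the link threshold, are concatenated
#' (the later track adopts the earlier track's id; crossed pole pairings
#' swap the stable labels). Gaps of two or more frames are never merged.
#'
#' @param tracks A [track_cells()] result.
#' @param config A [tracking_config()].
#' @return Tracks tibble with merged ids.
#' @export
merge_gap_tracks <- function(tracks, config = tracking_config()) {
  tr <- tracks
  repeat {
    info <- dplyr::summarise(dplyr::group_by(tr, .data$track_id),
                             first = min(.data$frame),
                             last = max(.data$frame), .groups = "drop")
    merged <- FALSE
    for (i in seq_len(nrow(info))) {
      ends <- tr[tr$track_id == info$track_id[i] &
                   tr$frame == info$last[i], ]
      cands <- info[info$first == info$last[i] + 2, ]
      if (nrow(cands) == 0) next
      best <- NULL
      for (j in seq_len(nrow(cands))) {
        starts <- tr[tr$track_id == cands$track_id[j] &
                       tr$frame == cands$first[j], ]
        pr <- pole_pairing(
          list(pole1_x = starts$poleA_x, pole1_y = starts$poleA_y,
               pole2_x = starts$poleB_x, pole2_y = starts$poleB_y),
          list(pole1_x = ends$poleA_x, pole1_y = ends$poleA_y,
               pole2_x = ends$poleB_x, pole2_y = ends$poleB_y))
        if (pr$total < config$link_distance_threshold &&
            (is.null(best) || pr$total < best$total))
          best <- list(id = cands$track_id[j], total = pr$total,
                       crossed = pr$crossed)
      }
      if (is.null(best)) next
      sel <- tr$track_id == best$id
      if (best$crossed) {
        tr[sel, c("poleA_x", "poleA_y", "poleB_x", "poleB_y",
                  "P_A", "P_B")] <-
          tr[sel, c("poleB_x", "poleB_y", "poleA_x", "poleA_y",
                    "P_B", "P_A")]
        tr$old_pole[sel] <- c(A = "B", B = "A")[tr$old_pole[sel]]
      }
      tr$track_id[sel] <- info$track_id[i]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  tr
}

#' Polarity inversion probability
#'
#' Over all consecutive frame pairs of all tracks with both polar fractions
#' defined, the fraction of pairs in which the dominant pole flips (the
#' pole with the weaker signal becomes the stronger one). Exact ties in
#' either frame are not inversions.
#'
#' @param tracks A [track_cells()] result.
#' @return List with `probability`, `n_events`, `n_pairs` and `events`
#'   (tibble of track_id, frame).
#' @export
inversion_probability <- function(tracks) {
  tr <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  n_pairs <- 0L
  events <- list()
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      if (sub$frame[i + 1] != sub$frame[i] + 1) next
      d0 <- sub$P_A[i] - sub$P_B[i]
      d1 <- sub$P_A[i + 1] - sub$P_B[i + 1]
      if (anyNA(c(d0, d1))) next
      n_pairs <- n_pairs + 1L
      if (d0 != 0 && d1 != 0 && sign(d0) != sign(d1))
        events[[length(events) + 1]] <-
          tibble(track_id = id, frame = sub$frame[i + 1])
    }
  }
  if (n_pairs == 0) abort("no eligible frame pairs")
  ev <- dplyr::bind_rows(events)
  list(probability = (if (nrow(ev) == 0) 0 else nrow(ev)) / n_pairs,
       n_events = nrow(ev), n_pairs = n_pairs, events = ev)
}

#' Old-pole bias after division
#'
#' For post-division tracks (those with an old/new pole identity), the mean
#' and standard deviation of the old-pole and new-pole fractions as a
#' function of time since division, and the fraction of cells whose larger
#' cluster sits at the old pole immediately after division, with a
#' two-sided exact binomial test against 0.5.
#'
#' @param tracks A [track_cells()] result.
#' @param max_time Maximum time since division (frames) to include.
#' @return List with `bias_fraction`, `n`, `p_value`, `timecourse` (tibble:
#'   time_since_division, n, old_mean, old_sd, new_mean, new_sd).
#' @export
pole_bias_after_division <- function(tracks, max_time = Inf) {
  tr <- tracks[!is.na(tracks$old_pole), ]
  if (nrow(tr) == 0) abort("no post-division tracks with old-pole identity")
  tr <- dplyr::mutate(
    dplyr::group_by(tr, .data$track_id),
    time_since_division = .data$frame - min(.data$frame))
  tr <- dplyr::ungroup(tr)
  tr <- tr[tr$time_since_division <= max_time, ]
  tr$P_old <- ifelse(tr$old_pole == "A", tr$P_A, tr$P_B)
  tr$P_new <- ifelse(tr$old_pole == "A", tr$P_B, tr$P_A)
  first <- tr[tr$time_since_division == 0, ]
  k <- sum(first$P_old > first$P_new)
  n <- nrow(first)
  test <- binom.test(k, n, p = 0.5, alternative = "two.sided")
  timecourse <- dplyr::summarise(
    dplyr::group_by(tr, .data$time_since_division),
    n = dplyr::n(),
    old_mean = mean(.data$P_old), old_sd = sd(.data$P_old),
    new_mean = mean(.data$P_new), new_sd = sd(.data$P_new),
    .groups = "drop")
  list(bias_fraction = k / n, n = n, p_value = test$p.value,
       timecourse = timecourse)
}

#' Autocorrelation of polar fractions
#'
#' Standardizes the polar fractions per frame across all cell poles
#' (`(p - mean) / sd`, population sd), then averages lag-n products over
#' all poles and frame pairs:
#' `C(n dt) = < dp_i(j) dp_{i+n}(j) >` over poles `j` and frames `i`.
#' `C(0) = 1` by construction; frames with zero cross-pole variance are
#' skipped with a warning.
#'
#' @param tracks A [track_cells()] result.
#' @param max_lag Maximum lag (frames).
#' @param frame_interval Minutes per frame (for the `lag_minutes` column).
#' @return Tibble of class `autocorr_series`: `lag`, `lag_minutes`, `C`,
#'   `n_pairs`.
#' @export
polar_autocorrelation <- function(tracks, max_lag = 10,
                                  frame_interval = attr(tracks, "config")$frame_interval %||% 10) {
  tr <- tracks
  frames <- sort(unique(tr$frame))
  # matrix poles x frames of standardized fractions
  pole_ids <- c(paste0(unique(tr$track_id), ":A"),
                paste0(unique(tr$track_id), ":B"))
  mat <- matrix(NA_real_, length(pole_ids), length(frames),
                dimnames = list(pole_ids, as.character(frames)))
  for (lab in c("A", "B")) {
    sub <- tr
    mat[cbind(paste0(sub$track_id, ":", lab), as.character(sub$frame))] <-
      if (lab == "A") sub$P_A else sub$P_B
  }
  skipped <- 0
  for (k in seq_along(frames)) {
    v <- mat[, k]
    ok <- !is.na(v)
    if (sum(ok) < 2) { mat[, k] <- NA; next }
    s <- sqrt(mean((v[ok] - mean(v[ok]))^2))
    if (s == 0) {
      mat[, k] <- NA
      skipped <- skipped + 1
      next
    }
    mat[, k] <- (v - mean(v[ok])) / s
  }
  if (skipped > 0)
    warn(sprintf("%d frame(s) with zero cross-pole variance skipped", skipped))
  out <- lapply(0:max_lag, function(n) {
    if (n >= length(frames)) return(NULL)
    a <- mat[, seq_len(length(frames) - n), drop = FALSE]
    b <- mat[, seq_len(length(frames) - n) + n, drop = FALSE]
    prod <- a * b
    tibble(lag = n, lag_minutes = n * frame_interval,
           C = mean(prod, na.rm = TRUE), n_pairs = sum(!is.na(prod)))
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("autocorr_series", class(res)))
}

#' Assign leading and lagging poles from motion
#'
#' Between consecutive frames in which the cell centroid moved at least
#' `min_move_fraction` of the cell length, the leading pole is the pole
#' whose body-axis direction makes an angle below 90 degrees with the
#' displacement (equivalently, the pole the cell moves towards); frames
#' below the movement threshold get no label.
#'
#' @param track Tibble of one track (rows = frames, columns as in
#'   [track_cells()]).
#' @param config A [tracking_config()].
#' @return The track with an added `leading_pole` column (`"A"`, `"B"` or
#'   NA; the label applies to the frame the cell arrived at).
#' @export
assign_leading_lagging <- function(track, config = tracking_config()) {
  tr <- dplyr::arrange(track, .data$frame)
  tr$leading_pole <- NA_character_
  for (i in 2:nrow(tr)) {
    if (tr$frame[i] != tr$frame[i - 1] + 1) next
    axis <- c(tr$poleA_x[i] - tr$poleB_x[i], tr$poleA_y[i] - tr$poleB_y[i])
    len <- sqrt(sum(axis^2))
    if (len == 0) abort("zero-length cell")
    c0 <- c((tr$poleA_x[i - 1] + tr$poleB_x[i - 1]) / 2,
            (tr$poleA_y[i - 1] + tr$poleB_y[i - 1]) / 2)
    c1 <- c((tr$poleA_x[i] + tr$poleB_x[i]) / 2,
            (tr$poleA_y[i] + tr$poleB_y[i]) / 2)
    disp <- c1 - c0
    if (sqrt(sum(disp^2)) < config$min_move_fraction * len) next
    tr$leading_pole[i] <- if (sum(axis * disp) > 0) "A" else "B"
  }
  tr
}
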