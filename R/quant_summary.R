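#' Summarize per-cell records for a strain
#'
#' Computes the strain-level summary used to characterise localization:
#' mean total polar fluorescence fraction `P1 + P2`, mean asymmetry omega,
#' the fractions of cells with two / one / no detectable polar clusters,
#' the mean `(P1, P2)` vector with the eigen-decomposition of its covariance
#' matrix (the dispersion ellipse: error-bar directions are the
#' eigenvectors, lengths the square roots of the eigenvalues), and a
#' histogram of the total polar fraction.
#'
#' @param records Tibble with columns `P1`, `P2`, `omega`, `n_spots`
#'   (e.g. from [quantify_scene()] or [generate_strain_sample()] after
#'   adding `omega`/`n_spots`).
#' @param bins Number of histogram bins.
#' @return An object of class `strain_summary`.
#' @export
#' @examples
#' s <- generate_strain_sample(0.212, 0.5, diag(0.03^2, 2), 500, seed = 1)
#' s$omega <- polar_asymmetry(s$P1, s$P2)
#' s$n_spots <- 2L
#' summarize_strain(s)
summarize_strain <- function(records, bins = 20) {
  if (is.null(records) || nrow(records) < 2)
    abort("need at least two records to summarize a strain")
  if (!all(c("P1", "P2") %in% names(records)))
    abort("records must contain P1 and P2")
  if (!"omega" %in% names(records))
    records$omega <- polar_asymmetry(records$P1, records$P2)
  total <- records$P1 + records$P2
  spot_frac <- if ("n_spots" %in% names(records)) {
    c(two = mean(records$n_spots == 2),
      one = mean(records$n_spots == 1),
      none = mean(records$n_spots == 0))
  } else c(two = NA_real_, one = NA_real_, none = NA_real_)
  m <- c(P1 = mean(records$P1), P2 = mean(records$P2))
  S <- stats::cov(cbind(records$P1, records$P2))
  ed <- eigen(S, symmetric = TRUE)
  h <- graphics::hist(total, breaks = bins, plot = FALSE)
  structure(list(
    n = nrow(records),
    mean_total = mean(total),
    mean_omega = mean(records$omega),
    spot_fractions = spot_frac,
    mean_poles = m,
    covariance = S,
    ellipse_axes = ed$vectors,
    ellipse_lengths = sqrt(pmax(ed$values, 0)),
    histogram = tibble(mid = h$mids, count = h$counts,
                       density = h$density),
    records = as_tibble(records)),
    class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf(
    "<strain_summary> n = %d, mean total polar fraction = %.3f, mean omega = %.3f\n",
    x$n, x$mean_total, x$mean_omega))
  cat(sprintf("cells with 2/1/0 spots: %.2f / %.2f / %.2f\n",
              x$spot_fractions["two"], x$spot_fractions["one"],
              x$spot_fractions["none"]))
  invisible(x)
}

#' @rdname tidy
#' @export
glance.strain_summary <- function(x, ...) {
  tibble(n = x$n, mean_total = x$mean_total, mean_omega = x$mean_omega,
         frac_two_spots = x$spot_fractions[["two"]],
         frac_one_spot = x$spot_fractions[["one"]],
         frac_no_spots = x$spot_fractions[["none"]])
}

#' Binned induction curve and cooperativity statistic
#'
#' Pools per-cell observations over frames, computes the fluorescence
#' concentration (total cellular fluorescence divided by cell area), bins
#' cells by concentration with at least `min_per_bin` cells per bin, and
#' reports per-bin mean and standard deviation of the polar fractions. The
#' cooperativity statistic is the Spearman rank correlation between
#' concentration and total polar fraction `P1 + P2`, with a permutation
#' p-value: under non-cooperative binding the polar fraction is constant in
#' concentration and the correlation is null.
#'
#' @param records Tibble with columns `total_fluorescence`, `area`, `P1`,
#'   `P2` (a `concentration` column is recomputed).
#' @param min_per_bin Minimum cells per concentration bin.
#' @param max_bins Upper bound on the number of bins.
#' @param n_perm Permutations for the p-value.
#' @param seed Integer seed for the permutations.
#' @return An object of class `induction_analysis`: list with `bins`
#'   (tibble: concentration, n, P1_mean, P1_sd, P2_mean, P2_sd),
#'   `correlation`, `p_value`, `n_cells`.
#' @export
#' @examples
#' rec <- generate_induction_series(induction_config(), per_cell = TRUE,
#'                                  seed = 1)
#' analyze_induction(rec)
analyze_induction <- function(records, min_per_bin = 5, max_bins = 20,
                              n_perm = 999, seed = 1) {
  need <- c("total_fluorescence", "area", "P1", "P2")
  if (!all(need %in% names(records)))
    abort("records must contain total_fluorescence, area, P1, P2")
  n <- nrow(records)
  if (n < min_per_bin)
    abort(sprintf("need at least %d cells for one bin", min_per_bin))
  rec <- dplyr::mutate(records,
                       concentration = .data$total_fluorescence / .data$area)
  rec <- dplyr::arrange(rec, .data$concentration)
  n_bins <- max(1, min(max_bins, floor(n / min_per_bin)))
  size <- ceiling(n / n_bins)
  bin <- ceiling(seq_len(n) / size)
  # merge a trailing bin that fell below the minimum occupancy
  if (sum(bin == max(bin)) < min_per_bin && max(bin) > 1)
    bin[bin == max(bin)] <- max(bin) - 1
  rec$bin <- bin
  bins <- dplyr::summarise(
    dplyr::group_by(rec, .data$bin),
    concentration = mean(.data$concentration),
    n = dplyr::n(),
    P1_mean = mean(.data$P1), P1_sd = sd(.data$P1),
    P2_mean = mean(.data$P2), P2_sd = sd(.data$P2),
    .groups = "drop")
  total <- rec$P1 + rec$P2
  rho <- cor(rec$concentration, total, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      cor(rec$concentration, sample(total), method = "spearman"),
      numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  structure(list(bins = bins, correlation = rho, p_value = p, n_cells = n),
            class = "induction_analysis")
}

#' @export
print.induction_analysis <- function(x, ...) {
  cat(sprintf(
    "<induction_analysis> %d cells in %d bins; Spearman rho = %.3f (p = %.3g)\n",
    x$n_cells, nrow(x$bins), x$correlation, x$p_value))
  invisible(x)
}
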