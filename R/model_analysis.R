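#' Linear stability of the symmetric fixed point
#'
#' Locates the symmetric fixed point (`X1 = X2` for every present species) of
#' the polarity model by root finding on the symmetric subsystem, then
#' evaluates the Jacobian of the pole-resolved system at that point
#' numerically and returns its eigenvalue spectrum. The old-pole bias is
#' switched off (`beta = 1`): a symmetric fixed point only exists without it.
#'
#' The Jacobian is restricted to the pools of present species (deleted
#' species contribute identically-zero rows). The fixed point is called
#' unstable if any eigenvalue has real part above `tol`.
#'
#' @inheritParams model_rhs
#' @param tol Tolerance on eigenvalue real parts for the stability call.
#' @return A list of class `symmetric_stability` with elements `state` (full
#'   6-pool symmetric fixed point), `eigenvalues`, `stable` (logical) and
#'   `residual`.
#' @export
#' @examples
#' st <- stability_of_symmetric_fixed_point(polarity_parameters(),
#'                                          polarity_condition("dAdB"))
#' st$stable
stability_of_symmetric_fixed_point <- function(params, condition,
                                               tol = 1e-8) {
  params$beta <- 1
  pres <- condition$present
  sp_on <- names(pres)[pres]
  if (length(sp_on) == 0) abort("no species present")
  codes <- c(MglA = "A", MglB = "B", RomR = "R")[sp_on]

  # symmetric subsystem: pole-1 derivatives with X1 = X2 = x
  sym_rhs <- function(x) {
    state <- setNames(numeric(6), state_names)
    state[paste0(codes, 1)] <- x
    state[paste0(codes, 2)] <- x
    full <- model_rhs(state, params, condition)
    full[paste0(codes, 1)]
  }
  # A symmetric initial condition stays symmetric under the flow, and the
  # symmetric fixed point is attracting within that manifold even when it is
  # pitchfork-unstable to antisymmetric perturbations. Integrate the
  # symmetric subsystem to locate it, then polish by root finding.
  locate <- function(x0) {
    init <- setNames(numeric(6), state_names)
    init[paste0(codes, 1)] <- x0
    init[paste0(codes, 2)] <- x0
    ss <- tryCatch(steady_state(params, condition, init = init, tol = 1e-10),
                   error = function(e) NULL)
    if (is.null(ss)) return(NULL)
    x_int <- ss$state[paste0(codes, 1)]
    sol <- tryCatch(
      pracma::fsolve(function(x) unname(sym_rhs(x)), unname(x_int),
                     tol = 1e-13),
      error = function(e) NULL)
    x <- if (!is.null(sol) && all(is.finite(sol$x))) sol$x else x_int
    if (all(x >= -1e-10) && all(2 * x <= 1 + 1e-10) &&
        max(abs(sym_rhs(pmax(x, 0)))) < 1e-8) pmax(x, 0) else NULL
  }
  root <- NULL
  for (x0 in c(0.01, 0.001, 0.1)) {
    root <- locate(x0)
    if (!is.null(root)) break
  }
  if (is.null(root)) abort("no symmetric fixed point found")

  state <- setNames(numeric(6), state_names)
  state[paste0(codes, 1)] <- root
  state[paste0(codes, 2)] <- root
  idx <- c(rbind(paste0(codes, 1), paste0(codes, 2)))
  f <- function(y) {
    s <- state
    s[idx] <- y
    unname(model_rhs(s, params, condition)[idx])
  }
  J <- pracma::jacobian(f, unname(state[idx]))
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = state, eigenvalues = ev,
                 stable = all(Re(ev) < tol),
                 residual = max(abs(sym_rhs(root))),
                 jacobian = J, pools = idx),
            class = "symmetric_stability")
}

#' Bifurcation scan over feedback strengths
#'
#' Computes the steady-state RomR asymmetry `omega_R = |R1 - R2|/(R1 + R2)`
#' of the wild-type model over a grid of the MglA suppression constant `K`
#' and the MglB-driven MglA dissociation strength `d_AB`, starting each run
#' from the default small pole-1 seed. Polar differentiation is sustained
#' only in an intermediate band of regulatory strengths: too-weak suppression
#' lets RomR and MglB accumulate at both poles (symmetric), too-strong
#' suppression extinguishes polar accumulation altogether.
#'
#' @inheritParams model_rhs
#' @param K_grid,dAB_grid Positive numeric grids. A length-one `dAB_grid`
#'   yields the one-dimensional branch diagram versus `K`.
#' @param condition Condition to scan (default wild type).
#' @return A tibble of class `bifurcation_scan` with columns `K`, `d_AB`,
#'   `R1`, `R2`, `B1`, `B2`, `A1`, `A2`, `omega_R`, `classification`.
#' @export
bifurcation_scan <- function(params, K_grid, dAB_grid = params$d_AB,
                             condition = polarity_condition("wt")) {
  if (any(K_grid <= 0) || any(dAB_grid <= 0))
    abort("grids must be positive")
  grid <- tidyr::expand_grid(K = K_grid, d_AB = dAB_grid)
  rows <- purrr::pmap(grid, function(K, d_AB) {
    p <- params
    p$K <- K
    p$d_AB <- d_AB
    ss <- steady_state(p, condition)
    s <- ss$state
    tibble(K = K, d_AB = d_AB,
           R1 = s[["R1"]], R2 = s[["R2"]], B1 = s[["B1"]], B2 = s[["B2"]],
           A1 = s[["A1"]], A2 = s[["A2"]],
           omega_R = polar_asymmetry(s[["R1"]], s[["R2"]]),
           classification = ss$classification)
  })
  structure(dplyr::bind_rows(rows),
            class = c("bifurcation_scan", class(grid)))
}

#' Minimal RomR seed overcoming an MglB seed
#'
#' In the wild-type model, seeds the two poles antagonistically -- an MglB
#' fraction `b0` at pole 1 against a RomR fraction `x` at pole 2 -- and finds
#' by bisection the smallest `x` for which pole 2 ends up as the RomR/MglB-
#' rich (lagging) pole at steady state. A small RomR asymmetry overcoming a
#' larger MglB asymmetry is the signature of RomR dominance in polarity
#' establishment.
#'
#' @inheritParams model_rhs
#' @param b0 MglB fraction seeded at pole 1.
#' @param baseline Common initial fraction for all non-seeded pools.
#' @param tol Bisection tolerance on the threshold (fraction).
#' @param x_max Upper end of the search bracket (default `10 * b0`).
#' @return A list of class `dominance_threshold` with elements `threshold`,
#'   `bracket`, `b0` and `baseline`.
#' @export
dominance_threshold <- function(params, b0 = 0.01, baseline = 0,
                                tol = 1e-4, x_max = 10 * b0) {
  condition <- polarity_condition("wt")
  pole2_wins <- function(x) {
    init <- setNames(rep(baseline, 6), state_names)
    init[["B1"]] <- b0
    init[["R2"]] <- x
    ss <- steady_state(params, condition, init = init)
    ss$state[["R2"]] > ss$state[["R1"]]
  }
  lo <- 0
  hi <- x_max
  if (pole2_wins(lo)) return(structure(
    list(threshold = 0, bracket = c(0, 0), b0 = b0, baseline = baseline),
    class = "dominance_threshold"))
  if (!pole2_wins(hi))
    abort(sprintf("no crossover found in (0, %g)", x_max))
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (pole2_wins(mid)) hi <- mid else lo <- mid
  }
  structure(list(threshold = hi, bracket = c(lo, hi), b0 = b0,
                 baseline = baseline),
            class = "dominance_threshold")
}
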