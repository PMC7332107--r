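#' Model parameters for the MglA/MglB/RomR polarity module
#'
#' Constructs the parameter set of the six-pool ordinary differential equation
#' model of front-rear polarity. Each protein species X (MglA, MglB, RomR/RomX)
#' is split into two polar pools `X1`, `X2` and a cytoplasmic pool
#' `Xc = 1 - X1 - X2`. The model combines basal polar binding, RomR
#' self-recruitment (cooperativity), mutual RomR/MglB recruitment, RomR/RomX
#' recruitment of MglA, and quadratic MglB-mediated dissociation of MglA
#' (with a matching MglA-driven MglB co-dissociation term, since active MglB
#' is thought to act as a multimer). MglA suppresses MglB-driven RomR
#' recruitment through the saturation factor `K/(K + A_i)`.
#'
#' The default values are a parameter set obtained by fitting the model to
#' the packaged per-strain mean localization table with
#' [fit_hierarchical()]; with them the wild-type condition polarizes
#' spontaneously from a small seed asymmetry.
#'
#' @param a_A,a_B,a_R Basal polar binding rates (1/min).
#' @param b_R RomR self-recruitment coefficient (1/min); the source of
#'   cooperative RomR polar accumulation.
#' @param c_A RomR/RomX-driven MglA recruitment coefficient (1/min).
#' @param c_B RomR-driven MglB recruitment coefficient (1/min).
#' @param c_R MglB-driven RomR recruitment coefficient (1/min).
#' @param d_A,d_B,d_R Basal polar dissociation rates (1/min). `d_R` defaults
#'   to `60/28` (a ~28 s polar exchange time measured by FRAP); `d_A` and
#'   `d_B` default to the same order of magnitude.
#' @param d_AB MglB-driven MglA dissociation strength (1/min).
#' @param d_BA MglA-driven MglB dissociation strength (1/min). `d_BA = 0`
#'   switches off the direct mode of MglA action on MglB.
#' @param K MglA suppression constant (dimensionless fraction). `K = Inf`
#'   switches off the suppression of MglB-driven RomR recruitment.
#' @param beta Old-pole bias factor in `(0, 1]`: the RomR dissociation rate at
#'   pole 1 is multiplied by `beta` in mutant conditions (never in wild type).
#'
#' @return An object of class `polarity_parameters` (a named list).
#' @seealso [polarity_condition()], [simulate_polarity()], [steady_state()]
#' @export
#' @examples
#' p <- polarity_parameters(d_AB = 50, K = 0.005)
#' p$K
polarity_parameters <- function(a_A = 0.00761, a_B = 0.00738, a_R = 0.00869,
                                b_R = 2.162, c_A = 1.395, c_B = 1.409,
                                c_R = 1.601,
                                d_A = 2, d_B = 2, d_R = 60 / 28,
                                d_AB = 91470, d_BA = 32640, K = 0.00185,
                                beta = 0.942) {
  p <- list(a_A = a_A, a_B = a_B, a_R = a_R, b_R = b_R, c_A = c_A,
            c_B = c_B, c_R = c_R, d_A = d_A, d_B = d_B, d_R = d_R,
            d_AB = d_AB, d_BA = d_BA, K = K, beta = beta)
  vals <- unlist(p)
  if (any(vals[setdiff(names(vals), "K")] < 0, na.rm = TRUE))
    abort("all rates must be non-negative")
  if (!is.na(p$K) && p$K <= 0) abort("K must be positive (Inf allowed)")
  if (p$beta <= 0 || p$beta > 1) abort("beta must be in (0, 1]")
  structure(p, class = "polarity_parameters")
}

#' Genotype condition for the polarity model
#'
#' Defines which species of the polarity module are present, and whether the
#' condition is wild type. Deleted species have all pools fixed at zero. The
#' old-pole bias (`beta` in [polarity_parameters()]) is applied in every
#' mutant condition but never in wild type, reflecting an inherent old-pole
#' preference of RomR that is masked in wild-type cells.
#'
#' @param genotype One of `"wt"`, `"dA"`, `"dB"`, `"dR"`, `"dAdB"`, `"dAdR"`,
#'   `"dBdR"` (`dA` = MglA deleted, etc.), or `NULL` when `present` is given.
#' @param present Optional character vector of present species among
#'   `"MglA"`, `"MglB"`, `"RomR"`; overrides `genotype`.
#' @param wild_type Logical; defaults to `TRUE` only when all three species
#'   are present and `genotype` is `"wt"`.
#'
#' @return An object of class `polarity_condition`.
#' @export
#' @examples
#' polarity_condition("dAdB")  # RomR-only condition, old-pole bias active
polarity_condition <- function(genotype = "wt", present = NULL,
                               wild_type = NULL) {
  species <- c("MglA", "MglB", "RomR")
  if (is.null(present)) {
    map <- list(wt = species, dA = c("MglB", "RomR"), dB = c("MglA", "RomR"),
                dR = c("MglA", "MglB"), dAdB = "RomR", dAdR = "MglB",
                dBdR = "MglA")
    if (!genotype %in% names(map))
      abort(paste0("unknown genotype '", genotype, "'"))
    present <- map[[genotype]]
  } else {
    present <- match.arg(present, species, several.ok = TRUE)
    genotype <- paste0(c("dA", "dB", "dR")[!species %in% present],
                       collapse = "")
    if (genotype == "") genotype <- "wt"
  }
  if (is.null(wild_type)) wild_type <- identical(genotype, "wt")
  if (wild_type && !all(species %in% present))
    abort("wild type requires all three species present")
  structure(list(genotype = genotype,
                 present = setNames(species %in% present, species),
                 wild_type = wild_type),
            class = "polarity_condition")
}

state_names <- c("A1", "A2", "B1", "B2", "R1", "R2")

# Flatten parameters + condition into the vector consumed by the C right-hand
# side (see src/polarity_rhs.c). The old-pole bias is folded into the pole-1
# RomR dissociation rate.
model_parms_vector <- function(params, condition) {
  bias <- if (condition$wild_type) 1 else params$beta
  K <- if (is.infinite(params$K)) 1e300 else params$K
  c(params$a_A, params$a_B, params$a_R, params$b_R,
    params$c_A, params$c_B, params$c_R,
    params$d_A, params$d_B, bias * params$d_R, params$d_R,
    params$d_AB, params$d_BA, K,
    as.numeric(condition$present[["MglA"]]),
    as.numeric(condition$present[["MglB"]]),
    as.numeric(condition$present[["RomR"]]))
}

#' Time derivatives of the polarity model pools
#'
#' Evaluates the right-hand side of the six-pool polarity model in pure R.
#' This is the reference implementation; [simulate_polarity()] integrates a
#' C translation of the same equations.
#'
#' @param state Named numeric vector `c(A1, A2, B1, B2, R1, R2)` of polar
#'   fractions; each species must satisfy `0 <= X1 + X2 <= 1`.
#' @param params A [polarity_parameters()] object.
#' @param condition A [polarity_condition()] object.
#'
#' @return Named numeric vector of time derivatives (1/min).
#' @export
#' @examples
#' s <- c(A1 = 0.011, A2 = 0.01, B1 = 0.011, B2 = 0.01, R1 = 0.011, R2 = 0.01)
#' model_rhs(s, polarity_parameters(), polarity_condition("wt"))
model_rhs <- function(state, params, condition = polarity_condition("wt")) {
  state <- state[state_names]
  if (anyNA(state)) abort("state must contain A1, A2, B1, B2, R1, R2")
  tol <- 1e-8
  for (sp in c("A", "B", "R")) {
    s <- state[paste0(sp, 1)] + state[paste0(sp, 2)]
    if (any(state[paste0(sp, 1:2)] < -tol) || s > 1 + tol)
      abort("state outside the [0, 1] simplex")
  }
  pv <- model_parms_vector(params, condition)
  A1 <- state[["A1"]]; A2 <- state[["A2"]]
  B1 <- state[["B1"]]; B2 <- state[["B2"]]
  R1 <- state[["R1"]]; R2 <- state[["R2"]]
  Ac <- 1 - A1 - A2; Bc <- 1 - B1 - B2; Rc <- 1 - R1 - R2
  s1 <- if (pv[14] >= 1e30) 1 else pv[14] / (pv[14] + A1)
  s2 <- if (pv[14] >= 1e30) 1 else pv[14] / (pv[14] + A2)
  d <- c(
    A1 = Ac * (pv[1] + pv[5] * R1) - pv[8] * A1 - pv[12] * A1 * B1^2,
    A2 = Ac * (pv[1] + pv[5] * R2) - pv[8] * A2 - pv[12] * A2 * B2^2,
    B1 = Bc * (pv[2] + pv[6] * R1) - pv[9] * B1 - pv[13] * A1 * B1^2,
    B2 = Bc * (pv[2] + pv[6] * R2) - pv[9] * B2 - pv[13] * A2 * B2^2,
    R1 = Rc * (pv[3] + pv[4] * R1 + pv[7] * B1 * s1) - pv[10] * R1,
    R2 = Rc * (pv[3] + pv[4] * R2 + pv[7] * B2 * s2) - pv[11] * R2
  )
  pres <- rep(as.numeric(condition$present), each = 2)
  d * pres
}

#' Default initial state of the polarity model
#'
#' Every present species starts with 1.1% of its total at pole 1 and 1% at
#' pole 2 (the small seed asymmetry from which wild-type polarity is
#' established); deleted species start at zero.
#'
#' @param condition A [polarity_condition()] object.
#' @param pole1,pole2 Initial polar fractions for each present species.
#' @return Named numeric state vector.
#' @export
default_init <- function(condition = polarity_condition("wt"),
                         pole1 = 0.011, pole2 = 0.01) {
  s <- setNames(rep(c(pole1, pole2), 3), state_names)
  s * rep(as.numeric(condition$present), each = 2)
}

#' Integrate the polarity model
#'
#' Integrates the six-pool model with `lsoda` (default) or an adaptive
#' Dormand-Prince 5th-order Runge-Kutta method. The quadratic dissociation
#' terms make the fitted parameter regime stiff, where the explicit
#' Runge-Kutta pair needs prohibitively small steps; `lsoda` switches to an
#' implicit method there. The two integrators agree to tolerance in the
#' non-stiff regime.
#'
#' @inheritParams model_rhs
#' @param init Initial state; defaults to [default_init()] for `condition`.
#' @param t_end Simulation time (minutes), default 1000.
#' @param t_step Output time step (minutes).
#' @param method `"lsoda"` or `"dopri"` (Dormand-Prince).
#' @param atol,rtol Integration tolerances.
#'
#' @return A tibble of class `polarity_trajectory` with columns `time`,
#'   `A1`, `A2`, `B1`, `B2`, `R1`, `R2`.
#' @export
#' @examples
#' traj <- simulate_polarity(polarity_parameters(), t_end = 100)
#' tail(traj, 1)
simulate_polarity <- function(params, condition = polarity_condition("wt"),
                              init = default_init(condition),
                              t_end = 1000, t_step = 1,
                              method = c("lsoda", "dopri"),
                              atol = 1e-10, rtol = 1e-8) {
  method <- match.arg(method)
  init <- init[state_names]
  if (anyNA(init)) abort("init must contain A1, A2, B1, B2, R1, R2")
  init <- init * rep(as.numeric(condition$present), each = 2)
  pv <- model_parms_vector(params, condition)
  times <- unique(c(seq(0, t_end, by = t_step), t_end))
  solver <- if (method == "dopri") deSolve::rkMethod("rk45dp7") else "lsoda"
  out <- suppressWarnings(
    deSolve::ode(y = init, times = times, func = "mxpol_rhs",
                 parms = pv, dllname = "mxpolarity",
                 initfunc = "mxpol_initmod", method = solver,
                 atol = atol, rtol = rtol, maxsteps = 1e5))
  if (attr(out, "istate")[1] < 0)
    abort("integration failed; see deSolve diagnostics")
  traj <- as_tibble(as.data.frame(out))
  names(traj)[1] <- "time"
  structure(traj,
            class = c("polarity_trajectory", class(traj)),
            params = params, condition = condition)
}

#' Steady state of the polarity model
#'
#' Integrates until the maximum absolute time-derivative falls below `tol`
#' (capped at `t_cap` minutes) and classifies the resulting state as
#' `"polarized"` if any present species has a pole asymmetry
#' `|X1 - X2| / (X1 + X2)` above `polar_threshold`, else `"symmetric"`.
#'
#' @inheritParams simulate_polarity
#' @param tol Convergence tolerance on `max |dX/dt|` (1/min).
#' @param t_cap Maximum total integration time (minutes).
#' @param polar_threshold Asymmetry threshold for the polarized call.
#'
#' @return A list of class `polarity_steady_state` with elements `state`
#'   (named vector), `classification`, `residual` (max `|dX/dt|`), `time`,
#'   `params` and `condition`.
#' @export
#' @examples
#' ss <- steady_state(polarity_parameters(), polarity_condition("dAdB"))
#' ss$classification
steady_state <- function(params, condition = polarity_condition("wt"),
                         init = default_init(condition),
                         tol = 1e-9, t_cap = 1e5,
                         method = c("lsoda", "dopri"),
                         polar_threshold = 0.05) {
  method <- match.arg(method)
  state <- init[state_names] * rep(as.numeric(condition$present), each = 2)
  t_done <- 0
  chunk <- 1000
  repeat {
    traj <- simulate_polarity(params, condition, init = state,
                              t_end = chunk, t_step = chunk,
                              method = method)
    state <- unlist(traj[nrow(traj), state_names])
    t_done <- t_done + chunk
    res <- max(abs(model_rhs(pmax(pmin(state, 1), 0), params, condition)))
    if (res < tol) break
    if (t_done >= t_cap)
      abort(sprintf(
        "steady state not reached within %g min (residual %.3g/min)",
        t_cap, res))
    chunk <- min(chunk * 2, t_cap - t_done)
  }
  state <- pmax(state, 0)
  asym <- vapply(c("A", "B", "R"), function(sp) {
    polar_asymmetry(state[[paste0(sp, 1)]], state[[paste0(sp, 2)]])
  }, numeric(1))
  classification <- if (any(asym > polar_threshold)) "polarized" else "symmetric"
  structure(list(state = state, classification = classification,
                 residual = res, time = t_done, asymmetry = asym,
                 params = params, condition = condition),
            class = "polarity_steady_state")
}

#' Pole asymmetry
#'
#' `|x1 - x2| / (x1 + x2)`, defined as 0 when `x1 + x2 = 0`.
#' @param x1,x2 Non-negative pole quantities.
#' @return Asymmetry in `[0, 1]`.
#' @export
polar_asymmetry <- function(x1, x2) {
  s <- x1 + x2
  ifelse(s > 0, abs(x1 - x2) / s, 0)
}

#' @export
print.polarity_steady_state <- function(x, ...) {
  cat("<polarity_steady_state>", x$condition$genotype, "-",
      x$classification, "\n")
  print(round(x$state, 5))
  invisible(x)
}

#' @rdname tidy
#' @param x A `polarity_steady_state` object.
#' @param ... Unused.
#' @export
tidy.polarity_steady_state <- function(x, ...) {
  tibble(species = c("MglA", "MglB", "RomR"),
         pole1 = x$state[c("A1", "B1", "R1")],
         pole2 = x$state[c("A2", "B2", "R2")],
         total = .data$pole1 + .data$pole2,
         asymmetry = polar_asymmetry(.data$pole1, .data$pole2))
}

#' Broom-style tidiers
#'
#' `tidy()` methods return per-term or per-species tibbles; `glance()`
#' methods return one-row model-level summaries.
#' @name tidy
NULL
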