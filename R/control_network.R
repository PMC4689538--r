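#' Define a two-compartment lineage control network
#'
#' A control network specifies how the per-update division rate `L`, the
#' probability `S` that a division is symmetric, the probability `P` that a
#' symmetric division is a differentiation event, and the death rate `D` of
#' differentiated cells depend on the two cell populations. Dependence is
#' through the scaled coordinates `x = epsilon * I`, `y = epsilon * J`, where
#' `I` and `J` are the stem-cell (SC) and differentiated-cell counts and
#' `epsilon > 0` measures the strength of the feedback. Optionally the network
#' carries an exogenous SC influx rate `E(x)` (e.g. SCs supplied by hair
#' follicles), a decreasing function of the SC population.
#'
#' All rate/probability functions must accept two numeric arguments `(x, y)`
#' (the influx `E` accepts one, `x`) and return finite values; `L`, `P` and
#' `S` must stay within `[0, 1]` and `D` must be nonnegative on the sampled
#' domain.
#'
#' @param L division rate function of `(x, y)`, values in `[0, 1]`.
#' @param P differentiation-probability function of `(x, y)`, values in `[0, 1]`.
#' @param D death-rate function of `(x, y)`, values `>= 0`.
#' @param S symmetric-division-probability function of `(x, y)`, values in
#'   `[0, 1]`. The built-in presets use a constant `S`; for non-constant
#'   user-supplied `S` only its equilibrium value (never its derivatives)
#'   enters the analytic results.
#' @param epsilon positive control-strength scale.
#' @param E optional influx rate function of `x` alone, values `>= 0`; `NULL`
#'   for a closed system.
#' @param derivs optional function `(x, y)` returning a named list with
#'   analytic partial derivatives `Lx, Ly, Px, Py, Dx, Dy` (with respect to
#'   the scaled coordinates). When absent, [evaluate_controls()] falls back to
#'   central finite differences.
#' @param name short label used in printing and serialization.
#' @param params named list of preset parameters (kept for serialization).
#'
#' @return An object of class `control_network`.
#' @seealso [make_model3()], [make_model5()], [make_follicle_model()],
#'   [evaluate_controls()]
#' @export
control_network <- function(L, P, D, S, epsilon, E = NULL, derivs = NULL,
                            name = "custom", params = list()) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  for (fn in list(L = L, P = P, D = D, S = S)) {
    if (!is.function(fn)) stop("L, P, D, S must be functions", call. = FALSE)
  }
  if (!is.null(E) && !is.function(E)) {
    stop("`E` must be a function of x, or NULL", call. = FALSE)
  }
  structure(
    list(L = L, P = P, D = D, S = S, E = E, epsilon = epsilon,
         derivs = derivs, name = name, params = params),
    class = "control_network"
  )
}

#' @export
print.control_network <- function(x, ...) {
  cat("<control_network>", x$name, "\n")
  cat("  epsilon:", format(x$epsilon), "\n")
  cat("  influx E:", if (is.null(x$E)) "absent" else "present", "\n")
  if (length(x$params)) {
    cat("  params:",
        paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

sech2 <- function(z) 1 / cosh(z)^2

#' Preset: divisions limited by differentiated cells, differentiation driven
#' by differentiated cells (minimal system #3)
#'
#' The division rate is positively controlled by SCs and negatively by
#' differentiated cells, and the differentiation probability is positively
#' controlled by differentiated cells:
#' \deqn{L = \frac{1 - e^{-x}}{1 - e^{-x} + y}, \quad P = 1 - e^{-3y}, \quad
#'       D = 1 - L, \quad S = c.}
#' Its mixed equilibrium in scaled coordinates is
#' `x0 = -log(1 - log(2)/3)`, `y0 = log(2)/3`, where `P = 1/2` and
#' `L = D = 1/2`. Increasing the symmetric fraction destabilizes this system
#' (variances grow with `S`).
#'
#' @param epsilon positive control-strength scale.
#' @param symmetry constant symmetric-division probability `c` in `(0, 1]`.
#' @return A [control_network] with analytic derivatives attached.
#' @examples
#' net <- make_model3(epsilon = 0.005, symmetry = 0.5)
#' net$L(0.26274, 0.23105)  # ~ 1/2 at the mixed equilibrium
#' @export
make_model3 <- function(epsilon, symmetry) {
  check_preset_args(epsilon, symmetry)
  force(symmetry)
  # L is 0/0 at the origin; its (y -> 0, x -> 0) limit 0 is used there
  m3_L <- function(x, y) {
    u <- 1 - exp(-x)
    if (u + y <= 0) 0 else u / (u + y)
  }
  control_network(
    L = m3_L,
    P = function(x, y) 1 - exp(-3 * y),
    D = function(x, y) 1 - m3_L(x, y),
    S = function(x, y) symmetry,
    epsilon = epsilon,
    derivs = function(x, y) {
      u <- 1 - exp(-x)
      den <- (u + y)^2
      Lx <- exp(-x) * y / den
      Ly <- -u / den
      list(Lx = Lx, Ly = Ly,
           Px = 0, Py = 3 * exp(-3 * y),
           Dx = -Lx, Dy = -Ly)
    },
    name = "model3",
    params = list(epsilon = epsilon, symmetry = symmetry)
  )
}

#' Preset: divisions and differentiation promoted by stem cells (minimal
#' system #5)
#'
#' Positive control of division by SCs and positive control of
#' differentiation by both populations:
#' \deqn{L = \frac{2\tanh x}{2\tanh x + 0.4}, \quad P = \tanh(x + 0.1 y),
#'       \quad D = 1 - L, \quad S = c.}
#' The mixed equilibrium is `x0 = log(1.5)/2`, `y0 = (log 3 - log 1.5)/0.2`.
#' For this network `q_y = 0`, hence the critical symmetry is `S_c = 0`:
#' the equilibrium is stable for every `S` in `(0, 1]`, `Var[I]` is
#' independent of `S`, and `Var[J]` decreases with `S` (symmetric divisions
#' are optimal).
#'
#' @inheritParams make_model3
#' @return A [control_network] with analytic derivatives attached.
#' @export
make_model5 <- function(epsilon, symmetry) {
  check_preset_args(epsilon, symmetry)
  force(symmetry)
  control_network(
    L = function(x, y) 2 * tanh(x) / (2 * tanh(x) + 0.4),
    P = function(x, y) tanh(x + 0.1 * y),
    D = function(x, y) 1 - 2 * tanh(x) / (2 * tanh(x) + 0.4),
    S = function(x, y) symmetry,
    epsilon = epsilon,
    derivs = function(x, y) {
      t <- tanh(x)
      Lx <- 0.8 * sech2(x) / (2 * t + 0.4)^2
      s2 <- sech2(x + 0.1 * y)
      list(Lx = Lx, Ly = 0,
           Px = s2, Py = 0.1 * s2,
           Dx = -Lx, Dy = 0)
    },
    name = "model5",
    params = list(epsilon = epsilon, symmetry = symmetry)
  )
}

#' Preset: epidermal lineage with optional hair-follicle stem-cell influx
#'
#' A variant of the system-#5 network used to contrast hairless (paw) and
#' hairy (ear/tail) epidermis. Death is no longer the complement of division,
#' and SCs may arrive from an exogenous source (hair follicles) at a rate
#' decreasing in the SC population:
#' \deqn{L = \frac{0.9\tanh x}{2\tanh x + 0.4}, \quad P = \tanh(x + 0.1y),
#'       \quad D = h + 0.01 y, \quad S = c, \quad E = \frac{0.02}{1 + x}.}
#'
#' @inheritParams make_model3
#' @param h baseline death rate of differentiated cells, `>= 0` (default 0.3).
#' @param influx logical; `FALSE` removes the exogenous source (`E = 0`),
#'   modeling skin without hair follicles.
#' @return A [control_network] with analytic derivatives attached.
#' @export
make_follicle_model <- function(epsilon, symmetry, h = 0.3, influx = TRUE) {
  check_preset_args(epsilon, symmetry)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0) {
    stop("`h` must be a single nonnegative number", call. = FALSE)
  }
  force(symmetry); force(h)
  control_network(
    L = function(x, y) 0.9 * tanh(x) / (2 * tanh(x) + 0.4),
    P = function(x, y) tanh(x + 0.1 * y),
    D = function(x, y) h + 0.01 * y,
    S = function(x, y) symmetry,
    E = if (influx) function(x) 0.02 / (1 + x) else NULL,
    epsilon = epsilon,
    derivs = function(x, y) {
      s2 <- sech2(x + 0.1 * y)
      list(Lx = 0.36 * sech2(x) / (2 * tanh(x) + 0.4)^2, Ly = 0,
           Px = s2, Py = 0.1 * s2,
           Dx = 0, Dy = 0.01)
    },
    name = "follicle",
    params = list(epsilon = epsilon, symmetry = symmetry, h = h,
                  influx = influx)
  )
}

check_preset_args <- function(epsilon, symmetry) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(symmetry) || length(symmetry) != 1L ||
      !is.finite(symmetry) || symmetry <= 0 || symmetry > 1) {
    stop("`symmetry` must lie in (0, 1]", call. = FALSE)
  }
  invisible(NULL)
}

#' Evaluate the four feedback controls of a network at a point
#'
#' The controls of a two-compartment system are the equilibrium partial
#' derivatives with respect to the cell *counts*:
#' `q_x`, `q_y` are the derivatives of `L - D` with respect to `I`, `J`, and
#' `p_x`, `p_y` are the derivatives of `P`. Because all rates depend on the
#' counts only through `x = epsilon I`, `y = epsilon J`, each control equals
#' `epsilon` times the corresponding scaled-coordinate derivative and is
#' therefore `O(epsilon)`.
#'
#' Derivatives come from the network's analytic `derivs` when available,
#' otherwise from central finite differences with step
#' `1e-6 * max(1, |coordinate|)` in the scaled coordinates.
#'
#' @param network a [control_network].
#' @param point numeric length-2 vector `(x, y)` of nonnegative scaled
#'   coordinates.
#' @param method `"auto"` (analytic when available), `"analytic"` or `"fd"`.
#' @return An object of class `controls`: named numeric vector with entries
#'   `q_x`, `q_y`, `p_x`, `p_y`.
#' @examples
#' net <- make_model5(0.005, 0.8)
#' eq <- solve_mixed(net)
#' evaluate_controls(net, c(eq$x0, eq$y0)) / net$epsilon  # (2.4, 0, 0.75, 0.075)
#' @export
evaluate_controls <- function(network, point,
                              method = c("auto", "analytic", "fd")) {
  stopifnot(inherits(network, "control_network"))
  method <- match.arg(method)
  if (!is.numeric(point) || length(point) != 2L || any(!is.finite(point)) ||
      any(point < 0)) {
    stop("`point` must be two finite nonnegative scaled coordinates",
         call. = FALSE)
  }
  x <- point[[1L]]; y <- point[[2L]]
  use_analytic <- switch(method,
    auto = !is.null(network$derivs),
    analytic = {
      if (is.null(network$derivs)) {
        stop("network supplies no analytic derivatives", call. = FALSE)
      }
      TRUE
    },
    fd = FALSE)
  if (use_analytic) {
    d <- network$derivs(x, y)
    out <- c(q_x = d$Lx - d$Dx, q_y = d$Ly - d$Dy, p_x = d$Px, p_y = d$Py)
  } else {
    q <- function(x, y) network$L(x, y) - network$D(x, y)
    out <- c(
      q_x = fd_partial(q, x, y, 1L),
      q_y = fd_partial(q, x, y, 2L),
      p_x = fd_partial(network$P, x, y, 1L),
      p_y = fd_partial(network$P, x, y, 2L)
    )
  }
  out <- out * network$epsilon
  if (any(!is.finite(out))) {
    stop("non-finite derivative estimate at (", x, ", ", y, ")",
         call. = FALSE)
  }
  structure(out, class = "controls")
}

# central difference in argument `arg` (1 = x, 2 = y); step scales with the
# coordinate so that O(epsilon) controls are not swamped by roundoff
fd_partial <- function(f, x, y, arg) {
  h <- 1e-6 * max(1, abs(if (arg == 1L) x else y))
  if (arg == 1L) (f(x + h, y) - f(x - h, y)) / (2 * h)
  else           (f(x, y + h) - f(x, y - h)) / (2 * h)
}

#' @export
print.controls <- function(x, ...) {
  cat("<controls> (derivatives of L - D and P with respect to I, J)\n")
  print(unclass(x), ...)
  invisible(x)
}
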