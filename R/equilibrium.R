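#' Solve for the mixed-divisions steady state
#'
#' The mixed-divisions equilibrium `(i0, j0)` of a closed network satisfies
#' `P(x0, y0) = 1/2` and `L(x0, y0) = D(x0, y0)` in scaled coordinates
#' `x0 = epsilon * i0`, `y0 = epsilon * j0`: divisions balance deaths and,
#' among symmetric divisions, differentiation balances proliferation. The
#' symmetric fraction `S` does not enter these conditions, so the equilibrium
#' populations are independent of `S` — only stability and fluctuation size
#' depend on it.
#'
#' The root is located by a damped Newton iteration on the residual
#' `(P - 1/2, L - D)` from the default initial guess `(1, 1)`; if that fails,
#' a multi-start on a log-spaced grid over `[1e-3, 10]^2` is tried. The
#' accepted root has residual norm below `tol`.
#'
#' @param network a closed [control_network] (`E` absent or identically zero).
#' @param guess optional initial guess `(x, y)` in scaled coordinates.
#' @param tol residual tolerance (default `1e-10`).
#' @return Object of class `equilibrium`: list with `i0`, `j0` (counts),
#'   `x0`, `y0` (scaled), `L_star`, `P_star`, `S_star`, `kind = "mixed"`,
#'   and `residuals`.
#' @examples
#' solve_mixed(make_model3(0.005, 0.5))  # i0 ~ 52.55, j0 ~ 46.21
#' @export
solve_mixed <- function(network, guess = c(1, 1), tol = 1e-10) {
  stopifnot(inherits(network, "control_network"))
  if (!is.null(network$E)) {
    ez <- tryCatch(network$E(1), error = function(e) NA_real_)
    if (!isTRUE(ez == 0)) {
      stop("mixed steady state is defined for closed systems; ",
           "drop the influx term (see `make_follicle_model(influx = FALSE)`)",
           call. = FALSE)
    }
  }
  res_fun <- function(p) c(network$P(p[1], p[2]) - 0.5,
                           network$L(p[1], p[2]) - network$D(p[1], p[2]))
  root <- newton_root(res_fun, guess, tol = tol)
  if (is.null(root)) {
    grid <- exp(seq(log(1e-3), log(10), length.out = 7))
    for (gx in grid) {
      for (gy in grid) {
        root <- newton_root(res_fun, c(gx, gy), tol = tol)
        if (!is.null(root)) break
      }
      if (!is.null(root)) break
    }
  }
  if (is.null(root)) {
    stop("no mixed equilibrium found in the search domain", call. = FALSE)
  }
  x0 <- root[1]; y0 <- root[2]
  eps <- network$epsilon
  structure(
    list(kind = "mixed",
         i0 = x0 / eps, j0 = y0 / eps, x0 = x0, y0 = y0,
         L_star = network$L(x0, y0),
         P_star = network$P(x0, y0),
         S_star = network$S(x0, y0),
         residuals = res_fun(root)),
    class = "equilibrium"
  )
}

#' Solve for the purely asymmetric steady state
#'
#' With `S = 0` every division is asymmetric, the SC count is conserved, and
#' the only equilibrium condition is the division/death balance
#' `L(x, y) = D(x, y)`; the differentiation probability `P` becomes
#' irrelevant. Because one equation constrains two coordinates, the balance
#' set is generically a curve: the SC population is pinned by the initial
#' condition, not by the dynamics. Supply `i0` to select the branch; without
#' it the solver returns the point reached from the initial guess and flags
#' the under-determinacy (rank of the residual Jacobian < 2).
#'
#' @inheritParams solve_mixed
#' @param i0 optional stem-cell count fixing `x0 = epsilon * i0`, in which
#'   case only `y` is solved for.
#' @return Object of class `equilibrium` with `kind = "purely_asymmetric"`,
#'   `S_star = 0`, the recorded (non-constraining) `P_star`, and a
#'   `degenerate` flag indicating a one-parameter solution curve.
#' @export
solve_asymmetric <- function(network, i0 = NULL, guess = c(1, 1),
                             tol = 1e-10) {
  stopifnot(inherits(network, "control_network"))
  eps <- network$epsilon
  if (!is.null(i0)) {
    x0 <- i0 * eps
    f <- function(y) network$L(x0, y) - network$D(x0, y)
    root <- newton_root(function(p) f(p[1]), guess[length(guess)], tol = tol)
    if (is.null(root)) {
      stop("no division/death balance found at the given stem-cell count",
           call. = FALSE)
    }
    y0 <- root[1]
    degenerate <- FALSE
  } else {
    res_fun <- function(p) network$L(p[1], p[2]) - network$D(p[1], p[2])
    # Gauss-Newton on the scalar residual; converges to some point on the curve
    root <- newton_root(function(p) c(res_fun(p), 0), guess, tol = tol,
                        allow_singular = TRUE)
    if (is.null(root)) {
      stop("no division/death balance found in the search domain",
           call. = FALSE)
    }
    x0 <- root[1]; y0 <- root[2]
    # rank of the 1x2 residual Jacobian is at most 1: the balance condition
    # alone cannot pin both populations
    jac <- num_jacobian(function(p) res_fun(p), c(x0, y0))
    degenerate <- qr(rbind(jac, c(0, 0)))$rank < 2L
    if (degenerate) {
      warning("purely asymmetric balance is under-determined: ",
              "L = D defines a curve; supply `i0` to pick a branch",
              call. = FALSE)
    }
  }
  structure(
    list(kind = "purely_asymmetric",
         i0 = x0 / eps, j0 = y0 / eps, x0 = x0, y0 = y0,
         L_star = network$L(x0, y0),
         P_star = network$P(x0, y0),
         S_star = 0,
         degenerate = degenerate,
         residuals = network$L(x0, y0) - network$D(x0, y0)),
    class = "equilibrium"
  )
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium>", x$kind, "\n")
  cat(sprintf("  i0 = %.6g, j0 = %.6g (x0 = %.6g, y0 = %.6g)\n",
              x$i0, x$j0, x$x0, x$y0))
  cat(sprintf("  L* = %.6g, P* = %.6g, S* = %.6g\n",
              x$L_star, x$P_star, x$S_star))
  cat("  max |residual| =", format(max(abs(x$residuals))), "\n")
  invisible(x)
}

#' Integrate the deterministic mean-field system
#'
#' The macroscopic counterpart of the stochastic update rules, in cell
#' counts `(I, J)`:
#' \deqn{dI/dt = L S (1 - 2P) + E, \qquad dJ/dt = 2 L S P + L(1 - S) - D,}
#' with all rates evaluated at `(epsilon I, epsilon J)` and `E = 0` for
#' closed systems. The mixed steady state of [solve_mixed()] is a fixed
#' point; trajectories started in its basin converge to it.
#'
#' Integration uses [deSolve::ode()] (`lsoda`, stiff-capable) with relative
#' tolerance `1e-9`.
#'
#' @param network a [control_network].
#' @param init nonnegative initial counts `(I, J)`.
#' @param horizon final time (in update-rate units), `> 0`.
#' @param n_out number of equally spaced output times.
#' @param blowup_bound divergence guard: integration aborts with an error if
#'   either population exceeds this bound.
#' @return A data frame with columns `time`, `I`, `J`.
#' @export
integrate_mean_field <- function(network, init, horizon, n_out = 200L,
                                 blowup_bound = 1e9) {
  stopifnot(inherits(network, "control_network"))
  if (!is.numeric(init) || length(init) != 2L || any(init < 0)) {
    stop("`init` must be two nonnegative counts", call. = FALSE)
  }
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("`horizon` must be positive", call. = FALSE)
  }
  eps <- network$epsilon
  rhs <- function(t, state, parms) {
    x <- eps * state[1]; y <- eps * state[2]
    L <- network$L(x, y); P <- network$P(x, y)
    S <- network$S(x, y); D <- network$D(x, y)
    E <- if (is.null(network$E)) 0 else network$E(x)
    list(c(L * S * (1 - 2 * P) + E,
           2 * L * S * P + L * (1 - S) - D))
  }
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::ode(y = c(I = init[1], J = init[2]), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  out <- as.data.frame(sol)
  names(out) <- c("time", "I", "J")
  if (any(!is.finite(as.matrix(out))) ||
      max(out$I, out$J, na.rm = TRUE) > blowup_bound) {
    stop("mean-field trajectory diverged beyond the configured bound",
         call. = FALSE)
  }
  out
}

# --- small numeric helpers ---------------------------------------------------

# damped Newton with numeric Jacobian; returns NULL on failure
newton_root <- function(f, start, tol = 1e-10, max_iter = 200L,
                        allow_singular = FALSE) {
  p <- as.numeric(start)
  n <- length(p)
  for (iter in seq_len(max_iter)) {
    r <- tryCatch(f(p), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(NULL)
    if (max(abs(r)) < tol) return(p)
    J <- num_jacobian(f, p)
    if (any(!is.finite(J))) return(NULL)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      if (!allow_singular) return(NULL)
      step <- tryCatch(-c(qr.solve(J, r)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        # steepest-descent fallback for rank-deficient residual systems
        step <- -c(crossprod(J, r)) / max(sum(J^2), .Machine$double.eps)
      }
    }
    # backtracking line search; keep the iterate in the nonnegative quadrant
    lambda <- 1
    r0 <- sum(r^2)
    repeat {
      cand <- pmax(p + lambda * step, 0)
      rc <- tryCatch(f(cand), error = function(e) NULL)
      if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) < r0) {
        p <- cand
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) return(NULL)
    }
  }
  if (max(abs(f(p))) < tol) p else NULL
}

num_jacobian <- function(f, p) {
  r0 <- f(p)
  m <- length(r0); n <- length(p)
  J <- matrix(0, m, n)
  for (k in seq_len(n)) {
    h <- 1e-7 * max(1, abs(p[k]))
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    J[, k] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}
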