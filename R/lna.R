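#' Linear-noise-approximation moments at the mixed steady state
#'
#' To leading order in the control strength `epsilon`, fluctuations of the
#' cell counts about the mixed equilibrium are Gaussian with
#' \deqn{Var[I] = \frac{K_x}{4 B \Delta}, \qquad
#'       Var[J] = \frac{K_y}{4 B \Delta},}
#' where, writing `L*` and `S*` for the equilibrium division rate and
#' symmetric fraction and `q_x, q_y, p_x, p_y` for the four controls,
#' \deqn{\Delta = q_x p_y - q_y p_x, \qquad
#'       B = 2 L^* S^* (p_x - p_y) - q_y,}
#' \deqn{K_x = 2 L^* S^* \Delta + q_y^2 + 8 L^{*2} S^* p_y^2, \qquad
#'       K_y = 2 L^* (2 + S^*) \Delta + q_x^2 + 8 L^{*2} S^* p_x^2.}
#' The means equal the deterministic equilibrium, `E[I] = i0`, `E[J] = j0`.
#' The equilibrium is stable (and the variances positive) precisely when
#' `Delta > 0` and `B > 0`; both `K_x` and `K_y` are positive whenever
#' `Delta > 0`.
#'
#' @param eq an `equilibrium` of kind `"mixed"` (see [solve_mixed()]).
#' @param controls a `controls` vector from [evaluate_controls()].
#' @param S_star symmetric-division fraction in `(0, 1]`; defaults to the
#'   equilibrium value stored in `eq`.
#' @return Object of class `lna_result`: list with `Delta`, `B`, `K_x`,
#'   `K_y`, `var_I`, `var_J`, `mean_I`, `mean_J`, `stable`, `S_c`,
#'   `L_star`, `S_star`.
#' @examples
#' net <- make_model5(0.005, 1)
#' eq <- solve_mixed(net)
#' ct <- evaluate_controls(net, c(eq$x0, eq$y0))
#' lna_moments(eq, ct)  # var_I ~ 78.70, var_J ~ 3055.6
#' @export
lna_moments <- function(eq, controls, S_star = eq$S_star) {
  stopifnot(inherits(eq, "equilibrium"))
  if (!identical(eq$kind, "mixed")) {
    stop("linear-noise variances are available at the mixed steady state ",
         "only; the purely asymmetric branch is simulation-only",
         call. = FALSE)
  }
  if (!is.numeric(S_star) || length(S_star) != 1L || S_star <= 0 ||
      S_star > 1) {
    stop("`S_star` must lie in (0, 1]", call. = FALSE)
  }
  ct <- as_controls(controls)
  Ls <- eq$L_star
  Delta <- ct[["q_x"]] * ct[["p_y"]] - ct[["q_y"]] * ct[["p_x"]]
  B <- 2 * Ls * S_star * (ct[["p_x"]] - ct[["p_y"]]) - ct[["q_y"]]
  if (Delta == 0 || B == 0) {
    stop("non-hyperbolic equilibrium (Delta or B vanishes): ",
         "variances are undefined", call. = FALSE)
  }
  K_x <- 2 * Ls * S_star * Delta + ct[["q_y"]]^2 +
    8 * Ls^2 * S_star * ct[["p_y"]]^2
  K_y <- 2 * Ls * (2 + S_star) * Delta + ct[["q_x"]]^2 +
    8 * Ls^2 * S_star * ct[["p_x"]]^2
  st <- stability(ct, Ls, S_star)
  structure(
    list(Delta = Delta, B = B, K_x = K_x, K_y = K_y,
         var_I = K_x / (4 * B * Delta), var_J = K_y / (4 * B * Delta),
         mean_I = eq$i0, mean_J = eq$j0,
         stable = st$stable, S_c = st$S_c,
         L_star = Ls, S_star = S_star),
    class = "lna_result"
  )
}

#' @export
print.lna_result <- function(x, ...) {
  cat("<lna_result>\n")
  cat(sprintf("  E[I] = %.6g, E[J] = %.6g\n", x$mean_I, x$mean_J))
  cat(sprintf("  Var[I] = %.6g, Var[J] = %.6g\n", x$var_I, x$var_J))
  cat(sprintf("  Delta = %.6g, B = %.6g, K_x = %.6g, K_y = %.6g\n",
              x$Delta, x$B, x$K_x, x$K_y))
  cat(sprintf("  stable = %s, S_c = %.6g (S* = %.6g)\n",
              x$stable, x$S_c, x$S_star))
  invisible(x)
}

#' Stability of the mixed steady state and the critical symmetry
#'
#' The mixed equilibrium is stable iff `Delta > 0` and `B > 0`. Since only
#' `B` depends on the symmetric fraction, `S*` controls stability through
#' the threshold
#' \deqn{S_c = \frac{q_y}{2 L^* (p_x - p_y)}:}
#' when `p_x > p_y` the stable side is `S* > S_c`; when `p_x < p_y` it is
#' `S* < S_c` (the inequality flips with the sign of the denominator). When
#' `p_x = p_y`, `B = -q_y` does not depend on `S*` and `S_c` degenerates to
#' a signed infinity (`-Inf` for `q_y < 0`, i.e. always stable in `S*`;
#' `+Inf` for `q_y > 0`, never stable; `NaN` when additionally `q_y = 0`,
#' where `B` vanishes identically).
#'
#' @param controls a `controls` vector (or named numeric with `q_x`, `q_y`,
#'   `p_x`, `p_y`).
#' @param L_star equilibrium division rate, `> 0`.
#' @param S_star symmetric fraction at which stability is assessed.
#' @return List with `stable` (logical), `S_c` (extended real), `Delta`, `B`.
#' @export
stability <- function(controls, L_star, S_star) {
  ct <- as_controls(controls)
  if (!is.numeric(L_star) || L_star <= 0) {
    stop("`L_star` must be positive", call. = FALSE)
  }
  Delta <- ct[["q_x"]] * ct[["p_y"]] - ct[["q_y"]] * ct[["p_x"]]
  B <- 2 * L_star * S_star * (ct[["p_x"]] - ct[["p_y"]]) - ct[["q_y"]]
  dp <- ct[["p_x"]] - ct[["p_y"]]
  S_c <- if (dp == 0) {
    if (ct[["q_y"]] < 0) -Inf else if (ct[["q_y"]] > 0) Inf else NaN
  } else {
    ct[["q_y"]] / (2 * L_star * dp)
  }
  list(stable = (Delta > 0 && B > 0), S_c = S_c, Delta = Delta, B = B)
}

#' Sensitivity of the variances to the symmetric-division fraction
#'
#' Differentiating `Var[I] = K_x/(4 B Delta)` and `Var[J] = K_y/(4 B Delta)`
#' with respect to `S*` (only `K_x`, `K_y` and `B` depend on it, all
#' linearly) gives the closed forms
#' \deqn{\frac{d\,Var[I]}{dS^*} =
#'   \frac{L^*\, p_y q_y (q_y - q_x - 4 L^* p_y)}{2 B^2 \Delta}, \qquad
#'   \frac{d\,Var[J]}{dS^*} =
#'   \frac{L^* (p_x q_x - \Delta)(q_y - q_x - 4 L^* p_y)}{2 B^2 \Delta}.}
#' For fixed controls the dependence of each variance on `S*` is therefore
#' monotonic. Notably `d Var[I]/dS* = 0` whenever `q_y = 0` or `p_y = 0`
#' (e.g. minimal systems #1, #2 and #5).
#'
#' @inheritParams stability
#' @return List with `dvarI_dS` and `dvarJ_dS`.
#' @export
variance_sensitivity <- function(controls, L_star, S_star) {
  ct <- as_controls(controls)
  Delta <- ct[["q_x"]] * ct[["p_y"]] - ct[["q_y"]] * ct[["p_x"]]
  B <- 2 * L_star * S_star * (ct[["p_x"]] - ct[["p_y"]]) - ct[["q_y"]]
  if (Delta == 0 || B == 0) {
    stop("non-hyperbolic equilibrium (Delta or B vanishes)", call. = FALSE)
  }
  common <- (ct[["q_y"]] - ct[["q_x"]] - 4 * L_star * ct[["p_y"]]) *
    L_star / (2 * B^2 * Delta)
  list(
    dvarI_dS = ct[["p_y"]] * ct[["q_y"]] * common,
    dvarJ_dS = (ct[["p_x"]] * ct[["q_x"]] - Delta) * common
  )
}

as_controls <- function(controls) {
  ct <- unclass(controls)
  need <- c("q_x", "q_y", "p_x", "p_y")
  if (!is.numeric(ct) || !all(need %in% names(ct))) {
    stop("`controls` must be a named numeric vector with entries ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(ct[need]))) {
    stop("controls must be finite", call. = FALSE)
  }
  ct[need]
}

#' One-call analytic report for a network
#'
#' Convenience wrapper chaining [solve_mixed()], [evaluate_controls()],
#' [lna_moments()], [stability()], [variance_sensitivity()] and
#' [classify_network()] into a single report, as emitted by the `analyze`
#' subcommand of [run_cli()].
#'
#' @param network a closed [control_network].
#' @param S_star symmetric fraction; defaults to the network's equilibrium
#'   value.
#' @return List with the equilibrium, controls, `lna_result`, sensitivities
#'   and classification.
#' @export
analyze_network <- function(network, S_star = NULL) {
  eq <- solve_mixed(network)
  if (is.null(S_star)) S_star <- eq$S_star
  ct <- evaluate_controls(network, c(eq$x0, eq$y0))
  st <- stability(ct, eq$L_star, S_star)
  if (!st$stable) {
    stop(sprintf(paste0("network is unstable at S* = %.4g (Delta = %.4g, ",
                        "B = %.4g, S_c = %.4g)"),
                 S_star, st$Delta, st$B, st$S_c), call. = FALSE)
  }
  lna <- lna_moments(eq, ct, S_star)
  sens <- variance_sensitivity(ct, eq$L_star, S_star)
  cls <- classify_network(sign_pattern(
    q_x = sign(ct[["q_x"]]), q_y = sign(ct[["q_y"]]),
    p_x = sign(ct[["p_x"]]), p_y = sign(ct[["p_y"]])))
  list(equilibrium = eq, controls = ct, lna = lna, sensitivity = sens,
       classification = cls)
}
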