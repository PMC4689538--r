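# Independent brute-force oracle for the stationary moments: solve the
# truncated linear moment system in (X10, X01, X20, X02, X11) directly,
# including the first-derivative terms of the division rate (lx, ly), the
# symmetry (sx, sy) and the death rate (dx, dy), which the closed-form
# variances do not contain. Because the first-moment equations force
# X10 = X01 = 0 whenever Delta != 0, those terms must cancel -- the oracle
# verifies that numerically rather than assuming it.
lna_oracle <- function(controls, L_star, S_star,
                       lx = 0, ly = 0, sx = 0, sy = 0, dx = 0, dy = 0) {
  qx <- controls[["q_x"]]; qy <- controls[["q_y"]]
  px <- controls[["p_x"]]; py <- controls[["p_y"]]
  Ls <- L_star; Ss <- S_star
  A <- rbind(
    c(-2 * Ls * Ss * px, -2 * Ls * Ss * py, 0, 0, 0),
    c(2 * Ls * Ss * px + qx, 2 * Ls * Ss * py + qy, 0, 0, 0),
    c(Ss * lx + Ls * sx, Ss * ly + Ls * sy,
      -4 * Ls * Ss * px, 0, -4 * Ls * Ss * py),
    c(-(Ss * lx + Ls * sx + 2 * Ls * Ss * px),
      -(Ss * ly + Ls * sy + 2 * Ls * Ss * py),
      2 * Ls * Ss * px + qx, -2 * Ls * Ss * py,
      2 * Ls * Ss * (py - px) + qy),
    c(Ss * (4 * Ls * px + lx) + lx + dx + Ls * sx,
      Ss * (4 * Ls * py + ly) + ly + dy + Ls * sy,
      0, 4 * Ls * Ss * py + 2 * qy, 4 * Ls * Ss * px + 2 * qx)
  )
  b <- c(0, 0, -Ls * Ss, Ls * Ss, -Ls * (2 + Ss))
  X <- solve(A, b)
  list(X10 = X[1], X01 = X[2],
       var_I = X[3] - X[1]^2, var_J = X[4] - X[2]^2, cov_IJ = X[5])
}

make_controls <- function(q_x, q_y, p_x, p_y) {
  structure(c(q_x = q_x, q_y = q_y, p_x = p_x, p_y = p_y),
            class = "controls")
}

# draw a control set with Delta > 0 and B > 0 at the given (L*, S*); the
# margin keeps the drawn system away from the non-hyperbolic boundary,
# where rational functions of B blow up and finite differences degrade
random_stable_controls <- function(L_star = 0.5, S_star = NULL,
                                   margin = 0.15) {
  repeat {
    ct <- make_controls(runif(1, -1, 1), runif(1, -1, 1),
                        runif(1, -1, 1), runif(1, -1, 1))
    Ss <- if (is.null(S_star)) runif(1, 0.05, 1) else S_star
    Delta <- ct[["q_x"]] * ct[["p_y"]] - ct[["q_y"]] * ct[["p_x"]]
    B <- 2 * L_star * Ss * (ct[["p_x"]] - ct[["p_y"]]) - ct[["q_y"]]
    if (Delta > margin && B > margin) {
      return(list(controls = ct, L_star = L_star, S_star = Ss))
    }
  }
}

# simple central difference used as an implementation-independent check
fd2 <- function(f, x, y, arg, h = 1e-6) {
  if (arg == 1L) (f(x + h, y) - f(x - h, y)) / (2 * h)
  else           (f(x, y + h) - f(x, y - h)) / (2 * h)
}
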