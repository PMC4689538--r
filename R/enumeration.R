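#' Sign pattern of a control network
#'
#' A control system is characterized, up to magnitudes, by the signs of its
#' four controls. Two networks with the same (support, sign) pair belong to
#' the same system; magnitudes are existentially quantified when asking
#' whether the pattern admits a stable equilibrium.
#'
#' @param q_x,q_y,p_x,p_y signs in `{-1, 0, 1}` for the controls on
#'   division/death (`q`) and differentiation (`p`) by stem cells (`x`) and
#'   differentiated cells (`y`).
#' @param label optional system label (e.g. `"#1"`).
#' @return Object of class `sign_pattern`: named integer vector.
#' @export
sign_pattern <- function(q_x = 0, q_y = 0, p_x = 0, p_y = 0, label = NULL) {
  v <- c(q_x = q_x, q_y = q_y, p_x = p_x, p_y = p_y)
  if (!all(v %in% c(-1, 0, 1))) {
    stop("sign entries must be -1, 0 or 1", call. = FALSE)
  }
  structure(as.integer(v), names = names(v), label = label,
            class = "sign_pattern")
}

#' @export
print.sign_pattern <- function(x, ...) {
  lbl <- attr(x, "label")
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")[as.character(unclass(x))]
  cat("<sign_pattern>", if (!is.null(lbl)) lbl else "",
      paste(names(unclass(x)), sym, sep = ":", collapse = " "), "\n")
  invisible(x)
}

# canonical sign patterns of the five minimal control systems
minimal_system_table <- function() {
  list(
    `#1` = sign_pattern(q_x = -1, p_y = -1, label = "#1"),
    `#2` = sign_pattern(q_y = -1, p_x = 1, label = "#2"),
    `#3` = sign_pattern(q_x = 1, q_y = -1, p_y = 1, label = "#3"),
    `#4` = sign_pattern(q_y = 1, p_x = -1, p_y = -1, label = "#4"),
    `#5` = sign_pattern(q_x = 1, p_x = 1, p_y = 1, label = "#5")
  )
}

#' Can a sign pattern support a stable mixed equilibrium?
#'
#' Decides whether strictly positive magnitudes for the nonzero controls,
#' some `L* > 0` and some `S*` in `(0, 1]` exist such that `Delta > 0` and
#' `B > 0`. The default decision is an exact sign calculus:
#' `Delta = q_x p_y - q_y p_x` can be made positive iff one of its two terms
#' can be (`sign(q_x p_y) = +1` or `sign(q_y p_x) = -1`), and
#' `B = 2 L* S* (p_x - p_y) - q_y` iff `p_x > 0`, `p_y < 0` or `q_y < 0`;
#' free magnitudes decouple the two conditions, so the conjunction is
#' achievable iff each is. `method = "sampling"` cross-checks by drawing
#' magnitudes log-uniformly from `[1e-2, 1e2]` (and `S*` uniformly) under a
#' fixed seed and searching for a witness.
#'
#' @param pattern a [sign_pattern()].
#' @param method `"sign"` (exact) or `"sampling"` (randomized witness
#'   search).
#' @param draws number of sampled magnitude sets for `method = "sampling"`.
#' @param seed RNG seed for the sampling cross-check.
#' @return Logical scalar.
#' @export
is_stabilizable <- function(pattern, method = c("sign", "sampling"),
                            draws = 1000L, seed = 0L) {
  stopifnot(inherits(pattern, "sign_pattern"))
  method <- match.arg(method)
  s <- unclass(pattern)
  if (method == "sign") {
    delta_ok <- (s[["q_x"]] * s[["p_y"]] == 1L) ||
      (s[["q_y"]] * s[["p_x"]] == -1L)
    b_ok <- (s[["p_x"]] == 1L) || (s[["p_y"]] == -1L) || (s[["q_y"]] == -1L)
    return(delta_ok && b_ok)
  }
  with_preserved_seed({
    set.seed(seed)
    found <- FALSE
    for (k in seq_len(draws)) {
      mag <- exp(runif(4, log(1e-2), log(1e2)))
      ct <- s * mag
      Ls <- exp(runif(1, log(1e-2), log(1e2)))
      Ss <- runif(1)
      Delta <- ct[["q_x"]] * ct[["p_y"]] - ct[["q_y"]] * ct[["p_x"]]
      B <- 2 * Ls * Ss * (ct[["p_x"]] - ct[["p_y"]]) - ct[["q_y"]]
      if (Delta > 0 && B > 0) {
        found <- TRUE
        break
      }
    }
    found
  })
}

#' Enumerate minimal (two-control) and irreducible three-control systems
#'
#' Brute force over all signed supports with exactly `k` nonzero controls
#' (`choose(4, k) * 2^k` patterns), keeping those that admit a stable mixed
#' equilibrium. For `k = 3`, only irreducible patterns are returned: those
#' for which zeroing any single control never leaves a stabilizable
#' two-control pattern. With two compartments there are exactly two minimal
#' two-control systems (#1, #2) and three irreducible three-control systems
#' (#3, #4, #5).
#'
#' @param k number of nonzero controls, 2 or 3 (set `all_supports = TRUE`
#'   to lift the restriction and enumerate any `k` in 0..4 without the
#'   irreducibility filter).
#' @param all_supports logical; enumerate without the minimality
#'   restriction.
#' @return List of [sign_pattern()] objects, labelled where they match one
#'   of systems #1-#5.
#' @export
enumerate_minimal <- function(k, all_supports = FALSE) {
  if (!all_supports && !k %in% c(2L, 3L)) {
    stop("`k` must be 2 or 3 (see `all_supports` for the full enumeration)",
         call. = FALSE)
  }
  if (!k %in% 0:4) stop("`k` must lie in 0..4", call. = FALSE)
  nm <- c("q_x", "q_y", "p_x", "p_y")
  out <- list()
  supports <- utils::combn(4L, k, simplify = FALSE)
  if (k == 0L) supports <- list(integer(0))
  for (sup in supports) {
    signs <- expand.grid(rep(list(c(-1L, 1L)), length(sup)))
    if (length(sup) == 0L) signs <- data.frame(row.names = 1L)
    for (r in seq_len(nrow(signs))) {
      v <- integer(4)
      v[sup] <- as.integer(signs[r, ])
      pat <- sign_pattern(q_x = v[1], q_y = v[2], p_x = v[3], p_y = v[4])
      if (!is_stabilizable(pat)) next
      if (!all_supports && k == 3L && !is_irreducible(pat)) next
      attr(pat, "label") <- match_minimal_label(pat)
      out[[length(out) + 1L]] <- pat
    }
  }
  out
}

# a three-control pattern is irreducible when no single zeroing of a nonzero
# control leaves a stabilizable pattern
is_irreducible <- function(pattern) {
  s <- unclass(pattern)
  nz <- which(s != 0L)
  for (idx in nz) {
    v <- s
    v[idx] <- 0L
    reduced <- sign_pattern(q_x = v[["q_x"]], q_y = v[["q_y"]],
                            p_x = v[["p_x"]], p_y = v[["p_y"]])
    if (is_stabilizable(reduced)) return(FALSE)
  }
  TRUE
}

match_minimal_label <- function(pattern) {
  s <- unclass(pattern)
  for (cand in minimal_system_table()) {
    if (all(unclass(cand) == s)) return(attr(cand, "label"))
  }
  NULL
}

#' Classify a sign pattern among the minimal control systems
#'
#' Matches the pattern against the five minimal systems and reports how each
#' population variance depends on the symmetric-division fraction together
#' with the fluctuation-minimizing division mode. Within the stable regime
#' the trends are sign-determined for all five systems:
#' \describe{
#'   \item{#1 `(q_x<0, p_y<0)`}{`Var[I]` constant, `Var[J]` decreasing —
#'     symmetric divisions optimal.}
#'   \item{#2 `(q_y<0, p_x>0)`}{`Var[I]` constant, `Var[J]` increasing —
#'     asymmetric divisions optimal.}
#'   \item{#3 `(q_x>0, q_y<0, p_y>0)`}{both increasing — asymmetric
#'     optimal.}
#'   \item{#4 `(q_y>0, p_x<0, p_y<0)`}{both decreasing — symmetric
#'     optimal.}
#'   \item{#5 `(q_x>0, p_x>0, p_y>0)`}{`Var[I]` constant, `Var[J]`
#'     decreasing — symmetric optimal.}
#' }
#' Stabilizable patterns that are none of the five are labelled
#' `"non-minimal"` (their trends can depend on magnitudes); patterns
#' admitting no stable regime are `"unstabilizable"`.
#'
#' @param pattern a [sign_pattern()].
#' @return List with `label`, `trend_I`, `trend_J` (each
#'   `"increasing"|"decreasing"|"constant"|"indeterminate"|NA`) and
#'   `optimal` (`"symmetric"|"asymmetric"|"indeterminate"|NA`).
#' @export
classify_network <- function(pattern) {
  stopifnot(inherits(pattern, "sign_pattern"))
  if (!is_stabilizable(pattern)) {
    return(list(label = "unstabilizable", trend_I = NA_character_,
                trend_J = NA_character_, optimal = NA_character_))
  }
  trends <- list(
    `#1` = list(trend_I = "constant", trend_J = "decreasing",
                optimal = "symmetric"),
    `#2` = list(trend_I = "constant", trend_J = "increasing",
                optimal = "asymmetric"),
    `#3` = list(trend_I = "increasing", trend_J = "increasing",
                optimal = "asymmetric"),
    `#4` = list(trend_I = "decreasing", trend_J = "decreasing",
                optimal = "symmetric"),
    `#5` = list(trend_I = "constant", trend_J = "decreasing",
                optimal = "symmetric")
  )
  lbl <- match_minimal_label(pattern)
  if (is.null(lbl)) {
    return(list(label = "non-minimal", trend_I = "indeterminate",
                trend_J = "indeterminate", optimal = "indeterminate"))
  }
  c(list(label = lbl), trends[[lbl]])
}

#' Tabulate the minimal control systems
#'
#' Runs [enumerate_minimal()] for `k = 2` and `k = 3` and assembles one row
#' per system: signs, label, the `S*` stability window implied by `S_c`, and
#' the fluctuation-optimal division mode.
#'
#' @return A data frame, one row per minimal system.
#' @export
minimal_systems_table <- function() {
  pats <- c(enumerate_minimal(2L), enumerate_minimal(3L))
  rows <- lapply(pats, function(p) {
    s <- unclass(p)
    cls <- classify_network(p)
    # stability window in S*: q_y = 0 or q_y < 0 with p_x >= p_y -> all of
    # (0,1]; otherwise bounded by S_c (sign of p_x - p_y decides the side)
    window <- if (s[["q_y"]] == 0L ||
                  (s[["q_y"]] < 0L && s[["p_x"]] >= s[["p_y"]])) {
      "(0, 1]"
    } else if (s[["q_y"]] > 0L) {
      "(S_c, 1] for magnitudes with S_c < 1"
    } else {
      "(0, min(1, S_c))"
    }
    data.frame(label = cls$label,
               q_x = s[["q_x"]], q_y = s[["q_y"]],
               p_x = s[["p_x"]], p_y = s[["p_y"]],
               n_controls = sum(s != 0L),
               stable_S_window = window,
               trend_var_I = cls$trend_I, trend_var_J = cls$trend_J,
               optimal_mode = cls$optimal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# evaluate `expr` without disturbing the caller's RNG stream
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
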