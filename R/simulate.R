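#' Micro-injury configuration for the stochastic simulator
#'
#' Models random tissue damage (e.g. abrasion of paw epidermis): each update
#' is independently declared an injury event with probability
#' `update_fraction`. In `"removal"` mode the injury removes the
#' nearest-integer of `removal_fraction` times the targeted population
#' (floored at zero) and the update performs no other event. In
#' `"death_multiplier"` mode the update proceeds normally but with the death
#' rate multiplied by `death_multiplier` for that update.
#'
#' @param update_fraction probability in `[0, 1]` that an update is an
#'   injury event.
#' @param removal_fraction fraction in `[0, 1]` of the targeted population
#'   removed per injury (removal mode).
#' @param target `"differentiated"`, `"stem"` or `"both"`. Injuries to the
#'   differentiated compartment are the biologically plausible default: the
#'   suprabasal layer faces the outside, while SCs sit deeper.
#' @param mode `"removal"` or `"death_multiplier"`.
#' @param death_multiplier factor applied to `D` on injured updates
#'   (multiplier mode).
#' @return Object of class `injury_config`.
#' @export
injury_config <- function(update_fraction, removal_fraction = 0.1,
                          target = c("differentiated", "stem", "both"),
                          mode = c("removal", "death_multiplier"),
                          death_multiplier = 10) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  for (p in c(update_fraction, removal_fraction)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("injury probabilities/fractions must lie in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(update_fraction = update_fraction,
                 removal_fraction = removal_fraction,
                 target = target, mode = mode,
                 death_multiplier = death_multiplier),
            class = "injury_config")
}

#' Simulate the discrete stochastic lineage process
#'
#' One update attempt per time step. At state `(I, J)` the candidate events
#' and weights are: symmetric differentiation `L S P` (`(I,J) -> (I-1,J+2)`),
#' symmetric proliferation `L S (1-P)` (`(I+1,J)`), asymmetric division
#' `L (1-S)` (`(I,J+1)`), death of a differentiated cell `D` (`(I,J-1)`),
#' and, when the network has an influx term, SC arrival `E` (`(I+1,J)`).
#' Rates are population-level (e.g. `L` is the probability that *a* SC
#' divides in one update), evaluated at `(epsilon I, epsilon J)`; division
#' weights are zeroed at `I = 0` and the death weight at `J = 0` so counts
#' stay nonnegative. When the weight sum exceeds 1 the event is drawn with
#' normalized probabilities; otherwise the weights are literal Bernoulli
#' probabilities and the update may be a `"none"` event. For the closed
#' `D = 1 - L` presets the weight sum is exactly 1, so every update is an
#' event.
#'
#' The built-in presets run through a compiled core; custom networks (and
#' `scheme = "exact"`) use an R stepper with the identical draw protocol, so
#' preset trajectories are bit-identical across the two engines for the same
#' seed. `scheme = "exact"` draws exponential waiting times with rate equal
#' to the weight sum (continuous-time sampling, no `"none"` events) and adds
#' a `time` column.
#'
#' @param network a [control_network].
#' @param steps maximum number of updates, `>= 1`.
#' @param seed integer RNG seed.
#' @param init starting counts `c(I, J)` with `I >= 1`, or `"equilibrium"`
#'   for the rounded-up mixed steady state (computed with the influx term
#'   dropped, which only sets the starting point).
#' @param scheme `"per-step"` (default, the update-per-step process) or
#'   `"exact"` (event-time sampling; R engine only).
#' @param stop_on_extinction stop when either population hits zero.
#' @param injury optional [injury_config()].
#' @param burn_in updates discarded from the streaming moment sums.
#' @param keep `"trajectory"` (full per-step series) or `"moments"`
#'   (streaming moments only; memory-light, used by sweeps).
#' @param engine `"auto"`, `"native"` (compiled; presets only) or `"r"`.
#' @return For `keep = "trajectory"`, a `trajectory`: data frame with
#'   columns `step`, `I`, `J`, `event` and attributes `config` (echo of the
#'   resolved configuration), `status` (`"completed"`, `"extinct"` or
#'   `"frozen"`) and `init`. For `keep = "moments"`, a `moment_estimate`
#'   (see [estimate_moments()]).
#' @examples
#' net <- make_model5(0.005, 0.8)
#' traj <- simulate(net, steps = 2000, seed = 1)
#' estimate_moments(traj)
#' @export
simulate <- function(network, steps, seed, init = "equilibrium",
                     scheme = c("per-step", "exact"),
                     stop_on_extinction = TRUE, injury = NULL, burn_in = 0L,
                     keep = c("trajectory", "moments"),
                     engine = c("auto", "native", "r")) {
  stopifnot(inherits(network, "control_network"))
  scheme <- match.arg(scheme)
  keep <- match.arg(keep)
  engine <- match.arg(engine)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1) {
    stop("`steps` must be >= 1", call. = FALSE)
  }
  steps <- as.integer(steps)
  if (!is.null(injury) && !inherits(injury, "injury_config")) {
    stop("`injury` must come from injury_config()", call. = FALSE)
  }
  if (burn_in < 0 || burn_in >= steps) {
    if (burn_in != 0) {
      stop("`burn_in` must lie in [0, steps)", call. = FALSE)
    }
  }
  init_counts <- resolve_init(network, init)
  if (init_counts[1] < 1) stop("initial stem-cell count must be >= 1",
                               call. = FALSE)

  native_ok <- scheme == "per-step" &&
    network$name %in% c("model3", "model5", "follicle")
  use_native <- switch(engine,
    auto = native_ok,
    native = {
      if (!native_ok) stop("compiled engine supports the built-in presets ",
                           "with the per-step scheme only", call. = FALSE)
      TRUE
    },
    r = FALSE)

  inj <- injury_params(injury)
  set.seed(as.integer(seed))
  raw <- if (use_native) {
    preset_id <- switch(network$name, model3 = 3L, model5 = 5L, 6L)
    sim_core_native(preset_id, network$epsilon,
                    network$params$symmetry %||% network$S(0, 0),
                    network$params$h %||% 0, !is.null(network$E),
                    steps, as.integer(init_counts[1]),
                    as.integer(init_counts[2]), stop_on_extinction,
                    inj$prob, inj$frac, inj$target, inj$mode, inj$mult,
                    as.integer(burn_in), keep == "trajectory")
  } else {
    sim_core_r(network, steps, init_counts, scheme, stop_on_extinction,
               inj, as.integer(burn_in), keep == "trajectory")
  }

  config <- list(network = network$name, params = network$params,
                 epsilon = network$epsilon, steps = steps, seed = seed,
                 init = init_counts, scheme = scheme,
                 stop_on_extinction = stop_on_extinction,
                 injury = if (is.null(injury)) NULL else unclass(injury),
                 burn_in = as.integer(burn_in), engine =
                   if (use_native) "native" else "r")
  if (keep == "moments") {
    return(moments_from_sums(raw, config))
  }
  traj <- data.frame(step = seq_len(raw$steps_done),
                     I = raw$I, J = raw$J,
                     event = event_names()[raw$event + 1L])
  if (!is.null(raw$time)) traj$time <- raw$time
  structure(traj, config = config, status = raw$status,
            init = init_counts, sums = raw[c("n", "sI", "sJ", "sII",
                                             "sJJ", "sIJ")],
            class = c("trajectory", "data.frame"))
}

event_names <- function() {
  c("none", "diff", "prolif", "asym", "death", "influx", "injury")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_init <- function(network, init) {
  if (is.character(init) && identical(init, "equilibrium")) {
    closed <- network
    closed$E <- NULL
    eq <- solve_mixed(closed)
    if (is.null(network$E)) {
      return(c(ceiling(eq$i0), ceiling(eq$j0)))
    }
    # with an exogenous source the steady state shifts (and depends on S);
    # relax the mean-field system from the closed equilibrium instead
    mf <- integrate_mean_field(network, c(eq$i0, eq$j0),
                               horizon = 1e5, n_out = 3L)
    return(c(ceiling(mf$I[nrow(mf)]), ceiling(mf$J[nrow(mf)])))
  }
  if (!is.numeric(init) || length(init) != 2L || any(init < 0)) {
    stop("`init` must be \"equilibrium\" or two nonnegative counts",
         call. = FALSE)
  }
  as.numeric(init)
}

injury_params <- function(injury) {
  if (is.null(injury)) {
    return(list(prob = 0, frac = 0, target = 0L, mode = 0L, mult = 1))
  }
  list(prob = injury$update_fraction,
       frac = injury$removal_fraction,
       target = match(injury$target,
                      c("differentiated", "stem", "both")) - 1L,
       mode = match(injury$mode, c("removal", "death_multiplier")) - 1L,
       mult = injury$death_multiplier)
}

# pure-R stepper; for scheme = "per-step" this consumes the RNG stream in
# exactly the same order as the compiled core
sim_core_r <- function(network, steps, init, scheme, stop_on_extinction,
                       inj, burn_in, keep_path) {
  I <- init[1]; J <- init[2]
  eps <- network$epsilon
  exact <- identical(scheme, "exact")
  if (keep_path) {
    pI <- integer(steps); pJ <- integer(steps); pev <- integer(steps)
    ptime <- if (exact) numeric(steps) else NULL
  }
  n <- 0; sI <- 0; sJ <- 0; sII <- 0; sJJ <- 0; sIJ <- 0
  status <- "completed"; done <- 0L; t_now <- 0
  for (step in seq_len(steps)) {
    ev <- 0L
    injured <- FALSE
    dmult <- 1
    if (inj$prob > 0) injured <- (runif(1) < inj$prob)
    if (injured && inj$mode == 0L) {
      if (inj$target %in% c(0L, 2L)) {
        J <- max(J - floor(inj$frac * J + 0.5), 0)
      }
      if (inj$target %in% c(1L, 2L)) {
        I <- max(I - floor(inj$frac * I + 0.5), 0)
      }
      ev <- 6L
    } else {
      if (injured && inj$mode == 1L) dmult <- inj$mult
      x <- eps * I; y <- eps * J
      L <- network$L(x, y); P <- network$P(x, y); S <- network$S(x, y)
      D <- network$D(x, y) * dmult
      E <- if (is.null(network$E)) 0 else network$E(x)
      w1 <- if (I > 0) L * S * P else 0
      w2 <- if (I > 0) L * S * (1 - P) else 0
      w3 <- if (I > 0) L * (1 - S) else 0
      w4 <- if (J > 0) D else 0
      w5 <- E
      W <- w1 + w2 + w3 + w4 + w5
      if (W <= 0) {
        status <- "frozen"
        break
      }
      if (exact) {
        t_now <- t_now + rexp(1, rate = W)
        u <- runif(1) * W
      } else {
        u <- runif(1) * max(W, 1)
      }
      if (u < w1) {
        I <- I - 1; J <- J + 2; ev <- 1L
      } else if (u < w1 + w2) {
        I <- I + 1; ev <- 2L
      } else if (u < w1 + w2 + w3) {
        J <- J + 1; ev <- 3L
      } else if (u < w1 + w2 + w3 + w4) {
        J <- J - 1; ev <- 4L
      } else if (u < W) {
        I <- I + 1; ev <- 5L
      }
    }
    if (keep_path) {
      pI[step] <- I; pJ[step] <- J; pev[step] <- ev
      if (exact) ptime[step] <- t_now
    }
    if (step > burn_in) {
      n <- n + 1
      sI <- sI + I; sJ <- sJ + J
      sII <- sII + I * I; sJJ <- sJJ + J * J; sIJ <- sIJ + I * J
    }
    done <- step
    if (stop_on_extinction && (I == 0 || J == 0)) {
      status <- "extinct"
      break
    }
  }
  out <- list(steps_done = done, status = status,
              final_I = I, final_J = J,
              n = n, sI = sI, sJ = sJ, sII = sII, sJJ = sJJ, sIJ = sIJ)
  if (keep_path) {
    out$I <- as.integer(pI[seq_len(done)])
    out$J <- as.integer(pJ[seq_len(done)])
    out$event <- pev[seq_len(done)]
    if (exact) out$time <- ptime[seq_len(done)]
  }
  out
}

moments_from_sums <- function(raw, config) {
  n <- raw$n
  if (n < 1) stop("no post-burn-in samples", call. = FALSE)
  mean_I <- raw$sI / n
  mean_J <- raw$sJ / n
  var_I <- if (n > 1) (raw$sII - n * mean_I^2) / (n - 1) else 0
  var_J <- if (n > 1) (raw$sJJ - n * mean_J^2) / (n - 1) else 0
  # guard against catastrophic cancellation producing tiny negatives
  var_I <- max(var_I, 0)
  var_J <- max(var_J, 0)
  structure(
    list(mean_I = mean_I, mean_J = mean_J, var_I = var_I, var_J = var_J,
         rel_sd_J = if (mean_J > 0) var_J / mean_J else NA_real_,
         cv_J = if (mean_J > 0) sqrt(var_J) / mean_J else NA_real_,
         n = n, status = raw$status, config = config),
    class = "moment_estimate"
  )
}

#' Empirical moments of a simulated trajectory
#'
#' Per-step (unweighted) means and variances of the cell counts over the
#' samples after `burn_in`, together with two relative-fluctuation measures
#' for the differentiated compartment: the variance-to-mean ratio
#' `rel_sd_J = var_J / mean_J` and the coefficient of variation
#' `cv_J = sqrt(var_J) / mean_J` (the relative standard deviation proper).
#' Variances use the `n - 1` denominator.
#'
#' @param traj a `trajectory` from [simulate()].
#' @param burn_in number of leading samples to discard.
#' @return Object of class `moment_estimate`: list with `mean_I`, `mean_J`,
#'   `var_I`, `var_J`, `rel_sd_J`, `cv_J`, `n` and `status`.
#' @export
estimate_moments <- function(traj, burn_in = 0L) {
  stopifnot(inherits(traj, "trajectory"))
  if (burn_in < 0 || burn_in >= nrow(traj)) {
    stop("`burn_in` must leave at least one sample", call. = FALSE)
  }
  keep <- traj$step > burn_in
  I <- traj$I[keep]; J <- traj$J[keep]
  n <- length(I)
  var_I <- if (n > 1) stats::var(I) else 0
  var_J <- if (n > 1) stats::var(J) else 0
  structure(
    list(mean_I = mean(I), mean_J = mean(J), var_I = var_I, var_J = var_J,
         rel_sd_J = if (mean(J) > 0) var_J / mean(J) else NA_real_,
         cv_J = if (mean(J) > 0) sqrt(var_J) / mean(J) else NA_real_,
         n = n, status = attr(traj, "status"),
         config = attr(traj, "config")),
    class = "moment_estimate"
  )
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat("<moment_estimate>", x$n, "samples,", x$status, "\n")
  cat(sprintf("  mean I = %.4f, mean J = %.4f\n", x$mean_I, x$mean_J))
  cat(sprintf("  var I = %.4f, var J = %.4f, Var(J)/E(J) = %.4f, CV(J) = %.4f\n",
              x$var_I, x$var_J, x$rel_sd_J, x$cv_J))
  invisible(x)
}

#' Replicate sweep of the symmetric-division fraction
#'
#' Re-runs the simulator over a grid of constant symmetric fractions `S`,
#' `replicates` runs per grid point, and tabulates the empirical moments.
#' Replicate seeds are derived deterministically from `seed` as
#' `seed + (cell_index - 1) * replicates + (replicate - 1)` so cells are
#' independent yet reproducible.
#'
#' @param network a [control_network] template; its symmetry is replaced by
#'   each grid value (presets are rebuilt with their constructor).
#' @param S_values symmetric fractions in `(0, 1]`.
#' @param replicates runs per `S` value.
#' @param steps,init,injury,burn_in,stop_on_extinction passed to
#'   [simulate()].
#' @param seed base seed for the derived per-replicate seeds.
#' @return Data frame with one row per `(S, replicate)` cell: `S`,
#'   `replicate`, `seed`, `mean_I`, `mean_J`, `var_I`, `var_J`, `rel_sd_J`,
#'   `n`, `status`. Failed cells are kept as rows of `NA` moments.
#' @seealso [aggregate_sweep()] for per-`S` averages.
#' @export
sweep_symmetry <- function(network, S_values, replicates, steps, seed,
                           init = "equilibrium", injury = NULL,
                           burn_in = 0L, stop_on_extinction = TRUE) {
  stopifnot(inherits(network, "control_network"))
  if (any(S_values <= 0 | S_values > 1)) {
    stop("all `S_values` must lie in (0, 1]", call. = FALSE)
  }
  rows <- vector("list", length(S_values) * replicates)
  idx <- 0L
  for (ci in seq_along(S_values)) {
    net_s <- set_symmetry(network, S_values[ci])
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      seed_r <- as.integer(seed) + (ci - 1L) * replicates + (r - 1L)
      mom <- tryCatch(
        simulate(net_s, steps = steps, seed = seed_r, init = init,
                 injury = injury, burn_in = burn_in,
                 stop_on_extinction = stop_on_extinction,
                 keep = "moments"),
        error = function(e) NULL)
      rows[[idx]] <- data.frame(
        S = S_values[ci], replicate = r, seed = seed_r,
        mean_I = mom$mean_I %||% NA_real_,
        mean_J = mom$mean_J %||% NA_real_,
        var_I = mom$var_I %||% NA_real_,
        var_J = mom$var_J %||% NA_real_,
        rel_sd_J = mom$rel_sd_J %||% NA_real_,
        cv_J = mom$cv_J %||% NA_real_,
        n = mom$n %||% NA_real_,
        status = mom$status %||% "error",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a symmetry sweep over replicates
#'
#' @param sweep output of [sweep_symmetry()].
#' @return Data frame with one row per `S`: replicate means of the moment
#'   columns plus the count of contributing replicates.
#' @export
aggregate_sweep <- function(sweep) {
  split_s <- split(sweep, sweep$S)
  rows <- lapply(split_s, function(d) {
    data.frame(S = d$S[1],
               mean_I = mean(d$mean_I, na.rm = TRUE),
               mean_J = mean(d$mean_J, na.rm = TRUE),
               var_I = mean(d$var_I, na.rm = TRUE),
               var_J = mean(d$var_J, na.rm = TRUE),
               rel_sd_J = mean(d$rel_sd_J, na.rm = TRUE),
               cv_J = mean(d$cv_J, na.rm = TRUE),
               replicates = sum(!is.na(d$mean_I)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$S), , drop = FALSE]
}

# rebuild a network with a different constant symmetric fraction
set_symmetry <- function(network, S) {
  if (network$name == "model3") {
    return(make_model3(network$epsilon, S))
  }
  if (network$name == "model5") {
    return(make_model5(network$epsilon, S))
  }
  if (network$name == "follicle") {
    return(make_follicle_model(network$epsilon, S,
                               h = network$params$h,
                               influx = isTRUE(network$params$influx)))
  }
  out <- network
  out$S <- function(x, y) S
  out$params$symmetry <- S
  out
}
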