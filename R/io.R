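#' Write / read a trajectory as CSV
#'
#' Comma-separated, header row, no row names, LF line endings. Columns:
#' `step`, `I`, `J`, `event` (plus `time` for the exact scheme).
#'
#' @param traj a `trajectory` from [simulate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "data.frame"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("trajectory", "data.frame"))
}

#' Write an analytic or moment report as JSON
#'
#' Scalars are unboxed and numeric values keep 12 significant digits.
#'
#' @param x a list (e.g. from [analyze_network()] after
#'   [report_from_analysis()], or a `moment_estimate`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(strip_functions(x), path, auto_unbox = TRUE,
                       digits = I(12), pretty = TRUE, null = "null")
  invisible(path)
}

strip_functions <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, strip_functions)
    x[!vapply(x, is.null, logical(1))]
  } else if (inherits(x, "controls")) {
    as.list(unclass(x))
  } else {
    x
  }
}

#' Flatten an [analyze_network()] result into a serializable report
#'
#' @param an output of [analyze_network()].
#' @return Named list with equilibrium, controls, variance, stability,
#'   sensitivity and classification fields.
#' @export
report_from_analysis <- function(an) {
  eq <- an$equilibrium
  lna <- an$lna
  list(kind = eq$kind, i0 = eq$i0, j0 = eq$j0,
       L_star = eq$L_star, P_star = eq$P_star, S_star = lna$S_star,
       residuals = eq$residuals,
       controls = as.list(unclass(an$controls)),
       Delta = lna$Delta, B = lna$B, Kx = lna$K_x, Ky = lna$K_y,
       varI = lna$var_I, varJ = lna$var_J,
       Sc = lna$S_c, stable = lna$stable,
       dvarI_dS = an$sensitivity$dvarI_dS,
       dvarJ_dS = an$sensitivity$dvarJ_dS,
       class_label = an$classification$label,
       trends = list(var_I = an$classification$trend_I,
                     var_J = an$classification$trend_J,
                     optimal = an$classification$optimal))
}

#' Serialize a network definition to / from a structured-text config
#'
#' Presets are stored as `preset` plus parameters; custom networks as inline
#' R expression strings in the scaled coordinates `x`, `y` (the influx `e`
#' in `x` alone), e.g. `L: "(1 - exp(-x)) / (1 - exp(-x) + y)"`.
#'
#' @param network a [control_network] (presets and expression-built customs
#'   round-trip; programmatic closures do not serialize).
#' @param path YAML file path.
#' @return `network_to_config()` returns `path` invisibly;
#'   `network_from_config()` returns a [control_network].
#' @export
network_to_config <- function(network, path) {
  stopifnot(inherits(network, "control_network"))
  cfg <- if (network$name %in% c("model3", "model5", "follicle")) {
    c(list(preset = network$name), network$params)
  } else if (!is.null(network$params$expressions)) {
    list(preset = "custom", epsilon = network$epsilon,
         expressions = network$params$expressions)
  } else {
    stop("only presets and expression-defined networks serialize",
         call. = FALSE)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname network_to_config
#' @export
network_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$preset)) stop("config lacks a `preset` field",
                                call. = FALSE)
  switch(cfg$preset,
    model3 = make_model3(cfg$epsilon, cfg$symmetry),
    model5 = make_model5(cfg$epsilon, cfg$symmetry),
    follicle = make_follicle_model(cfg$epsilon, cfg$symmetry,
                                   h = cfg$h %||% 0.3,
                                   influx = isTRUE(cfg$influx %||% TRUE)),
    custom = network_from_expressions(cfg$expressions, cfg$epsilon),
    stop("unknown preset: ", cfg$preset, call. = FALSE)
  )
}

#' Build a network from rate-expression strings
#'
#' @param expressions named list/character with entries `L`, `P`, `D`, `S`
#'   (expressions in `x` and `y`) and optionally `E` (in `x`).
#' @param epsilon control-strength scale.
#' @return A [control_network].
#' @export
network_from_expressions <- function(expressions, epsilon) {
  need <- c("L", "P", "D", "S")
  if (!all(need %in% names(expressions))) {
    stop("expressions must define L, P, D and S", call. = FALSE)
  }
  mk2 <- function(txt) {
    body <- parse(text = txt)[[1]]
    f <- function(x, y) NULL
    body(f) <- body
    environment(f) <- baseenv()
    f
  }
  mk1 <- function(txt) {
    body <- parse(text = txt)[[1]]
    f <- function(x) NULL
    body(f) <- body
    environment(f) <- baseenv()
    f
  }
  control_network(
    L = mk2(expressions$L), P = mk2(expressions$P),
    D = mk2(expressions$D), S = mk2(expressions$S),
    E = if (!is.null(expressions$E)) mk1(expressions$E) else NULL,
    epsilon = epsilon, name = "custom",
    params = list(expressions = as.list(expressions), epsilon = epsilon)
  )
}

#' Run manifest: a reproducibility record for CLI artifacts
#'
#' @param subcommand CLI subcommand name.
#' @param config resolved configuration list.
#' @param seed RNG seed used.
#' @param outputs character vector of artifact paths.
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(subcommand, config, seed, outputs) {
  structure(list(subcommand = subcommand, config = config,
                 seed = seed,
                 tool_version = as.character(
                   utils::packageVersion("sclineage")),
                 outputs = as.character(outputs)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = I(12), pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Generate a small seeded regression fixture
#'
#' Produces a 5,000-step trajectory and its moment summary for one of four
#' canonical setups; regeneration with the same seed is bit-exact, which
#' makes the pair usable as a regression fixture.
#'
#' @param name one of `"model3-short"`, `"model5-short"`, `"injury-short"`,
#'   `"follicle-short"`.
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed); `NULL` returns the
#'   objects without writing.
#' @return List with `trajectory`, `moments`, `injury_draws` (number of
#'   injury events, for the injury fixture) and, when `dir` is given,
#'   `paths`.
#' @export
make_fixture <- function(name, seed = 20231L, dir = NULL) {
  steps <- 5000L
  setup <- switch(name,
    "model3-short" = list(net = make_model3(0.005, 0.5), injury = NULL),
    "model5-short" = list(net = make_model5(0.005, 0.8), injury = NULL),
    "injury-short" = list(net = make_model5(0.005, 0.8),
                          injury = injury_config(update_fraction = 0.01,
                                                 removal_fraction = 0.1)),
    "follicle-short" = list(net = make_follicle_model(0.05, 0.5, h = 0.3),
                            injury = NULL),
    stop("unknown fixture name: ", name, call. = FALSE)
  )
  traj <- simulate(setup$net, steps = steps, seed = seed,
                   injury = setup$injury)
  mom <- estimate_moments(traj)
  out <- list(trajectory = traj, moments = mom,
              injury_draws = sum(traj$event == "injury"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      trajectory = file.path(dir, paste0(name, "-trajectory.csv")),
      moments = file.path(dir, paste0(name, "-moments.json"))
    )
    write_trajectory_csv(traj, paths[["trajectory"]])
    write_report_json(mom[c("mean_I", "mean_J", "var_I", "var_J",
                            "rel_sd_J", "n", "status")],
                      paths[["moments"]])
    out$paths <- paths
  }
  out
}
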