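# R interface to the event-driven cell-level simulator.  The channel is a
# vector of species labels over positions 1..N; every division event picks
# a cell proportionally to fitness, a direction by the linear bias, inserts
# the daughter next to its mother, shifts everything beyond it and expels
# the terminal cell on that side.  The total event rate is r * (N - 1)
# regardless of composition (fitness weights cancel between selection and
# normalisation), so null edge divisions consume time but change nothing.

#' Channel configuration for the cell-level simulator
#'
#' Builds the initial label vector.  Single-boundary mode (`n0`): species 1
#' occupies the prefix `1..n0` (segregated start).  Invasion mode (`x0`): a
#' single species-1 invader at position `x0` in an otherwise species-2
#' channel.  Alternatively pass an arbitrary `labels` vector of 1s and 2s.
#'
#' @param params A [competition_params()] object (`N >= 3`).
#' @param n0 Initial abundance of species 1 (single-boundary mode).
#' @param x0 Insertion position of a single invader (invasion mode).
#' @param labels Explicit integer label vector (values 1 and 2) of length `N`.
#' @return An object of class `channel_config`: list with `cells`, `params`,
#'   `mode`.
#' @export
channel_config <- function(params, n0 = NULL, x0 = NULL, labels = NULL) {
  params <- as_competition_params(params)
  N <- params$N
  if (N < 3) stop("the cell-level simulator requires N >= 3")
  given <- c(!is.null(n0), !is.null(x0), !is.null(labels))
  if (sum(given) != 1)
    stop("supply exactly one of 'n0', 'x0' or 'labels'")
  if (!is.null(n0)) {
    if (n0 < 0 || n0 > N) stop("'n0' must be in 0..N")
    cells <- c(rep(1L, n0), rep(2L, N - n0))
    mode <- "single_boundary"
  } else if (!is.null(x0)) {
    if (x0 < 1 || x0 > N) stop("'x0' must be in 1..N")
    cells <- rep(2L, N)
    cells[x0] <- 1L
    mode <- "invasion"
  } else {
    if (length(labels) != N || !all(labels %in% c(1L, 2L)))
      stop("'labels' must be a length-N vector of 1s and 2s")
    cells <- as.integer(labels)
    mode <- "custom"
  }
  structure(list(cells = cells, params = params, mode = mode),
            class = "channel_config")
}

#' @export
print.channel_config <- function(x, ...) {
  cat(sprintf("Channel configuration (N = %d, w = %g, mode = %s)\n",
              x$params$N, x$params$w, x$mode))
  cat("  ", paste(x$cells, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Advance the channel by one division event
#'
#' Pure-R reference implementation of a single event, exposing the event
#' record (which cell divided, in which direction, and the abundance
#' change).  Uses R's RNG; ensemble runs use the compiled equivalent.
#'
#' @param config A [channel_config()].
#' @return A list with `config` (updated), `dt` (exponential waiting time),
#'   and `event` (list `i`, `direction` (`"left"`/`"right"`), `delta_n1`).
#' @export
sim_step <- function(config) {
  stopifnot(inherits(config, "channel_config"))
  cells <- config$cells
  N <- length(cells)
  w <- config$params$w
  weights <- ifelse(cells == 1L, w, 1)
  i <- sample.int(N, 1L, prob = weights)
  right <- stats::runif(1) < (i - 1) / (N - 1)
  dt <- stats::rexp(1, rate = config$params$r * (N - 1))
  n1_before <- sum(cells == 1L)
  if (right) {
    if (i < N) cells <- c(cells[1:i], cells[i], cells[(i + 1):N])[1:N]
  } else {
    if (i > 1) cells <- c(cells[1:(i - 1)], cells[i], cells[i:N])[2:(N + 1)]
  }
  config$cells <- cells
  list(config = config, dt = dt,
       event = list(i = i, direction = if (right) "right" else "left",
                    delta_n1 = sum(cells == 1L) - n1_before))
}

#' Run the cell-level channel simulation to fixation
#'
#' Repeats division events until one label occupies every position.
#'
#' @param config A [channel_config()].
#' @param max_events Safety cap on the number of events (default `1e9`).
#' @return A list with `winner` (`"species1"` or `"species2"`) and `time`.
#' @export
run_to_fixation <- function(config, max_events = 1e9) {
  stopifnot(inherits(config, "channel_config"))
  res <- cpp_channel_run(config$cells, config$params$w, config$params$r,
                         max_events)
  list(winner = c("species1", "species2")[res$winner], time = res$time,
       events = res$events)
}

#' Run one Moran realisation
#'
#' Gillespie simulation of the Moran chain ([moran_rates()]) from initial
#' abundance `n0`.
#'
#' @param params A [competition_params()] object.
#' @param n0 Initial abundance of species 1.
#' @return A list with `winner` and `time`.
#' @export
run_moran <- function(params, n0) {
  params <- as_competition_params(params)
  if (n0 < 0 || n0 > params$N) stop("'n0' must be in 0..N")
  res <- cpp_moran_run(params$N, params$w, params$r, as.integer(n0))
  list(winner = c("species1", "species2")[res$winner], time = res$time)
}

#' Simulate an ensemble of replicates
#'
#' Runs `reps` independent realisations of either the cell-level spatial
#' simulator or the Moran process from a common initial condition.  A
#' single RNG stream seeded once with `seed` is consumed sequentially
#' across replicates, so identical `seed` and parameters reproduce the
#' ensemble exactly.
#'
#' @param params A [competition_params()] object.
#' @param reps Number of replicates (positive integer).
#' @param n0,x0 Initial condition, as in [channel_config()] (`n0` only for
#'   `model = "moran"`).
#' @param model `"spatial"` or `"moran"`.
#' @param seed Integer master seed.
#' @param max_events Per-replicate event cap (spatial model).
#' @return An object of class `simulation_ensemble`: a data frame with
#'   columns `replicate`, `winner`, `time`, with the call parameters in
#'   attributes.
#' @export
simulate_ensemble <- function(params, reps, n0 = NULL, x0 = NULL,
                              model = c("spatial", "moran"), seed = 1L,
                              max_events = 1e9) {
  params <- as_competition_params(params)
  model <- match.arg(model)
  if (reps < 1) stop("'reps' must be a positive integer")
  set.seed(seed)
  if (model == "moran") {
    if (is.null(n0)) stop("Moran ensembles need 'n0'")
    df <- cpp_moran_ensemble(params$N, params$w, params$r, as.integer(n0),
                             as.integer(reps))
  } else {
    cfg <- channel_config(params, n0 = n0, x0 = x0)
    df <- cpp_channel_ensemble(cfg$cells, params$w, params$r,
                               as.integer(reps), max_events)
  }
  out <- data.frame(replicate = seq_len(reps),
                    winner = c("species1", "species2")[df$winner],
                    time = df$time)
  class(out) <- c("simulation_ensemble", "data.frame")
  attr(out, "params") <- params
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Summarise a simulated ensemble
#'
#' Estimates the fixation probability of the focal species (binomial
#' proportion with a Wilson 95% interval, non-degenerate even when every
#' replicate agrees) and the mean absorption time (with a normal-theory
#' standard-error interval, `NA` for a single replicate), plus per-winner
#' conditional mean times.
#'
#' @param ensemble A [simulate_ensemble()] result (or compatible data frame
#'   with `winner` and `time` columns).
#' @param focal Which species counts as success (default `"species1"`).
#' @param level Confidence level (default 0.95).
#' @return A list with `n`, `p_hat`, `p_ci`, `time_mean`, `time_ci`,
#'   `time_mean_by_winner`.
#' @export
estimate_first_passage <- function(ensemble, focal = "species1",
                                   level = 0.95) {
  if (NROW(ensemble) == 0) stop("empty ensemble")
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- NROW(ensemble)
  wins <- sum(ensemble$winner == focal)
  p <- wins / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tmean <- mean(ensemble$time)
  tci <- if (n > 1) {
    se <- stats::sd(ensemble$time) / sqrt(n)
    c(tmean - z * se, tmean + z * se)
  } else c(NA_real_, NA_real_)
  list(n = n, p_hat = p, p_ci = c(centre - half, centre + half),
       time_mean = tmean, time_ci = tci,
       time_mean_by_winner = tapply(ensemble$time, ensemble$winner, mean))
}
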