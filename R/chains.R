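#' Birth-death chain with absorbing ends
#'
#' A tabulated continuous-time birth-death chain over abundance states
#' `n = 0..N` with absorbing boundaries at `0` and `N`.  This is the common
#' substrate for both the spatial exclusion model and the Moran model; all
#' first-passage solvers operate on it.
#'
#' @param up_rate,down_rate Numeric vectors of length `N + 1` giving the
#'   rates of `n -> n + 1` and `n -> n - 1` (units 1/time).  Entries at
#'   `n = 0` and `n = N` must be zero (absorbing ends).
#'
#' @return An object of class `bd_chain`: a list with elements `N`,
#'   `up_rate` and `down_rate`.
#'
#' @seealso [spatial_rates()], [moran_rates()], [first_passage()]
#' @export
bd_chain <- function(up_rate, down_rate) {
  if (length(up_rate) != length(down_rate))
    stop("'up_rate' and 'down_rate' must have the same length")
  if (length(up_rate) < 3)
    stop("a chain needs at least one interior state (length >= 3)")
  if (any(!is.finite(up_rate)) || any(!is.finite(down_rate)))
    stop("all rates must be finite")
  if (any(up_rate < 0) || any(down_rate < 0))
    stop("all rates must be non-negative")
  N <- length(up_rate) - 1L
  ends <- c(1L, N + 1L)
  if (any(up_rate[ends] != 0) || any(down_rate[ends] != 0))
    stop("states 0 and N are absorbing: their rates must be zero")
  structure(list(N = N, up_rate = as.numeric(up_rate),
                 down_rate = as.numeric(down_rate)),
            class = "bd_chain")
}

#' @export
print.bd_chain <- function(x, ...) {
  cat(sprintf("Birth-death chain on n = 0..%d (absorbing ends)\n", x$N))
  k <- min(x$N - 1, 5)
  cat(sprintf("  up rates   n=1..%d : %s%s\n", k,
              paste(signif(x$up_rate[2:(k + 1)], 4), collapse = " "),
              if (x$N - 1 > k) " ..." else ""))
  cat(sprintf("  down rates n=1..%d : %s%s\n", k,
              paste(signif(x$down_rate[2:(k + 1)], 4), collapse = " "),
              if (x$N - 1 > k) " ..." else ""))
  invisible(x)
}

#' Boundary-motion rates of the spatial exclusion model
#'
#' Tabulates the rates at which the inter-species boundary of a full,
#' segregated channel moves right (`n -> n + 1`) or left (`n -> n - 1`).
#' A cell at position `i` is picked for division proportionally to its
#' fitness (`w` for species 1 occupying positions `1..n`, `1` for species 2)
#' and divides toward the right opening with probability `(i - 1)/(N - 1)`,
#' pushing every cell on that side one position over and expelling the
#' terminal cell.  Summing the per-cell rates gives
#' \deqn{r^+(n) = \frac{r\,w\,n(n-1)}{2[(N-n)+wn]},\qquad
#'       r^-(n) = \frac{r\,(N-n)(N-n-1)}{2[(N-n)+wn]}.}
#'
#' The factors `n(n-1)` and `(N-n)(N-n-1)` make `n = 1` a one-way street
#' down and `n = N - 1` a one-way street up: a single cell at the channel
#' edge can never divide inward.
#'
#' @param params A [competition_params()] object with `N >= 3`.
#' @return A [bd_chain()].
#'
#' @examples
#' spatial_rates(competition_params(N = 10, w = 1.5))
#' @export
spatial_rates <- function(params) {
  params <- as_competition_params(params)
  N <- params$N; w <- params$w; r <- params$r
  if (N < 3)
    stop("spatial exclusion model requires N >= 3: at N = 2 the interior ",
         "state has no outgoing rate (frozen) and the (N - 1) direction ",
         "bias normalisation degenerates")
  n <- 0:N
  D <- (N - n) + w * n
  up <- r * w * n * (n - 1) / (2 * D)
  down <- r * (N - n) * (N - n - 1) / (2 * D)
  up[c(1L, N + 1L)] <- 0
  down[c(1L, N + 1L)] <- 0
  bd_chain(up, down)
}

#' Transition rates of the Moran model
#'
#' The classical well-mixed baseline: at each event one individual is picked
#' to give birth (proportionally to fitness) while another is picked
#' uniformly to die.  The per-event probabilities are
#' `T+(n) = [wn/((N-n)+wn)] (N-n)/N` and `T-(n) = [(N-n)/((N-n)+wn)] n/N`,
#' converted to continuous-time rates as `N * T(n)` per unit of `1/r` so
#' that one unit of time corresponds to one generation (`N` events),
#' matching the time convention of [spatial_rates()].  The ratio
#' `T+/T- = w` at every interior state.
#'
#' @param params A [competition_params()] object with `N >= 2`.
#' @return A [bd_chain()].
#' @export
moran_rates <- function(params) {
  params <- as_competition_params(params)
  N <- params$N; w <- params$w; r <- params$r
  n <- 0:N
  D <- (N - n) + w * n
  up <- r * w * n * (N - n) / D
  down <- r * n * (N - n) / D
  up[c(1L, N + 1L)] <- 0
  down[c(1L, N + 1L)] <- 0
  bd_chain(up, down)
}

#' Division direction bias along the channel
#'
#' Probability that a cell at position `i` (1-based) divides toward the
#' right opening, `p_right(i) = (i - 1)/(N - 1)`, and toward the left,
#' `p_left(i) = (N - i)/(N - 1)`: a cell pushes preferentially toward the
#' closer opening, linearly in the number of cells it must displace.
#'
#' @param N Channel length (`>= 2`).
#' @return A data frame with columns `i`, `p_right`, `p_left`.
#' @export
direction_bias <- function(N) {
  if (N < 2) stop("'N' must be >= 2")
  i <- seq_len(N)
  data.frame(i = i, p_right = (i - 1) / (N - 1), p_left = (N - i) / (N - 1))
}
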