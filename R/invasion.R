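# Two-boundary invasion model.
#
# A single invader inserted at position x of a fixated channel creates a
# contiguous invader segment [a, b] (initially a = b = x) with two
# inter-species boundaries.  Division rules are identical to the
# single-boundary model: a cell is picked proportionally to fitness
# (invader w, native 1, normaliser D = (N - m) + w m for segment size m)
# and divides right with probability (i - 1)/(N - 1).  Summing per-cell
# rates over each of the four cell blocks gives the segment transitions:
#
#   left natives (i < a) divide right : r (a-1)(a-2)/(2D) -> segment shifts
#       right, (a+1, min(b+1, N)); if b = N the rightmost invader is
#       expelled instead and the segment shrinks
#   right natives (i > b) divide left : r (N-b)(N-b-1)/(2D) -> mirrored
#   invader divides right             : r w m (a+b-2)/(2D)  -> (a, b+1)
#       when b < N (null when b = N: the daughter expels an invader)
#   invader divides left              : r w m (2N-a-b)/(2D) -> (a-1, b)
#       when a > 1
#
# Native divisions that only push natives out are null events and are
# omitted from the continuous-time generator (self-loops do not alter
# first-passage laws).  Absorbing outcomes: EXTINCT (m = 0) and FIXED
# (a = 1, b = N).  Transient states are all (a, b) with 1 <= a <= b <= N
# except (1, N), i.e. N(N+1)/2 - 1 of them, enumerated row-major in a.

#' Build the two-boundary invasion chain
#'
#' Constructs the sparse continuous-time generator of the invader-segment
#' process on its two-dimensional state space.
#'
#' @param params A [competition_params()] object with `N >= 3`; `w` is the
#'   relative fitness of the invader.
#' @return An object of class `invasion_chain`: a list with `N`, `w`, `r`,
#'   `states` (data frame `a`, `b`), `Q` (sparse generator restricted to
#'   transient states), `rate_to_fixed`, `rate_to_extinct` and `index`
#'   (an `N x N` lookup matrix mapping `(a, b)` to row number).
#'
#' @examples
#' ch <- invasion_chain(competition_params(10, w = 2))
#' nrow(ch$states)  # 10 * 11 / 2 - 1 transient states
#' @export
invasion_chain <- function(params) {
  params <- as_competition_params(params)
  N <- params$N; w <- params$w; r <- params$r
  if (N < 3) stop("invasion model requires N >= 3")

  a <- rep(seq_len(N), times = N:1)
  b <- unlist(lapply(seq_len(N), function(k) k:N))
  keep <- !(a == 1L & b == N)  # (1, N) is the FIXED absorbing state
  a <- a[keep]; b <- b[keep]
  nT <- length(a)
  index <- matrix(0L, N, N)
  index[cbind(a, b)] <- seq_len(nT)

  m <- b - a + 1L
  D <- (N - m) + w * m
  # from-state, destination (a2, b2), rate; one block per transition type
  from <- c(seq_len(nT), seq_len(nT), seq_len(nT), seq_len(nT))
  a2 <- c(a + 1L, pmax(a - 1L, 1L), a, a - 1L)
  b2 <- c(pmin(b + 1L, N), b - 1L, b + 1L, b)
  rate <- c(r * (a - 1) * (a - 2) / (2 * D),
            r * (N - b) * (N - b - 1) / (2 * D),
            ifelse(b < N, r * w * m * (a + b - 2) / (2 * D), 0),
            ifelse(a > 1, r * w * m * (2 * N - a - b) / (2 * D), 0))
  pos <- rate > 0
  from <- from[pos]; a2 <- a2[pos]; b2 <- b2[pos]; rate <- rate[pos]

  to_extinct <- a2 > b2
  to_fixed <- !to_extinct & a2 == 1L & b2 == N
  internal <- !to_extinct & !to_fixed

  diag_out <- numeric(nT)
  tot <- tapply(rate, from, sum)
  diag_out[as.integer(names(tot))] <- tot
  rate_to_fixed <- numeric(nT)
  if (any(to_fixed)) {
    s <- tapply(rate[to_fixed], from[to_fixed], sum)
    rate_to_fixed[as.integer(names(s))] <- s
  }
  rate_to_extinct <- numeric(nT)
  if (any(to_extinct)) {
    s <- tapply(rate[to_extinct], from[to_extinct], sum)
    rate_to_extinct[as.integer(names(s))] <- s
  }
  Q <- Matrix::sparseMatrix(i = from[internal],
                            j = index[cbind(a2[internal], b2[internal])],
                            x = rate[internal], dims = c(nT, nT)) -
    Matrix::Diagonal(nT, diag_out)

  structure(list(N = N, w = w, r = r,
                 states = data.frame(a = a, b = b),
                 Q = Q, rate_to_fixed = rate_to_fixed,
                 rate_to_extinct = rate_to_extinct, index = index),
            class = "invasion_chain")
}

#' @export
print.invasion_chain <- function(x, ...) {
  cat(sprintf(
    "Two-boundary invasion chain: N = %d, w = %g, %d transient states\n",
    x$N, x$w, nrow(x$states)))
  invisible(x)
}

#' Solve the invasion chain exactly
#'
#' Computes, for every transient segment state, the probability that the
#' invader fixates (absorption at FIXED), the probability of extinction,
#' and the mean first-passage time conditioned on fixation, by sparse
#' linear solves of the backward system.
#'
#' @param chain An [invasion_chain()] (or a [competition_params()] object,
#'   in which case the chain is built first).
#' @return A list with numeric vectors over transient states:
#'   `p_fixed`, `p_extinct`, `mfpt_cond_fixed` (`NA` where `p_fixed = 0`),
#'   plus the `chain`.
#' @export
invasion_solve <- function(chain) {
  if (inherits(chain, "competition_params")) chain <- invasion_chain(chain)
  stopifnot(inherits(chain, "invasion_chain"))
  p_fixed <- as.numeric(Matrix::solve(chain$Q, -chain$rate_to_fixed))
  p_extinct <- as.numeric(Matrix::solve(chain$Q, -chain$rate_to_extinct))
  g <- as.numeric(Matrix::solve(chain$Q, -p_fixed))
  list(chain = chain,
       p_fixed = p_fixed,
       p_extinct = p_extinct,
       mfpt_cond_fixed = ifelse(p_fixed > 0, g / p_fixed, NA_real_))
}

.diagonal_states <- function(chain) chain$index[cbind(1:chain$N, 1:chain$N)]

#' Invasion success probability by insertion location
#'
#' Probability that a single invader inserted at position `x` (replacing
#' the native there; the channel stays full) eventually fixates, for every
#' `x = 1..N`.  Edge insertions (`x = 1` or `N`) can never succeed: the
#' direction bias forbids dividing inward from the wall and any native
#' push expels the invader.
#'
#' @param params A [competition_params()] object (invader fitness `w`), or
#'   a pre-computed [invasion_solve()] result.
#' @return A data frame with columns `x`, `p_success`, `mfpt_cond`
#'   (conditional fixation time, `NA` where success is impossible).
#' @export
invasion_probability_profile <- function(params) {
  sol <- if (inherits(params, "invasion_chain") ||
             inherits(params, "competition_params"))
    invasion_solve(params) else params
  d <- .diagonal_states(sol$chain)
  data.frame(x = seq_len(sol$chain$N),
             p_success = sol$p_fixed[d],
             mfpt_cond = sol$mfpt_cond_fixed[d])
}

#' Average invasion success probability
#'
#' Uniform average of the success probability over all insertion locations
#' `x = 1..N`.  In the neutral case this equals exactly `1/N`: each of the
#' `N` founder lineages is equally likely to be the eventual ancestor of
#' the whole channel.
#'
#' @inheritParams invasion_probability_profile
#' @return A single probability.
#' @export
average_invasion_probability <- function(params) {
  mean(invasion_probability_profile(params)$p_success)
}

#' Conditional invasion fixation time
#'
#' Mean time for a successful invasion, per insertion location and averaged
#' over locations weighted by the success probability,
#' `sum_x P(x) tau_c(x) / sum_x P(x)`.
#'
#' @inheritParams invasion_probability_profile
#' @return A list with `profile` (the data frame of
#'   [invasion_probability_profile()]) and `average` (success-weighted
#'   mean conditional time).
#' @export
conditional_invasion_mfpt <- function(params) {
  prof <- invasion_probability_profile(params)
  ok <- prof$p_success > 0
  if (!any(ok)) stop("no insertion location has positive success probability")
  list(profile = prof,
       average = sum(prof$p_success[ok] * prof$mfpt_cond[ok]) /
         sum(prof$p_success[ok]))
}

#' Write an invasion profile to CSV and a JSON summary
#'
#' CSV columns `x, p_success, mfpt_cond` (empty where undefined); the JSON
#' summary records `N`, `w`, `avg_probability` and `avg_cond_mfpt`.
#'
#' @param params A [competition_params()] object.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the summary list.
#' @export
write_invasion_results <- function(params, csv_path = NULL, json_path = NULL) {
  res <- conditional_invasion_mfpt(params)
  params <- as_competition_params(params)
  if (!is.null(csv_path)) .write_num_csv(res$profile, csv_path)
  summary <- list(N = params$N, w = params$w,
                  avg_probability = mean(res$profile$p_success),
                  avg_cond_mfpt = res$average)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
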