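# Exact first-passage solvers for 1D birth-death chains with absorbing ends.
#
# Probabilities use the gambler's-ruin product recursion with the ratio
# products accumulated in log space (stable up to N ~ 1e4); mean times use a
# sparse tridiagonal solve of the backward system.  Structural zeros (states
# that can only exit in one direction, e.g. n = 1 and n = N - 1 of the
# spatial model) are short-circuited exactly, never regularised.

# Largest interior state whose up-rate is structurally zero (0 if none) and
# smallest interior state whose down-rate is zero (N if none).  States at or
# below the former are certain to be absorbed at 0; states at or above the
# latter fix at N.
.structural_cut <- function(chain) {
  N <- chain$N
  up <- chain$up_rate; down <- chain$down_rate
  interior <- 2:N  # R indices of n = 1..N-1
  frozen <- interior[up[interior] == 0 & down[interior] == 0]
  if (length(frozen) > 0)
    stop("frozen state: interior state n = ", frozen[1] - 1,
         " has no outgoing rate")
  zu <- interior[up[interior] == 0]
  zd <- interior[down[interior] == 0]
  k_low <- if (length(zu)) max(zu) - 1L else 0L
  k_high <- if (length(zd)) min(zd) - 1L else N
  if (k_low >= k_high)
    stop("chain has no path connecting the two absorbing ends")
  list(k_low = k_low, k_high = k_high)
}

.logsumexp_cum <- function(lw) {
  m <- max(lw)
  cumsum(exp(lw - m)) # common factor cancels in the ratio taken by callers
}

#' Fixation probability on a birth-death chain
#'
#' Probability of absorption at the upper end `N` (species-1 fixation) from
#' every initial abundance `n = 0..N`, solving the backward equation by the
#' gambler's-ruin product form with log-space accumulation.
#'
#' For the spatial exclusion chain this returns exactly 0 at `n = 1` and
#' exactly 1 at `n = N - 1`: an edge singleton can never divide inward, so
#' those states are one-way streets.
#'
#' @param chain A [bd_chain()].
#' @param target `"high"` for absorption at `N`, `"low"` for absorption
#'   at `0` (computed independently via the mirrored chain, not as a
#'   complement).
#' @return Numeric vector of length `N + 1`.
#'
#' @examples
#' p <- fixation_probability(spatial_rates(competition_params(100, w = 1)))
#' p[51]  # = 1/2 at the equiprobable midpoint
#' @export
fixation_probability <- function(chain, target = c("high", "low")) {
  target <- match.arg(target)
  if (target == "low") {
    rev_chain <- bd_chain(rev(chain$down_rate), rev(chain$up_rate))
    return(rev(fixation_probability(rev_chain, "high")))
  }
  N <- chain$N
  cut <- .structural_cut(chain)
  a <- cut$k_low; b <- cut$k_high
  p <- numeric(N + 1)
  p[(b:N) + 1L] <- 1
  if (b - a >= 2) {
    j <- (a + 1):(b - 1)                       # states with both rates > 0
    lgam <- log(chain$down_rate[j + 1L]) - log(chain$up_rate[j + 1L])
    S <- .logsumexp_cum(c(0, cumsum(lgam)))    # S[k] = sum_{m<=k} prod gamma
    p[j + 1L] <- S[j - a] / S[b - a]
  }
  p
}

#' Unconditional mean first-passage time to fixation
#'
#' Expected time until absorption at either end from every initial
#' abundance, solving the tridiagonal backward linear system
#' `-1 = r+(n)[tau(n+1) - tau(n)] + r-(n)[tau(n-1) - tau(n)]` with
#' `tau(0) = tau(N) = 0` by a direct sparse solve.
#'
#' @param chain A [bd_chain()].
#' @return Numeric vector of length `N + 1` (units of `1/r`).
#' @export
mfpt_unconditional <- function(chain) {
  .backward_solve(chain, rep(-1, chain$N - 1))
}

# Solve the interior backward system L tau = rhs with absorbing boundary
# values zero; rhs has length N - 1 (states n = 1..N-1).
.backward_solve <- function(chain, rhs) {
  N <- chain$N
  .structural_cut(chain)  # frozen-state guard
  up <- chain$up_rate[2:N]
  down <- chain$down_rate[2:N]
  m <- N - 1L
  if (m == 1L) return(c(0, rhs / -(up + down), 0))
  L <- Matrix::bandSparse(m, k = -1:1,
                          diagonals = list(down[-1], -(up + down), up[-m]))
  c(0, as.numeric(Matrix::solve(L, rhs)), 0)
}

#' Conditional mean first-passage time
#'
#' Mean time to absorption at one specific end, conditioned on being
#' absorbed there.  Solves the backward system for
#' `g(n) = P_target(n) * tau_target(n)` with source `-P_target(n)`, then
#' divides by the absorption probability.  Where that probability is zero
#' the conditional time is undefined and reported as `NA` (never silently
#' 0 or `Inf`).
#'
#' @param chain A [bd_chain()].
#' @param target `"high"` (absorption at `N`) or `"low"` (at `0`).
#' @return A list with components `probability` and `time`, both numeric
#'   vectors of length `N + 1`; `time` is `NA` where `probability` is 0.
#' @export
mfpt_conditional <- function(chain, target = c("high", "low")) {
  target <- match.arg(target)
  p <- fixation_probability(chain, target)
  g <- .backward_solve(chain, -p[2:chain$N])
  tau <- ifelse(p > 0, g / p, NA_real_)
  tau[if (target == "high") chain$N + 1L else 1L] <- 0
  list(probability = p, time = tau)
}

#' Full first-passage solution of a birth-death chain
#'
#' Convenience wrapper computing, for every initial abundance, the fixation
#' probabilities of both species, the unconditional mean first-passage time
#' and both conditional times.
#'
#' @param chain A [bd_chain()].
#' @return An object of class `first_passage`, a data frame with columns
#'   `n`, `f = n/N`, `p_fix_high`, `p_fix_low`, `mfpt`, `mfpt_cond_high`,
#'   `mfpt_cond_low` (conditional columns `NA` where the conditioning event
#'   has probability zero).
#'
#' @examples
#' fp <- first_passage(spatial_rates(competition_params(50, w = 2)))
#' head(fp)
#' @export
first_passage <- function(chain) {
  N <- chain$N
  hi <- mfpt_conditional(chain, "high")
  lo <- mfpt_conditional(chain, "low")
  out <- data.frame(
    n = 0:N,
    f = (0:N) / N,
    p_fix_high = hi$probability,
    p_fix_low = lo$probability,
    mfpt = mfpt_unconditional(chain),
    mfpt_cond_high = hi$time,
    mfpt_cond_low = lo$time
  )
  class(out) <- c("first_passage", "data.frame")
  attr(out, "N") <- N
  out
}

#' @export
print.first_passage <- function(x, ...) {
  cat(sprintf("First-passage solution on n = 0..%d\n", attr(x, "N")))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  cat("  ...\n")
  print.data.frame(utils::tail(as.data.frame(x), 2), row.names = FALSE)
  invisible(x)
}

#' Write a first-passage solution to CSV
#'
#' Columns `n, f, p_fix_high, p_fix_low, mfpt, mfpt_cond_high,
#' mfpt_cond_low`; undefined conditional times are written as empty fields.
#'
#' @param x A [first_passage()] object (or compatible data frame).
#' @param path Output file path.
#' @export
write_first_passage_csv <- function(x, path) {
  .write_num_csv(as.data.frame(x), path)
}

#' Average a per-state quantity over initial abundances
#'
#' Uniform mean over the interior states `n = 1..N-1`; the absorbing states
#' are excluded because they are not competitions.
#'
#' @param values Numeric vector of length `N + 1` indexed by `n = 0..N`.
#' @return A single number.
#' @export
average_over_initials <- function(values) {
  if (length(values) < 3) stop("need at least one interior state")
  mean(values[2:(length(values) - 1L)])
}
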