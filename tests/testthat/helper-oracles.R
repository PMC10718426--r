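# Independent brute-force reference solvers used as oracles.  They build
# the full dense linear systems with base::solve and, for the invasion
# model, re-derive every transition by applying the microscopic
# shift-and-expel rule to an explicit label vector, cell by cell --
# deliberately avoiding the closed-form block sums used in production.

random_chain <- function(N, seed) {
  set.seed(seed)
  bd_chain(c(0, stats::runif(N - 1, 0.1, 2), 0),
           c(0, stats::runif(N - 1, 0.1, 2), 0))
}

# Dense interior operator of the backward equations.
.bf_operator <- function(chain) {
  N <- chain$N
  A <- matrix(0, N - 1, N - 1)
  for (n in 1:(N - 1)) {
    up <- chain$up_rate[n + 1]
    dn <- chain$down_rate[n + 1]
    A[n, n] <- -(up + dn)
    if (n > 1) A[n, n - 1] <- dn
    if (n < N - 1) A[n, n + 1] <- up
  }
  A
}

bf_absorption_high <- function(chain) {
  N <- chain$N
  rhs <- numeric(N - 1)
  rhs[N - 1] <- -chain$up_rate[N]  # boundary term h(N) = 1
  c(0, solve(.bf_operator(chain), rhs), 1)
}

bf_mfpt <- function(chain) {
  c(0, solve(.bf_operator(chain), rep(-1, chain$N - 1)), 0)
}

bf_conditional_high <- function(chain) {
  p <- bf_absorption_high(chain)
  g <- c(0, solve(.bf_operator(chain), -p[2:chain$N]), 0)
  list(probability = p, time = ifelse(p > 0, g / p, NA_real_))
}

# --- invasion oracle ------------------------------------------------------

# Apply one division event (cell i, 1-based; direction "right"/"left") to a
# label vector: daughter inserted next to the mother, everything beyond on
# that side shifts over, terminal cell expelled.
apply_division <- function(labels, i, direction) {
  N <- length(labels)
  if (direction == "right") {
    if (i == N) return(labels)
    c(labels[1:i], labels[i], labels[(i + 1):N])[1:N]
  } else {
    if (i == 1) return(labels)
    c(labels[1:(i - 1)], labels[i], labels[i:N])[2:(N + 1)]
  }
}

# Invader segment of a label vector (1 = invader): c(a, b), or NULL if the
# invader is extinct.
segment_of <- function(labels) {
  pos <- which(labels == 1L)
  if (length(pos) == 0) return(NULL)
  stopifnot(all(diff(pos) == 1))  # contiguity is an invariant of the model
  c(pos[1], pos[length(pos)])
}

# Dense solve of the two-boundary invasion model for all transient states.
# Per-cell rates: cell i (fitness ww = w for invader, 1 for native) divides
# right at rate r * ww * (i - 1) / D and left at r * ww * (N - i) / D,
# where D is the total fitness.  Null events are dropped.
bf_invasion <- function(N, w, r = 1) {
  states <- do.call(rbind, lapply(1:N, function(a) cbind(a, a:N)))
  states <- states[!(states[, 1] == 1 & states[, 2] == N), , drop = FALSE]
  nT <- nrow(states)
  id <- matrix(0L, N, N)
  id[states] <- seq_len(nT)
  Q <- matrix(0, nT, nT)
  r_fix <- numeric(nT)
  for (k in seq_len(nT)) {
    a <- states[k, 1]; b <- states[k, 2]
    labels <- rep(2L, N); labels[a:b] <- 1L
    D <- sum(ifelse(labels == 1L, w, 1))
    for (i in 1:N) {
      ww <- if (labels[i] == 1L) w else 1
      for (dir in c("right", "left")) {
        rate <- r * ww * (if (dir == "right") i - 1 else N - i) / D
        if (rate == 0) next
        seg <- segment_of(apply_division(labels, i, dir))
        if (is.null(seg)) {
          Q[k, k] <- Q[k, k] - rate            # -> EXTINCT
        } else if (seg[1] == a && seg[2] == b) {
          next                                  # null event
        } else if (seg[1] == 1 && seg[2] == N) {
          Q[k, k] <- Q[k, k] - rate
          r_fix[k] <- r_fix[k] + rate           # -> FIXED
        } else {
          Q[k, k] <- Q[k, k] - rate
          Q[k, id[seg[1], seg[2]]] <- Q[k, id[seg[1], seg[2]]] + rate
        }
      }
    }
  }
  p <- solve(Q, -r_fix)
  g <- solve(Q, -p)
  list(states = as.data.frame(states), id = id, p_fixed = p,
       mfpt_cond_fixed = ifelse(p > 0, g / p, NA_real_))
}

# Fitted exponent of y ~ N^e.
power_exponent <- function(N, y) {
  unname(stats::coef(stats::lm(log(y) ~ log(N)))[2])
}
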