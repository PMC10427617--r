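#' Specify a discrete-trait rate model
#'
#' Defines the state space, the rate-matrix constraint pattern, how observed
#' symbols map onto (possibly several) model states, and the root prior
#' policy for a continuous-time Markov model of a discrete character:
#'
#' * `ER` — equal rates: one free rate for every transition.
#' * `SYM` — symmetric: forward and reverse rates equal, `k(k-1)/2` free.
#' * `ARD` — all rates different: `k(k-1)` free.
#' * `PREC` — precursor model: exactly three states (ancestral `absent`,
#'   hidden `precursor`, derived `used`); the derived state is reachable
#'   only through the precursor, so direct `absent <-> used` transitions are
#'   prohibited (rates fixed at zero) and 4 rates are free
#'   (`absent <-> precursor` and `precursor <-> used`). The precursor is
#'   observationally identical to `absent`: the default observation map
#'   sends symbol `"0"` to `{absent, precursor}` and `"1"` to `{used}`.
#'
#' The symbol `"?"` (and `NA`) always maps to all states (a fully ambiguous
#' tip, contributing likelihood 1 to every state).
#'
#' @param pattern One of `"ER"`, `"SYM"`, `"ARD"`, `"PREC"`.
#' @param states Character vector of state labels. Required except for
#'   `PREC`, which defaults to `c("absent", "precursor", "used")`.
#' @param observation_map Named list: observed symbol -> character vector of
#'   compatible states. Defaults to the identity map (plus `"?"`), or the
#'   hidden-state map described above for `PREC`.
#' @param root_prior `"flat"` (default), `"stationary"`, or `"fitzjohn"`.
#' @return Object of class `rate_model_spec`.
#' @export
rate_model_spec <- function(pattern = c("ER", "SYM", "ARD", "PREC"),
                            states = NULL, observation_map = NULL,
                            root_prior = c("flat", "stationary", "fitzjohn")) {
  pattern <- match.arg(pattern)
  root_prior <- match.arg(root_prior)
  if (pattern == "PREC") {
    if (is.null(states)) states <- c("absent", "precursor", "used")
    if (length(states) != 3L) {
      stop("the precursor model has exactly 3 states (absent, precursor, used)")
    }
  } else if (is.null(states)) {
    stop("states must be given for pattern ", pattern)
  }
  if (anyDuplicated(states)) stop("duplicate state labels")
  k <- length(states)
  if (k < 2L) stop("need at least 2 states")
  if (is.null(observation_map)) {
    observation_map <- if (pattern == "PREC") {
      list("0" = states[c(1L, 2L)], "1" = states[3L])
    } else {
      setNames(as.list(states), states)
    }
  }
  observation_map[["?"]] <- states
  bad <- vapply(observation_map, function(s) any(!s %in% states), logical(1))
  if (any(bad)) {
    stop("observation map refers to unknown states for symbol(s): ",
         paste(names(observation_map)[bad], collapse = ", "))
  }
  n_free <- switch(pattern, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
                   ARD = k * (k - 1L), PREC = 4L)
  structure(list(pattern = pattern, states = states, k = k, n_free = n_free,
                 observation_map = observation_map, root_prior = root_prior),
            class = "rate_model_spec")
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat(x$pattern, "model on", x$k, "states (", paste(x$states, collapse = ", "),
      "),", x$n_free, "free rate(s), root prior", x$root_prior, "\n")
  invisible(x)
}

#' Build the rate matrix (CTMC generator) for a model
#'
#' Maps a free-parameter vector into the `k x k` generator `Q` under the
#' spec's constraint pattern. Off-diagonal entries are transition rates,
#' rows sum to zero. Parameter order: `ER` a single rate; `SYM` the upper
#' triangle row by row; `ARD` all off-diagonals row by row; `PREC` the
#' vector `(absent->precursor, precursor->absent, precursor->used,
#' used->precursor)` with both `absent <-> used` entries fixed at zero.
#'
#' @param spec A [rate_model_spec()].
#' @param params Numeric vector of non-negative rates, of length
#'   `spec$n_free`.
#' @return A `k x k` generator matrix with state dimnames and the parameter
#'   vector attached as attribute `params`.
#' @export
build_rate_matrix <- function(spec, params) {
  stopifnot(inherits(spec, "rate_model_spec"))
  if (length(params) != spec$n_free) {
    stop("expected ", spec$n_free, " rate parameter(s) for ", spec$pattern,
         ", got ", length(params))
  }
  if (any(params < 0) || anyNA(params)) stop("rates must be non-negative")
  k <- spec$k
  Q <- matrix(0, k, k, dimnames = list(spec$states, spec$states))
  switch(spec$pattern,
    ER = {
      Q[] <- params[1]
    },
    SYM = {
      idx <- 1L
      for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
        Q[i, j] <- Q[j, i] <- params[idx]
        idx <- idx + 1L
      }
    },
    ARD = {
      idx <- 1L
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i != j) {
          Q[i, j] <- params[idx]
          idx <- idx + 1L
        }
      }
    },
    PREC = {
      Q[1, 2] <- params[1]  # absent -> precursor
      Q[2, 1] <- params[2]  # precursor -> absent
      Q[2, 3] <- params[3]  # precursor -> used
      Q[3, 2] <- params[4]  # used -> precursor
      # Q[1,3] and Q[3,1] stay exactly 0: no direct absent <-> used
    }
  )
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  attr(Q, "params") <- params
  Q
}

# A propagator closure: tvec -> n x k^2 matrix whose rows are vec(P(t)).
# Uses the spectral decomposition of Q (one eigendecomposition per Q, then
# k rank-one updates for all branch lengths at once); falls back to
# scaling-and-squaring (Matrix::expm) per branch when the eigenvector
# matrix is ill-conditioned or defective.
make_propagator <- function(Q, cond_limit = 1e8) {
  k <- nrow(Q)
  eig <- tryCatch(eigen(Q), error = function(e) NULL)
  use_spectral <- FALSE
  if (!is.null(eig)) {
    V <- eig$vectors
    rc <- tryCatch(rcond(Mod(V)), error = function(e) 0)
    use_spectral <- is.finite(rc) && rc > 1 / cond_limit
  }
  clamp <- function(P) {
    P[P < 0] <- 0
    P[P > 1] <- 1
    P
  }
  if (use_spectral) {
    Vi <- solve(V)
    lam <- eig$values
    # C[s,] = vec(V[,s] %o% Vi[s,]) so vec(P(t)) = sum_s exp(lam_s t) C[s,]
    C <- t(vapply(seq_len(k),
                  function(s) as.vector(V[, s] %o% Vi[s, ]),
                  if (is.complex(V)) complex(k * k) else numeric(k * k)))
    function(tvec) {
      E <- exp(outer(tvec, lam))     # n x k (possibly complex)
      clamp(Re(E %*% C))             # n x k^2
    }
  } else {
    function(tvec) {
      P <- t(vapply(tvec, function(tt) {
        as.vector(as.matrix(Matrix::expm(Q * tt)))
      }, numeric(k * k)))
      clamp(P)
    }
  }
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q A generator matrix from [build_rate_matrix()] (or any valid
#'   CTMC generator).
#' @param t Non-negative elapsed time.
#' @return The `k x k` stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  k <- nrow(Q)
  P <- matrix(make_propagator(Q)(t), k, k, dimnames = dimnames(Q))
  P
}

#' Project true states onto observed symbols
#'
#' Inverts a spec's observation map: each model state is reported as the
#' most specific observed symbol compatible with it (ignoring the catch-all
#' `"?"`). Under the precursor model both `absent` and `precursor` project
#' to `"0"` — the hidden state is observationally identical to absence —
#' while `used` projects to `"1"`.
#'
#' @param states Character vector of true state labels.
#' @param spec A [rate_model_spec()].
#' @return Character vector of observed symbols, names preserved.
#' @export
observe_states <- function(states, spec) {
  om <- spec$observation_map
  om <- om[names(om) != "?"]
  sym_for <- vapply(spec$states, function(s) {
    hits <- names(om)[vapply(om, function(cs) s %in% cs, logical(1))]
    if (!length(hits)) {
      stop("state ", s, " is not observable under this map")
    }
    sizes <- lengths(om[hits])
    hits[which.min(sizes)]
  }, character(1))
  out <- sym_for[states]
  names(out) <- names(states)
  out
}

# Stationary distribution of a generator (left null vector, normalized).
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q)[-k, , drop = FALSE], rep(1, k))
  b <- c(rep(0, k - 1L), 1)
  pi <- tryCatch(solve(A, b), error = function(e) rep(1 / k, k))
  pi[pi < 0] <- 0
  pi / sum(pi)
}
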