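# Moth-flame optimizer with Levy-flight and opposition-based-learning
# mutation strategies (MFOS), plus the plain moth-flame baseline (MFO).
#
# Moths are the search agents (matrix Q, one row per moth); flames are
# the best positions found so far (matrix R, sorted by fitness). Each
# iteration every moth spirals around its assigned flame, the flame list
# is rebuilt from the merged population, and the flame count is annealed
# from N down to 1 so that late iterations exploit around the single best
# solution.

#' Optimizer configuration
#'
#' Builds the control list for [mfos()]. Defaults follow the standard
#' operating point of the method: population 50, 500 iterations,
#' arithmetic crossover of the two best individuals with probability 0.8,
#' and mutation probability 0.05 applied to the Levy-flight and
#' opposition-based-learning (OBL) strategies.
#'
#' @param pop_size Number of moths N (>= 2).
#' @param iterations Number of iterations T (>= 1).
#' @param crossover_prob Per-iteration probability of applying arithmetic
#'   crossover of the two best individuals; the child replaces the worst
#'   moth when it improves on it.
#' @param mutation_prob Per-moth probability of each mutation strategy.
#' @param levy_beta Stability index of the Levy step distribution,
#'   `1 < beta <= 2`.
#' @param levy_scale Step-size factor; steps are scaled by
#'   `levy_scale * (upper - lower)` per dimension.
#' @param spiral_b Shape constant of the logarithmic spiral.
#' @param use_levy,use_obl,use_crossover Strategy switches. Disabling all
#'   three gives the plain moth-flame baseline.
#' @param variant `"mfos"` (default) or `"mfo"`; the latter disables all
#'   three auxiliary strategies.
#' @param vectorized If `TRUE`, the objective is called with a matrix
#'   (one candidate per row) and must return a numeric vector.
#' @param stop_value Stop early once the best value is `<= stop_value`
#'   (default `-Inf`: never).
#' @param seed Optional RNG seed for a fully reproducible run.
#' @return A list of class `mfos_control`.
#' @export
mfos_control <- function(pop_size = 50, iterations = 500,
                         crossover_prob = 0.8, mutation_prob = 0.05,
                         levy_beta = 1.5, levy_scale = 0.01, spiral_b = 1,
                         use_levy = TRUE, use_obl = TRUE,
                         use_crossover = TRUE,
                         variant = c("mfos", "mfo"),
                         vectorized = FALSE, stop_value = -Inf,
                         seed = NULL) {
  variant <- match.arg(variant)
  if (variant == "mfo") use_levy <- use_obl <- use_crossover <- FALSE
  if (pop_size < 2) stop("pop_size must be >= 2", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (levy_beta <= 1 || levy_beta > 2) {
    stop("levy_beta must satisfy 1 < beta <= 2", call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 levy_beta = levy_beta, levy_scale = levy_scale,
                 spiral_b = spiral_b,
                 use_levy = use_levy, use_obl = use_obl,
                 use_crossover = use_crossover, variant = variant,
                 vectorized = vectorized, stop_value = stop_value,
                 seed = seed),
            class = "mfos_control")
}

#' Logarithmic spiral move of a moth around a flame
#'
#' The new position is `D * exp(b * t) * cos(2 * pi * t) + flame` per
#' coordinate, where `D = |flame - moth|`. With `t` near -1 the moth lands
#' close to the flame; `t` near 1 throws it outward.
#'
#' @param moth,flame Numeric vectors of equal length.
#' @param t Spiral parameter(s), recycled per coordinate.
#' @param b Spiral shape constant.
#' @return The new position (unclipped).
#' @examples
#' spiral_move(c(0, 0), c(1, 1), t = -1)
#' @export
spiral_move <- function(moth, flame, t, b = 1) {
  D <- abs(flame - moth)
  D * exp(b * t) * cos(2 * pi * t) + flame
}

#' Levy-flight displacement (Mantegna generator)
#'
#' Draws a heavy-tailed step `u / |w|^(1/beta)` per dimension with
#' `u ~ N(0, sigma_u^2)` and `w ~ N(0, 1)`, where `sigma_u` is the
#' Mantegna constant for stability index `beta`. Used as a small-scale
#' mutation that occasionally produces long exploratory jumps.
#'
#' @param v Number of dimensions.
#' @param beta Stability index, `1 < beta <= 2`.
#' @return Numeric vector of `v` unscaled step components.
#' @export
levy_step <- function(v, beta = 1.5) {
  if (beta <= 1 || beta > 2) {
    stop("beta must satisfy 1 < beta <= 2", call. = FALSE)
  }
  s <- levy_sigma_u(beta)
  u <- stats::rnorm(v, 0, s)
  w <- stats::rnorm(v)
  u / abs(w)^(1 / beta)
}

# Mantegna sigma_u for the numerator normal
levy_sigma_u <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Opposition-based-learning point
#'
#' The coordinate-wise opposite of `x` in the box `[lower, upper]`:
#' `lower + upper - x`. An involution whose fixed point is the box center.
#'
#' @param x Numeric vector.
#' @param lower,upper Box bounds (recycled).
#' @return The opposite point.
#' @examples
#' obl_opposite(0.3, 0, 1)  # 0.7
#' @export
obl_opposite <- function(x, lower, upper) {
  lower + upper - x
}

# evaluate objective on a population matrix
eval_pop <- function(fn, Q, vectorized) {
  if (vectorized) as.numeric(fn(Q)) else apply(Q, 1, fn)
}

#' Initialize an optimizer state
#'
#' Draws `pop_size` moths uniformly in the search box, evaluates them,
#' and seeds the flame list with the sorted population.
#'
#' @param fn Objective function to minimize.
#' @param lower,upper Bounds, recycled to the dimension `v`.
#' @param v Problem dimension; defaults to `length(lower)`.
#' @param control An [mfos_control] list.
#' @return An `mfos_state` list with moth matrix `Q`, fitness `Qf`, flame
#'   matrix `R` with fitness `Rf`, the incumbent `best_par`/`best_value`,
#'   and counters.
#' @export
mfos_init <- function(fn, lower, upper, v = length(lower),
                      control = mfos_control()) {
  stopifnot(inherits(control, "mfos_control"))
  lower <- rep_len(as.numeric(lower), v)
  upper <- rep_len(as.numeric(upper), v)
  if (any(lower >= upper)) stop("need lower < upper", call. = FALSE)
  if (!is.null(control$seed)) set.seed(control$seed)
  N <- control$pop_size
  Q <- matrix(stats::runif(N * v), N, v)
  Q <- sweep(sweep(Q, 2, upper - lower, "*"), 2, lower, "+")
  Qf <- eval_pop(fn, Q, control$vectorized)
  o <- order(Qf)
  state <- list(fn = fn, lower = lower, upper = upper, v = v,
                control = control,
                Q = Q, Qf = Qf,
                R = Q[o, , drop = FALSE], Rf = Qf[o],
                best_par = Q[o[1], ], best_value = Qf[o[1]],
                iter = 0L, trace = numeric(0),
                n_evals = N)
  class(state) <- "mfos_state"
  state
}

#' Advance the optimizer by one iteration
#'
#' One iteration: (1) flames are rebuilt from the merged moth + flame
#' population, sorted by fitness, with the flame count annealed as
#' `round(N - iter * (N - 1) / T)`; (2) each moth spirals around its
#' assigned flame with `t` drawn uniformly in `[r, 1]`, `r` annealed from
#' -1 to -2; (3) Levy-flight and OBL mutations fire per moth with
#' `mutation_prob` (the OBL candidate is accepted only if it improves);
#' (4) arithmetic crossover of the two best individuals fires with
#' `crossover_prob` and replaces the worst moth when better; (5) the
#' incumbent best is updated. Positions are clipped to the box after
#' every move.
#'
#' @param state An `mfos_state` from [mfos_init()].
#' @return The advanced state; `state$trace` gains one entry.
#' @export
mfos_step <- function(state) {
  ctrl <- state$control
  N <- ctrl$pop_size; v <- state$v
  Tmax <- ctrl$iterations
  it <- state$iter + 1L
  lower <- state$lower; upper <- state$upper
  lo <- matrix(lower, N, v, byrow = TRUE)
  hi <- matrix(upper, N, v, byrow = TRUE)

  # (1) flame update: merge, sort, keep best N; annealed flame count
  allP <- rbind(state$R, state$Q)
  allF <- c(state$Rf, state$Qf)
  o <- order(allF)[1:N]
  R <- allP[o, , drop = FALSE]; Rf <- allF[o]
  n_flames <- max(1L, round(N - it * (N - 1) / Tmax))

  # (2) spiral move toward assigned flame (moth i beyond the flame count
  # is assigned the last flame)
  r <- -1 - it / Tmax
  tmat <- matrix(stats::runif(N * v, r, 1), N, v)
  fl <- pmin(seq_len(N), n_flames)
  Fl <- R[fl, , drop = FALSE]
  D <- abs(Fl - state$Q)
  Q <- D * exp(ctrl$spiral_b * tmat) * cos(2 * pi * tmat) + Fl

  # (3a) Levy mutation
  if (ctrl$use_levy) {
    hit <- which(stats::runif(N) < ctrl$mutation_prob)
    for (i in hit) {
      Q[i, ] <- Q[i, ] + ctrl$levy_scale * (upper - lower) *
        levy_step(v, ctrl$levy_beta)
    }
  }
  Q <- pmin(pmax(Q, lo), hi)
  Qf <- eval_pop(state$fn, Q, ctrl$vectorized)
  state$n_evals <- state$n_evals + N

  # (3b) OBL mutation, greedy acceptance
  if (ctrl$use_obl) {
    hit <- which(stats::runif(N) < ctrl$mutation_prob)
    for (i in hit) {
      opp <- obl_opposite(Q[i, ], lower, upper)
      fo <- if (ctrl$vectorized)
        as.numeric(state$fn(matrix(opp, 1, v)))[1] else state$fn(opp)
      state$n_evals <- state$n_evals + 1L
      if (fo < Qf[i]) { Q[i, ] <- opp; Qf[i] <- fo }
    }
  }

  # (4) arithmetic crossover of the two best individuals
  if (ctrl$use_crossover && stats::runif(1) < ctrl$crossover_prob) {
    a <- stats::runif(1)
    child <- a * R[1, ] + (1 - a) * R[2, ]
    fc <- if (ctrl$vectorized)
      as.numeric(state$fn(matrix(child, 1, v)))[1] else state$fn(child)
    state$n_evals <- state$n_evals + 1L
    worst <- which.max(Qf)
    if (fc < Qf[worst]) { Q[worst, ] <- child; Qf[worst] <- fc }
  }

  # (5) incumbent update (replace only when strictly better)
  ib <- which.min(Qf)
  if (Qf[ib] < state$best_value) {
    state$best_value <- Qf[ib]
    state$best_par <- Q[ib, ]
  }
  if (Rf[1] < state$best_value) {
    state$best_value <- Rf[1]
    state$best_par <- R[1, ]
  }
  state$Q <- Q; state$Qf <- Qf; state$R <- R; state$Rf <- Rf
  state$iter <- it
  state$trace <- c(state$trace, state$best_value)
  state
}

#' Minimize an objective with the moth-flame optimizer
#'
#' Runs the synergistic moth-flame optimizer (MFOS: spiral core plus
#' Levy-flight and OBL mutations and elitist arithmetic crossover) for
#' `control$iterations` iterations and returns the incumbent best with
#' its convergence trace. Set `variant = "mfo"` in [mfos_control()] for
#' the plain baseline.
#'
#' @param fn Objective function mapping a numeric vector of length `v`
#'   (or a population matrix when `control$vectorized`) to a value to be
#'   minimized.
#' @param lower,upper Box bounds, recycled to dimension `v`.
#' @param v Problem dimension; defaults to `length(lower)`.
#' @param control An [mfos_control] list.
#' @return Object of class `mfos`: list with `par`, `value`, `trace`
#'   (best-so-far per iteration, non-increasing), `iterations`,
#'   `n_evals`, and the resolved `control`.
#' @examples
#' fit <- mfos(function(x) sum(x^2), -5, 5, v = 2,
#'             control = mfos_control(pop_size = 10, iterations = 50,
#'                                    seed = 1))
#' fit$value
#' @export
mfos <- function(fn, lower, upper, v = length(lower),
                 control = mfos_control()) {
  state <- mfos_init(fn, lower, upper, v, control)
  for (it in seq_len(control$iterations)) {
    state <- mfos_step(state)
    if (state$best_value <= control$stop_value) break
  }
  # pad the trace so its length always equals the configured iterations
  tr <- state$trace
  if (length(tr) < control$iterations) {
    tr <- c(tr, rep(state$best_value, control$iterations - length(tr)))
  }
  structure(list(par = state$best_par, value = state$best_value,
                 trace = tr, iterations = state$iter,
                 n_evals = state$n_evals, control = control,
                 lower = state$lower, upper = state$upper),
            class = "mfos")
}

#' @export
print.mfos <- function(x, ...) {
  cat(sprintf("%s run: %d iterations, %d evaluations\n",
              toupper(x$control$variant), x$iterations, x$n_evals))
  cat("  best value:", format(x$value, digits = 6), "\n")
  cat("  best par:  ", paste(format(x$par, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mfos <- function(object, ...) {
  tr <- object$trace
  out <- list(variant = object$control$variant,
              value = object$value,
              iterations = object$iterations,
              n_evals = object$n_evals,
              first_quartile_value = tr[ceiling(length(tr) / 4)],
              midpoint_value = tr[ceiling(length(tr) / 2)])
  class(out) <- "summary.mfos"
  out
}

#' @export
print.summary.mfos <- function(x, ...) {
  cat(sprintf("%s: best %.6g after %d iterations (%d evals)\n",
              toupper(x$variant), x$value, x$iterations, x$n_evals))
  cat(sprintf("  best-so-far at T/4: %.6g, at T/2: %.6g\n",
              x$first_quartile_value, x$midpoint_value))
  invisible(x)
}

#' @export
coef.mfos <- function(object, ...) object$par

#' Plot a convergence trace
#'
#' @param x An `mfos` fit.
#' @param log Axis spec passed to [graphics::plot()]; best-so-far values
#'   are usually viewed on a log scale.
#' @param ... Further plot arguments.
#' @export
plot.mfos <- function(x, log = "y", ...) {
  tr <- x$trace
  if (any(tr <= 0) && grepl("y", log)) log <- sub("y", "", log)
  graphics::plot(seq_along(tr), tr, type = "l", log = log,
                 xlab = "iteration", ylab = "best value so far",
                 main = toupper(x$control$variant), ...)
  invisible(x)
}
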