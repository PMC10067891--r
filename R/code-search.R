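# Optimizer-driven construction of constraint-satisfying code sets and
# lower-bound tables.
#
# The continuous optimizer proposes candidate words through a
# floor-decoding of real vectors in [0, 4)^n (digit map A=0, T=1, C=2,
# G=3, the same bijection used by the storage codec). Sets are grown
# greedily: the optimizer minimizes a violation score against the words
# accepted so far, a candidate is accepted only at score exactly 0, and
# plateau-escape moves (dropping a few words and regrowing, keeping the
# best set seen) let the search climb past locally maximal sets.

#' Decode a real vector into a DNA word
#'
#' Each coordinate in `[0, 4)` maps to a base by its integer part:
#' 0 -> A, 1 -> T, 2 -> C, 3 -> G. Out-of-range coordinates are clipped
#' before decoding. The decoding is surjective onto all `4^n` words.
#'
#' @param v Numeric vector (or matrix, one candidate per row).
#' @return A character vector of DNA words.
#' @examples
#' decode_vector(c(0.2, 1.9, 2.5, 3.01))  # "ATCG"
#' @export
decode_vector <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  int_to_seq(decode_int(v))
}

# matrix version kept in integer space for the search inner loop
decode_int <- function(v) {
  D <- floor(v)
  D[D < 0] <- 0L
  D[D > 3] <- 3L
  storage.mode(D) <- "integer"
  D
}

#' Violation score of a candidate word against an accepted set
#'
#' Returns 0 if and only if `x` satisfies all enabled single-word
#' constraints (GC count, no-runlength, secondary-structure screen) and
#' keeps Hamming distance and, when enabled, reverse-complement distance
#' of at least `d` from every accepted word (and from its own reverse
#' complement). Otherwise the score sums the violation magnitudes:
#' distance deficits `max(0, d - H)` per offending pair, the GC-count
#' distance to the admissible set, the number of excess adjacent repeats,
#' and an indicator penalty for a detected stem. Suitable as a
#' minimization objective.
#'
#' @param x A DNA word (length-1 character vector).
#' @param accepted A [dna_codeset] or character vector of accepted words
#'   (may be empty: `character(0)`).
#' @param constraints A [dna_constraints] object.
#' @return Non-negative numeric score.
#' @examples
#' cc <- dna_constraints(4, 2)
#' candidate_fitness("AGCT", character(0), cc)  # 0
#' @export
candidate_fitness <- function(x, accepted, constraints) {
  if (inherits(accepted, "dna_codeset")) accepted <- accepted$words
  A <- if (length(accepted)) seq_to_int(accepted) else
    matrix(integer(0), 0, constraints$n)
  Arc <- if (nrow(A)) t(apply(A, 1, rc_int)) else A
  if (nrow(A) && constraints$n == 1) Arc <- matrix(Arc, ncol = 1)
  fitness_int(seq_to_int(x), A, Arc, constraints)[1]
}

# vectorized violation score over an integer population matrix
fitness_int <- function(D, A, Arc, cons) {
  n <- ncol(D)
  pen <- numeric(nrow(D))
  if (cons$use_gc) {
    g <- rowSums(D >= 2L)
    dev <- vapply(g, function(gi) min(abs(gi - cons$gc_tolerance)), 0)
    pen <- pen + dev
  }
  if (cons$use_nl && n > 1) {
    run <- rowSums(D[, -1, drop = FALSE] == D[, -n, drop = FALSE])
    # with max_run > 1 count only runs beyond the cap
    if (cons$max_run == 1L) pen <- pen + run
    else {
      pen <- pen + vapply(seq_len(nrow(D)), function(i) {
        r <- rle(D[i, ])
        sum(pmax(0L, r$lengths - cons$max_run))
      }, 0)
    }
  }
  if (cons$use_ss) {
    pen <- pen + vapply(seq_len(nrow(D)), function(i) {
      as.numeric(has_secondary_structure(int_to_seq(D[i, , drop = FALSE]),
                                         cons$ss_min_stem))
    }, 0)
  }
  d <- cons$d
  if (nrow(A)) {
    H <- hamming_matrix(D, A)
    pen <- pen + rowSums(pmax(d - H, 0))  # matrix first: pmax keeps dims
    if (cons$use_rc) {
      Hrc <- hamming_matrix(D, Arc)
      pen <- pen + rowSums(pmax(d - Hrc, 0))
    }
  }
  if (cons$use_rc && cons$rc_include_self) {
    hs <- vapply(seq_len(nrow(D)), function(i) {
      sum(D[i, ] != rc_int(D[i, ]))
    }, 0)
    pen <- pen + pmax(0, d - hs)
  }
  pen
}

#' Search configuration for code-set construction
#'
#' @param constraints A [dna_constraints] object.
#' @param optimizer An [mfos_control] for the candidate-proposal runs.
#'   The default uses a small population and iteration budget per
#'   proposal with a raised mutation probability, early-stopping as soon
#'   as a zero-violation candidate is found; proposals are capped at the
#'   standard 500 iterations.
#' @param stall_limit Consecutive failed proposals before the growth
#'   phase is considered stalled.
#' @param phases Number of grow/perturb phases (plateau-escape restarts).
#' @param big_ruin_prob Probability that a plateau-escape move drops a
#'   large fraction of the current set instead of 1-3 words.
#' @param seed Master seed for the whole search.
#' @return A list of class `code_search_config`.
#' @export
code_search_config <- function(constraints,
                               optimizer = mfos_control(
                                 pop_size = 30, iterations = 40,
                                 mutation_prob = 0.3,
                                 levy_scale = 0.01,
                                 vectorized = TRUE, stop_value = 0),
                               stall_limit = 6, phases = 40,
                               big_ruin_prob = 0.2, seed = NULL) {
  stopifnot(inherits(constraints, "dna_constraints"),
            inherits(optimizer, "mfos_control"))
  if (optimizer$iterations > 500) {
    stop("proposal runs are capped at 500 iterations", call. = FALSE)
  }
  if (stall_limit < 1 || phases < 1) {
    stop("stall_limit and phases must be >= 1", call. = FALSE)
  }
  structure(list(constraints = constraints, optimizer = optimizer,
                 stall_limit = stall_limit, phases = as.integer(phases),
                 big_ruin_prob = big_ruin_prob, seed = seed),
            class = "code_search_config")
}

# one optimizer run proposing a zero-violation word; NULL on failure
propose_word <- function(A, Arc, cons, optimizer) {
  n <- cons$n
  fn <- function(M) fitness_int(decode_int(M), A, Arc, cons)
  fit <- mfos(fn, lower = rep(0, n), upper = rep(4, n), v = n,
              control = optimizer)
  if (fit$value == 0) decode_int(matrix(fit$par, 1))[1, ] else NULL
}

#' Construct a constraint-satisfying code set
#'
#' Greedily grows a code set: the moth-flame optimizer repeatedly
#' proposes candidate words minimizing [candidate_fitness()] against the
#' words accepted so far, and a word is accepted only when its violation
#' score is exactly 0 (so the emitted set always passes
#' [validate_codeset()]). When `stall_limit` consecutive proposals fail,
#' the search records the incumbent set, drops a few random words
#' (occasionally a large fraction), and regrows; the largest set seen
#' over all `phases` is returned.
#'
#' @param config A [code_search_config].
#' @return A validated [dna_codeset] (possibly empty when the constraints
#'   are unsatisfiable within the budget).
#' @examples
#' \donttest{
#' cfg <- code_search_config(dna_constraints(4, 3), phases = 10, seed = 1)
#' construct_code_set(cfg)
#' }
#' @export
construct_code_set <- function(config) {
  stopifnot(inherits(config, "code_search_config"))
  cons <- config$constraints
  n <- cons$n
  if (!is.null(config$seed)) set.seed(config$seed)
  A <- matrix(integer(0), 0, n)
  Arc <- A
  best <- A
  for (ph in seq_len(config$phases)) {
    fails <- 0L
    while (fails < config$stall_limit) {
      w <- propose_word(A, Arc, cons, config$optimizer)
      dup <- !is.null(w) && nrow(A) &&
        any(rowSums(A != matrix(w, nrow(A), n, byrow = TRUE)) == 0)
      if (is.null(w) || dup) {
        fails <- fails + 1L
      } else {
        fails <- 0L
        A <- rbind(A, w)
        Arc <- rbind(Arc, rc_int(w))
      }
    }
    if (nrow(A) > nrow(best)) best <- A
    if (nrow(A) > 0 && ph < config$phases) {
      k <- if (stats::runif(1) < config$big_ruin_prob) {
        max(1L, floor(nrow(A) * stats::runif(1, 0.4, 0.8)))
      } else {
        sample.int(min(3L, nrow(A)), 1)
      }
      drop <- sample.int(nrow(A), k)
      A <- A[-drop, , drop = FALSE]
      Arc <- Arc[-drop, , drop = FALSE]
    }
  }
  if (nrow(best) == 0) {
    return(structure(list(words = character(0), constraints = cons,
                          provenance = "mfos search (empty)"),
                     class = "dna_codeset"))
  }
  # canonical order for reproducible presentation
  words <- sort(int_to_seq(best))
  cs <- dna_codeset(words, constraints = cons, provenance = "mfos search")
  stopifnot(validate_codeset(cs)$overall_pass)
  cs
}

#' Build a lower-bound table over (n, d) ranges
#'
#' Runs [construct_code_set()] once per `(n, d)` cell and tabulates the
#' found code size: each valid constructed set certifies a lower bound on
#' the maximum code size. Cells are compared, when available, against the
#' packaged reference bounds (see [ref_lower_bounds()]).
#'
#' @param n_range,d_range Integer vectors of word lengths and distances;
#'   cells with `d > n` are skipped.
#' @param use_rc Whether the reverse-complement constraint is enforced in
#'   addition to GC content and no-runlength.
#' @param seed Master seed; cell seeds are derived from it.
#' @param phases Search phases per cell (see [code_search_config()]).
#' @param reference Reference table to compare against:
#'   `"mfos"`, `"prior"`, or `"none"`.
#' @return Object of class `bounds_table`: a data frame with columns
#'   `n`, `d`, `size`, `seed`, `elapsed_s`, `reference`, `pct_vs_ref`,
#'   with the constructed sets in `attr(, "codes")`.
#' @export
build_bounds_table <- function(n_range, d_range, use_rc = FALSE,
                               seed = 1, phases = 40,
                               reference = c("mfos", "prior", "none")) {
  reference <- match.arg(reference)
  stopifnot(length(n_range) > 0, length(d_range) > 0)
  ref <- if (reference == "none") NULL else
    ref_lower_bounds(if (use_rc) "gc_nl_rc" else "gc_nl")
  rows <- list(); codes <- list()
  cell_seeds <- withr_seed(seed, sample.int(2^30,
                                            length(n_range) * length(d_range)))
  i <- 0
  for (n in n_range) for (d in d_range) {
    i <- i + 1
    if (d > n) next
    cons <- dna_constraints(n = n, d = d, use_rc = use_rc)
    cfg <- code_search_config(cons, phases = phases, seed = cell_seeds[i])
    t0 <- proc.time()[["elapsed"]]
    cs <- construct_code_set(cfg)
    el <- proc.time()[["elapsed"]] - t0
    refv <- NA_real_
    if (!is.null(ref)) {
      hit <- ref$n == n & ref$d == d
      if (any(hit)) {
        refv <- if (reference == "mfos") ref$mfos[hit][1] else ref$prior[hit][1]
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      n = n, d = d, size = length(cs$words), seed = cell_seeds[i],
      elapsed_s = round(el, 2), reference = refv,
      pct_vs_ref = if (is.na(refv) || refv <= 0) NA_real_ else
        percent_change(length(cs$words), refv, digits = 2))
    codes[[paste0("n", n, "_d", d)]] <- cs
  }
  out <- do.call(rbind, rows)
  attr(out, "codes") <- codes
  class(out) <- c("bounds_table", class(out))
  out
}

#' @export
print.bounds_table <- function(x, ...) {
  cat("Lower-bound table (found code-set sizes; each cell validated)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
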