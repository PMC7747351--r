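#' Cost of a parameter triple under a frozen CV evaluator
#'
#' The cost is the distance from a perfect prediction: F = 1 - AUC, where
#' the AUC comes from a cross-validation evaluator holding its fold
#' division fixed so that repeated evaluations of the same point are
#' bit-identical.
#'
#' @param params a [parameter_set()] (or list with alpha, beta, gamma).
#' @param evaluator function mapping a parameter set to an AUC in \[0,1\].
#' @return scalar cost in \[0,1\]; lower is better.
#' @export
abc_fitness <- function(params, evaluator) {
  auc <- evaluator(params)
  stopifnot(is.numeric(auc), length(auc) == 1L, auc >= 0, auc <= 1)
  1 - auc
}

#' Employed-bee neighbourhood move
#'
#' Perturbs one coordinate towards/away from a partner source:
#' new[dim] = p[dim] + phi * (p[dim] - partner[dim]), clipped to \[0,1\]
#' since the parameters are convex-combination weights.
#'
#' @param position,partner numeric length-3 vectors in \[0,1\]^3.
#' @param dim coordinate index in 1..3.
#' @param phi step scale.
#' @return new position vector.
#' @export
abc_neighbor <- function(position, partner, dim, phi) {
  stopifnot(dim %in% seq_along(position))
  new <- position
  new[dim] <- position[dim] + phi * (position[dim] - partner[dim])
  new[dim] <- min(max(new[dim], 0), 1)
  new
}

#' Onlooker selection probabilities from source costs
#'
#' Costs are normalised by their mean M and mapped through a softmax-like
#' transform: Fi = exp(-Ci / M), Pi = Fi / sum(Fk). Lower cost means
#' higher probability. When every cost is zero the distribution is
#' uniform.
#'
#' @param costs numeric vector of finite costs, length >= 1.
#' @return probability vector summing to 1.
#' @export
selection_probabilities <- function(costs) {
  stopifnot(length(costs) >= 1L, all(is.finite(costs)))
  m <- mean(costs)
  if (m == 0) return(rep(1 / length(costs), length(costs)))
  f <- exp(-costs / m)
  f / sum(f)
}

#' Artificial bee colony search over the mixing weights
#'
#' Minimises `1 - AUC` over (alpha, beta, gamma) in \[0,1\]^3 with the
#' canonical employed / onlooker / scout cycle: each employed bee proposes
#' a neighbourhood move (greedy acceptance), onlookers re-sample sources
#' by [selection_probabilities()] roulette and propose again, and any
#' source whose trial counter exceeds `limit` is re-initialised uniformly.
#' The step scale phi is drawn uniformly on `phi_range` (default \[0,1\];
#' set `c(-1, 1)` for the symmetric textbook variant). Fully deterministic
#' given `seed` and a deterministic evaluator.
#'
#' @param evaluator function(parameter_set) -> AUC in \[0,1\].
#' @param n_sources number of honey sources (>= 2); 10 by default.
#' @param max_iter iterations; 40 by default.
#' @param limit scout trial limit; default `n_sources * 3` (sources times
#'   search dimension).
#' @param seed integer seed.
#' @param phi_range length-2 numeric range for phi.
#' @return list with `best` (a [parameter_set()]), `best_cost`, `trace`
#'   (per-iteration best cost, non-increasing), `n_evaluations`.
#' @export
abc_optimize <- function(evaluator, n_sources = 10L, max_iter = 40L,
                         limit = n_sources * 3L, seed = 1L,
                         phi_range = c(0, 1)) {
  stopifnot(n_sources >= 2L, max_iter >= 1L, limit >= 0L,
            length(phi_range) == 2L)
  d <- 3L
  cost_of <- function(x) {
    abc_fitness(parameter_set(x[1L], x[2L], x[3L]), evaluator)
  }
  n_eval <- 0L
  with_seed(seed, {
    pos <- matrix(stats::runif(n_sources * d), n_sources, d)
    cost <- apply(pos, 1L, cost_of)
    n_eval <- n_sources
    trials <- integer(n_sources)
    best_i <- which.min(cost)
    best <- pos[best_i, ]
    best_cost <- cost[best_i]
    trace <- numeric(max_iter)

    propose <- function(i) {
      k <- sample(setdiff(seq_len(n_sources), i), 1L)
      dim <- sample.int(d, 1L)
      phi <- stats::runif(1L, phi_range[1L], phi_range[2L])
      cand <- abc_neighbor(pos[i, ], pos[k, ], dim, phi)
      c_cand <- cost_of(cand)
      n_eval <<- n_eval + 1L
      if (c_cand < cost[i]) {
        pos[i, ] <<- cand
        cost[i] <<- c_cand
        trials[i] <<- 0L
      } else {
        trials[i] <<- trials[i] + 1L
      }
    }

    for (it in seq_len(max_iter)) {
      for (i in seq_len(n_sources)) propose(i)          # employed phase
      p <- selection_probabilities(cost)                # onlooker phase
      for (o in seq_len(n_sources)) {
        i <- sample.int(n_sources, 1L, prob = p)
        propose(i)
      }
      for (i in seq_len(n_sources)) {                   # scout phase
        if (trials[i] > limit) {
          pos[i, ] <- stats::runif(d)
          cost[i] <- cost_of(pos[i, ])
          n_eval <- n_eval + 1L
          trials[i] <- 0L
        }
      }
      i_min <- which.min(cost)
      if (cost[i_min] < best_cost) {
        best_cost <- cost[i_min]
        best <- pos[i_min, ]
      }
      trace[it] <- best_cost
    }
    list(best = parameter_set(best[1L], best[2L], best[3L]),
         best_cost = best_cost, trace = trace, n_evaluations = n_eval)
  })
}
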