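# Adaptive dropout-rate search: a population metaheuristic over the scalar
# dropout rate.  Odd iterations run water-strider-style global exploration
# (attraction toward the population best plus surface-tension noise, with a
# repulsion "ripple" on failed moves); even iterations run genetic-style
# local refinement (tournament selection, arithmetic crossover, Gaussian
# mutation, elitist replacement of the worst candidates).

#' Control parameters for the adaptive dropout search
#'
#' Defaults follow the customary ranges for this family of optimizers:
#' population 10--30 (default 20), 20--50 iterations per round (default 30),
#' tension coefficient alpha starting near 0.7 and decaying multiplicatively,
#' crossover probability 0.8, mutation probability 0.1--0.2 (default 0.15),
#' local mutation scale 0.05--0.1 (default 0.075) in units of the search
#' span, and dropout bounds `[0.1, 0.6]`.
#'
#' @param pop_size candidate population size.
#' @param max_iters iterations per scheduling round.
#' @param alpha0 initial tension (exploration step) coefficient.
#' @param alpha_decay multiplicative per-iteration decay in `(0, 1]`.
#' @param crossover_prob probability of arithmetic crossover per child.
#' @param mutation_prob probability of Gaussian mutation per child.
#' @param local_rate mutation sd as a fraction of the bounds span.
#' @param bounds admissible dropout range, `0 < lo < hi < 1`.
#' @param fitness_kind what the fitness function returns: a score where
#'   larger is better (`"val_f1"`, `"val_accuracy"`) or a loss
#'   (`"neg_val_loss"`, negated internally so larger is always better).
#' @param eval_budget training mini-batches per candidate evaluation (used by
#'   the training integration).
#' @param max_evals optional cap on total fitness evaluations per round;
#'   when exhausted the search returns its incumbent with a warning flag.
#' @param rescore_elite re-score the incumbent once per iteration, averaging
#'   repeated draws, so a stochastic fitness cannot be captured by a single
#'   lucky evaluation.  A no-op (beyond one extra call per iteration) for
#'   deterministic fitness functions; disable to save evaluations there.
#' @param seed integer seed for the search substream.
#' @return An object of class `"dropout_search_control"`.
#' @export
dropout_search_control <- function(pop_size = 20L, max_iters = 30L,
                                   alpha0 = 0.7, alpha_decay = 0.95,
                                   crossover_prob = 0.8, mutation_prob = 0.15,
                                   local_rate = 0.075, bounds = c(0.1, 0.6),
                                   fitness_kind = c("val_f1", "val_accuracy",
                                                    "neg_val_loss"),
                                   eval_budget = 2L, max_evals = Inf,
                                   rescore_elite = TRUE, seed = 1L) {
  fitness_kind <- match.arg(fitness_kind)
  stopifnot(pop_size >= 2L, max_iters >= 0L,
            length(bounds) == 2L, bounds[1] > 0, bounds[2] < 1,
            bounds[1] < bounds[2],
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            alpha_decay > 0, alpha_decay <= 1, alpha0 >= 0, local_rate > 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters),
                 alpha0 = alpha0, alpha_decay = alpha_decay,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, local_rate = local_rate,
                 bounds = bounds, fitness_kind = fitness_kind,
                 eval_budget = as.integer(eval_budget), max_evals = max_evals,
                 rescore_elite = isTRUE(rescore_elite),
                 seed = as.integer(seed)),
            class = "dropout_search_control")
}

new_search_state <- function(ctrl) {
  cand <- stats::runif(ctrl$pop_size, ctrl$bounds[1], ctrl$bounds[2])
  list(candidates = cand, fitness = rep(NA_real_, ctrl$pop_size),
       best_rate = NA_real_, best_fitness = -Inf,
       alpha = ctrl$alpha0, iteration = 0L, n_evals = 0L,
       exhausted = FALSE, stochastic = FALSE, trace = list(),
       cache = new.env(parent = emptyenv()))
}

# Evaluate one candidate rate (larger = better).  Results are cached per
# rate rounded to 1e-4; the cache keeps a running mean over repeated draws
# (`rescore = TRUE` forces a fresh draw and folds it into the mean), which
# makes the incumbent noise-robust while reducing to plain caching when the
# fitness function is deterministic.  Every evaluation is traced.
eval_candidate <- function(rate, fitness_fn, state, ctrl, round_i, phase,
                           cand_id = NA_integer_, rescore = FALSE) {
  key <- sprintf("%.4f", round(rate, 4))
  entry <- state$cache[[key]]
  if (!is.null(entry) && !rescore) {
    f <- entry$mean
  } else {
    if (state$n_evals >= ctrl$max_evals) {
      state$exhausted <- TRUE
      return(list(fitness = NA_real_, state = state))
    }
    raw <- tryCatch(fitness_fn(rate), error = function(e) {
      stop("fitness evaluation failed at dropout rate ", signif(rate, 4),
           ": ", conditionMessage(e))
    })
    draw <- if (ctrl$fitness_kind == "neg_val_loss") -raw else raw
    if (is.null(entry)) {
      entry <- list(mean = draw, n = 1L, rate = rate)
    } else {
      if (abs(draw - entry$mean) > 1e-10) state$stochastic <- TRUE
      entry$mean <- (entry$mean * entry$n + draw) / (entry$n + 1L)
      entry$n <- entry$n + 1L
    }
    state$cache[[key]] <- entry
    state$n_evals <- state$n_evals + 1L
    f <- entry$mean
    if (draw > state$best_fitness) state$best_fitness <- draw
  }
  state$trace[[length(state$trace) + 1L]] <-
    data.frame(round = round_i, iteration = state$iteration,
               candidate = cand_id, rate = rate, fitness = f, phase = phase)
  list(fitness = f, state = state)
}

# Rate with the highest mean fitness over all draws so far (the incumbent).
incumbent_rate <- function(state) {
  ks <- ls(state$cache)
  if (!length(ks)) return(NA_real_)
  means <- vapply(ks, function(k) state$cache[[k]]$mean, numeric(1))
  state$cache[[ks[which.max(means)]]]$rate
}

# Water-strider exploration sweep: attraction toward the population best with
# tension noise; failed moves trigger a repulsion ripple.  Alpha decays.
strider_sweep <- function(state, fitness_fn, ctrl, round_i) {
  span <- diff(ctrl$bounds)
  best_i <- which.max(state$fitness)
  # attraction target: the noise-robust incumbent (mean-based) when elite
  # re-scoring is on, else the population best
  best <- if (ctrl$rescore_elite) incumbent_rate(state)
          else state$candidates[best_i]
  if (is.na(best)) best <- state$candidates[best_i]
  for (i in seq_along(state$candidates)) {
    if (i == best_i) next
    if (state$exhausted) break
    d <- state$candidates[i]
    u <- stats::runif(1)
    g <- stats::rnorm(1)
    d1 <- clip_to(d + state$alpha * u * (best - d) + state$alpha * g * span,
                  ctrl$bounds[1], ctrl$bounds[2])
    ev <- eval_candidate(d1, fitness_fn, state, ctrl, round_i, "explore", i)
    state <- ev$state
    if (state$exhausted) break
    if (ev$fitness < state$fitness[i]) {
      # failed ripple: repulsion away from the best
      u2 <- stats::runif(1)
      d2 <- clip_to(d - state$alpha * u2 * (best - d),
                    ctrl$bounds[1], ctrl$bounds[2])
      ev2 <- eval_candidate(d2, fitness_fn, state, ctrl, round_i, "explore", i)
      state <- ev2$state
      if (state$exhausted) break
      state$candidates[i] <- d2
      state$fitness[i] <- ev2$fitness
    } else {
      state$candidates[i] <- d1
      state$fitness[i] <- ev$fitness
    }
  }
  state$alpha <- state$alpha * ctrl$alpha_decay
  state
}

# Tournament pick (size 2) from the top half, returning a population index.
tournament_pick <- function(top_idx, fitness) {
  pick <- sample(top_idx, min(2L, length(top_idx)), replace = length(top_idx) < 2L)
  pick[which.max(fitness[pick])]
}

# Crossover/mutation refinement restricted to the top half of the
# population; children replace the current worst only when fitter.
refine_sweep <- function(state, fitness_fn, ctrl, round_i) {
  span <- diff(ctrl$bounds)
  n <- length(state$candidates)
  top_idx <- order(state$fitness, decreasing = TRUE)[seq_len(ceiling(n / 2))]
  for (ch in seq_len(max(1L, n %/% 2L))) {
    if (state$exhausted) break
    do_cx <- stats::runif(1) < ctrl$crossover_prob
    if (do_cx) {
      p1 <- tournament_pick(top_idx, state$fitness)
      p2 <- p1
      tries <- 0L
      while (p2 == p1 && tries < 10L && length(top_idx) > 1L) {
        p2 <- tournament_pick(top_idx, state$fitness)
        tries <- tries + 1L
      }
      if (p2 == p1 && length(top_idx) > 1L) p2 <- setdiff(top_idx, p1)[1L]
      lam <- stats::runif(1)
      child <- lam * state$candidates[p1] + (1 - lam) * state$candidates[p2]
    } else {
      child <- state$candidates[tournament_pick(top_idx, state$fitness)]
    }
    do_mut <- stats::runif(1) < ctrl$mutation_prob
    if (do_mut) child <- child + stats::rnorm(1, 0, ctrl$local_rate * span)
    if (!do_cx && !do_mut) next   # nothing happened: no child produced
    child <- clip_to(child, ctrl$bounds[1], ctrl$bounds[2])
    ev <- eval_candidate(child, fitness_fn, state, ctrl, round_i, "refine")
    state <- ev$state
    if (state$exhausted) break
    w <- which.min(state$fitness)
    if (ev$fitness > state$fitness[w]) {
      state$candidates[w] <- child
      state$fitness[w] <- ev$fitness
    }
  }
  state
}

#' Run one round of the adaptive dropout-rate search
#'
#' Initializes (or warm-starts) a candidate population of dropout rates
#' within the control's bounds, evaluates it, then alternates exploration
#' (odd iterations) and refinement (even iterations) for `max_iters`
#' iterations.  Returns the incumbent best rate; the full per-evaluation
#' trace (round, iteration, candidate, rate, fitness, phase) is attached.
#'
#' @param fitness_fn function of one dropout rate returning the fitness (a
#'   score, or a loss when `fitness_kind = "neg_val_loss"`).
#' @param control a [dropout_search_control()].
#' @param state optional state from a previous round (warm start; candidates
#'   are re-evaluated because the fitness landscape may have moved).
#' @param round_index integer round label used in the trace and cache.
#' @return List with `best_rate`, `best_fitness`, `state`, `trace`
#'   (data frame), `n_evals`, and `budget_exhausted`.
#' @export
dropout_search <- function(fitness_fn, control = dropout_search_control(),
                           state = NULL, round_index = 1L) {
  ctrl <- control
  with_seed(hash_seed(ctrl$seed, round_index, "dropout-search"), {
    if (is.null(state)) {
      state <- new_search_state(ctrl)
    } else {
      # warm start: keep candidates, reset per-round bookkeeping
      state$cache <- new.env(parent = emptyenv())
      state$trace <- list()
      state$fitness <- rep(NA_real_, length(state$candidates))
      state$best_fitness <- -Inf
      state$best_rate <- NA_real_
      state$alpha <- ctrl$alpha0
      state$n_evals <- 0L
      state$exhausted <- FALSE
      state$stochastic <- FALSE
      state$iteration <- 0L
    }
    for (i in seq_along(state$candidates)) {
      if (state$exhausted) break
      ev <- eval_candidate(state$candidates[i], fitness_fn, state, ctrl,
                           round_index, "init", i)
      state <- ev$state
      if (!is.na(ev$fitness)) state$fitness[i] <- ev$fitness
    }
    it <- 0L
    while (it < ctrl$max_iters && !state$exhausted) {
      it <- it + 1L
      state$iteration <- it
      state <- if (it %% 2L == 1L) {
        strider_sweep(state, fitness_fn, ctrl, round_index)
      } else {
        refine_sweep(state, fitness_fn, ctrl, round_index)
      }
      # elite re-scoring: under a stochastic fitness a single lucky draw
      # cannot hold the incumbency -- its estimate is averaged over draws.
      if (ctrl$rescore_elite && !state$exhausted) {
        inc <- incumbent_rate(state)
        if (!is.na(inc)) {
          state <- eval_candidate(inc, fitness_fn, state, ctrl, round_index,
                                  "rescore", rescore = TRUE)$state
        }
      }
    }
    # racing verification: keep re-drawing whichever rate currently tops the
    # mean-fitness ranking until the leader's estimate rests on several
    # draws, so no single lucky evaluation decides the returned rate.
    if (ctrl$rescore_elite) {
      extra <- 0L
      repeat {
        inc <- incumbent_rate(state)
        if (is.na(inc) || state$exhausted || extra >= 120L) break
        key <- sprintf("%.4f", round(inc, 4))
        if (state$cache[[key]]$n >= 5L) break
        state <- eval_candidate(inc, fitness_fn, state, ctrl, round_index,
                                "race", rescore = TRUE)$state
        extra <- extra + 1L
      }
    }
    if (state$exhausted) {
      warning("dropout search: evaluation budget exhausted; returning ",
              "incumbent best rate")
    }
    # Returned rate: for a deterministic fitness, the rate with the highest
    # (cached) fitness.  When repeated draws reveal a stochastic fitness, a
    # single lucky evaluation must not decide the answer, so the consensus
    # of the top half of the final population (ranked by averaged fitness)
    # is returned instead -- the same reasoning that makes CMA-ES return its
    # recombination mean rather than the best sampled point.
    state$best_rate <- if (state$stochastic) {
      cm <- vapply(state$candidates, function(d) {
        e <- state$cache[[sprintf("%.4f", round(d, 4))]]
        if (is.null(e)) -Inf else e$mean
      }, numeric(1))
      top <- order(cm, decreasing = TRUE)[seq_len(ceiling(length(cm) / 2))]
      mean(state$candidates[top])
    } else {
      incumbent_rate(state)
    }
    trace <- do.call(rbind, state$trace)
    list(best_rate = state$best_rate, best_fitness = state$best_fitness,
         state = state, trace = trace, n_evals = state$n_evals,
         budget_exhausted = state$exhausted)
  })
}
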