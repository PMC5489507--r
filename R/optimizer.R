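#' Configuration of the multilevel structure optimizer
#'
#' @param GS Working population size (also the number of parent pyramid
#'   slots; the restoration list holds `2 * GS` pyramids). Default 6.
#' @param gen_max Number of EA generations. Default 30.
#' @param Pc Crossover rate in `[0, 1]`. Default 0.8.
#' @param alpha Mutation-rule base of the restoration list; `alpha = 0`
#'   protects every stored record.
#' @param beta Probability scale of the local-search operator: each incident
#'   edge of node `i` triggers an edge-switch attempt with probability
#'   `min(1, beta * d_i / sum(d))`. Default 20.
#' @param max_levels Pyramid capacity (records per pyramid). Default 5.
#' @param init_samples Independent evaluations averaged the first time any
#'   structure is evaluated (1 for the plain variants, 5 for the
#'   multi-sampling variant).
#' @param rule An [update_rule()].
#' @param pp A [payoff_params()].
#' @param mode An [evaluation_mode()].
#' @param init_swaps Edge-swap attempts used to derive each initial
#'   population member from the input structure; default `2 * N`.
#' @param mutation_swaps Accepted edge swaps applied to each offspring as
#'   mutation. Default 1.
#' @param seed Optional integer; when given, `set.seed(seed)` is called at
#'   the start of [run_mlea()] / [run_ea_cluster()].
#' @return An object of class `mlea_config`.
#' @export
mlea_config <- function(GS = 6L, gen_max = 30L, Pc = 0.8, alpha = 0.5,
                        beta = 20, max_levels = 5L, init_samples = 1L,
                        rule = update_rule("recolonize"),
                        pp = payoff_params(0.95), mode = mode_a(),
                        init_swaps = NULL, mutation_swaps = 1L,
                        seed = NULL) {
  stopifnot(GS >= 2, gen_max >= 1, Pc >= 0, Pc <= 1, alpha >= 0, alpha <= 1,
            beta > 0, max_levels >= 1, init_samples >= 1, mutation_swaps >= 0)
  structure(list(GS = as.integer(GS), gen_max = as.integer(gen_max), Pc = Pc,
                 alpha = alpha, beta = beta,
                 max_levels = as.integer(max_levels),
                 init_samples = as.integer(init_samples), rule = rule,
                 pp = pp, mode = mode, init_swaps = init_swaps,
                 mutation_swaps = as.integer(mutation_swaps), seed = seed),
            class = "mlea_config")
}

#' Preset optimizer variants
#'
#' The four studied variants differ only in pyramid depth, record
#' protection, and first-evaluation sampling:
#' * `lv1`: one level per pyramid, `alpha = 0`, single-sample evaluation.
#' * `lv1-M`: as `lv1` but every first evaluation averages 5 samples.
#' * `lv5`: five levels, `alpha = 0.5`, single-sample evaluation.
#' * `lv10`: ten levels, `alpha = 0.5`, single-sample evaluation.
#'
#' @param variant One of `"lv1"`, `"lv1-M"`, `"lv5"`, `"lv10"`.
#' @param ... Further arguments passed to [mlea_config()].
#' @return An `mlea_config`.
#' @export
variant_config <- function(variant = c("lv1", "lv1-M", "lv5", "lv10"), ...) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    "lv1" = list(max_levels = 1L, alpha = 0, init_samples = 1L),
    "lv1-M" = list(max_levels = 1L, alpha = 0, init_samples = 5L),
    "lv5" = list(max_levels = 5L, alpha = 0.5, init_samples = 1L),
    "lv10" = list(max_levels = 10L, alpha = 0.5, init_samples = 1L))
  cfg <- do.call(mlea_config, c(preset, list(...)))
  cfg$variant <- variant
  cfg
}

#' Counting evaluators
#'
#' An evaluator wraps a single-evaluation fitness function with an audit
#' counter so that every simulator invocation is accounted for.  `once(g)`
#' performs one evaluation; `first(g)` performs the configured number of
#' first-evaluation samples and returns the aggregate `list(sum, num)`;
#' `count()` reports the total number of evaluations so far.
#'
#' @param fn Function taking a graph and returning one (possibly noisy)
#'   fitness evaluation.
#' @param init_samples Default sample count of `first()` when the caller
#'   does not pass one.
#' @return A list of closures `once`, `first`, `count`, `reset`.
#' @export
make_evaluator <- function(fn, init_samples = 1L) {
  count <- 0L
  list(
    once = function(g) {
      count <<- count + 1L
      fn(g)
    },
    first = function(g, n = init_samples) {
      s <- 0
      for (i in seq_len(n)) {
        count <<- count + 1L
        s <- s + fn(g)
      }
      list(sum = s, num = as.integer(n))
    },
    count = function() count,
    reset = function() count <<- 0L
  )
}

#' @rdname make_evaluator
#' @param config An [mlea_config()]; its rule, payoffs and mode define the
#'   cooperation-level evaluator.
#' @export
make_coop_evaluator <- function(config) {
  make_evaluator(
    function(g) evaluate_cooperation(g, config$rule, config$pp, config$mode)$sum
  )
}

# Apply n accepted, connectivity-preserving double edge swaps.
mutate_swaps <- function(g, n_swaps, tries_per_swap = 20L) {
  for (s in seq_len(n_swaps)) {
    for (t in seq_len(tries_per_swap)) {
      g2 <- simple_edge_swap(g)
      if (isTRUE(igraph::graph_attr(g2, "swapped")) && graph_is_connected(g2)) {
        g <- g2
        break
      }
    }
  }
  g
}

#' Initialize the optimizer population
#'
#' Derives `GS` connected variants of the input structure by repeated double
#' edge swaps (degree sequence unchanged) and evaluates each with the
#' configured first-evaluation sampling.
#'
#' @param g0 Connected simple igraph object.
#' @param config An [mlea_config()].
#' @param evaluator A counting evaluator from [make_evaluator()].
#' @return List of `GS` [solution()]s.
#' @export
initialize_population <- function(g0, config, evaluator) {
  validate_graph(g0, connected = TRUE)
  n_attempts <- config$init_swaps
  if (is.null(n_attempts)) n_attempts <- 2L * igraph::vcount(g0)
  lapply(seq_len(config$GS), function(i) {
    g <- g0
    for (a in seq_len(n_attempts)) {
      g2 <- simple_edge_swap(g)
      if (isTRUE(igraph::graph_attr(g2, "swapped")) && graph_is_connected(g2))
        g <- g2
    }
    fa <- evaluator$first(g, config$init_samples)
    solution(g, fa$sum, fa$num)
  })
}

#' Roulette-wheel parent selection
#'
#' Each parent index is drawn with probability proportional to its
#' solution's `avg`; when every `avg` is zero the draw is uniform.
#'
#' @param population List of [solution()]s.
#' @return Integer vector of two (possibly equal) indices.
#' @export
roulette_select <- function(population) {
  stopifnot(length(population) >= 1L)
  w <- vapply(population, sol_avg, numeric(1))
  if (sum(w) <= 0) w <- rep(1, length(w))
  sample.int(length(population), 2L, replace = TRUE, prob = w)
}

# Sorted numeric edge keys (a < b -> a * (n + 1) + b) of a graph.
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  a * (igraph::vcount(g) + 1) + b
}

keys_to_edges <- function(keys, n) {
  a <- floor(keys / (n + 1))
  b <- keys - a * (n + 1)
  rbind(a, b)
}

#' Degree-preserving recombination of two structures
#'
#' The child keeps every edge both parents share, fills remaining per-node
#' degree deficits preferentially from the parents' symmetric difference,
#' and pairs any residual stubs at random (avoiding self-loops and duplicate
#' edges).  The construction is retried until the child is connected; on
#' failure the fitter parent's graph is returned.  Parents must have
#' identical per-node degrees, which all solutions in a run share by
#' construction.
#'
#' @param pa,pb Parent [solution()]s.
#' @param config An [mlea_config()] (uses `Pc`).
#' @param max_tries Construction retries before falling back to a parent.
#' @return An igraph object with the parents' degree sequence.
#' @export
crossover <- function(pa, pb, config, max_tries = 20L) {
  ga <- pa$graph; gb <- pb$graph
  if (!identical(degree_sequence(ga), degree_sequence(gb)))
    stop("parents must share one degree sequence", call. = FALSE)
  if (stats::runif(1) >= config$Pc) {
    return(if (stats::runif(1) < 0.5) ga else gb)
  }
  n <- igraph::vcount(ga)
  ka <- edge_keys(ga); kb <- edge_keys(gb)
  common <- intersect(ka, kb)
  symdiff <- setdiff(union(ka, kb), common)
  target <- degree_sequence(ga)
  fitter <- if (compare_solutions(pa, pb) >= 0L) ga else gb

  if (length(symdiff) == 0L) return(ga) # identical parents

  for (try in seq_len(max_tries)) {
    keys <- common
    deg <- integer(n)
    ce <- keys_to_edges(keys, n)
    for (idx in seq_along(keys)) {
      deg[ce[1L, idx]] <- deg[ce[1L, idx]] + 1L
      deg[ce[2L, idx]] <- deg[ce[2L, idx]] + 1L
    }
    # fill deficits from the shuffled symmetric difference
    for (key in sample(symdiff)) {
      ab <- keys_to_edges(key, n)
      if (deg[ab[1L]] < target[ab[1L]] && deg[ab[2L]] < target[ab[2L]]) {
        keys <- c(keys, key)
        deg[ab[1L]] <- deg[ab[1L]] + 1L
        deg[ab[2L]] <- deg[ab[2L]] + 1L
      }
    }
    # pair residual stubs randomly
    stubs <- rep(seq_len(n), pmax(target - deg, 0L))
    ok <- TRUE
    if (length(stubs) > 0L) {
      ok <- FALSE
      for (shuffle in seq_len(50L)) {
        perm <- sample(stubs)
        new_keys <- numeric(0)
        good <- TRUE
        for (q in seq_len(length(perm) / 2L)) {
          a <- perm[2L * q - 1L]; b <- perm[2L * q]
          if (a == b) { good <- FALSE; break }
          key <- min(a, b) * (n + 1) + max(a, b)
          if (key %in% keys || key %in% new_keys) { good <- FALSE; break }
          new_keys <- c(new_keys, key)
        }
        if (good) {
          keys <- c(keys, new_keys)
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) next
    child <- igraph::make_empty_graph(n, directed = FALSE)
    child <- igraph::add_edges(child, keys_to_edges(keys, n))
    if (graph_is_connected(child)) return(child)
  }
  fitter
}

#' The multilevel local-search operator
#'
#' Hill-climbing over degree-preserving edge switches, augmented with the
#' restoration-list memory.  The working aggregate is reset to the latest
#' single evaluation (`sum = avg`, `num = 1`).  Then, for every node `i` in
#' identifier order and each of its incident edges, with probability
#' `min(1, beta * d_i / sum(d))` an edge switch is proposed and the adjusted
#' structure evaluated once (with the configured first-evaluation sampling):
#'
#' * rejected (disconnected, or adjusted `avg` not above the current one):
#'   the current structure is re-evaluated once more, its aggregate updated,
#'   and its backup synchronized if one is linked — promising survivors thus
#'   accumulate samples and their estimate sharpens;
#' * accepted with the current `avg` above the pyramid top: the current
#'   solution is backed up (insertion rule, then mutation rule on failure),
#'   the pyramid sorted, and the adjusted structure adopted with a fresh
#'   aggregate;
#' * accepted but with the pyramid top above the adjusted `avg`: the top
#'   record is restored as the working solution (it keeps its aggregate and
#'   is linked as its own backup);
#' * otherwise the adjusted structure is adopted with a fresh aggregate.
#'
#' @param sol Working [solution()] (evaluated at least once).
#' @param k Pyramid index associated with this population slot (1-based).
#' @param rl The run's [restoration_list()].
#' @param config An [mlea_config()].
#' @param evaluator Counting evaluator from [make_evaluator()].
#' @return The final working [solution()].
#' @export
multilevel_operator <- function(sol, k, rl, config, evaluator) {
  g <- sol$graph
  sumv <- sol_avg(sol) # reset aggregate to the incoming mean
  numv <- 1L
  avg <- sumv
  flag_list <- FALSE
  deg <- degree_sequence(g) # invariant under every edge switch
  total_deg <- sum(deg)

  for (i in seq_along(deg)) {
    p_attempt <- min(1, config$beta * deg[i] / total_deg)
    for (e in seq_len(deg[i])) {
      if (stats::runif(1) >= p_attempt) next
      prop <- node_select(g)
      if (!prop$found) next
      g2 <- edge_switch(g, prop)
      fa <- evaluator$first(g2, config$init_samples)
      avg2 <- fa$sum / fa$num
      if (!graph_is_connected(g2) || avg2 <= avg) {
        # rejection branch: re-sample the current structure
        numv <- numv + 1L
        sumv <- sumv + evaluator$once(g)
        avg <- sumv / numv
        if (flag_list) record_synchronize(rl, k, sumv, numv)
      } else {
        avg_top <- pyramid_top_avg(rl, k)
        if (avg > avg_top) {
          backup <- solution(g, sumv, numv)
          if (!insert_record(rl, k, backup)) {
            recs <- pyramid_records(rl, k)
            for (m in rev(seq_along(recs)) - 1L) { # bottom level first
              if (sol_avg(recs[[m + 1L]]) < avg &&
                  mutation_replace(rl, k, m, backup, config$alpha)) break
            }
          }
          sort_pyramid(rl, k)
          g <- g2; sumv <- fa$sum; numv <- fa$num; avg <- avg2
          flag_list <- FALSE
        } else if (avg_top > avg2) {
          rec <- restore_top(rl, k)
          g <- rec$graph; sumv <- rec$sum; numv <- rec$num
          avg <- sol_avg(rec)
          flag_list <- TRUE
          link_backup(rl, k, rec$id)
        } else {
          g <- g2; sumv <- fa$sum; numv <- fa$num; avg <- avg2
          flag_list <- FALSE
        }
      }
    }
  }
  solution(g, sumv, numv)
}

new_mlea_result <- function(best, trajectory, evaluations, config, seed,
                            objective) {
  structure(list(best = best,
                 trajectory = tibble::tibble(generation = seq_along(trajectory),
                                             best_avg = trajectory),
                 evaluations = evaluations, config = config, seed = seed,
                 objective = objective),
            class = "mlea_result")
}

#' @export
print.mlea_result <- function(x, ...) {
  cat(sprintf("<mlea_result> objective=%s best avg=%.4f (num=%d), %d generations, %d evaluations\n",
              x$objective, sol_avg(x$best), x$best$num,
              nrow(x$trajectory), x$evaluations))
  invisible(x)
}

#' Run the multilevel structure optimizer
#'
#' The full loop: initialize `GS` degree-preserving variants of `g0`; each
#' generation, roulette-select parents and produce `GS` offspring by
#' degree-preserving crossover plus edge-swap mutation; apply the
#' [multilevel_operator()] to every parent and offspring against its own
#' pyramid of the restoration list; keep the best `GS` solutions by mean
#' fitness.  Every candidate ever created has `g0`'s degree sequence and is
#' connected.
#'
#' @param g0 Connected simple igraph object to optimize.
#' @param config An [mlea_config()].
#' @param evaluator Optional counting evaluator; defaults to the
#'   cooperation-level evaluator implied by `config`.  Supplying e.g. a
#'   deterministic or synthetically noisy objective turns the same machinery
#'   into a generic degree-preserving structure optimizer.
#' @return An object of class `mlea_result`: fields `best` (a
#'   [solution()]), `trajectory` (tibble of per-generation best `avg`),
#'   `evaluations` (audited evaluation count), `config`, `seed`,
#'   `objective`.
#' @export
run_mlea <- function(g0, config = mlea_config(), evaluator = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  objective <- if (is.null(evaluator)) "cooperation" else "custom"
  if (is.null(evaluator)) evaluator <- make_coop_evaluator(config)
  validate_graph(g0, connected = TRUE)

  pop <- initialize_population(g0, config, evaluator)
  rl <- restoration_list(2L * config$GS, config$max_levels)
  traj <- numeric(config$gen_max)

  for (gen in seq_len(config$gen_max)) {
    offspring <- vector("list", config$GS)
    for (o in seq_len(config$GS)) {
      pidx <- roulette_select(pop)
      child <- crossover(pop[[pidx[1L]]], pop[[pidx[2L]]], config)
      child <- mutate_swaps(child, config$mutation_swaps)
      fa <- evaluator$first(child, config$init_samples)
      offspring[[o]] <- solution(child, fa$sum, fa$num)
    }
    all_sol <- c(pop, offspring)
    for (kk in seq_along(all_sol)) {
      all_sol[[kk]] <- multilevel_operator(all_sol[[kk]], kk, rl, config,
                                           evaluator)
    }
    avgs <- vapply(all_sol, sol_avg, numeric(1))
    pop <- all_sol[order(-avgs)][seq_len(config$GS)] # stable ranking
    traj[gen] <- sol_avg(pop[[1L]])
  }
  new_mlea_result(pop[[1L]], traj, evaluator$count(), config, config$seed,
                  objective)
}

#' Baseline: optimize the clustering coefficient
#'
#' The comparative optimizer shares the EA skeleton of [run_mlea()] but its
#' objective is the deterministic mean local clustering coefficient, its
#' local search is the canonical accept-if-better hill climb over the same
#' edge-switch proposals, and it uses no restoration list or re-sampling.
#'
#' @param g0 Connected simple igraph object.
#' @param config An [mlea_config()]; `gen_max` defaults to 120 here if the
#'   config was built with [mlea_config()] defaults unchanged, pass
#'   `gen_max` explicitly to control it.
#' @return An `mlea_result` whose `best` solution carries the final
#'   clustering coefficient as its `avg`.
#' @export
run_ea_cluster <- function(g0, config = mlea_config(gen_max = 120L)) {
  if (!is.null(config$seed)) set.seed(config$seed)
  validate_graph(g0, connected = TRUE)
  evaluator <- make_evaluator(clustering_coefficient, init_samples = 1L)

  pop <- initialize_population(g0, config, evaluator)
  traj <- numeric(config$gen_max)
  deg <- degree_sequence(g0)
  total_deg <- sum(deg)

  climb <- function(sol) {
    g <- sol$graph
    fit <- sol_avg(sol)
    for (i in seq_along(deg)) {
      p_attempt <- min(1, config$beta * deg[i] / total_deg)
      for (e in seq_len(deg[i])) {
        if (stats::runif(1) >= p_attempt) next
        prop <- node_select(g)
        if (!prop$found) next
        g2 <- edge_switch(g, prop)
        fit2 <- evaluator$once(g2)
        if (graph_is_connected(g2) && fit2 > fit) {
          g <- g2
          fit <- fit2
        }
      }
    }
    solution(g, fit, 1L)
  }

  for (gen in seq_len(config$gen_max)) {
    offspring <- vector("list", config$GS)
    for (o in seq_len(config$GS)) {
      pidx <- roulette_select(pop)
      child <- crossover(pop[[pidx[1L]]], pop[[pidx[2L]]], config)
      child <- mutate_swaps(child, config$mutation_swaps)
      offspring[[o]] <- solution(child, evaluator$once(child), 1L)
    }
    all_sol <- c(pop, lapply(offspring, climb))
    all_sol[seq_len(config$GS)] <- lapply(all_sol[seq_len(config$GS)], climb)
    avgs <- vapply(all_sol, sol_avg, numeric(1))
    pop <- all_sol[order(-avgs)][seq_len(config$GS)]
    traj[gen] <- sol_avg(pop[[1L]])
  }
  new_mlea_result(pop[[1L]], traj, evaluator$count(), config, config$seed,
                  "clustering")
}
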