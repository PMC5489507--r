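const_evaluator <- function(value) make_evaluator(function(g) value)

test_that("population initialization preserves structure and sampling plan", {
  set.seed(3)
  g0 <- generate_ba(60, 2)
  cfg <- mlea_config(GS = 4, init_samples = 5)
  ev <- const_evaluator(0.4)
  pop <- initialize_population(g0, cfg, ev)
  expect_length(pop, 4)
  for (s in pop) {
    expect_equal(sort(degree_sequence(s$graph)), sort(degree_sequence(g0)))
    expect_true(graph_is_connected(s$graph))
    expect_equal(s$num, 5L)
    expect_equal(sol_avg(s), 0.4)
  }
  expect_equal(ev$count(), 20L) # 4 members x 5 first-evaluation samples
  expect_error(initialize_population(igraph::make_ring(4) +
                                       igraph::make_ring(3), cfg, ev),
               "connected")
})

test_that("roulette selection is fitness-proportional with uniform fallbacks", {
  pop <- list(solution(igraph::make_ring(5), 1, 1),
              solution(igraph::make_ring(5), 3, 1))
  set.seed(10)
  n_draws <- 1e5
  draws <- replicate(n_draws, roulette_select(pop)[1])
  p_hat <- mean(draws == 2)
  se <- sqrt(0.75 * 0.25 / n_draws)
  expect_lt(abs(p_hat - 0.75), 3 * se)
  # all-zero fitness: uniform
  pop0 <- list(solution(igraph::make_ring(5), 0, 1),
               solution(igraph::make_ring(5), 0, 1))
  draws0 <- replicate(2e4, roulette_select(pop0)[1])
  expect_lt(abs(mean(draws0 == 1) - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("crossover keeps common edges and the exact degree sequence", {
  set.seed(21)
  g <- generate_ba(20, 2)
  pa <- solution(g, 0.5, 1)
  # second parent differs by one accepted double swap (<= 4 edge difference)
  g2 <- g
  repeat {
    g2 <- simple_edge_swap(g)
    if (isTRUE(igraph::graph_attr(g2, "swapped")) && graph_is_connected(g2))
      break
  }
  pb <- solution(g2, 0.6, 1)
  common <- intersect(sorted_edge_keys(g), sorted_edge_keys(g2))
  cfg <- mlea_config(Pc = 1)
  for (i in 1:100) {
    child <- crossover(pa, pb, cfg)
    expect_equal(degree_sequence(child), degree_sequence(g))
    expect_true(graph_is_connected(child))
    expect_true(all(common %in% sorted_edge_keys(child)))
  }
  # identical parents reproduce themselves
  child <- crossover(pa, pa, cfg)
  expect_true(graph_identical(child, g))
  # mismatched degree sequences are a contract error
  set.seed(22)
  expect_error(crossover(pa, solution(generate_ba(20, 3), 0.5, 1), cfg),
               "degree sequence")
  # Pc = 0 always returns a parent copy
  cfg0 <- mlea_config(Pc = 0)
  child0 <- crossover(pa, pb, cfg0)
  expect_true(graph_identical(child0, g) || graph_identical(child0, g2))
})

test_that("constant fitness drives every proposal through the rejection path", {
  set.seed(30)
  g0 <- generate_ba(40, 2)
  cfg <- mlea_config(GS = 2, beta = 20, max_levels = 3)
  ev <- const_evaluator(0.5)
  rl <- restoration_list(4, 3)
  out <- multilevel_operator(solution(g0, 0.5, 1), 1, rl, cfg, ev)
  expect_true(graph_identical(out$graph, g0)) # graph never changes
  expect_gt(out$num, 1L) # every attempt re-samples the current structure
  expect_equal(sol_avg(out), 0.5)
  expect_length(pyramid_records(rl, 1), 0) # nothing was ever backed up
})

test_that("with a noise-free objective the operator is a hill climber", {
  set.seed(33)
  g0 <- generate_hk(60, 2, 0.3)
  cfg <- mlea_config(GS = 2, max_levels = 3)
  ev <- make_evaluator(clustering_coefficient)
  rl <- restoration_list(4, 3)
  cc0 <- clustering_coefficient(g0)
  out <- multilevel_operator(solution(g0, cc0, 1), 1, rl, cfg, ev)
  expect_gte(sol_avg(out), cc0)
  expect_equal(sol_avg(out), clustering_coefficient(out$graph),
               tolerance = 1e-12)
})

test_that("run_mlea on a deterministic objective is elitist end to end", {
  set.seed(40)
  g0 <- generate_hk(60, 2, 0.3)
  cfg <- mlea_config(GS = 3, gen_max = 4, max_levels = 3, seed = 8)
  res <- run_mlea(g0, cfg, evaluator = make_evaluator(clustering_coefficient))
  expect_true(all(diff(res$trajectory$best_avg) >= 0))
  expect_equal(sort(degree_sequence(res$best$graph)),
               sort(degree_sequence(g0)))
  expect_true(graph_is_connected(res$best$graph))
  expect_gte(sol_avg(res$best), clustering_coefficient(g0))
})

test_that("the audited evaluation count equals the simulator invocations", {
  calls <- new.env(); calls$n <- 0L
  fn <- function(g) { calls$n <- calls$n + 1L; clustering_coefficient(g) }
  set.seed(50)
  g0 <- generate_ba(40, 2)
  res <- run_mlea(g0, mlea_config(GS = 2, gen_max = 2, seed = 5),
                  evaluator = make_evaluator(fn, init_samples = 2))
  expect_equal(res$evaluations, calls$n)
  expect_gt(res$evaluations, 0L)
})

test_that("deeper pyramids resist noisy fitness better than lv1", {
  # true score = clustering coefficient; evaluations add N(0, 0.05) noise
  noisy <- function(g) clustering_coefficient(g) + stats::rnorm(1, 0, 0.05)
  set.seed(60)
  g0 <- generate_hk(50, 2, 0.3)
  wins <- 0L
  for (i in 1:10) {
    seed_i <- 1000L + i
    r1 <- run_mlea(g0, variant_config("lv1", gen_max = 2, seed = seed_i),
                   evaluator = make_evaluator(noisy))
    r5 <- run_mlea(g0, variant_config("lv5", gen_max = 2, seed = seed_i),
                   evaluator = make_evaluator(noisy))
    if (clustering_coefficient(r5$best$graph) >=
        clustering_coefficient(r1$best$graph)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 6L)
})

test_that("baseline clustering optimizer improves monotonically", {
  set.seed(70)
  g0 <- generate_hk(60, 2, 0.5)
  cc0 <- clustering_coefficient(g0)
  res <- run_ea_cluster(g0, mlea_config(GS = 3, gen_max = 5, seed = 9))
  expect_equal(res$objective, "clustering")
  expect_true(all(diff(res$trajectory$best_avg) >= 0))
  expect_gt(sol_avg(res$best), cc0)
  expect_equal(sort(degree_sequence(res$best$graph)),
               sort(degree_sequence(g0)))
})

test_that("variant presets match their published settings", {
  expect_equal(variant_config("lv1")[c("max_levels", "alpha", "init_samples")],
               list(max_levels = 1L, alpha = 0, init_samples = 1L))
  expect_equal(variant_config("lv1-M")$init_samples, 5L)
  expect_equal(variant_config("lv5")[c("max_levels", "alpha")],
               list(max_levels = 5L, alpha = 0.5))
  expect_equal(variant_config("lv10")$max_levels, 10L)
  cfg <- mlea_config()
  expect_equal(cfg$GS, 6L)
  expect_equal(cfg$gen_max, 30L)
  expect_equal(cfg$beta, 20)
  expect_equal(cfg$pp$r, 0.95)
})

test_that("tidy, glance and autoplot expose the run", {
  set.seed(80)
  g0 <- generate_ba(40, 2)
  res <- run_mlea(g0, mlea_config(GS = 2, gen_max = 3, seed = 4),
                  evaluator = make_evaluator(clustering_coefficient))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(res)
  expect_equal(gl$evaluations, res$evaluations)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
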