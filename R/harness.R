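#' Specification of a structure-optimization experiment
#'
#' @param family Network family, `"ba"` or `"hk"`.
#' @param n Nodes per structure.
#' @param m_attach Edges per new node for the generator.
#' @param p_triad Triad-formation probability (HK family only).
#' @param replicates Independent initial structures per group.
#' @param variants Character vector of optimizer variants (see
#'   [variant_config()]).
#' @param rule An [update_rule()].
#' @param r Cost-to-benefit ratio.
#' @param mode An [evaluation_mode()].
#' @param gen_max EA generations per run.
#' @param post_samples Independent evaluations used for post-hoc scoring of
#'   the initial and optimized structures (the headline assessment protocol;
#'   default 200, configurable up to full scale).
#' @param seed Master seed; every run derives its own sub-seed from it.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(family = c("ba", "hk"), n = 200L, m_attach = 2L,
                            p_triad = 0.5, replicates = 5L,
                            variants = "lv5",
                            rule = update_rule("recolonize"), r = 0.95,
                            mode = mode_a(), gen_max = 10L,
                            post_samples = 200L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(replicates >= 1, post_samples >= 1)
  structure(list(family = family, n = as.integer(n),
                 m_attach = as.integer(m_attach), p_triad = p_triad,
                 replicates = as.integer(replicates), variants = variants,
                 rule = rule, r = r, mode = mode,
                 gen_max = as.integer(gen_max),
                 post_samples = as.integer(post_samples),
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

# deterministic small sub-seed derived from a master seed and labels
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

spec_graph <- function(spec, replicate) {
  set.seed(derive_seed(spec$seed, "graph", replicate))
  if (spec$family == "ba") {
    generate_ba(spec$n, spec$m_attach)
  } else {
    generate_hk(spec$n, spec$m_attach, spec$p_triad)
  }
}

#' Distribution of independent equilibrium evaluations
#'
#' Evaluates one structure `n_evals` times under each evaluation mode and
#' returns every sample, ready for summarizing or plotting.  This is the
#' diagnostic behind the package's treatment of fitness noise: the spread of
#' this distribution is what misleads a naive EA.
#'
#' @param g A connected igraph object.
#' @param n_evals Independent evaluations per mode (>= 2).
#' @param modes Named list of [evaluation_mode()]s.
#' @param rule An [update_rule()].
#' @param pp A [payoff_params()].
#' @return A tibble with columns `mode`, `sample`, `coop`.
#' @seealso [distribution_summary()], [plot_distribution()]
#' @export
run_distribution_study <- function(g, n_evals,
                                   modes = list("Mode-A" = mode_a()),
                                   rule = update_rule("recolonize"),
                                   pp = payoff_params()) {
  stopifnot(n_evals >= 2)
  out <- lapply(names(modes), function(mn) {
    coop <- vapply(seq_len(n_evals), function(s) {
      evaluate_cooperation(g, rule, pp, modes[[mn]])$avg
    }, numeric(1))
    tibble::tibble(mode = mn, sample = seq_len(n_evals), coop = coop)
  })
  dplyr::bind_rows(out)
}

#' Summarize an evaluation distribution
#'
#' @param samples A tibble from [run_distribution_study()].
#' @param bins Number of histogram bins over `[0, 1]`.
#' @return A tibble with one row per mode: `n`, `mean`, `sd`, and a
#'   list-column `hist` of bin counts.
#' @export
distribution_summary <- function(samples, bins = 20L) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  samples |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$coop),
      sd = stats::sd(.data$coop),
      hist = list(graphics::hist(.data$coop, breaks = breaks,
                                 plot = FALSE)$counts),
      .groups = "drop"
    )
}

#' Run a variant-comparison experiment
#'
#' For each replicate structure and each optimizer variant: generate the
#' initial structure, optimize it, and score both the initial and the
#' optimized structure post hoc with `post_samples` independent evaluations.
#' Failed runs are recorded with an error message rather than dropped.
#'
#' @param spec An [experiment_spec()].
#' @return A tibble with one row per replicate x variant: `replicate`,
#'   `variant`, `seed`, `coop_initial`, `coop_optimized`, `evaluations`,
#'   `error`.
#' @export
run_comparison <- function(spec) {
  pp <- payoff_params(spec$r)
  rows <- list()
  for (rep_i in seq_len(spec$replicates)) {
    g0 <- spec_graph(spec, rep_i)
    set.seed(derive_seed(spec$seed, "post", rep_i))
    coop0 <- multi_sample_evaluate(g0, spec$post_samples, spec$rule, pp,
                                   spec$mode)$avg
    for (v in spec$variants) {
      run_seed <- derive_seed(spec$seed, "run", rep_i, v)
      row <- tibble::tibble(replicate = rep_i, variant = v, seed = run_seed,
                            coop_initial = coop0, coop_optimized = NA_real_,
                            evaluations = NA_integer_, error = NA_character_)
      res <- tryCatch({
        cfg <- variant_config(v, gen_max = spec$gen_max, rule = spec$rule,
                              pp = pp, mode = spec$mode, seed = run_seed)
        run_mlea(g0, cfg)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        set.seed(derive_seed(spec$seed, "post-opt", rep_i, v))
        row$coop_optimized <- multi_sample_evaluate(
          res$best$graph, spec$post_samples, spec$rule, pp, spec$mode)$avg
        row$evaluations <- res$evaluations
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Group-level summary of a comparison table
#'
#' @param results A tibble from [run_comparison()].
#' @return One row per variant: mean initial and optimized cooperation,
#'   per-structure range of the optimized scores, mean evaluation count.
#' @export
comparison_summary <- function(results) {
  results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_initial = mean(.data$coop_initial),
      mean_optimized = mean(.data$coop_optimized),
      min_optimized = min(.data$coop_optimized),
      max_optimized = max(.data$coop_optimized),
      mean_evaluations = mean(.data$evaluations),
      .groups = "drop"
    )
}

#' Deterministic test fixtures
#'
#' Builds the small hand-checkable graphs used throughout the test suite
#' (triangle, K4 minus an edge, 6-cycle, 3-path, the edge-switch gadget, two
#' squares sharing a node) plus seeded BA/HK structures.
#'
#' @param seed Seed for the random structures.
#' @param sizes Node counts of the seeded BA/HK graphs.
#' @param dir Optional directory; when given, every fixture is also written
#'   as an edge-list file.
#' @return Named list of igraph objects.
#' @export
make_fixtures <- function(seed = 1L, sizes = c(200L, 300L, 500L),
                          dir = NULL) {
  fx <- list(
    k3 = igraph::make_full_graph(3),
    k4_minus_edge = igraph::delete_edges(igraph::make_full_graph(4), 1),
    path3 = igraph::make_graph(c(1, 2, 2, 3), directed = FALSE),
    cycle6 = igraph::make_ring(6),
    # u = 1 adjacent to i = 2 and j = 3; j-k edge (3-4); i-m edge (2-5)
    switch_gadget = igraph::make_graph(c(1, 2, 1, 3, 3, 4, 2, 5),
                                       directed = FALSE),
    # two 4-cycles joined at node 1
    two_squares = igraph::make_graph(
      c(1, 2, 2, 3, 3, 4, 4, 1, 1, 5, 5, 6, 6, 7, 7, 1), directed = FALSE)
  )
  for (n in sizes) {
    set.seed(derive_seed(seed, "ba", n))
    fx[[paste0("ba", n)]] <- generate_ba(n, 2L)
    set.seed(derive_seed(seed, "hk", n))
    fx[[paste0("hk", n)]] <- generate_hk(n, 2L, 0.5)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(fx)) {
      write_edgelist(fx[[nm]], file.path(dir, paste0(nm, ".edgelist")))
    }
  }
  fx
}
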