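#' Solutions and the restoration-list memory
#'
#' A *solution* couples a population structure (graph) with its running
#' evaluation aggregate.  The *restoration list* is the optimizer's defense
#' against noisy-fitness selection errors: `2 * GS` pyramid-shaped sub-lists,
#' one per working-population slot, each holding up to `max_levels` backed-up
#' solutions sorted by their mean evaluated cooperation level (`avg`), best
#' on top.  When a promising working solution is displaced by a lucky but
#' actually worse rival, the top record can be restored.
#'
#' The list has reference semantics (it is an environment): insertion,
#' mutation-replacement, sorting and synchronization mutate it in place.
#' Pyramid indices are 1-based.
#'
#' @name restoration-memory
#' @keywords internal
NULL

#' Create a solution
#'
#' @param graph An igraph object.
#' @param sum Sum of evaluation results for this structure.
#' @param num Number of evaluations aggregated in `sum` (>= 1).
#' @return An object of class `pd_solution` with fields `graph`, `sum`,
#'   `num`.
#' @export
solution <- function(graph, sum, num = 1L) {
  stopifnot(num >= 1)
  structure(list(graph = graph, sum = sum, num = as.integer(num)),
            class = "pd_solution")
}

#' Mean evaluated fitness of a solution
#'
#' @param sol A `pd_solution`.
#' @return `sum / num`.
#' @export
sol_avg <- function(sol) sol$sum / sol$num

#' @export
print.pd_solution <- function(x, ...) {
  cat(sprintf("<pd_solution> avg=%.4f (num=%d) on %d nodes / %d edges\n",
              sol_avg(x), x$num, igraph::vcount(x$graph),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Create an empty restoration list
#'
#' @param n_pyramids Number of pyramids (one per working-population slot;
#'   `2 * GS` in the full algorithm).
#' @param max_levels Capacity of each pyramid (records per pyramid); level 1
#'   is the top (best).
#' @return An object of class `restoration_list`.
#' @export
restoration_list <- function(n_pyramids, max_levels) {
  stopifnot(n_pyramids >= 1, max_levels >= 1)
  rl <- new.env(parent = emptyenv())
  rl$n_pyramids <- as.integer(n_pyramids)
  rl$max_levels <- as.integer(max_levels)
  rl$records <- rep(list(list()), n_pyramids) # each: list of pd_solutions
  rl$backup_id <- rep(NA_integer_, n_pyramids) # record id backing the ontology
  rl$next_id <- 1L
  class(rl) <- "restoration_list"
  rl
}

#' @export
print.restoration_list <- function(x, ...) {
  cat(sprintf("<restoration_list> %d pyramids, capacity %d\n",
              x$n_pyramids, x$max_levels))
  for (i in seq_len(x$n_pyramids)) {
    if (length(x$records[[i]]) > 0L) {
      avgs <- vapply(x$records[[i]], sol_avg, numeric(1))
      cat(sprintf("  pyramid %d: avg = %s\n", i,
                  paste(sprintf("%.4f", avgs), collapse = ", ")))
    }
  }
  invisible(x)
}

check_pyramid_index <- function(rl, i) {
  if (!(i >= 1L && i <= rl$n_pyramids))
    stop("pyramid index out of range", call. = FALSE)
}

#' Records currently stored in a pyramid
#'
#' @param rl A [restoration_list()].
#' @param i Pyramid index (1-based).
#' @return List of `pd_solution` records, top (best) first once sorted.
#' @export
pyramid_records <- function(rl, i) {
  check_pyramid_index(rl, i)
  rl$records[[i]]
}

#' Mean fitness of a pyramid's top record
#'
#' @inheritParams pyramid_records
#' @return The highest stored `avg`, or `-Inf` for an empty pyramid.
#' @export
pyramid_top_avg <- function(rl, i) {
  check_pyramid_index(rl, i)
  recs <- rl$records[[i]]
  if (length(recs) == 0L) return(-Inf)
  max(vapply(recs, sol_avg, numeric(1)))
}

#' Back up a solution into a pyramid (insertion rule)
#'
#' If pyramid `i` has a vacant slot the solution is appended at the bottom.
#' Otherwise one stored record with strictly smaller `avg` and `num` no
#' larger than the candidate's is evicted (the worst-`avg` such record);
#' if no record qualifies, the solution is not backed up.
#'
#' @inheritParams pyramid_records
#' @param sol The `pd_solution` to back up.
#' @param link If `TRUE`, mark the stored record as the backup of the
#'   caller's current working solution so that [record_synchronize()] can
#'   update it later.
#' @return `TRUE` if the solution was stored, `FALSE` otherwise.
#' @export
insert_record <- function(rl, i, sol, link = FALSE) {
  check_pyramid_index(rl, i)
  recs <- rl$records[[i]]
  if (length(recs) >= rl$max_levels) {
    avgs <- vapply(recs, sol_avg, numeric(1))
    nums <- vapply(recs, function(r) r$num, integer(1))
    cand <- which(avgs < sol_avg(sol) & nums <= sol$num)
    if (length(cand) == 0L) return(FALSE)
    evict <- cand[[which.min(avgs[cand])]]
    if (identical(rl$backup_id[[i]], recs[[evict]]$id))
      rl$backup_id[[i]] <- NA_integer_
    recs[[evict]] <- NULL
  }
  sol$id <- rl$next_id
  rl$next_id <- rl$next_id + 1L
  recs[[length(recs) + 1L]] <- sol
  rl$records[[i]] <- recs
  if (link) rl$backup_id[[i]] <- sol$id
  TRUE
}

#' Probabilistic replacement of a stored record (mutation rule)
#'
#' When the insertion rule could not store a solution whose `avg` exceeds
#' that of record at level `m`, the solution may still replace that record
#' with probability `alpha ^ (max_levels - m)`, where `m` is the 0-based
#' level index from the top.  With `alpha = 0` every record is protected;
#' with `alpha = 1` replacement is certain.
#'
#' @inheritParams insert_record
#' @param m 0-based level index from the top (0 = top record).
#' @param alpha Mutation-rule base probability in `[0, 1]`.
#' @return `TRUE` if the record was replaced.
#' @export
mutation_replace <- function(rl, i, m, sol, alpha) {
  check_pyramid_index(rl, i)
  stopifnot(alpha >= 0, alpha <= 1)
  recs <- rl$records[[i]]
  if (!(m >= 0L && m < length(recs)))
    stop("level index out of range", call. = FALSE)
  old <- recs[[m + 1L]]
  if (!(sol_avg(sol) > sol_avg(old)))
    stop("mutation rule requires a candidate with larger avg", call. = FALSE)
  if (stats::runif(1) >= alpha^(rl$max_levels - m)) return(FALSE)
  if (identical(rl$backup_id[[i]], old$id)) rl$backup_id[[i]] <- NA_integer_
  sol$id <- rl$next_id
  rl$next_id <- rl$next_id + 1L
  recs[[m + 1L]] <- sol
  rl$records[[i]] <- recs
  TRUE
}

#' Sort a pyramid by mean fitness (sort rule)
#'
#' Stable descending sort by `avg`: the top slot holds the best record and
#' equal-`avg` records keep their relative order.
#'
#' @inheritParams pyramid_records
#' @return The restoration list, invisibly.
#' @export
sort_pyramid <- function(rl, i) {
  check_pyramid_index(rl, i)
  recs <- rl$records[[i]]
  if (length(recs) > 1L) {
    avgs <- vapply(recs, sol_avg, numeric(1))
    rl$records[[i]] <- recs[order(-avgs)] # base order() is stable
  }
  invisible(rl)
}

#' Synchronize a working solution's backup (information update rule)
#'
#' When the working solution linked to pyramid `i` accumulates further
#' evaluations, its stored backup must reflect the same `sum` and `num`.
#' The stored graph is never touched; the pyramid is re-sorted afterwards.
#'
#' @inheritParams pyramid_records
#' @param sum,num The ontology's updated aggregate.
#' @return `TRUE` if a linked backup was updated, `FALSE` (with a warning)
#'   when no backup is linked.
#' @export
record_synchronize <- function(rl, i, sum, num) {
  check_pyramid_index(rl, i)
  id <- rl$backup_id[[i]]
  if (is.na(id)) {
    warning("no linked backup in pyramid ", i, "; nothing synchronized",
            call. = FALSE)
    return(FALSE)
  }
  recs <- rl$records[[i]]
  hit <- which(vapply(recs, function(r) identical(r$id, id), logical(1)))
  if (length(hit) != 1L) {
    warning("linked backup vanished from pyramid ", i, call. = FALSE)
    rl$backup_id[[i]] <- NA_integer_
    return(FALSE)
  }
  recs[[hit]]$sum <- sum
  recs[[hit]]$num <- as.integer(num)
  rl$records[[i]] <- recs
  sort_pyramid(rl, i)
  TRUE
}

#' Restore the top record of a pyramid
#'
#' Returns a copy of the best backed-up solution; the list itself is not
#' modified.  The caller replaces its working solution with the copy and may
#' link it back via `link_backup()` semantics (handled inside the
#' optimizer).
#'
#' @inheritParams pyramid_records
#' @return A `pd_solution` (value copy; mutating it does not alter the
#'   stored record).
#' @export
restore_top <- function(rl, i) {
  check_pyramid_index(rl, i)
  recs <- rl$records[[i]]
  if (length(recs) == 0L) stop("pyramid ", i, " is empty", call. = FALSE)
  avgs <- vapply(recs, sol_avg, numeric(1))
  recs[[which.max(avgs)]]
}

# Mark the record with the given id as the backup of pyramid i's ontology.
link_backup <- function(rl, i, id) {
  check_pyramid_index(rl, i)
  rl$backup_id[[i]] <- id
  invisible(rl)
}

#' Compare two solutions by mean fitness (strategy 1)
#'
#' The population-level comparison ignores sampling counts entirely:
#' a solution is better iff its `avg` is larger.
#'
#' @param a,b `pd_solution` objects.
#' @return `1` if `a` is better, `-1` if `b` is better, `0` on a tie.
#' @export
compare_solutions <- function(a, b) {
  da <- sol_avg(a); db <- sol_avg(b)
  if (da > db) 1L else if (da < db) -1L else 0L
}

#' Three-way comparison against a stored record (strategy 2)
#'
#' Given the current working solution, its one-edge-switch variant, and a
#' pyramid record: the record wins only when
#' `avg_current < avg_adjusted < avg_record`; the current solution wins only
#' when `avg_adjusted > avg_current > avg_record`; anything else is neither.
#' This verdict selects among the acceptance branches of the multilevel
#' operator.
#'
#' @param current,adjusted,record `pd_solution` objects; `adjusted` derives
#'   from `current` by one edge switch.
#' @return One of `"record-wins"`, `"current-wins"`, `"neither"`.
#' @export
compare_with_record <- function(current, adjusted, record) {
  ac <- sol_avg(current); aa <- sol_avg(adjusted); ar <- sol_avg(record)
  if (ac < aa && aa < ar) "record-wins"
  else if (aa > ac && ac > ar) "current-wins"
  else "neither"
}

#' Dump restoration-list state as JSON lines
#'
#' One JSON object per stored record: pyramid, level (0-based from top after
#' sorting), `avg`, `num`, and a hash of the stored graph's sorted edge
#' list.  Intended for debugging and test assertions.
#'
#' @param rl A [restoration_list()].
#' @param con A connection or file path (default: standard output).
#' @return The JSON lines, invisibly, as a character vector.
#' @export
dump_restoration_list <- function(rl, con = stdout()) {
  lines <- character(0)
  for (i in seq_len(rl$n_pyramids)) {
    sort_pyramid(rl, i)
    recs <- rl$records[[i]]
    for (m in seq_along(recs)) {
      r <- recs[[m]]
      lines <- c(lines, jsonlite::toJSON(
        list(pyramid = i, level = m - 1L, avg = sol_avg(r), num = r$num,
             graph_hash = graph_hash(r$graph)),
        auto_unbox = TRUE, digits = NA))
    }
  }
  if (!is.null(con)) writeLines(lines, con)
  invisible(lines)
}

# Deterministic content hash of a graph's sorted 0-based edge list.
graph_hash <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  txt <- paste(el[, 1L], el[, 2L], collapse = ";")
  # small polynomial rolling hash, hex encoded (stays in exact double range)
  h <- 0
  for (ch in utf8ToInt(txt)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}
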