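#' Tidy a Physarum graph into its edge table
#'
#' @param x a `physarum_graph`.
#' @param ... unused.
#' @return A tibble: `region_a`, `region_b`, `count`, `p`.
#' @export
tidy.physarum_graph <- function(x, ...) {
  x$edges
}

#' @rdname tidy.physarum_graph
#' @export
tidy.threshold_graph <- function(x, ...) {
  x$edges
}

#' Tidy a skeleton graph into its edge list
#' @param x a `skeleton_graph`.
#' @param ... unused.
#' @return A tibble: `node_a`, `node_b`, `length_cells`.
#' @export
tidy.skeleton_graph <- function(x, ...) {
  nm <- node_names(x$nodes)
  tibble::tibble(
    node_a = nm[match(x$edges$from, x$nodes$id)],
    node_b = nm[match(x$edges$to, x$nodes$id)],
    length_cells = x$edges$length
  )
}

#' Tidy an adjacency record into region pairs
#' @param x an `adjacency_record`.
#' @param ... unused.
#' @return A tibble: `region_a`, `region_b` (observed pairs only).
#' @export
tidy.adjacency_record <- function(x, ...) {
  m <- unclass(x)
  idx <- which(m == 1L & upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    region_a = rownames(m)[idx[, 1]],
    region_b = colnames(m)[idx[, 2]]
  )
}

#' One-row summary of a Physarum graph
#' @param x a `physarum_graph` or `threshold_graph`.
#' @param ... unused.
#' @return A one-row tibble: region/edge/replicate counts, component count,
#'   isolated count, planarity.
#' @export
glance.physarum_graph <- function(x, ...) {
  rep <- connectivity_report(x)
  tibble::tibble(
    n_regions = length(x$regions),
    n_edges = nrow(x$edges),
    n_replicates = x$n_replicates,
    n_components = length(rep$components),
    n_isolated = length(rep$isolated),
    planar = rep$planar
  )
}

#' @rdname glance.physarum_graph
#' @export
glance.threshold_graph <- function(x, ...) {
  out <- glance.physarum_graph(x, ...)
  out$theta <- x$theta
  out
}

#' One-row summary of a finished simulation
#' @param x a `sim_state`.
#' @param ... unused.
#' @return A one-row tibble: step, particle count, trail mass, occupied
#'   fraction.
#' @export
glance.sim_state <- function(x, ...) {
  tibble::tibble(
    step = x$step,
    n_particles = nrow(x$particles),
    trail_mass = sum(x$trail),
    occupied_fraction = mean(x$occupancy > 0)
  )
}
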