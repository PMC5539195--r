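#' Exact edge observation frequency
#'
#' The weight of a Physarum-graph edge: the number of replicates in which a
#' protoplasmic connection was observed divided by the replicate count, kept
#' as an exact rational so threshold comparisons never suffer float-equality
#' hazards (e.g. an edge seen in 3 of 13 experiments has frequency 3/13).
#'
#' @param count observation count, `0 <= count <= n_replicates`.
#' @param n_replicates number of replicate experiments, `>= 1`.
#' @return An `edge_frequency`: list with `numerator`, `denominator`, and
#'   float `value`; `as.numeric()` gives the float view.
#' @export
edge_probability <- function(count, n_replicates) {
  count <- as.integer(count)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (any(count < 0L) || any(count > n_replicates)) {
    stop("count must lie in [0, n_replicates]", call. = FALSE)
  }
  structure(
    list(numerator = count, denominator = n_replicates,
         value = count / n_replicates),
    class = "edge_frequency"
  )
}

#' @export
print.edge_frequency <- function(x, ...) {
  cat(paste0(x$numerator, "/", x$denominator, " = ",
             format(x$value, digits = 6), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.double.edge_frequency <- function(x, ...) x$value

# ---------------------------------------------------------------------------
# Canonical replicate-observation form: a long tibble (replicate, region_a,
# region_b) with region_a < region_b in the region ordering, plus the region
# set and replicate count. Accepts a list of adjacency_record matrices, a
# lab fixture, or an observation tibble.
# ---------------------------------------------------------------------------
as_observations <- function(x, regions = NULL, n_replicates = NULL) {
  if (inherits(x, "lab_fixture")) {
    return(list(obs = x$observations, regions = x$regions,
                n = x$n_replicates))
  }
  if (inherits(x, "adjacency_record")) x <- list(x)
  if (is.list(x) && length(x) > 0L && inherits(x[[1]], "adjacency_record")) {
    reg <- rownames(x[[1]])
    rows <- list()
    for (i in seq_along(x)) {
      m <- x[[i]]
      if (!identical(rownames(m), reg)) {
        stop("replicate records must share one region set", call. = FALSE)
      }
      idx <- which(unclass(m) == 1L & upper.tri(m), arr.ind = TRUE)
      if (nrow(idx)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          replicate = i, region_a = reg[idx[, 1]], region_b = reg[idx[, 2]]
        )
      }
    }
    obs <- if (length(rows)) dplyr::bind_rows(rows) else {
      tibble::tibble(replicate = integer(0), region_a = character(0),
                     region_b = character(0))
    }
    return(list(obs = obs, regions = reg, n = length(x)))
  }
  if (is.data.frame(x)) {
    if (!all(c("replicate", "region_a", "region_b") %in% names(x))) {
      stop("observations need columns replicate, region_a, region_b",
           call. = FALSE)
    }
    obs <- tibble::as_tibble(x)
    obs$region_a <- as.character(obs$region_a)
    obs$region_b <- as.character(obs$region_b)
    if (is.null(regions)) {
      regions <- sort(unique(c(obs$region_a, obs$region_b)))
    }
    if (is.null(n_replicates)) n_replicates <- max(obs$replicate, 1L)
    # canonical pair order
    ia <- match(obs$region_a, regions)
    ib <- match(obs$region_b, regions)
    if (anyNA(ia) || anyNA(ib)) {
      stop("observation regions not in region set", call. = FALSE)
    }
    if (any(ia == ib)) stop("self-loops are not allowed", call. = FALSE)
    swap <- ia > ib
    tmp <- obs$region_a[swap]
    obs$region_a[swap] <- obs$region_b[swap]
    obs$region_b[swap] <- tmp
    obs <- dplyr::distinct(obs, .data$replicate, .data$region_a,
                           .data$region_b)
    return(list(obs = obs, regions = regions, n = as.integer(n_replicates)))
  }
  stop("cannot interpret replicate records", call. = FALSE)
}

#' Build a weighted Physarum graph from replicate records
#'
#' The Physarum graph P = (C, R, p): regions C, the union R of edges
#' observed in at least one replicate, and per-edge frequency
#' p = count / N over the N replicates.
#'
#' @param records a list of `adjacency_record` matrices over one region set,
#'   a long observation tibble (`replicate`, `region_a`, `region_b`), or a
#'   [lab_fixture()].
#' @param regions optional region set (required to retain never-observed
#'   regions when passing a tibble).
#' @param n_replicates optional replicate count N (inferred otherwise).
#' @return A `physarum_graph`: list with `regions`, `edges` (tibble:
#'   `region_a`, `region_b`, `count`, `p`), and `n_replicates`.
#' @export
build_physarum_graph <- function(records, regions = NULL,
                                 n_replicates = NULL) {
  parts <- as_observations(records, regions, n_replicates)
  if (parts$n < 1L) stop("need at least one replicate", call. = FALSE)
  edges <- parts$obs |>
    dplyr::count(.data$region_a, .data$region_b, name = "count") |>
    dplyr::arrange(match(.data$region_a, parts$regions),
                   match(.data$region_b, parts$regions)) |>
    dplyr::mutate(p = .data$count / parts$n)
  structure(
    list(regions = parts$regions, edges = edges, n_replicates = parts$n,
         observations = parts$obs),
    class = "physarum_graph"
  )
}

#' @export
print.physarum_graph <- function(x, ...) {
  cat(sprintf(
    "<physarum_graph> %d regions, %d edges, %d replicates; p in [%s, %s]\n",
    length(x$regions), nrow(x$edges), x$n_replicates,
    if (nrow(x$edges)) sprintf("%d/%d", min(x$edges$count), x$n_replicates)
    else "-",
    if (nrow(x$edges)) sprintf("%d/%d", max(x$edges$count), x$n_replicates)
    else "-"
  ))
  invisible(x)
}

# parse a threshold into an exact rational (num/den).
# character "a/b" -> a/b; integer -> count w (w/N); double -> float
parse_theta <- function(theta, n_replicates) {
  if (is.character(theta)) {
    parts <- strsplit(theta, "/", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      return(list(num = as.numeric(parts[1]), den = as.numeric(parts[2])))
    }
    return(list(num = as.numeric(theta), den = 1))
  }
  if (is.integer(theta)) {
    return(list(num = as.numeric(theta), den = as.numeric(n_replicates)))
  }
  # float: snap to an exact rational over a large denominator
  list(num = round(theta * 720720), den = 720720)
}

#' Threshold transform of a Physarum graph
#'
#' Retains exactly the edges with frequency `p(e) >= theta` (keep at
#' equality). The comparison is exact rational arithmetic:
#' `count / N >= a / b` is evaluated as `count * b >= a * N`, so thresholds
#' written as fractions of the replicate count never suffer float round-off.
#'
#' @param graph a `physarum_graph`.
#' @param theta threshold: a string `"k/N"`, an integer observation count
#'   (interpreted as `k/N`), or a bare numeric frequency in `[0, 1]` (use
#'   fractions or counts when exact equality matters).
#' @return A `threshold_graph`: the parent graph, `theta` (float view),
#'   `theta_num`/`theta_den`, and `edges` — the retained subset T(R).
#' @export
threshold_graph <- function(graph, theta) {
  stopifnot(inherits(graph, "physarum_graph"))
  th <- parse_theta(theta, graph$n_replicates)
  keep <- graph$edges$count * th$den >= th$num * graph$n_replicates
  structure(
    list(parent = graph, theta = th$num / th$den, theta_num = th$num,
         theta_den = th$den, edges = graph$edges[keep, ],
         regions = graph$regions, n_replicates = graph$n_replicates),
    class = "threshold_graph"
  )
}

#' @export
print.threshold_graph <- function(x, ...) {
  cat(sprintf("<threshold_graph> theta = %s; %d of %d edges retained\n",
              format(x$theta, digits = 4), nrow(x$edges),
              nrow(x$parent$edges)))
  invisible(x)
}

graph_igraph <- function(x) {
  edges <- x$edges
  igraph::graph_from_data_frame(
    d = data.frame(from = edges$region_a, to = edges$region_b,
                   weight = edges$count),
    directed = FALSE,
    vertices = data.frame(name = x$regions)
  )
}

#' Edge-weight sweep over replicate records
#'
#' For each integer weight `w` retains the edges observed in at least `w`
#' replicates — identical to the threshold transform at `theta = w/N` — and
#' summarises the resulting connectivity.
#'
#' @param records replicate records (as in [build_physarum_graph()]) or an
#'   existing `physarum_graph`.
#' @param w integer weights to sweep, each in `[1, N]` (default `1:N`).
#' @inheritParams build_physarum_graph
#' @return A tibble with one row per `w`: `w`, `theta`, `n_edges`,
#'   `n_components`, `n_isolated`, `planar`, and the `threshold_graph` in
#'   list-column `graph`.
#' @export
weight_sweep <- function(records, w = NULL, regions = NULL,
                         n_replicates = NULL) {
  P <- if (inherits(records, "physarum_graph")) {
    records
  } else {
    build_physarum_graph(records, regions, n_replicates)
  }
  if (is.null(w)) w <- seq_len(P$n_replicates)
  w <- as.integer(w)
  if (any(w < 1L | w > P$n_replicates)) {
    stop("w must lie in [1, n_replicates]", call. = FALSE)
  }
  purrr::map_dfr(w, function(wi) {
    tg <- threshold_graph(P, wi)
    rep <- connectivity_report(tg)
    tibble::tibble(
      w = wi, theta = wi / P$n_replicates, n_edges = nrow(tg$edges),
      n_components = length(rep$components),
      n_isolated = length(rep$isolated),
      planar = rep$planar, graph = list(tg)
    )
  })
}

#' Connectivity report for a graph over the region set
#'
#' Connected components (singletons included), isolated regions, exact
#' planarity (via [is_planar()]), and per-region degree.
#'
#' @param g a `physarum_graph`, `threshold_graph`, `adjacency_record`, or
#'   igraph object.
#' @return A `connectivity_report`: list with `components` (list of region
#'   character vectors, largest first), `isolated`, `planar`, `degrees`
#'   (tibble `region`, `degree`).
#' @export
connectivity_report <- function(g) {
  ig <- as_undirected_igraph(g)
  comp <- igraph::components(ig)
  members <- split(igraph::V(ig)$name, comp$membership)
  members <- members[order(-vapply(members, length, integer(1)))]
  deg <- igraph::degree(ig)
  structure(
    list(
      components = unname(members),
      isolated = names(deg)[deg == 0],
      planar = as.logical(is_planar(ig)),
      degrees = tibble::tibble(region = names(deg), degree = as.numeric(deg))
    ),
    class = "connectivity_report"
  )
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf("<connectivity_report> %d components, %d isolated, %splanar\n",
              length(x$components), length(x$isolated),
              if (x$planar) "" else "non-"))
  invisible(x)
}

#' Edge-count statistics over replicates
#'
#' Per-replicate edge counts with their mean, sample standard deviation
#' (n - 1 denominator), and a relative-frequency histogram (bin masses sum
#' to 1).
#'
#' @param records replicate records (list of `adjacency_record`, observation
#'   tibble, or [lab_fixture()]).
#' @inheritParams build_physarum_graph
#' @return List with `counts` (tibble `replicate`, `n_edges`), `mean`, `sd`,
#'   and `histogram` (tibble `n_edges`, `rel_freq`).
#' @export
edge_count_stats <- function(records, regions = NULL, n_replicates = NULL) {
  parts <- as_observations(records, regions, n_replicates)
  if (parts$n < 2L) {
    stop("need at least 2 replicates for a standard deviation", call. = FALSE)
  }
  counts <- tibble::tibble(replicate = seq_len(parts$n)) |>
    dplyr::left_join(
      dplyr::count(parts$obs, .data$replicate, name = "n_edges"),
      by = "replicate"
    ) |>
    dplyr::mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L))
  hist <- counts |>
    dplyr::count(.data$n_edges, name = "freq") |>
    dplyr::mutate(rel_freq = .data$freq / sum(.data$freq)) |>
    dplyr::select(-"freq")
  list(
    counts = counts,
    mean = mean(counts$n_edges),
    sd = stats::sd(counts$n_edges),
    histogram = hist
  )
}

#' Mean region degree over replicates
#'
#' Each region's degree is computed per replicate (regions absent from a
#' replicate's edges count 0) and averaged over all N replicates; the table
#' is ranked by descending mean degree with ties broken by region name.
#'
#' @inheritParams edge_count_stats
#' @return A tibble: `region`, `mean_degree`, `rank`.
#' @export
mean_degree_table <- function(records, regions = NULL, n_replicates = NULL) {
  parts <- as_observations(records, regions, n_replicates)
  long <- dplyr::bind_rows(
    dplyr::select(parts$obs, "replicate", region = "region_a"),
    dplyr::select(parts$obs, "replicate", region = "region_b")
  )
  deg <- long |>
    dplyr::count(.data$region, name = "total_degree") |>
    dplyr::right_join(tibble::tibble(region = parts$regions), by = "region") |>
    dplyr::mutate(
      mean_degree = dplyr::coalesce(.data$total_degree, 0L) / parts$n
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_degree), .data$region) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("region", "mean_degree", "rank")
  deg
}

#' Edge incidence counts over replicates
#'
#' Observation count per edge (for proportional edge-width rendering and
#' export); pairs never observed are absent. Dividing the counts by N gives
#' exactly the p of [build_physarum_graph()].
#'
#' @inheritParams edge_count_stats
#' @return A tibble: `region_a`, `region_b`, `count`.
#' @export
edge_incidence_weights <- function(records, regions = NULL,
                                   n_replicates = NULL) {
  parts <- as_observations(records, regions, n_replicates)
  parts$obs |>
    dplyr::count(.data$region_a, .data$region_b, name = "count") |>
    dplyr::arrange(match(.data$region_a, parts$regions),
                   match(.data$region_b, parts$regions))
}

#' Export a Physarum or threshold graph as GraphML
#' @param graph a `physarum_graph` or `threshold_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph_igraph(graph), path, format = "graphml")
  invisible(path)
}
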