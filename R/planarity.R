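#' Exact planarity test
#'
#' Decides planarity with Demoucron's face-embedding algorithm, run per
#' biconnected block (a graph is planar iff every block is). When the graph
#' is planar the embedding's face cycles are attached as attribute
#' `"faces"`, a constructive certificate; non-planarity is reported when
#' some fragment of the partial embedding has no admissible face, which in
#' Demoucron's procedure is conclusive.
#'
#' Exactness notes: the edge-count bound `m <= 3n - 6` is used only as a
#' shortcut rejection; all acceptance goes through the embedding. Multiple
#' edges and self-loops are ignored (planarity is a property of the
#' underlying simple graph).
#'
#' @param g an igraph object, a `physarum_graph`, a `threshold_graph`, an
#'   `adjacency_record`, or a two-column edge data frame.
#' @return `TRUE`/`FALSE`, with attribute `faces` when `TRUE`.
#' @export
is_planar <- function(g) {
  g <- as_undirected_igraph(g)
  g <- igraph::simplify(g)
  if (igraph::ecount(g) == 0L) return(structure(TRUE, faces = list()))
  blocks <- igraph::biconnected_components(g)
  faces_all <- list()
  for (bl in blocks$component_edges) {
    sub <- igraph::subgraph_from_edges(g, bl, delete.vertices = TRUE)
    el <- igraph::as_edgelist(sub, names = FALSE)
    res <- demoucron(el, igraph::vcount(sub))
    if (!res$planar) return(FALSE)
    faces_all <- c(faces_all, res$faces)
  }
  structure(TRUE, faces = faces_all)
}

as_undirected_igraph <- function(g) {
  if (igraph::is_igraph(g)) return(igraph::as_undirected(g))
  if (inherits(g, "physarum_graph") || inherits(g, "threshold_graph")) {
    return(graph_igraph(g))
  }
  if (inherits(g, "adjacency_record")) {
    m <- unclass(g)
    attr(m, "replicate_id") <- NULL
    return(igraph::graph_from_adjacency_matrix(m, mode = "undirected"))
  }
  if (is.data.frame(g)) {
    return(igraph::graph_from_data_frame(g[, 1:2], directed = FALSE))
  }
  stop("cannot interpret input as an undirected graph", call. = FALSE)
}

# Demoucron's algorithm on one biconnected block.
# el: m x 2 integer edge list over vertices 1..n
demoucron <- function(el, n) {
  m <- nrow(el)
  if (m <= 3L) {
    return(list(planar = TRUE, faces = list()))
  }
  if (m > 3L * n - 6L) return(list(planar = FALSE, faces = NULL))

  adj <- vector("list", n)
  for (i in seq_len(m)) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ekey <- function(a, b) paste0(min(a, b), "-", max(a, b))
  all_keys <- vapply(seq_len(m), function(i) ekey(el[i, 1], el[i, 2]),
                     character(1))

  cyc <- find_cycle(adj, n)
  if (is.null(cyc)) return(list(planar = TRUE, faces = list())) # tree block

  in_h <- rep(FALSE, n)
  in_h[cyc] <- TRUE
  embedded <- new.env(hash = TRUE)
  for (i in seq_along(cyc)) {
    a <- cyc[i]; b <- cyc[if (i == length(cyc)) 1L else i + 1L]
    assign(ekey(a, b), TRUE, envir = embedded)
  }
  faces <- list(cyc, rev(cyc))

  repeat {
    frags <- find_fragments(el, adj, n, in_h, embedded, ekey)
    if (length(frags) == 0L) {
      return(list(planar = TRUE, faces = faces))
    }
    # admissible faces per fragment
    best <- NULL
    best_count <- Inf
    best_faces <- NULL
    for (fr in frags) {
      adm <- which(vapply(faces, function(f) all(fr$attach %in% f),
                          logical(1)))
      if (length(adm) == 0L) return(list(planar = FALSE, faces = NULL))
      if (length(adm) < best_count) {
        best <- fr
        best_count <- length(adm)
        best_faces <- adm
        if (best_count == 1L) break
      }
    }
    path <- fragment_path(best, adj, in_h)
    fi <- best_faces[1L]
    f <- faces[[fi]]
    a <- path[1L]; b <- path[length(path)]
    ia <- match(a, f); ib <- match(b, f)
    arc1 <- if (ia <= ib) f[ia:ib] else c(f[ia:length(f)], f[1:ib])
    arc2 <- if (ib <= ia) f[ib:ia] else c(f[ib:length(f)], f[1:ia])
    interior <- if (length(path) > 2L) path[2:(length(path) - 1L)] else integer(0)
    faces[[fi]] <- c(arc1, rev(interior))
    faces[[length(faces) + 1L]] <- c(arc2, interior)
    # commit path to H
    in_h[path] <- TRUE
    for (i in seq_len(length(path) - 1L)) {
      assign(ekey(path[i], path[i + 1L]), TRUE, envir = embedded)
    }
  }
}

# first cycle found by DFS; graph is simple, so skipping the parent edge
# wholesale is safe (no multi-edges)
find_cycle <- function(adj, n) {
  color <- rep(0L, n)
  parent <- rep(0L, n)
  result <- NULL
  dfs <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (!is.null(result)) return(invisible())
      if (w == parent[v]) next
      if (color[w] == 1L) {
        cyc <- v
        u <- v
        while (u != w) {
          u <- parent[u]
          cyc <- c(cyc, u)
        }
        result <<- rev(cyc)
        return(invisible())
      }
      if (color[w] == 0L) {
        parent[w] <<- v
        dfs(w)
      }
    }
    color[v] <<- 2L
  }
  for (root in seq_len(n)) {
    if (color[root] == 0L) {
      dfs(root)
      if (!is.null(result)) return(result)
    }
  }
  NULL
}

find_fragments <- function(el, adj, n, in_h, embedded, ekey) {
  frags <- list()
  # type A: single unembedded edges with both ends in H
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (in_h[a] && in_h[b] &&
        !exists(ekey(a, b), envir = embedded, inherits = FALSE)) {
      frags[[length(frags) + 1L]] <- list(type = "edge", attach = c(a, b),
                                          comp = integer(0))
    }
  }
  # type B: components of G - V(H) with their attachments
  seen <- rep(FALSE, n)
  for (v in seq_len(n)) {
    if (in_h[v] || seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!in_h[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    attach <- unique(unlist(lapply(comp, function(u) {
      adj[[u]][in_h[adj[[u]]]]
    })))
    frags[[length(frags) + 1L]] <- list(type = "comp", attach = attach,
                                        comp = comp)
  }
  frags
}

fragment_path <- function(fr, adj, in_h) {
  if (fr$type == "edge") return(fr$attach)
  # BFS from one attachment through the component to another attachment
  a <- fr$attach[1L]
  allowed <- rep(FALSE, length(adj))
  allowed[fr$comp] <- TRUE
  prev <- rep(NA_integer_, length(adj))
  start_nbrs <- intersect(adj[[a]], fr$comp)
  queue <- start_nbrs
  for (s in start_nbrs) prev[s] <- a
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[u]]) {
      if (in_h[w] && w != a && w %in% fr$attach) {
        path <- c(w, u)
        x <- u
        while (prev[x] != a) {
          x <- prev[x]
          path <- c(path, x)
        }
        return(rev(c(path, a)))
      }
      if (allowed[w] && is.na(prev[w])) {
        prev[w] <- u
        queue <- c(queue, w)
      }
    }
  }
  stop("internal: fragment path not found", call. = FALSE)
}
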