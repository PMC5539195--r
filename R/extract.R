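#' Binarize a trail or occupancy field
#'
#' @param field numeric matrix (trail, or smoothed occupancy).
#' @param tau threshold, `>= 0`; a cell is foreground iff `value > tau`.
#' @return Logical matrix.
#' @export
binarize_trails <- function(field, tau) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  field > tau
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Zhang-Suen morphological thinning under 8-connectivity. Thinning never
#' splits or merges foreground components, so the component count of the
#' input is preserved.
#'
#' @param mask logical matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  cpp_thin(mask)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a 3x3 structuring element, applied
#' `iterations` times each. Bridges hairline gaps in binarized trail bands
#' (where a lane momentarily dips below the threshold) without fattening
#' solid regions.
#'
#' @param mask logical matrix.
#' @param iterations dilation/erosion repetitions (0 = no-op).
#' @return Logical matrix.
#' @export
close_mask <- function(mask, iterations = 1L) {
  if (iterations < 1L) return(mask)
  dil <- function(m) {
    o <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      o <- o | shift_lgl(m, dr, dc)
    }
    o
  }
  ero <- function(m) {
    o <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      o <- o & shift_lgl(m, dr, dc, fill = FALSE)
    }
    o
  }
  for (i in seq_len(iterations)) mask <- dil(mask)
  for (i in seq_len(iterations)) mask <- ero(mask)
  mask
}

shift_lgl <- function(m, dr, dc, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbour_counts <- function(sk) {
  ski <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  n <- matrix(0L, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + shift_mat(ski, dr, dc)
  }
  n
}

# label 8-connected clusters among `cells` (matrix of 1-based row, col)
cluster_cells <- function(cells, H, W) {
  if (nrow(cells) == 0L) return(integer(0))
  key <- (cells[, 1] - 1L) * W + cells[, 2]
  index <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cells))) assign(as.character(key[i]), i, envir = index)
  labels <- integer(nrow(cells))
  lab <- 0L
  for (i in seq_len(nrow(cells))) {
    if (labels[i] != 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      r <- cells[j, 1]; c <- cells[j, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        k <- as.character((r + dr - 1L) * W + (c + dc))
        hit <- if (exists(k, envir = index, inherits = FALSE)) {
          get(k, envir = index)
        }
        if (!is.null(hit) && labels[hit] == 0L) {
          labels[hit] <- lab
          queue <- c(queue, hit)
        }
      }
    }
  }
  labels
}

#' Build a node/edge graph from a skeleton
#'
#' Resolves the thinned trail network into region nodes and Steiner nodes:
#'
#' * each site captures its nearest skeleton cell within `capture_radius`
#'   (Euclidean); uncaptured sites become isolated region nodes;
#' * maximal 8-connected clusters of skeleton cells with three or more
#'   skeleton neighbours become Steiner (junction) nodes — clusters are
#'   merged so thick crossings yield a single junction;
#' * edges are pixel chains traced along the skeleton between nodes, with
#'   length counted in cells stepped;
#' * skeleton components containing no region node are discarded (trapped
#'   trail remnants do not enter the analysis);
#' * Steiner nodes left with degree below 3 are smoothed away (degree-2
#'   junction artifacts merge their two incident chains).
#'
#' @param skeleton logical skeleton matrix from [skeletonize()].
#' @param sites site tibble (0-based `row`, `col`, `region_id`).
#' @param capture_radius maximum site-to-skeleton capture distance in cells.
#'   The default 12 allows for the half-width of a thick trail band whose
#'   centreline the thinning extracts; sites engulfed by a band sit up to
#'   that far from the skeleton.
#' @return A `skeleton_graph`: list with `nodes` (tibble: `node`, `type`
#'   `"region"`/`"steiner"`, `region_id`, 0-based `row`, `col`, `captured`)
#'   and `edges` (tibble: `from`, `to`, `length`).
#' @export
build_skeleton_graph <- function(skeleton, sites, capture_radius = 12) {
  if (capture_radius < 0) stop("capture_radius must be >= 0", call. = FALSE)
  H <- nrow(skeleton); W <- ncol(skeleton)
  sites <- tibble::as_tibble(sites)
  sk_cells <- which(skeleton, arr.ind = TRUE) # 1-based (row, col)
  nbr <- neighbour_counts(skeleton)

  node_id <- matrix(0L, H, W) # cell -> node index (0 = path cell / empty)
  nodes <- list()
  add_node <- function(type, region_id, row, col, captured) {
    nodes[[length(nodes) + 1L]] <<- list(
      type = type, region_id = region_id, row = row, col = col,
      captured = captured
    )
    length(nodes)
  }

  # junction clusters -> provisional Steiner nodes
  jc <- sk_cells[skeleton[sk_cells] & nbr[sk_cells] >= 3L, , drop = FALSE]
  jlab <- cluster_cells(jc, H, W)
  n_clusters <- if (length(jlab)) max(jlab) else 0L
  cluster_node <- integer(n_clusters)
  for (l in seq_len(n_clusters)) {
    members <- jc[jlab == l, , drop = FALSE]
    cen <- round(colMeans(members))
    id <- add_node("steiner", NA_integer_, cen[1] - 1L, cen[2] - 1L, TRUE)
    cluster_node[l] <- id
    node_id[members] <- id
  }

  # region capture: nearest skeleton cell within radius; region overrides
  # a junction cluster it lands on
  for (i in seq_len(nrow(sites))) {
    sr <- sites$row[i] + 1L; sc <- sites$col[i] + 1L
    if (nrow(sk_cells) > 0L) {
      d2 <- (sk_cells[, 1] - sr)^2 + (sk_cells[, 2] - sc)^2
      best <- which.min(d2)
      if (d2[best] <= capture_radius^2) {
        br <- sk_cells[best, 1]; bc <- sk_cells[best, 2]
        existing <- node_id[br, bc]
        if (existing > 0L && nodes[[existing]]$type == "steiner") {
          # promote the whole junction cluster to this region
          nodes[[existing]]$type <- "region"
          nodes[[existing]]$region_id <- sites$region_id[i]
          next
        }
        if (existing > 0L) {
          # second site capturing the same cell: its own node, linked below
          id <- add_node("region", sites$region_id[i], br - 1L, bc - 1L, TRUE)
          attr(nodes[[id]], "alias_of") <- existing
          next
        }
        id <- add_node("region", sites$region_id[i], br - 1L, bc - 1L, TRUE)
        node_id[br, bc] <- id
        next
      }
    }
    add_node("region", sites$region_id[i], sites$row[i], sites$col[i], FALSE)
  }

  # trace pixel chains between node cells
  edges <- list()
  add_edge <- function(a, b, len) {
    edges[[length(edges) + 1L]] <<- list(from = a, to = b, length = len)
  }
  visited <- matrix(FALSE, H, W) # interior path cells consumed by a trace
  node_cells <- which(node_id > 0L, arr.ind = TRUE)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  for (i in seq_len(nrow(node_cells))) {
    pr <- node_cells[i, 1]; pc <- node_cells[i, 2]
    pid <- node_id[pr, pc]
    for (o in seq_len(8L)) {
      qr <- pr + offs[o, 1]; qc <- pc + offs[o, 2]
      if (qr < 1 || qr > H || qc < 1 || qc > W) next
      if (!skeleton[qr, qc]) next
      qid <- node_id[qr, qc]
      if (qid > 0L) {
        # direct node-node contact; dedupe by linear cell order, skip
        # intra-cluster contacts
        if (qid != pid &&
            ((pr - 1L) * W + pc) < ((qr - 1L) * W + qc)) {
          add_edge(pid, qid, 1)
        }
        next
      }
      if (visited[qr, qc]) next
      # walk the chain
      path_len <- 1L
      prev_r <- pr; prev_c <- pc
      cr <- qr; cc <- qc
      visited[cr, cc] <- TRUE
      repeat {
        nxt <- NULL
        for (o2 in seq_len(8L)) {
          tr <- cr + offs[o2, 1]; tc <- cc + offs[o2, 2]
          if (tr < 1 || tr > H || tc < 1 || tc > W) next
          if (tr == prev_r && tc == prev_c) next
          if (!skeleton[tr, tc]) next
          tid <- node_id[tr, tc]
          if (tid > 0L) {
            if (tid == pid && path_len == 1L) next # immediate backtrack
            nxt <- c(tr, tc, tid)
            break
          }
          if (!visited[tr, tc]) {
            nxt <- c(tr, tc, 0L)
            break
          }
        }
        if (is.null(nxt)) break # dangling tip: drop the chain
        if (nxt[3] > 0L) {
          add_edge(pid, nxt[3], path_len + 1L)
          break
        }
        prev_r <- cr; prev_c <- cc
        cr <- nxt[1]; cc <- nxt[2]
        visited[cr, cc] <- TRUE
        path_len <- path_len + 1L
      }
    }
  }

  nodes_tbl <- tibble::tibble(
    id = seq_along(nodes),
    type = vapply(nodes, function(n) n$type, character(1)),
    region_id = vapply(nodes, function(n) as.integer(n$region_id), integer(1)),
    row = vapply(nodes, function(n) as.integer(n$row), integer(1)),
    col = vapply(nodes, function(n) as.integer(n$col), integer(1)),
    captured = vapply(nodes, function(n) isTRUE(n$captured), logical(1))
  )
  edges_tbl <- if (length(edges)) {
    tibble::tibble(
      from = vapply(edges, function(e) e$from, numeric(1)),
      to = vapply(edges, function(e) e$to, numeric(1)),
      length = vapply(edges, function(e) e$length, numeric(1))
    )
  } else {
    tibble::tibble(from = numeric(0), to = numeric(0), length = numeric(0))
  }
  # aliased region nodes (two sites on one cell): zero-length link
  for (i in nodes_tbl$id) {
    al <- attr(nodes[[i]], "alias_of")
    if (!is.null(al)) {
      edges_tbl <- dplyr::bind_rows(
        edges_tbl, tibble::tibble(from = i, to = al, length = 0)
      )
    }
  }

  sg <- prune_skeleton_graph(nodes_tbl, edges_tbl)
  structure(sg, class = "skeleton_graph")
}

# drop components without region nodes; smooth Steiner nodes of degree < 3
prune_skeleton_graph <- function(nodes, edges) {
  repeat {
    deg <- rep(0, nrow(nodes))
    if (nrow(edges)) {
      tab <- table(factor(c(edges$from, edges$to), levels = nodes$id))
      deg <- as.numeric(tab)
    }
    low <- which(nodes$type == "steiner" & deg < 3)
    if (!length(low)) break
    v <- nodes$id[low[1]]
    inc <- which(edges$from == v | edges$to == v)
    if (deg[low[1]] == 2 && length(inc) == 2) {
      e1 <- edges[inc[1], ]; e2 <- edges[inc[2], ]
      a <- if (e1$from == v) e1$to else e1$from
      b <- if (e2$from == v) e2$to else e2$from
      edges <- edges[-inc, ]
      edges <- dplyr::bind_rows(
        edges, tibble::tibble(from = a, to = b,
                              length = e1$length + e2$length)
      )
    } else {
      edges <- if (length(inc)) edges[-inc, ] else edges
    }
    keep <- nodes$id != v
    nodes <- nodes[keep, ]
  }
  # discard components with no region node
  if (nrow(nodes)) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(edges$from),
                     to = as.character(edges$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$id))
    )
    comp <- igraph::components(g)
    memb <- comp$membership[as.character(nodes$id)]
    has_region <- tapply(nodes$type == "region", memb, any)
    keep <- as.logical(has_region[as.character(memb)])
    kept_ids <- nodes$id[keep]
    nodes <- nodes[keep, ]
    edges <- edges[edges$from %in% kept_ids & edges$to %in% kept_ids, ]
  }
  list(nodes = nodes, edges = edges)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d region nodes, %d Steiner nodes, %d edges\n",
    sum(x$nodes$type == "region"), sum(x$nodes$type == "steiner"),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Region-region adjacency from a skeleton graph
#'
#' Two regions are adjacent iff a path exists between them whose interior
#' nodes are all Steiner nodes — indirect connections through junctions
#' count as direct, while an intermediate region node blocks the
#' connection. By default Steiner transparency is unlimited-depth; `strict`
#' restricts paths to at most one interior Steiner node (the minimal reading
#' of a single-junction illustration).
#'
#' @param sg a `skeleton_graph`.
#' @param strict allow at most one interior Steiner node.
#' @param replicate_id optional identifier stored on the record.
#' @return An `adjacency_record`: symmetric 0/1 matrix with zero diagonal,
#'   dimnames the region ids (as character, sorted numerically).
#' @export
region_adjacency <- function(sg, strict = FALSE, replicate_id = NA) {
  nodes <- sg$nodes
  edges <- sg$edges
  regions <- nodes[nodes$type == "region", ]
  rids <- sort(regions$region_id)
  A <- matrix(0L, length(rids), length(rids),
              dimnames = list(as.character(rids), as.character(rids)))
  if (nrow(regions) >= 2L) {
    adj <- lapply(nodes$id, function(v) {
      unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
    })
    names(adj) <- as.character(nodes$id)
    is_steiner <- stats::setNames(nodes$type == "steiner",
                                  as.character(nodes$id))
    rid_of <- stats::setNames(nodes$region_id, as.character(nodes$id))
    for (i in seq_len(nrow(regions))) {
      start <- regions$id[i]
      if (strict) {
        reach <- adj[[as.character(start)]]
        one_hop <- unlist(lapply(reach[is_steiner[as.character(reach)]],
                                 function(s) adj[[as.character(s)]]))
        reach <- unique(c(reach, one_hop))
      } else {
        # BFS passing through Steiner nodes only
        seen <- character(0)
        queue <- as.character(adj[[as.character(start)]])
        reach <- numeric(0)
        while (length(queue)) {
          v <- queue[[1]]; queue <- queue[-1]
          if (v %in% seen) next
          seen <- c(seen, v)
          reach <- c(reach, as.numeric(v))
          if (is_steiner[[v]]) {
            queue <- c(queue, as.character(adj[[v]]))
          }
        }
      }
      reach <- setdiff(reach, start)
      hit <- reach[!is_steiner[as.character(reach)]]
      if (length(hit)) {
        a <- as.character(rid_of[[as.character(start)]])
        for (h in hit) {
          b <- as.character(rid_of[[as.character(h)]])
          if (a != b) {
            A[a, b] <- 1L
            A[b, a] <- 1L
          }
        }
      }
    }
  }
  structure(A, class = c("adjacency_record", "matrix"),
            replicate_id = replicate_id)
}

#' Extract a region adjacency record from a finished simulation
#'
#' Convenience pipeline: binarize the chosen field, repair hairline gaps by
#' morphological closing, thin to a skeleton, build the skeleton graph, and
#' resolve region adjacency. The default source is the trail field smoothed
#' once with the diffusion kernel: the trail carries both the particle lanes
#' and the nutrient-stimulus dots at the sites, exactly the bright features
#' a digitized network image shows, so sites stay attached to the network
#' they anchor. (`"occupancy"` uses the particle positions instead, scaled
#' by the deposit so the same `tau` applies; it lacks the stimulus anchor.)
#'
#' @param state a `sim_state`.
#' @param arena the arena the state was simulated on.
#' @param cfg the [sim_config()] used (supplies kernel and deposit).
#' @param source `"trail"` (smoothed trail, default) or `"occupancy"`
#'   (smoothed deposit-scaled occupancy).
#' @param tau binarization threshold; default `cfg$deposit / 2`.
#' @param closing closing iterations applied to the binarized mask.
#' @param capture_radius site capture radius in cells.
#' @param strict strict (single-Steiner) adjacency mode.
#' @param replicate_id identifier stored on the record.
#' @return An `adjacency_record`; the `skeleton_graph` is attached as
#'   attribute `"skeleton_graph"` and the skeleton mask as `"skeleton"`.
#' @export
extract_network <- function(state, arena, cfg = sim_config(),
                            source = c("trail", "occupancy"), tau = NULL,
                            closing = 1L, capture_radius = 12,
                            strict = FALSE, replicate_id = NA) {
  source <- match.arg(source)
  field <- if (source == "occupancy") {
    cpp_diffuse_decay(occupancy_matrix(state) * cfg$deposit,
                      cfg$diffusion_kernel, 0, FALSE)
  } else {
    cpp_diffuse_decay(state$trail, cfg$diffusion_kernel, 0, FALSE)
  }
  if (is.null(tau)) tau <- cfg$deposit / 2
  mask <- close_mask(binarize_trails(field, tau), closing)
  sk <- skeletonize(mask)
  sg <- build_skeleton_graph(sk, arena$sites, capture_radius)
  rec <- region_adjacency(sg, strict = strict, replicate_id = replicate_id)
  attr(rec, "skeleton_graph") <- sg
  attr(rec, "skeleton") <- sk
  rec
}

#' Export a skeleton graph
#'
#' GraphML export goes through igraph; the TSV edge list has columns
#' `node_a`, `node_b`, `length_cells`.
#'
#' @param sg a `skeleton_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton_graphml <- function(sg, path) {
  g <- skeleton_igraph(sg)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_skeleton_graphml
#' @export
write_skeleton_tsv <- function(sg, path) {
  nm <- node_names(sg$nodes)
  df <- data.frame(
    node_a = nm[match(sg$edges$from, sg$nodes$id)],
    node_b = nm[match(sg$edges$to, sg$nodes$id)],
    length_cells = sg$edges$length
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

node_names <- function(nodes) {
  ifelse(nodes$type == "region",
         paste0("region_", nodes$region_id),
         paste0("steiner_", cumsum(nodes$type == "steiner")))
}

skeleton_igraph <- function(sg) {
  nm <- node_names(sg$nodes)
  igraph::graph_from_data_frame(
    d = data.frame(from = nm[match(sg$edges$from, sg$nodes$id)],
                   to = nm[match(sg$edges$to, sg$nodes$id)],
                   length = sg$edges$length),
    directed = FALSE,
    vertices = data.frame(name = nm, type = sg$nodes$type,
                          region_id = sg$nodes$region_id,
                          row = sg$nodes$row, col = sg$nodes$col)
  )
}

#' Write an adjacency record as CSV
#'
#' The matrix is written with region ids as header row and first column.
#'
#' @param record an `adjacency_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(record, path) {
  m <- unclass(record)
  attr(m, "replicate_id") <- NULL
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency record CSV written by [write_adjacency_csv()]
#' @param path CSV path.
#' @param replicate_id identifier to attach.
#' @return An `adjacency_record`.
#' @export
read_adjacency_csv <- function(path, replicate_id = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(m) != 0L)) stop("adjacency diagonal must be zero", call. = FALSE)
  structure(m, class = c("adjacency_record", "matrix"),
            replicate_id = replicate_id)
}
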