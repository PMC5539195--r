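# Independent oracles and generators used across the suite.

# --- planarity oracle: networkx (Boyer-Myrvold) through the python on PATH --
# Takes a list of igraph objects, returns a logical vector. One python call
# for the whole batch.
networkx_planar <- function(graphs) {
  lines <- vapply(graphs, function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    n <- igraph::vcount(g)
    paste(n, paste(t(el), collapse = " "))
  }, character(1))
  inp <- tempfile(fileext = ".txt")
  writeLines(lines, inp)
  script <- paste(
    "import sys, networkx as nx",
    "for line in open(sys.argv[1]):",
    "    xs = line.split()",
    "    n = int(xs[0]); es = list(map(int, xs[1:]))",
    "    g = nx.Graph(); g.add_nodes_from(range(1, n + 1))",
    "    g.add_edges_from(zip(es[::2], es[1::2]))",
    "    print(int(nx.check_planarity(g)[0]))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(inp)),
                 stdout = TRUE)
  as.logical(as.integer(out))
}

random_gnp <- function(n, p) {
  igraph::sample_gnp(n, p, directed = FALSE)
}

# --- brute-force Steiner-transparent adjacency -----------------------------
# Enumerates all simple paths between each region pair; adjacent iff some
# path has only Steiner interior nodes. Independent of region_adjacency's
# BFS formulation.
brute_force_adjacency <- function(sg, strict = FALSE) {
  nodes <- sg$nodes
  edges <- sg$edges
  adj <- lapply(nodes$id, function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  names(adj) <- as.character(nodes$id)
  type <- stats::setNames(nodes$type, as.character(nodes$id))
  rid <- stats::setNames(nodes$region_id, as.character(nodes$id))
  regions <- nodes$id[nodes$type == "region"]
  rids <- sort(rid[as.character(regions)])
  A <- matrix(0L, length(rids), length(rids),
              dimnames = list(as.character(rids), as.character(rids)))
  path_exists <- function(a, b) {
    found <- FALSE
    dfs <- function(v, visited, interior_ok) {
      if (found) return(invisible())
      for (w in adj[[as.character(v)]]) {
        if (w == b) {
          found <<- TRUE
          return(invisible())
        }
        if (w %in% visited) next
        if (type[[as.character(w)]] != "steiner") next # interior must be Steiner
        if (strict && !interior_ok) next # already used the one Steiner hop
        dfs(w, c(visited, w), FALSE)
      }
    }
    dfs(a, c(a), TRUE)
    found
  }
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i >= j) next
      if (path_exists(regions[i], regions[j])) {
        a <- as.character(rid[[as.character(regions[i])]])
        b <- as.character(rid[[as.character(regions[j])]])
        A[a, b] <- A[b, a] <- 1L
      }
    }
  }
  A
}

# construct a skeleton_graph object directly from node/edge specs
make_sg <- function(types, edges) {
  n <- length(types)
  region_ids <- cumsum(types == "region")
  nodes <- tibble::tibble(
    id = seq_len(n), type = types,
    region_id = ifelse(types == "region", region_ids, NA_integer_),
    row = seq_len(n), col = rep(0L, n), captured = TRUE
  )
  ed <- tibble::tibble(from = edges[, 1], to = edges[, 2],
                       length = rep(1, nrow(edges)))
  structure(list(nodes = nodes, edges = ed), class = "skeleton_graph")
}

random_sg <- function(n_region, n_steiner, p_edge = 0.4) {
  types <- sample(c(rep("region", n_region), rep("steiner", n_steiner)))
  n <- length(types)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  make_sg(types, pairs[keep, , drop = FALSE])
}

# --- lattice component count (flood fill, 8-connectivity) ------------------
component_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      if (!mask[r0, c0] || lab[r0, c0] != 0L) next
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r < 1 || r > H || c < 1 || c > W) next
          if (mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  cur
}

# --- small raster writers for I/O tests ------------------------------------
write_test_pgm <- function(pixels, path, ascii = FALSE, maxval = 255L) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (ascii) {
    writeLines(c("P2", paste(w, h), as.character(maxval),
                 apply(pixels, 1, paste, collapse = " ")), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", w, h, maxval)), con)
    flat <- as.integer(t(pixels))
    if (maxval > 255L) writeBin(flat, con, size = 2L, endian = "big")
    else writeBin(as.raw(flat), con)
  }
  path
}

flat_arena <- function(n = 30L, sites = NULL) {
  if (is.null(sites)) {
    sites <- tibble::tibble(region_id = 1L, name = "a",
                            row = n %/% 2L, col = n %/% 2L)
  }
  make_arena(matrix(TRUE, n, n), sites)
}
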