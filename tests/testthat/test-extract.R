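test_that("binarization thresholds strictly above tau", {
  f <- matrix(c(0, 2, 0, 0, 2, 0, 0, 2, 0), 3, 3)
  expect_equal(binarize_trails(f, 1), f > 1)
  expect_equal(sum(binarize_trails(f, 1)), 3L)
  expect_equal(binarize_trails(f, 0), f > 0)
  expect_false(any(binarize_trails(f, 2)))
  expect_error(binarize_trails(f, -1), "tau")
})

test_that("thinning preserves 1-px lines, empties, and component counts", {
  # an already-thin line is unchanged
  line <- matrix(FALSE, 9, 9)
  line[5, 2:8] <- TRUE
  expect_equal(skeletonize(line), line)
  # empty stays empty
  expect_false(any(skeletonize(matrix(FALSE, 5, 5))))
  # a solid block thins to a connected skeleton with one component
  block <- matrix(FALSE, 11, 11)
  block[3:9, 3:9] <- TRUE
  sk <- skeletonize(block)
  expect_true(any(sk))
  expect_equal(component_count(sk), 1L)
  # fuzz: random blobs never gain or lose components
  set.seed(99)
  for (i in 1:8) {
    m <- matrix(stats::runif(400) < 0.55, 20, 20)
    m <- close_mask(m, 1L)
    expect_equal(component_count(skeletonize(m)), component_count(m))
  }
})

test_that("a straight skeleton between two captured sites gives one edge", {
  sk <- matrix(FALSE, 15, 15)
  sk[8, 3:13] <- TRUE
  sites <- tibble::tibble(region_id = c(1L, 2L), name = c("a", "b"),
                          row = c(7L, 7L), col = c(2L, 12L))
  sg <- build_skeleton_graph(sk, sites, capture_radius = 3)
  expect_equal(sum(sg$nodes$type == "region"), 2L)
  expect_equal(sum(sg$nodes$type == "steiner"), 0L)
  expect_equal(nrow(sg$edges), 1L)
  expect_equal(sg$edges$length, 10)
  A <- region_adjacency(sg)
  expect_equal(unclass(A)[1, 2], 1L)
})

test_that("a Y junction resolves to one Steiner node and a triangle adjacency", {
  sk <- matrix(FALSE, 21, 21)
  sk[11, 11:19] <- TRUE              # east arm
  for (d in 0:8) {
    sk[11 - d, 11 - d] <- TRUE       # northwest arm
    sk[11 + d, 11 - d] <- TRUE       # southwest arm
  }
  sites <- tibble::tibble(region_id = 1:3, name = c("a", "b", "c"),
                          row = c(10L, 2L, 18L), col = c(18L, 2L, 2L))
  sg <- build_skeleton_graph(sk, sites, capture_radius = 3)
  expect_equal(sum(sg$nodes$type == "region"), 3L)
  expect_equal(sum(sg$nodes$type == "steiner"), 1L)
  expect_equal(nrow(sg$edges), 3L)
  # regions joined through the Steiner point count as pairwise connected
  A <- region_adjacency(sg)
  expect_equal(sum(A), 6L)
  expect_true(all(diag(unclass(A)) == 0L))
})

test_that("floating components without region nodes are discarded", {
  sk <- matrix(FALSE, 20, 20)
  sk[5, 2:8] <- TRUE # component near the sites
  # far floating loop
  sk[14:17, 14] <- TRUE
  sk[14:17, 17] <- TRUE
  sk[14, 14:17] <- TRUE
  sk[17, 14:17] <- TRUE
  sites <- tibble::tibble(region_id = c(1L, 2L), name = c("a", "b"),
                          row = c(4L, 4L), col = c(1L, 7L))
  sg <- build_skeleton_graph(sk, sites, capture_radius = 3)
  expect_true(all(sg$nodes$type == "region"))
  expect_true(all(sg$nodes$row < 10))
  expect_equal(nrow(sg$edges), 1L)
})

test_that("uncaptured sites become isolated region nodes", {
  sk <- matrix(FALSE, 15, 15)
  sk[3, 3:10] <- TRUE
  sites <- tibble::tibble(region_id = c(1L, 2L, 3L),
                          name = c("a", "b", "far"),
                          row = c(2L, 2L, 13L), col = c(2L, 9L, 13L))
  sg <- build_skeleton_graph(sk, sites, capture_radius = 3)
  expect_equal(sum(sg$nodes$type == "region"), 3L)
  far <- sg$nodes[sg$nodes$region_id == 3L, ]
  expect_false(far$captured)
  A <- region_adjacency(sg)
  expect_equal(sum(unclass(A)["3", ]), 0L)
})

test_that("an interior region node blocks transparency; Steiner chains do not", {
  # chain: region1 - region2 - region3 as direct skeleton edges
  chain <- make_sg(c("region", "region", "region"),
                   rbind(c(1, 2), c(2, 3)))
  A <- region_adjacency(chain)
  expect_equal(unclass(A)["1", "2"], 1L)
  expect_equal(unclass(A)["2", "3"], 1L)
  expect_equal(unclass(A)["1", "3"], 0L)
  # region1 - steiner - steiner - region2: unlimited-depth transparency
  deep <- make_sg(c("region", "steiner", "steiner", "region"),
                  rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(unclass(region_adjacency(deep))["1", "2"], 1L)
  # ... but strict mode allows at most one interior Steiner node
  expect_equal(unclass(region_adjacency(deep, strict = TRUE))["1", "2"], 0L)
  one <- make_sg(c("region", "steiner", "region"),
                 rbind(c(1, 2), c(2, 3)))
  expect_equal(unclass(region_adjacency(one, strict = TRUE))["1", "2"], 1L)
})

test_that("adjacency equals brute-force path search on random skeleton graphs", {
  set.seed(2024)
  for (i in 1:40) {
    sg <- random_sg(n_region = sample(2:4, 1), n_steiner = sample(0:4, 1),
                    p_edge = stats::runif(1, 0.2, 0.6))
    for (strict in c(FALSE, TRUE)) {
      got <- unclass(region_adjacency(sg, strict = strict))
      attr(got, "replicate_id") <- NULL
      class(got) <- NULL
      want <- brute_force_adjacency(sg, strict = strict)
      expect_identical(got, want)
    }
  }
})

test_that("adjacency records are symmetric with zero diagonal (fuzzed)", {
  set.seed(7)
  for (i in 1:20) {
    sg <- random_sg(n_region = sample(2:5, 1), n_steiner = sample(0:5, 1))
    A <- unclass(region_adjacency(sg))
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0L))
  }
})

test_that("adjacency CSV round-trips and rejects malformed matrices", {
  sg <- make_sg(c("region", "steiner", "region", "region"),
                rbind(c(1, 2), c(2, 3), c(3, 4)))
  rec <- region_adjacency(sg, replicate_id = 7L)
  f <- tempfile(fileext = ".csv")
  write_adjacency_csv(rec, f)
  got <- read_adjacency_csv(f, replicate_id = 7L)
  expect_equal(unclass(got), unclass(rec), ignore_attr = TRUE)
  # asymmetric input is rejected
  writeLines(c("region_id,1,2", "1,0,1", "2,0,0"), f)
  expect_error(read_adjacency_csv(f), "symmetric")
})

test_that("skeleton graph exports to TSV and GraphML", {
  sg <- make_sg(c("region", "steiner", "region", "region"),
                rbind(c(1, 2), c(2, 3), c(2, 4)))
  tsv <- tempfile(fileext = ".tsv")
  write_skeleton_tsv(sg, tsv)
  df <- utils::read.delim(tsv)
  expect_equal(names(df), c("node_a", "node_b", "length_cells"))
  expect_equal(nrow(df), 3L)
  gml <- tempfile(fileext = ".graphml")
  write_skeleton_graphml(sg, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
})
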