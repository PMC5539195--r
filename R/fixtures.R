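#' Synthetic 13-replicate laboratory fixture
#'
#' The raw adjacency sets of the 13 laboratory replicates behind the
#' published Balkans threshold analysis were never released, so this package
#' ships an openly SYNTHETIC edge-observation table over the 17 regional
#' centres, constructed only from the qualitative threshold transitions the
#' analysis reports:
#'
#' * the frequency-1/13 graph is non-planar while the 2/13 graph is planar
#'   (a K5 is embedded among the count-1 edges);
#' * the 3/13 graph is connected; when the threshold exceeds 3/13 Tomis
#'   becomes isolated and the Sirmium--Singidunum segment detaches (their
#'   maximal incident/cut counts are 3);
#' * at 6/13 exactly Tomis, Marcianopolis, Sirmium and Singidunum are
#'   isolated;
#' * at 7/13 the surviving 3-node segments are exactly
#'   Doclea--Dyrrachium--Nicopolis, Remesiana--Serdica--Philippopolis and
#'   Scupi--Thessaloniki--Philippoi (the long-lived
#'   Traianoupolis--Hadrianopolis edge also survives here);
#' * at 10/13 only the Traianoupolis--Hadrianopolis edge remains (its count
#'   is at least 10 and every other edge's is below 10).
#'
#' Every invariant is re-validated at construction time; violation is a
#' packaging error. The counts are expanded into 13 deterministic replicate
#' observation sets (edge j with count k appears in replicates
#' `((j-1) + 0:(k-1)) mod 13 + 1`), so per-replicate statistics are
#' exercised end to end. The table validates the analysis code — it is not
#' the unpublished laboratory data.
#'
#' @return A `lab_fixture`: list with `regions` (17 names), `counts`
#'   (tibble `region_a`, `region_b`, `count`), `observations` (long
#'   replicate tibble), and `n_replicates = 13`.
#' @export
lab_fixture <- function() {
  regions <- c(
    "Thessaloniki", "Philippoi", "Nicopolis", "Scupi", "Traianoupolis",
    "Dyrrachium", "Heraclea", "Constantinople", "Marcianopolis", "Serdica",
    "Sirmium", "Doclea", "Remesiana", "Hadrianopolis", "Philippopolis",
    "Singidunum", "Tomis"
  )
  counts <- tibble::tribble(
    ~region_a, ~region_b, ~count,
    # three long-lived triads
    "Doclea", "Dyrrachium", 9L,
    "Dyrrachium", "Nicopolis", 8L,
    "Remesiana", "Serdica", 9L,
    "Serdica", "Philippopolis", 8L,
    "Scupi", "Thessaloniki", 9L,
    "Thessaloniki", "Philippoi", 8L,
    # the most persistent edge
    "Traianoupolis", "Hadrianopolis", 11L,
    # mid-frequency attachments
    "Heraclea", "Thessaloniki", 6L,
    "Constantinople", "Hadrianopolis", 6L,
    "Marcianopolis", "Constantinople", 5L,
    "Sirmium", "Singidunum", 5L,
    # weak periphery: Tomis and the Sirmium-Singidunum cut
    "Tomis", "Marcianopolis", 3L,
    "Tomis", "Constantinople", 2L,
    "Sirmium", "Serdica", 3L,
    "Singidunum", "Remesiana", 3L,
    # connectors keeping the 3/13 graph whole
    "Dyrrachium", "Scupi", 4L,
    "Philippoi", "Philippopolis", 4L,
    "Hadrianopolis", "Philippopolis", 4L,
    # K5 completion among count-1 edges (non-planar union graph)
    "Serdica", "Singidunum", 1L,
    "Remesiana", "Philippopolis", 1L,
    "Remesiana", "Sirmium", 1L,
    "Philippopolis", "Sirmium", 1L,
    "Philippopolis", "Singidunum", 1L
  )
  obs <- purrr::map_dfr(seq_len(nrow(counts)), function(j) {
    k <- counts$count[j]
    reps <- ((j - 1L) + seq_len(k) - 1L) %% 13L + 1L
    tibble::tibble(replicate = reps, region_a = counts$region_a[j],
                   region_b = counts$region_b[j])
  })
  fixture <- structure(
    list(regions = regions, counts = counts, observations = obs,
         n_replicates = 13L),
    class = "lab_fixture"
  )
  validate_lab_fixture(fixture)
  fixture
}

validate_lab_fixture <- function(fx) {
  P <- build_physarum_graph(fx$observations, regions = fx$regions,
                            n_replicates = fx$n_replicates)
  comp_at <- function(w) connectivity_report(threshold_graph(P, as.integer(w)))
  fail <- function(msg) stop("lab fixture invariant violated: ", msg,
                             call. = FALSE)
  e <- P$edges
  inc_tomis <- e$count[e$region_a == "Tomis" | e$region_b == "Tomis"]
  if (max(inc_tomis) != 3L) fail("Tomis max incident count must be 3")
  seg <- c("Sirmium", "Singidunum")
  cut <- e$count[xor(e$region_a %in% seg, e$region_b %in% seg)]
  if (max(cut) != 3L) fail("Sirmium-Singidunum cut max count must be 3")
  th <- e$count[(e$region_a == "Traianoupolis" & e$region_b == "Hadrianopolis") |
                  (e$region_b == "Traianoupolis" & e$region_a == "Hadrianopolis")]
  if (length(th) != 1L || th < 10L) fail("Traianoupolis-Hadrianopolis >= 10")
  th_pair <- e$region_a %in% c("Traianoupolis", "Hadrianopolis") &
    e$region_b %in% c("Traianoupolis", "Hadrianopolis")
  if (any(e$count[!th_pair] >= 10L)) {
    fail("only Traianoupolis-Hadrianopolis may reach count 10")
  }
  if (!connectivity_report(threshold_graph(P, 3L))$planar ||
      length(comp_at(3L)$components) != 1L) {
    fail("3/13 graph must be one planar component")
  }
  if (comp_at(1L)$planar) fail("1/13 graph must be non-planar")
  if (!comp_at(2L)$planar) fail("2/13 graph must be planar")
  r4 <- comp_at(4L)
  if (!"Tomis" %in% r4$isolated) fail("Tomis isolated above 3/13")
  if (!any(vapply(r4$components, function(cc) setequal(cc, seg), logical(1)))) {
    fail("Sirmium-Singidunum a 2-node segment above 3/13")
  }
  r6 <- comp_at(6L)
  if (!setequal(r6$isolated,
                c("Tomis", "Marcianopolis", "Sirmium", "Singidunum"))) {
    fail("exactly Tomis, Marcianopolis, Sirmium, Singidunum isolated at 6/13")
  }
  r7 <- comp_at(7L)
  triads <- r7$components[vapply(r7$components, length, integer(1)) == 3L]
  want <- list(c("Doclea", "Dyrrachium", "Nicopolis"),
               c("Remesiana", "Serdica", "Philippopolis"),
               c("Scupi", "Thessaloniki", "Philippoi"))
  ok <- length(triads) == 3L && all(vapply(want, function(w) {
    any(vapply(triads, function(tt) setequal(tt, w), logical(1)))
  }, logical(1)))
  if (!ok) fail("7/13 three-node segments must be the three listed triads")
  t10 <- threshold_graph(P, 10L)
  if (nrow(t10$edges) != 1L ||
      !setequal(c(t10$edges$region_a, t10$edges$region_b),
                c("Traianoupolis", "Hadrianopolis"))) {
    fail("only Traianoupolis-Hadrianopolis survives at 10/13")
  }
  invisible(fx)
}

#' @export
print.lab_fixture <- function(x, ...) {
  cat(sprintf(
    "<lab_fixture> synthetic: %d regions, %d distinct edges, %d replicates\n",
    length(x$regions), nrow(x$counts), x$n_replicates
  ))
  invisible(x)
}

#' Ridge test arena
#'
#' A 200 x 200 fully habitable arena split by a Gaussian ridge of amplitude
#' 0.9 running down the middle, with low-elevation corridors around its two
#' ends; two sites sit on opposite sides of the ridge at elevation below
#' 0.1. Used for the terrain-avoidance and pore-localisation experiments.
#' Deterministic for a given seed.
#'
#' @param seed integer seed (reserved for optional terrain noise).
#' @param noise_sd additive Gaussian terrain noise (default 0).
#' @return An `arena` with heightfield.
#' @export
ridge_arena <- function(seed = 1L, noise_sd = 0) {
  hf <- synth_heightfield(
    width = 200L, height_px = 200L,
    ridges = tibble::tibble(
      center_row = 99.5, center_col = 99.5, orientation = 90,
      amplitude = 0.9, sigma_along = 55, sigma_across = 12
    ),
    seed = seed, noise_sd = noise_sd
  )
  sites <- tibble::tibble(
    region_id = c(1L, 2L), name = c("west", "east"),
    row = c(100L, 100L), col = c(30L, 170L)
  )
  make_arena(matrix(TRUE, 200L, 200L), sites, hf)
}

#' Flat three-site arena
#'
#' A 200 x 200 fully habitable arena with no heightfield and three sites in
#' an equilateral layout — the minimal analogue of a full-coverage
#' adaptation run constrained by three nutrient stimuli.
#'
#' @return An `arena` (no-height condition).
#' @export
triangle_arena <- function() {
  r <- 60
  cx <- 100
  ang <- c(90, 210, 330) * pi / 180
  sites <- tibble::tibble(
    region_id = 1:3, name = c("north", "southwest", "southeast"),
    row = as.integer(round(cx - r * sin(ang))),
    col = as.integer(round(cx + r * cos(ang)))
  )
  make_arena(matrix(TRUE, 200L, 200L), sites, NULL)
}
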