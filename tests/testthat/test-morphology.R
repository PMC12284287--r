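straight_dendrite <- function(n = 10, total = 100, radius = 1) {
  step <- total / n
  nodes <- data.frame(id = 1:(n + 1), type = c(1L, rep(3L, n)),
                      x = seq(0, total, by = step), y = 0, z = 0,
                      radius = radius, parent = c(-1L, 1:n))
  new_morphology(nodes, cell_id = "straight")
}

symmetric_y <- function(stem = 50, daughter = 50, r_stem = 1,
                        r_daughter = 0.5) {
  nodes <- data.frame(
    id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
    x = c(0, stem / 2, stem, stem + daughter / sqrt(2),
          stem + daughter / sqrt(2)),
    y = c(0, 0, 0, daughter / sqrt(2), -daughter / sqrt(2)),
    z = 0,
    radius = c(1, r_stem, r_stem, r_daughter, r_daughter),
    parent = c(-1L, 1L, 2L, 3L, 3L))
  new_morphology(nodes, cell_id = "y")
}

test_that("SWC parsing validates the tree and reports offending lines", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"), f)
  m <- read_swc(f)
  expect_equal(nrow(m$nodes), 2)
  expect_equal(morpho_metrics(m)$total_dendritic_length, 10)
  # undefined parent: error names the line
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 7"), f)
  expect_error(read_swc(f), "undefined parent ids at lines: 2")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 0 1"), f)
  expect_error(read_swc(f), "non-positive radius")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 1", "3 3 2 0 0 1 1",
               "4 3 3 0 0 1 5", "5 3 4 0 0 1 4"), f)
  expect_error(read_swc(f), "parent does not precede")
})

test_that("generated trees round-trip through SWC unchanged", {
  p <- sample_cell("prototypic_Nkx", rng_seed = 4)
  m <- generate_swc(p, rng_seed = 11)
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f, group = m$group)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-8)
  expect_equal(m2$nodes$radius, m$nodes$radius, tolerance = 1e-8)
  expect_identical(m2$nodes$parent, m$nodes$parent)
})

test_that("cylinder and Y geometries give textbook metrics", {
  m <- straight_dendrite()
  mm <- morpho_metrics(m, soma_surface = "disc")
  expect_equal(mm$total_dendritic_length, 100)
  expect_equal(mm$bifurcation_count, 0L)
  expect_equal(mm$termination_count, 1L)
  expect_equal(mm$primary_dendrite_count, 1L)
  expect_equal(mm$soma_area, pi * 1^2)
  expect_equal(mm$total_surface_area - pi, 2 * pi * 1 * 100,
               tolerance = 1e-9)
  y <- symmetric_y()
  my <- morpho_metrics(y)
  expect_equal(my$total_dendritic_length, 150)
  expect_equal(my$bifurcation_count, 1L)
  expect_equal(my$termination_count, 2L)
  expect_equal(my$mean_dendrite_length, 150)
})

test_that("unbranched stems follow the zero-bifurcation limit", {
  p <- sample_cell("prototypic_PV", rng_seed = 5)
  p$dendrite_geometry$bifurcation_prob <- 0
  m <- generate_swc(p, rng_seed = 6)
  mm <- morpho_metrics(m)
  expect_equal(mm$bifurcation_count, 0L)
  expect_equal(mm$termination_count, mm$primary_dendrite_count)
})

test_that("the Euler identity holds on random generated trees", {
  set.seed(14)
  for (i in 1:150) {
    p <- sample_cell(sample(gpe_groups(), 1))
    mm <- morpho_metrics(generate_swc(p))
    expect_identical(mm$termination_count,
                     mm$bifurcation_count + mm$primary_dendrite_count)
  }
})

test_that("mean bifurcation count matches the branching-process expectation", {
  p <- sample_cell("prototypic_PV", rng_seed = 1)
  p$dendrite_geometry$bifurcation_prob <- 0.5
  set.seed(10)
  bif <- 0; stems <- 0
  for (i in 1:400) {
    m <- generate_swc(p)
    mm <- morpho_metrics(m)
    bif <- bif + mm$bifurcation_count
    stems <- stems + mm$primary_dendrite_count
  }
  per_stem <- bif / stems
  expected <- expected_bifurcations(0.5, 1)
  expect_lt(abs(per_stem - expected) / expected, 0.10)
})

test_that("Sholl profiles match the stated simple geometries", {
  m <- straight_dendrite()
  s <- sholl(m, step = 10)
  expect_equal(s$intersections, rep(1L, 10))
  expect_equal(max(s$radius), 100)
  y <- symmetric_y()  # bifurcation at 50, daughters reach ~100
  sy <- sholl(y, step = 10)
  expect_true(all(sy$intersections[sy$radius <= 50] == 1L))
  expect_true(all(sy$intersections[sy$radius > 50 &
                                     sy$radius <= 70] == 2L))
})

test_that("Sholl counts equal the dense-resampling oracle on random trees", {
  set.seed(3)
  for (i in 1:40) {
    p <- sample_cell(sample(gpe_groups(), 1))
    m <- generate_swc(p)
    expect_identical(sholl(m), sholl_bruteforce(m))
  }
})

test_that("branch-order diameters decrease with order under taper", {
  y <- symmetric_y()
  bo <- branch_order_diameters(y)
  expect_equal(unname(bo$order_diameters["order1"]), 2)
  expect_equal(unname(bo$order_diameters["order2"]), 1)
  expect_true(is.na(bo$order_diameters["order_gt2"]))
  m1 <- straight_dendrite()
  b1 <- branch_order_diameters(m1)
  expect_true(is.na(b1$order_diameters["order2"]))
  expect_true("order2" %in% attr(b1$order_diameters, "empty_classes"))
  # generator trees: strict decrease across populated classes
  set.seed(8)
  p <- sample_cell("prototypic_PV",
                   overrides = list(dendrite_geometry = list(
                     n_primary = 4, mean_segment_len = 40, taper = 0.006,
                     base_diameter = 2, bifurcation_prob = 0.8)))
  m <- generate_swc(p)
  od <- branch_order_diameters(m)$order_diameters
  od <- od[!is.na(od)]
  expect_true(all(diff(od) < 0))
})

test_that("metrics are invariant to rigid motion and scale as expected", {
  p <- sample_cell("arkypallidal", rng_seed = 9)
  m <- generate_swc(p, rng_seed = 10)
  base <- morpho_metrics(m)
  # rotation about z plus translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% R
  m2 <- m
  m2$nodes$x <- xyz[, 1] + 40; m2$nodes$y <- xyz[, 2] - 13
  m2$nodes$z <- xyz[, 3] + 5
  rot <- morpho_metrics(m2)
  expect_equal(rot$total_dendritic_length, base$total_dendritic_length,
               tolerance = 1e-9)
  expect_equal(rot$total_surface_area, base$total_surface_area,
               tolerance = 1e-9)
  expect_identical(rot$bifurcation_count, base$bifurcation_count)
  expect_equal(sholl(m2)$intersections, sholl(m)$intersections)
  # scaling coordinates and radii by k: lengths x k, areas x k^2
  k <- 2.5
  m3 <- m
  m3$nodes[, c("x", "y", "z", "radius")] <- m$nodes[, c("x", "y", "z",
                                                        "radius")] * k
  sc <- morpho_metrics(m3)
  expect_equal(sc$total_dendritic_length, k * base$total_dendritic_length,
               tolerance = 1e-9)
  expect_equal(sc$soma_area, k^2 * base$soma_area, tolerance = 1e-9)
  expect_equal(sc$total_surface_area, k^2 * base$total_surface_area,
               tolerance = 1e-9)
})
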