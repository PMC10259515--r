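make_tables <- function(cells, bonds) {
  structure(list(cells = cells, bonds = bonds), class = "cell_bond_tables")
}

toy_tables <- function() {
  cells <- expand.grid(
    cell_id = c("c1", "c2", "c3"), frame = 0:9,
    stringsAsFactors = FALSE
  )
  cells$cx_um <- 0
  cells$cy_um <- 0
  cells$area_um2 <- 30
  cells$perimeter_um <- 20
  bonds <- rbind(
    data.frame(frame = 0:9, cell_id_a = "c1", cell_id_b = "c2", length_um = 2),
    data.frame(frame = 0:4, cell_id_a = "c2", cell_id_b = "c3", length_um = 2)
  )
  bonds$polyline <- rep(list(NULL), nrow(bonds))
  make_tables(cells, bonds)
}

test_that("the dynamic network mirrors the bond table frame by frame", {
  net <- build_dynamic_network(toy_tables())
  expect_length(net, 10)
  deg <- function(f, id) length(igraph::neighbors(net[[as.character(f)]], id))
  expect_equal(deg(0, "c2"), 2)
  expect_equal(deg(4, "c2"), 2)
  expect_equal(deg(5, "c2"), 1) # c2-c3 bond disappears exactly at frame 5
  expect_equal(deg(5, "c3"), 0)

  # empty bond table -> edgeless graphs
  tb <- toy_tables()
  tb$bonds <- tb$bonds[0, ]
  net0 <- build_dynamic_network(tb)
  expect_true(all(vapply(net0, igraph::ecount, numeric(1)) == 0))
})

test_that("cumulative neighbor difference obeys its defining identities", {
  ns <- generate_neighbor_series(60, bias = 0, p_exchange = 0.5, seed = 8)

  # telescoping: D(T) - D(T-1) = N_T - M_T at every frame
  d <- cumulative_neighbor_difference(ns, cumulative = TRUE)
  expect_equal(diff(d), (ns$n_a - ns$m_b)[-1])
  expect_equal(d[1], ns$n_a[1] - ns$m_b[1])

  # swapping sibling labels negates D exactly
  swapped <- ns
  names(swapped)[match(c("n_a", "m_b"), names(swapped))] <- c("m_b", "n_a")
  expect_equal(
    cumulative_neighbor_difference(swapped, cumulative = TRUE),
    -d
  )

  # constant difference accumulates linearly
  flat <- data.frame(frame = 1:10, n_a = rep(5, 10), m_b = rep(4, 10))
  expect_equal(cumulative_neighbor_difference(flat, 10), 10)
  # equal counts give identically zero
  eq <- data.frame(frame = 1:10, n_a = rep(6, 10), m_b = rep(6, 10))
  expect_equal(cumulative_neighbor_difference(eq, cumulative = TRUE), rep(0, 10))
  # alternating +1/-1 stays bounded by 1
  alt <- data.frame(frame = 1:20, n_a = 6 + rep(c(1, 0), 10), m_b = 6 + rep(c(0, 1), 10))
  expect_lte(max(abs(cumulative_neighbor_difference(alt, cumulative = TRUE))), 1)

  expect_error(cumulative_neighbor_difference(ns, T = 0), "out of range")
  expect_error(cumulative_neighbor_difference(ns, T = 61), "out of range")
})

test_that("counting or excluding the sibling-sibling edge leaves D unchanged", {
  ns <- generate_neighbor_series(50, bias = 1, seed = 5)
  with_edge <- ns
  with_edge$n_a <- with_edge$n_a + 1L # both siblings gain the mutual edge
  with_edge$m_b <- with_edge$m_b + 1L
  expect_equal(
    cumulative_neighbor_difference(with_edge, cumulative = TRUE),
    cumulative_neighbor_difference(ns, cumulative = TRUE)
  )
})

test_that("the popular cell is detected from biased neighbor series", {
  up <- generate_neighbor_series(50, bias = 1, seed = 2)
  res <- popular_cell(up)
  expect_equal(res$popular, "A")
  expect_equal(res$slope, 1, tolerance = 0.05)

  dn <- popular_cell(generate_neighbor_series(50, bias = -1, seed = 2))
  expect_equal(dn$popular, "B")

  bal <- popular_cell(generate_neighbor_series(200, bias = 0, seed = 2))
  expect_equal(bal$popular, "none")
})

test_that("loess smoothing reproduces polynomials and orders spans by roughness", {
  # constant and linear trajectories are reproduced exactly
  lin <- data.frame(group = "g", frame = 1:40, D = 2 * (1:40) + 3)
  sm <- smooth_difference(lin, absolute = FALSE)
  expect_equal(sm$smoothed, lin$D, tolerance = 1e-6)
  const <- data.frame(group = "g", frame = 1:40, D = rep(7, 40))
  expect_equal(smooth_difference(const, absolute = FALSE)$smoothed, rep(7, 40),
    tolerance = 1e-9
  )

  # larger span -> smaller total variation on a noisy series
  set.seed(9)
  noisy <- data.frame(group = "g", frame = 1:80, D = cumsum(rnorm(80)))
  tv <- function(span) {
    s <- smooth_difference(noisy, span = span, absolute = FALSE)$smoothed
    sum(abs(diff(s)))
  }
  expect_lt(tv(1), tv(0.3))

  # grouping keeps trajectories separate
  two <- rbind(
    data.frame(group = "inverting", frame = 1:30, D = 1:30),
    data.frame(group = "stationary", frame = 1:30, D = rep(0, 30))
  )
  sm2 <- smooth_difference(two)
  expect_equal(sm2$smoothed[sm2$group == "stationary"], rep(0, 30), tolerance = 1e-9)
})

test_that("siblings are labeled retrospectively from final position", {
  tr <- make_tracks(
    a = cbind(seq(0, 5, length.out = 12), 0), # finishes posterior (larger x)
    b = cbind(seq(0, -5, length.out = 12), 0) # finishes anterior
  )
  p <- cell_pair(tr, "a", "b")
  expect_equal(label_siblings(p, "a", "b"), c("b", "a"))
})

test_that("neighbor series extracted from a network match the bond table", {
  net <- build_dynamic_network(toy_tables())
  ns <- neighbor_series(net, "c2", "c3")
  expect_equal(ns$n_a[1], 2) # c2 touches c1 and c3 at frame 0
  expect_equal(ns$m_b[1], 1)
  expect_equal(ns$n_a[6], 1) # after the c2-c3 bond vanished
  expect_equal(ns$m_b[6], 0)
  d <- cumulative_neighbor_difference(ns, cumulative = TRUE)
  expect_equal(d[10], sum(ns$n_a - ns$m_b))
})
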