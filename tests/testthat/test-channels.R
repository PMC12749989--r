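single_atom <- function(x = 0, y = 0, z = 0, element = "X") {
  as_structure(tibble::tibble(chain = "A", resno = 1L, resname = "UNK",
                              atom = "C", element = element,
                              x = x, y = y, z = z, occ = 1, b = 0), "one")
}

test_that("clearance is distance to the nearest atom surface", {
  rt <- c(X = 1.5)
  expect_warning(
    g <- build_clearance_grid(single_atom(element = "Q"), spacing = 1,
                              radius_table = rt, padding = 4),
    "fallback")
  g <- suppressWarnings(build_clearance_grid(single_atom(), spacing = 1,
                                             radius_table = rt, padding = 4))
  node <- round((c(4, 0, 0) - g$origin) / g$spacing) + 1
  expect_equal(g$clearance[node[1], node[2], node[3]], 4 - 1.5)
  ## two atoms: clearance is the min of the single-atom clearances
  two <- as_structure(tibble::tibble(
    chain = "A", resno = 1:2, resname = "UNK", atom = "C", element = "X",
    x = c(0, 6), y = 0, z = 0, occ = 1, b = 0), "two")
  g2 <- build_clearance_grid(two, spacing = 1, radius_table = rt, padding = 4)
  node2 <- round((c(4, 0, 0) - g2$origin) / g2$spacing) + 1
  expect_equal(g2$clearance[node2[1], node2[2], node2[3]],
               min(4 - 1.5, 2 - 1.5))
})

test_that("the clearance field is equivariant under grid-aligned translation", {
  s <- make_channel_fixture("cylinder", radius = 2.5)
  g0 <- build_clearance_grid(s, spacing = 0.8)
  shift <- c(2, -1, 3) * 0.8          # integer number of spacings
  s2 <- set_coords(s, sweep(coords(s), 2, shift, "+"))
  g2 <- build_clearance_grid(s2, spacing = 0.8)
  expect_equal(g2$origin, g0$origin + shift, tolerance = 1e-9)
  expect_equal(g2$clearance, g0$clearance, tolerance = 1e-9)
})

test_that("boundary nodes are exterior and spacing is validated", {
  s <- single_atom()
  g <- suppressWarnings(build_clearance_grid(s, spacing = 1, padding = 5))
  expect_true(all(g$exterior[1, , ]))
  expect_true(all(g$exterior[, , dim(g$exterior)[3]]))
  expect_error(build_clearance_grid(s, spacing = 0.1), class = "rnd_config_error")
  expect_error(build_clearance_grid(s, spacing = 3), class = "rnd_config_error")
})

test_that("a cylindrical pore is recovered within one grid spacing", {
  fx <- make_channel_fixture("cylinder", radius = 3)
  g <- build_clearance_grid(fx)
  ch <- find_channel(g, attr(fx, "seed_point"))
  expect_true(ch$reached_exterior)
  expect_equal(ch$bottleneck_radius, 3, tolerance = g$spacing)
})

test_that("a blind cone bottlenecks at its narrow end", {
  fx <- make_channel_fixture("cone", radius = 1.2, radius_wide = 4)
  g <- build_clearance_grid(fx)
  ch <- find_channel(g, attr(fx, "seed_point"))
  expect_true(ch$reached_exterior)
  expect_equal(ch$bottleneck_radius, 1.2, tolerance = g$spacing)
})

test_that("a sealed cavity reports no exit with the best achievable clearance", {
  fx <- make_channel_fixture("sealed", radius = 3)
  g <- build_clearance_grid(fx)
  ch <- find_channel(g, attr(fx, "seed_point"))
  expect_false(ch$reached_exterior)
  expect_true(is.finite(ch$bottleneck_radius))
  expect_lte(ch$bottleneck_radius, 0)
})

test_that("a seed in bulk solvent reaches the exterior immediately", {
  fx <- make_channel_fixture("cylinder", radius = 2.5)
  g <- build_clearance_grid(fx)
  corner <- g$origin + (g$dims - 2) * g$spacing
  ch <- find_channel(g, corner)
  expect_true(ch$reached_exterior)
  expect_gte(ch$bottleneck_radius, g$probe)
  expect_lte(nrow(ch$path), 2)
})

test_that("channel profiles are monotone in arc length with min at the bottleneck", {
  fx <- make_channel_fixture("cylinder", radius = 3)
  g <- build_clearance_grid(fx)
  ch <- find_channel(g, attr(fx, "seed_point"))
  prof <- channel_profile(ch)
  expect_equal(prof$arc_length[1], 0)
  expect_true(all(diff(prof$arc_length) > 0))
  expect_equal(min(prof$clearance), ch$bottleneck_radius)
  ## path nodes are 26-adjacent: steps no longer than a body diagonal
  expect_true(all(diff(prof$arc_length) <= sqrt(3) * g$spacing + 1e-9))
  ## roughly constant profile inside the tube
  inside <- prof$clearance[prof$clearance < g$probe]
  expect_true(all(abs(inside - 3) <= g$spacing + 1e-9))
})

test_that("inflating van der Waals radii never widens a bottleneck", {
  fx <- make_channel_fixture("cylinder", radius = 2.5)
  bott <- vapply(c(0, 0.3, 0.6), function(delta) {
    g <- build_clearance_grid(fx, radius_table = c(C = 1.7 + delta))
    find_channel(g, attr(fx, "seed_point"))$bottleneck_radius
  }, numeric(1))
  expect_true(all(diff(bott) <= 1e-9))
  ## with a single atom type the shift is exactly -delta
  expect_equal(bott[2], bott[1] - 0.3, tolerance = 1e-9)
})

test_that("halving the spacing moves the estimate by less than the coarser spacing", {
  fx <- make_channel_fixture("cylinder", radius = 2.5)
  b1 <- find_channel(build_clearance_grid(fx, spacing = 1.2),
                     attr(fx, "seed_point"))$bottleneck_radius
  b2 <- find_channel(build_clearance_grid(fx, spacing = 0.6),
                     attr(fx, "seed_point"))$bottleneck_radius
  expect_lt(abs(b2 - b1), 1.2)
  expect_equal(b2, 2.5, tolerance = 0.6)
})

test_that("the maximin value matches the naive widest-path oracle on small grids", {
  for (seed in 1:4) {
    set.seed(700 + seed)
    n <- 12
    s <- as_structure(tibble::tibble(
      chain = "A", resno = seq_len(n), resname = "UNK", atom = "C",
      element = "C", x = stats::runif(n, -2.5, 2.5),
      y = stats::runif(n, -2.5, 2.5), z = stats::runif(n, -2.5, 2.5),
      occ = 1, b = 0), "rand")
    g <- build_clearance_grid(s, spacing = 0.8, padding = 2.4, probe = 1.5)
    expect_true(all(g$dims <= 20))
    seed_pt <- c(0, 0, 0)
    ch <- find_channel(g, seed_pt)
    ora <- maximin_oracle(g, rndcensus:::node_at(g, seed_pt))
    expect_equal(ch$bottleneck_radius, ora, tolerance = 1e-12)
  }
})

test_that("channel results write as pseudo-atom PDB with clearance in B", {
  fx <- make_channel_fixture("cylinder", radius = 3)
  g <- build_clearance_grid(fx)
  ch <- find_channel(g, attr(fx, "seed_point"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_channel_pdb(ch, f)
  back <- read_structure(f)
  expect_equal(nrow(back), nrow(ch$path))
  expect_equal(back$b, round(ch$clearance, 2), tolerance = 0.01)
})
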