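test_that("signed distance is exact for circles and minimal over unions", {
  c5 <- shape_circle(c(0, 0), 5)
  expect_equal(signed_distance(c5, 3, 4), 0)
  expect_equal(signed_distance(c5, 6, 8), 5)
  expect_equal(signed_distance(c5, 0, 0), -5)
  expect_equal(signed_distance(shape_line("x", 10), 3, 99), -7)

  # union = pointwise min of member signed distances (brute force)
  set.seed(7)
  shapes <- list(shape_circle(c(0, 0), 5), shape_circle(c(4, 0), 3),
                 shape_line("y", -2))
  px <- runif(200, -10, 10); py <- runif(200, -10, 10)
  expected <- pmin(sqrt(px^2 + py^2) - 5,
                   sqrt((px - 4)^2 + py^2) - 3,
                   py - (-2))
  expect_equal(signed_distance(shapes, px, py), expected)
  expect_error(signed_distance(list(), 0, 0), "nonempty")
})

test_that("grid invariants are enforced and node coordinates are exact", {
  g <- grid_spec(0.5, 11, 7, origin = c(1, 2))
  expect_equal(g$x[3], 1 + 2 * 0.5)
  expect_equal(g$y[7], 2 + 6 * 0.5)
  expect_error(grid_spec(0, 10, 10), "h must be > 0")
  expect_error(grid_spec(1, 2, 10), "nx")
  expect_error(grid_spec(1, 10, 0), "ny")
})

test_that("interface roles fix their boundary-condition kind", {
  sec <- interface_spec(shape_circle(c(0, 0), 5), "secreting_cell",
                        bc_value = 1)
  expect_identical(sec$bc_kind, "dirichlet")
  bm <- interface_spec(shape_circle(c(0, 0), 40), "basement_membrane")
  expect_identical(bm$bc_kind, "zero_flux")
  expect_error(interface_spec(shape_circle(c(0, 0), 5), "inert_cell",
                              bc_value = 1), "secreting")
})

test_that("single-source scenario fields match brute-force node counts", {
  sc <- build_single_source_scenario(h = 1, domain_um = c(60, 60),
                                     disc_radius_um = 5)
  expect_length(sc$interfaces, 1)
  expect_identical(sc$interfaces[[1]]$bc_kind, "dirichlet")

  # brute-force point-in-disc count over all nodes
  g <- sc$grid
  xs <- matrix(g$x, g$nx, g$ny)
  ys <- matrix(rep(g$y, each = g$nx), g$nx, g$ny)
  inside <- sqrt((xs - 30)^2 + (ys - 30)^2) <= 5
  expect_identical(sum(sc$inside_secreting), sum(inside))
  expect_true(all(sc$initial_M[inside] == 1))
  expect_true(all(sc$initial_M[!inside] == 0))
  expect_true(all(sc$initial_E[!inside] == 0.85))
  expect_true(all(sc$initial_E[inside] == 0))

  # initial degraded-equivalent radius ~ disc radius
  mask <- degraded_mask(sc$initial_E, sc)
  expect_equal(equivalent_radius(mask, g), 5, tolerance = 1 / 5)
  expect_error(build_single_source_scenario(h = 1, domain_um = c(8, 8),
                                            disc_radius_um = 5),
               "outside the domain")
})

test_that("scenario invariants hold on construction", {
  for (sc in list(build_single_source_scenario(h = 1, domain_um = c(40, 40)),
                  build_duct_scenario(h = 2),
                  build_1d_column_scenario(length_um = 100))) {
    expect_true(all(sc$initial_E >= 0 & sc$initial_E <= 1))
    expect_true(all(sc$initial_M >= 0))
    expect_true(all(sc$initial_M[sc$phi_secreting < 0] ==
                      sc$params$M_boundary))
    expect_true(all(sc$initial_E[sc$stroma] == sc$params$E_init))
    expect_true(all(sc$initial_E[!sc$outside_bm & sc$active] == 0))  # lumen
  }
})

test_that("ductal scenario places stromal cells 10 um outside the BM", {
  sc <- build_duct_scenario()
  bm <- sc$interfaces[[1]]
  expect_identical(bm$role, "basement_membrane")
  stromal <- Filter(function(i) i$role == "secreting_cell", sc$interfaces)
  expect_length(stromal, 3)
  for (s in stromal) {
    circ <- s$shapes[[1]]
    gap <- sqrt(sum((circ$center - bm$shapes[[1]]$center)^2)) -
      bm$shapes[[1]]$radius - circ$radius
    expect_equal(gap, 10, tolerance = 1e-10)
  }
  # tumor cells sit strictly inside the BM
  tumor <- Filter(function(i) i$role == "inert_cell", sc$interfaces)
  for (circ in tumor[[1]]$shapes) {
    expect_lt(sqrt(sum((circ$center - bm$shapes[[1]]$center)^2)) +
                circ$radius, bm$shapes[[1]]$radius)
  }
})

test_that("ductal scenario without stromal cells has no MMP source, ever", {
  sc <- build_duct_scenario(h = 2, stromal_angles_deg = numeric(0))
  expect_true(all(sc$initial_M == 0))
  st <- run_steps(sc, 5)
  expect_true(all(st$M == 0))
})

test_that("geometry violations are rejected with the offending interface", {
  expect_error(
    build_duct_scenario(domain_um = c(100, 100), bm_center = c(50, 50),
                           bm_radius_um = 40),
    "stromal cell")
  g <- grid_spec(1, 41, 41)
  expect_error(new_scenario(g, list(
    interface_spec(shape_circle(c(10, 10), 5), "secreting_cell"),
    interface_spec(shape_circle(c(16, 10), 5), "inert_cell", bc_value = 0,
                   label = "blocker"))), "overlap")
})

test_that("deterministic rebuilds give identical scenarios", {
  a <- build_duct_scenario(h = 2)
  b <- build_duct_scenario(h = 2)
  expect_identical(a$initial_M, b$initial_M)
  expect_identical(a$phi_secreting, b$phi_secreting)
})

test_that("1-D column warns when shorter than 10 length scales", {
  expect_silent(build_1d_column_scenario(length_um = 100, h = 1))
  expect_warning(build_1d_column_scenario(length_um = 40, h = 1),
                 "truncation")
  # L(0) = 126.5 um: a 50 um column is far too short
  expect_warning(sc <- build_1d_column_scenario(length_um = 50, h = 1,
                                                E_init = 0), "10 L")
  expect_equal(sc$grid$ny, 1L)
})
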