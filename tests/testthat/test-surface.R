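test_that("every vertex of a simplex is a surface atom", {
  tet <- atom_table(1:4, c(0, 2, 0, 0), c(0, 0, 2, 0), c(0, 0, 0, 2),
                    weight = 2)
  s <- alpha_surface(tet, alpha = 0)
  expect_true(all(s$on_surface))
  expect_equal(s$omega[1], pi / 2, tolerance = 1e-12)
})

test_that("solid angles match the closed-form oracle on random tetrahedra", {
  for (seed in 1:20) {
    set.seed(seed)
    tet <- matrix(rnorm(12), 4, 3)
    # reject near-degenerate draws
    if (abs(det(sweep(tet[2:4, ], 2, tet[1, ]))) < 0.1) next
    om <- solid_angle_at_vertex(tet[1, ], list(tet))
    om_vos <- oracle_vertex_solid_angle(tet[1, ], tet[2, ], tet[3, ],
                                        tet[4, ])
    expect_equal(om, om_vos, tolerance = 1e-9)
  }
})

test_that("solid angle is additive over tetrahedra sharing the apex", {
  # two congruent orthogonal-corner tetrahedra with disjoint interiors
  t1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  t2 <- rbind(c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(solid_angle_at_vertex(c(0, 0, 0), list(t1)), pi / 2,
               tolerance = 1e-12)
  expect_equal(solid_angle_at_vertex(c(0, 0, 0), list(t1, t2)), pi,
               tolerance = 1e-12)
  expect_error(
    solid_angle_at_vertex(c(0, 0, 0),
                          list(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                     c(3, 0, 0)))),
    "degenerate")
})

test_that("an interior lattice atom is excluded from the surface and closes 4*pi", {
  g <- expand.grid(x = 0:2, y = 0:2, z = 0:2)
  gr <- atom_table(1:27, g$x, g$y, g$z, weight = 1)
  s <- alpha_surface(gr, alpha = 0)
  center <- which(g$x == 1 & g$y == 1 & g$z == 1)
  expect_equal(sum(s$on_surface), 26)
  expect_false(s$on_surface[center])
  expect_equal(s$omega[center], 4 * pi, tolerance = 1e-9)
})

test_that("a point enclosed by a sphere of atoms is interior at large alpha", {
  set.seed(11)
  n <- 80
  phi <- runif(n, 0, 2 * pi); cz <- runif(n, -1, 1)
  sph <- atom_table(
    serial = 1:(n + 1),
    x = c(10 * sqrt(1 - cz^2) * cos(phi), 0),
    y = c(10 * sqrt(1 - cz^2) * sin(phi), 0),
    z = c(10 * cz, 0), weight = 1)
  s <- alpha_surface(sph, alpha = 150)
  expect_false(s$on_surface[n + 1])
})

test_that("convexity classification follows the cosine score with the documented tie-break", {
  r <- classify_convexity(c(0, pi, pi / 2))
  expect_equal(r$omega_prime, c(0.25, -0.25, cos(pi / 2) / 4))
  expect_equal(r$shape_label, c("convex", "concave", "concave"))
  expect_equal(r$boundary_score, c(FALSE, FALSE, TRUE))
  expect_true(all(abs(classify_convexity(runif(100, 0, 4 * pi))$omega_prime)
                  <= 0.25))
})

test_that("orthogonality distinguishes tangent, overlapping and separated spheres", {
  mk <- function(x2, w1, w2) {
    a <- atom_table(1:2, c(0, x2), c(0, 0), c(0, 0), weight = c(w1, w2))
    orthogonality(a[1, ], a[2, ])
  }
  expect_equal(mk(5, 2, 3)$relation, "orthogonal")
  expect_equal(mk(5, 2, 3)$gap, 0)
  expect_equal(mk(4, 2, 3)$relation, "sub_orthogonal")
  expect_equal(mk(4, 2, 3)$gap, -1)
  expect_equal(mk(9, 1, 1)$relation, "neither")
  expect_equal(mk(9, 1, 1)$gap, 7)
  a <- atom_table(1:2, c(0, 0), c(0, 0), c(0, 0), weight = 1)
  expect_error(orthogonality(a[1, ], a[2, ]), "coincident")
})

test_that("degenerate geometry is rejected", {
  expect_error(alpha_surface(atom_table(1:3, 0:2, c(0, 1, 0), c(0, 0, 0))),
               "at least 4")
  flat <- atom_table(1:5, runif(5), runif(5), rep(0, 5))
  expect_error(alpha_surface(flat), "coplanar")
})

test_that("surface sets and solid angles are invariant under rigid motion", {
  for (seed in c(2, 9, 31)) {
    atoms <- random_atoms(25, seed)
    s1 <- alpha_surface(atoms, alpha = 0)
    s2 <- alpha_surface(rotate_frame(atoms, seed + 100), alpha = 0)
    expect_equal(s1$on_surface, s2$on_surface)
    expect_equal(s1$omega, s2$omega, tolerance = 1e-9)
    expect_equal(s1$omega_prime, s2$omega_prime, tolerance = 1e-9)
  }
})

test_that("alpha_surface agrees with the brute-force enumeration oracle", {
  for (seed in 1:25) {
    n <- sample(8:24, 1)
    atoms <- random_atoms(n, seed + 500)
    alpha <- sample(c(0, 1, 4), 1)
    s <- alpha_surface(atoms, alpha = alpha)
    o <- oracle_alpha_complex(atoms, alpha)
    expect_equal(s$on_surface, o$on_surface,
                 info = paste("seed", seed, "alpha", alpha))
    expect_equal(s$n_incident, o$n_incident)
    expect_equal(s$omega, o$omega, tolerance = 1e-8)
  }
})

test_that("repeated runs on identical input are identical", {
  atoms <- random_atoms(30, 77)
  s1 <- alpha_surface(atoms, 0)
  s2 <- alpha_surface(atoms, 0)
  expect_identical(s1, s2)
})
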