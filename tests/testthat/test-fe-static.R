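# Uniaxial-traction patch test with roller supports on the three
# coordinate planes: the discrete solution must carry the exact constant
# stress state on any admissible mesh.
patch_test <- function(order) {
  p <- 2.5
  m <- generate_block_fixture(2, 2, 2, c(10, 10, 10), order = order)
  E <- rep(1000, n_elements(m))
  K <- assemble_elastic(m, E, 0.3)
  f <- osteosim:::traction_forces(m, m$facet_sets$zmax, c(0, 0, p * 100))
  fix <- unlist(lapply(1:3, function(c3) {
    3L * (which(abs(m$nodes[, c3]) < 1e-9) - 1L) + c3
  }))
  sol <- osteosim:::solve_dirichlet(K, f, fix, 0)
  S <- osteosim:::fem_element_stress(m$nodes, m$tets, E, 0.3, sol$u)
  list(S = S, p = p, sol = sol, m = m)
}

test_that("constant-stress patch test is exact for tet4 and tet10", {
  for (ord in 1:2) {
    pt <- patch_test(ord)
    expect_lt(max(abs(pt$S[, 3] - pt$p)) / pt$p, 1e-8)
    expect_lt(max(abs(pt$S[, c(1, 2, 4, 5, 6)])) / pt$p, 1e-8)
    vm <- osteosim:::von_mises_voigt(pt$S)
    expect_lt(max(abs(vm - pt$p)) / pt$p, 1e-8)
  }
})

test_that("zero loads give zero displacement and stress", {
  m <- generate_block_fixture(2, 2, 2, c(5, 5, 5))
  E <- rep(500, n_elements(m))
  K <- assemble_elastic(m, E, 0.3)
  fixn <- osteosim:::facet_nodes(m, m$facet_sets$zmin)
  fix <- as.vector(outer(3L * (fixn - 1L), 1:3, `+`))
  sol <- osteosim:::solve_dirichlet(K, numeric(nrow(K)), fix, 0)
  expect_equal(max(abs(sol$u)), 0)
})

test_that("unconstrained or bad-material systems raise distinct errors", {
  m <- generate_block_fixture(1, 1, 1, c(1, 1, 1))
  E <- rep(100, 6)
  K <- assemble_elastic(m, E, 0.3)
  expect_error(osteosim:::solve_dirichlet(K, numeric(nrow(K)), integer()),
               class = "osteosim_singular_system")
  expect_error(assemble_elastic(m, rep(0, 6), 0.3),
               class = "osteosim_bad_material")
  expect_error(assemble_elastic(m, c(NA, rep(1, 5)), 0.3),
               class = "osteosim_bad_material")
})

test_that("global equilibrium: base reactions balance the applied loads", {
  sl <- small_pair_solves()
  st <- assemble_and_solve(sl$pair$implanted, sl$mat_p,
                           default_load_cases()[[1]])
  expect_lt(sqrt(sum((st$reaction + st$applied)^2)) /
              sqrt(sum(st$applied^2)), 1e-6)
  expect_lt(st$residual, 1e-8)
})

test_that("cantilever tip deflection matches the Euler-Bernoulli closed form", {
  L <- 50; h <- 5; P <- 10; E0 <- 2000
  m <- generate_block_fixture(20, 2, 2, c(L, h, h), order = 2)
  E <- rep(E0, n_elements(m))
  K <- assemble_elastic(m, E, 0.3)
  f <- osteosim:::traction_forces(m, m$facet_sets$xmax, c(0, 0, -P))
  fixn <- osteosim:::facet_nodes(m, m$facet_sets$xmin)
  fix <- as.vector(outer(3L * (fixn - 1L), 1:3, `+`))
  sol <- osteosim:::solve_dirichlet(K, f, fix, 0)
  U <- matrix(sol$u, ncol = 3L, byrow = TRUE)
  tip <- mean(U[osteosim:::facet_nodes(m, m$facet_sets$xmax), 3])
  w_eb <- -P * L^3 / (3 * E0 * h^4 / 12)
  expect_lt(abs(tip - w_eb) / abs(w_eb), 0.05)
})

test_that("strain energy converges monotonically under beam refinement", {
  L <- 40; h <- 4; P <- 5; E0 <- 1000
  energy <- vapply(c(4L, 8L, 16L), function(nx) {
    m <- generate_block_fixture(nx, 1, 1, c(L, h, h), order = 2)
    E <- rep(E0, n_elements(m))
    K <- assemble_elastic(m, E, 0.3)
    f <- osteosim:::traction_forces(m, m$facet_sets$xmax, c(0, 0, -P))
    fixn <- osteosim:::facet_nodes(m, m$facet_sets$xmin)
    fix <- as.vector(outer(3L * (fixn - 1L), 1:3, `+`))
    sol <- osteosim:::solve_dirichlet(K, f, fix, 0)
    sum(sol$u * f) / 2
  }, 0)
  # displacement-based FE under-estimates compliance; energy grows to the limit
  expect_true(all(diff(energy) > 0))
})

test_that("principal stresses sort eigenvalues and preserve invariants", {
  expect_equal(principal_stresses(diag(c(3, 1, -2))), c(3, 1, -2))
  expect_equal(principal_stresses(diag(c(5, 5, 5))), c(5, 5, 5))
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    S <- (A + t(A)) / 2
    pr <- principal_stresses(S)
    expect_true(all(diff(pr) <= 1e-12))
    expect_equal(sum(pr), sum(diag(S)), tolerance = 1e-10)
    expect_equal(prod(pr), det(S), tolerance = 1e-9)
    # vectorized field path agrees with the dense eigensolver
    voigt <- matrix(c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[3, 1]),
                    nrow = 1)
    expect_equal(drop(osteosim:::principal_stress_field(voigt)), pr,
                 tolerance = 1e-9)
  }
  asym <- matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)
  expect_error(principal_stresses(asym), "symmetric")
})

test_that("von Mises stress has the uniaxial, hydrostatic and shifted limits", {
  expect_equal(von_mises(7, 0, 0), 7)
  expect_equal(von_mises(3, 3, 3), 0)
  expect_equal(von_mises(3, 1, -2), sqrt(19))
  expect_equal(von_mises(3 + 10, 1 + 10, -2 + 10), sqrt(19))
})

test_that("the stiffer implant shields the neck bone under standing load", {
  sl <- small_pair_solves()
  zone <- sl$pair$implanted$meta$zone
  neck_bone <- which(zone == "neck" & sl$pair$implanted$region == "bone")
  intact_neck <- which(sl$pair$intact$meta$zone == "neck")
  expect_lt(mean(sl$vm_p[neck_bone, "standing"]),
            mean(sl$vm_i[intact_neck, "standing"]))
})
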