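test_that("block fixture has the 6-tets-per-cell structure", {
  m <- generate_block_fixture(1, 1, 1, c(10, 10, 10))
  expect_equal(n_elements(m), 6L)
  expect_equal(n_nodes(m), 8L)
  expect_equal(n_elements(generate_block_fixture(2, 2, 2, c(10, 10, 10))),
               48L)
  expect_equal(n_elements(generate_block_fixture(3, 2, 1, c(30, 20, 10))),
               36L)
  expect_error(generate_block_fixture(0, 1, 1, c(1, 1, 1)))
  expect_error(generate_block_fixture(1, 1, 1, c(0, 1, 1)))
})

test_that("block fixture volumes tile the box and facet sets tile the faces", {
  for (ord in 1:2) {
    m <- generate_block_fixture(2, 3, 2, c(4, 6, 5), order = ord)
    expect_equal(sum(element_volumes(m)), 4 * 6 * 5)
    expect_true(all(element_volumes(m) > 0))
    a <- osteosim:::face_areas
    expect_equal(sum(a(m, m$facet_sets$zmax)), 4 * 6)
    expect_equal(sum(a(m, m$facet_sets$xmin)), 6 * 5)
    expect_true(all(check_mesh(m)$pass))
  }
})

test_that("femur fixture variants pass all mesh invariants", {
  pair <- small_femur_pair()
  for (m in pair) {
    expect_true(all(check_mesh(m)$pass))
    expect_true(all(c("base", "joint_patch", "greater_trochanter",
                      "neck_electrode") %in% names(m$facet_sets)))
  }
  expect_equal(sum(pair$intact$region == "implant"), 0L)
  expect_gt(sum(pair$implanted$region == "implant"), 0L)
  # no implant element owns a base facet
  bf <- boundary_faces(pair$implanted)
  base_key <- osteosim:::face_key(pair$implanted$facet_sets$base)
  owners <- bf$owner[osteosim:::face_key(bf$faces) %in% base_key]
  expect_true(all(pair$implanted$region[owners] == "bone"))
  # intact head exists, implanted head removed except the neck-sphere overlap
  expect_gt(sum(pair$intact$meta$zone == "head"),
            sum(pair$implanted$meta$zone == "head"))
})

test_that("femur generator is deterministic and variants share bone geometry", {
  fx <- femur_fixture_params(target_element_count = 2000)
  m1 <- generate_proximal_femur(fx)
  m2 <- generate_proximal_femur(fx)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  pair <- small_femur_pair()
  mt <- match_elements(pair$implanted, pair$intact)
  expect_true(all(!is.na(mt$ref_id)))
  expect_true(all(mt$distance < 1e-9))
})

test_that("stem-fit and parameter validation reject bad fixtures", {
  expect_error(femur_fixture_params(implanted = TRUE,
                                    implant_stem_radius = 10,
                                    shaft_inner_radius = 7),
               "does not fit")
  expect_error(femur_fixture_params(implanted = TRUE,
                                    implant_stem_length = 200),
               "shorter than the shaft")
  expect_error(femur_fixture_params(neck_length = -1), "positive")
  expect_error(femur_fixture_params(shaft_inner_radius = 20), "smaller")
})

test_that("synthetic HU field has three clean levels without noise", {
  pair <- small_femur_pair()
  hu <- synthetic_hu_field(pair$intact, noise_sd = 0)
  expect_setequal(unique(hu), c(1700, 700, 100))
  # marrow only inside the canal, cortical shell near the surface
  cent <- element_centroids(pair$intact)
  marrow <- hu == 100
  expect_true(all(cent[marrow, 1]^2 + cent[marrow, 2]^2 <
                    pair$intact$meta$canal_radius^2))
  hu_imp <- synthetic_hu_field(pair$implanted, noise_sd = 0)
  expect_true(all(is.na(hu_imp[pair$implanted$region == "implant"])))
  expect_true(all(!is.na(hu_imp[pair$implanted$region == "bone"])))
})

test_that("HU noise is seeded, clipped, and centred on the level means", {
  pair <- small_femur_pair()
  h1 <- synthetic_hu_field(pair$intact, noise_sd = 40, seed = 7)
  h2 <- synthetic_hu_field(pair$intact, noise_sd = 40, seed = 7)
  h3 <- synthetic_hu_field(pair$intact, noise_sd = 40, seed = 8)
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
  base <- synthetic_hu_field(pair$intact, noise_sd = 0)
  expect_true(all(abs(h1 - base) <= 3 * 40 + 1e-12))
  shell <- base == 1700
  n <- sum(shell)
  expect_lt(abs(mean(h1[shell]) - 1700), 2 * 40 / sqrt(n) + 40 * 0.1)
  expect_error(synthetic_hu_field(pair$intact, hu_marrow = 900,
                                  hu_cancellous = 700), "hu_marrow")
})

test_that("quadratic conversion inserts shared midside nodes", {
  m <- generate_block_fixture(2, 2, 2, c(2, 2, 2))
  q <- to_quadratic(m)
  expect_equal(q$order, 2L)
  expect_equal(ncol(q$tets), 10L)
  # every midside node sits at the midpoint of its corner pair
  for (e in c(1L, 17L, 48L)) {
    corners <- q$nodes[q$tets[e, 1:4], ]
    ep <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
    mids <- q$nodes[q$tets[e, 5:10], ]
    expect_equal(mids, (corners[ep[, 1], ] + corners[ep[, 2], ]) / 2)
  }
  expect_true(all(check_mesh(q)$pass))
})
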