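test_that("vtu round trip preserves nodes, connectivity, fields, facet sets", {
  m <- generate_block_fixture(2, 2, 2, c(10, 10, 10))
  m$region[1:5] <- "implant"
  fields <- list(hu = seq_len(n_elements(m)) * 1.5,
                 rho = runif(n_elements(m)))
  path <- withr::local_tempfile(fileext = ".vtu")
  write_mesh(m, path, fields = fields)
  r <- read_mesh(path)
  expect_equal(r$nodes, m$nodes, tolerance = 1e-12)
  expect_identical(r$tets, m$tets)
  expect_identical(r$region, m$region)
  expect_equal(r$meta$fields$hu, fields$hu)
  expect_equal(r$meta$fields$rho, fields$rho)
  expect_setequal(names(r$facet_sets), names(m$facet_sets))
  for (nm in names(m$facet_sets)) {
    expect_setequal(osteosim:::face_key(r$facet_sets[[nm]]),
                    osteosim:::face_key(m$facet_sets[[nm]]))
  }
})

test_that("vtu round trip preserves tet10 midside nodes", {
  m <- generate_block_fixture(1, 2, 1, c(5, 10, 5), order = 2)
  path <- withr::local_tempfile(fileext = ".vtu")
  write_mesh(m, path)
  r <- read_mesh(path)
  expect_equal(r$order, 2L)
  expect_identical(r$tets, m$tets)
  expect_equal(r$nodes, m$nodes, tolerance = 1e-12)
})

test_that("gmsh round trip preserves the mesh and element data", {
  m <- generate_block_fixture(2, 1, 2, c(4, 2, 4))
  m$region[seq(1, 9)] <- "implant"
  fields <- list(E = 100 + seq_len(n_elements(m)))
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, path, fields = fields)
  r <- read_mesh(path)
  expect_equal(r$nodes, m$nodes, tolerance = 1e-12)
  # element order may be grouped by region; compare as sets keyed by corners
  perm <- match(osteosim:::face_key(m$tets[, c(1, 2, 3)]),
                osteosim:::face_key(r$tets[, c(1, 2, 3)]))
  expect_true(all(!is.na(perm)))
  expect_identical(r$region[perm], m$region)
  expect_equal(r$meta$fields$E[perm], fields$E)
  expect_setequal(names(r$facet_sets), names(m$facet_sets))
})

test_that("gmsh tet10 round trip restores the canonical node ordering", {
  m <- generate_block_fixture(1, 1, 2, c(3, 3, 6), order = 2)
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, path)
  r <- read_mesh(path)
  expect_identical(r$tets, m$tets)
})

test_that("unsupported and malformed files raise distinct errors", {
  m <- generate_block_fixture(1, 1, 1, c(1, 1, 1))
  expect_error(write_mesh(m, "mesh.xyz"),
               class = "osteosim_unsupported_format")
  expect_error(read_mesh("mesh.xyz"), class = "osteosim_file_not_found")
  bad <- withr::local_tempfile(fileext = ".vtu")
  writeLines("<not-vtk/>", bad)
  expect_error(read_mesh(bad), class = "osteosim_malformed_file")
  badmsh <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), badmsh)
  expect_error(read_mesh(badmsh), class = "osteosim_malformed_file")
})

test_that("csv field export round trips", {
  f <- list(rho = c(1.1, 2.2, 3.3), E = c(10, 20, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  r <- read_field_csv(path)
  expect_equal(r$element_id, 1:3)
  expect_equal(r$rho, f$rho)
  expect_equal(r$E, f$E)
})
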