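#' Read and write tetrahedral meshes
#'
#' Formats are inferred from the file extension: `.vtu` (VTK XML
#' unstructured grid, ASCII) and `.msh` (Gmsh v4.1 ASCII). Round trips
#' preserve connectivity and named per-element fields exactly and node
#' coordinates to full double precision. Facet sets are serialized as
#' boundary-triangle cells carrying indicator cell-data arrays
#' (`facet_<name>`) in `.vtu`, and as physical surface groups in `.msh`.
#'
#' @param mesh a [mesh_model()].
#' @param path file path ending in `.vtu` or `.msh`.
#' @param fields optional named list of per-element numeric vectors written
#'   as cell data.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns a
#'   [mesh_model()] whose `meta$fields` holds any per-element cell data.
#' @export
write_mesh <- function(mesh, path, fields = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtu = write_vtu(mesh, path, fields),
    msh = write_msh(mesh, path, fields),
    abort(paste0("unsupported mesh format: .", ext),
          class = "osteosim_unsupported_format")
  )
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mesh file not found: ", path),
          class = "osteosim_file_not_found")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtu = read_vtu(path),
    msh = read_msh(path),
    abort(paste0("unsupported mesh format: .", ext),
          class = "osteosim_unsupported_format")
  )
}

num_fmt <- function(x) sprintf("%.17g", x)

# ---- VTK XML unstructured grid ---------------------------------------------

write_vtu <- function(mesh, path, fields = NULL) {
  nn <- n_nodes(mesh); m <- n_elements(mesh)
  bf_sets <- mesh$facet_sets
  tris <- do.call(rbind, c(list(matrix(0L, 0L, 3L)), unname(bf_sets)))
  ntri <- nrow(tris)
  tri_set <- rep(names(bf_sets), vapply(bf_sets, nrow, 0L))

  tet_type <- if (mesh$order == 1L) 10L else 24L
  conn <- c(as.vector(t(mesh$tets)) - 1L, as.vector(t(tris)) - 1L)
  offs <- c(seq_len(m) * ncol(mesh$tets), m * ncol(mesh$tets) + seq_len(ntri) * 3L)
  types <- c(rep(tet_type, m), rep(5L, ntri))

  da <- function(name, type, ncomp, values) {
    paste0('      <DataArray type="', type, '" Name="', name,
           '" NumberOfComponents="', ncomp, '" format="ascii">\n',
           paste(values, collapse = " "), "\n      </DataArray>")
  }
  cell_arrays <- c(
    da("region", "Int32", 1L,
       c(ifelse(mesh$region == "implant", 1L, 0L), rep(-1L, ntri))),
    vapply(names(bf_sets), function(nm) {
      da(paste0("facet_", nm), "Int32", 1L,
         c(rep(0L, m), as.integer(tri_set == nm)))
    }, character(1))
  )
  if (!is.null(fields)) {
    cell_arrays <- c(cell_arrays, vapply(names(fields), function(nm) {
      v <- fields[[nm]]
      if (length(v) != m) abort(paste0("field '", nm, "' has wrong length"))
      da(nm, "Float64", 1L, c(num_fmt(v), rep("nan", ntri)))
    }, character(1)))
  }

  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, m + ntri),
    "      <Points>",
    da("Points", "Float64", 3L, num_fmt(as.vector(t(mesh$nodes)))),
    "      </Points>",
    "      <Cells>",
    da("connectivity", "Int64", 1L, conn),
    da("offsets", "Int64", 1L, offs),
    da("types", "UInt8", 1L, types),
    "      </Cells>",
    "      <CellData>",
    cell_arrays,
    "      </CellData>",
    "    </Piece>",
    "  </UnstructuredGrid>",
    "</VTKFile>"
  )
  writeLines(xml, path)
}

read_vtu <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed .vtu file: ", conditionMessage(e)),
          class = "osteosim_malformed_file")
  })
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    abort("malformed .vtu file: no <Piece>", class = "osteosim_malformed_file")
  }
  get_arr <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- get_arr(".//Points/DataArray")
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- get_arr(".//Cells/DataArray[@Name='connectivity']") + 1L
  offs <- get_arr(".//Cells/DataArray[@Name='offsets']")
  types <- get_arr(".//Cells/DataArray[@Name='types']")
  if (!all(types %in% c(5, 10, 24))) {
    abort("unsupported cell types in .vtu (expected tetrahedra and triangles)",
          class = "osteosim_unsupported_cells")
  }
  starts <- c(0, head(offs, -1L))
  is_tet <- types %in% c(10, 24)
  npc <- ifelse(types == 10, 4L, ifelse(types == 24, 10L, 3L))
  cells <- lapply(seq_along(offs), function(i) conn[(starts[i] + 1):offs[i]])
  tets <- do.call(rbind, cells[is_tet])
  tris <- if (any(!is_tet)) do.call(rbind, cells[!is_tet]) else NULL

  cd <- xml2::xml_find_all(piece, ".//CellData/DataArray")
  cdata <- list()
  for (nd in cd) {
    cdata[[xml2::xml_attr(nd, "Name")]] <-
      scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  region <- rep("bone", sum(is_tet))
  if (!is.null(cdata$region)) {
    region <- ifelse(cdata$region[is_tet] == 1, "implant", "bone")
  }
  facet_sets <- list()
  for (nm in names(cdata)) {
    if (startsWith(nm, "facet_") && !is.null(tris)) {
      ind <- cdata[[nm]][!is_tet] == 1
      if (any(ind)) facet_sets[[sub("^facet_", "", nm)]] <-
          tris[ind, , drop = FALSE]
    }
  }
  fields <- cdata[setdiff(names(cdata),
                          c("region", grep("^facet_", names(cdata), value = TRUE)))]
  fields <- lapply(fields, function(v) v[is_tet])

  mesh <- mesh_model(nodes, tets, region = region, facet_sets = facet_sets,
                     meta = list(fields = fields))
  if (mesh$order == 2L) mesh <- rebuild_edge_mid(mesh)
  mesh
}

# Rebuild the edge -> midside-node lookup of a quadratic mesh read from file.
rebuild_edge_mid <- function(mesh) {
  tt <- mesh$tets
  ep <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(1L, 4L), c(2L, 4L), c(3L, 4L))
  key <- unlist(lapply(seq_len(6L), function(k) {
    a <- tt[, ep[k, 1]]; b <- tt[, ep[k, 2]]
    paste(pmin(a, b), pmax(a, b))
  }))
  mid <- as.vector(tt[, 5:10])
  keep <- !duplicated(key)
  em <- mid[keep]
  names(em) <- key[keep]
  mesh$edge_mid <- em
  mesh
}

# ---- Gmsh v4.1 ASCII -------------------------------------------------------

# Canonical (VTK-style) tet10 ordering differs from Gmsh in the last two
# midside nodes.
gmsh_tet10_perm <- c(1:8, 10L, 9L)

write_msh <- function(mesh, path, fields = NULL) {
  regions <- c("bone", "implant")
  regions <- regions[regions %in% mesh$region]
  fs <- mesh$facet_sets
  nsurf <- length(fs)
  bb <- apply(mesh$nodes, 2L, range)
  bbs <- paste(num_fmt(c(bb[1, ], bb[2, ])), collapse = " ")

  lines <- c("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  # physical groups: surfaces 101.., volumes 1..
  phys <- c(sprintf('2 %d "%s"', 100L + seq_len(nsurf), names(fs)),
            sprintf('3 %d "%s"', seq_along(regions), regions))
  lines <- c(lines, "$PhysicalNames", length(phys), phys, "$EndPhysicalNames")
  ent <- c(sprintf("%d 0 0", length(c(fs, regions))))
  surf_ent <- sprintf("%d %s 1 %d 0", seq_len(nsurf), bbs, 100L + seq_len(nsurf))
  vol_ent <- sprintf("%d %s 1 %d 0", seq_along(regions), bbs, seq_along(regions))
  lines <- c(lines, "$Entities",
             sprintf("0 0 %d %d", nsurf, length(regions)),
             surf_ent, vol_ent, "$EndEntities")

  nn <- n_nodes(mesh)
  lines <- c(lines, "$Nodes",
             sprintf("1 %d 1 %d", nn, nn),
             sprintf("3 %d 0 %d", if (length(regions)) 1L else 1L, nn),
             as.character(seq_len(nn)),
             apply(mesh$nodes, 1L, function(r) paste(num_fmt(r), collapse = " ")),
             "$EndNodes")

  tet_type <- if (mesh$order == 1L) 4L else 11L
  blocks <- character(0)
  etag <- 0L
  nblocks <- 0L
  for (si in seq_len(nsurf)) {
    f <- fs[[si]]
    rows <- apply(f, 1L, function(r) paste(r, collapse = " "))
    etags <- etag + seq_len(nrow(f)); etag <- etag + nrow(f)
    blocks <- c(blocks, sprintf("2 %d 2 %d", si, nrow(f)),
                paste(etags, rows))
    nblocks <- nblocks + 1L
  }
  for (ri in seq_along(regions)) {
    sel <- which(mesh$region == regions[ri])
    tt <- mesh$tets[sel, , drop = FALSE]
    if (mesh$order == 2L) tt <- tt[, gmsh_tet10_perm, drop = FALSE]
    rows <- apply(tt, 1L, function(r) paste(r, collapse = " "))
    etags <- etag + seq_along(sel); etag <- etag + length(sel)
    blocks <- c(blocks, sprintf("3 %d %d %d", ri, tet_type, length(sel)),
                paste(etags, rows))
    nblocks <- nblocks + 1L
  }
  lines <- c(lines, "$Elements",
             sprintf("%d %d 1 %d", nblocks, etag, etag),
             blocks, "$EndElements")
  writeLines(lines, path)
  # per-element fields as $ElementData blocks (one per field, tets only,
  # element tags follow the region block order above)
  if (!is.null(fields)) {
    con <- file(path, open = "a")
    on.exit(close(con))
    order_idx <- unlist(lapply(regions, function(r) which(mesh$region == r)))
    first_tet_tag <- etag - n_elements(mesh)
    for (nm in names(fields)) {
      v <- fields[[nm]][order_idx]
      writeLines(c("$ElementData", "1", paste0('"', nm, '"'), "1", "0.0",
                   "3", "0", "1", as.character(length(v)),
                   paste(first_tet_tag + seq_along(v), num_fmt(v))),
                 con)
      writeLines("$EndElementData", con)
    }
  }
}

read_msh <- function(path) {
  txt <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- match(paste0("$", name), txt)
    i1 <- match(paste0("$End", name), txt)
    if (is.na(i0) || is.na(i1)) return(NULL)
    txt[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "4")) {
    abort("not a Gmsh v4 ASCII file", class = "osteosim_malformed_file")
  }
  # physical names
  phys_name <- character(0)
  pn <- sect("PhysicalNames")
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      m <- regmatches(ln, regexec('^(\\d+)\\s+(\\d+)\\s+"(.*)"$', ln))[[1]]
      if (length(m) == 4L) phys_name[paste(m[2], m[3], sep = ":")] <- m[4]
    }
  }
  phys_of <- function(dim, tag) {
    nm <- phys_name[paste(dim, tag, sep = ":")]
    if (is.na(nm)) NA_character_ else unname(nm)
  }
  # entities: map (dim, entity tag) -> physical tag
  ent <- sect("Entities")
  ent_phys <- list()
  if (!is.null(ent)) {
    counts <- scan(text = ent[1], quiet = TRUE)
    i <- 2L
    i <- i + counts[1] + counts[2]     # skip points and curves
    for (k in seq_len(counts[3])) {    # surfaces
      v <- scan(text = ent[i], quiet = TRUE); i <- i + 1L
      if (v[8] >= 1) ent_phys[[paste0("2:", v[1])]] <- v[9]
    }
    for (k in seq_len(counts[4])) {    # volumes
      v <- scan(text = ent[i], quiet = TRUE); i <- i + 1L
      if (v[8] >= 1) ent_phys[[paste0("3:", v[1])]] <- v[9]
    }
  }
  # nodes
  nd <- sect("Nodes")
  hdr <- scan(text = nd[1], quiet = TRUE)
  i <- 2L
  tags <- integer(0); coords <- list()
  for (b in seq_len(hdr[1])) {
    bh <- scan(text = nd[i], quiet = TRUE); i <- i + 1L
    nb <- bh[4]
    btags <- as.integer(nd[i:(i + nb - 1L)]); i <- i + nb
    bxyz <- do.call(rbind, lapply(nd[i:(i + nb - 1L)], function(s) {
      scan(text = s, quiet = TRUE)[1:3]
    }))
    i <- i + nb
    tags <- c(tags, btags); coords <- c(coords, list(bxyz))
  }
  xyz <- do.call(rbind, coords)
  remap <- integer(max(tags)); remap[tags] <- seq_along(tags)
  # elements
  el <- sect("Elements")
  hdr <- scan(text = el[1], quiet = TRUE)
  i <- 2L
  tets <- list(); tet_region <- list(); tris <- list(); tri_set <- list()
  for (b in seq_len(hdr[1])) {
    bh <- scan(text = el[i], quiet = TRUE); i <- i + 1L
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    rows <- do.call(rbind, lapply(el[i:(i + nb - 1L)], function(s) {
      scan(text = s, quiet = TRUE)
    }))
    i <- i + nb
    conn <- matrix(remap[rows[, -1L, drop = FALSE]], nrow = nb)
    if (etype %in% c(4, 11)) {
      if (etype == 11) conn <- conn[, order(gmsh_tet10_perm), drop = FALSE]
      ph <- ent_phys[[paste0("3:", etag)]]
      nm <- if (!is.null(ph)) phys_of(3L, ph) else NA_character_
      tets <- c(tets, list(conn))
      tet_region <- c(tet_region, list(rep(ifelse(identical(nm, "implant"),
                                                  "implant", "bone"), nb)))
    } else if (etype == 2) {
      ph <- ent_phys[[paste0("2:", etag)]]
      nm <- if (!is.null(ph)) phys_of(2L, ph) else NA_character_
      tris <- c(tris, list(conn)); tri_set <- c(tri_set, list(nm))
    } else {
      abort(sprintf("unsupported Gmsh element type %d", etype),
            class = "osteosim_unsupported_cells")
    }
  }
  if (!length(tets)) {
    abort("no tetrahedra in mesh file", class = "osteosim_malformed_file")
  }
  tetm <- do.call(rbind, tets)
  region <- unlist(tet_region)
  facet_sets <- list()
  for (k in seq_along(tris)) {
    nm <- tri_set[[k]]
    if (!is.na(nm)) {
      facet_sets[[nm]] <- rbind(facet_sets[[nm]], tris[[k]])
    }
  }
  # element data fields (values ordered by element tag; tets only)
  fields <- list()
  i0 <- which(txt == "$ElementData")
  for (s in i0) {
    e <- which(txt == "$EndElementData")
    e <- e[e > s][1]
    blk <- txt[(s + 1L):(e - 1L)]
    nm <- gsub('"', "", blk[2])
    nv <- as.integer(blk[8])
    vals <- do.call(rbind, lapply(blk[8L + seq_len(nv)], function(ln) {
      scan(text = ln, quiet = TRUE)
    }))
    fields[[nm]] <- vals[order(vals[, 1]), 2]
  }
  mesh <- mesh_model(xyz, tetm, region = region, facet_sets = facet_sets,
                     meta = list(fields = fields))
  if (mesh$order == 2L) mesh <- rebuild_edge_mid(mesh)
  mesh
}

# ---- CSV per-element fields ------------------------------------------------

#' Export / import per-element fields as CSV
#'
#' @param fields named list of per-element numeric vectors.
#' @param path CSV file path.
#' @return `write_field_csv()` returns `path` invisibly; `read_field_csv()`
#'   returns a tibble with `element_id` plus one column per field.
#' @export
write_field_csv <- function(fields, path) {
  n <- unique(vapply(fields, length, 0L))
  if (length(n) != 1L) abort("all fields must have equal length")
  df <- data.frame(element_id = seq_len(n), fields, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  as_tibble(read.csv(path, check.names = FALSE))
}
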