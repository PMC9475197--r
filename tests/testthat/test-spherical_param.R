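# Mesh fixtures are generated in code and written to tempfiles in the three
# supported formats.

write_vtk_fixture <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "elasurf fixture", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mesh$vertices))), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  nf <- nrow(mesh$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  path
}

write_ply_ascii_fixture <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  path
}

write_ply_binary_fixture <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  for (i in seq_len(nrow(mesh$vertices))) {
    writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4,
             endian = "little")
  }
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  path
}

test_that("mesh readers parse all three formats and validate topology", {
  ico <- icosphere(0)
  expect_equal(nrow(ico$vertices), 12)
  expect_equal(nrow(ico$faces), 20)   # V - E + F = 12 - 30 + 20 = 2

  off_path <- tempfile(fileext = ".off")
  write_off(ico, off_path)
  m_off <- read_mesh(off_path)
  expect_equal(m_off$vertices, ico$vertices, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_identical(m_off$faces, ico$faces)

  vtk_path <- write_vtk_fixture(ico, tempfile(fileext = ".vtk"))
  m_vtk <- read_mesh(vtk_path)
  expect_identical(m_vtk$faces, ico$faces)

  pa <- write_ply_ascii_fixture(ico, tempfile(fileext = ".ply"))
  m_pa <- read_mesh(pa)
  expect_identical(m_pa$faces, ico$faces)

  pb <- write_ply_binary_fixture(ico, tempfile(fileext = ".ply"))
  m_pb <- read_mesh(pb)
  expect_identical(m_pb$faces, ico$faces)
  expect_equal(m_pb$vertices, ico$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("defective meshes are rejected with a named invariant", {
  ico <- icosphere(0)
  expect_error(tri_mesh(ico$vertices, ico$faces[-1, ]), "open surface")
  # torus: genus 1 -> chi = 0
  nu <- 8; nv <- 8
  us <- 2 * pi * (0:(nu - 1)) / nu
  vs <- 2 * pi * (0:(nv - 1)) / nv
  vid <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  verts <- do.call(rbind, lapply(seq_len(nu), function(i) {
    t(vapply(seq_len(nv), function(j) {
      u <- us[i]; v <- vs[j]
      c((2 + cos(v)) * cos(u), (2 + cos(v)) * sin(u), sin(v))
    }, numeric(3)))
  }))
  faces <- do.call(rbind, lapply(seq_len(nu), function(i) {
    do.call(rbind, lapply(seq_len(nv), function(j) {
      rbind(c(vid(i, j), vid(i + 1, j), vid(i, j + 1)),
            c(vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1)))
    }))
  }))
  expect_error(tri_mesh(verts, faces), "genus")
  # inward orientation is fixed silently (signed volume check)
  flipped <- tri_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  expect_gt(elasurf:::mesh_signed_volume(flipped), 0)
})

test_that("Tuette map: monotone energy, stationary at its own minimizer", {
  sph <- icosphere(2)
  tm0 <- tuette_map(sph, max_iter = 500)
  expect_true(all(diff(tm0$energy_trace) <= 0))
  # restarting from the converged state finds (almost) nothing left
  sph_min <- sph
  sph_min$vertices <- tm0$sphere_vertices
  tm1 <- tuette_map(sph_min, max_iter = 100)
  e <- tm1$energy_trace
  expect_lt((e[1] - tail(e, 1)) / e[1], 1e-4)
  expect_equal(tm0$flipped, 0)
  expect_equal(sqrt(rowSums(tm0$sphere_vertices^2)), rep(1, nrow(sph$vertices)),
               tolerance = 1e-12)
  # ellipsoid: energy decreases, no flips at convergence
  em <- icosphere(2, transform = bumpy_ellipsoid_transform())
  tm <- tuette_map(em, max_iter = 400)
  expect_true(all(diff(tm$energy_trace) <= 0))
  expect_equal(tm$flipped, 0)
})

test_that("conformal relaxation reduces angle distortion and stays centered", {
  em <- icosphere(3, transform = bumpy_ellipsoid_transform())
  tm <- tuette_map(em, max_iter = 300)
  cm <- conformal_relax(em, tm, max_iter = 300)
  expect_true(all(diff(cm$energy_trace) <= 0))
  expect_equal(cm$flipped, 0)
  ctr <- elasurf:::sphere_map_centroid(em, cm$sphere_vertices)
  expect_lt(sqrt(sum(ctr^2)), 0.1)
  expect_lte(angle_distortion(em, cm), angle_distortion(em, tm))
  # restarting the relaxation from its own output changes essentially nothing
  sph <- icosphere(2)
  tms <- tuette_map(sph, max_iter = 200)
  cms <- conformal_relax(sph, tms, max_iter = 300)
  cms2 <- conformal_relax(sph, cms, max_iter = 100)
  es <- cms2$energy_trace
  expect_lt((es[1] - tail(es, 1)) / es[1], 1e-4)
})

test_that("resampling matches analytic shapes and conserves area", {
  g <- sphere_grid(32, 32)
  # unit-sphere mesh with identity (Gauss) map
  sph <- icosphere(3)
  map_id <- list(sphere_vertices = sph$vertices)
  gs <- resample_to_grid(sph, map_id, g)
  expect_lt(max(abs(sqrt(gs$f[, , 1]^2 + gs$f[, , 2]^2 + gs$f[, , 3]^2) - 1)),
            0.02)  # below the mesh edge length
  # refinement: finer mesh gets closer to the analytic ellipsoid
  target <- ellipsoid_surface(g)
  errs <- vapply(2:3, function(k) {
    m <- icosphere(k, transform = function(V)
      cbind(1.3 * V[, 1], 0.8 * V[, 2], 1.1 * V[, 3]))
    gsk <- resample_to_grid(m, list(sphere_vertices = icosphere(k)$vertices), g)
    vec_distance(gsk, target)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # area conservation within 2%
  em <- icosphere(3, transform = bumpy_ellipsoid_transform())
  surf <- spherical_parameterization(em, g, max_iter = 300)
  expect_lt(abs(surface_area(surf) - mesh_area(em)) / mesh_area(em), 0.02)
})

test_that("subdivision refines and preserves topology", {
  m <- subdivide_mesh(icosphere(0), 1)
  expect_equal(nrow(m$faces), 80)
  expect_equal(nrow(m$vertices), 42)
})
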