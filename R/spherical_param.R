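# Spherical parameterization of triangulated genus-zero meshes: mesh readers
# with topology validation, Tuette and conformal (harmonic) sphere mappings,
# and resampling of the mapped mesh onto a regular spherical grid.

#' Triangle mesh container
#'
#' @param vertices `V x 3` numeric matrix.
#' @param faces `F x 3` integer matrix of 1-based vertex indices.
#' @param format_tag source dialect label.
#' @return An object of class `tri_mesh` (validated: closed, orientable,
#'   genus zero, consistently outward-oriented).
#' @export
tri_mesh <- function(vertices, faces, format_tag = "constructed") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("tri_mesh: vertices must be V x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("tri_mesh: face index out of range")
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      format_tag = format_tag),
                 class = "tri_mesh")
  validate_mesh(m)
}

validate_mesh <- function(m) {
  V <- nrow(m$vertices)
  Fc <- nrow(m$faces)
  # undirected edge table
  e <- rbind(
    m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)]
  )
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ekey)
  if (any(cnt > 2)) stop("tri_mesh: non-manifold edge (shared by > 2 faces)")
  if (any(cnt < 2)) stop("tri_mesh: open surface (boundary edge found)")
  E <- length(cnt)
  chi <- V - E + Fc
  if (chi != 2L) {
    stop(sprintf("tri_mesh: genus != 0 (Euler characteristic %d, expected 2)", chi))
  }
  # orientability: each directed edge must appear exactly once
  dkey <- paste(e[, 1], e[, 2])
  if (any(table(dkey) > 1)) stop("tri_mesh: inconsistent face orientation")
  # outward orientation by signed volume
  vol <- mesh_signed_volume(m)
  if (vol < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

mesh_signed_volume <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh [%s]: %d vertices, %d faces\n",
              x$format_tag, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total triangle area of a mesh
#' @param mesh a [tri_mesh()].
#' @return Scalar area (sum of triangle areas).
#' @export
mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Read a triangle mesh (VTK legacy polydata, OFF, or PLY)
#'
#' Format is inferred from the extension (`.vtk`, `.off`, `.ply`) or from the
#' file header. PLY is supported in ascii and binary little-endian form.
#' The mesh is validated: closed, orientable, genus zero, outward-oriented.
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: file not found: ", path)
  head_raw <- readBin(path, "raw", n = 16)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  ext <- tolower(tools::file_ext(path))
  if (ext == "off" || startsWith(head_txt, "OFF")) {
    return(read_off(path))
  }
  if (ext == "ply" || startsWith(head_txt, "ply")) {
    return(read_ply(path))
  }
  if (ext == "vtk" || startsWith(head_txt, "# vtk")) {
    return(read_vtk(path))
  }
  stop("read_mesh: unrecognized mesh format: ", path)
}

read_off <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toupper(toks[1]) != "OFF") stop("read_off: missing OFF header")
  nv <- as.integer(toks[2])
  nf <- as.integer(toks[3])
  pos <- 5L  # skip edge count
  verts <- matrix(as.numeric(toks[pos:(pos + 3 * nv - 1)]), ncol = 3, byrow = TRUE)
  pos <- pos + 3L * nv
  faces <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("read_off: non-triangular face")
    faces[i, ] <- as.integer(toks[(pos + 1):(pos + 3)]) + 1L
    pos <- pos + k + 1L
  }
  tri_mesh(verts, faces, "off")
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^# vtk", lines))) stop("read_vtk: not a VTK legacy file")
  if (!any(grepl("ASCII", lines, fixed = TRUE))) {
    stop("read_vtk: only ASCII VTK legacy files are supported")
  }
  toks <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  ip <- which(toupper(toks) == "POINTS")
  if (!length(ip)) stop("read_vtk: POINTS section missing")
  nv <- as.integer(toks[ip + 1])
  start <- ip + 3L
  verts <- matrix(as.numeric(toks[start:(start + 3 * nv - 1)]),
                  ncol = 3, byrow = TRUE)
  ipoly <- which(toupper(toks) == "POLYGONS")
  if (!length(ipoly)) stop("read_vtk: POLYGONS section missing")
  nf <- as.integer(toks[ipoly + 1])
  pos <- ipoly + 3L
  faces <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("read_vtk: non-triangular polygon")
    faces[i, ] <- as.integer(toks[(pos + 1):(pos + 3)]) + 1L
    pos <- pos + k + 1L
  }
  tri_mesh(verts, faces, "vtk-legacy")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 500) stop("read_ply: header not terminated")
  }
  if (!identical(trimws(header[1]), "ply")) stop("read_ply: missing ply magic")
  fmt <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt)) {
    stop("read_ply: unsupported format: ", fmt)
  }
  # parse element/property declarations
  elems <- list()
  cur <- NULL
  for (ln in header) {
    t <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (t[1] == "element") {
      cur <- t[2]
      elems[[cur]] <- list(count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1]] <-
        if (t[2] == "list") list(list = TRUE, count_type = t[3], type = t[4], name = t[5])
        else list(list = FALSE, type = t[2], name = t[3])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face)) {
    stop("read_ply: vertex or face element missing")
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4,
                 double = 8, float64 = 8)
  read_scalar <- function(type, n = 1) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", n = n, size = sz, endian = "little")
    } else {
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", type)))
    }
  }
  if (binary) {
    nv <- elems$vertex$count
    vp <- elems$vertex$props
    vdat <- matrix(NA_real_, nv, length(vp))
    for (i in seq_len(nv)) {
      for (j in seq_along(vp)) vdat[i, j] <- read_scalar(vp[[j]]$type)
    }
    colnames(vdat) <- vapply(vp, `[[`, "", "name")
    nf <- elems$face$count
    fp <- elems$face$props[[1]]
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      k <- read_scalar(fp$count_type)
      idx <- read_scalar(fp$type, n = k)
      if (k != 3L) stop("read_ply: non-triangular face")
      faces[i, ] <- idx + 1L
    }
  } else {
    toks <- scan(con, what = character(), quiet = TRUE)
    nv <- elems$vertex$count
    npv <- length(elems$vertex$props)
    vdat <- matrix(as.numeric(toks[seq_len(nv * npv)]), nv, npv, byrow = TRUE)
    colnames(vdat) <- vapply(elems$vertex$props, `[[`, "", "name")
    pos <- nv * npv + 1L
    nf <- elems$face$count
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      k <- as.integer(toks[pos])
      if (k != 3L) stop("read_ply: non-triangular face")
      faces[i, ] <- as.integer(toks[(pos + 1):(pos + 3)]) + 1L
      pos <- pos + k + 1L
    }
  }
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  tri_mesh(verts, faces, if (binary) "ply-binary" else "ply-ascii")
}

#' Write a mesh in OFF format
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  fa <- cbind(3L, mesh$faces - 1L)
  utils::write.table(fa, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# sparse vertex-vertex structure of a mesh
mesh_edges <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique_e <- e[!duplicated(key), , drop = FALSE]
  cbind(pmin(unique_e[, 1], unique_e[, 2]), pmax(unique_e[, 1], unique_e[, 2]))
}

tuette_energy <- function(U, edges, wts = 1) {
  d <- U[edges[, 1], , drop = FALSE] - U[edges[, 2], , drop = FALSE]
  sum(wts * rowSums(d^2))
}

# weighted graph Laplacian gradient: grad_i = 2 sum_j w_ij (u_i - u_j)
laplacian_grad <- function(U, L) 2 * as.matrix(L %*% U)

graph_laplacian <- function(edges, n, wts = 1) {
  if (length(wts) == 1) wts <- rep(wts, nrow(edges))
  A <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = c(wts, wts), dims = c(n, n)
  )
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Tuette map of a genus-zero mesh onto the sphere
#'
#' Minimizes the Tuette energy `sum_edges ||u_i - u_j||^2` over unit-vector
#' vertex positions by projected gradient descent with a backtracking line
#' search (energy is non-increasing by construction). Initialized with the
#' Gauss map (normalized centered vertices). The Tuette minimizer is unique
#' up to rotation and provides a bijective initialization for
#' [conformal_relax()].
#'
#' @param mesh a [tri_mesh()].
#' @param max_iter iteration cap (default 2000).
#' @param step initial step size (default 1e-2, adapted by backtracking).
#' @param tol relative energy-decrease tolerance (default 1e-9).
#' @return An object of class `spherical_map`: `sphere_vertices` (unit
#'   vectors), `energy_trace`, `flipped` (count of flipped spherical
#'   triangles at the final state).
#' @export
tuette_map <- function(mesh, max_iter = 2000, step = 1e-2, tol = 1e-9) {
  V <- mesh$vertices
  U <- sweep(V, 2, colMeans(V))
  U <- U / sqrt(rowSums(U^2))
  edges <- mesh_edges(mesh)
  L <- graph_laplacian(edges, nrow(U))
  E <- tuette_energy(U, edges)
  trace <- E
  for (it in seq_len(max_iter)) {
    G <- laplacian_grad(U, L)
    # tangential projection
    G <- G - U * rowSums(G * U)
    gnorm <- sqrt(sum(G^2))
    if (gnorm < 1e-12) break
    s <- step
    accepted <- FALSE
    for (h in 1:30) {
      Un <- U - s * G
      Un <- Un / sqrt(rowSums(Un^2))
      En <- tuette_energy(Un, edges)
      if (En < E) {
        U <- Un
        Eprev <- E
        E <- En
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) break
    trace <- c(trace, E)
    if ((Eprev - E) < tol * max(Eprev, 1e-300)) break
  }
  fl <- count_flipped(mesh, U)
  if (fl > 0) {
    warning(sprintf("tuette_map: %d flipped spherical triangles", fl))
  }
  structure(list(sphere_vertices = U, energy_trace = trace, flipped = fl),
            class = "spherical_map")
}

#' @export
print.spherical_map <- function(x, ...) {
  cat(sprintf(
    "spherical_map: %d vertices, final energy %.6g (%d iterations, %d flipped)\n",
    nrow(x$sphere_vertices), tail(x$energy_trace, 1),
    length(x$energy_trace) - 1L, x$flipped
  ))
  invisible(x)
}

count_flipped <- function(mesh, U) {
  a <- U[mesh$faces[, 1], , drop = FALSE]
  b <- U[mesh$faces[, 2], , drop = FALSE]
  cc <- U[mesh$faces[, 3], , drop = FALSE]
  dets <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(dets <= 0)
}

cot_weights <- function(mesh) {
  V <- mesh$vertices
  Fm <- mesh$faces
  ekey_all <- character(0)
  w_all <- numeric(0)
  corner <- function(i, j, k) {
    # cotangent of angle at vertex k, opposite edge (i, j)
    u <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
    v <- V[j, , drop = FALSE] - V[k, , drop = FALSE]
    dotp <- rowSums(u * v)
    cr <- cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
    dotp / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  combos <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (cmb in combos) {
    i <- Fm[, cmb[1]]; j <- Fm[, cmb[2]]; k <- Fm[, cmb[3]]
    ekey_all <- c(ekey_all, paste(pmin(i, j), pmax(i, j)))
    w_all <- c(w_all, 0.5 * corner(i, j, k))
  }
  agg <- tapply(w_all, ekey_all, sum)
  e <- do.call(rbind, strsplit(names(agg), " "))
  n_clamped <- sum(agg < 0)
  structure(
    list(edges = cbind(as.integer(e[, 1]), as.integer(e[, 2])),
         weights = pmax(as.numeric(agg), 0), n_clamped = n_clamped),
    class = "cot_weights"
  )
}

#' Conformal (harmonic) relaxation of a spherical map
#'
#' Starting from a Tuette map, minimizes the harmonic energy with cotangent
#' edge weights (negative weights clamped at zero, count reported) by
#' projected tangential gradient descent, interleaved with a centering step
#' that keeps the area-weighted centroid of the spherical vertices near the
#' origin (preventing the well-known collapse of harmonic sphere maps onto a
#' point). The recorded energy trace is non-increasing; a centering move
#' that would increase the energy above the previous trace value is skipped.
#'
#' @param mesh a [tri_mesh()].
#' @param init a `spherical_map` from [tuette_map()].
#' @param max_iter iteration cap (default 2000).
#' @param step initial step size.
#' @param tol relative energy-decrease tolerance.
#' @return A `spherical_map`; element `n_clamped` counts clamped cotangent
#'   weights.
#' @export
conformal_relax <- function(mesh, init, max_iter = 2000, step = 1e-2,
                            tol = 1e-9) {
  U <- init$sphere_vertices
  cw <- cot_weights(mesh)
  edges <- cw$edges
  L <- graph_laplacian(edges, nrow(U), cw$weights)
  energy <- function(U) tuette_energy(U, edges, cw$weights)
  center <- function(U) {
    ctr <- sphere_map_centroid(mesh, U)
    if (sqrt(sum(ctr^2)) > 0.99) {
      stop("conformal_relax: map collapsed (centroid norm > 0.99)")
    }
    Un <- sweep(U, 2, ctr)
    Un / sqrt(rowSums(Un^2))
  }
  E <- energy(U)
  trace <- E
  for (it in seq_len(max_iter)) {
    G <- laplacian_grad(U, L)
    G <- G - U * rowSums(G * U)
    if (sqrt(sum(G^2)) < 1e-12) break
    s <- step
    accepted <- FALSE
    for (h in 1:30) {
      Un <- U - s * G
      Un <- Un / sqrt(rowSums(Un^2))
      En <- energy(Un)
      if (En < E) {
        Uc <- center(Un)
        Ec <- energy(Uc)
        if (Ec < E) {
          Un <- Uc
          En <- Ec
        }
        U <- Un
        Eprev <- E
        E <- En
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) break
    trace <- c(trace, E)
    if ((Eprev - E) < tol * max(Eprev, 1e-300)) break
  }
  fl <- count_flipped(mesh, U)
  structure(
    list(sphere_vertices = U, energy_trace = trace, flipped = fl,
         n_clamped = cw$n_clamped),
    class = "spherical_map"
  )
}

# area-weighted centroid of the spherical image (weights: spherical triangle
# areas approximated by Euclidean triangle areas of the image)
sphere_map_centroid <- function(mesh, U) {
  a <- U[mesh$faces[, 1], , drop = FALSE]
  b <- U[mesh$faces[, 2], , drop = FALSE]
  cc <- U[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  ar <- sqrt(rowSums(cr^2)) / 2
  ctr <- (a + b + cc) / 3
  colSums(ctr * ar) / sum(ar)
}

#' Per-triangle angle distortion of a spherical map
#'
#' Median absolute deviation between each triangle's angles on the mesh and
#' the corresponding (Euclidean) angles of its spherical image; lower is
#' closer to conformal.
#'
#' @param mesh a [tri_mesh()].
#' @param map a `spherical_map`.
#' @return Median absolute angle deviation in radians.
#' @export
angle_distortion <- function(mesh, map) {
  ang <- function(P) {
    a <- P[mesh$faces[, 1], , drop = FALSE]
    b <- P[mesh$faces[, 2], , drop = FALSE]
    cc <- P[mesh$faces[, 3], , drop = FALSE]
    angle_at <- function(p, q, r) {
      u <- q - p
      v <- r - p
      acos(pmin(pmax(rowSums(u * v) /
        sqrt(rowSums(u^2) * rowSums(v^2)), -1), 1))
    }
    cbind(angle_at(a, b, cc), angle_at(b, cc, a), angle_at(cc, a, b))
  }
  stats::median(abs(ang(mesh$vertices) - ang(map$sphere_vertices)))
}

#' Resample a spherically mapped mesh onto a regular grid
#'
#' For each grid direction, finds the spherical triangle of the map that
#' contains it and interpolates the mesh vertex positions with the
#' (gnomonic) barycentric coordinates. Requires a bijective map (no flipped
#' triangles); a grid direction covered by no triangle is a hard error.
#'
#' @param mesh a [tri_mesh()].
#' @param map a `spherical_map` of the mesh.
#' @param grid a [sphere_grid()].
#' @return A [grid_surface()].
#' @export
resample_to_grid <- function(mesh, map, grid) {
  if (count_flipped(mesh, map$sphere_vertices) > 0) {
    stop("resample_to_grid: map has flipped triangles (not bijective)")
  }
  P <- grid_directions(grid)
  n <- nrow(P)
  U <- map$sphere_vertices
  Fm <- mesh$faces
  out <- matrix(NA_real_, n, 3)
  assigned <- rep(FALSE, n)
  tol <- -1e-9
  for (fidx in seq_len(nrow(Fm))) {
    if (all(assigned)) break
    tri <- Fm[fidx, ]
    M <- t(U[tri, ])
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) next
    todo <- which(!assigned)
    lam <- P[todo, , drop = FALSE] %*% t(Minv)
    inside <- lam[, 1] >= tol & lam[, 2] >= tol & lam[, 3] >= tol
    if (any(inside)) {
      sel <- todo[inside]
      lamn <- lam[inside, , drop = FALSE]
      lamn <- lamn / rowSums(lamn)
      out[sel, ] <- lamn %*% mesh$vertices[tri, , drop = FALSE]
      assigned[sel] <- TRUE
    }
  }
  if (!all(assigned)) {
    stop(sprintf(
      "resample_to_grid: %d grid directions not covered by any spherical triangle",
      sum(!assigned)
    ))
  }
  grid_surface(out, grid, sprintf("resampled:%s", mesh$format_tag))
}

#' One-to-four midpoint subdivision of a triangle mesh
#'
#' Splits every triangle into four by edge midpoints (optionally repeated),
#' producing the progressively finer mesh used before spherical mapping.
#'
#' @param mesh a [tri_mesh()].
#' @param n number of subdivision rounds.
#' @return A [tri_mesh()].
#' @export
subdivide_mesh <- function(mesh, n = 1) {
  m <- mesh
  for (r in seq_len(n)) {
    V <- m$vertices
    Fm <- m$faces
    ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    e <- rbind(Fm[, c(1, 2)], Fm[, c(2, 3)], Fm[, c(3, 1)])
    keys <- ekey(e[, 1], e[, 2])
    uk <- unique(keys)
    midx <- stats::setNames(seq_along(uk) + nrow(V), uk)
    pairs <- do.call(rbind, strsplit(uk, " "))
    mids <- (V[as.integer(pairs[, 1]), , drop = FALSE] +
             V[as.integer(pairs[, 2]), , drop = FALSE]) / 2
    Vn <- rbind(V, mids)
    m12 <- midx[ekey(Fm[, 1], Fm[, 2])]
    m23 <- midx[ekey(Fm[, 2], Fm[, 3])]
    m31 <- midx[ekey(Fm[, 3], Fm[, 1])]
    Fn <- rbind(
      cbind(Fm[, 1], m12, m31),
      cbind(Fm[, 2], m23, m12),
      cbind(Fm[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
    m <- tri_mesh(Vn, Fn, m$format_tag)
  }
  m
}

#' Icosphere test mesh
#'
#' Regular icosahedron subdivided `n` times with vertices projected to the
#' unit sphere; optionally mapped through `transform` (a function of the
#' `V x 3` vertex matrix) to build analytic test shapes such as ellipsoids.
#'
#' @param n subdivision rounds (0 gives the icosahedron).
#' @param transform optional vertex transform.
#' @return A [tri_mesh()].
#' @export
icosphere <- function(n = 3, transform = NULL) {
  gr <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, gr, 0), c(1, gr, 0), c(-1, -gr, 0), c(1, -gr, 0),
    c(0, -1, gr), c(0, 1, gr), c(0, -1, -gr), c(0, 1, -gr),
    c(gr, 0, -1), c(gr, 0, 1), c(-gr, 0, -1), c(-gr, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  Fm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  m <- tri_mesh(V, Fm, "icosphere")
  if (n > 0) {
    for (r in seq_len(n)) {
      m <- subdivide_mesh(m, 1)
      m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
    }
  }
  if (!is.null(transform)) {
    m <- tri_mesh(transform(m$vertices), m$faces, "icosphere-transformed")
  }
  m
}

#' Full mesh-to-grid spherical parameterization
#'
#' Convenience pipeline: [tuette_map()] then [conformal_relax()] then
#' [resample_to_grid()].
#'
#' @param mesh a [tri_mesh()].
#' @param grid target [sphere_grid()].
#' @param subdivide optional subdivision rounds before mapping.
#' @param max_iter iteration cap for both energy minimizations.
#' @return A [grid_surface()] with attribute `map` (the final
#'   `spherical_map`).
#' @export
spherical_parameterization <- function(mesh, grid, subdivide = 0,
                                       max_iter = 2000) {
  if (subdivide > 0) mesh <- subdivide_mesh(mesh, subdivide)
  tm <- tuette_map(mesh, max_iter = max_iter)
  cm <- conformal_relax(mesh, tm, max_iter = max_iter)
  out <- resample_to_grid(mesh, cm, grid)
  attr(out, "map") <- cm
  out
}
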