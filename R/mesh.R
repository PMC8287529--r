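#' Triangle-mesh surface with per-vertex contact quadrature data
#'
#' A `trimesh` is the surface representation used by the elastic-foundation
#' contact model: a vertex/face soup augmented with the per-vertex area
#' weights \eqn{A_i} (one third of the area of the incident triangles) and
#' outward unit normals that the penetration-volume quadrature needs.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (m).
#' @param faces integer m x 3 matrix of 1-based vertex indices with
#'   consistent winding.
#' @param normals optional n x 3 matrix of outward unit normals; computed
#'   by area-weighted face-normal averaging when omitted.
#' @param sphere optional list with elements `center` (3-vector, m),
#'   `radius` (m) and `concave` (logical). Present on meshes generated as
#'   spherical primitives; the contact module uses it for exact signed
#'   distances and exact radial normals.
#'
#' @return An object of class `trimesh`: a list with elements `vertices`,
#'   `faces`, `vertex_area`, `vertex_normal` and (optionally) `sphere`.
#' @export
trimesh <- function(vertices, faces, normals = NULL, sphere = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")

  fa <- face_areas(vertices, faces)
  va <- vertex_areas(vertices, faces, fa)
  if (is.null(normals)) {
    normals <- averaged_vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-9)) stop("supplied normals are not unit length")
  }
  structure(
    list(vertices = vertices, faces = faces,
         vertex_area = va, vertex_normal = normals, sphere = sphere),
    class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, area %.6g m^2%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x),
              if (!is.null(x$sphere))
                sprintf(" (spherical primitive, R = %.4g m%s)",
                        x$sphere$radius,
                        if (isTRUE(x$sphere$concave)) ", concave" else "")
              else ""))
  invisible(x)
}

face_areas <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# A_i = one third of the summed areas of triangles incident on vertex i,
# so that sum(A_i) equals the total surface area exactly.
vertex_areas <- function(v, f, fa = face_areas(v, f)) {
  va <- numeric(nrow(v))
  third <- fa / 3
  for (k in 1:3) {
    s <- tapply(third, f[, k], sum)
    idx <- as.integer(names(s))
    va[idx] <- va[idx] + as.numeric(s)
  }
  va
}

averaged_vertex_normals <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (c in 1:3) {
      s <- tapply(fn[, c], f[, k], sum)
      idx <- as.integer(names(s))
      n[idx, c] <- n[idx, c] + as.numeric(s)
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Total surface area of a mesh
#' @param mesh a [trimesh()].
#' @return total area in m^2 (equals the sum of the per-vertex areas).
#' @export
mesh_area <- function(mesh) sum(mesh$vertex_area)

# --- icosphere cap generation ------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(v, f) {
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  k <- key(edges[, 1], edges[, 2])
  uk <- unique(k)
  mid_index <- setNames(seq_along(uk) + nrow(v), uk)
  ue <- edges[!duplicated(k), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  v2 <- rbind(v, mids)
  m12 <- mid_index[key(f[, 1], f[, 2])]
  m23 <- mid_index[key(f[, 2], f[, 3])]
  m31 <- mid_index[key(f[, 3], f[, 1])]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(vertices = v2, faces = unname(f2))
}

unit_icosphere <- function(subdivisions) {
  s <- icosahedron()
  for (i in seq_len(subdivisions)) s <- subdivide_once(s$vertices, s$faces)
  s
}

#' Spherical-cap triangle mesh by subdivided-icosahedron sampling
#'
#' Samples a sphere with a subdivided icosahedron (near-uniform vertex
#' areas, which benefits the vertex-area contact quadrature), keeps the
#' faces whose centroid lies within `cap_angle` of the pole axis, and
#' clamps boundary vertices onto the rim circle so the mesh area matches
#' the analytic cap area \eqn{2\pi R^2 (1-\cos\theta)} closely.
#'
#' @param radius sphere radius (m).
#' @param center sphere center (3-vector, m).
#' @param axis pole direction (cap is centred on this axis).
#' @param cap_angle half-opening angle of the cap, degrees (180 = full
#'   sphere).
#' @param target_faces requested triangle count for the cap; the
#'   subdivision level is chosen as the smallest that reaches it. Must be
#'   at least 100.
#' @param concave logical; `TRUE` builds a concave (cup) surface whose
#'   outward material normals point toward the sphere center.
#' @return a [trimesh()] carrying a `sphere` attribute for exact-distance
#'   contact evaluation.
#' @export
sphere_cap_mesh <- function(radius, center = c(0, 0, 0), axis = c(0, 0, -1),
                            cap_angle = 60, target_faces = 2000,
                            concave = FALSE) {
  if (radius <= 0) stop("radius must be positive")
  if (target_faces < 100) stop("mesh resolution below minimum (100 triangles)")
  if (cap_angle <= 0 || cap_angle > 180) stop("cap_angle must be in (0, 180]")
  axis <- axis / sqrt(sum(axis^2))
  frac <- (1 - cos(cap_angle * pi / 180)) / 2
  subdiv <- 0
  while (20 * 4^subdiv * frac < target_faces && subdiv < 8) subdiv <- subdiv + 1
  s <- unit_icosphere(subdiv)
  v <- s$vertices
  f <- s$faces

  cosang <- drop(v %*% axis)
  if (cap_angle < 180) {
    cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
    cent <- cent / sqrt(rowSums(cent^2))
    keep <- drop(cent %*% axis) >= cos(cap_angle * pi / 180)
    f <- f[keep, , drop = FALSE]
    if (nrow(f) == 0L) stop("cap too small for requested resolution")
    # clamp vertices outside the rim onto the rim circle (same azimuth)
    used <- sort(unique(as.vector(f)))
    out <- used[cosang[used] < cos(cap_angle * pi / 180)]
    if (length(out)) {
      ca <- cos(cap_angle * pi / 180); sa <- sin(cap_angle * pi / 180)
      for (i in out) {
        p <- v[i, ]
        t_comp <- p - sum(p * axis) * axis
        tl <- sqrt(sum(t_comp^2))
        if (tl < 1e-12) next
        v[i, ] <- ca * axis + sa * t_comp / tl
      }
    }
    # reindex to used vertices
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
  }

  verts <- sweep(v * radius, 2, center, "+")
  normals <- if (concave) -v else v
  trimesh(verts, f, normals = normals,
          sphere = list(center = center, radius = radius, concave = concave))
}

# --- STL input/output --------------------------------------------------------

#' Read or write STL surface files
#'
#' Minimal STL support for exchanging implant surfaces with CAD tools.
#' Both ASCII and binary flavours are handled; `write_stl` defaults to
#' ASCII so that generated fixtures stay text-only.
#'
#' @param mesh a [trimesh()].
#' @param path file path.
#' @param binary write the 80-byte-header binary flavour instead of ASCII.
#' @return `read_stl` returns a [trimesh()] (vertices are welded by exact
#'   coordinate match); `write_stl` returns `path` invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
               con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid atsasim", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", fn[i, 1], fn[i, 2], fn[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid atsasim", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 5L)
  is_ascii <- identical(rawToChar(hdr), "solid") && {
    txt <- readLines(path, n = 20L, warn = FALSE)
    any(grepl("facet", txt))
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangles(tri)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  num <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(num) %% 3 != 0) stop("malformed ASCII STL: vertex count not multiple of 3")
  num
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  out <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3L, byrow = TRUE)
  }
  out
}

weld_triangles <- function(tri) {
  key <- apply(tri, 1, function(r) paste(sprintf("%.9e", r), collapse = ","))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- tri[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces)
}
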