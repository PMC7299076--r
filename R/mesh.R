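# Triangle-surface handling: minimal ASCII OFF/OBJ/STL IO, programmatic
# fixture surfaces (icosphere, truncated ellipsoid), and the
# divergence-theorem cavity volume.

#' Triangle surface mesh
#'
#' A simple triangle surface: `vertices` (n x 3 matrix, cm) and `faces`
#' (m x 3 integer matrix, 1-based vertex indices).
#'
#' @param vertices numeric matrix n x 3.
#' @param faces integer matrix m x 3.
#' @return list of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) abort("vertices must have three columns.")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of vertex range.")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' Read / write ASCII triangle meshes
#'
#' Readers and writers for the ASCII OFF, Wavefront OBJ and ASCII STL
#' formats (triangles only). STL files carry no connectivity, so reading
#' STL welds coincident vertices.
#'
#' @param path file path; format inferred from the extension
#'   (`.off`, `.obj`, `.stl`).
#' @param mesh a [tri_mesh()] (for writing).
#' @return a [tri_mesh()] (readers); `path` invisibly (writer).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = read_off(path),
    obj = read_obj(path),
    stl = read_stl_ascii(path),
    abort(paste0("unsupported mesh format: .", ext))
  )
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "off") {
    writeLines("OFF", con)
    writeLines(paste(nrow(v), nrow(f), 0L), con)
    writeLines(apply(v, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
    writeLines(apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
  } else if (ext == "obj") {
    writeLines(apply(v, 1, function(r) paste("v", paste(format(r, digits = 12), collapse = " "))), con)
    writeLines(apply(f, 1, function(r) paste("f", paste(r, collapse = " "))), con)
  } else if (ext == "stl") {
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- tri_normal(tri)
      writeLines(paste("facet normal", paste(format(n, digits = 9), collapse = " ")), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        writeLines(paste("    vertex", paste(format(tri[k, ], digits = 12), collapse = " ")), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  } else {
    abort(paste0("unsupported mesh format: .", ext))
  }
  invisible(path)
}

read_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") abort("not an ASCII OFF file.")
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vt <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s) as.numeric(strsplit(s, "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    x <- as.integer(strsplit(s, "\\s+")[[1]])
    if (x[1] != 3L) abort("only triangle faces are supported.")
    x[2:4] + 1L
  }))
  tri_mesh(vt, fc)
}

read_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  vt <- do.call(rbind, lapply(vs, function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4])))
  fc <- do.call(rbind, lapply(fs, function(s) {
    parts <- strsplit(trimws(s), "\\s+")[[1]][-1]
    if (length(parts) != 3L) abort("only triangle faces are supported.")
    as.integer(vapply(strsplit(parts, "/"), `[[`, "", 1L))
  }))
  tri_mesh(vt, fc)
}

read_stl_ascii <- function(path) {
  ln <- trimws(readLines(path))
  vx <- ln[startsWith(ln, "vertex")]
  coords <- do.call(rbind, lapply(vx, function(s) as.numeric(strsplit(s, "\\s+")[[1]][2:4])))
  key <- apply(round(coords, 9), 1, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- coords[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

tri_normal <- function(tri) {
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0) return(c(0, 0, 0))
  n / nn
}

#' Icosphere fixture
#'
#' Geodesic sphere obtained by subdividing an icosahedron `level` times and
#' projecting onto the sphere of radius `radius`. Outward-oriented faces;
#' closed manifold with Euler characteristic 2.
#'
#' @param level subdivision level (0 = icosahedron, 4 gives 5120 faces).
#' @param radius sphere radius.
#' @return a [tri_mesh()].
#' @export
icosphere <- function(level = 4, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (l in seq_len(level)) {
    mid_cache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ])
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      id <- nv + length(vlist)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, vlist))
    f <- nf
  }
  m <- tri_mesh(v * radius, f)
  if (mesh_enclosed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Truncated-ellipsoid ventricular surface fixture
#'
#' Parametric triangulation of the ellipsoid `x^2/a^2 + y^2/b^2 + z^2/c^2 = 1`
#' truncated by the plane `z = z_base`, with a flat triangulated basal lid
#' lying exactly in that plane (fan around the lid centre). Outward-oriented.
#' The closed-form cap volume `pi a b (z - z^3/(3 c^2) + 2c/3)` evaluated at
#' `z_base` gives the exact enclosed volume for convergence checks.
#'
#' @param a,b,c semi-axes (cm); `c` is apico-basal.
#' @param z_base truncation height, `-c < z_base < c`.
#' @param n_theta,n_phi angular resolutions.
#' @return a [tri_mesh()] with attribute `basal_z = z_base`.
#' @export
truncated_ellipsoid <- function(a = 2.5, b = 2.5, c = 4.5, z_base = 2,
                                n_theta = 64, n_phi = 64) {
  if (z_base <= -c || z_base >= c) abort("z_base must lie strictly inside (-c, c).")
  # polar angle from apex (z = -c) up to the truncation plane
  th_max <- acos(z_base / c)           # theta measured from +z
  th <- seq(pi, th_max, length.out = n_phi)  # apex (pi) to rim (th_max)
  ph <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- list(c(0, 0, -c))  # apex point
  idx <- function(i, j) 1L + (i - 2L) * n_theta + ((j - 1L) %% n_theta) + 1L
  for (i in 2:length(th)) {
    for (j in seq_len(n_theta)) {
      verts[[length(verts) + 1L]] <-
        c(a * sin(th[i]) * cos(ph[j]), b * sin(th[i]) * sin(ph[j]), c * cos(th[i]))
    }
  }
  faces <- list()
  # apex fan (theta ring 2)
  for (j in seq_len(n_theta)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(2L, j + 1L), idx(2L, j))
  }
  for (i in 2:(length(th) - 1L)) {
    for (j in seq_len(n_theta)) {
      v00 <- idx(i, j); v01 <- idx(i, j + 1L)
      v10 <- idx(i + 1L, j); v11 <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(v00, v01, v11)
      faces[[length(faces) + 1L]] <- c(v00, v11, v10)
    }
  }
  # basal lid: fan around the centre, in the plane z = z_base, facing +z
  centre_id <- length(verts) + 1L
  verts[[centre_id]] <- c(0, 0, z_base)
  rim <- length(th)
  for (j in seq_len(n_theta)) {
    faces[[length(faces) + 1L]] <- c(centre_id, idx(rim, j), idx(rim, j + 1L))
  }
  m <- tri_mesh(do.call(rbind, verts), do.call(rbind, faces))
  # orientation check: make normals outward (positive enclosed volume)
  if (mesh_enclosed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  attr(m, "basal_z") <- z_base
  m
}

# signed enclosed volume via the divergence theorem (x/3 . n integral)
mesh_enclosed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Euler characteristic of a triangle mesh
#'
#' `V - E + F`; 2 for a closed surface of sphere topology.
#'
#' @param mesh a [tri_mesh()].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  ne <- nrow(unique(edges))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Cavity volume by the divergence theorem
#'
#' Computes the enclosed cavity volume from a closed endocardial surface
#' (flat basal lid convention) as the surface integral
#' `integral (x . axis)(axis . n) dA`. The integrand is linear per triangle,
#' so each face contributes exactly `A_T (centroid . axis)(axis . n_T)`.
#' With the axis parallel to the basal plane (i.e. `axis . n = 0` on the
#' lid) the lid contributes nothing; for a lid normal along the axis the
#' lid term is included, which the divergence theorem still makes exact for
#' a closed surface.
#'
#' @param surface a [tri_mesh()] of the (deformed) endocardial surface.
#' @param displacement optional n x 3 displacement field added to the
#'   vertices before integration.
#' @param axis unit 3-vector, default `e1 = (1, 0, 0)`.
#' @param check if `TRUE`, error when the surface has boundary edges.
#' @return volume (ml for cm coordinates).
#' @export
cavity_volume <- function(surface, displacement = NULL, axis = c(1, 0, 0),
                          check = TRUE) {
  v <- surface$vertices
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    if (!all(dim(displacement) == dim(v))) abort("displacement must match vertices.")
    v <- v + displacement
  }
  f <- surface$faces
  if (check) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    edges <- t(apply(edges, 1, sort))
    cnt <- table(apply(edges, 1, paste, collapse = "_"))
    if (any(cnt != 2L)) abort("surface is not closed (boundary or non-manifold edges).")
  }
  axis <- axis / sqrt(sum(axis^2))
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )                                       # 2 A_T n_T
  centroid <- (p1 + p2 + p3) / 3
  sum((centroid %*% axis) * (cr %*% axis)) / 2
}
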