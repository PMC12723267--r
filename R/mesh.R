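#' Build an unstructured triangular mesh of a disk
#'
#' Meshes the disk of the given diameter with concentric rings of nodes and a
#' two-pointer stitching triangulation between consecutive rings, yielding a
#' conforming, positively oriented P1 mesh whose boundary nodes lie exactly on
#' the circle.  The number of rings is chosen so the radial spacing matches
#' `targetElementSize`; ring node counts keep the azimuthal spacing comparable.
#'
#' @param diameter disk diameter in mm (50-150).
#' @param targetElementSize requested characteristic element size in mm; must
#'   be smaller than diameter/10.
#' @return a \linkS4class{DOTMesh}.
#' @examples
#' m <- buildCircularMesh(60, 5)
#' abs(sum(triangleAreas(m)) - pi * 30^2) / (pi * 30^2)  # < 1%
#' @export
buildCircularMesh <- function(diameter, targetElementSize = diameter / 30) {
  if (diameter < 50 || diameter > 150)
    stop("diameter must be in [50, 150] mm")
  if (targetElementSize >= diameter / 10)
    stop("target element size must be below diameter/10")
  if (targetElementSize < diameter / 400)
    stop("target element size infeasibly small")
  R <- diameter / 2
  nr <- max(3L, as.integer(round(R / targetElementSize)))
  # meshes with the same ring count are geometrically similar: build a unit
  # mesh once per ring count and always return a scaled copy of it (never
  # the direct construction, so results do not depend on the cache state)
  key <- as.character(nr)
  unit <- .meshCache[[key]]
  if (!is.null(unit)) {
    return(new("DOTMesh", nodes = unit@nodes * R, triangles = unit@triangles,
               boundary = unit@boundary, radius = R, h = R / nr))
  }
  ringR <- seq_len(nr) / nr
  ringN <- pmax(6L, as.integer(round(2 * pi * seq_len(nr))))
  nodes <- matrix(0, 1, 2)          # center node first
  ringStart <- integer(nr)          # index of first node of each ring
  for (k in seq_len(nr)) {
    ringStart[k] <- nrow(nodes) + 1L
    th <- 2 * pi * (seq_len(ringN[k]) - 1L) / ringN[k]
    nodes <- rbind(nodes, cbind(ringR[k] * cos(th), ringR[k] * sin(th)))
  }
  tris <- vector("list", nr)
  # innermost fan around the center node
  m1 <- ringN[1]
  j <- seq_len(m1)
  tris[[1]] <- cbind(1L, ringStart[1] + j - 1L, ringStart[1] + (j %% m1))
  for (k in 2:nr) {
    tris[[k]] <- stitchRings(ringStart[k - 1L], ringN[k - 1L],
                             ringStart[k], ringN[k])
  }
  tri <- do.call(rbind, tris)
  storage.mode(tri) <- "integer"
  # enforce CCW orientation
  a <- signedAreas(nodes, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  boundary <- logical(nrow(nodes))
  boundary[ringStart[nr]:(ringStart[nr] + ringN[nr] - 1L)] <- TRUE
  .meshCache[[key]] <- new("DOTMesh", nodes = nodes, triangles = tri,
                           boundary = boundary, radius = 1, h = 1 / nr)
  unit <- .meshCache[[key]]
  new("DOTMesh", nodes = unit@nodes * R, triangles = unit@triangles,
      boundary = unit@boundary, radius = R, h = R / nr)
}

.meshCache <- new.env(parent = emptyenv())

# Triangulate the annulus between two concentric node rings by advancing the
# pointer whose next node comes first in angle (classic two-pointer stitch).
stitchRings <- function(innerStart, nInner, outerStart, nOuter) {
  # angle of node j (0-based) plus a sentinel 2*pi for the wrap-around
  AI <- c(2 * pi * (seq_len(nInner) - 1L) / nInner, 2 * pi)
  AO <- c(2 * pi * (seq_len(nOuter) - 1L) / nOuter, 2 * pi)
  tris <- matrix(0L, nInner + nOuter, 3L)
  i <- 0L; o <- 0L; t <- 0L
  while (i < nInner || o < nOuter) {
    curIn <- innerStart + (i %% nInner)
    curOut <- outerStart + (o %% nOuter)
    advInner <- i < nInner && (o >= nOuter || AI[i + 2L] <= AO[o + 2L])
    t <- t + 1L
    if (advInner) {
      tris[t, ] <- c(curIn, curOut, innerStart + ((i + 1L) %% nInner))
      i <- i + 1L
    } else {
      tris[t, ] <- c(curIn, curOut, outerStart + ((o + 1L) %% nOuter))
      o <- o + 1L
    }
  }
  tris
}

signedAreas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Triangle areas of a mesh
#' @param mesh a \linkS4class{DOTMesh}.
#' @return vector of positive triangle areas (mm^2).
#' @export
triangleAreas <- function(mesh) {
  abs(signedAreas(mesh@nodes, mesh@triangles))
}

# P1 shape-function gradients per triangle.
# Returns list(bx, by: m x 3 matrices, area: length-m vector) with
# grad(phi_l) = (bx[e,l], by[e,l]) constant on element e.
triangleGradients <- function(mesh) {
  nodes <- mesh@nodes; tri <- mesh@triangles
  x <- matrix(nodes[tri, 1], ncol = 3); y <- matrix(nodes[tri, 2], ncol = 3)
  area <- signedAreas(nodes, tri)
  bx <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * area)
  by <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * area)
  list(bx = bx, by = by, area = abs(area))
}

# Boundary edges (pairs of adjacent boundary nodes on the circle), ordered.
boundaryEdges <- function(mesh) {
  idx <- which(mesh@boundary)
  ang <- atan2(mesh@nodes[idx, 2], mesh@nodes[idx, 1])
  idx <- idx[order(ang)]
  cbind(idx, c(idx[-1], idx[1]))
}

#' Locate points in a mesh and compute barycentric weights
#'
#' Brute-force point location: for each query point, the enclosing triangle
#' (ties broken by lowest triangle index) and the P1 interpolation weights of
#' its three vertices.  Points outside the mesh get triangle index NA.
#'
#' @param mesh a \linkS4class{DOTMesh}.
#' @param points q x 2 matrix of coordinates (mm).
#' @param tol barycentric tolerance for boundary/edge membership.
#' @return list with integer vector `triangle` and q x 3 matrix `weights`.
#' @export
locatePoints <- function(mesh, points, tol = 1e-9) {
  g <- triangleGradients(mesh)
  tri <- mesh@triangles
  nodes <- mesh@nodes
  q <- nrow(points)
  triIdx <- rep(NA_integer_, q)
  wts <- matrix(NA_real_, q, 3)
  # barycentric coordinate of point p wrt element e for vertex l:
  # lambda_l = phi_l(p) = phi_l(v_l) + grad phi_l . (p - centroid-ish);
  # use lambda_l(p) = c_l + bx_l x + by_l y with c_l fixed by lambda at nodes.
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  c1 <- 1 - g$bx[, 1] * x1 - g$by[, 1] * y1
  c2 <- 0 - g$bx[, 2] * x1 - g$by[, 2] * y1
  c3 <- 0 - g$bx[, 3] * x1 - g$by[, 3] * y1
  R <- mesh@radius
  for (p in seq_len(q)) {
    l1 <- c1 + g$bx[, 1] * points[p, 1] + g$by[, 1] * points[p, 2]
    l2 <- c2 + g$bx[, 2] * points[p, 1] + g$by[, 2] * points[p, 2]
    l3 <- 1 - l1 - l2
    ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    e <- NA_integer_
    if (length(ok)) {
      e <- ok[1L]  # lowest-index tie-break
    } else if (sqrt(sum(points[p, ]^2)) <= R * (1 + 1e-9)) {
      # on the circle but outside the polygonal hull (boundary chords):
      # take the least-violating triangle
      e <- which.max(pmin(l1, l2, l3))
    }
    if (!is.na(e)) {
      triIdx[p] <- e
      wts[p, ] <- pmax(c(l1[e], l2[e], l3[e]), 0)
      wts[p, ] <- wts[p, ] / sum(wts[p, ])
    }
  }
  list(triangle = triIdx, weights = wts)
}

# Sparse interpolation operator (q x n) for points inside the mesh.
interpolationMatrix <- function(mesh, points, tol = 1e-9) {
  loc <- locatePoints(mesh, points, tol)
  if (anyNA(loc$triangle)) stop("point outside mesh")
  q <- nrow(points)
  rows <- rep(seq_len(q), each = 3)
  cols <- as.vector(t(mesh@triangles[loc$triangle, , drop = FALSE]))
  vals <- as.vector(t(loc$weights))
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(q, nrow(mesh@nodes)))
}

#' Write a mesh as plain-text node/element lists
#' @param mesh a \linkS4class{DOTMesh}.
#' @param file path of the text file to create.
#' @return invisibly, the file path.
#' @export
writeMesh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fdDOT mesh radius=%.10g h=%.10g", mesh@radius, mesh@h), con)
  writeLines(sprintf("nodes %d", nrow(mesh@nodes)), con)
  utils::write.table(cbind(mesh@nodes, as.integer(mesh@boundary)), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("triangles %d", nrow(mesh@triangles)), con)
  utils::write.table(mesh@triangles, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a mesh written by [writeMesh()]
#' @param file path of the mesh text file.
#' @return a \linkS4class{DOTMesh}.
#' @export
readMesh <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(sub("^# fdDOT mesh ", "", lines[1]), " ")[[1]]
  radius <- as.numeric(sub("radius=", "", hdr[1]))
  h <- as.numeric(sub("h=", "", hdr[2]))
  nN <- as.integer(strsplit(lines[2], " ")[[1]][2])
  nodeRows <- lines[3:(2 + nN)]
  nm <- do.call(rbind, lapply(strsplit(nodeRows, " "), as.numeric))
  nT <- as.integer(strsplit(lines[3 + nN], " ")[[1]][2])
  triRows <- lines[(4 + nN):(3 + nN + nT)]
  tm <- do.call(rbind, lapply(strsplit(triRows, " "), as.integer))
  new("DOTMesh", nodes = nm[, 1:2, drop = FALSE], triangles = tm,
      boundary = as.logical(nm[, 3]), radius = radius, h = h)
}
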