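# Shared computational-geometry primitives. No installed R package provides
# nearest-neighbour search, marching cubes/tetrahedra or triangle-mesh
# plumbing, so these are implemented here (vectorized base R).

#' Nearest neighbours between point sets (brute force, chunked)
#'
#' @param query M x 3 matrix.
#' @param ref N x 3 matrix.
#' @param chunk rows of \code{query} processed per block.
#' @return list with \code{index} (row in \code{ref}) and \code{dist} (mm).
#' @export
nearestNeighbors <- function(query, ref, chunk = 512L) {
  m <- nrow(query)
  idx <- integer(m); dst <- numeric(m)
  rr <- rowSums(ref^2)
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rr, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    # recompute the winning distances directly (the expanded form above
    # loses ~1e-7 to cancellation, which matters for exact-match queries)
    dst[s:e] <- sqrt(rowSums((q - ref[j, , drop = FALSE])^2))
  }
  list(index = idx, dist = dst)
}

# Neighbour index lists within a fixed radius (includes the point itself when
# query and ref are the same matrix).
radiusNeighbors <- function(query, ref, radius, chunk = 256L) {
  m <- nrow(query)
  out <- vector("list", m)
  rr <- rowSums(ref^2)
  r2 <- radius^2 + 1e-12
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rr, "+") - 2 * tcrossprod(q, ref)
    hits <- which(d2 <= r2, arr.ind = TRUE)
    if (nrow(hits)) {
      sp <- split(hits[, 2L], hits[, 1L])
      out[s - 1L + as.integer(names(sp))] <- sp
    }
  }
  out
}

#' Area of a closed planar polygon (shoelace)
#' @param xy K x 2 matrix of vertices in order (not repeated at the end).
#' @export
polygonArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Even-odd point-in-polygon test (vectorized over points)
#' @param pts N x 2 matrix.
#' @param poly K x 2 closed polygon (first vertex not repeated).
#' @export
pointInPolygon <- function(pts, poly) {
  n <- nrow(pts)
  inside <- rep(FALSE, n)
  k <- nrow(poly)
  px <- pts[, 1L]; py <- pts[, 2L]
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Do any two segments of a closed polygon (projected 2D) properly intersect,
# ignoring adjacent segments?
polygonSelfIntersects <- function(xy) {
  k <- nrow(xy)
  seg <- cbind(xy, xy[c(2:k, 1L), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(k - 2L)) {
    js <- setdiff(seq(i + 2L, k), c(i, if (i == 1L) k else integer()))
    for (j in js) {
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Construct a triangle mesh
#' @param vertices N x 3 matrix, mm.
#' @param faces M x 3 integer matrix (1-based).
#' @param vertexLabels,faceTags optional annotations.
#' @export
triangleMesh <- function(vertices, faces, vertexLabels = NULL, faceTags = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  new("TriangleMesh", vertices = vertices,
      faces = matrix(as.integer(faces), ncol = 3L),
      vertexLabels = unname(vertexLabels), faceTags = unname(faceTags))
}

faceNormals <- function(mesh, normalize = TRUE) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

faceAreas <- function(mesh) {
  n <- faceNormals(mesh, normalize = FALSE)
  sqrt(rowSums(n^2)) / 2
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a \linkS4class{TriangleMesh}.
#' @export
meshArea <- function(mesh) sum(faceAreas(mesh))

faceCentroids <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

# Fast grouped sum onto a fixed-length vector.
tapply2 <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s
  out
}

# Area-weighted per-vertex normals.
vertexNormals <- function(mesh) {
  fn <- faceNormals(mesh, normalize = FALSE)
  nv <- nrow(mesh@vertices)
  n <- matrix(0, nv, 3L)
  for (k in 1:3) {
    idx <- mesh@faces[, k]
    for (c_ in 1:3) n[, c_] <- n[, c_] + tapply2(fn[, c_], idx, nv)
  }
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle selection with uniform barycentric coordinates;
#' per-point labels are inherited from the nearest triangle corner.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param n number of points.
#' @param seed integer seed.
#' @return a \linkS4class{PointCloud} with normals (face normals) and labels.
#' @export
samplePointsOnMesh <- function(mesh, n, seed = 1L) {
  set.seed(seed)
  ar <- faceAreas(mesh)
  tri <- sample.int(nrow(mesh@faces), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  v <- mesh@vertices; f <- mesh@faces[tri, , drop = FALSE]
  P <- w1 * v[f[, 1L], , drop = FALSE] + w2 * v[f[, 2L], , drop = FALSE] +
    w3 * v[f[, 3L], , drop = FALSE]
  N <- faceNormals(mesh)[tri, , drop = FALSE]
  labs <- NULL
  if (!is.null(mesh@vertexLabels)) {
    wmax <- max.col(cbind(w1, w2, w3))
    labs <- mesh@vertexLabels[f[cbind(seq_len(n), wmax)]]
  }
  new("PointCloud", positions = P, normals = N, labels = labs,
      metadata = list(sourceFace = tri))
}

# Undirected edge table with face counts; boundary edges appear once.
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  first <- !duplicated(key)
  list(edges = e[first, , drop = FALSE],
       count = as.integer(cnt[key[first]]))
}

# Ordered boundary loops (lists of vertex indices) of an open mesh.
boundaryLoops <- function(mesh) {
  ed <- meshEdges(mesh)
  be <- ed$edges[ed$count == 1L, , drop = FALSE]
  if (!nrow(be)) return(list())
  nxt <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  visitedEdge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (i in seq_len(nrow(be))) {
    a <- be[i, 1L]; b <- be[i, 2L]
    if (!is.null(visitedEdge[[ekey(a, b)]])) next
    loop <- c(a, b)
    visitedEdge[[ekey(a, b)]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      cand <- nxt[[as.character(cur)]]
      cand <- cand[vapply(cand, function(x) is.null(visitedEdge[[ekey(cur, x)]]), logical(1))]
      if (!length(cand)) break
      nxtv <- cand[1L]
      visitedEdge[[ekey(cur, nxtv)]] <- TRUE
      if (nxtv == loop[1L]) break
      loop <- c(loop, nxtv)
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Connected components over mesh vertices (edge connectivity); returns an
# integer component id per vertex (0 for isolated vertices keeps own id).
vertexComponents <- function(mesh) {
  nv <- nrow(mesh@vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)])
  for (i in seq_len(nrow(e))) {
    ra <- find(e[i, 1L]); rb <- find(e[i, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(nv), find, integer(1))
}

# --- Marching tetrahedra -----------------------------------------------------

# 6-tet decomposition of the unit cube around the 0-7 diagonal. Corner ids are
# 0-based bit triples (bit0 = x, bit1 = y, bit2 = z).
.mtCorners <- matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
                       0, 0, 1,  1, 0, 1,  0, 1, 1,  1, 1, 1),
                     ncol = 3L, byrow = TRUE)
.mtTets <- matrix(c(0, 1, 3, 7,  0, 3, 2, 7,  0, 2, 6, 7,
                    0, 6, 4, 7,  0, 4, 5, 7,  0, 5, 1, 7) + 1L,
                  ncol = 4L, byrow = TRUE)
# Tet edges as local vertex index pairs (1..4).
.mtEdges <- matrix(c(1, 2,  1, 3,  1, 4,  2, 3,  2, 4,  3, 4),
                   ncol = 2L, byrow = TRUE)
# Case table: for each of the 16 sign patterns (bit k-1 = vertex k inside),
# the list of triangles given as triples of tet-edge indices (1..6).
.mtCases <- {
  cs <- vector("list", 16L)
  cs[[1 + 1]] <- list(c(1, 2, 3))              # vertex 1 in
  cs[[2 + 1]] <- list(c(1, 4, 5))              # vertex 2 in
  cs[[4 + 1]] <- list(c(2, 6, 4))              # vertex 3 in
  cs[[8 + 1]] <- list(c(3, 5, 6))              # vertex 4 in
  cs[[3 + 1]] <- list(c(2, 3, 4), c(3, 5, 4))  # 1,2 in
  cs[[5 + 1]] <- list(c(1, 6, 3), c(1, 4, 6))  # 1,3 in
  cs[[9 + 1]] <- list(c(1, 2, 5), c(2, 6, 5))  # 1,4 in
  cs[[6 + 1]] <- list(c(1, 5, 2), c(2, 5, 6))  # 2,3 in
  cs[[10 + 1]] <- list(c(1, 3, 4), c(3, 6, 4)) # 2,4 in
  cs[[12 + 1]] <- list(c(2, 4, 3), c(3, 4, 5)) # 3,4 in
  cs[[7 + 1]] <- list(c(3, 5, 6))              # all but 4
  cs[[11 + 1]] <- list(c(2, 6, 4))
  cs[[13 + 1]] <- list(c(1, 4, 5))
  cs[[14 + 1]] <- list(c(1, 2, 3))
  cs
}

#' Iso-surface of a 3D array by marching tetrahedra
#'
#' Each grid cube is split into six tetrahedra; within a tetrahedron the
#' field is linear, so the iso-surface is a plane cut yielding one or two
#' triangles. Triangles are oriented with normals pointing toward decreasing
#' field values (outward for a bright object).
#'
#' @param vol 3D numeric array.
#' @param level iso value.
#' @param spacing,origin grid geometry (mm, center-of-voxel convention).
#' @return a \linkS4class{TriangleMesh} (possibly empty).
#' @export
isoSurfaceFromArray <- function(vol, level, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  d <- dim(vol)
  if (any(d < 2L)) return(triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  n1 <- d[1] - 1L; n2 <- d[2] - 1L; n3 <- d[3] - 1L
  corner <- function(dx, dy, dz)
    vol[(1L + dx):(n1 + dx), (1L + dy):(n2 + dy), (1L + dz):(n3 + dz)]
  cv <- lapply(seq_len(8L), function(k)
    as.vector(corner(.mtCorners[k, 1], .mtCorners[k, 2], .mtCorners[k, 3])))
  cmin <- Reduce(pmin, cv); cmax <- Reduce(pmax, cv)
  active <- which(cmin < level & cmax >= level)
  if (!length(active))
    return(triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  # 0-based cube indices -> world coordinates of corner 0
  i1 <- (active - 1L) %% n1
  i2 <- ((active - 1L) %/% n1) %% n2
  i3 <- (active - 1L) %/% (n1 * n2)
  base <- cbind(origin[1] + i1 * spacing[1],
                origin[2] + i2 * spacing[2],
                origin[3] + i3 * spacing[3])
  cvals <- vapply(cv, function(v) v[active], numeric(length(active)))
  if (is.null(dim(cvals))) cvals <- matrix(cvals, nrow = 1L)
  tris <- list()
  for (t in seq_len(6L)) {
    vid <- .mtTets[t, ]
    off <- .mtCorners[vid, , drop = FALSE]
    vals <- cvals[, vid, drop = FALSE]
    inside <- vals >= level
    caseId <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cid in setdiff(unique(caseId), c(0L, 15L))) {
      rows <- which(caseId == cid)
      vertsAt <- function(edge) {
        a <- .mtEdges[edge, 1L]; b <- .mtEdges[edge, 2L]
        va <- vals[rows, a]; vb <- vals[rows, b]
        tt <- (level - va) / (vb - va)
        pa <- base[rows, , drop = FALSE] +
          matrix(off[a, ] * spacing, length(rows), 3L, byrow = TRUE)
        pb <- base[rows, , drop = FALSE] +
          matrix(off[b, ] * spacing, length(rows), 3L, byrow = TRUE)
        pa + tt * (pb - pa)
      }
      # linear-field gradient within the tet (for outward orientation)
      E <- t(off[2:4, , drop = FALSE] - rep(1, 3) %o% off[1, ]) * spacing
      Ginv <- solve(t(E))
      dv <- cbind(vals[rows, 2] - vals[rows, 1],
                  vals[rows, 3] - vals[rows, 1],
                  vals[rows, 4] - vals[rows, 1])
      grad <- dv %*% t(Ginv)
      for (tr in .mtCases[[cid + 1L]]) {
        p1 <- vertsAt(tr[1]); p2 <- vertsAt(tr[2]); p3 <- vertsAt(tr[3])
        e1 <- p2 - p1; e2 <- p3 - p1
        nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                     e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                     e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        flip <- rowSums(nrm * grad) > 0  # normal must point down-gradient
        tmp <- p2[flip, , drop = FALSE]
        p2[flip, ] <- p3[flip, , drop = FALSE]
        p3[flip, ] <- tmp
        tris[[length(tris) + 1L]] <- cbind(p1, p2, p3)
      }
    }
  }
  if (!length(tris))
    return(triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  allTri <- do.call(rbind, tris)
  V <- rbind(allTri[, 1:3, drop = FALSE], allTri[, 4:6, drop = FALSE],
             allTri[, 7:9, drop = FALSE])
  m <- nrow(allTri)
  F <- cbind(seq_len(m), seq_len(m) + m, seq_len(m) + 2L * m)
  # weld coincident vertices
  tolr <- min(spacing) * 1e-6
  key <- paste(round(V[, 1] / tolr), round(V[, 2] / tolr), round(V[, 3] / tolr))
  uid <- match(key, unique(key))
  keep <- !duplicated(key)
  V2 <- V[keep, , drop = FALSE]
  F2 <- matrix(uid[F], ncol = 3L)
  degen <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
  triangleMesh(V2, F2[!degen, , drop = FALSE])
}

# --- Mesh voxelization (z-column parity ray casting) -------------------------

# Returns a logical array of the same dims as the target grid marking voxels
# whose centers lie inside the closed mesh.
voxelizeMesh <- function(mesh, dims, spacing, origin) {
  xs <- origin[1] + (seq_len(dims[1]) - 1L) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1L) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1L) * spacing[3]
  v <- mesh@vertices; f <- mesh@faces
  colHits <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; c_ <- v[f[i, 3L], ]
    xr <- range(a[1], b[1], c_[1]); yr <- range(a[2], b[2], c_[2])
    ix <- which(xs >= xr[1] - 1e-9 & xs <= xr[2] + 1e-9)
    iy <- which(ys >= yr[1] - 1e-9 & ys <= yr[2] + 1e-9)
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(ix = ix, iy = iy)
    px <- xs[g$ix]; py <- ys[g$iy]
    d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(d) < 1e-12) next
    w1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / d
    w2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / d
    w3 <- 1 - w1 - w2
    ok <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(ok)) next
    z <- w1[ok] * a[3] + w2[ok] * b[3] + w3[ok] * c_[3]
    colHits[[i]] <- cbind(col = (g$iy[ok] - 1L) * dims[1] + g$ix[ok], z = z)
  }
  hits <- do.call(rbind, colHits)
  occ <- array(FALSE, dims)
  if (is.null(hits) || !nrow(hits)) return(occ)
  sp <- split(hits[, "z"], hits[, "col"])
  for (colKey in names(sp)) {
    z <- sort(sp[[colKey]])
    # collapse duplicate crossings (shared edges)
    z <- z[c(TRUE, diff(z) > 1e-9)]
    if (length(z) < 2L) next
    ci <- as.integer(colKey)
    ixy <- c((ci - 1L) %% dims[1] + 1L, (ci - 1L) %/% dims[1] + 1L)
    for (k in seq(1L, length(z) - 1L, by = 2L)) {
      inz <- which(zs > z[k] & zs < z[k + 1L])
      if (length(inz)) occ[ixy[1], ixy[2], inz] <- TRUE
    }
  }
  occ
}

# Exact point-to-triangle distances, vectorized over (point, triangle) pairs.
pointTriangleDistance <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  res <- matrix(NA_real_, nrow(P), 3L)
  done <- rep(FALSE, nrow(P))
  setres <- function(mask, Q) {
    m <- mask & !done
    res[m, ] <<- Q[m, , drop = FALSE]
    done[m] <<- TRUE
  }
  setres(d1 <= 0 & d2 <= 0, A)
  setres(d3 >= 0 & d4 <= d3, B)
  setres(d6 >= 0 & d5 <= d6, C)
  vc <- d1 * d4 - d3 * d2
  tAB <- d1 / (d1 - d3)
  setres(vc <= 0 & d1 >= 0 & d3 <= 0, A + tAB * ab)
  vb <- d5 * d2 - d1 * d6
  tAC <- d2 / (d2 - d6)
  setres(vb <= 0 & d2 >= 0 & d6 <= 0, A + tAC * ac)
  va <- d3 * d6 - d5 * d4
  tBC <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  setres(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + tBC * (C - B))
  denom <- va + vb + vc
  vv <- vb / denom; ww <- vc / denom
  setres(rep(TRUE, nrow(P)), A + vv * ab + ww * ac)
  sqrt(rowSums((P - res)^2))
}

# Distance from query points to a mesh surface: nearest vertex, then exact
# distance to the triangles incident to that vertex.
pointToMeshDistance <- function(points, mesh) {
  nn <- nearestNeighbors(points, mesh@vertices)
  f <- mesh@faces
  incid <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  best <- nn$dist
  triList <- incid[as.character(nn$index)]
  counts <- lengths(triList)
  if (any(counts > 0)) {
    pid <- rep(seq_len(nrow(points)), counts)
    tid <- unlist(triList, use.names = FALSE)
    v <- mesh@vertices
    d <- pointTriangleDistance(points[pid, , drop = FALSE],
                               v[f[tid, 1L], , drop = FALSE],
                               v[f[tid, 2L], , drop = FALSE],
                               v[f[tid, 3L], , drop = FALSE])
    ord <- order(pid, d)
    firstOfGroup <- !duplicated(pid[ord])
    best2 <- numeric(nrow(points))
    best2[pid[ord][firstOfGroup]] <- d[ord][firstOfGroup]
    touched <- unique(pid)
    best[touched] <- pmin(best[touched], best2[touched])
  }
  best
}

#' Fraction of reference surface points covered by a query cloud
#'
#' A reference point counts as covered when a query point lies within
#' \code{radius}. Used as the area-coverage oracle for partial scans.
#'
#' @param reference,query \linkS4class{PointCloud}s or N x 3 matrices.
#' @param radius coverage radius, mm.
#' @export
surfaceCoverage <- function(reference, query, radius = 0.25) {
  P <- if (is(reference, "PointCloud")) reference@positions else reference
  Q <- if (is(query, "PointCloud")) query@positions else query
  if (!nrow(Q)) return(0)
  mean(nearestNeighbors(P, Q)$dist <= radius)
}

# Rasterize a set of closed polygons (world mm, in-slice) onto a pixel grid;
# even-odd across polygons so holes subtract.
rasterizePolygons <- function(loops, xs, ys) {
  mask <- matrix(FALSE, length(xs), length(ys))
  if (!length(loops)) return(mask)
  g <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)))
  for (poly in loops) mask <- xor(mask, matrix(pointInPolygon(g, poly),
                                               length(xs), length(ys)))
  mask
}
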