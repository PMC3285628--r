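#' Triangulated spherical membrane with finite-element operators
#'
#' Builds an icosphere (icosahedron subdivided `subdivision_level` times,
#' nodes projected to radius `R`) and assembles the matrices of a linear
#' finite-element discretization of the Laplace-Beltrami operator: the
#' cotangent-weight stiffness matrix `K` (symmetric, rows summing to zero)
#' and the lumped (diagonal) mass matrix of node areas.  With these,
#' surface diffusion of a nodal field `u` is `M du/dt = -D K u`, which
#' conserves the total `sum(areas * u)` exactly.
#'
#' @param subdivision_level nonnegative integer; the mesh has
#'   `10 * 4^level + 2` nodes and `20 * 4^level` faces.
#' @param R sphere radius (um).
#' @return object of class `sphere_mesh` with fields:
#'   `vertices` (n x 3), `faces` (m x 3, integer), `areas` (lumped node
#'   areas, um^2), `stiffness` (sparse `dgCMatrix`), `neighbors` (list of
#'   integer vectors), `equator` (ordered node indices of a great-circle
#'   path, see [kymograph()]), `equator_angle` (their longitudes), `R`,
#'   `level`.
#' @examples
#' m <- build_sphere_mesh(1)
#' c(nrow(m$vertices), nrow(m$faces))  # 42 nodes, 80 faces
#' sum(m$areas) / (4 * pi)             # close to 1 for R = 1
#' @export
build_sphere_mesh <- function(subdivision_level, R = 1) {
  stopifnot(subdivision_level >= 0, R > 0)
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  if (subdivision_level > 0) {
    for (lev in seq_len(subdivision_level)) {
      nv <- nrow(v)
      edge_key <- new.env(hash = TRUE, size = 4L * nrow(f))
      verts <- vector("list", 0L)
      midpoint <- function(i, j) {
        key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
        idx <- edge_key[[key]]
        if (!is.null(idx)) return(idx)
        p <- v[i, ] + v[j, ]
        p <- p / sqrt(sum(p^2))
        verts[[length(verts) + 1L]] <<- p
        idx <- nv + length(verts)
        edge_key[[key]] <- idx
        idx
      }
      newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
      for (k in seq_len(nrow(f))) {
        a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
        newf[4L * k - 3L, ] <- c(a, ab, ca)
        newf[4L * k - 2L, ] <- c(b, bc, ab)
        newf[4L * k - 1L, ] <- c(c_, ca, bc)
        newf[4L * k, ] <- c(ab, bc, ca)
      }
      v <- rbind(v, do.call(rbind, verts))
      f <- newf
    }
  }
  v <- v * R
  n <- nrow(v); m <- nrow(f)

  # cotangent stiffness and lumped mass, assembled triangle by triangle
  ii <- integer(9L * m); jj <- integer(9L * m); xx <- numeric(9L * m)
  areas <- numeric(n)
  pos <- 0L
  for (k in seq_len(m)) {
    tri <- f[k, ]
    p <- v[tri, , drop = FALSE]
    e <- list(p[3, ] - p[2, ], p[1, ] - p[3, ], p[2, ] - p[1, ])
    cr <- c(e[[2]][2] * e[[3]][3] - e[[2]][3] * e[[3]][2],
            e[[2]][3] * e[[3]][1] - e[[2]][1] * e[[3]][3],
            e[[2]][1] * e[[3]][2] - e[[2]][2] * e[[3]][1])
    area2 <- sqrt(sum(cr^2))            # twice the triangle area
    areas[tri] <- areas[tri] + area2 / 6
    for (c_ in 1:3) {                   # corner opposite edge c_
      a <- c_ %% 3L + 1L; b <- a %% 3L + 1L
      cot <- -sum(e[[a]] * e[[b]]) / area2
      w <- cot / 2
      i <- tri[a]; j <- tri[b]
      ii[pos + 1:4] <- c(i, j, i, j)
      jj[pos + 1:4] <- c(j, i, i, j)
      xx[pos + 1:4] <- c(-w, -w, w, w)
      pos <- pos + 4L
    }
  }
  K <- Matrix::sparseMatrix(i = ii[1:pos], j = jj[1:pos], x = xx[1:pos],
                            dims = c(n, n))
  K <- Matrix::forceSymmetric(Matrix::drop0(K))

  nb <- vector("list", n)
  edges <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]))
  edges <- unique(t(apply(edges, 1, sort)))
  for (r in seq_len(nrow(edges))) {
    nb[[edges[r, 1]]] <- c(nb[[edges[r, 1]]], edges[r, 2])
    nb[[edges[r, 2]]] <- c(nb[[edges[r, 2]]], edges[r, 1])
  }
  nb <- lapply(nb, sort)

  eq <- equator_path(v, R)
  structure(list(vertices = v, faces = f, areas = areas,
                 stiffness = as(K, "generalMatrix"),
                 neighbors = nb, equator = eq$path,
                 equator_angle = eq$angle, R = R,
                 level = subdivision_level),
            class = "sphere_mesh")
}

# ordered node path closest to the z = 0 great circle
equator_path <- function(v, R, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  # local frame
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  n <- nrow(v)
  h <- 4 * R / sqrt(n)                    # about one edge length
  nsamp <- max(12L, ceiling(2 * pi * R / (h / 2)))
  ang <- seq(0, 2 * pi, length.out = nsamp + 1L)[-(nsamp + 1L)]
  pts <- outer(cos(ang), e1) + outer(sin(ang), e2)
  vn <- v / R
  idx <- apply(pts, 1, function(p) which.max(vn %*% p))
  keep <- c(TRUE, diff(idx) != 0)
  idx <- idx[keep]
  if (length(idx) > 1 && idx[1] == idx[length(idx)]) idx <- idx[-length(idx)]
  theta <- atan2(vn[idx, ] %*% e2, vn[idx, ] %*% e1)
  ord <- order(theta)
  list(path = idx[ord], angle = as.numeric(theta[ord]))
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat(sprintf("icosphere level %d: %d nodes, %d faces, R = %g um, area = %.6g um^2\n",
              x$level, nrow(x$vertices), nrow(x$faces), x$R, sum(x$areas)))
  invisible(x)
}

#' Verify the structural invariants of a sphere mesh
#'
#' Euler characteristic 2, positive node areas summing to the sphere area
#' within 1%, symmetric stiffness matrix with zero row sums.
#'
#' @param mesh a [build_sphere_mesh()] object.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
mesh_check <- function(mesh) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  e <- sum(lengths(mesh$neighbors)) / 2
  if (n - e + m != 2) stop("Euler characteristic is not 2")
  if (any(mesh$areas <= 0)) stop("nonpositive node area")
  S <- 4 * pi * mesh$R^2
  if (abs(sum(mesh$areas) - S) > 0.01 * S)
    stop("node areas deviate from the sphere area by more than 1%")
  K <- mesh$stiffness
  if (max(abs(K - Matrix::t(K))) > 1e-10) stop("stiffness not symmetric")
  if (max(abs(Matrix::rowSums(K))) > 1e-9 * max(abs(K@x)))
    stop("stiffness rows do not sum to zero")
  invisible(TRUE)
}

#' Smallest nonzero Laplace-Beltrami eigenvalue
#'
#' Computes the smallest nonzero generalized eigenvalue of
#' `K v = lambda M v` (M the lumped mass) by shift-inverted subspace
#' iteration with deflation of the constant mode.  On the sphere the exact
#' spectrum is `l (l + 1) / R^2`, so the target value is `2 / R^2`
#' (threefold degenerate).
#'
#' @param mesh a [build_sphere_mesh()] object.
#' @param k subspace dimension (>= 4 recommended: the eigenvalue is
#'   threefold degenerate).
#' @param iter number of subspace iterations.
#' @return the smallest nonzero eigenvalue (1/um^2).
#' @export
lb_min_eigenvalue <- function(mesh, k = 5L, iter = 40L) {
  n <- nrow(mesh$vertices)
  k <- min(as.integer(k), 5L)
  M <- mesh$areas
  delta <- 1e-8 * 2 / mesh$R^2
  Kreg <- mesh$stiffness + delta * Matrix::Diagonal(n, M)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kreg))
  const <- rep(1, n)
  mtot <- sum(M)
  # deterministic start spanning the first spherical harmonics
  vx <- mesh$vertices
  X <- cbind(vx[, 1], vx[, 2], vx[, 3], vx[, 1] * vx[, 2],
             vx[, 1]^2 - vx[, 2]^2)[, seq_len(k), drop = FALSE]
  for (it in seq_len(iter)) {
    X <- as.matrix(Matrix::solve(ch, X * M))
    # deflate the constant mode in the M inner product
    X <- X - outer(const, colSums(X * M) / mtot)
    qr_ <- qr(X * sqrt(M))
    X <- qr.Q(qr_) / sqrt(M)
  }
  A_r <- crossprod(X, as.matrix(mesh$stiffness %*% X))
  M_r <- crossprod(X * sqrt(M), X * sqrt(M))
  ev <- eigen(solve(M_r, A_r), only.values = TRUE)$values
  min(Re(ev))
}
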