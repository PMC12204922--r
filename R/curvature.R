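#' Discrete mean curvature of a triangulated surface
#'
#' Signed mean curvature (1/mm) at every vertex via the cotangent-Laplacian
#' estimator: the mean-curvature normal at vertex i is
#' K_i = (1 / 2A_i) * sum_j (cot a_ij + cot b_ij) (x_i - x_j), where the sum
#' runs over the one-ring edges, a/b are the angles opposite edge ij and A_i
#' is the one-third barycentric vertex area. H_i = |K_i| / 2, signed positive
#' where the surface bulges along the outward vertex normal (convex), so a
#' sphere of radius r has H = 1/r everywhere and an aneurysm sac reads
#' positive on its dome. Boundary vertices of open meshes inherit the value
#' of their nearest interior vertex; degenerate (zero-area) triangles are
#' dropped from the stencil with a warning.
#'
#' @param mesh an `mv_mesh` with at least 4 vertices, outward-oriented faces.
#' @return an [scalar_field()] named `"curvature"` (units 1/mm) with
#'   estimator metadata in attribute `"estimator"`.
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  if (nv < 4L) stop("mean curvature needs a mesh with >= 4 vertices")
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  cr <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  area2 <- sqrt(rowSums(cr^2))            # twice the triangle area
  ok <- area2 > 1e-14
  if (!all(ok)) {
    warning(sum(!ok), " degenerate (zero-area) triangle(s) excluded from the",
            " curvature stencil")
  }
  # cotangents of the three corner angles: cot = dot / |cross|
  cot1 <- rowSums(e12 * e13) / area2       # angle at vertex 1 (opposite e23)
  cot2 <- rowSums(-e12 * e23) / area2      # angle at vertex 2 (opposite e13)
  cot3 <- rowSums(e23 * e13) / area2       # angle at vertex 3 (opposite e12)
  cot1[!ok] <- 0; cot2[!ok] <- 0; cot3[!ok] <- 0
  # Vectorized accumulation: for each face, the angle at a corner weights the
  # OPPOSITE edge. Edge (2,3) gets cot1, edge (1,3) gets cot2, edge (1,2) cot3.
  ii <- c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 3], f[, 1], f[, 2], f[, 1])
  ww <- c(cot1, cot1, cot2, cot2, cot3, cot3)
  dd <- v[ii, , drop = FALSE] - v[jj, , drop = FALSE]
  K <- rowsum(ww * dd, ii, reorder = FALSE)
  Kfull <- matrix(0, nv, 3L)
  Kfull[as.integer(rownames(K)), ] <- K
  # Meyer mixed vertex areas: Voronoi weights on non-obtuse triangles,
  # area/2 at the obtuse corner and area/4 elsewhere otherwise
  l23 <- rowSums(e23^2); l13 <- rowSums(e13^2); l12 <- rowSums(e12^2)
  tarea <- area2 / 2
  a1 <- (l12 * cot3 + l13 * cot2) / 8
  a2 <- (l12 * cot3 + l23 * cot1) / 8
  a3 <- (l13 * cot2 + l23 * cot1) / 8
  obtuse <- cot1 < 0 | cot2 < 0 | cot3 < 0
  a1[obtuse] <- ifelse(cot1[obtuse] < 0, tarea[obtuse] / 2, tarea[obtuse] / 4)
  a2[obtuse] <- ifelse(cot2[obtuse] < 0, tarea[obtuse] / 2, tarea[obtuse] / 4)
  a3[obtuse] <- ifelse(cot3[obtuse] < 0, tarea[obtuse] / 2, tarea[obtuse] / 4)
  A <- rowsum(c(a1[ok], a2[ok], a3[ok]),
              c(f[ok, 1], f[ok, 2], f[ok, 3]), reorder = FALSE)
  Afull <- rep(1e-300, nv)
  Afull[as.integer(rownames(A))] <- A
  Kn <- Kfull / (2 * Afull)
  # outward vertex normals: area-weighted face normals
  Nv <- rowsum(rbind(cr[ok, , drop = FALSE], cr[ok, , drop = FALSE],
                     cr[ok, , drop = FALSE]),
               c(f[ok, 1], f[ok, 2], f[ok, 3]), reorder = FALSE)
  Nfull <- matrix(0, nv, 3L)
  Nfull[as.integer(rownames(Nv)), ] <- Nv
  sgn <- ifelse(rowSums(Kn * Nfull) >= 0, 1, -1)
  H <- sgn * sqrt(rowSums(Kn^2)) / 2
  # boundary vertices: nearest interior value (cot weights are wrong there)
  bnd <- boundary_vertices(f)
  interior <- setdiff(seq_len(nv), bnd)
  if (length(bnd) && length(interior)) {
    for (b in bnd) {
      d2 <- rowSums((v[interior, , drop = FALSE] -
                       matrix(v[b, ], length(interior), 3L, byrow = TRUE))^2)
      H[b] <- H[interior[which.min(d2)]]
    }
  }
  out <- scalar_field("curvature", H, units = "1/mm")
  attr(out, "estimator") <- "cotangent-laplacian"
  out
}

# Vertices on edges referenced by exactly one face.
boundary_vertices <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_e <- names(cnt)[cnt == 1L]
  if (!length(open_e)) return(integer(0))
  unique(as.integer(unlist(strsplit(open_e, " "))))
}

#' Clip a vector to inner percentiles
#'
#' Discrete curvature estimators spike on sliver triangles; clipping to the
#' central percentile band keeps the colormap range informative.
#'
#' @param x numeric vector.
#' @param lower,upper percentile bounds in `[0, 1]`.
#' @export
clip_percentiles <- function(x, lower = 0.01, upper = 0.99) {
  q <- stats::quantile(x, c(lower, upper), names = FALSE)
  pmin(pmax(x, q[1]), q[2])
}
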