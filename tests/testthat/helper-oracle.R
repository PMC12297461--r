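# Independent brute-force oracle for restricted Voronoi cells.
#
# A cell is the intersection of half-spaces (the 12 bounding-dodecahedron
# planes plus the bisector to every other seed). The oracle enumerates the
# polytope's vertices as the feasible intersections of all plane triples
# (Cramer solves), groups vertices by supporting plane, and measures volume,
# centroid, face areas and face-sharing neighbours by polygon fans. It
# shares no code path with the package's sequential clipping.

oracle_dodeca_planes <- function(edge_length) {
  phi <- (1 + sqrt(5)) / 2
  s <- edge_length * phi / 2
  cyc <- function(a, b) {
    g <- as.matrix(expand.grid(a, b))
    rbind(cbind(0, g[, 1], g[, 2]), cbind(g[, 1], g[, 2], 0),
          cbind(g[, 2], 0, g[, 1]))
  }
  nrm <- cyc(c(-phi, phi), c(-1, 1))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # inradius of a regular dodecahedron with the given edge length
  inradius <- edge_length / 2 * sqrt((25 + 11 * sqrt(5)) / 10)
  list(normals = nrm, offsets = rep(inradius, 12))
}

oracle_cell <- function(points, i, edge_length = 100, tol = 1e-7) {
  p <- points[i, ]
  dod <- oracle_dodeca_planes(edge_length)
  rel <- sweep(points[-i, , drop = FALSE], 2, p)
  d <- sqrt(rowSums(rel^2))
  normals <- rbind(dod$normals, rel / d)
  offsets <- c(dod$offsets, d / 2)
  owner <- c(rep(NA_integer_, 12), seq_len(nrow(points))[-i])
  m <- nrow(normals)

  verts <- matrix(0, 0, 3)
  vplanes <- list()
  for (a in 1:(m - 2)) for (b in (a + 1):(m - 1)) for (cc in (b + 1):m) {
    A <- normals[c(a, b, cc), ]
    det <- abs(det(A))
    if (det < 1e-10) next
    v <- tryCatch(solve(A, offsets[c(a, b, cc)]), error = function(e) NULL)
    if (is.null(v)) next
    if (all(normals %*% v - offsets <= tol)) {
      verts <- rbind(verts, v)
      vplanes[[nrow(verts)]] <- c(a, b, cc)
    }
  }
  if (nrow(verts) == 0) stop("oracle: empty cell")
  key <- apply(round(verts / 1e-6), 1, paste, collapse = ",")
  keep <- !duplicated(key)
  verts <- verts[keep, , drop = FALSE]

  vol <- 0
  cen <- c(0, 0, 0)
  neighbours <- integer(0)
  inner <- colMeans(verts)
  for (f in seq_len(m)) {
    on_f <- which(abs(verts %*% normals[f, ] - offsets[f]) <= 10 * tol)
    if (length(on_f) < 3) next
    fv <- verts[on_f, , drop = FALSE]
    ctr <- colMeans(fv)
    e1 <- fv[1, ] - ctr; e1 <- e1 / sqrt(sum(e1^2))
    nf <- normals[f, ]
    e2 <- c(nf[2] * e1[3] - nf[3] * e1[2], nf[3] * e1[1] - nf[1] * e1[3],
            nf[1] * e1[2] - nf[2] * e1[1])
    relv <- sweep(fv, 2, ctr)
    ord <- order(atan2(relv %*% e2, relv %*% e1))
    fv <- fv[ord, , drop = FALSE]
    # polygon area (Newell)
    nw <- c(0, 0, 0)
    nfv <- nrow(fv)
    for (k in seq_len(nfv)) {
      aa <- fv[k, ]; bb <- fv[k %% nfv + 1, ]
      nw <- nw + c((aa[2] - bb[2]) * (aa[3] + bb[3]),
                   (aa[3] - bb[3]) * (aa[1] + bb[1]),
                   (aa[1] - bb[1]) * (aa[2] + bb[2]))
    }
    area <- 0.5 * sqrt(sum(nw^2))
    if (area < 1e-9) next
    if (!is.na(owner[f])) neighbours <- c(neighbours, owner[f])
    # fan of tetrahedra from the polytope's inner point
    for (k in 2:(nfv - 1)) {
      va <- fv[1, ] - inner; vb <- fv[k, ] - inner; vc <- fv[k + 1, ] - inner
      sv <- det(rbind(va, vb, vc)) / 6
      if (sum((nw) * nf) < 0) sv <- -sv
      sv <- abs(sv)
      vol <- vol + sv
      cen <- cen + sv * (inner + (va + vb + vc) / 4)
    }
  }
  cen <- cen / vol
  list(volume = vol, centroid = cen + p, neighbours = sort(unique(neighbours)))
}
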