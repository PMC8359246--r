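# Statistical shape modeling of subchondral bone: iso-surface extraction from
# segmentation masks, spectral mesh correspondence (Laplacian eigenmodes with
# sign/order matching), generalized Procrustes alignment, PCA shape modes with
# per-mode covariate-adjusted group tests, and +/- k SD mode visualization.

#' Construct a triangle mesh
#' @param vertices V x 3 matrix of mm coordinates
#' @param faces F x 3 integer matrix of 1-based vertex indices
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, faces) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  structure(list(vertices = unname(as.matrix(vertices)),
                 faces = unname(as.matrix(faces))),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract the bone surface from a binary mask (marching tetrahedra)
#'
#' The mask is optionally smoothed (sub-voxel anti-aliasing of the binary
#' boundary) and the 0.5 iso-surface is extracted by a marching-tetrahedra
#' decomposition, which produces a watertight, consistently oriented triangle
#' mesh in physical mm coordinates. If the mask has several connected
#' components the largest is taken with a warning.
#'
#' @param mask binary volume (array with spacing)
#' @param spacing voxel spacing (mm)
#' @param smooth_sigma_mm Gaussian pre-smoothing (0 to disable)
#' @return a `surface_mesh`
#' @export
extract_surface <- function(mask, spacing = attr(mask, "spacing"),
                            smooth_sigma_mm = 1) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  m <- array(as.numeric(mask) > 0.5, dim(mask))
  if (!any(m)) stop("empty mask")
  cc <- array(connected_components_cpp(m, dim(m)), dim(m))
  ncc <- max(cc)
  if (ncc > 1) {
    warning(sprintf("mask has %d connected components; taking the largest", ncc))
    counts <- tabulate(cc[cc > 0], ncc)
    m <- cc == which.max(counts)
  }
  f <- array(as.numeric(m), dim(m))
  if (smooth_sigma_mm > 0)
    f <- array(gauss_smooth_cpp(f, dim(f), smooth_sigma_mm / spacing), dim(f))
  # guard: smoothing must not erase the object
  if (max(f) <= 0.5) f <- array(as.numeric(m), dim(m))
  res <- marching_tetrahedra_cpp(f, dim(f), spacing, 0.5)
  surface_mesh(res$vertices, res$faces)
}

#' Mesh diagnostics: watertightness, Euler characteristic, enclosed volume
#'
#' @param mesh a `surface_mesh`
#' @return list with `watertight` (every edge shared by exactly 2 faces),
#'   `euler` (V - E + F), `volume_mm3` (signed, positive for outward
#'   orientation), `n_degenerate_faces`
#' @export
mesh_diagnostics <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  e <- rbind(Fc[, c(1, 2)], Fc[, c(2, 3)], Fc[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ekey)
  v1 <- V[Fc[, 1], , drop = FALSE]
  v2 <- V[Fc[, 2], , drop = FALSE]
  v3 <- V[Fc[, 3], , drop = FALSE]
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  cr <- cross(v2 - v1, v3 - v1)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  vol <- sum((v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
              v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
              v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3]))) / 6
  list(watertight = all(tab == 2),
       euler = nrow(V) - length(tab) + nrow(Fc),
       volume_mm3 = vol,
       n_degenerate_faces = sum(areas < 1e-12))
}

#' Decimate a mesh by grid vertex clustering
#'
#' Vertices falling in the same spatial cell are merged at their centroid;
#' faces collapsing onto fewer than 3 distinct clusters are dropped. Used to
#' bring meshes to a tractable size before eigen-decomposition.
#'
#' @param mesh a `surface_mesh`
#' @param target_vertices approximate vertex budget
#' @return a decimated `surface_mesh`
#' @export
decimate_mesh <- function(mesh, target_vertices = 2000) {
  V <- mesh$vertices
  if (nrow(V) <= target_vertices) return(mesh)
  bb <- apply(V, 2, range)
  ext <- pmax(bb[2, ] - bb[1, ], 1e-9)
  # surface scaling: number of occupied cells grows ~ (1/h)^2
  h <- sqrt(2.2 * prod(ext)^(2 / 3) / target_vertices)
  repeat {
    cell <- floor(sweep(V, 2, bb[1, ]) / h)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    uk <- unique(key)
    if (length(uk) <= 1.3 * target_vertices || h < 1e-6) break
    h <- h * 1.15
  }
  idx <- match(key, uk)
  newV <- matrix(0, length(uk), 3)
  for (c in 1:3) newV[, c] <- tapply(V[, c], idx, mean)
  newF <- matrix(idx[mesh$faces], ncol = 3)
  keep <- newF[, 1] != newF[, 2] & newF[, 2] != newF[, 3] &
    newF[, 1] != newF[, 3]
  newF <- newF[keep, , drop = FALSE]
  used <- sort(unique(as.integer(newF)))
  remap <- match(seq_len(nrow(newV)), used)
  surface_mesh(newV[used, , drop = FALSE],
               matrix(remap[newF], ncol = 3))
}

# symmetric-normalized graph Laplacian with cotangent weights (combinatorial
# fallback on degenerate triangles)
mesh_laplacian <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  n <- nrow(V)
  W <- matrix(0, n, n)
  cot3 <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- V[b, ] - V[a, ]; v <- V[c, ] - V[a, ]
    num <- sum(u * v)
    den <- sqrt(max(sum(u * u) * sum(v * v) - num^2, 0))
    if (den < 1e-12) return(NA_real_)
    num / den
  }
  for (f in seq_len(nrow(Fc))) {
    a <- Fc[f, 1]; b <- Fc[f, 2]; c <- Fc[f, 3]
    wab <- cot3(c, a, b); wbc <- cot3(a, b, c); wca <- cot3(b, c, a)
    if (is.na(wab) || is.na(wbc) || is.na(wca)) { wab <- wbc <- wca <- 1 }
    W[a, b] <- W[a, b] + wab / 2; W[b, a] <- W[a, b]
    W[b, c] <- W[b, c] + wbc / 2; W[c, b] <- W[b, c]
    W[c, a] <- W[c, a] + wca / 2; W[a, c] <- W[c, a]
  }
  W[W < 0] <- 0  # clamp negative cotangent weights for a proper graph
  dg <- rowSums(W)
  dg[dg < 1e-12] <- 1e-12
  Dm <- 1 / sqrt(dg)
  L <- -W * outer(Dm, Dm)
  diag(L) <- 1
  L
}

spectral_embedding <- function(mesh, k, buffer = 4) {
  L <- mesh_laplacian(mesh)
  eg <- eigen(L, symmetric = TRUE)
  n <- nrow(L)
  ord <- n:1  # ascending eigenvalues
  kk <- min(k + buffer, n - 2)
  vals <- eg$values[ord][2:(kk + 1)]   # drop the trivial constant mode
  vecs <- eg$vectors[, ord, drop = FALSE][, 2:(kk + 1), drop = FALSE]
  list(values = vals, vectors = vecs)
}

# choose an embedding dimension that does not cut an eigenvalue multiplet:
# near-equal eigenvalues (symmetric shapes) must be kept or dropped together,
# otherwise the two meshes' embeddings span different subspaces
gap_adjusted_k <- function(vals_t, vals_s, k, rel_tol = 0.05) {
  kk <- min(length(vals_t), length(vals_s))
  ok <- function(vals, j) {
    if (j >= length(vals)) return(TRUE)
    (vals[j + 1] - vals[j]) > rel_tol * max(vals[j], 1e-12)
  }
  for (j in seq(min(k, kk), 2)) if (ok(vals_t, j) && ok(vals_s, j)) return(j)
  min(k, kk)
}

# sign/order alignment of target eigenvectors to the template's by matching
# quantile profiles of the eigenvector value distributions (feature matching)
match_spectra <- function(Et, Es) {
  k <- ncol(Et)
  qs <- seq(0, 1, length.out = 101)
  prof <- function(v) quantile(v, qs, names = FALSE)
  Pt <- apply(Et, 2, prof)
  Ps <- apply(Es, 2, prof)
  corr <- matrix(0, k, k); sgn <- matrix(1, k, k)
  for (i in 1:k) for (j in 1:k) {
    cp <- suppressWarnings(cor(Pt[, i], Ps[, j]))
    cm <- suppressWarnings(cor(Pt[, i], -rev(Ps[, j])))
    cp <- ifelse(is.na(cp), 0, cp); cm <- ifelse(is.na(cm), 0, cm)
    if (cm > cp) { corr[i, j] <- cm; sgn[i, j] <- -1 } else corr[i, j] <- cp
  }
  # greedy assignment maximizing total profile correlation
  perm <- integer(k); sign_out <- numeric(k)
  used <- rep(FALSE, k)
  for (step in order(-apply(corr, 1, max))) {
    j <- which.max(ifelse(used, -Inf, corr[step, ]))
    perm[step] <- j; sign_out[step] <- sgn[step, j]; used[j] <- TRUE
  }
  list(perm = perm, sign = sign_out)
}

#' Spectral correspondence between two meshes
#'
#' Vertices are embedded by the first `k` nontrivial eigenvectors of the mesh
#' graph Laplacian (cotangent weights, combinatorial fallback on degenerate
#' triangles). Per-eigenvector sign and ordering ambiguities between the two
#' meshes are resolved by feature matching of the eigenvector value profiles;
#' the aligned embeddings are then iteratively refined with an orthogonal
#' alignment (spectral ICP), matched by nearest neighbour, and optionally
#' refined by a final nearest-point pass in spatial coordinates after a
#' Procrustes pose estimate from the spectral matches.
#'
#' @param template,target `surface_mesh` objects
#' @param k number of nontrivial eigenmodes (>= 3)
#' @param icp_iters spectral ICP refinement iterations
#' @param refine_spatial run the final spatial nearest-point pass
#' @return object of class `mesh_correspondence`: integer vector `index`
#'   (target vertex for each template vertex) plus the matched target points
#'   `points`
#' @export
spectral_correspondence <- function(template, target, k = 6, icp_iters = 8,
                                    n_restarts = 8, refine_spatial = TRUE) {
  stopifnot(k >= 3)
  k <- min(k, nrow(template$vertices) - 2, nrow(target$vertices) - 2)
  emb_t <- spectral_embedding(template, k)
  emb_s <- spectral_embedding(target, k)
  k <- gap_adjusted_k(emb_t$values, emb_s$values, k)
  scale_emb <- function(e) {
    E <- sweep(e$vectors[, 1:k, drop = FALSE], 2,
               sqrt(pmax(e$values[1:k], 1e-12)), "/")
    E / sqrt(mean(E^2))
  }
  Et <- scale_emb(emb_t); Es <- scale_emb(emb_s)
  m <- match_spectra(Et, Es)
  Qh <- matrix(0, k, k)
  for (i in 1:k) Qh[m$perm[i], i] <- m$sign[i]
  # spectral ICP from several deterministic starts: eigenvector sign (and,
  # for near-symmetric shapes, orthogonal mixing) is not identifiable from
  # value profiles alone, so candidate alignments are scored by the mean
  # nearest-neighbour residual in the aligned embeddings
  rand_orth <- function(seed) {
    g <- matrix(sin(seed * 1000 + seq_len(k * k) * 2.399), k, k)
    qr.Q(qr(g))
  }
  # candidate score: spatial residual of the matches under the best proper
  # rigid motion; an eigenvector flip corresponds to a spatial reflection,
  # which no proper rotation can absorb, so wrong flips score badly
  spatial_cost <- function(idx) {
    A <- target$vertices[idx, , drop = FALSE]
    B <- template$vertices
    ca <- colMeans(A); cb <- colMeans(B)
    s <- svd(crossprod(sweep(A, 2, ca), sweep(B, 2, cb)))
    R <- s$v %*% t(s$u)
    if (det(R) < 0) { s$v[, 3] <- -s$v[, 3]; R <- s$v %*% t(s$u) }
    Aal <- sweep(sweep(A, 2, ca) %*% t(R), 2, cb, "+")
    mean(sqrt(rowSums((Aal - B)^2)))
  }
  run_icp <- function(Q, iters) {
    idx <- nn_index_cpp(Et %*% Q, Es)
    for (it in seq_len(iters)) {
      s <- svd(crossprod(Et, Es[idx, , drop = FALSE]))
      Q <- s$u %*% t(s$v)
      idx_new <- nn_index_cpp(Et %*% Q, Es)
      if (all(idx_new == idx)) break
      idx <- idx_new
    }
    list(idx = idx, Q = Q, cost = spatial_cost(idx))
  }
  # candidates: profile-matched start; identity ordering (eigenvalue ranks of
  # similar shapes agree) under all sign flips; random orthogonal restarts
  cands <- list(Qh)
  nsign <- min(k, 6)
  for (s in 0:(2^nsign - 1)) {
    sg <- 1 - 2 * as.integer(intToBits(s)[1:k])
    sg[is.na(sg)] <- 1
    cands[[length(cands) + 1L]] <- diag(sg, k)
  }
  for (r in seq_len(n_restarts)) cands[[length(cands) + 1L]] <- rand_orth(r)
  best <- NULL
  for (Q in cands) {
    cand <- run_icp(Q, 3)
    if (is.null(best) || cand$cost < best$cost) best <- cand
  }
  best <- run_icp(best$Q, icp_iters)
  idx <- best$idx
  pts <- target$vertices[idx, , drop = FALSE]
  if (refine_spatial) {
    # nearest-point passes in spatial coordinates: estimate the rigid pose of
    # the target implied by the current matches, re-match by nearest vertex,
    # and project onto the target surface (removes tessellation quantization)
    for (pass in 1:3) {
      A <- pts
      B <- template$vertices
      ca <- colMeans(A); cb <- colMeans(B)
      s <- svd(crossprod(sweep(A, 2, ca), sweep(B, 2, cb)))
      R <- s$v %*% t(s$u)
      if (det(R) < 0) { s$v[, 3] <- -s$v[, 3]; R <- s$v %*% t(s$u) }
      tgt_al <- sweep(sweep(target$vertices, 2, ca) %*% t(R), 2, cb, "+")
      idx <- nn_index_cpp(template$vertices, tgt_al)
      proj <- project_to_surface(template$vertices, idx, tgt_al, target$faces)
      # back to the target's native coordinates: inverse of y = R (x-ca) + cb
      pts <- sweep(sweep(proj, 2, cb) %*% R, 2, ca, "+")
    }
  }
  structure(list(index = as.integer(idx), points = pts),
            class = "mesh_correspondence")
}

# closest point on the one-ring triangles of the matched vertex
project_to_surface <- function(query, idx, verts, faces) {
  n <- nrow(verts)
  incident <- vector("list", n)
  for (f in seq_len(nrow(faces)))
    for (v in faces[f, ]) incident[[v]] <- c(incident[[v]], f)
  out <- matrix(0, nrow(query), 3)
  for (q in seq_len(nrow(query))) {
    p <- query[q, ]
    best <- verts[idx[q], ]; bd <- sum((p - best)^2)
    for (f in incident[[idx[q]]]) {
      tri <- verts[faces[f, ], , drop = FALSE]
      cp <- closest_point_triangle(p, tri[1, ], tri[2, ], tri[3, ])
      d <- sum((p - cp)^2)
      if (d < bd) { bd <- d; best <- cp }
    }
    out[q, ] <- best
  }
  out
}

closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Generalized Procrustes alignment of corresponded point sets
#'
#' Rotation and translation only by default; scaling is off so that size
#' differences remain shape modes. Reflections are corrected to proper
#' rotations.
#'
#' @param point_sets list of V x 3 matrices with equal vertex counts
#' @param scaling align scale as well (default FALSE)
#' @param max_iter,tol convergence controls
#' @return list of aligned V x 3 matrices
#' @export
align_pointsets <- function(point_sets, scaling = FALSE, max_iter = 50,
                            tol = 1e-10) {
  nv <- vapply(point_sets, nrow, 0L)
  if (length(unique(nv)) != 1) stop("point sets must have equal vertex counts")
  centred <- lapply(point_sets, function(P) sweep(P, 2, colMeans(P)))
  ref <- centred[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(centred, function(P) {
      s <- svd(crossprod(P, ref))
      R <- s$u %*% t(s$v)
      if (det(R) < 0) { s$u[, 3] <- -s$u[, 3]; R <- s$u %*% t(s$v) }
      Pa <- P %*% R
      if (scaling) Pa <- Pa * sum(diag(crossprod(Pa, ref))) / sum(Pa^2)
      Pa
    })
    newref <- Reduce(`+`, aligned) / length(aligned)
    if (sqrt(mean((newref - ref)^2)) < tol) { ref <- newref; break }
    ref <- newref
    centred <- aligned
  }
  lapply(centred, function(P) {
    s <- svd(crossprod(P, ref))
    R <- s$u %*% t(s$v)
    if (det(R) < 0) { s$u[, 3] <- -s$u[, 3]; R <- s$u %*% t(s$v) }
    Pa <- P %*% R
    if (scaling) Pa <- Pa * sum(diag(crossprod(Pa, ref))) / sum(Pa^2)
    Pa
  })
}

#' Build a PCA shape model from corresponded, aligned point sets
#'
#' PCA of the stacked per-subject vertex-coordinate vectors (length 3V).
#' Modes are orthonormal displacement fields sorted by descending variance;
#' per-subject scores have zero mean per mode and reconstruction with all
#' modes is exact.
#'
#' @param point_sets list of V x 3 matrices in correspondence and alignment
#' @param n_modes modes to retain (clipped to subjects - 1 with a warning)
#' @return object of class `shape_model`: `mean_vertices` (V x 3), `modes`
#'   (3V x m, orthonormal), `variances` (mm^2), `scores` (n x m),
#'   `cum_var_fraction`, `n_modes`
#' @export
build_shape_model <- function(point_sets, n_modes = 10) {
  n <- length(point_sets)
  stopifnot(n >= 3)
  X <- t(vapply(point_sets, function(P) as.numeric(P),
                numeric(length(point_sets[[1]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n, nv = min(n, ncol(Xc)))
  pos <- sv$d > max(sv$d) * 1e-12
  total_var <- sum(sv$d^2) / (n - 1)
  maxm <- min(n - 1, sum(pos))
  if (n_modes > maxm) {
    warning(sprintf("n_modes clipped from %d to %d (subjects - 1)",
                    n_modes, maxm))
    n_modes <- as.integer(maxm)
  }
  if (n_modes == 0) {
    modes <- matrix(0, ncol(X), 0); vars <- numeric(0)
    scores <- matrix(0, n, 0)
  } else {
    modes <- sv$v[, seq_len(n_modes), drop = FALSE]
    vars <- (sv$d[seq_len(n_modes)]^2) / (n - 1)
    scores <- Xc %*% modes
  }
  V <- nrow(point_sets[[1]])
  structure(list(mean_vertices = matrix(mu, V, 3), modes = modes,
                 variances = vars, scores = scores,
                 total_variance = total_var,
                 cum_var_fraction = if (total_var > 0)
                   cumsum(vars) / total_var else rep(0, n_modes),
                 n_modes = n_modes, n_subjects = n),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d subjects, %d vertices, %d modes (%.1f%% var)\n",
              x$n_subjects, nrow(x$mean_vertices), x$n_modes,
              100 * if (length(x$cum_var_fraction))
                x$cum_var_fraction[x$n_modes] else 0))
  invisible(x)
}

#' Reconstruct a subject from the shape model
#' @param model a `shape_model`
#' @param scores length-m score vector
#' @return V x 3 vertex matrix
#' @export
reconstruct_shape <- function(model, scores) {
  v <- as.numeric(model$mean_vertices) + model$modes %*% scores
  matrix(v, ncol = 3)
}

#' Per-mode covariate-adjusted group tests of shape scores
#'
#' Runs the compartmental ANCOVA on each retained mode's scores. Shaft-related
#' modes supplied via `exclude_modes` are dropped from the table (they are
#' never auto-dropped by the flagging helper).
#'
#' @param model a `shape_model`
#' @param meta subject table aligned with the model's score rows
#' @param exclude_modes integer modes to disregard
#' @param covariates adjustment factors
#' @return data.frame mode, variance_pct, F, p
#' @export
mode_group_test <- function(model, meta, exclude_modes = integer(0),
                            covariates = c("gender", "bmi", "site")) {
  stopifnot(nrow(meta) == nrow(model$scores))
  keep <- setdiff(seq_len(model$n_modes), exclude_modes)
  out <- lapply(keep, function(m) {
    r <- ancova_group_effect(model$scores[, m], meta, covariates)
    data.frame(mode = m,
               variance_pct = 100 * model$variances[m] /
                 max(model$total_variance, 1e-300),
               F = r$statistic, p = r$p_value)
  })
  if (!length(out))
    return(data.frame(mode = integer(0), variance_pct = numeric(0),
                      F = numeric(0), p = numeric(0)))
  do.call(rbind, out)
}

#' Flag modes whose displacement energy concentrates in the bone shaft
#'
#' Modes with more than `energy_threshold` of their squared displacement in
#' the superior/inferior `z_fraction` of the mesh are flagged (to be reviewed
#' and, if confirmed, passed to `exclude_modes`); nothing is dropped
#' automatically.
#'
#' @param model a `shape_model`
#' @param z_fraction fraction of the z-extent regarded as shaft at each end
#' @param energy_threshold flagging threshold on the shaft energy fraction
#' @return integer vector of flagged modes
#' @export
flag_shaft_modes <- function(model, z_fraction = 0.2, energy_threshold = 0.5) {
  z <- model$mean_vertices[, 3]
  zr <- range(z)
  shaft <- z < zr[1] + z_fraction * diff(zr) | z > zr[2] - z_fraction * diff(zr)
  V <- nrow(model$mean_vertices)
  flagged <- integer(0)
  for (m in seq_len(model$n_modes)) {
    disp <- matrix(model$modes[, m], V, 3)
    energy <- rowSums(disp^2)
    if (sum(energy[shaft]) / max(sum(energy), 1e-300) > energy_threshold)
      flagged <- c(flagged, m)
  }
  flagged
}

#' Visualize a shape mode at +/- `magnitude` SD
#'
#' @param model a `shape_model`
#' @param mode mode index
#' @param magnitude displacement in SD multiples (default 3)
#' @return list with `mesh_plus`, `mesh_minus` (V x 3 vertex matrices) and
#'   `displacement_norm` (per-vertex Euclidean norm of the +/- displacement,
#'   for color mapping)
#' @export
mode_visualization <- function(model, mode, magnitude = 3) {
  stopifnot(mode >= 1, mode <= model$n_modes)
  V <- nrow(model$mean_vertices)
  disp <- matrix(model$modes[, mode], V, 3) *
    magnitude * sqrt(model$variances[mode])
  list(mesh_plus = model$mean_vertices + disp,
       mesh_minus = model$mean_vertices - disp,
       displacement_norm = sqrt(rowSums(disp^2)))
}

#' Write / read a mesh in OFF format
#' @param mesh a `surface_mesh`
#' @param path output path
#' @return the path (write) or a `surface_mesh` (read)
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  write.table(format(mesh$vertices, digits = 9), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(cbind(3, mesh$faces - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  faces <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:4] + 1L))
  surface_mesh(verts, faces)
}
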