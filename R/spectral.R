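# Spectral surface correspondence: mesh Laplacians, low-frequency spectral
# embeddings, rigid coherent-point-drift initialisation, joint spectral
# matching of a longitudinal surface pair, and post-to-pre field transfer.
#
# The two surfaces of a pair differ in folding, area and volume, but their
# low-frequency Laplacian eigenmodes are similar; embedding both layers of
# a coupled graph (intra-layer mesh Laplacians plus inter-layer links from
# the rigid initialisation) into shared eigenmodes makes nearest-neighbour
# vertex matching meaningful across time points.

#' Mesh Laplacian operator
#'
#' Symmetric positive semi-definite Laplacian `L = D - W` with either
#' cotangent weights (geometry-aware; negative cotangent sums from obtuse
#' or degenerate triangles are clamped to zero, which keeps the operator
#' PSD) or combinatorial (unit) weights, plus the lumped vertex mass
#' (one third of the incident triangle area; unit mass for combinatorial).
#'
#' @param mesh a connected `surface_mesh`.
#' @param kind `"cotangent"` (default) or `"combinatorial"`.
#' @param on_disconnected `"error"` (default) or `"largest"` (use the
#'   largest connected component, with a warning).
#' @return list with sparse `L` (dgCMatrix), numeric `mass`, `kind`, and
#'   `vertex_keep` (indices retained when a component was dropped).
#' @export
mesh_laplacian <- function(mesh, kind = c("cotangent", "combinatorial"),
                           on_disconnected = c("error", "largest")) {
  kind <- match.arg(kind)
  on_disconnected <- match.arg(on_disconnected)
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)$edges
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  keep <- seq_len(n)
  if (comp$no > 1L) {
    if (on_disconnected == "error")
      stop("mesh is disconnected (", comp$no, " components)")
    warning("mesh is disconnected; using largest component")
    keep <- which(comp$membership == which.max(comp$csize))
    fkeep <- rowSums(matrix(mesh$faces %in% keep, ncol = 3L)) == 3L
    remap <- integer(n); remap[keep] <- seq_along(keep)
    mesh <- surface_mesh(mesh$vertices[keep, , drop = FALSE],
                         matrix(remap[mesh$faces[fkeep, ]], ncol = 3L))
    n <- nrow(mesh$vertices)
  }
  f <- mesh$faces
  v <- mesh$vertices
  if (kind == "cotangent") {
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    corners <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
    for (cs in corners) {
      a <- f[, cs[1]]; b <- f[, cs[2]]; cc <- f[, cs[3]]
      u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
      w2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
      dot <- rowSums(u * w2)
      crx <- cbind(u[, 2] * w2[, 3] - u[, 3] * w2[, 2],
                   u[, 3] * w2[, 1] - u[, 1] * w2[, 3],
                   u[, 1] * w2[, 2] - u[, 2] * w2[, 1])
      crn <- sqrt(rowSums(crx^2))
      cot <- dot / pmax(crn, 1e-12)  # cot of the angle at corner a
      ii <- c(ii, b); jj <- c(jj, cc); ww <- c(ww, cot / 2)
    }
    W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                              dims = c(n, n))
    W@x[W@x < 0] <- 0  # clamp: PSD even with obtuse/degenerate triangles
    mass <- vertex_areas(mesh)
    mass[mass <= 0] <- min(mass[mass > 0])
  } else {
    e <- mesh_edges(mesh)$edges
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
    mass <- rep(1, n)
  }
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  list(L = methods::as(L, "CsparseMatrix"), mass = mass, kind = kind,
       vertex_keep = keep)
}

# k smallest eigenpairs of the generalized problem L v = lambda * M v,
# via the symmetric form B = M^-1/2 L M^-1/2 (dense below a size cutoff,
# ARPACK shift-invert above it). Deterministic given inputs and seed.
.eigs_smallest <- function(L, mass, k, seed = 1, dense_cutoff = 1600) {
  n <- nrow(L)
  if (k >= n) stop("k must be smaller than the number of vertices")
  s <- 1 / sqrt(mass)
  B <- Matrix::Diagonal(n, s) %*% L %*% Matrix::Diagonal(n, s)
  B <- Matrix::forceSymmetric(B)
  if (n <= dense_cutoff) {
    eg <- eigen(as.matrix(B), symmetric = TRUE)
    ix <- n:(n - k + 1L)
    vals <- eg$values[ix]
    vecs <- eg$vectors[, ix, drop = FALSE]
  } else {
    sigma <- 1e-6 * mean(Matrix::diag(B))
    ch <- Matrix::Cholesky(B + Matrix::Diagonal(n, sigma), LDL = FALSE)
    fn <- function(x, extra) as.vector(Matrix::solve(ch, x))
    old <- .Random.seed_save()
    set.seed(seed)
    start <- stats::runif(n, -1, 1)
    .Random.seed_restore(old)
    res <- igraph::arpack(fn, sym = TRUE,
                          options = list(n = n, nev = k,
                                         ncv = min(n, max(2L * k + 10L, 40L)),
                                         which = "LM", maxiter = 5000,
                                         start = start))
    vals <- 1 / res$values - sigma
    vecs <- res$vectors
    o <- order(vals)
    vals <- vals[o]; vecs <- vecs[, o, drop = FALSE]
  }
  # back-transform to the generalized eigenvectors, fix norms and signs
  vecs <- vecs * s
  for (j in seq_len(ncol(vecs))) {
    vecs[, j] <- vecs[, j] / sqrt(sum(vecs[, j]^2))
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = pmax(vals, 0) * (abs(vals) > 1e-12) + vals * (abs(vals) <= 1e-12),
       vectors = vecs)
}

#' Spectral embedding of a surface mesh
#'
#' The `k` smallest eigenpairs of the (generalized) mesh Laplacian
#' `L v = lambda M v`. For a connected mesh the first eigenvalue is zero
#' with a constant mode; the following low-frequency modes partition the
#' surface into progressively finer sign regions.
#'
#' @param mesh a connected `surface_mesh`.
#' @param k number of modes.
#' @param kind Laplacian kind, see [mesh_laplacian()].
#' @param seed seed for the iterative eigensolver start vector.
#' @return a `spectral_embedding`: list with `values` (ascending,
#'   non-negative), `vectors` (N x k, unit norm, deterministic sign),
#'   `laplacian_kind`, `k`.
#' @export
spectral_embedding <- function(mesh, k = 30, kind = "cotangent", seed = 1) {
  lap <- mesh_laplacian(mesh, kind)
  eg <- .eigs_smallest(lap$L, lap$mass, k, seed = seed)
  structure(list(values = eg$values, vectors = eg$vectors,
                 laplacian_kind = lap$kind, k = k),
            class = "spectral_embedding")
}

#' @export
print.spectral_embedding <- function(x, ...) {
  cat(sprintf("spectral_embedding: %d modes (%s Laplacian)\n  eigenvalues: %s%s\n",
              x$k, x$laplacian_kind,
              paste(signif(utils::head(x$values, 6), 4), collapse = ", "),
              if (x$k > 6) ", ..." else ""))
  invisible(x)
}

# ---------------------------------------------------------------- CPD -----

#' Rigid coherent point drift registration
#'
#' EM fitting of a Gaussian-mixture point-set model: the moving (source)
#' points are GMM centroids with isotropic variance `sigma2` plus a uniform
#' outlier component of weight `w`; each M step re-estimates the rigid
#' transform (rotation `R`, translation `t`, optional scale `s`) in closed
#' form from the soft assignments. Converges when the `sigma2` update
#' stalls or `max_iter` is reached.
#'
#' @param source M x 3 moving points.
#' @param target N x 3 fixed points.
#' @param w uniform outlier weight in [0, 1).
#' @param scale estimate a global scale factor (default FALSE: strictly
#'   rigid).
#' @param tol relative `sigma2` convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param max_points subsample cap applied to both clouds (deterministic
#'   given `seed`); the returned transform is still defined on full clouds.
#' @param seed subsampling seed.
#' @return list with `R`, `t`, `s`, `sigma2`, `iterations`, `converged`;
#'   apply as `s * R %*% y + t` (see [apply_rigid()]).
#' @export
cpd_rigid <- function(source, target, w = 0.1, scale = FALSE, tol = 1e-6,
                      max_iter = 150, max_points = 3000, multistart = TRUE,
                      seed = 1) {
  Y0 <- as.matrix(source); X0 <- as.matrix(target)
  if (nrow(Y0) < 4 || nrow(X0) < 4)
    stop("CPD needs at least 4 points in each cloud")
  sub <- function(P, cap) {
    if (nrow(P) <= cap) return(P)
    old <- .Random.seed_save()
    set.seed(seed)
    idx <- sample.int(nrow(P), cap)
    .Random.seed_restore(old)
    P[idx, , drop = FALSE]
  }
  Y <- sub(Y0, max_points); X <- sub(X0, max_points)
  if (qr(sweep(X, 2, colMeans(X)))$rank < 3 ||
      qr(sweep(Y, 2, colMeans(Y)))$rank < 3)
    stop("degenerate (coplanar/collinear) geometry: rigid CPD is ill-posed")
  R0 <- diag(3)
  if (multistart) {
    # the EM landscape is multimodal for near-symmetric shapes; score a
    # deterministic set of initial rotations (identity, principal-axes
    # alignments, octahedral group) with a few coarse EM steps
    Yc <- sub(Y0, 400L); Xc <- sub(X0, 400L)
    pax <- function(P) {
      ev <- eigen(stats::cov(P), symmetric = TRUE)$vectors
      if (det(ev) < 0) ev[, 3] <- -ev[, 3]
      ev
    }
    Ux <- pax(Xc); Uy <- pax(Yc)
    cands <- list(diag(3))
    for (sx in c(1, -1)) for (sy in c(1, -1)) {
      S <- diag(c(sx, sy, sx * sy))  # proper sign flips of matched axes
      cands[[length(cands) + 1L]] <- Ux %*% S %*% t(Uy)
    }
    cands <- c(cands, .octahedral_rotations())
    best <- Inf
    for (Rc in cands) {
      fit <- .cpd_em(Yc, Xc, w = w, scale = scale, tol = tol,
                     max_iter = 12L, R_init = Rc)
      if (fit$sigma2 < best) { best <- fit$sigma2; R0 <- Rc }
    }
  }
  out <- .cpd_em(Y, X, w = w, scale = scale, tol = tol,
                 max_iter = max_iter, R_init = R0)
  out
}

# all 24 proper signed-permutation rotations (octahedral group)
.octahedral_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    R <- matrix(0, 3, 3)
    R[cbind(1:3, p)] <- c(sx, sy, sz)
    if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
  }
  out
}

# core CPD-rigid EM loop on prepared clouds
.cpd_em <- function(Y, X, w, scale, tol, max_iter, R_init = diag(3)) {
  M <- nrow(Y); N <- nrow(X); D <- 3
  R <- R_init; s <- 1
  t <- colMeans(X) - as.vector(R %*% colMeans(Y))
  sigma2 <- (N * sum(Y^2) + M * sum(X^2) -
             2 * sum(colSums(Y) * colSums(X))) / (D * M * N)
  sigma2_0 <- sigma2
  X2 <- rowSums(X^2)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    TY <- sweep(s * (Y %*% t(R)), 2, t, "+")
    d2 <- outer(rowSums(TY^2), X2, "+") - 2 * tcrossprod(TY, X)  # M x N
    P <- exp(-pmax(d2, 0) / (2 * sigma2))
    cden <- (2 * pi * sigma2)^(D / 2) * (w / (1 - w)) * (M / N)
    den <- colSums(P) + cden
    P <- sweep(P, 2, den, "/")
    P1 <- rowSums(P); Pt1 <- colSums(P)
    Np <- sum(P1)
    mu_x <- colSums(X * Pt1) / Np
    mu_y <- colSums(Y * P1) / Np
    Xh <- sweep(X, 2, mu_x); Yh <- sweep(Y, 2, mu_y)
    A <- t(Xh) %*% (t(P) %*% Yh)
    sv <- svd(A)
    C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% C %*% t(sv$v)
    trAR <- sum(diag(C) * sv$d)
    yPy <- sum(P1 * rowSums(Yh^2))
    xPx <- sum(Pt1 * rowSums(Xh^2))
    s <- if (scale) trAR / yPy else 1
    t <- mu_x - s * as.vector(R %*% mu_y)
    sigma2_new <- max((xPx - 2 * s * trAR + s^2 * yPy) / (Np * D), 1e-12)
    if (abs(sigma2 - sigma2_new) < tol * sigma2_0) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  list(R = R, t = as.vector(t), s = s, sigma2 = sigma2,
       iterations = iter, converged = converged)
}

# ------------------------------------------------------- joint matching ---

#' Joint spectral matching of a longitudinal surface pair
#'
#' Builds a dual-layer graph whose layers are the pre and post surfaces
#' (intra-layer cotangent Laplacians) connected by correspondence links
#' from the rigid CPD initialisation (mutual nearest neighbours after
#' alignment, capped at N/10, weighted `gamma` relative to the mean
#' intra-layer weight). The shared eigenmodes of this joint Laplacian embed
#' both layers in one spectral space; each pre vertex is matched to its
#' nearest post vertex there (optionally augmenting the spectral
#' coordinates with CPD-aligned, normalized 3D coordinates).
#'
#' @param pre,post connected `surface_mesh` objects (pre/post surfaces).
#' @param k number of shared (non-constant) eigenmodes.
#' @param method `"aligned"` (default): per-surface embeddings whose modes
#'   are sign/order-aligned by greedy correlation matching through the
#'   initial links; `"joint"`: eigenmodes of the coupled dual-layer graph,
#'   filtered to the link-coherent ones. Both end in the same
#'   nearest-neighbour matching.
#' @param gamma inter-layer link weight relative to the mean intra weight
#'   (`method = "joint"` only).
#' @param spatial_weight relative weight of the CPD-aligned, normalized 3D
#'   coordinates appended to the spectral coordinates (0 = pure spectral
#'   matching; 1 = equal total variance with the spectral block).
#' @param cpd_args list of extra arguments for [cpd_rigid()].
#' @param seed eigensolver/subsampling seed.
#' @return a `correspondence`: `target_vertex[i]` is the post vertex
#'   matched to pre vertex `i` (so post fields are pulled back to the pre
#'   surface), with per-vertex `match_cost`, plus the CPD initialisation
#'   and link set.
#' @export
joint_spectral_match <- function(pre, post, k = 30,
                                 method = c("aligned", "joint"), gamma = 1,
                                 spatial_weight = 1, cpd_args = list(),
                                 seed = 1) {
  method <- match.arg(method)
  n1 <- nrow(pre$vertices); n2 <- nrow(post$vertices)
  cpd <- do.call(cpd_rigid, c(list(source = post$vertices,
                                   target = pre$vertices, seed = seed),
                              cpd_args))
  post_al <- apply_rigid(post$vertices, cpd$R, cpd$t, cpd$s)
  # mutual nearest neighbours after alignment = inter-layer links
  fwd <- nn_index(pre$vertices, post_al)       # pre -> post
  bwd <- nn_index(post_al, pre$vertices)       # post -> pre
  mutual <- which(bwd[fwd] == seq_len(n1))
  links <- cbind(pre = mutual, post = fwd[mutual])
  if (nrow(links) == 0L) stop("empty inter-layer link set after CPD")
  cap <- max(10L, ceiling(max(n1, n2) / 10))
  if (nrow(links) > cap) {
    d <- sqrt(rowSums((pre$vertices[links[, 1], , drop = FALSE] -
                       post_al[links[, 2], , drop = FALSE])^2))
    links <- links[order(d)[seq_len(cap)], , drop = FALSE]
  }
  emb <- if (method == "aligned")
    .jsm_aligned_embedding(pre, post, links, k, seed)
  else
    .jsm_joint_embedding(pre, post, links, k, gamma, seed)
  emb_pre <- emb$pre; emb_post <- emb$post
  if (spatial_weight > 0) {
    # append aligned 3D coordinates, scaled so their total variance is
    # spatial_weight^2 times that of the spectral block
    specvar <- sum(apply(emb_pre, 2, stats::var))
    ctr <- colMeans(pre$vertices)
    sp_pre <- sweep(pre$vertices, 2, ctr)
    sp_post <- sweep(post_al, 2, ctr)
    spvar <- sum(apply(sp_pre, 2, stats::var))
    fac <- spatial_weight * sqrt(specvar / spvar)
    emb_pre <- cbind(emb_pre, fac * sp_pre)
    emb_post <- cbind(emb_post, fac * sp_post)
  }
  target <- nn_index(emb_pre, emb_post)
  cost <- sqrt(rowSums((emb_pre - emb_post[target, , drop = FALSE])^2))
  structure(list(direction = "post_to_pre", target_vertex = target,
                 match_cost = cost, n_pre = n1, n_post = n2, method = method,
                 cpd = cpd, links = links, eigenvalues = emb$values, k = k),
            class = "correspondence")
}

# Separate per-surface embeddings; sign/order ambiguity resolved by greedy
# pairing of modes maximizing |correlation| through the link set, with an
# eigenvalue-similarity guard. Returns per-layer coordinates (paired modes,
# unit-normalized per layer, weighted by inverse sqrt eigenvalue).
.jsm_aligned_embedding <- function(pre, post, links, k, seed) {
  e1 <- spectral_embedding(pre, k + 1L, seed = seed)
  e2 <- spectral_embedding(post, k + 1L, seed = seed)
  V1 <- e1$vectors[, -1, drop = FALSE]; l1 <- e1$values[-1]
  V2 <- e2$vectors[, -1, drop = FALSE]; l2 <- e2$values[-1]
  C <- suppressWarnings(stats::cor(V1[links[, 1], , drop = FALSE],
                                   V2[links[, 2], , drop = FALSE]))
  C[!is.finite(C)] <- 0
  # only modes of comparable frequency may pair
  ratio <- outer(pmax(l1, 1e-12), pmax(l2, 1e-12), "/")
  C[ratio > 3 | ratio < 1 / 3] <- 0
  pairs <- NULL
  Cw <- abs(C)
  while (nrow(pairs %||% matrix(0, 0, 2)) < k && any(Cw > 0.3)) {
    ix <- arrayInd(which.max(Cw), dim(Cw))
    pairs <- rbind(pairs, c(ix[1], ix[2], sign(C[ix[1], ix[2]])))
    Cw[ix[1], ] <- 0; Cw[, ix[2]] <- 0
  }
  if (is.null(pairs)) stop("no alignable spectral modes through the links")
  lam <- (l1[pairs[, 1]] + l2[pairs[, 2]]) / 2
  o <- order(lam)
  pairs <- pairs[o, , drop = FALSE]; lam <- lam[o]
  wmode <- 1 / sqrt(pmax(lam, max(lam) * 1e-8))
  P1 <- sweep(V1[, pairs[, 1], drop = FALSE], 2, wmode, "*")
  P2 <- sweep(V2[, pairs[, 2], drop = FALSE], 2,
              wmode * pairs[, 3] * sqrt(nrow(V1) / nrow(V2)), "*")
  list(pre = P1, post = P2, values = lam)
}

# Dual-layer joint graph: block Laplacians coupled by the links (weight
# gamma x mean intra weight); keep the k link-coherent low modes, normalize
# each per layer.
.jsm_joint_embedding <- function(pre, post, links, k, gamma, seed) {
  n1 <- nrow(pre$vertices); n2 <- nrow(post$vertices)
  l1 <- mesh_laplacian(pre, "cotangent")
  l2 <- mesh_laplacian(post, "cotangent")
  wmean <- function(L) {
    x <- -L@x[L@x < 0]
    if (length(x)) mean(x) else 1
  }
  lw <- gamma * mean(c(wmean(l1$L), wmean(l2$L)))
  n <- n1 + n2
  iL <- links[, 1]; jL <- n1 + links[, 2]
  Clink <- Matrix::sparseMatrix(i = c(iL, jL, iL, jL),
                                j = c(jL, iL, iL, jL),
                                x = c(rep(-lw, 2 * nrow(links)),
                                      rep(lw, 2 * nrow(links))),
                                dims = c(n, n))
  Ljoint <- Matrix::bdiag(l1$L, l2$L) + Clink
  mass <- c(l1$mass, l2$mass)
  nm <- min(2L * (k + 1L) + 4L, n - 1L)
  eg <- .eigs_smallest(methods::as(Ljoint, "CsparseMatrix"), mass, nm,
                       seed = seed)
  coh <- vapply(seq_len(ncol(eg$vectors)), function(j) {
    a <- eg$vectors[links[, 1], j]
    b <- eg$vectors[n1 + links[, 2], j]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(1)
    stats::cor(a, b)
  }, numeric(1))
  cand <- setdiff(order(eg$values), which.min(eg$values))
  shared <- cand[coh[cand] >= 0.6]
  if (length(shared) < k) shared <- cand[order(-coh[cand])][seq_len(k)]
  shared <- shared[seq_len(min(k, length(shared)))]
  Fv <- eg$vectors[, shared, drop = FALSE]
  lam <- eg$values[shared]
  emb_pre <- Fv[seq_len(n1), , drop = FALSE]
  emb_post <- Fv[n1 + seq_len(n2), , drop = FALSE]
  nz <- function(x) sqrt(sum(x^2)) + 1e-300
  for (j in seq_along(lam)) {
    emb_pre[, j] <- emb_pre[, j] / nz(emb_pre[, j]) / sqrt(n1)
    emb_post[, j] <- emb_post[, j] / nz(emb_post[, j]) / sqrt(n2)
  }
  wmode <- 1 / sqrt(pmax(lam, max(lam) * 1e-8))
  list(pre = sweep(emb_pre, 2, wmode, "*"),
       post = sweep(emb_post, 2, wmode, "*"), values = lam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf(paste0("correspondence (%s): %d pre vertices -> %d post ",
                     "vertices\n  %d CPD links, %d shared modes, mean match ",
                     "cost %.4g\n"),
              x$direction, x$n_pre, x$n_post, nrow(x$links), x$k,
              mean(x$match_cost)))
  invisible(x)
}

#' Pull a post-surface field back to the pre surface
#'
#' Nearest-neighbour transfer through a [joint_spectral_match()]
#' correspondence: the pre-vertex value is the field value at its matched
#' post vertex, so the transferred range is a subset of the source range.
#'
#' @param corr a `correspondence`.
#' @param field_on_post numeric vector, one value per post vertex.
#' @return numeric vector, one value per pre vertex.
#' @export
transfer_field <- function(corr, field_on_post) {
  if (length(field_on_post) != corr$n_post)
    stop("field length (", length(field_on_post),
         ") does not match the post vertex count (", corr$n_post, ")")
  field_on_post[corr$target_vertex]
}

#' Per-vertex longitudinal change of a field (post minus pre)
#'
#' @param pre_field field on the pre surface.
#' @param transferred_post_field post field transferred to the pre surface
#'   (see [transfer_field()]).
#' @return per-vertex change (B - A convention: post minus pre).
#' @export
delta_field <- function(pre_field, transferred_post_field) {
  if (length(pre_field) != length(transferred_post_field))
    stop("field lengths differ")
  transferred_post_field - pre_field
}
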