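#' Mass-univariate longitudinal linear mixed model
#'
#' Fits, at every voxel, the Gaussian linear mixed model
#' `y_ij = beta0 + beta1 t_ij + b_i0 + b_i1 t_ij + eps_ij` with correlated
#' random intercept and slope, by maximum likelihood. All voxels share the
#' same design (subjects and times), so the profiled ML deviance is
#' evaluated from per-time-pattern sufficient statistics: for each value of
#' the relative covariance factor, the per-subject marginal covariance,
#' its inverse and log-determinant are computed once per distinct time
#' pattern and reused across subjects; the fixed effects and the residual
#' variance are profiled out in closed form. The three free parameters of
#' the relative covariance Cholesky factor are optimized by Nelder-Mead.
#'
#' Inference on the slope uses the Wald statistic `t1 = beta1 / SE(beta1)`
#' with a standard-normal reference distribution.
#'
#' Fallbacks: a voxel whose full fit fails is refitted with a random
#' intercept only (`convergence = 1`); if that also fails, ordinary least
#' squares with a cluster-robust (CR0, clustered by subject) variance is
#' used (`convergence = 2`); a constant-response voxel is flagged
#' (`convergence = 3`) with `p1 = 1`. Voxels fitted by the full model have
#' `convergence = 0`.
#'
#' @param stack an [image_stack]; every subject needs at least 2 visits and
#'   within-subject time variation.
#' @param reltol convergence tolerance passed to the optimizer.
#' @return object of class `vbm_result` with per-voxel vectors `beta0`,
#'   `beta1`, `t1`, `p1`, variance components (`sigma0_sq`, `sigma1_sq`,
#'   `sigma01`, `sigma_eps_sq`) and `convergence`; `q1`/`reject`/`clusters`
#'   are filled by [vbm()].
#' @export
fit_voxelwise <- function(stack, reltol = 1e-9) {
  tt <- stack$time
  cols <- subject_columns(stack)
  if (any(vapply(cols, function(jj) diff(range(tt[jj])) == 0, logical(1))))
    stop_design("every subject needs within-subject time variation")

  ctx <- vbm_context(tt, cols)
  Y <- stack$data
  p <- nrow(Y)
  out <- list(beta0 = numeric(p), beta1 = numeric(p), t1 = numeric(p),
              p1 = numeric(p), sigma0_sq = numeric(p), sigma1_sq = numeric(p),
              sigma01 = numeric(p), sigma_eps_sq = numeric(p),
              convergence = integer(p))
  for (v in seq_len(p)) {
    fv <- fit_one_voxel(Y[v, ], ctx, reltol)
    out$beta0[v] <- fv$beta[1]; out$beta1[v] <- fv$beta[2]
    out$t1[v] <- fv$t1; out$p1[v] <- fv$p1
    out$sigma0_sq[v] <- fv$vc[1]; out$sigma1_sq[v] <- fv$vc[2]
    out$sigma01[v] <- fv$vc[3]; out$sigma_eps_sq[v] <- fv$vc[4]
    out$convergence[v] <- fv$convergence
  }
  structure(c(out, list(stack_geometry = list(
    grid_shape = stack$grid_shape, mask_index = stack$mask_index,
    voxel_size = stack$voxel_size), n = ncol(Y))),
    class = "vbm_result")
}

# Precompute the shared design structures: per distinct within-subject time
# pattern, the Z matrix and the column indices of its subjects.
vbm_context <- function(tt, cols) {
  keys <- vapply(cols, function(jj) paste(signif(tt[jj], 12), collapse = ","),
                 character(1))
  pat_of <- match(keys, unique(keys))
  patterns <- lapply(which(!duplicated(keys)), function(i) {
    jj <- cols[[i]]
    list(t = tt[jj], Z = cbind(1, tt[jj]), Ji = length(jj))
  })
  groups <- lapply(seq_along(patterns), function(k) {
    members <- which(pat_of == k)
    # (Ji x n_members) matrix of data-column indices
    vapply(members, function(i) cols[[i]], integer(patterns[[k]]$Ji))
  })
  list(patterns = patterns, groups = groups, n = length(tt),
       nsub = length(cols))
}

# Profiled ML deviance pieces for a given relative covariance factor
# theta = (l11, l21, l22): Vstar_i = Z_i L L' Z_i' + I.
vbm_theta_pieces <- function(theta, ctx) {
  L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  A <- matrix(0, 2, 2); logdet <- 0
  per <- vector("list", length(ctx$patterns))
  for (k in seq_along(ctx$patterns)) {
    pat <- ctx$patterns[[k]]
    Vs <- tcrossprod(pat$Z %*% L) + diag(pat$Ji)
    ch <- tryCatch(chol(Vs), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    nmem <- ncol(ctx$groups[[k]])
    logdet <- logdet + 2 * sum(log(diag(ch))) * nmem
    XtVinv <- crossprod(pat$Z, Vinv)
    A <- A + XtVinv %*% pat$Z * nmem
    per[[k]] <- list(Vinv = Vinv, XtVinv = XtVinv)
  }
  list(A = A, logdet = logdet, per = per, L = L)
}

vbm_profile <- function(pieces, y, ctx) {
  b <- c(0, 0); q <- 0
  for (k in seq_along(ctx$patterns)) {
    idx <- ctx$groups[[k]]                 # Ji x nmem
    Yg <- matrix(y[idx], nrow = nrow(idx))
    b <- b + rowSums(pieces$per[[k]]$XtVinv %*% Yg)
    q <- q + sum(Yg * (pieces$per[[k]]$Vinv %*% Yg))
  }
  beta <- tryCatch(solve(pieces$A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- q - sum(b * beta)
  if (!is.finite(rss) || rss <= 0) return(NULL)
  sig2 <- rss / ctx$n
  list(beta = beta, sig2 = sig2,
       dev = ctx$n * log(2 * pi * sig2) + pieces$logdet + ctx$n)
}

fit_one_voxel <- function(y, ctx, reltol) {
  if (var(y) == 0) {
    return(list(beta = c(mean(y), 0), t1 = 0, p1 = 1,
                vc = c(0, 0, 0, 0), convergence = 3L))
  }
  devfun <- function(theta) {
    pieces <- vbm_theta_pieces(theta, ctx)
    if (is.null(pieces)) return(1e10)
    prof <- vbm_profile(pieces, y, ctx)
    if (is.null(prof)) return(1e10)
    prof$dev
  }
  opt <- tryCatch(
    optim(c(0.5, 0, 0.5), devfun, method = "Nelder-Mead",
          control = list(reltol = reltol, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e10) {
    res <- vbm_wald(opt$par, y, ctx)
    if (!is.null(res)) {
      res$convergence <- 0L
      return(res)
    }
  }
  # fallback 1: random intercept only
  dev1 <- function(l) devfun(c(l, 0, 0))
  opt1 <- tryCatch(optimize(dev1, c(0, 50)), error = function(e) NULL)
  if (!is.null(opt1) && is.finite(opt1$objective) && opt1$objective < 1e10) {
    res <- vbm_wald(c(opt1$minimum, 0, 0), y, ctx)
    if (!is.null(res)) {
      res$convergence <- 1L
      return(res)
    }
  }
  # fallback 2: OLS with cluster-robust variance
  vbm_ols_fallback(y, ctx)
}

vbm_wald <- function(theta, y, ctx) {
  pieces <- vbm_theta_pieces(theta, ctx)
  if (is.null(pieces)) return(NULL)
  prof <- vbm_profile(pieces, y, ctx)
  if (is.null(prof)) return(NULL)
  Vb <- prof$sig2 * tryCatch(solve(pieces$A), error = function(e) NULL)
  if (is.null(Vb)) return(NULL)
  se1 <- sqrt(Vb[2, 2])
  t1 <- prof$beta[2] / se1
  G <- prof$sig2 * tcrossprod(pieces$L)
  list(beta = prof$beta, t1 = t1, p1 = 2 * pnorm(-abs(t1)),
       vc = c(G[1, 1], G[2, 2], G[1, 2], prof$sig2))
}

vbm_ols_fallback <- function(y, ctx) {
  tt_all <- unlist(lapply(seq_along(ctx$patterns), function(k)
    rep(ctx$patterns[[k]]$t, ncol(ctx$groups[[k]]))))
  idx_all <- unlist(lapply(ctx$groups, as.vector))
  cl <- unlist(lapply(seq_along(ctx$groups), function(k)
    rep(paste(k, seq_len(ncol(ctx$groups[[k]])), sep = "."),
        each = nrow(ctx$groups[[k]]))))
  df <- data.frame(y = y[idx_all], t = tt_all, cl = cl)
  fit <- lm(y ~ t, data = df)
  Vb <- sandwich::vcovCL(fit, cluster = df$cl)
  beta <- coef(fit)
  t1 <- beta[2] / sqrt(Vb[2, 2])
  list(beta = unname(beta), t1 = unname(t1),
       p1 = unname(2 * pnorm(-abs(t1))),
       vc = c(NA_real_, NA_real_, NA_real_, summary(fit)$sigma^2),
       convergence = 2L)
}

#' Benjamini-Yekutieli FDR control
#'
#' Step-up procedure with the harmonic-sum correction
#' `c(m) = sum_{i=1}^m 1/i`, valid under arbitrary dependence. Adjusted
#' values are monotone nondecreasing in p-rank and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level for the rejection set (default 0.05).
#' @return list with `adjusted` (same length as `pvals`) and `reject`
#'   (logical, `adjusted <= q`).
#' @export
by_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_validation("p-values must lie in [0, 1]")
  adjusted <- p.adjust(pvals, method = "BY")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Connected clusters of rejected voxels with extent thresholding
#'
#' Labels connected components separately among rejected voxels with
#' positive and negative test statistic, drops components smaller than
#' `min_extent`, and summarizes each surviving cluster: size, extreme
#' statistic (maximum for positive clusters, minimum for negative), the
#' grid coordinates of the extreme voxel, and the unweighted centre of
#' gravity of the cluster's voxel coordinates. Positive clusters are
#' labeled "enlargement" and negative ones "atrophy".
#'
#' @param reject logical vector over mask voxels.
#' @param tmap numeric statistic vector over mask voxels.
#' @param geometry list with `grid_shape` and `mask_index` (e.g. an
#'   [image_stack] or the `stack_geometry` of a `vbm_result`).
#' @param min_extent minimal cluster size in voxels; the default 21 keeps
#'   clusters of spatial extent strictly greater than 20 voxels.
#' @param connectivity 4/8 in 2D, 6/18/26 in 3D; default 8 in 2D and 26 in
#'   3D (edge-, face-/edge-/corner-touching voxels connect).
#' @return data frame of class `cluster_table`, sorted by size descending
#'   within sign, with columns `sign`, `size`, `t_extreme`, `x`, `y`, `z`
#'   (extreme voxel), `cog_x`, `cog_y`, `cog_z`.
#' @export
cluster_extent <- function(reject, tmap, geometry, min_extent = 21L,
                           connectivity = NULL) {
  grid <- geometry$grid_shape
  mask_index <- geometry$mask_index
  is3d <- grid[3] > 1L
  if (is.null(connectivity)) connectivity <- if (is3d) 26L else 8L
  empty <- data.frame(sign = character(0), size = integer(0),
                      t_extreme = numeric(0), x = integer(0), y = integer(0),
                      z = integer(0), cog_x = numeric(0), cog_y = numeric(0),
                      cog_z = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("cluster_table", "data.frame")
  out <- empty
  for (sgn in c(1, -1)) {
    sel <- which(reject & sign(tmap) == sgn)
    if (length(sel) == 0L) next
    lin <- mask_index[sel]
    labels <- label_components(lin, grid, connectivity)
    coords <- arrayInd(lin, grid)
    for (lab in unique(labels)) {
      members <- labels == lab
      size <- sum(members)
      if (size < min_extent) next
      tv <- tmap[sel[members]]
      ext <- if (sgn > 0) which.max(tv) else which.min(tv)
      cc <- coords[members, , drop = FALSE]
      out <- rbind(out, data.frame(
        sign = if (sgn > 0) "enlargement" else "atrophy",
        size = size, t_extreme = tv[ext],
        x = cc[ext, 1], y = cc[ext, 2], z = cc[ext, 3],
        cog_x = mean(cc[, 1]), cog_y = mean(cc[, 2]), cog_z = mean(cc[, 3]),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(out))
    out <- out[order(out$sign, -out$size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

neighbor_offsets <- function(connectivity, is3d) {
  zr <- if (is3d) -1:1 else 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = zr)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "4" = manh == 1, "6" = manh == 1,
                 "8" = manh >= 1, "18" = manh <= 2, "26" = manh >= 1,
                 stop_validation(sprintf("unsupported connectivity %s",
                                         connectivity)))
  offs[keep, , drop = FALSE]
}

# Connected-component labels of a set of voxels given by linear indices.
label_components <- function(lin, grid, connectivity) {
  vol <- array(0L, dim = grid)
  vol[lin] <- seq_along(lin)
  coords <- arrayInd(lin, grid)
  offs <- neighbor_offsets(connectivity, grid[3] > 1L)
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + offs$dx[o]
    nb[, 2] <- nb[, 2] + offs$dy[o]
    nb[, 3] <- nb[, 3] + offs$dz[o]
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * grid[1] +
      (nb[ok, 3] - 1L) * grid[1] * grid[2]
    nb_id <- vol[nb_lin]
    hit <- nb_id > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb_id[hit]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Longitudinal VBM analysis
#'
#' Convenience wrapper running the voxelwise linear mixed model, BY-FDR
#' correction of the slope p-values, and cluster-extent thresholding of the
#' rejection map.
#'
#' @inheritParams fit_voxelwise
#' @param q FDR level (default 0.05).
#' @param min_extent,connectivity passed to [cluster_extent()].
#' @return a `vbm_result` with `q1`, `reject` and `clusters` filled in.
#' @export
vbm <- function(stack, q = 0.05, min_extent = 21L, connectivity = NULL) {
  res <- fit_voxelwise(stack)
  fdr <- by_fdr(res$p1, q = q)
  res$q1 <- fdr$adjusted
  res$reject <- fdr$reject
  res$fdr_level <- q
  res$clusters <- cluster_extent(res$reject, res$t1, res$stack_geometry,
                                 min_extent = min_extent,
                                 connectivity = connectivity)
  res
}

#' @export
print.vbm_result <- function(x, ...) {
  cat(sprintf("vbm_result: %d voxels, %d images\n", length(x$beta1), x$n))
  if (!is.null(x$reject))
    cat(sprintf("  %d voxels rejected at BY-FDR %.3g; %d clusters pass extent threshold\n",
                sum(x$reject), x$fdr_level, nrow(x$clusters)))
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' @param clusters a `cluster_table`.
#' @param file output path.
#' @export
write_cluster_table <- function(clusters, file) {
  write.table(clusters, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
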