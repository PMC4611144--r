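#' Voxelwise mean and demeaned stack
#'
#' Estimates the fixed effect by the sample mean over all image
#' observations (a single map, not a time-varying surface) and subtracts it
#' from every column.
#'
#' @param stack an [image_stack] with at least 2 images.
#' @return list with `mean_map` (length-`p` vector) and `stack` (the
#'   demeaned [image_stack]).
#' @export
demean <- function(stack) {
  if (ncol(stack$data) < 2L) stop_validation("need at least 2 images to demean")
  mean_map <- rowMeans(stack$data)
  out <- stack
  out$data <- stack$data - mean_map
  list(mean_map = mean_map, stack = out)
}

#' SVD reduction of a demeaned stack
#'
#' Decomposes the demeaned `p x J` data matrix as `V S U'` by a thin
#' singular value decomposition and keeps the `r` singular values above a
#' machine-scaled tolerance. Column `j` of `W_red = S U'` is the
#' `r`-dimensional representation of demeaned image `j`; all covariance and
#' score computations downstream operate on `W_red` and are mapped back to
#' voxel space through `V`.
#'
#' @param stack a demeaned [image_stack] (output of [demean()]).
#' @param mean_map optional mean map to carry along for reconstruction.
#' @return object of class `reduced_data`: `V` (`p x r`), `S` (length `r`),
#'   `U` (`J x r`), `W_red` (`r x J`), `mean_map`, plus the stack metadata
#'   (`subject_id`, `visit_index`, `time`) and a reference to the stack's
#'   mask geometry.
#' @export
reduce_stack <- function(stack, mean_map = NULL) {
  X <- stack$data
  if (all(X == 0)) stop_numerical("all-zero (degenerate) demeaned data")
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (r == 0L) stop_numerical("data matrix has numerical rank 0")
  V <- sv$u[, seq_len(r), drop = FALSE]
  S <- sv$d[seq_len(r)]
  U <- sv$v[, seq_len(r), drop = FALSE]
  structure(list(V = V, S = S, U = U,
                 W_red = t(U * rep(S, each = nrow(U))),
                 mean_map = mean_map,
                 subject_id = stack$subject_id,
                 visit_index = stack$visit_index,
                 time = stack$time,
                 grid_shape = stack$grid_shape,
                 mask_index = stack$mask_index,
                 voxel_size = stack$voxel_size),
            class = "reduced_data")
}

#' Moment design matrix over within-subject visit pairs
#'
#' For every ordered within-subject visit pair `(j1, j2)` (including
#' `j1 = j2`) builds the column
#' `f = (1, t_ij2, t_ij1, t_ij1 * t_ij2, delta_j1j2)'`, giving the 5 x m
#' design of the method-of-moments regression, `m = sum_i J_i^2`.
#'
#' @param stack an [image_stack] or `reduced_data` (any object with
#'   `subject_id` and `time`).
#' @param cond_bound maximal accepted condition number of `F F'`.
#' @return list of class `moment_design`: `F` (5 x m), `pair_index`
#'   (data frame subject/j1/j2 with the column index of each image), `m`.
#' @export
build_moment_design <- function(stack, cond_bound = 1e10) {
  cols <- split(seq_along(stack$subject_id),
                factor(stack$subject_id, levels = unique(stack$subject_id)))
  pairs <- do.call(rbind, lapply(names(cols), function(s) {
    jj <- cols[[s]]
    Ji <- length(jj)
    expand <- expand.grid(j2 = seq_len(Ji), j1 = seq_len(Ji))[, c("j1", "j2")]
    data.frame(subject = s,
               j1 = expand$j1, j2 = expand$j2,
               col1 = jj[expand$j1], col2 = jj[expand$j2],
               stringsAsFactors = FALSE)
  }))
  t1 <- stack$time[pairs$col1]
  t2 <- stack$time[pairs$col2]
  F <- rbind(1, t2, t1, t1 * t2, as.numeric(pairs$j1 == pairs$j2))
  rownames(F) <- c("const", "t_j2", "t_j1", "t_j1_t_j2", "delta")
  FFt <- tcrossprod(F)
  ev <- eigen(FFt, symmetric = TRUE, only.values = TRUE)$values
  cond <- ev[1] / max(ev[5], 0)
  if (is.finite(cond_bound) && (!is.finite(cond) || cond > cond_bound))
    stop_numerical(sprintf(
      "moment design F F' is ill-conditioned (condition number %.3g); do within-subject times vary?",
      cond))
  structure(list(F = F, pair_index = pairs, m = ncol(F), FFt = FFt),
            class = "moment_design")
}

#' Method-of-moments covariance blocks in the reduced space
#'
#' Regresses the reduced outer products `vec(w_ij1 w_ij2')` on the moment
#' design by ordinary least squares, `K = Y F'(F F')^{-1}`, and reshapes the
#' five coefficient columns into the `r x r` covariance blocks of the
#' subject-specific process (`K00`, `K01`, `K10`, `K11`) and the
#' visit-specific process (`KW`). The cross-product `Y F'` is accumulated
#' from per-subject sums, so the `r^2 x m` response matrix is never
#' materialized and memory scales with `r^2`, not `p^2`.
#'
#' Blocks are symmetrized on return: `K00`, `K11`, `KW` by averaging with
#' their transposes and `K01 <- (K01 + K10')/2`, `K10 <- K01'`.
#'
#' @param reduced a `reduced_data` object.
#' @param design a `moment_design` built from the same metadata.
#' @return object of class `cov_blocks` with fields `K00`, `K01`, `K10`,
#'   `K11`, `KW` and `r`.
#' @export
estimate_cov_blocks <- function(reduced, design = build_moment_design(reduced)) {
  W <- reduced$W_red
  r <- nrow(W)
  subj <- factor(reduced$subject_id, levels = unique(reduced$subject_id))
  ind <- stats::model.matrix(~ subj - 1)           # J x N membership
  tt <- reduced$time
  S0 <- W %*% ind                                   # r x N: sum_j w_ij
  S1 <- (W * rep(tt, each = r)) %*% ind             # r x N: sum_j t_ij w_ij
  # Y F' columns, in the order of the f-vector entries:
  YFt <- list(tcrossprod(S0),          # sum over pairs of w_j1 w_j2'
              tcrossprod(S0, S1),      # weight t_j2
              tcrossprod(S1, S0),      # weight t_j1
              tcrossprod(S1),          # weight t_j1 t_j2
              tcrossprod(W))           # delta term: same-visit pairs
  G <- solve(design$FFt)
  K <- lapply(seq_len(5), function(q) {
    acc <- matrix(0, r, r)
    for (q2 in seq_len(5)) acc <- acc + YFt[[q2]] * G[q2, q]
    acc
  })
  K00 <- (K[[1]] + t(K[[1]])) / 2
  K01 <- (K[[2]] + t(K[[3]])) / 2
  K11 <- (K[[4]] + t(K[[4]])) / 2
  KW  <- (K[[5]] + t(K[[5]])) / 2
  structure(list(K00 = K00, K01 = K01, K10 = t(K01), K11 = K11, KW = KW,
                 r = r),
            class = "cov_blocks")
}

#' Eigendecomposition and truncation of the covariance blocks
#'
#' Diagonalizes the stacked `2r x 2r` subject-specific covariance
#' `[[K00, K01], [K10, K11]]` and the `r x r` visit-specific covariance
#' `KW`. Eigenvalues are sorted descending; nonpositive eigenvalues (which
#' the method-of-moments estimator can produce) are discarded before
#' truncation, never clipped into the retained set. Truncation keeps
#' `n_x` (`n_w`) components when given, otherwise the smallest number of
#' components reaching `pve` of the summed positive eigenvalue mass, capped
#' at `max_comp` per process.
#'
#' The eigenvector sign convention makes the entry of largest absolute
#' value in each (stacked) eigenvector positive, so maps and score signs
#' are reproducible.
#'
#' @param blocks a `cov_blocks` object.
#' @param n_x,n_w optional integer number of components to retain.
#' @param pve proportion of positive-eigenvalue mass to reach (default 0.9).
#' @param max_comp per-process cap on retained components (default 10).
#' @param reduced optionally attach the `reduced_data` for score estimation
#'   and back-projection.
#' @return object of class `lfpca_fit`: `lambda_x`, `lambda_w`, `A_x0`,
#'   `A_x1` (`r x N_X` reduced baseline/longitudinal eigenvector halves),
#'   `A_w` (`r x N_W`), `var_total`, and empty score slots.
#' @export
eigendecompose <- function(blocks, n_x = NULL, n_w = NULL, pve = 0.9,
                           max_comp = 10L, reduced = NULL) {
  r <- blocks$r
  KX <- rbind(cbind(blocks$K00, blocks$K01), cbind(blocks$K10, blocks$K11))
  ex <- eigen((KX + t(KX)) / 2, symmetric = TRUE)
  ew <- eigen((blocks$KW + t(blocks$KW)) / 2, symmetric = TRUE)

  keep_x <- truncate_components(ex$values, n_x, pve, max_comp, "subject-specific")
  keep_w <- truncate_components(ew$values, n_w, pve, max_comp, "visit-specific")

  VX <- fix_signs(ex$vectors[, keep_x, drop = FALSE])
  VW <- fix_signs(ew$vectors[, keep_w, drop = FALSE])
  fit <- structure(list(
    lambda_x = ex$values[keep_x],
    lambda_w = ew$values[keep_w],
    A_x0 = VX[seq_len(r), , drop = FALSE],
    A_x1 = VX[r + seq_len(r), , drop = FALSE],
    A_w = VW,
    var_total = sum(ex$values[keep_x]) + sum(ew$values[keep_w]),
    xi = NULL, zeta = NULL,
    reduced = reduced),
    class = "lfpca_fit")
  fit
}

truncate_components <- function(values, n, pve, max_comp, what) {
  pos <- which(values > 0)
  if (length(pos) == 0L) {
    if (is.null(n) || n > 0)
      warning(sprintf("no positive %s eigenvalue; retaining 0 components", what))
    return(integer(0))
  }
  if (!is.null(n)) return(pos[seq_len(min(n, length(pos)))])
  cum <- cumsum(values[pos]) / sum(values[pos])
  k <- which(cum >= pve)[1]
  pos[seq_len(min(k, max_comp, length(pos)))]
}

fix_signs <- function(M) {
  if (ncol(M) == 0L) return(M)
  for (k in seq_len(ncol(M))) {
    i <- which.max(abs(M[, k]))
    if (M[i, k] < 0) M[, k] <- -M[, k]
  }
  M
}

#' @export
print.lfpca_fit <- function(x, ...) {
  cat(sprintf("lfpca_fit: %d subject-specific, %d visit-specific components\n",
              length(x$lambda_x), length(x$lambda_w)))
  if (length(x$lambda_x)) {
    vt <- variance_table(x)
    sub <- vt[vt$process == "subject", ]
    cat(sprintf("  top subject component: %.1f%% of variance, longitudinal ratio %.2f\n",
                100 * sub$var_share[1], sub$longitudinal_ratio[1]))
  }
  invisible(x)
}

#' Variance attribution table
#'
#' For each retained component: its share of the total retained variance
#' and, for subject-specific components, the longitudinal ratio
#' `||A_x1_k||^2` — the fraction of the component's (unit) norm carried by
#' the longitudinal half. Because the stacked eigenvector has unit norm and
#' the SVD basis `V` has orthonormal columns, this equals
#' `||Phi_x1_k||^2 / (||Phi_x0_k||^2 + ||Phi_x1_k||^2)` in voxel space.
#'
#' @param fit an `lfpca_fit`.
#' @return data frame with columns `process` ("subject"/"visit"),
#'   `component`, `eigenvalue`, `var_share`, `longitudinal_ratio` (NA for
#'   visit components).
#' @export
variance_table <- function(fit) {
  nx <- length(fit$lambda_x); nw <- length(fit$lambda_w)
  out <- data.frame(
    process = c(rep("subject", nx), rep("visit", nw)),
    component = c(seq_len(nx), seq_len(nw)),
    eigenvalue = c(fit$lambda_x, fit$lambda_w),
    var_share = if (length(c(fit$lambda_x, fit$lambda_w)) && fit$var_total > 0)
      c(fit$lambda_x, fit$lambda_w) / fit$var_total else numeric(0),
    longitudinal_ratio = c(if (nx) colSums(fit$A_x1^2) else numeric(0),
                           rep(NA_real_, nw)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Least-squares (BLUP-type) component scores
#'
#' For each subject stacks its reduced visit vectors and solves the
#' unweighted least-squares problem with the per-visit design blocks
#' `[A_x0 + t_ij A_x1 | A_w (block-diagonal across visits)]`, i.e. the
#' normal-equations estimator `omega_i = (B_i'B_i)^{-1} B_i' vec(w_i)`.
#' When the cross-product is rank deficient the minimum-norm solution is
#' returned with a warning. Because the SVD basis has orthonormal columns
#' the scores are identical whether computed in the reduced or the full
#' voxel space.
#'
#' @param fit an `lfpca_fit` with an attached `reduced` component (or pass
#'   `reduced` explicitly).
#' @param reduced a `reduced_data` object.
#' @return the fit with `xi` (`N x N_X`, rownames = subject ids) and `zeta`
#'   (`J x N_W`, one row per image column) filled in.
#' @export
estimate_scores <- function(fit, reduced = fit$reduced) {
  if (is.null(reduced))
    stop_validation("estimate_scores needs the reduced data (fit$reduced)")
  nx <- length(fit$lambda_x); nw <- length(fit$lambda_w)
  W <- reduced$W_red
  r <- nrow(W)
  cols <- split(seq_along(reduced$subject_id),
                factor(reduced$subject_id, levels = unique(reduced$subject_id)))
  N <- length(cols)
  xi <- matrix(NA_real_, N, nx, dimnames = list(names(cols), NULL))
  zeta <- matrix(NA_real_, ncol(W), nw)
  for (i in seq_len(N)) {
    jj <- cols[[i]]
    Ji <- length(jj)
    if (nx + Ji * nw > Ji * r)
      warning(sprintf("subject %s: more scores than data (rank deficiency)",
                      names(cols)[i]))
    BX <- do.call(rbind, lapply(reduced$time[jj], function(t)
      fit$A_x0 + t * fit$A_x1))                       # (Ji r) x nx
    BW <- if (nw > 0) kronecker(diag(Ji), fit$A_w) else
      matrix(0, Ji * r, 0)                            # (Ji r) x (Ji nw)
    B <- cbind(BX, BW)
    y <- as.vector(W[, jj])
    omega <- lstsq_minnorm(B, y, warn_subject = names(cols)[i])
    if (nx > 0) xi[i, ] <- omega[seq_len(nx)]
    if (nw > 0)
      zeta[jj, ] <- matrix(omega[nx + seq_len(Ji * nw)], ncol = nw,
                           byrow = TRUE)
  }
  fit$xi <- xi
  fit$zeta <- zeta
  fit
}

# minimum-norm least squares via SVD; warns on rank deficiency
lstsq_minnorm <- function(B, y, warn_subject = NULL) {
  if (ncol(B) == 0L) return(numeric(0))
  sv <- svd(B)
  tol <- max(dim(B)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos) && !is.null(warn_subject))
    warning(sprintf(
      "subject %s: rank-deficient score design; returning minimum-norm solution",
      warn_subject))
  d_inv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (d_inv * crossprod(sv$u, y))
}

#' Back-project reduced eigenvectors to voxel-space component maps
#'
#' Maps the reduced eigenvectors through the SVD basis:
#' `Phi_x0 = V A_x0`, `Phi_x1 = V A_x1`, `Phi_w = V A_w`. Since `V` has
#' orthonormal columns the stacked baseline+longitudinal map keeps unit
#' norm.
#'
#' @param fit an `lfpca_fit` with attached `reduced`.
#' @param process `"subject"` or `"visit"`.
#' @param components integer indices of the components to back-project
#'   (default all retained).
#' @return for `process = "subject"`, list with `phi_x0` and `phi_x1`
#'   (`p x k` matrices); for `"visit"`, list with `phi_w`.
#' @export
backproject <- function(fit, process = c("subject", "visit"),
                        components = NULL) {
  process <- match.arg(process)
  if (is.null(fit$reduced))
    stop_validation("backproject needs the reduced data (fit$reduced)")
  V <- fit$reduced$V
  nk <- if (process == "subject") length(fit$lambda_x) else length(fit$lambda_w)
  if (is.null(components)) components <- seq_len(nk)
  if (length(components) && (min(components) < 1 || max(components) > nk))
    stop_longvbm(sprintf("component selector out of range 1..%d", nk),
                 "longvbm_index_error")
  if (process == "subject")
    list(phi_x0 = V %*% fit$A_x0[, components, drop = FALSE],
         phi_x1 = V %*% fit$A_x1[, components, drop = FALSE])
  else
    list(phi_w = V %*% fit$A_w[, components, drop = FALSE])
}

#' Temporal trajectory of a subject-specific component
#'
#' The longitudinal half is added to the baseline half with time as a
#' multiplicative weight: `map(t) = Phi_x0_k + t * Phi_x1_k`.
#'
#' @param fit an `lfpca_fit` with attached `reduced`.
#' @param k subject-specific component index.
#' @param times numeric vector of times.
#' @return `p x length(times)` matrix, one map per requested time.
#' @export
component_trajectory <- function(fit, k, times) {
  maps <- backproject(fit, "subject", components = k)
  maps$phi_x0[, 1] + outer(as.vector(maps$phi_x1[, 1]), as.numeric(times))
}

#' Fit the longitudinal functional PCA decomposition
#'
#' Runs the full estimation pipeline on a longitudinal image stack:
#' demeaning by the overall sample mean, SVD reduction, method-of-moments
#' covariance-block estimation over all within-subject visit pairs,
#' eigendecomposition with truncation, and least-squares score estimation.
#'
#' @param stack an [image_stack].
#' @inheritParams eigendecompose
#' @param scores estimate subject and visit scores (default `TRUE`).
#' @param cond_bound condition bound for the moment design.
#' @return an `lfpca_fit` with scores and the reduced data attached.
#' @export
lfpca <- function(stack, n_x = NULL, n_w = NULL, pve = 0.9, max_comp = 10L,
                  scores = TRUE, cond_bound = 1e10) {
  dm <- demean(stack)
  reduced <- reduce_stack(dm$stack, mean_map = dm$mean_map)
  design <- build_moment_design(reduced, cond_bound = cond_bound)
  blocks <- estimate_cov_blocks(reduced, design)
  fit <- eigendecompose(blocks, n_x = n_x, n_w = n_w, pve = pve,
                        max_comp = max_comp, reduced = reduced)
  if (scores) fit <- estimate_scores(fit)
  fit
}

#' Serialize / restore an LFPCA fit
#'
#' Writes the eigenvalues, reduced eigenvector halves, SVD basis, scores,
#' mean map and mask geometry to a single JSON archive (plain text), and
#' reads it back. Round-trips through `read_lfpca()` up to double
#' precision of the JSON encoding.
#'
#' @param fit an `lfpca_fit`.
#' @param file path of the archive.
#' @export
write_lfpca <- function(fit, file) {
  payload <- list(
    lambda_x = fit$lambda_x, lambda_w = fit$lambda_w,
    A_x0 = fit$A_x0, A_x1 = fit$A_x1, A_w = fit$A_w,
    var_total = fit$var_total,
    xi = fit$xi, zeta = fit$zeta,
    subject_ids = rownames(fit$xi),
    V = fit$reduced$V, S = fit$reduced$S,
    mean_map = fit$reduced$mean_map,
    subject_id = fit$reduced$subject_id,
    visit_index = fit$reduced$visit_index,
    time = fit$reduced$time,
    grid_shape = fit$reduced$grid_shape,
    mask_index = fit$reduced$mask_index,
    voxel_size = fit$reduced$voxel_size)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_lfpca
#' @export
read_lfpca <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  as_mat <- function(m) if (is.null(m)) NULL else as.matrix(m)
  reduced <- structure(list(
    V = as_mat(x$V), S = as.numeric(x$S), U = NULL, W_red = NULL,
    mean_map = as.numeric(x$mean_map),
    subject_id = as.character(x$subject_id),
    visit_index = as.integer(x$visit_index),
    time = as.numeric(x$time),
    grid_shape = as.integer(x$grid_shape),
    mask_index = as.integer(x$mask_index),
    voxel_size = as.numeric(x$voxel_size)), class = "reduced_data")
  xi <- as_mat(x$xi)
  if (!is.null(xi)) rownames(xi) <- x$subject_ids
  structure(list(lambda_x = as.numeric(x$lambda_x),
                 lambda_w = as.numeric(x$lambda_w),
                 A_x0 = as_mat(x$A_x0), A_x1 = as_mat(x$A_x1),
                 A_w = as_mat(x$A_w),
                 var_total = as.numeric(x$var_total),
                 xi = xi, zeta = as_mat(x$zeta),
                 reduced = reduced),
            class = "lfpca_fit")
}
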