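# Shared fixtures, all generated in code.

# random image stack on a p x 1 x 1 grid
random_stack <- function(p = 20, n_subjects = 4, visits = 3, seed = 1,
                         times = seq_len(visits) - 1) {
  set.seed(seed)
  J <- n_subjects * visits
  image_stack(matrix(rnorm(p * J), p, J),
              subject_id = rep(sprintf("s%02d", seq_len(n_subjects)),
                               each = visits),
              time = rep(times, n_subjects))
}

# orthonormal component set for the reduced-rank model: stacked
# (phi_x0; phi_x1) columns orthonormal, phi_w orthonormal
random_components <- function(p, n_x = 2, n_w = 2, seed = 1) {
  set.seed(seed)
  qx <- qr.Q(qr(matrix(rnorm(2 * p * n_x), 2 * p, n_x)))
  qw <- qr.Q(qr(matrix(rnorm(p * n_w), p, n_w)))
  list(phi_x0 = qx[seq_len(p), , drop = FALSE],
       phi_x1 = qx[p + seq_len(p), , drop = FALSE],
       phi_w = qw)
}

# brute-force full-space method-of-moments OLS: builds the p^2 x m response
# explicitly and solves K = Y F'(FF')^-1; independent of the package's
# accumulation shortcut
full_space_moment_ols <- function(data, design) {
  p <- nrow(data)
  pairs <- design$pair_index
  Y <- vapply(seq_len(nrow(pairs)), function(q)
    as.vector(tcrossprod(data[, pairs$col1[q]], data[, pairs$col2[q]])),
    numeric(p * p))
  K <- Y %*% t(design$F) %*% solve(tcrossprod(design$F))
  lapply(seq_len(5), function(q) matrix(K[, q], p, p))
}

# flood-fill connected-component labeling oracle (recursive BFS over an
# explicit neighbour scan), independent of the package's graph approach
flood_fill_labels <- function(lin, grid, connectivity) {
  coords <- arrayInd(lin, grid)
  n <- length(lin)
  labels <- integer(n)
  cur <- 0L
  is_nb <- function(a, b) {
    d <- abs(coords[a, ] - coords[b, ])
    if (max(d) > 1) return(FALSE)
    if (connectivity %in% c(4, 6)) sum(d) == 1 else max(d) == 1 && sum(d) >= 1
  }
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (labels[b] == 0L && is_nb(a, b)) {
          labels[b] <- cur
          queue <- c(queue, b)
        }
      }
    }
  }
  labels
}

# definition-based BY step-up oracle: largest k with p_(k) <= k q / (m c(m))
by_stepup_oracle <- function(p, q) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  thr <- seq_len(m) * q / (m * cm)
  k <- suppressWarnings(max(which(ps <= thr)))
  reject <- logical(m)
  if (is.finite(k) && k >= 1) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# principal angles (degrees) between the column spaces of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(1, pmax(-1, sv))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
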