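test_that("demeaning subtracts the overall sample mean", {
  st <- image_stack(matrix(c(0, 2), 1, 2), c("a", "a"), time = 0:1)
  dm <- demean(st)
  expect_equal(dm$mean_map, 1)
  expect_equal(as.vector(dm$stack$data), c(-1, 1))
  # identical images demean to zero
  st2 <- image_stack(matrix(3, 4, 2), c("a", "a"), time = 0:1)
  expect_true(all(demean(st2)$stack$data == 0))
  # per-voxel residual means vanish
  st3 <- random_stack(p = 5, n_subjects = 2, visits = 3, seed = 5)
  expect_lt(max(abs(rowMeans(demean(st3)$stack$data))), 1e-12)
})

test_that("SVD reduction reconstructs the data and detects rank", {
  set.seed(6)
  # rank-1 outer product
  st <- image_stack(outer(rnorm(10), rnorm(6)),
                    subject_id = rep(c("a", "b"), each = 3),
                    time = rep(0:2, 2))
  red <- reduce_stack(st)
  expect_equal(length(red$S), 1L)
  # random stack: exact reconstruction and orthonormal basis
  st2 <- random_stack(p = 50, n_subjects = 4, visits = 3, seed = 7)
  red2 <- reduce_stack(st2)
  expect_lt(norm(red2$V %*% red2$W_red - st2$data, "F") /
              norm(st2$data, "F"), 1e-10)
  expect_lt(max(abs(crossprod(red2$V) - diag(length(red2$S)))), 1e-10)
  st0 <- image_stack(matrix(0, 3, 4), rep(c("a", "b"), each = 2),
                     time = rep(0:1, 2))
  expect_error(reduce_stack(st0), class = "longvbm_numerical_error")
})

test_that("moment design enumerates ordered within-subject pairs", {
  st <- image_stack(matrix(rnorm(2), 1), c("a", "a"), time = 0:1)
  d <- build_moment_design(st, cond_bound = Inf)
  # pairs (1,1),(1,2),(2,1),(2,2) with f = (1, t2, t1, t1 t2, delta)
  expect_equal(unname(d$F),
               cbind(c(1, 0, 0, 0, 1), c(1, 1, 0, 0, 0),
                     c(1, 0, 1, 0, 0), c(1, 1, 1, 1, 1)))
  st2 <- random_stack(p = 3, n_subjects = 2, visits = 3, seed = 8)
  expect_equal(build_moment_design(st2)$m, 18L)
  # a single distinct time cannot identify the moment regression
  st3 <- image_stack(matrix(rnorm(8), 2, 4), rep(c("a", "b"), each = 2),
                     time = rep(1, 4), recenter_times = FALSE)
  expect_error(build_moment_design(st3), class = "longvbm_numerical_error")
})

test_that("reduced-space moment blocks equal the projected full-space OLS", {
  comps <- random_components(p = 6, n_x = 2, n_w = 1, seed = 9)
  sim <- simulate_from_model(comps$phi_x0, comps$phi_x1, comps$phi_w,
                             lambda_x = c(3, 1), lambda_w = 0.5,
                             subject_id = rep(sprintf("s%d", 1:8), each = 3),
                             time = rep(0:2, 8), seed = 10)
  dm <- demean(sim$stack)
  red <- reduce_stack(dm$stack)
  design <- build_moment_design(red)
  blocks <- estimate_cov_blocks(red, design)
  Kfull <- full_space_moment_ols(dm$stack$data, design)
  V <- red$V
  proj <- function(K) crossprod(V, K %*% V)
  sym <- function(K) (K + t(K)) / 2
  expect_lt(norm(blocks$K00 - sym(proj(Kfull[[1]])), "F") /
              max(norm(blocks$K00, "F"), 1e-12), 1e-8)
  expect_lt(norm(blocks$K11 - sym(proj(Kfull[[4]])), "F") /
              norm(blocks$K11, "F"), 1e-8)
  expect_lt(norm(blocks$KW - sym(proj(Kfull[[5]])), "F") /
              norm(blocks$KW, "F"), 1e-8)
  K01p <- (proj(Kfull[[2]]) + t(proj(Kfull[[3]]))) / 2
  expect_lt(norm(blocks$K01 - K01p, "F") / norm(blocks$K01, "F"), 1e-8)
  # symmetry invariants
  expect_lt(max(abs(blocks$K00 - t(blocks$K00))), 1e-10)
  expect_lt(max(abs(blocks$KW - t(blocks$KW))), 1e-10)
  expect_identical(blocks$K10, t(blocks$K01))
})

test_that("pure-noise data yields KW close to identity and vanishing K^X", {
  # w_ij ~ N(0, I): expect KW ~ I, subject blocks ~ 0, error shrinking in N
  gen <- function(N, p = 4, seed) {
    set.seed(seed)
    image_stack(matrix(rnorm(p * N * 3), p),
                subject_id = rep(sprintf("s%03d", 1:N), each = 3),
                time = rep(0:2, N))
  }
  err <- sapply(c(25, 50, 100), function(N) {
    mean(sapply(1:6, function(rep) {
      st <- gen(N, seed = 100 * N + rep)
      red <- reduce_stack(demean(st)$stack)
      bl <- estimate_cov_blocks(red)
      KW_vox <- red$V %*% bl$KW %*% t(red$V)
      KX_vox <- red$V %*% bl$K00 %*% t(red$V)
      norm(KW_vox - diag(4), "F") + norm(KX_vox, "F")
    }))
  })
  expect_true(all(diff(err) < 0))     # consistency as N doubles
  st <- gen(400, seed = 11)
  red <- reduce_stack(demean(st)$stack)
  bl <- estimate_cov_blocks(red)
  KW_vox <- red$V %*% bl$KW %*% t(red$V)
  expect_lt(max(abs(KW_vox - diag(4))), 0.25)
})

test_that("eigendecomposition handles diagonal blocks and truncation", {
  r <- 2
  blocks <- structure(list(K00 = diag(c(4, 1)), K01 = matrix(0, r, r),
                           K10 = matrix(0, r, r), K11 = matrix(0, r, r),
                           KW = diag(c(0.5, 0)), r = r),
                      class = "cov_blocks")
  fit <- eigendecompose(blocks)
  expect_equal(fit$lambda_x, c(4, 1))
  expect_equal(abs(fit$A_x0), diag(2), tolerance = 1e-12)
  expect_true(all(fit$A_x1 == 0))
  # variance shares and longitudinal ratios: lambda (3,1) + (1)
  stacked <- diag(c(3, 0, 1, 0))      # baseline-only 3, longitudinal-only 1
  blocks2 <- structure(list(K00 = diag(c(3, 0)), K01 = matrix(0, 2, 2),
                            K10 = matrix(0, 2, 2), K11 = diag(c(1, 0)),
                            KW = diag(c(1, 0)), r = 2),
                       class = "cov_blocks")
  fit2 <- eigendecompose(blocks2)
  vt <- variance_table(fit2)
  expect_equal(vt$var_share, c(0.6, 0.2, 0.2))
  expect_equal(vt$longitudinal_ratio[1:2], c(0, 1))
  expect_equal(sum(vt$var_share), 1)
  # pve = 1 keeps every positive component, zero/negative are discarded
  fit3 <- eigendecompose(blocks2, pve = 1)
  expect_equal(length(fit3$lambda_x), 2L)
  blocks_neg <- blocks2
  blocks_neg$K00 <- -diag(2); blocks_neg$K11 <- -diag(2)
  expect_warning(fit4 <- eigendecompose(blocks_neg, n_w = 1),
                 regexp = "no positive")
  expect_equal(length(fit4$lambda_x), 0L)
})

test_that("eigenvalues and eigenvectors are recovered from constructed blocks", {
  set.seed(12)
  r <- 6
  Q <- qr.Q(qr(matrix(rnorm(2 * r * 2), 2 * r, 2)))
  lam <- c(5, 2)
  KX <- Q %*% diag(lam) %*% t(Q)
  blocks <- structure(list(K00 = KX[1:r, 1:r], K01 = KX[1:r, r + 1:r],
                           K10 = KX[r + 1:r, 1:r], K11 = KX[r + 1:r, r + 1:r],
                           KW = diag(r) * 0, r = r),
                      class = "cov_blocks")
  fit <- suppressWarnings(eigendecompose(blocks, n_w = 0))
  expect_equal(length(fit$lambda_x), 2L)
  expect_equal(fit$lambda_x, lam, tolerance = 1e-6)
  est <- rbind(fit$A_x0, fit$A_x1)
  expect_lt(max(principal_angles(Q, est)), 1e-4)
  # unit-norm invariant of the stacked eigenvectors
  expect_equal(colSums(fit$A_x0^2) + colSums(fit$A_x1^2), rep(1, 2),
               tolerance = 1e-8)
})

test_that("scores are recovered exactly in the noiseless linear model", {
  comps <- random_components(p = 30, n_x = 2, n_w = 0, seed = 13)
  sim <- simulate_from_model(comps$phi_x0, comps$phi_x1, phi_w = NULL,
                             lambda_x = c(4, 1), lambda_w = NULL,
                             subject_id = rep(sprintf("s%02d", 1:12), each = 3),
                             time = rep(0:2, 12), seed = 14)
  red <- reduce_stack(sim$stack)   # data already zero-mean in the model sense
  A_x0 <- crossprod(red$V, comps$phi_x0)
  A_x1 <- crossprod(red$V, comps$phi_x1)
  fit <- structure(list(lambda_x = c(4, 1), lambda_w = numeric(0),
                        A_x0 = A_x0, A_x1 = A_x1,
                        A_w = matrix(0, length(red$S), 0),
                        var_total = 5, xi = NULL, zeta = NULL,
                        reduced = red),
                   class = "lfpca_fit")
  fit <- estimate_scores(fit)
  expect_equal(unname(fit$xi), unname(sim$xi), tolerance = 1e-8)
})

test_that("scores are identical in reduced and full space", {
  st <- random_stack(p = 40, n_subjects = 8, visits = 3, seed = 15)
  dm <- demean(st)
  fit <- lfpca(st, n_x = 3, n_w = 2)
  red <- fit$reduced
  phi <- backproject(fit, "subject")
  phi_w <- backproject(fit, "visit")$phi_w
  cols <- split(seq_along(red$subject_id),
                factor(red$subject_id, levels = unique(red$subject_id)))
  for (i in seq_along(cols)) {
    jj <- cols[[i]]
    BX <- do.call(rbind, lapply(red$time[jj], function(t)
      phi$phi_x0 + t * phi$phi_x1))
    BW <- kronecker(diag(length(jj)), phi_w)
    B <- cbind(BX, BW)
    y <- as.vector(dm$stack$data[, jj])
    omega <- qr.solve(crossprod(B), crossprod(B, y))
    expect_equal(unname(fit$xi[i, ]), unname(omega[1:3]), tolerance = 1e-9)
  }
})

test_that("single-component projection score at t = 0", {
  p <- 10
  phi <- rep(1 / sqrt(p), p)
  data <- cbind(phi, phi, phi, phi)
  st <- image_stack(data, subject_id = rep(c("a", "b"), each = 2),
                    time = rep(0, 4), recenter_times = FALSE)
  red <- reduce_stack(st)
  fit <- structure(list(lambda_x = 1, lambda_w = numeric(0),
                        A_x0 = crossprod(red$V, phi),
                        A_x1 = matrix(0, length(red$S), 1),
                        A_w = matrix(0, length(red$S), 0),
                        var_total = 1, xi = NULL, zeta = NULL, reduced = red),
                   class = "lfpca_fit")
  fit <- estimate_scores(fit)
  expect_equal(unname(fit$xi[, 1]), c(1, 1), tolerance = 1e-10)
})

test_that("back-projection preserves norms and round-trips", {
  st <- random_stack(p = 25, n_subjects = 5, visits = 3, seed = 16)
  fit <- lfpca(st, n_x = 2, n_w = 1)
  V <- fit$reduced$V
  maps <- backproject(fit, "subject")
  # A = e1 -> first column of V
  e1 <- replace(rep(0, length(fit$reduced$S)), 1, 1)
  expect_equal(as.vector(V %*% e1), V[, 1])
  expect_equal(sqrt(sum(maps$phi_x0[, 1]^2) + sum(maps$phi_x1[, 1]^2)), 1,
               tolerance = 1e-8)
  expect_equal(crossprod(V, V %*% fit$A_x0), fit$A_x0, tolerance = 1e-10)
  expect_error(backproject(fit, "subject", components = 99),
               class = "longvbm_index_error")
  # trajectory: t = 0 is the baseline map; increments equal phi_x1
  tr <- component_trajectory(fit, 1, times = c(0, 1, 2))
  expect_equal(tr[, 1], as.vector(maps$phi_x0[, 1]))
  expect_equal(tr[, 3] - tr[, 2], as.vector(maps$phi_x1[, 1]), tolerance = 1e-12)
})

test_that("fit invariants hold after a full pipeline run and serialization", {
  comps <- random_components(p = 35, n_x = 2, n_w = 2, seed = 17)
  sim <- simulate_from_model(comps$phi_x0, comps$phi_x1, comps$phi_w,
                             lambda_x = c(6, 2), lambda_w = c(1, 0.3),
                             subject_id = rep(sprintf("s%02d", 1:25), each = 4),
                             time = rep(0:3, 25), seed = 18)
  fit <- lfpca(sim$stack)
  expect_equal(colSums(fit$A_x0^2) + colSums(fit$A_x1^2),
               rep(1, length(fit$lambda_x)), tolerance = 1e-8)
  expect_equal(colSums(fit$A_w^2), rep(1, length(fit$lambda_w)),
               tolerance = 1e-8)
  stacked <- rbind(fit$A_x0, fit$A_x1)
  expect_lt(max(abs(crossprod(stacked) - diag(length(fit$lambda_x)))), 1e-8)
  vt <- variance_table(fit)
  expect_true(all(vt$var_share >= 0))
  expect_equal(sum(vt$var_share), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$lambda_x) <= 0))
  # JSON archive round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_lfpca(fit, f)
  fit2 <- read_lfpca(f)
  expect_equal(fit2$lambda_x, fit$lambda_x)
  expect_equal(unname(fit2$A_x0), unname(fit$A_x0))
  expect_equal(unname(fit2$xi), unname(fit$xi))
  expect_equal(variance_table(fit2), variance_table(fit))
})
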