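make_noise_stack <- function(p, N, visits, seed, f = function(t) 0 * t,
                             noise_sd = 1) {
  set.seed(seed)
  tt <- rep(seq_len(visits) - 1, N)
  subj <- rep(sprintf("s%03d", seq_len(N)), each = visits)
  Y <- matrix(rnorm(p * N * visits, sd = noise_sd), nrow = p)
  Y <- Y + rep(f(tt), each = p)
  image_stack(Y, subject_id = subj, time = tt)
}

test_that("a noiseless linear trend is fitted exactly", {
  tt <- rep(0:2, 5)
  subj <- rep(sprintf("s%d", 1:5), each = 3)
  st <- image_stack(matrix(2 + 3 * tt, 1), subj, time = tt)
  res <- fit_voxelwise(st)
  expect_equal(res$beta0, 2, tolerance = 1e-8)
  expect_equal(res$beta1, 3, tolerance = 1e-8)
  # constant voxel is flagged degenerate with p = 1
  stc <- image_stack(matrix(1, 1, 15), subj, time = tt)
  resc <- fit_voxelwise(stc)
  expect_equal(resc$p1, 1)
  expect_equal(resc$convergence, 3L)
})

test_that("voxelwise ML matches lme4 on a simulated voxel", {
  skip_if_not_installed("lme4")
  set.seed(21)
  N <- 30; visits <- 4
  tt <- rep(0:3, N)
  subj <- rep(sprintf("s%02d", seq_len(N)), each = visits)
  idx <- match(subj, unique(subj))
  b0 <- rnorm(N, 0, 0.8); b1 <- rnorm(N, 0, 0.3)
  y <- 1.5 + 0.4 * tt + b0[idx] + b1[idx] * tt + rnorm(N * visits, 0, 0.5)
  st <- image_stack(matrix(y, 1), subj, time = tt)
  res <- fit_voxelwise(st)
  m <- lme4::lmer(y ~ tt + (tt | subj), REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(res$beta1, unname(lme4::fixef(m)[2]), tolerance = 1e-4)
  expect_equal(res$beta0, unname(lme4::fixef(m)[1]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(res$sigma_eps_sq, vc$vcov[4], tolerance = 1e-3)
  expect_equal(res$sigma0_sq, vc$vcov[1], tolerance = 1e-3)
})

test_that("BY adjustment matches the hand-computed step-up example", {
  out <- by_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.1)
  # c(4) = 25/12; adjusted_k = min over step-up of 4 * c(4) * p_(k) / k = 1/12
  expect_equal(out$adjusted, rep(1 / 12, 4), tolerance = 1e-12)
  expect_true(all(out$reject))
  out1 <- by_fdr(rep(1, 5), q = 0.05)
  expect_false(any(out1$reject))
  expect_identical(by_fdr(numeric(0))$adjusted, numeric(0))
  expect_error(by_fdr(c(0.5, 1.2)), class = "longvbm_validation_error")
})

test_that("BY decisions match enumeration and dominate BH", {
  set.seed(22)
  for (i in 1:100) {
    m <- sample(2:12, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    out <- by_fdr(p, q)
    expect_identical(out$reject, by_stepup_oracle(p, q))
    expect_true(all(out$adjusted >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(out$adjusted >= p - 1e-12))
    expect_true(all(out$adjusted <= 1))
  }
})

test_that("cluster extent thresholding matches hand-worked 2D cases", {
  geom <- list(grid_shape = c(5L, 5L, 1L), mask_index = 1:25)
  tmap <- rep(1, 25)
  # L-shape: (1,1),(2,1),(2,2)
  rej <- rep(FALSE, 25); rej[c(1, 2, 7)] <- TRUE
  expect_equal(nrow(cluster_extent(rej, tmap, geom, min_extent = 20)), 0L)
  tab <- cluster_extent(rej, tmap, geom, min_extent = 2)
  expect_equal(tab$size, 3L)
  expect_equal(c(tab$cog_x, tab$cog_y), c(mean(c(1, 2, 2)), mean(c(1, 1, 2))))
  expect_equal(tab$sign, "enlargement")
  # diagonal voxels: one cluster under 8-connectivity, two under 4
  rej2 <- rep(FALSE, 25); rej2[c(1, 7)] <- TRUE
  expect_equal(nrow(cluster_extent(rej2, tmap, geom, 1, connectivity = 8)), 1L)
  expect_equal(nrow(cluster_extent(rej2, tmap, geom, 1, connectivity = 4)), 2L)
  # extreme voxel: maximum t for positive, minimum for negative clusters
  tmap2 <- c(5, 2, rep(1, 23)); tmap2[7] <- 9
  tab2 <- cluster_extent(rej, tmap2, geom, min_extent = 1)
  expect_equal(tab2$t_extreme, 9)
  expect_equal(c(tab2$x, tab2$y), c(2, 2))
  tabn <- cluster_extent(rej, -tmap2, geom, min_extent = 1)
  expect_equal(tabn$t_extreme, -9)
  expect_equal(tabn$sign, "atrophy")
})

test_that("cluster sizes sum to the rejected count and match flood fill", {
  set.seed(23)
  for (rep in 1:5) {
    grid <- c(12L, 12L, 1L)
    geom <- list(grid_shape = grid, mask_index = seq_len(144))
    rej <- runif(144) < 0.25
    tmap <- rnorm(144)
    for (conn in c(4L, 8L)) {
      tab <- cluster_extent(rej, tmap, geom, min_extent = 1,
                            connectivity = conn)
      expect_equal(sum(tab$size[tab$sign == "enlargement"]),
                   sum(rej & tmap > 0))
      expect_equal(sum(tab$size[tab$sign == "atrophy"]),
                   sum(rej & tmap < 0))
      # component partition matches an independent flood fill
      sel <- which(rej & tmap > 0)
      if (length(sel) > 1) {
        ours <- longvbm:::label_components(sel, grid, conn)
        oracle <- flood_fill_labels(sel, grid, conn)
        # same partition up to label permutation
        expect_equal(length(unique(ours)), length(unique(oracle)))
        expect_true(all(tapply(oracle, ours, function(z)
          length(unique(z))) == 1))
      }
    }
  }
})

test_that("vbm wrapper ties the stages together", {
  st <- make_noise_stack(p = 50, N = 12, visits = 3, seed = 24,
                         f = function(t) 0.0 * t)
  res <- vbm(st, q = 0.05, min_extent = 2)
  expect_length(res$q1, 50)
  expect_true(all(res$q1 >= res$p1 - 1e-12))
  expect_true(all(res$p1 >= 0 & res$p1 <= 1))
  expect_true(all(res$reject == (res$q1 <= 0.05)))
  expect_s3_class(res$clusters, "cluster_table")
})
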