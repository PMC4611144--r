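#' Parameters of the geometric longitudinal phantom
#'
#' The phantom renders 2D images with four canonical structures on a square
#' grid: background (B), a large white-matter square (W), a small ventricle
#' square (V) strictly inside W, and a gray-matter rectangle (G) below W.
#' Across subjects it draws five independent latent variables: a W-intensity
#' deviation, a rigid integer shift (dx, dy) applied to all structures and
#' constant across a subject's visits (emulating a subject-specific
#' registration error), integer size deviations of V and G, and a scalar
#' longitudinal factor. Over visits, structure intensities and sizes change
#' linearly in time through (i) population-mean trend parameters shared by
#' all subjects (ventricular enlargement, gray/white-matter atrophy) and
#' (ii) loadings on the zero-mean subject longitudinal factor; finally each
#' visit receives i.i.d. pixel noise (optionally smoothed).
#'
#' Geometry defaults scale with the grid so that a smaller grid yields the
#' same layout: W spans 20-80% of each axis vertically offset upward, V is a
#' centered square of half-width 15.5% of the grid, and G is a flat rectangle
#' near the bottom. Intensities are dimensionless tissue-density-like units.
#'
#' @param grid integer vector of 2 pixel dimensions.
#' @param n_subjects number of subjects.
#' @param visit_times numeric vector of visit times shared by all subjects
#'   (unit: years from baseline).
#' @param base_intensity named numeric vector with entries `B`, `W`, `V`, `G`.
#' @param sd_w_intensity SD of the subject W-intensity deviation.
#' @param max_shift maximal rigid shift in pixels; shifts are drawn
#'   independently per axis, uniform on `-max_shift:max_shift`.
#' @param sd_v_size,sd_g_size SD (pixels) of the rounded-normal symmetric
#'   dilation/erosion of V and G.
#' @param long_sd SD of the zero-mean subject longitudinal factor.
#' @param load_v_int,load_v_area,load_g_int,load_g_area,load_w_int loadings
#'   of the longitudinal factor (per unit factor per unit time) on V
#'   intensity/area (positive), G intensity/area (negative) and W intensity
#'   (negative). Area loadings are in pixels of symmetric dilation.
#' @param trend_v_int,trend_v_area,trend_g_int,trend_g_area,trend_w_int
#'   population-mean change per unit time applied to every subject:
#'   ventricle intensity/area increase, gray/white-matter intensity decrease
#'   and (sub-threshold by default) gray-matter area decrease.
#' @param sd_noise SD of the visit-specific i.i.d. pixel noise.
#' @param noise_fwhm optional FWHM (pixels) to spatially smooth the visit
#'   noise; 0 keeps it i.i.d.
#' @param seed integer seed recorded in the parameters and used by
#'   [simulate_phantom()]; `NULL` leaves the RNG state alone.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(grid = c(200L, 200L),
                           n_subjects = 50L,
                           visit_times = 0:3,
                           base_intensity = c(B = 0, W = 0.8, V = 0.1, G = 0.6),
                           sd_w_intensity = 0.07,
                           max_shift = 1L,
                           sd_v_size = 0.3,
                           sd_g_size = 0.75,
                           long_sd = 1,
                           load_v_int = 0.2,
                           load_v_area = 0.05,
                           load_g_int = -0.005,
                           load_g_area = -0.03,
                           load_w_int = -0.004,
                           trend_v_int = 0.02,
                           trend_v_area = 0.8,
                           trend_g_int = -0.002,
                           trend_g_area = -0.1,
                           trend_w_int = -0.002,
                           sd_noise = 0.04,
                           noise_fwhm = 0,
                           seed = NULL) {
  grid <- as.integer(rep_len(grid, 2L))
  p <- structure(as.list(environment()), class = "phantom_params")
  sds <- c(sd_w_intensity, sd_v_size, sd_g_size, long_sd, sd_noise)
  if (any(sds < 0)) stop_validation("all phantom SDs must be >= 0")
  if (max_shift < 0) stop_validation("max_shift must be >= 0")
  p$geometry <- phantom_geometry(grid)
  check_phantom_geometry(p)
  p
}

# Structure bounds: half-open integer pixel ranges [x0, x1] x [y0, y1].
phantom_geometry <- function(grid) {
  g1 <- grid[1]; g2 <- grid[2]
  W <- c(x0 = round(0.20 * g1) + 1L, x1 = round(0.80 * g1),
         y0 = round(0.10 * g2) + 1L, y1 = round(0.70 * g2))
  v_half <- max(2L, round(0.155 * min(grid)))
  V <- c(cx = round((W["x0"] + W["x1"]) / 2), cy = round((W["y0"] + W["y1"]) / 2),
         half = v_half)
  names(V) <- c("cx", "cy", "half")
  G <- c(x0 = round(0.20 * g1) + 1L, x1 = round(0.80 * g1),
         y0 = round(0.82 * g2) + 1L, y1 = round(0.90 * g2))
  list(W = W, V = V, G = G)
}

check_phantom_geometry <- function(p) {
  geo <- p$geometry
  tmax <- max(abs(p$visit_times))
  # worst-case dilation: size deviations are truncated at 3 SD and the
  # longitudinal factor at 4 SD when drawn, so these bounds are exact
  slack_v <- ceiling(3 * p$sd_v_size + tmax * (abs(p$trend_v_area) +
                     4 * p$long_sd * abs(p$load_v_area)))
  slack_g <- ceiling(3 * p$sd_g_size + tmax * (abs(p$trend_g_area) +
                     4 * p$long_sd * abs(p$load_g_area)))
  s <- p$max_shift
  geo_ok <-
    geo$W["x0"] - s >= 1 && geo$W["x1"] + s <= p$grid[1] &&
    geo$W["y0"] - s >= 1 && geo$G["y1"] + s + slack_g <= p$grid[2] &&
    geo$G["x0"] - s - slack_g >= 1 && geo$G["x1"] + s + slack_g <= p$grid[1] &&
    geo$V["half"] + slack_v + 1 <
      min(geo$V["cx"] - geo$W["x0"], geo$W["x1"] - geo$V["cx"],
          geo$V["cy"] - geo$W["y0"], geo$W["y1"] - geo$V["cy"]) &&
    geo$W["y1"] + s < geo$G["y0"] - s - slack_g
  if (!geo_ok)
    stop_validation("phantom geometry leaves the grid (or V leaves W) after maximal shift/dilation")
  invisible(TRUE)
}

fill_rect <- function(img, x0, x1, y0, y1, value) {
  img[max(1L, x0):min(nrow(img), x1), max(1L, y0):min(ncol(img), y1)] <- value
  img
}

# Render the noiseless image of one subject at time t given its latents.
render_phantom_image <- function(p, t, lat) {
  geo <- p$geometry
  b <- p$base_intensity
  img <- matrix(b[["B"]], p$grid[1], p$grid[2])
  dx <- lat$shift_x; dy <- lat$shift_y
  u <- lat$long_factor

  w_int <- b[["W"]] + lat$w_intensity_dev + t * (p$trend_w_int + p$load_w_int * u)
  img <- fill_rect(img, geo$W["x0"] + dx, geo$W["x1"] + dx,
                   geo$W["y0"] + dy, geo$W["y1"] + dy, w_int)

  g_grow <- lat$g_size_dev + round(t * (p$trend_g_area + p$load_g_area * u))
  if (geo$G["x1"] - geo$G["x0"] + 2 * g_grow >= 0 &&
      geo$G["y1"] - geo$G["y0"] + 2 * g_grow >= 0) {
    g_int <- b[["G"]] + t * (p$trend_g_int + p$load_g_int * u)
    img <- fill_rect(img, geo$G["x0"] + dx - g_grow, geo$G["x1"] + dx + g_grow,
                     geo$G["y0"] + dy - g_grow, geo$G["y1"] + dy + g_grow, g_int)
  }

  v_half <- geo$V["half"] + lat$v_size_dev +
    round(t * (p$trend_v_area + p$load_v_area * u))
  v_half <- max(1L, v_half)
  v_int <- b[["V"]] + t * (p$trend_v_int + p$load_v_int * u)
  img <- fill_rect(img, geo$V["cx"] + dx - v_half, geo$V["cx"] + dx + v_half,
                   geo$V["cy"] + dy - v_half, geo$V["cy"] + dy + v_half, v_int)
  img
}

#' Simulate a longitudinal phantom stack with ground truth
#'
#' Draws the five subject latent variables, renders every subject-visit
#' image, adds visit-specific pixel noise and returns the stack (full-grid
#' mask) together with a per-subject truth table for recovery testing.
#'
#' With the same `seed` in `params`, the output is bitwise identical.
#'
#' @param params a [phantom_params()] object.
#' @return list with elements `stack` (an [image_stack]) and `truth`
#'   (data frame with one row per subject: `subject_id`, `w_intensity_dev`,
#'   `shift_x`, `shift_y`, `v_size_dev`, `g_size_dev`, `long_factor`).
#' @export
simulate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  check_phantom_geometry(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- params$n_subjects
  times <- params$visit_times
  Jv <- length(times)
  ids <- sprintf("S%03d", seq_len(N))

  clamp <- function(x, b) pmin(pmax(x, -b), b)
  truth <- data.frame(
    subject_id = ids,
    w_intensity_dev = rnorm(N, 0, params$sd_w_intensity),
    shift_x = sample(-params$max_shift:params$max_shift, N, replace = TRUE),
    shift_y = sample(-params$max_shift:params$max_shift, N, replace = TRUE),
    v_size_dev = round(clamp(rnorm(N, 0, params$sd_v_size),
                             3 * params$sd_v_size)),
    g_size_dev = round(clamp(rnorm(N, 0, params$sd_g_size),
                             3 * params$sd_g_size)),
    long_factor = clamp(rnorm(N, 0, params$long_sd), 4 * params$long_sd),
    stringsAsFactors = FALSE)

  npix <- prod(params$grid)
  data <- matrix(NA_real_, nrow = npix, ncol = N * Jv)
  smooth_noise <- params$noise_fwhm > 0
  if (smooth_noise) {
    sig <- fwhm_to_sigma(params$noise_fwhm)
    K1 <- gaussian_conv_matrix(params$grid[1], sig)
    K2 <- gaussian_conv_matrix(params$grid[2], sig)
  }
  col <- 0L
  for (i in seq_len(N)) {
    lat <- truth[i, ]
    for (j in seq_len(Jv)) {
      img <- render_phantom_image(params, times[j], lat)
      if (params$sd_noise > 0) {
        noise <- matrix(rnorm(npix, 0, params$sd_noise),
                        params$grid[1], params$grid[2])
        if (smooth_noise) noise <- K1 %*% noise %*% t(K2)
        img <- img + noise
      }
      col <- col + 1L
      data[, col] <- as.vector(img)
    }
  }
  mask <- array(1L, dim = c(params$grid, 1L))
  stack <- image_stack(data,
                       subject_id = rep(ids, each = Jv),
                       time = rep(times, N),
                       mask = mask,
                       visit_index = rep(seq_len(Jv), N),
                       voxel_size = c(1, 1, 1))
  list(stack = stack, truth = truth)
}

#' Pixel masks of the phantom structure regions
#'
#' Region masks at the unshifted base geometry, as used when summarizing
#' which structures a voxelwise analysis flags. The V region is grown by
#' `grow_v` pixels so it covers the enlargement ring traced out by the
#' population trend and small registration shifts.
#'
#' @param params a [phantom_params()] object.
#' @param grow_v pixels by which to dilate the V region (default covers the
#'   mean-trend ring plus the default maximal shift).
#' @return list of logical vectors (`W`, `V`, `G`) in unfolded pixel order;
#'   `W` excludes the grown V region.
#' @export
phantom_regions <- function(params, grow_v = NULL) {
  geo <- params$geometry
  if (is.null(grow_v))
    grow_v <- params$max_shift +
      ceiling(max(abs(params$visit_times)) * abs(params$trend_v_area))
  img <- matrix(0L, params$grid[1], params$grid[2])
  W <- fill_rect(img, geo$W["x0"], geo$W["x1"], geo$W["y0"], geo$W["y1"], 1L)
  V <- fill_rect(img, geo$V["cx"] - geo$V["half"] - grow_v,
                 geo$V["cx"] + geo$V["half"] + grow_v,
                 geo$V["cy"] - geo$V["half"] - grow_v,
                 geo$V["cy"] + geo$V["half"] + grow_v, 1L)
  G <- fill_rect(img, geo$G["x0"], geo$G["x1"], geo$G["y0"], geo$G["y1"], 1L)
  list(W = as.vector(W == 1L & V != 1L), V = as.vector(V == 1L),
       G = as.vector(G == 1L))
}

#' Simulate directly from the reduced-rank longitudinal model
#'
#' Generates images exactly from the truncated random intercept/slope
#' model: `y_ij = Phi_X0 xi_i + t_ij Phi_X1 xi_i + Phi_W zeta_ij` (plus an
#' optional mean map), with scores drawn as independent zero-mean Gaussians
#' of the given variances. Used for parameter-recovery testing with known
#' components.
#'
#' @param phi_x0,phi_x1 `p x N_X` matrices; the stacked columns
#'   `(phi_x0[,k]; phi_x1[,k])` must be orthonormal.
#' @param phi_w `p x N_W` matrix with orthonormal columns, or `NULL` for a
#'   model without a visit-specific process.
#' @param lambda_x,lambda_w positive score variances.
#' @param subject_id,time design vectors, one entry per image.
#' @param mean_map optional `p`-vector added to every image.
#' @param seed optional integer seed.
#' @return list with `stack` (an [image_stack] on a `p x 1 x 1` grid),
#'   `xi` (`N x N_X`) and `zeta` (`J x N_W`) true scores.
#' @export
simulate_from_model <- function(phi_x0, phi_x1, phi_w, lambda_x, lambda_w,
                                subject_id, time, mean_map = NULL,
                                seed = NULL) {
  phi_x0 <- as.matrix(phi_x0); phi_x1 <- as.matrix(phi_x1)
  if (is.null(phi_w)) phi_w <- matrix(0, nrow(phi_x0), 0)
  phi_w <- as.matrix(phi_w)
  if (is.null(lambda_w)) lambda_w <- numeric(0)
  stacked <- rbind(phi_x0, phi_x1)
  check_orthonormal(stacked, "stacked (phi_x0; phi_x1)")
  if (ncol(phi_w) > 0) check_orthonormal(phi_w, "phi_w")
  if (length(lambda_x) != ncol(phi_x0) || length(lambda_w) != ncol(phi_w))
    stop_dimension("variance vectors must match the number of components")
  if (!is.null(seed)) set.seed(seed)
  subject_id <- as.character(subject_id)
  time <- as.numeric(time)
  J <- length(time)
  uid <- unique(subject_id)
  N <- length(uid)
  xi <- matrix(rnorm(N * length(lambda_x)), N) %*% diag(sqrt(lambda_x),
                                                        length(lambda_x))
  zeta <- matrix(rnorm(J * length(lambda_w)), J) %*% diag(sqrt(lambda_w),
                                                          length(lambda_w))
  rownames(xi) <- uid
  idx <- match(subject_id, uid)
  data <- matrix(0, nrow(phi_x0), J)
  for (j in seq_len(J)) {
    data[, j] <- phi_x0 %*% xi[idx[j], ] + time[j] * (phi_x1 %*% xi[idx[j], ]) +
      phi_w %*% zeta[j, ]
  }
  if (!is.null(mean_map)) data <- data + mean_map
  stack <- image_stack(data, subject_id = subject_id, time = time,
                       recenter_times = FALSE)
  # image_stack may reorder columns; zeta rows follow the same order
  ord <- order(subject_id, time)
  list(stack = stack, xi = xi, zeta = zeta[ord, , drop = FALSE])
}

check_orthonormal <- function(M, what, tol = 1e-6) {
  G <- crossprod(M)
  if (max(abs(G - diag(ncol(M)))) > tol)
    stop_validation(sprintf("%s columns are not orthonormal", what))
  invisible(TRUE)
}
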