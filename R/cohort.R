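# Synthetic cohorts with the statistical structure the analysis assumes:
#
#   transformed fiducial j of subject k:
#       F_jk = T_j + s_k * Phi(T_j) + R_k(T_j) + eta_jk
#   electrode tip (per side):
#       X_k  = E + s_k * Phi(E) + R_k(E) + delta_k
#
# with s_k ~ N(0, score_sd^2) a per-subject latent misregistration score,
# Phi a fixed smooth Gaussian-bump vector field (the shared pattern),
# R_k an independent smooth residual field per subject (fresh random bumps),
# eta iid per-axis rater localization noise and delta iid per-axis surgical
# deviation.  Everything is reproducible bit-for-bit from (spec, seed).

#' Specify a synthetic cohort
#'
#' Defaults describe a plausible STN-DBS-like cohort in template space: the
#' shared pattern is strongest near the midbrain with a dominantly
#' anteroposterior (y) direction, rater noise is sub-voxel, and surgical
#' deviation dominates tip variance.  Pattern bump centers sit on the
#' midline so the pattern is identical at the two (mirrored) electrode
#' targets.
#'
#' @param n_subjects number of subjects (>= 2); each has 2 electrodes (R/L).
#' @param pattern_centers matrix (bumps x 3) of Gaussian bump centers, mm.
#' @param pattern_widths per-bump width (mm, > 0).
#' @param pattern_amplitudes matrix (bumps x 3) of bump amplitude vectors, mm.
#' @param score_sd sd of the per-subject latent score (dimensionless).
#' @param residual_sd per-axis sd of each residual bump amplitude, mm.
#' @param residual_n_bumps residual bumps per subject.
#' @param residual_width residual bump width, mm.
#' @param residual_box 3 x 2 matrix (rows x/y/z) bounding residual bump
#'   centers, mm.
#' @param localization_sd per-axis rater localization noise sd, mm.
#' @param surgical_sd per-axis surgical (application) deviation sd, mm.
#' @param electrode_target right-side target, mm; the left target is its
#'   x-mirror.
#' @param fiducial_truth template-space [fiducial_set()] of true landmark
#'   positions.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24L,
                        pattern_centers = rbind(c(0, -20, -8), c(0, -32, -15)),
                        pattern_widths = c(20, 18),
                        pattern_amplitudes = rbind(c(0.25, 0.90, 0.35),
                                                   c(0.10, 0.60, 0.45)),
                        score_sd = 1,
                        residual_sd = 0.5,
                        residual_n_bumps = 12L,
                        residual_width = 15,
                        residual_box = cbind(c(-40, -60, -50), c(40, 30, 30)),
                        localization_sd = 0.4,
                        surgical_sd = 1.5,
                        electrode_target = c(12, -13, -7),
                        fiducial_truth = template_consensus("synthetic32")) {
  pattern_centers <- matrix(as.numeric(pattern_centers), ncol = 3)
  pattern_amplitudes <- matrix(as.numeric(pattern_amplitudes), ncol = 3)
  stopifnot(n_subjects >= 2,
            nrow(pattern_centers) >= 1,
            nrow(pattern_centers) == nrow(pattern_amplitudes),
            length(pattern_widths) == nrow(pattern_centers),
            all(pattern_widths > 0), residual_width > 0,
            score_sd >= 0, residual_sd >= 0,
            localization_sd >= 0, surgical_sd >= 0,
            inherits(fiducial_truth, "fiducial_set"))
  residual_box <- matrix(as.numeric(residual_box), nrow = 3)
  structure(list(n_subjects = as.integer(n_subjects),
                 pattern_centers = pattern_centers,
                 pattern_widths = as.numeric(pattern_widths),
                 pattern_amplitudes = pattern_amplitudes,
                 score_sd = score_sd, residual_sd = residual_sd,
                 residual_n_bumps = as.integer(residual_n_bumps),
                 residual_width = residual_width,
                 residual_box = residual_box,
                 localization_sd = localization_sd,
                 surgical_sd = surgical_sd,
                 electrode_target = as.numeric(electrode_target),
                 fiducial_truth = fiducial_truth),
            class = "cohort_spec")
}

gaussian_bump_field <- function(centers, widths, amplitudes) {
  force(centers); force(widths); force(amplitudes)
  function(points) {
    pts <- to_points_matrix(points)
    out <- matrix(0, nrow(pts), 3)
    for (b in seq_len(nrow(centers))) {
      d2 <- (pts[, 1] - centers[b, 1])^2 + (pts[, 2] - centers[b, 2])^2 +
            (pts[, 3] - centers[b, 3])^2
      w <- exp(-d2 / (2 * widths[b]^2))
      out <- out + outer(w, amplitudes[b, ])
    }
    out
  }
}

#' The shared misregistration pattern of a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return a function mapping an n x 3 matrix of template-space points (mm)
#'   to an n x 3 matrix of pattern displacement vectors (mm):
#'   `Phi(p) = sum_b amplitude_b * exp(-|p - c_b|^2 / (2 width_b^2))`.
#' @export
make_pattern <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gaussian_bump_field(spec$pattern_centers, spec$pattern_widths,
                      spec$pattern_amplitudes)
}

electrode_targets <- function(spec) {
  rbind(R = spec$electrode_target,
        L = spec$electrode_target * c(-1, 1, 1))
}

#' Simulate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the cohort is bit-reproducible given
#'   (spec, seed).  Random numbers are consumed strictly subject by subject,
#'   so cohorts are prefix-stable: the first k subjects are identical for any
#'   larger `n_subjects`.
#' @return list with `fiducial_sets` (per-subject template-space
#'   [fiducial_set()]s of transformed landmarks), `tips` (data frame
#'   `subject`, `side`, `x`, `y`, `z`), and `truth` (latent scores, pattern
#'   values at landmarks and targets, residual values, and planted surgical
#'   deviations).
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  phi <- make_pattern(spec)
  truth_fid <- spec$fiducial_truth
  Tj <- fiducial_coords(truth_fid)
  targets <- electrode_targets(spec)
  phi_fid <- phi(Tj)
  phi_tgt <- phi(targets)
  n_fid <- nrow(Tj)
  B <- spec$residual_n_bumps
  sets <- vector("list", spec$n_subjects)
  tips <- vector("list", spec$n_subjects)
  scores <- numeric(spec$n_subjects)
  deviations <- vector("list", spec$n_subjects)
  residual_tgt <- matrix(0, spec$n_subjects * 2, 3)
  for (k in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub-%03d", k)
    s_k <- stats::rnorm(1, 0, spec$score_sd)
    centers <- cbind(stats::runif(B, spec$residual_box[1, 1], spec$residual_box[1, 2]),
                     stats::runif(B, spec$residual_box[2, 1], spec$residual_box[2, 2]),
                     stats::runif(B, spec$residual_box[3, 1], spec$residual_box[3, 2]))
    amps <- matrix(stats::rnorm(B * 3, 0, spec$residual_sd), B, 3)
    R_k <- gaussian_bump_field(centers, rep(spec$residual_width, B), amps)
    eta <- matrix(stats::rnorm(n_fid * 3, 0, spec$localization_sd), n_fid, 3)
    delta <- matrix(stats::rnorm(6, 0, spec$surgical_sd), 2, 3)
    fid_obs <- Tj + s_k * phi_fid + R_k(Tj) + eta
    df <- as.data.frame(truth_fid)
    df$x <- fid_obs[, 1]; df$y <- fid_obs[, 2]; df$z <- fid_obs[, 3]
    sets[[k]] <- fiducial_set(df, subject_id = sid,
                              rater_id = "consensus-transformed",
                              space = "template",
                              provenance = "simulate_cohort")
    rt <- R_k(targets)
    residual_tgt[(2 * k - 1):(2 * k), ] <- rt
    tip_xyz <- targets + s_k * phi_tgt + rt + delta
    tips[[k]] <- data.frame(subject = sid, side = c("R", "L"),
                            x = tip_xyz[, 1], y = tip_xyz[, 2], z = tip_xyz[, 3],
                            stringsAsFactors = FALSE)
    scores[k] <- s_k
    deviations[[k]] <- delta
  }
  list(fiducial_sets = sets,
       tips = do.call(rbind, tips),
       truth = list(scores = scores,
                    pattern_at_fiducials = phi_fid,
                    pattern_at_targets = phi_tgt,
                    residual_at_targets = residual_tgt,
                    surgical_deviations = deviations,
                    targets = targets))
}

# analytic per-axis variance of the residual field at a point: bump centers
# are uniform over the box, amplitudes iid N(0, residual_sd^2) per axis, so
# Var[R(p)_axis] = residual_sd^2 * B * prod_d Integral(exp(-(p_d-c)^2/w^2))/L_d
# (the exponent halves twice: the bump kernel squared).
residual_variance_at <- function(spec, p) {
  w <- spec$residual_width
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  q <- 1
  for (d in 1:3) {
    lo <- spec$residual_box[d, 1]; hi <- spec$residual_box[d, 2]
    L <- hi - lo
    q <- q * (w * sqrt(pi) / 2) * (erf((hi - p[d]) / w) - erf((lo - p[d]) / w)) / L
  }
  spec$residual_sd^2 * spec$residual_n_bumps * q
}

# analytic same-axis covariance of the residual field between two points:
# centers uniform over the box, amplitudes iid per axis, bump kernel
# exp(-|p-c|^2/(2 w^2)), so
# Cov[R(p)_ax, R(q)_ax] =
#   residual_sd^2 * B * prod_d exp(-(p_d-q_d)^2/(4 w^2)) *
#     Integral_box(exp(-(c-m_d)^2/w^2))/L_d ,  m = (p+q)/2.
residual_covariance_between <- function(spec, p, q) {
  w <- spec$residual_width
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  cov <- spec$residual_sd^2 * spec$residual_n_bumps
  for (d in 1:3) {
    lo <- spec$residual_box[d, 1]; hi <- spec$residual_box[d, 2]
    L <- hi - lo
    m <- (p[d] + q[d]) / 2
    cov <- cov * exp(-(p[d] - q[d])^2 / (4 * w^2)) *
      (w * sqrt(pi) / 2) * (erf((hi - m) / w) - erf((lo - m) / w)) / L
  }
  cov
}

# population covariance blocks of the joint (stacked AFRE features, tip axes)
# vector under the generative model; features ordered AFID-major, axes x/y/z.
analytic_joint_covariance <- function(spec, afids) {
  truth <- spec$fiducial_truth
  idx <- match(afids, truth$afid_id)
  if (anyNA(idx)) stop("afids not present in fiducial_truth: ",
                       paste(afids[is.na(idx)], collapse = ", "))
  Tj <- fiducial_coords(truth)[idx, , drop = FALSE]
  E <- spec$electrode_target
  phi <- make_pattern(spec)
  phi_f <- as.numeric(t(phi(Tj)))               # length 3k, AFID-major
  phi_E <- as.numeric(phi(matrix(E, 1)))
  k <- length(afids)
  nf <- 3 * k
  s2 <- spec$score_sd^2
  Saa <- s2 * tcrossprod(phi_f)
  for (j in seq_len(k)) for (l in seq_len(k)) {
    kr <- residual_covariance_between(spec, Tj[j, ], Tj[l, ])
    for (ax in 1:3) {
      r <- 3 * (j - 1) + ax; c <- 3 * (l - 1) + ax
      Saa[r, c] <- Saa[r, c] + kr + if (r == c) spec$localization_sd^2 else 0
    }
  }
  Stt <- s2 * tcrossprod(phi_E) +
    diag(residual_covariance_between(spec, E, E) + spec$surgical_sd^2, 3)
  Sat <- s2 * outer(phi_f, phi_E)
  for (j in seq_len(k)) {
    kr <- residual_covariance_between(spec, Tj[j, ], E)
    for (ax in 1:3) Sat[3 * (j - 1) + ax, ax] <- Sat[3 * (j - 1) + ax, ax] + kr
  }
  list(Saa = Saa, Stt = Stt, Sat = Sat)
}

#' Expected attribution r-squared of a cohort spec
#'
#' The population value of the PrC1-on-PrC1 attribution regression under the
#' generative model, computed analytically: the joint covariance of the
#' stacked AFRE features and the tip displacement axes is built in closed
#' form (shared pattern, residual-field kernel with uniformly distributed
#' bump centers, localization and surgical noise), the population principal
#' axes are its leading eigenvectors, and
#' `r2 = (u_a' S_at u_t)^2 / ((u_a' S_aa u_a) (u_t' S_tt u_t))`.
#' To first order this equals the simpler ratio
#' `score_sd^2 |Phi(E)|^2 / (score_sd^2 |Phi(E)|^2 + Var[R(E)] + surgical_sd^2)`,
#' but it also accounts for the attenuation from estimating the latent score
#' through noisy fiducials and for residual-field covariance shared between
#' fiducials and target.  A spec with no shared pattern at the target is
#' degenerate and returns 0.
#'
#' @param spec a [cohort_spec()].
#' @param afids landmark subset whose stacked AFRE features carry the
#'   attribution (default the pipeline's subset).
#' @return expected r-squared in `[0, 1]`.
#' @export
theoretical_r2 <- function(spec, afids = c(2L, 3L, 4L, 14L)) {
  stopifnot(inherits(spec, "cohort_spec"))
  phi <- make_pattern(spec)
  P <- spec$score_sd^2 * sum(phi(matrix(spec$electrode_target, 1))^2)
  if (P == 0) return(0)
  S <- analytic_joint_covariance(spec, afids)
  u_a <- eigen(S$Saa, symmetric = TRUE)$vectors[, 1]
  u_t <- eigen(S$Stt, symmetric = TRUE)$vectors[, 1]
  num <- drop(crossprod(u_a, S$Sat %*% u_t))^2
  num / (drop(crossprod(u_a, S$Saa %*% u_a)) * drop(crossprod(u_t, S$Stt %*% u_t)))
}

#' Calibrate the surgical-noise level to a target attribution r-squared
#'
#' Solves `theoretical_r2(spec) = target` for `surgical_sd` (monotone
#' root-finding), leaving all other parameters fixed.
#'
#' @param spec a [cohort_spec()].
#' @param target desired r-squared in (0, 1].
#' @param afids landmark subset passed to [theoretical_r2()].
#' @return a new `cohort_spec` with `surgical_sd` replaced.
#' @export
calibrate_surgical_sd <- function(spec, target, afids = c(2L, 3L, 4L, 14L)) {
  stopifnot(target > 0, target <= 1)
  f <- function(s) {
    spec$surgical_sd <- s
    theoretical_r2(spec, afids) - target
  }
  if (f(0) < 0)
    stop("target r-squared unreachable: noise without surgical deviation ",
         "already leaves less than the target explained")
  if (f(0) == 0) { spec$surgical_sd <- 0; return(spec) }
  upper <- 1
  while (f(upper) > 0 && upper < 1e3) upper <- upper * 2
  spec$surgical_sd <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  spec
}

#' Coarse displacement-field rendering of one subject's warp
#'
#' Evaluates the subject's total smooth displacement (shared pattern times
#' the subject score plus the subject residual field) on a regular coarse
#' grid, for export as a NIfTI field and end-to-end transform tests.  Rater
#' localization noise is not part of the warp.
#'
#' @param spec a [cohort_spec()].
#' @param seed the cohort seed used with [simulate_cohort()].
#' @param subject subject index (1-based).
#' @param grid_n grid nodes per axis.
#' @param box 3 x 2 bounding box (defaults to the residual box padded 10 mm).
#' @return a [displacement_field()].
#' @export
subject_displacement_field <- function(spec, seed, subject, grid_n = 16L,
                                       box = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), subject >= 1,
            subject <= spec$n_subjects)
  if (is.null(box)) box <- spec$residual_box + cbind(c(-10, -10, -10), c(10, 10, 10))
  # replay the subject's random draws (subject-by-subject consumption order)
  set.seed(as.integer(seed))
  B <- spec$residual_n_bumps
  n_fid <- nrow(spec$fiducial_truth)
  s_k <- NA_real_; centers <- NULL; amps <- NULL
  for (k in seq_len(subject)) {
    s_k <- stats::rnorm(1, 0, spec$score_sd)
    centers <- cbind(stats::runif(B, spec$residual_box[1, 1], spec$residual_box[1, 2]),
                     stats::runif(B, spec$residual_box[2, 1], spec$residual_box[2, 2]),
                     stats::runif(B, spec$residual_box[3, 1], spec$residual_box[3, 2]))
    amps <- matrix(stats::rnorm(B * 3, 0, spec$residual_sd), B, 3)
    invisible(stats::rnorm(n_fid * 3))  # localization noise
    invisible(stats::rnorm(6))          # surgical deviations
  }
  phi <- make_pattern(spec)
  R_k <- gaussian_bump_field(centers, rep(spec$residual_width, B), amps)
  gx <- seq(box[1, 1], box[1, 2], length.out = grid_n)
  gy <- seq(box[2, 1], box[2, 2], length.out = grid_n)
  gz <- seq(box[3, 1], box[3, 2], length.out = grid_n)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  disp <- s_k * phi(nodes) + R_k(nodes)
  vec <- array(0, dim = c(grid_n, grid_n, grid_n, 3))
  for (ax in 1:3) vec[, , , ax] <- array(disp[, ax], dim = rep(grid_n, 3))
  aff <- diag(4)
  aff[1, 1] <- diff(gx[1:2]); aff[2, 2] <- diff(gy[1:2]); aff[3, 3] <- diff(gz[1:2])
  aff[1:3, 4] <- c(gx[1], gy[1], gz[1])
  displacement_field(vec, aff)
}
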