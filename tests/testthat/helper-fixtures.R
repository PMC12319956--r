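# Fixtures built in code: toy fiducial sets, small cohorts, and the
# independent oracles used by the derived-value tests.

toy_set <- function(xyz, labels = NULL, ids = NULL, subject = "sub-001",
                    rater = "r1", space = "subject") {
  xyz <- matrix(xyz, ncol = 3, byrow = FALSE)
  n <- nrow(xyz)
  if (is.null(labels)) labels <- afid_registry()$label[seq_len(n)]
  if (is.null(ids)) ids <- label_ids(labels)
  fiducial_set(data.frame(afid_id = ids, label = labels,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE),
               subject_id = subject, rater_id = rater, space = space)
}

label_ids <- function(labels) {
  reg <- afid_registry()
  idx <- match(labels, reg$label)
  ifelse(is.na(idx), 0L, reg$afid_id[idx])
}

random_set <- function(n = 5, subject = "sub-001", rater = "r1",
                       space = "subject") {
  toy_set(matrix(stats::runif(n * 3, -50, 50), n, 3),
          subject = subject, rater = rater, space = space)
}

# independent brute-force trilinear interpolation (scalar loop, no shared
# code with the implementation)
oracle_trilinear <- function(vectors, voxel_to_world, point) {
  v <- solve(voxel_to_world) %*% c(point, 1)
  v <- v[1:3]
  i <- pmin(floor(v), dim(vectors)[1:3] - 2)
  i <- pmax(i, 0)
  f <- v - i
  acc <- c(0, 0, 0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + w * vectors[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1, ]
  }
  acc
}

# exhaustive signed-rank null: every sign assignment of the nonzero
# differences, mid-ranks, two-sided p = min(1, 2 * min(tails))
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, 0)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exhaustive rank-sum null over all subsets of the pooled ranks
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  sums <- combn(r, n_a, sum)
  min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs)))
}

# small electrode-tip table with both sides
toy_tips <- function(n_subj = 6, seed = 42) {
  set.seed(seed)
  data.frame(subject = rep(sprintf("sub-%03d", seq_len(n_subj)), each = 2),
             side = rep(c("R", "L"), n_subj),
             x = stats::rnorm(2 * n_subj, c(12, -12), 1.5),
             y = stats::rnorm(2 * n_subj, -13, 1.5),
             z = stats::rnorm(2 * n_subj, -7, 1.5),
             stringsAsFactors = FALSE)
}

run_cohort_attribution <- function(spec, seed, afids = c(2, 3, 4, 14)) {
  sim <- simulate_cohort(spec, seed = seed)
  afre <- do.call(rbind, lapply(sim$fiducial_sets, registration_error,
                                template_consensus = spec$fiducial_truth))
  tips <- center_targets(sim$tips, "pooled_after_per_side_centering")
  sp <- stacked_pca(afre, afids, align_to = tips)
  tp <- pca(as.matrix(tips[, c("dx_mm", "dy_mm", "dz_mm")]),
            feature_labels = c("x", "y", "z"))
  list(afre = afre, tips = tips, stacked = sp, tip_axes = tp,
       attribution = attribute_variance(sp, tp), sim = sim)
}
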