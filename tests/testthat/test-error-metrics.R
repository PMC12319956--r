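test_that("consensus is the component-wise mean and enforces min_raters", {
  sets <- list(toy_set(c(0, 0, 0)), toy_set(c(1, 0, 0), rater = "r2"),
               toy_set(c(2, 0, 0), rater = "r3"))
  cons <- consensus_coordinates(sets)
  expect_equal(as.numeric(cons[1, c("x", "y", "z")]), c(1, 0, 0))

  same <- replicate(3, toy_set(c(3.2, -1.1, 0.4)), simplify = FALSE)
  expect_equal(as.numeric(consensus_coordinates(same)[1, c("x", "y", "z")]),
               c(3.2, -1.1, 0.4))

  set.seed(10)
  r5 <- lapply(1:5, function(i) {
    s <- random_set(n = 4, rater = paste0("r", i))
    s
  })
  # raters must annotate the same landmarks at different positions
  coords <- lapply(1:5, function(i) matrix(rnorm(12), 4, 3))
  r5 <- lapply(1:5, function(i) toy_set(coords[[i]], rater = paste0("r", i)))
  cons <- consensus_coordinates(r5)
  expect_equal(unname(fiducial_coords(cons)),
               unname(Reduce(`+`, coords) / 5), tolerance = 1e-12)

  expect_error(consensus_coordinates(sets[1:2]), "min_raters")
})

test_that("localization distance is the 1-2-2 style Euclidean with unsigned axes", {
  a <- toy_set(rbind(c(0, 0, 0), c(5, 5, 5)))
  b <- toy_set(rbind(c(1, 2, 2), c(5, 5, 5)), rater = "r2")
  ld <- localization_distance(a, b)
  expect_equal(ld$euclidean_mm, c(3, 0))
  expect_equal(ld$kind, rep("LD", 2))
  expect_true(all(ld$dx_mm >= 0 & ld$dy_mm >= 0 & ld$dz_mm >= 0))
  # symmetry
  ld2 <- localization_distance(b, a)
  expect_equal(ld2[, c("dx_mm", "dy_mm", "dz_mm", "euclidean_mm")],
               ld[, c("dx_mm", "dy_mm", "dz_mm", "euclidean_mm")])
  # random pairs match brute force
  set.seed(11)
  pa <- matrix(rnorm(30), 10, 3); pb <- matrix(rnorm(30), 10, 3)
  got <- localization_distance(toy_set(pa), toy_set(pb, rater = "r2"))
  expect_equal(got$euclidean_mm, sqrt(rowSums((pa - pb)^2)), tolerance = 1e-12)
})

test_that("localization error is rater-minus-consensus and needs >= 3 raters", {
  base <- c(4, -2, 7)
  sets <- lapply(c(-1, 0, 1), function(o)
    toy_set(base + c(o, 0, 0), rater = paste0("r", o + 2)))
  afle <- localization_error(sets)
  expect_equal(sort(afle$euclidean_mm), c(0, 1, 1))
  expect_equal(afle$kind, rep("AFLE", 3))
  expect_error(localization_error(sets[1:2]), ">= 3 raters")
  expect_silent(localization_error(sets[1:2], allow_fewer = TRUE))

  set.seed(12)
  coords <- lapply(1:5, function(i) matrix(rnorm(9), 3, 3))
  r5 <- lapply(1:5, function(i) toy_set(coords[[i]], rater = paste0("r", i)))
  afle <- localization_error(r5)
  mean_c <- Reduce(`+`, coords) / 5
  want <- unlist(lapply(coords, function(m) sqrt(rowSums((m - mean_c)^2))))
  expect_equal(afle$euclidean_mm, want, tolerance = 1e-12)
})

test_that("registration error is signed and requires template space", {
  tc <- template_consensus("acpc")
  shifted <- toy_set(fiducial_coords(tc) + rep(c(0, 1.22, -1.40), each = 2),
                     labels = tc$label, subject = "sub-001",
                     rater = "consensus", space = "template")
  afre <- registration_error(shifted, tc)
  expect_equal(afre$dy_mm, c(1.22, 1.22))
  expect_equal(afre$dz_mm, c(-1.40, -1.40))
  expect_equal(afre$kind, rep("AFRE", 2))
  expect_error(registration_error(toy_set(c(0, 0, 0)), tc), "template space")

  same <- registration_error(
    transform_fiducials(affine_transform(diag(4)), tc), tc)
  expect_equal(same$euclidean_mm, c(0, 0))
})

test_that("global AFRE is the per-subject mean Euclidean error", {
  t1 <- data.frame(subject = "s1", afid = 1:2, label = c("AC", "PC"),
                   rater = NA, dx_mm = c(1, 3), dy_mm = 0, dz_mm = 0,
                   euclidean_mm = c(1, 3), kind = "AFRE")
  expect_equal(global_afre(t1)$global_afre_mm, 2)
  set.seed(13)
  big <- data.frame(subject = rep(c("a", "b"), each = 5), afid = rep(1:5, 2),
                    label = "x", rater = NA, dx_mm = rnorm(10),
                    dy_mm = rnorm(10), dz_mm = rnorm(10), kind = "AFRE")
  big$euclidean_mm <- sqrt(big$dx_mm^2 + big$dy_mm^2 + big$dz_mm^2)
  g <- global_afre(big)
  expect_equal(g$global_afre_mm,
               c(mean(big$euclidean_mm[1:5]), mean(big$euclidean_mm[6:10])))
  expect_error(global_afre(big[0, ]), "empty")
  expect_error(global_afre(transform(big, kind = "LD")), "AFRE")
})

test_that("summaries use interpolated quartiles, n-1 variance and RMSE", {
  s <- summarize_errors(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr_low, 1.75)
  expect_equal(s$iqr_high, 3.25)
  cs <- summarize_errors(rep(-2.5, 7))
  expect_equal(cs$median, -2.5)
  expect_equal(cs$variance, 0)
  expect_equal(cs$rmse, 2.5)
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("per-axis RMSE matches brute force and the Euclidean identity holds", {
  t2 <- data.frame(subject = "s", afid = 1:2, label = "x", rater = NA,
                   dx_mm = c(1, -1), dy_mm = 0, dz_mm = 0,
                   euclidean_mm = 1, kind = "AFRE")
  expect_equal(unname(rmse_by_axis(t2)), c(1, 0, 0))
  set.seed(14)
  tb <- data.frame(subject = "s", afid = 1:20, label = "x", rater = NA,
                   dx_mm = rnorm(20), dy_mm = rnorm(20), dz_mm = rnorm(20),
                   kind = "AFRE")
  tb$euclidean_mm <- sqrt(tb$dx_mm^2 + tb$dy_mm^2 + tb$dz_mm^2)
  r <- rmse_by_axis(tb)
  expect_equal(unname(r["y"]), sqrt(mean(tb$dy_mm^2)), tolerance = 1e-12)
  # mean squared Euclidean = sum of squared per-axis RMSE
  expect_equal(mean(tb$euclidean_mm^2), sum(r^2), tolerance = 1e-12)
  # row invariant
  expect_equal(tb$euclidean_mm^2, tb$dx_mm^2 + tb$dy_mm^2 + tb$dz_mm^2,
               tolerance = 1e-9)
})
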