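#' Affine point transform
#'
#' A 4x4 homogeneous transform in RAS+ millimeters mapping subject-space
#' points toward template space.
#'
#' @param matrix 4x4 numeric matrix; last row must be (0,0,0,1) and the
#'   upper-left 3x3 block invertible.
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(all(dim(m) == c(4, 4)), all(is.finite(m)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("affine last row must be (0,0,0,1)")
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps * 10)
    stop("affine upper-left 3x3 block is not invertible")
  structure(list(matrix = m), class = "affine_transform")
}

#' Dense displacement field
#'
#' A gridded 3-vector field: `vectors[i,j,k,]` is the world-frame millimeter
#' displacement at voxel (i-1, j-1, k-1) (voxel indices are 0-based in the
#' world convention; R arrays are 1-based).  Displacements are RAS+ world
#' millimeters, never voxel units.
#'
#' @param vectors numeric array X x Y x Z x 3, finite.
#' @param voxel_to_world 4x4 affine mapping 0-based voxel indices to world mm.
#' @param frame frame of the *vectors* as stored: `"RAS"` or `"LPS"`.  LPS
#'   vectors are negated in x and y so the object always holds RAS.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, voxel_to_world, frame = c("RAS", "LPS")) {
  frame <- match.arg(frame)
  stopifnot(is.array(vectors), length(dim(vectors)) == 4, dim(vectors)[4] == 3)
  if (any(!is.finite(vectors))) stop("displacement vectors must be finite")
  m <- as.matrix(voxel_to_world)
  stopifnot(all(dim(m) == c(4, 4)))
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps * 10)
    stop("voxel_to_world affine is not invertible")
  if (frame == "LPS") vectors[, , , 1:2] <- -vectors[, , , 1:2]
  structure(list(vectors = vectors, voxel_to_world = m, frame = "RAS"),
            class = "displacement_field")
}

#' Read a displacement field from a NIfTI-1 volume
#'
#' Accepts shapes X x Y x Z x 3 and the NIfTI vector convention
#' X x Y x Z x 1 x 3.  Vectors are taken as world millimeters; set
#' `itk_vectors = TRUE` for ITK-style fields whose vectors follow the LPS
#' convention (first two components negated on load).
#'
#' @param path path to an uncompressed `.nii` file.
#' @param itk_vectors logical; negate x/y vector components on load.
#' @return a [displacement_field()].
#' @export
read_displacement_field <- function(path, itk_vectors = FALSE) {
  vol <- read_nifti1(path)
  d <- dim(vol$data)
  if (length(d) == 5 && d[4] == 1 && d[5] == 3) {
    vol$data <- array(vol$data, dim = d[c(1, 2, 3, 5)])
  } else if (!(length(d) == 4 && d[4] == 3)) {
    stop("not a displacement field: expected X*Y*Z*3 or X*Y*Z*1*3, got ",
         paste(d, collapse = "x"))
  }
  displacement_field(vol$data, vol$affine,
                     frame = if (itk_vectors) "LPS" else "RAS")
}

#' Write a displacement field as NIfTI-1
#'
#' Written with the 5-D vector layout (X x Y x Z x 1 x 3), float64 data and
#' RAS vectors, so a write/read round trip is exact.
#'
#' @param field a [displacement_field()].
#' @param path output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$vectors)
  write_nifti1(array(field$vectors, dim = c(d[1:3], 1, 3)),
               field$voxel_to_world, path)
}

world_to_voxel <- function(field, points) {
  inv <- solve(field$voxel_to_world)
  pts <- rbind(t(points), 1)
  t(inv %*% pts)[, 1:3, drop = FALSE]
}

#' Sample a displacement field at world points
#'
#' Trilinear interpolation of the stored vectors at each point's continuous
#' (0-based) voxel coordinate.  Points outside the grid raise an error naming
#' the offending point; with `clamp = TRUE` continuous voxel coordinates are
#' clamped to the grid edge instead (opt-in, since silent extrapolation
#' corrupts registration-error estimates).
#'
#' @param field a [displacement_field()].
#' @param points numeric n x 3 matrix (or length-3 vector) of world mm.
#' @param clamp clamp out-of-bounds points to the grid edge instead of erroring.
#' @return n x 3 matrix of displacement vectors, world mm.
#' @export
sample_displacement <- function(field, points, clamp = FALSE) {
  pts <- to_points_matrix(points)
  vox <- world_to_voxel(field, pts)
  d <- dim(field$vectors)[1:3]
  lo <- rep(0, 3); hi <- d - 1
  oob <- vox[, 1] < lo[1] | vox[, 1] > hi[1] |
         vox[, 2] < lo[2] | vox[, 2] > hi[2] |
         vox[, 3] < lo[3] | vox[, 3] > hi[3]
  if (any(oob)) {
    if (!clamp) {
      bad <- pts[which(oob)[1], ]
      stop(sprintf("point (%.3f, %.3f, %.3f) mm is outside the displacement-field grid",
                   bad[1], bad[2], bad[3]))
    }
    for (ax in 1:3) vox[, ax] <- pmin(pmax(vox[, ax], lo[ax]), hi[ax])
  }
  # floor, but keep the upper face inside the last cell
  i0 <- floor(vox)
  for (ax in 1:3) i0[, ax] <- pmin(i0[, ax], max(hi[ax] - 1, 0))
  f <- vox - i0
  out <- matrix(0, nrow(pts), 3)
  v <- field$vectors
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    ii <- pmin(i0[, 1] + dx, hi[1]) + 1
    jj <- pmin(i0[, 2] + dy, hi[2]) + 1
    kk <- pmin(i0[, 3] + dz, hi[3]) + 1
    idx <- cbind(ii, jj, kk)
    for (ax in 1:3)
      out[, ax] <- out[, ax] + w * v[cbind(idx, ax)]
  }
  out
}

#' Transform chain
#'
#' Ordered composition of affine and displacement-field steps mapping
#' subject-space coordinates to template-space coordinates.  Which on-disk
#' warp (forward vs inverse) realizes this point mapping is the caller's
#' responsibility: registration packages differ, and a field suitable for
#' resampling images is typically the *inverse* of the point transform.
#'
#' @param ... steps: [affine_transform()] or [displacement_field()] objects.
#' @return an object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) &&
      !inherits(steps[[1]], c("affine_transform", "displacement_field")))
    steps <- steps[[1]]
  if (!length(steps)) stop("transform chain must have at least one step")
  ok <- vapply(steps, inherits, TRUE, what = c("affine_transform", "displacement_field"))
  if (!all(ok)) stop("chain steps must be affine_transform or displacement_field objects")
  structure(list(steps = steps), class = "transform_chain")
}

to_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3)
  storage.mode(pts) <- "double"
  pts
}

#' Apply a transform chain to points
#'
#' Affine steps map p to M p; displacement-field steps map p to
#' p + field(p) (trilinear sampling).
#'
#' @param chain a [transform_chain()], or a single step.
#' @param points n x 3 matrix (or length-3 vector) of world mm.
#' @param clamp passed to [sample_displacement()].
#' @return n x 3 matrix of transformed points, world mm.
#' @export
transform_points <- function(chain, points, clamp = FALSE) {
  if (inherits(chain, c("affine_transform", "displacement_field")))
    chain <- transform_chain(chain)
  stopifnot(inherits(chain, "transform_chain"))
  pts <- to_points_matrix(points)
  for (step in chain$steps) {
    if (inherits(step, "affine_transform")) {
      pts <- t(step$matrix %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
    } else {
      pts <- pts + sample_displacement(step, pts, clamp = clamp)
    }
  }
  pts
}

#' Apply a transform chain to a fiducial set
#'
#' @param chain a [transform_chain()] (or single step).
#' @param set a [fiducial_set()] in subject space.
#' @param to_space space label for the result (default `"template"`).
#' @return a [fiducial_set()] with transformed coordinates.
#' @export
transform_fiducials <- function(chain, set, to_space = "template") {
  pts <- transform_points(chain, fiducial_coords(set))
  out <- as.data.frame(set)
  out$x <- pts[, 1]; out$y <- pts[, 2]; out$z <- pts[, 3]
  fiducial_set(out, subject_id = attr(set, "subject_id"),
               rater_id = attr(set, "rater_id"), space = to_space,
               provenance = paste0(attr(set, "provenance"), " [transformed]"))
}
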