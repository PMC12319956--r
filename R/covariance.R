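# Shared-misregistration inference: centered electrode displacements,
# axiswise regressions of tip position on registration error, per-landmark
# and stacked PCA of signed AFRE vectors, correlation matrices in Cartesian
# and principal-component bases, and attribution of tip variance to the
# leading shared component.

#' Center electrode tip coordinates
#'
#' Subtracts the mean tip coordinate within each grouping cell (side, by
#' default), yielding per-electrode displacement vectors from the group mean
#' plus their Euclidean magnitude.  With
#' `grouping = "pooled_after_per_side_centering"` tips are centered per side
#' and then treated as one pooled sample (sides are not mirrored).
#'
#' @param tips data frame with columns `subject`, `side`, `x`, `y`, `z`
#'   (template-space millimeters).
#' @param grouping `"per_side"` or `"pooled_after_per_side_centering"`.
#' @return data frame with columns `subject`, `side`, `dx_mm`, `dy_mm`,
#'   `dz_mm`, `euclidean_mm`; per-cell column means are zero.
#' @export
center_targets <- function(tips, grouping = c("per_side",
                                              "pooled_after_per_side_centering")) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("subject", "side", "x", "y", "z") %in% names(tips)))
  cells <- split(seq_len(nrow(tips)), tips$side)
  sizes <- vapply(cells, length, 0L)
  if (any(sizes < 2))
    stop("singleton grouping cell(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  out <- tips
  for (idx in cells) {
    for (ax in c("x", "y", "z"))
      out[[ax]][idx] <- tips[[ax]][idx] - mean(tips[[ax]][idx])
  }
  res <- data.frame(subject = tips$subject, side = tips$side,
                    dx_mm = out$x, dy_mm = out$y, dz_mm = out$z,
                    euclidean_mm = sqrt(out$x^2 + out$y^2 + out$z^2),
                    stringsAsFactors = FALSE)
  attr(res, "grouping") <- grouping
  res
}

#' Simple linear regression
#'
#' Least squares of `y` on `x`; `r_squared` is the squared Pearson
#' correlation and the two-sided p comes from the t statistic on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
simple_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("simple regression needs n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("predictor is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy == 0) 0 else (sxy^2) / (sxx * syy)
  # guard rounding: r2 in [0,1]
  r2 <- min(1, max(0, r2))
  if (r2 >= 1) {
    p <- 0
  } else {
    tstat <- sqrt(r2 * (n - 2) / (1 - r2)) * sign(slope)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p, n = n)
}

afre_axis_columns <- c(x = "dx_mm", y = "dy_mm", z = "dz_mm")

#' Map of tip-displacement variance explained by AFRE, per landmark and axis
#'
#' For every landmark and Cartesian axis, regresses the tip displacement
#' component on the signed AFRE component of the *same* axis across aligned
#' electrodes, with two-tier Bonferroni flags (`*` p < alpha, `**`
#' p < alpha/m).  Subject-level AFREs are matched to every electrode of that
#' subject (both sides share the subject's registration).
#'
#' @param afre an error table with `kind = "AFRE"` (one row per subject and
#'   landmark).
#' @param tips a centered displacement table from [center_targets()].
#' @param m Bonferroni divisor (default 32, the protocol landmark count).
#' @param alpha nominal level.
#' @return data frame: `afid`, `label`, `axis`, `slope`, `r_squared`, `p`,
#'   `n`, `nominal`, `corrected`; cells with fewer than 3 aligned electrodes
#'   are `NA`.
#' @export
r2_map <- function(afre, tips, m = 32L, alpha = 0.05) {
  stopifnot(all(afre$kind == "AFRE"))
  out <- list()
  for (id in sort(unique(afre$afid))) {
    sub <- afre[afre$afid == id, ]
    idx <- match(tips$subject, sub$subject)
    lab <- sub$label[1]
    for (ax in names(afre_axis_columns)) {
      col <- afre_axis_columns[[ax]]
      xv <- sub[[col]][idx]
      yv <- tips[[col]]
      ok <- is.finite(xv) & is.finite(yv)
      row <- data.frame(afid = id, label = lab, axis = ax, slope = NA_real_,
                        r_squared = NA_real_, p = NA_real_, n = sum(ok),
                        stringsAsFactors = FALSE)
      if (sum(ok) >= 3 && stats::sd(xv[ok]) > 0) {
        fit <- simple_regression(xv[ok], yv[ok])
        row$slope <- fit$slope; row$r_squared <- fit$r_squared; row$p <- fit$p_value
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- do.call(rbind, out)
  flags <- bonferroni(out$p, m = m, alpha = alpha)
  out$nominal <- flags$nominal
  out$corrected <- flags$corrected
  out
}

#' Screen covariates against tip displacement
#'
#' One nonparametric test per covariate per axis: rank-sum for binary
#' covariates, Spearman rank correlation for continuous ones, with
#' per-covariate Bonferroni flags over the axes tested.
#'
#' @param tips centered displacement table from [center_targets()].
#' @param covariates data frame keyed by `subject` (and optionally `side`).
#' @param types named character vector: `"binary"` or `"continuous"` per
#'   covariate column.
#' @param alpha nominal level.
#' @return data frame: `covariate`, `axis`, `type`, `statistic`, `p`,
#'   `nominal`, `corrected`.
#' @export
covariate_screen <- function(tips, covariates, types, alpha = 0.05) {
  stopifnot("subject" %in% names(covariates))
  by_side <- "side" %in% names(covariates)
  key_t <- if (by_side) paste(tips$subject, tips$side) else tips$subject
  key_c <- if (by_side) paste(covariates$subject, covariates$side) else covariates$subject
  idx <- match(key_t, key_c)
  axes <- c(afre_axis_columns, euclidean = "euclidean_mm")
  rows <- list()
  for (cv in names(types)) {
    v <- covariates[[cv]][idx]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("covariate '", cv, "' has a single level; skipped")
      next
    }
    for (ax in names(axes)) {
      y <- tips[[axes[[ax]]]]
      ok <- !is.na(v) & is.finite(y)
      if (types[[cv]] == "binary") {
        lv <- sort(unique(v[ok]))
        if (length(lv) != 2) stop("binary covariate '", cv, "' has ", length(lv), " levels")
        res <- compare_unpaired(y[ok][v[ok] == lv[1]], y[ok][v[ok] == lv[2]])
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, axis = ax, type = "binary",
          statistic = res$statistic, p = res$p_value, stringsAsFactors = FALSE)
      } else {
        rho <- stats::cor(v[ok], y[ok], method = "spearman")
        n <- sum(ok)
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, axis = ax, type = "continuous",
          statistic = rho, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  n_axes <- length(unique(out$axis))
  flags <- bonferroni(out$p, m = n_axes, alpha = alpha)
  out$nominal <- flags$nominal
  out$corrected <- flags$corrected
  out
}

#' Multivariate linear regression of a displacement axis
#'
#' Ordinary least squares of one tip-displacement component on a design of
#' covariates and AFRE columns, with per-coefficient t tests and overall R².
#' Binary columns are encoded 0/1; a rank-deficient design raises an error
#' naming the collinear columns.
#'
#' @param design data frame of predictors.
#' @param y numeric response (one displacement axis).
#' @return list with `coefficients` (data frame: term, estimate, std_error,
#'   t, p), `r_squared`, `n`.
#' @export
multivariate_regression <- function(design, y) {
  stopifnot(is.data.frame(design), nrow(design) == length(y))
  X <- as.data.frame(design)
  for (cn in names(X)) {
    v <- X[[cn]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) != 2)
        stop("column '", cn, "' is categorical with ", length(lv),
             " levels; only binary encoding is supported")
      X[[cn]] <- as.numeric(as.character(v) == lv[2])
    }
  }
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- nrow(Xm); k <- ncol(Xm)
  if (n <= k) stop("need n > number of predictors + 1")
  qrX <- qr(Xm)
  if (qrX$rank < k) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(Xm %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - k)
  list(coefficients = data.frame(term = colnames(Xm), estimate = beta,
                                 std_error = se, t = tstat, p = p,
                                 row.names = NULL, stringsAsFactors = FALSE),
       r_squared = if (tss > 0) 1 - rss / tss else 0,
       n = n)
}

#' Principal-component analysis of a subjects-by-features matrix
#'
#' Covariance PCA (features share millimeter units, so no standardization):
#' columns are centered, the sample covariance is eigendecomposed, and
#' components are unit eigenvectors sorted by descending eigenvalue.  The
#' sign of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param x numeric matrix, subjects in rows (>= 2), features in columns.
#' @param feature_labels optional column labels.
#' @return object of class `principal_axes`: `components` (features x k),
#'   `eigenvalues`, `explained_fraction`, `scores` (subjects x k),
#'   `feature_labels`, `column_means`.
#' @export
pca <- function(x, feature_labels = colnames(x)) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 subjects")
  if (is.null(feature_labels)) feature_labels <- paste0("f", seq_len(ncol(x)))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / (nrow(x) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- feature_labels
  structure(list(components = vecs,
                 eigenvalues = vals,
                 explained_fraction = if (sum(vals) > 0) vals / sum(vals) else vals,
                 scores = xc %*% vecs,
                 feature_labels = feature_labels,
                 column_means = mu),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat(sprintf("<principal_axes> %d features, %d subjects\n",
              nrow(x$components), nrow(x$scores)))
  cat("explained fraction:",
      paste(sprintf("%.3f", x$explained_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Pivot an AFRE table to a subjects-by-features matrix
#'
#' Rows are subjects (or electrodes, when `align_to` is given: the subject's
#' AFRE row is repeated for each of the subject's electrodes, matching
#' analyses that pair per-subject registration error with per-electrode
#' position).  Columns are the signed AFRE components, labeled
#' `"AFID<id>.<axis>"`.
#'
#' @param afre error table with `kind = "AFRE"`.
#' @param afids landmark ids to include (default: all present).
#' @param align_to optional centered tip table from [center_targets()].
#' @return numeric matrix with feature labels as column names.
#' @export
afre_feature_matrix <- function(afre, afids = NULL, align_to = NULL) {
  stopifnot(all(afre$kind == "AFRE"))
  if (is.null(afids)) afids <- sort(unique(afre$afid))
  subjects <- if (is.null(align_to)) sort(unique(afre$subject)) else align_to$subject
  cols <- list()
  for (id in afids) {
    sub <- afre[afre$afid == id, ]
    idx <- match(subjects, sub$subject)
    for (ax in names(afre_axis_columns))
      cols[[sprintf("AFID%02d.%s", id, ax)]] <- sub[[afre_axis_columns[[ax]]]][idx]
  }
  out <- do.call(cbind, cols)
  rownames(out) <- if (is.null(align_to)) subjects else
    paste(align_to$subject, align_to$side, sep = ".")
  out
}

#' Stacked PCA over several landmarks' AFRE vectors
#'
#' PCA of the subjects x 3k matrix of signed AFRE components of k landmarks
#' (e.g. 4 landmarks = 12 features), revealing shared misregistration axes.
#'
#' @param afre error table with `kind = "AFRE"`.
#' @param afids landmark ids to stack (>= 2).
#' @param align_to optional tip table for electrode-level alignment.
#' @return a [pca()] result over the stacked features.
#' @export
stacked_pca <- function(afre, afids, align_to = NULL) {
  if (length(afids) < 2) stop("stacked PCA needs at least 2 landmarks")
  m <- afre_feature_matrix(afre, afids, align_to)
  if (anyNA(m)) stop("misaligned subjects: missing AFRE rows for some subjects")
  pca(m)
}

#' Pairwise AFRE correlation matrix
#'
#' Squared Pearson correlations between all per-landmark AFRE components
#' across aligned subjects, either in Cartesian axes or with each landmark's
#' AFRE projected onto its own principal components first.
#'
#' @param afre error table with `kind = "AFRE"`.
#' @param afids landmark ids (>= 2; default all present).
#' @param basis `"cartesian"` or `"per_afid_prc"`.
#' @return symmetric matrix of r-squared values with labeled dimnames.
#' @export
afre_correlation_matrix <- function(afre, afids = NULL,
                                    basis = c("cartesian", "per_afid_prc")) {
  basis <- match.arg(basis)
  if (is.null(afids)) afids <- sort(unique(afre$afid))
  if (length(afids) < 2) stop("need at least 2 landmarks")
  m <- afre_feature_matrix(afre, afids)
  if (anyNA(m)) stop("misaligned subjects: missing AFRE rows for some subjects")
  if (basis == "per_afid_prc") {
    blocks <- lapply(afids, function(id) {
      cols <- sprintf("AFID%02d.%s", id, names(afre_axis_columns))
      s <- pca(m[, cols])$scores
      colnames(s) <- sprintf("AFID%02d.PrC%d", id, 1:3)
      s
    })
    m <- do.call(cbind, blocks)
  }
  r2 <- stats::cor(m)^2
  r2
}

#' Attribute tip-position variance to shared misregistration components
#'
#' Regresses every tip principal-component score on every AFRE
#' principal-component score (simple regressions across aligned electrodes).
#' The headline quantity is the PrC1-on-PrC1 cell: its r-squared is the
#' fraction of tip variance along the dominant tip axis explained by the
#' dominant shared-misregistration axis, and `explained_mm` holds the
#' absolute fitted displacements |slope * AFRE-PrC1 score| of that
#' regression, in millimeters along the tip PrC1 axis.
#'
#' @param afre_axes [pca()] result on stacked AFRE features (electrode-aligned).
#' @param tip_axes [pca()] result on centered tip displacements.
#' @param n_components number of AFRE components to correlate (default 4,
#'   truncated to what is available).
#' @return list with `r2_matrix` (AFRE PrC x tip PrC), `p_matrix`,
#'   `explained_mm` (per electrode), and `summary` (median, min, max mm).
#' @export
attribute_variance <- function(afre_axes, tip_axes, n_components = 4L) {
  sa <- afre_axes$scores
  st <- tip_axes$scores
  if (nrow(sa) != nrow(st))
    stop("AFRE and tip principal axes are not aligned (different row counts)")
  ka <- min(n_components, ncol(sa))
  kt <- ncol(st)
  r2 <- matrix(NA_real_, ka, kt,
               dimnames = list(paste0("AFRE.PrC", seq_len(ka)),
                               paste0("tip.PrC", seq_len(kt))))
  pm <- r2
  slopes <- r2
  for (i in seq_len(ka)) for (j in seq_len(kt)) {
    if (stats::sd(sa[, i]) == 0 || stats::sd(st[, j]) == 0) next
    fit <- simple_regression(sa[, i], st[, j])
    r2[i, j] <- fit$r_squared
    pm[i, j] <- fit$p_value
    slopes[i, j] <- fit$slope
  }
  explained <- NULL
  if (is.finite(slopes[1, 1])) explained <- abs(slopes[1, 1] * sa[, 1])
  list(r2_matrix = r2, p_matrix = pm,
       explained_mm = explained,
       summary = if (is.null(explained)) NULL else
         list(median_mm = stats::median(explained),
              min_mm = min(explained), max_mm = max(explained)))
}
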