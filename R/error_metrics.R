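# Localization and registration error metrics.
#
# All metrics share one table layout (the "error table"): one row per
# (subject, landmark[, rater]) with signed or unsigned per-axis components in
# millimeters, the Euclidean magnitude, and a kind tag:
#   LD   - inter-rater localization distance; axis components are UNSIGNED
#          (absolute differences), as reported per axis.
#   AFLE - rater-vs-consensus localization error; components signed
#          (rater minus consensus).
#   AFRE - registration error in template space; components signed
#          (transformed minus template consensus), because downstream
#          correlation analyses need direction.

error_table <- function(subject, afid, label, rater, dx, dy, dz, kind) {
  data.frame(subject = subject, afid = as.integer(afid), label = label,
             rater = rater, dx_mm = dx, dy_mm = dy, dz_mm = dz,
             euclidean_mm = sqrt(dx^2 + dy^2 + dz^2),
             kind = kind, stringsAsFactors = FALSE)
}

landmark_key <- function(set) ifelse(set$afid_id != 0L, paste0("afid", set$afid_id), set$label)

match_landmarks <- function(setA, setB) {
  ka <- landmark_key(setA); kb <- landmark_key(setB)
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no shared landmarks between fiducial sets")
  list(a = match(shared, ka), b = match(shared, kb), key = shared)
}

#' Consensus coordinates from multiple raters
#'
#' Component-wise mean placement per landmark across independent rater
#' annotations.  Consensus ("ground truth") placements conventionally require
#' at least three raters; landmarks present in fewer than `min_raters` sets
#' raise an error naming them.
#'
#' @param sets list of [fiducial_set()] objects sharing subject and space.
#' @param min_raters minimum number of raters per landmark (default 3).
#' @return a [fiducial_set()] with `rater_id = "consensus"`.
#' @export
consensus_coordinates <- function(sets, min_raters = 3L) {
  stopifnot(is.list(sets), length(sets) >= 2)
  subj <- unique(vapply(sets, fs_subject, ""))
  spc <- unique(vapply(sets, fs_space, ""))
  if (length(subj) != 1 || length(spc) != 1)
    stop("all rater sets must share subject_id and space")
  keys <- lapply(sets, landmark_key)
  all_keys <- unique(unlist(keys))
  count <- vapply(all_keys, function(k) sum(vapply(keys, function(x) k %in% x, TRUE)), 0L)
  low <- all_keys[count < min_raters]
  if (length(low))
    stop("landmarks below min_raters (", min_raters, "): ",
         paste(low, collapse = ", "))
  rows <- lapply(all_keys, function(k) {
    mats <- do.call(rbind, lapply(seq_along(sets), function(i) {
      j <- match(k, keys[[i]])
      if (is.na(j)) NULL else as.numeric(sets[[i]][j, c("x", "y", "z")])
    }))
    first <- sets[[which(vapply(keys, function(x) k %in% x, TRUE))[1]]]
    j <- match(k, landmark_key(first))
    data.frame(afid_id = first$afid_id[j], label = first$label[j],
               x = mean(mats[, 1]), y = mean(mats[, 2]), z = mean(mats[, 3]),
               stringsAsFactors = FALSE)
  })
  fiducial_set(do.call(rbind, rows), subject_id = subj, rater_id = "consensus",
               space = spc, provenance = sprintf("consensus of %d raters", length(sets)))
}

#' Inter-rater localization distance (LD)
#'
#' Pairwise distance between two raters' placements of the same points:
#' absolute per-axis differences plus the Euclidean distance.
#'
#' @param setA,setB [fiducial_set()] objects for the same subject and space.
#' @return an error table with `kind = "LD"` (axis components unsigned).
#' @export
localization_distance <- function(setA, setB) {
  if (!identical(fs_subject(setA), fs_subject(setB)) ||
      !identical(fs_space(setA), fs_space(setB)))
    stop("localization distance requires the same subject and space")
  m <- match_landmarks(setA, setB)
  d <- fiducial_coords(setA)[m$a, , drop = FALSE] -
       fiducial_coords(setB)[m$b, , drop = FALSE]
  error_table(fs_subject(setA), setA$afid_id[m$a], setA$label[m$a],
              paste(attr(setA, "rater_id"), attr(setB, "rater_id"), sep = "|"),
              abs(d[, 1]), abs(d[, 2]), abs(d[, 3]), "LD")
}

#' Fiducial localization error (AFLE)
#'
#' Signed displacement of each rater's placement from the consensus placement
#' (rater minus consensus), one row per rater and landmark.  A consensus from
#' fewer than three raters is refused unless explicitly overridden, since
#' such "errors" can be misleading.
#'
#' @param rater_sets list of [fiducial_set()] objects.
#' @param consensus optional precomputed consensus; built from `rater_sets`
#'   when `NULL`.
#' @param allow_fewer permit fewer than 3 raters (default `FALSE`).
#' @return an error table with `kind = "AFLE"`.
#' @export
localization_error <- function(rater_sets, consensus = NULL, allow_fewer = FALSE) {
  if (length(rater_sets) < 3 && !allow_fewer)
    stop("localization error requires >= 3 raters (set allow_fewer = TRUE to override)")
  if (is.null(consensus))
    consensus <- consensus_coordinates(rater_sets,
                                       min_raters = if (allow_fewer) 2L else 3L)
  out <- lapply(rater_sets, function(s) {
    m <- match_landmarks(s, consensus)
    d <- fiducial_coords(s)[m$a, , drop = FALSE] -
         fiducial_coords(consensus)[m$b, , drop = FALSE]
    error_table(fs_subject(s), s$afid_id[m$a], s$label[m$a],
                attr(s, "rater_id"), d[, 1], d[, 2], d[, 3], "AFLE")
  })
  do.call(rbind, out)
}

#' Fiducial registration error (AFRE)
#'
#' Signed displacement between a subject's landmarks transformed into
#' template space and the homologous template consensus placements
#' (transformed minus consensus), per axis, plus the Euclidean magnitude.
#'
#' @param transformed a [fiducial_set()] in template space.
#' @param template_consensus the template consensus [fiducial_set()].
#' @return an error table with `kind = "AFRE"`.
#' @export
registration_error <- function(transformed, template_consensus) {
  if (!identical(fs_space(transformed), "template") ||
      !identical(fs_space(template_consensus), "template"))
    stop("registration error is defined in template space on both sides")
  m <- match_landmarks(transformed, template_consensus)
  d <- fiducial_coords(transformed)[m$a, , drop = FALSE] -
       fiducial_coords(template_consensus)[m$b, , drop = FALSE]
  error_table(fs_subject(transformed), transformed$afid_id[m$a],
              transformed$label[m$a], attr(transformed, "rater_id"),
              d[, 1], d[, 2], d[, 3], "AFRE")
}

#' Global registration error per subject
#'
#' Mean Euclidean AFRE over all available landmarks, one value per subject.
#'
#' @param table an error table with `kind = "AFRE"`.
#' @return data frame with columns `subject`, `global_afre_mm`, `n_afids`.
#' @export
global_afre <- function(table) {
  if (!nrow(table)) stop("empty error table")
  if (!all(table$kind == "AFRE")) stop("global AFRE is defined on AFRE tables")
  agg <- stats::aggregate(euclidean_mm ~ subject, data = table, FUN = mean)
  n <- stats::aggregate(euclidean_mm ~ subject, data = table, FUN = length)
  data.frame(subject = agg$subject, global_afre_mm = agg$euclidean_mm,
             n_afids = n$euclidean_mm)
}

#' Summary statistics for a set of error values
#'
#' Median and IQR use linear-interpolation percentiles (quantile type 7);
#' variance uses the n-1 denominator; RMSE is the root of the mean square.
#'
#' @param values numeric vector, millimeters; must be nonempty.
#' @return one-row data frame: `median`, `iqr_low`, `iqr_high`, `mean`,
#'   `variance`, `rmse`, `n`.
#' @export
summarize_errors <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot summarize an empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(median = q[2], iqr_low = q[1], iqr_high = q[3],
             mean = mean(values),
             variance = if (length(values) > 1) stats::var(values) else 0,
             rmse = sqrt(mean(values^2)), n = length(values))
}

#' Per-axis and Euclidean summary of an error table
#'
#' @param table an error table.
#' @return data frame with one summary row per component (`x`, `y`, `z`,
#'   `euclidean`).
#' @export
summarize_error_table <- function(table) {
  comps <- list(x = table$dx_mm, y = table$dy_mm, z = table$dz_mm,
                euclidean = table$euclidean_mm)
  out <- do.call(rbind, lapply(comps, summarize_errors))
  cbind(component = names(comps), out, row.names = NULL)
}

#' Root-mean-square error per Cartesian axis
#'
#' RMSE of the signed per-axis components, the re-expression used to compare
#' against groups reporting axiswise RMSE rather than Euclidean error.
#'
#' @param table an error table (nonempty).
#' @return named numeric vector with elements `x`, `y`, `z`.
#' @export
rmse_by_axis <- function(table) {
  if (!nrow(table)) stop("empty error table")
  c(x = sqrt(mean(table$dx_mm^2)),
    y = sqrt(mean(table$dy_mm^2)),
    z = sqrt(mean(table$dz_mm^2)))
}
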