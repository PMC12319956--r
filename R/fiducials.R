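#' Construct a fiducial set
#'
#' A fiducial set holds labeled 3D landmark coordinates for one subject, one
#' rater (or a consensus), and one space.  It is a plain data frame with
#' columns `afid_id`, `label`, `x`, `y`, `z` (RAS+ world millimeters) and
#' attributes `subject_id`, `rater_id`, `space` and `provenance`.
#'
#' @param coords data frame with columns `afid_id`, `label`, `x`, `y`, `z`.
#' @param subject_id subject identifier.
#' @param rater_id rater identifier (use e.g. `"consensus"` for averages).
#' @param space `"subject"` or `"template"`.
#' @param provenance free-text source description (e.g. a file path).
#' @return an object of class `fiducial_set`.
#' @export
fiducial_set <- function(coords, subject_id = "unknown", rater_id = "unknown",
                         space = c("subject", "template"),
                         provenance = "constructed") {
  space <- match.arg(space)
  stopifnot(is.data.frame(coords),
            all(c("afid_id", "label", "x", "y", "z") %in% names(coords)))
  coords <- as.data.frame(coords)[, c("afid_id", "label", "x", "y", "z")]
  coords$afid_id <- as.integer(coords$afid_id)
  for (ax in c("x", "y", "z")) {
    coords[[ax]] <- as.numeric(coords[[ax]])
    if (any(!is.finite(coords[[ax]])))
      stop("non-finite ", ax, " coordinate in fiducial set")
  }
  nz <- coords$afid_id[coords$afid_id != 0L]
  if (anyDuplicated(nz))
    stop("duplicate nonzero afid_id in fiducial set: ",
         paste(unique(nz[duplicated(nz)]), collapse = ", "))
  structure(coords,
            subject_id = subject_id, rater_id = rater_id, space = space,
            provenance = provenance,
            class = c("fiducial_set", "data.frame"))
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> subject=%s rater=%s space=%s (%d points)\n",
              attr(x, "subject_id"), attr(x, "rater_id"), attr(x, "space"),
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

fs_space <- function(set) attr(set, "space")
fs_subject <- function(set) attr(set, "subject_id")

#' Coordinate matrix of a fiducial set
#'
#' @param set a `fiducial_set`.
#' @return numeric matrix, one row per point, columns x/y/z, rownames afid ids.
#' @export
fiducial_coords <- function(set) {
  m <- as.matrix(as.data.frame(set)[, c("x", "y", "z")])
  rownames(m) <- set$afid_id
  m
}

#' The AFID protocol registry
#'
#' Returns the bundled 32-landmark registry mapping protocol ids to labels
#' and anatomical descriptions.  Labels for landmarks used in computations
#' (AC, PC, ICS, PMJ, PG, ...) follow the protocol; the full description text
#' is loaded from an editable JSON file shipped with the package.
#'
#' @param path optional path to an alternative registry JSON.
#' @return data frame with columns `afid_id`, `label`, `description` (32 rows).
#' @export
afid_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "afid_protocol.json", package = "afidqc")
  reg <- jsonlite::fromJSON(path)$afids
  reg <- as.data.frame(reg)[, c("afid_id", "label", "description")]
  reg$afid_id <- as.integer(reg$afid_id)
  if (nrow(reg) != 32L || anyDuplicated(reg$label) || !identical(sort(reg$afid_id), 1:32))
    stop("protocol registry must define exactly 32 uniquely labeled landmarks with ids 1-32")
  reg
}

# map labels to protocol ids; unmatched labels get 0 so ad-hoc points
# (electrode tips etc.) ride the same format
label_to_afid_id <- function(labels, registry = afid_registry()) {
  idx <- match(toupper(trimws(labels)), toupper(registry$label))
  # also accept "AFID01".."AFID32" style labels
  m <- regmatches(labels, regexpr("^AFID[0-9]{1,2}$", toupper(trimws(labels))))
  num <- suppressWarnings(as.integer(sub("AFID", "", toupper(trimws(labels)))))
  afid_style <- grepl("^AFID[0-9]{1,2}$", toupper(trimws(labels))) &
    !is.na(num) & num >= 1 & num <= 32
  out <- ifelse(is.na(idx), 0L, registry$afid_id[idx])
  out[afid_style] <- num[afid_style]
  as.integer(out)
}

#' Read a 3D Slicer markups fiducial file (.fcsv)
#'
#' Parses the comment header for the declared coordinate system and returns
#' coordinates normalized to RAS+ millimeters (LPS files have x and y negated
#' on read).  Both the string form (`RAS`/`LPS`) and the older numeric flag
#' (0 = RAS, 1 = LPS) are accepted.  Point labels are mapped to protocol ids
#' via [afid_registry()]; unmatched labels get `afid_id` 0.
#'
#' @param path path to a `.fcsv` file.
#' @param subject_id,rater_id,space metadata for the resulting set; defaults
#'   are taken from the file name where possible.
#' @param registry protocol registry data frame (see [afid_registry()]).
#' @return a [fiducial_set()].
#' @export
read_fcsv <- function(path, subject_id = "unknown", rater_id = "unknown",
                      space = c("subject", "template"),
                      registry = afid_registry()) {
  space <- match.arg(space)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines)
  body_idx <- setdiff(seq_along(lines), header)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  cs <- "RAS"
  cs_line <- grep("CoordinateSystem", lines[header], value = TRUE)
  if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1]))
    cs <- switch(val,
                 "RAS" = "RAS", "LPS" = "LPS",
                 "0" = "RAS", "1" = "LPS",
                 stop("unknown coordinate system declaration: '", val, "'"))
  }
  if (!length(body_idx)) stop("no fiducial rows in ", path)
  cols <- c("id", "x", "y", "z", "ow", "ox", "oy", "oz", "vis", "sel",
            "lock", "label", "desc", "associatedNodeID")
  parts <- strsplit(lines[body_idx], ",", fixed = TRUE)
  n <- length(parts)
  get <- function(p, i) if (length(p) >= i) p[i] else ""
  xyz <- matrix(NA_real_, n, 3)
  labels <- character(n)
  for (k in seq_len(n)) {
    p <- parts[[k]]
    if (length(p) < 4)
      stop("malformed fiducial row at line ", body_idx[k], " of ", path)
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(v)))
      stop("non-numeric coordinate at line ", body_idx[k], " of ", path)
    xyz[k, ] <- v
    labels[k] <- trimws(get(p, 12))
  }
  if (cs == "LPS") xyz[, 1:2] <- -xyz[, 1:2]
  fiducial_set(
    data.frame(afid_id = label_to_afid_id(labels, registry),
               label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    subject_id = subject_id, rater_id = rater_id, space = space,
    provenance = path)
}

#' Write a fiducial set as a Slicer markups fiducial file
#'
#' @param set a [fiducial_set()]; must be nonempty.
#' @param path output path.
#' @param coordinate_system `"RAS"` or `"LPS"`; LPS output negates x and y.
#' @return `path`, invisibly.
#' @export
write_fcsv <- function(set, path, coordinate_system = c("RAS", "LPS")) {
  coordinate_system <- match.arg(coordinate_system)
  if (!inherits(set, "fiducial_set")) stop("set must be a fiducial_set")
  if (nrow(set) == 0L) stop("refusing to write an empty fiducial set")
  xyz <- fiducial_coords(set)
  if (coordinate_system == "LPS") xyz[, 1:2] <- -xyz[, 1:2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Markups fiducial file version = 4.11",
               paste0("# CoordinateSystem = ", coordinate_system),
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
             con)
  rows <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s,%s,",
                  seq_len(nrow(set)),
                  formatC(xyz[, 1], format = "fg", digits = 15),
                  formatC(xyz[, 2], format = "fg", digits = 15),
                  formatC(xyz[, 3], format = "fg", digits = 15),
                  set$label, "")
  writeLines(rows, con)
  invisible(path)
}

#' Bundled template-space consensus fiducials
#'
#' The template consensus AC/PC coordinates ship as a bundled fixture; the
#' full 32-landmark template is a synthetic stand-in (only AC and PC are
#' published consensus values) and is clearly labeled as such.
#'
#' @param which `"acpc"` for the two published consensus points, or
#'   `"synthetic32"` for the synthetic full-protocol template.
#' @return a [fiducial_set()] in template space.
#' @export
template_consensus <- function(which = c("acpc", "synthetic32")) {
  which <- match.arg(which)
  f <- switch(which,
              acpc = "template_consensus_acpc.fcsv",
              synthetic32 = "template_afids_synthetic.fcsv")
  read_fcsv(system.file("extdata", f, package = "afidqc"),
            subject_id = "template", rater_id = "consensus",
            space = "template")
}
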