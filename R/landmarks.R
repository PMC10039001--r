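#' Named 3D landmark configuration
#'
#' Container for an ordered, named set of 3D anatomical landmarks (in mm) on
#' one specimen, with a missing-value mask and an optional bilateral pairing
#' table (left/right pairs plus midline landmark names).
#'
#' @param coords numeric N x 3 matrix of coordinates in mm. Rows of a missing
#'   landmark may be `NA`.
#' @param landmark_names character vector of unique landmark names, one per row.
#' @param specimen_id single string identifying the specimen.
#' @param missing logical vector marking missing landmarks; defaults to rows
#'   containing any `NA`.
#' @param pairing optional list with elements `pairs` (list of
#'   `c(left, right)` name pairs) and `midline` (character vector). Every
#'   landmark name must appear exactly once across pairs and midline.
#' @param estimated logical vector flagging landmarks whose coordinates were
#'   estimated (e.g. by TPS from a reference) rather than observed.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(coords, landmark_names, specimen_id = "specimen",
                            missing = NULL, pairing = NULL, estimated = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  landmark_names <- as.character(landmark_names)
  if (nrow(coords) != length(landmark_names))
    stop("coords row count must equal the number of landmark names")
  if (anyDuplicated(landmark_names))
    stop("duplicate landmark names: ",
         paste(unique(landmark_names[duplicated(landmark_names)]), collapse = ", "))
  if (is.null(missing)) missing <- apply(coords, 1L, function(r) any(!is.finite(r)))
  missing <- as.logical(missing)
  if (length(missing) != nrow(coords)) stop("missing mask length mismatch")
  if (any(!is.finite(coords[!missing, , drop = FALSE])))
    stop("non-missing coordinates must be finite")
  if (!is.null(pairing)) validate_pairing(pairing, landmark_names)
  if (is.null(estimated)) estimated <- rep(FALSE, nrow(coords))
  dimnames(coords) <- list(landmark_names, c("x", "y", "z"))
  structure(list(specimen_id = as.character(specimen_id)[1L],
                 landmark_names = landmark_names,
                 coords = coords, missing = missing,
                 pairing = pairing, estimated = as.logical(estimated)),
            class = "landmark_config")
}

validate_pairing <- function(pairing, landmark_names) {
  if (!is.list(pairing) || is.null(pairing$pairs) && is.null(pairing$midline))
    stop("pairing must be a list with elements 'pairs' and/or 'midline'")
  used <- c(unlist(pairing$pairs, use.names = FALSE), pairing$midline)
  bad <- setdiff(used, landmark_names)
  if (length(bad)) stop("pairing names absent from configuration: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(used))
    stop("landmark appears more than once in pairing: ",
         paste(unique(used[duplicated(used)]), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks (%d missing%s)\n",
              x$specimen_id, nrow(x$coords), sum(x$missing),
              if (any(x$estimated)) sprintf(", %d estimated", sum(x$estimated)) else ""))
  invisible(x)
}

#' @export
as.matrix.landmark_config <- function(x, ...) x$coords

#' Replace the coordinates of a configuration, keeping its metadata
#'
#' @param config a [landmark_config].
#' @param coords replacement N x 3 coordinate matrix.
#' @param missing,estimated optional replacement masks.
#' @return a [landmark_config] with the same names, pairing and specimen id.
#' @export
set_coords <- function(config, coords, missing = config$missing,
                       estimated = config$estimated) {
  landmark_config(coords, config$landmark_names, config$specimen_id,
                  missing = missing, pairing = config$pairing,
                  estimated = estimated)
}

#' Subset or reorder a configuration by landmark names
#'
#' @param config a [landmark_config].
#' @param names landmark names to keep, in the requested order; the pairing
#'   table is trimmed to surviving pairs and midline names.
#' @return a [landmark_config] over `names`.
#' @export
subset_config <- function(config, names) {
  idx <- match(names, config$landmark_names)
  if (anyNA(idx)) stop("landmarks not present: ",
                       paste(names[is.na(idx)], collapse = ", "))
  pairing <- config$pairing
  if (!is.null(pairing)) {
    keep_pair <- vapply(pairing$pairs, function(p) all(p %in% names), logical(1))
    pairing <- list(pairs = pairing$pairs[keep_pair],
                    midline = intersect(pairing$midline, names))
    if (!length(pairing$pairs) && !length(pairing$midline)) pairing <- NULL
  }
  landmark_config(config$coords[idx, , drop = FALSE], names, config$specimen_id,
                  missing = config$missing[idx], pairing = pairing,
                  estimated = config$estimated[idx])
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared deviations of the (non-missing) landmarks from their
#' centroid.
#'
#' @param config a [landmark_config], or a bare N x 3 matrix.
#' @return positive scalar, in mm.
#' @export
centroid_size <- function(config) {
  m <- if (inherits(config, "landmark_config"))
    config$coords[!config$missing, , drop = FALSE] else as.matrix(config)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("centroid size needs at least 3 usable landmarks")
  sqrt(sum(scale(m, scale = FALSE)^2))
}

#' Read landmarks from CSV
#'
#' Expects a header `name,x,y,z` (optionally an `estimated` column). Empty
#' coordinate fields mark the landmark as missing. A JSON pairing sidecar
#' (same path with extension `.pairing.json`, or given explicitly) is loaded
#' if present.
#'
#' @param path CSV file path.
#' @param pairing_path optional explicit path to the pairing JSON sidecar.
#' @param specimen_id defaults to the file base name.
#' @return a [landmark_config].
#' @export
read_landmarks <- function(path, pairing_path = NULL, specimen_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z: ", path)
  if (anyDuplicated(df$name))
    stop("duplicate landmark name(s) in ", path, ": ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  coords <- as.matrix(df[, c("x", "y", "z")])
  pairing <- NULL
  if (is.null(pairing_path)) {
    cand <- sub("\\.csv$", ".pairing.json", path)
    if (file.exists(cand) && cand != path) pairing_path <- cand
  }
  if (!is.null(pairing_path)) {
    pj <- jsonlite::read_json(pairing_path, simplifyVector = FALSE)
    pairing <- list(pairs = lapply(pj$pairs, function(p) unlist(p)),
                    midline = unlist(pj$midline))
  }
  est <- if ("estimated" %in% names(df)) as.logical(df$estimated) else NULL
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  landmark_config(coords, df$name, specimen_id, pairing = pairing, estimated = est)
}

#' Write landmarks to CSV
#'
#' Inverse of [read_landmarks()]: missing landmarks get empty coordinate
#' fields; the pairing table, if any, is written to a `.pairing.json` sidecar.
#'
#' @param config a [landmark_config].
#' @param path output CSV path.
#' @export
write_landmarks <- function(config, path) {
  co <- config$coords
  fmt <- function(v, miss) ifelse(miss, "", formatC(v, digits = 9, format = "g"))
  df <- data.frame(name = config$landmark_names,
                   x = fmt(co[, 1], config$missing),
                   y = fmt(co[, 2], config$missing),
                   z = fmt(co[, 3], config$missing),
                   estimated = config$estimated)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config$pairing)) {
    jsonlite::write_json(list(pairs = config$pairing$pairs,
                              midline = config$pairing$midline),
                         sub("\\.csv$", ".pairing.json", path))
  }
  invisible(path)
}
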