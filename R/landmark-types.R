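#' Landmark configurations for tooth marks
#'
#' Two configuration types are used throughout the package.  A tooth
#' *score* (an elongated drag mark) is analysed through its mid-length
#' cross-section, a 2D polyline reduced to 7 landmarks: LM1 and LM7 are
#' the left and right shoulders, LM4 the deepest point, and LM2/LM3
#' (left wall) and LM5/LM6 (right wall) are computed landmarks placed at
#' equal arc-length intervals along the walls.  A tooth *pit* (a cusp
#' depression) is captured by 30 landmarks in 3D: 5 fixed landmarks
#' (LM1/LM2 ends of the maximum-length axis, LM3/LM4 ends of the
#' perpendicular maximum-width axis, LM5 the deepest point) followed by
#' a row-major 5 x 5 patch sampling the internal surface.
#'
#' Coordinates are stored in millimetres.
#'
#' @name landmark-configs
NULL

#' Construct a 7-landmark tooth-score cross-section profile
#'
#' @param landmarks Numeric 7 x 2 matrix of coordinates in mm, rows
#'   ordered LM1..LM7.
#' @param specimen_id Character scalar identifying the specimen.
#' @param group_labels Named list or character vector with entries
#'   `park`, `captivity`, `prey_size` (any may be `NA`).
#' @return An object of class `score_profile`.
#' @export
score_profile <- function(landmarks, specimen_id = "specimen",
                          group_labels = list(park = NA, captivity = NA,
                                              prey_size = NA)) {
  landmarks <- as.matrix(landmarks)
  if (!is.numeric(landmarks) || nrow(landmarks) != 7 || ncol(landmarks) != 2) {
    stop("a score profile requires exactly 7 landmarks in 2D", call. = FALSE)
  }
  if (any(!is.finite(landmarks))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  obj <- structure(
    list(landmarks = unname(landmarks),
         specimen_id = as.character(specimen_id),
         group_labels = as.list(group_labels)),
    class = "score_profile"
  )
  validate_score_profile(obj)
  obj
}

# Geometric invariants.  Depth is defined as the absolute perpendicular
# distance from LM4 to the LM1-LM7 chord, so it is non-negative in any
# coordinate frame (the profile may enter reflected or rotated).  The
# wall landmarks LM2/LM3/LM5/LM6 must lie on the same side of the chord
# as the base LM4 (or on the chord itself, for flat profiles).
validate_score_profile <- function(x) {
  lm <- x$landmarks
  chord <- lm[7, ] - lm[1, ]
  len <- sqrt(sum(chord^2))
  if (len < .Machine$double.eps) {
    stop("degenerate profile: LM1 and LM7 coincide", call. = FALSE)
  }
  normal <- c(chord[2], -chord[1]) / len
  side <- as.numeric((lm[c(2, 3, 4, 5, 6), ] -
                        matrix(lm[1, ], 5, 2, byrow = TRUE)) %*% normal)
  base_side <- side[3]
  if (any(side * sign(base_side) < -1e-9 * max(1, len))) {
    stop("wall landmarks must lie on the same side of the LM1-LM7 chord as LM4",
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a 30-landmark tooth-pit configuration
#'
#' @param landmarks Numeric 30 x 3 matrix (mm): 5 fixed landmarks then
#'   the 25 patch points in row-major 5 x 5 order.
#' @inheritParams score_profile
#' @return An object of class `pit_config`.
#' @export
pit_config <- function(landmarks, specimen_id = "specimen",
                       group_labels = list(park = NA, captivity = NA,
                                           prey_size = NA)) {
  landmarks <- as.matrix(landmarks)
  if (!is.numeric(landmarks) || nrow(landmarks) != 30 || ncol(landmarks) != 3) {
    stop("a pit configuration requires exactly 30 landmarks in 3D",
         call. = FALSE)
  }
  if (any(!is.finite(landmarks))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  obj <- structure(
    list(landmarks = unname(landmarks),
         specimen_id = as.character(specimen_id),
         group_labels = as.list(group_labels)),
    class = "pit_config"
  )
  validate_pit_config(obj)
  obj
}

# Orientation rules: the LM1-LM2 length axis is at least as long as the
# LM3-LM4 width axis, and LM1 is the length endpoint farther from the
# width axis (d1 > d2).
validate_pit_config <- function(x, tol = 1e-9) {
  lm <- x$landmarks
  len <- sqrt(sum((lm[1, ] - lm[2, ])^2))
  wid <- sqrt(sum((lm[3, ] - lm[4, ])^2))
  if (len < wid - tol) {
    stop("pit length axis (LM1-LM2) must be >= width axis (LM3-LM4)",
         call. = FALSE)
  }
  mid <- (lm[3, ] + lm[4, ]) / 2
  d1 <- sqrt(sum((lm[1, ] - mid)^2))
  d2 <- sqrt(sum((lm[2, ] - mid)^2))
  if (d1 < d2 - tol) {
    stop("LM1 must be the length endpoint farther from the width axis",
         call. = FALSE)
  }
  invisible(x)
}

#' Bundle landmark configurations with specimen metadata
#'
#' @param configs List of [score_profile()] or [pit_config()] objects,
#'   all of the same type.
#' @param metadata Optional data frame with columns `specimen_id`,
#'   `park`, `captivity`, `prey_size`.  When missing it is assembled
#'   from the configurations' own group labels.
#' @return An object of class `landmark_dataset` with elements
#'   `configs`, `dimensionality`, `n_landmarks`, `metadata`.
#' @export
landmark_dataset <- function(configs, metadata = NULL) {
  if (length(configs) == 0) stop("empty dataset", call. = FALSE)
  dims <- vapply(configs, function(cf) ncol(cf$landmarks), integer(1))
  nlm <- vapply(configs, function(cf) nrow(cf$landmarks), integer(1))
  if (length(unique(dims)) != 1L || length(unique(nlm)) != 1L) {
    stop("all configurations must share landmark count and dimensionality",
         call. = FALSE)
  }
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids)) {
    stop("specimen ids must be unique", call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- data.frame(
      specimen_id = ids,
      park = vapply(configs, function(cf)
        as.character(cf$group_labels$park %||% NA), character(1)),
      captivity = vapply(configs, function(cf)
        as.character(cf$group_labels$captivity %||% NA), character(1)),
      prey_size = vapply(configs, function(cf)
        as.character(cf$group_labels$prey_size %||% NA), character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!all(ids %in% metadata$specimen_id)) {
    stop("every configuration needs a metadata row", call. = FALSE)
  }
  metadata <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(configs = configs, dimensionality = dims[1],
         n_landmarks = nlm[1], metadata = metadata),
    class = "landmark_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("<landmark_dataset> %d specimens, %d landmarks, %dD\n",
              length(x$configs), x$n_landmarks, x$dimensionality))
  invisible(x)
}

#' @export
length.landmark_dataset <- function(x) length(x$configs)

#' Stack a landmark dataset into an array
#'
#' @param dataset A [landmark_dataset()].
#' @return A `n_landmarks` x `dim` x `n_specimens` numeric array with
#'   specimen ids as the third dimension names.
#' @export
as_landmark_array <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- length(dataset$configs)
  arr <- array(NA_real_,
               dim = c(dataset$n_landmarks, dataset$dimensionality, n),
               dimnames = list(NULL, NULL, dataset$metadata$specimen_id))
  for (i in seq_len(n)) arr[, , i] <- dataset$configs[[i]]$landmarks
  arr
}

#' Subset a landmark dataset by specimen
#'
#' @param dataset A [landmark_dataset()].
#' @param keep Logical or integer index over specimens.
#' @return A [landmark_dataset()] restricted to the selected specimens.
#' @export
subset_dataset <- function(dataset, keep) {
  landmark_dataset(dataset$configs[keep],
                   dataset$metadata[keep, , drop = FALSE])
}
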