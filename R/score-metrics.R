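#' Place computed wall landmarks on a cross-section polyline
#'
#' The four wall landmarks of the 7-landmark tooth-score model are not
#' digitised by hand: given a traced cross-section polyline and the
#' indices of the two shoulders (LM1, LM7) and the deepest point (LM4),
#' LM2 and LM3 are placed at 1/3 and 2/3 of the arc length along the
#' left wall (LM1 to LM4), and LM5 and LM6 at 1/3 and 2/3 of the arc
#' length from LM4 towards LM7.  LM5 is therefore nearer the base and
#' LM6 nearer the shoulder, mirroring the LM2/LM3 order, so that
#' WIM = |LM2-LM6| pairs the shoulder-adjacent computed points and
#' WIB = |LM3-LM5| the base-adjacent ones.
#'
#' @param profile Numeric matrix (>= 3 x 2) of polyline vertices in mm.
#' @param shoulders_and_base Integer vector of length 3: the row indices
#'   of LM1, LM4 and LM7 within `profile`, with LM4 strictly between the
#'   other two.
#' @inheritParams score_profile
#' @return A [score_profile()].
#' @export
compute_wall_landmarks <- function(profile, shoulders_and_base = c(1, NA, NA),
                                   specimen_id = "specimen",
                                   group_labels = list(park = NA,
                                                       captivity = NA,
                                                       prey_size = NA)) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 3 || ncol(profile) != 2) {
    stop("profile must be a polyline of at least 3 points in 2D",
         call. = FALSE)
  }
  idx <- shoulders_and_base
  if (length(idx) != 3 || anyNA(idx)) {
    stop("shoulders_and_base must give the indices of LM1, LM4 and LM7",
         call. = FALSE)
  }
  i1 <- idx[1]; i4 <- idx[2]; i7 <- idx[3]
  if (!(i1 < i4 && i4 < i7) && !(i7 < i4 && i4 < i1)) {
    stop("LM4 must lie strictly between the shoulders along the polyline",
         call. = FALSE)
  }
  left <- profile[i1:i4, , drop = FALSE]
  right <- profile[i4:i7, , drop = FALSE]
  lm23 <- interp_arclength(left, c(1 / 3, 2 / 3))
  lm56 <- interp_arclength(right, c(1 / 3, 2 / 3))
  lms <- rbind(profile[i1, ], lm23[1, ], lm23[2, ], profile[i4, ],
               lm56[1, ], lm56[2, ], profile[i7, ])
  score_profile(lms, specimen_id, group_labels)
}

# Points at given fractions of total arc length along a polyline.
interp_arclength <- function(poly, fracs) {
  seg <- diff(poly)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total < .Machine$double.eps) {
    stop("degenerate wall of zero length", call. = FALSE)
  }
  cum <- c(0, cumsum(seg_len))
  t(vapply(fracs, function(f) {
    s <- f * total
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(j, nrow(poly) - 1L)
    w <- if (seg_len[j] > 0) (s - cum[j]) / seg_len[j] else 0
    poly[j, ] + w * seg[j, ]
  }, numeric(2)))
}

#' Derived measurements of a tooth-score cross-section
#'
#' Computes the seven standard measurements from a 7-landmark profile:
#' the widths of the incision at the surface (WIS = |LM1-LM7|), midway
#' (WIM = |LM2-LM6|) and near the base (WIB = |LM3-LM5|); the left and
#' right depths at convergent (LDC = |LM1-LM4|, RDC = |LM7-LM4|); the
#' depth D, the perpendicular distance from LM4 to the LM1-LM7 chord;
#' and the opening angle OA, the interior angle of the LM1-LM4-LM7
#' triangle at LM4, in degrees.
#'
#' @param config A [score_profile()] (or bare 7 x 2 matrix).
#' @return A one-row data frame with columns `WIS`, `WIM`, `WIB`, `D`,
#'   `LDC`, `RDC` (mm) and `OA` (degrees).
#' @export
score_metrics <- function(config) {
  lm <- if (inherits(config, "score_profile")) config$landmarks else
    as.matrix(config)
  if (nrow(lm) != 7 || ncol(lm) != 2) {
    stop("score_metrics requires a 7-landmark 2D configuration",
         call. = FALSE)
  }
  d <- function(i, j) sqrt(sum((lm[i, ] - lm[j, ])^2))
  wis <- d(1, 7)
  if (wis < .Machine$double.eps) {
    stop("coincident LM1/LM7: opening width undefined", call. = FALSE)
  }
  u <- lm[1, ] - lm[4, ]
  v <- lm[7, ] - lm[4, ]
  ldc <- sqrt(sum(u^2))
  rdc <- sqrt(sum(v^2))
  if (ldc < .Machine$double.eps || rdc < .Machine$double.eps) {
    stop("LM4 coincides with a shoulder: opening angle undefined",
         call. = FALSE)
  }
  # perpendicular distance via the 2D cross product |u x v| / |LM1-LM7|
  depth <- abs(u[1] * v[2] - u[2] * v[1]) / wis
  cosang <- sum(u * v) / (ldc * rdc)
  oa <- rad2deg(acos(min(1, max(-1, cosang))))
  data.frame(WIS = wis, WIM = d(2, 6), WIB = d(3, 5), D = depth,
             LDC = ldc, RDC = rdc, OA = oa)
}

#' Measurement table for a whole dataset
#'
#' Applies [score_metrics()] to every specimen and binds the group
#' metadata columns.
#'
#' @param dataset A [landmark_dataset()] of score profiles.
#' @return A data frame with one row per specimen: `specimen_id`,
#'   `park`, `captivity`, `prey_size`, then the seven measurements.
#' @export
score_metrics_table <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  mets <- do.call(rbind, lapply(dataset$configs, score_metrics))
  cbind(dataset$metadata, mets)
}

#' Write a measurement table to CSV
#' @param metrics Data frame from [score_metrics_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
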