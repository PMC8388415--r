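#' Read a morphologika landmark file
#'
#' Parses the classic whitespace-delimited morphologika dialect:
#' bracketed, case-insensitive keywords (`[individuals]`, `[landmarks]`,
#' `[dimensions]`, `[names]`, `[labels]`, `[labelvalues]`,
#' `[rawpoints]`), one coordinate row per landmark.  Group labels
#' (`park`, `captivity`, `prey_size`) are recovered from the
#' `[labels]`/`[labelvalues]` block when present.  Unknown blocks are
#' skipped with a warning.  Coordinates are taken to be in mm.
#'
#' @param path Path to the file.
#' @return A [landmark_dataset()].
#' @export
read_morphologika <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)

  is_key <- grepl("^\\[.+\\]$", trimmed)
  key_at <- which(is_key)
  if (length(key_at) == 0) {
    stop("malformed morphologika file: no [keyword] blocks found",
         call. = FALSE)
  }
  keys <- tolower(gsub("^\\[|\\]$", "", trimmed[key_at]))

  block <- function(name) {
    i <- which(keys == name)
    if (length(i) == 0) return(NULL)
    from <- key_at[i[1]] + 1L
    to <- if (i[1] < length(key_at)) key_at[i[1] + 1L] - 1L else length(lines)
    if (to < from) return(character(0))
    body <- trimmed[from:to]
    body[nzchar(body)]
  }

  known <- c("individuals", "landmarks", "dimensions", "names", "labels",
             "labelvalues", "rawpoints")
  unknown <- setdiff(unique(keys), known)
  if (length(unknown)) {
    warning("ignoring unknown morphologika block(s): ",
            paste0("[", unknown, "]", collapse = ", "), call. = FALSE)
  }

  read_count <- function(name) {
    b <- block(name)
    if (is.null(b) || length(b) == 0) {
      stop("malformed header: missing [", name, "] block", call. = FALSE)
    }
    n <- suppressWarnings(as.integer(b[1]))
    if (is.na(n) || n < 1) {
      stop("malformed header: [", name, "] must declare a positive count ",
           "(got '", b[1], "')", call. = FALSE)
    }
    n
  }
  n_ind <- read_count("individuals")
  n_lm <- read_count("landmarks")
  n_dim <- read_count("dimensions")
  if (!n_dim %in% c(2L, 3L)) {
    stop("[dimensions] must be 2 or 3, got ", n_dim, call. = FALSE)
  }

  nm <- block("names")
  names_vec <- if (!is.null(nm) && length(nm) >= n_ind) {
    nm[seq_len(n_ind)]
  } else {
    sprintf("specimen_%d", seq_len(n_ind))
  }

  label_names <- block("labels")
  label_vals <- block("labelvalues")
  labels_df <- NULL
  if (!is.null(label_names) && !is.null(label_vals)) {
    label_names <- unlist(strsplit(paste(label_names, collapse = " "),
                                   "\\s+"))
    vals <- lapply(label_vals, function(l) unlist(strsplit(l, "\\s+")))
    if (length(vals) >= n_ind &&
        all(lengths(vals[seq_len(n_ind)]) == length(label_names))) {
      labels_df <- as.data.frame(do.call(rbind, vals[seq_len(n_ind)]),
                                 stringsAsFactors = FALSE)
      names(labels_df) <- tolower(label_names)
    } else {
      warning("label block inconsistent with declared counts; ignored",
              call. = FALSE)
    }
  }

  raw <- block("rawpoints")
  if (is.null(raw)) {
    stop("malformed file: missing [rawpoints] block", call. = FALSE)
  }
  # specimen separators start with a quote (e.g. "' specimen_1"); they are
  # optional, in which case coordinates are read in declared-count order.
  sep_at <- grepl("^'", raw)
  coord_lines <- raw[!sep_at]
  coords <- lapply(seq_along(coord_lines), function(i) {
    v <- suppressWarnings(as.numeric(unlist(strsplit(coord_lines[i], "\\s+"))))
    if (length(v) != n_dim || any(is.na(v))) {
      stop("coordinate parse error in [rawpoints] at line '",
           coord_lines[i], "' (expected ", n_dim, " numeric values)",
           call. = FALSE)
    }
    v
  })
  if (length(coords) != n_ind * n_lm) {
    stop("coordinate count mismatch: declared ", n_ind, " x ", n_lm,
         " = ", n_ind * n_lm, " rows but found ", length(coords),
         call. = FALSE)
  }
  mat <- do.call(rbind, coords)

  get_label <- function(i, what) {
    if (!is.null(labels_df) && what %in% names(labels_df)) {
      labels_df[[what]][i]
    } else {
      NA_character_
    }
  }
  configs <- lapply(seq_len(n_ind), function(i) {
    lm <- mat[((i - 1) * n_lm + 1):(i * n_lm), , drop = FALSE]
    gl <- list(park = get_label(i, "park"),
               captivity = get_label(i, "captivity"),
               prey_size = get_label(i, "prey_size"))
    if (n_lm == 7 && n_dim == 2) {
      score_profile(lm, names_vec[i], gl)
    } else if (n_lm == 30 && n_dim == 3) {
      pit_config(lm, names_vec[i], gl)
    } else {
      structure(list(landmarks = lm, specimen_id = names_vec[i],
                     group_labels = gl), class = "landmark_config")
    }
  })
  landmark_dataset(configs)
}

#' Write a landmark dataset to a morphologika file
#'
#' Inverse of [read_morphologika()]; the round trip is lossless to the
#' printed precision (15 significant digits).
#'
#' @param dataset A [landmark_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morphologika <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- length(dataset$configs)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("[individuals]", as.character(n))
  w("[landmarks]", as.character(dataset$n_landmarks))
  w("[dimensions]", as.character(dataset$dimensionality))
  w("[names]")
  w(dataset$metadata$specimen_id)
  w("[labels]", "park captivity prey_size")
  w("[labelvalues]")
  for (i in seq_len(n)) {
    w(paste(dataset$metadata$park[i], dataset$metadata$captivity[i],
            dataset$metadata$prey_size[i]))
  }
  w("[rawpoints]")
  for (i in seq_len(n)) {
    w(paste0("' ", dataset$metadata$specimen_id[i]))
    lm <- dataset$configs[[i]]$landmarks
    for (j in seq_len(nrow(lm))) {
      w(paste(formatC(lm[j, ], format = "g", digits = 15), collapse = " "))
    }
  }
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Supports the common tpsDig dialect: repeated records of `LM=<k>`
#' followed by k coordinate rows, with optional `ID=`, `IMAGE=` and
#' `SCALE=` lines per record.  When a `SCALE=` factor is present,
#' coordinates are multiplied by it (yielding mm for mm-calibrated
#' digitisations).
#'
#' @param path Path to the file.
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines, ignore.case = TRUE)
  if (length(starts) == 0) {
    stop("malformed TPS file: no LM= records", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    hdr <- rec[1]
    is3d <- grepl("^LM3=", hdr, ignore.case = TRUE)
    k <- suppressWarnings(as.integer(sub("^LM3?=", "", hdr,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1) {
      stop("malformed TPS record header: '", hdr, "'", call. = FALSE)
    }
    body <- rec[-1]
    coord_rows <- body[!grepl("^[A-Za-z]+=", body)]
    if (length(coord_rows) < k) {
      stop("TPS record declares ", k, " landmarks but holds ",
           length(coord_rows), " coordinate rows", call. = FALSE)
    }
    ndim <- if (is3d) 3L else 2L
    mat <- t(vapply(coord_rows[seq_len(k)], function(l) {
      v <- suppressWarnings(as.numeric(unlist(strsplit(l, "\\s+"))))
      if (length(v) != ndim || any(is.na(v))) {
        stop("TPS coordinate parse error at line '", l, "'", call. = FALSE)
      }
      v
    }, numeric(ndim)))
    id_line <- grep("^ID=", body, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1],
                                   ignore.case = TRUE) else sprintf("tps_%d", r)
    sc_line <- grep("^SCALE=", body, ignore.case = TRUE, value = TRUE)
    if (length(sc_line)) {
      mat <- mat * as.numeric(sub("^SCALE=", "", sc_line[1],
                                  ignore.case = TRUE))
    }
    gl <- list(park = NA, captivity = NA, prey_size = NA)
    configs[[r]] <- if (k == 7 && ndim == 2) {
      score_profile(mat, id, gl)
    } else if (k == 30 && ndim == 3) {
      pit_config(mat, id, gl)
    } else {
      structure(list(landmarks = unname(mat), specimen_id = id,
                     group_labels = gl), class = "landmark_config")
    }
  }
  landmark_dataset(configs)
}

#' Read a specimen metadata table
#'
#' @param path CSV file with columns `specimen_id`, `park`, `captivity`,
#'   `prey_size`.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "park", "captivity", "prey_size")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md
}
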