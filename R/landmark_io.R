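# Landmark sequence container and I/O.
#
# A record is one short video of one subject: N frames x 106 points x 2
# absolute pixel coordinates (image origin top-left, n growing downward),
# plus subject/record/label metadata.  Records with any missing point are
# rejected at load -- filtering happens at record level, never by imputation.

VALID_LABELS <- c("PD", "control")

#' Construct a landmark sequence
#'
#' @param coords Numeric array `N x P x 2` (frames x points x (m, n)) with
#'   point names as the second dimnames, or a list of `P x 2` per-frame
#'   matrices.
#' @param subject_id,record_id Opaque identifier strings.
#' @param label `"PD"` or `"control"`.
#' @param frame_interval_s Seconds between consecutive frames (default 0.1,
#'   i.e. 10 frames per second of video).
#' @param schema A [face_schema()]; coordinates are checked and ordered
#'   against it.
#' @return Object of class `landmark_sequence` with fields `coords` (array),
#'   `subject_id`, `record_id`, `label`, `frame_interval_s`.
#' @export
landmark_sequence <- function(coords, subject_id, record_id, label,
                              frame_interval_s = 0.1,
                              schema = face_schema()) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 2)
  pn <- dimnames(coords)[[2]]
  if (is.null(pn)) {
    if (dim(coords)[2] != length(schema$names)) {
      stop("coords has ", dim(coords)[2], " points, schema has ",
           length(schema$names))
    }
    dimnames(coords) <- list(NULL, schema$names, c("m", "n"))
  } else {
    miss <- setdiff(schema$names, pn)
    extra <- setdiff(pn, schema$names)
    if (length(miss) || length(extra)) {
      stop("point names do not match schema; missing: [",
           paste(miss, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    }
    coords <- coords[, schema$names, , drop = FALSE]
    dimnames(coords)[[3]] <- c("m", "n")
  }
  if (dim(coords)[1] < 1) stop("a landmark sequence needs at least 1 frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in record ",
                                    record_id)
  label <- normalize_label(label)
  structure(
    list(coords = coords, subject_id = as.character(subject_id),
         record_id = as.character(record_id), label = label,
         frame_interval_s = as.numeric(frame_interval_s)),
    class = "landmark_sequence"
  )
}

normalize_label <- function(label) {
  lab <- trimws(as.character(label))
  out <- c(pd = "PD", control = "control", ctrl = "control",
           healthy = "control", hc = "control")[tolower(lab)]
  if (anyNA(out)) {
    stop("unknown label '", lab[is.na(out)][1], "'; expected one of ",
         paste(VALID_LABELS, collapse = "/"))
  }
  unname(out)
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf(
    "<landmark_sequence> record %s (subject %s, %s): %d frames x %d points, dt=%gs\n",
    x$record_id, x$subject_id, x$label, n_frames(x), dim(x$coords)[2],
    x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `landmark_sequence` or `relative_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Frame times in seconds
#' @param seq A `landmark_sequence` or `relative_sequence`.
#' @return Numeric vector `(0:(N-1)) * frame_interval_s`.
#' @export
frame_times <- function(seq) (seq_len(n_frames(seq)) - 1) * seq$frame_interval_s

#' Read one frame of landmarks from a Face++-dialect JSON file
#'
#' The dialect is a JSON object with a `landmark` mapping (or the mapping at
#' top level) from point name to `{x, y}` pixel coordinates; files produced
#' by a Detect-style landmark endpoint with 106-point output can be reshaped
#' into it.  All 106 schema points must be present.
#'
#' @param path JSON file path.
#' @param schema A [face_schema()].
#' @return Numeric matrix `106 x 2` (columns `m`, `n`) in schema order.
#' @export
read_faceplusplus_json <- function(path, schema = face_schema()) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (!is.null(obj$landmark)) obj <- obj$landmark
  if (!is.list(obj) || (length(obj) && is.null(names(obj)))) {
    stop("no landmark mapping found in ", path)
  }
  miss <- setdiff(schema$names, names(obj))
  extra <- setdiff(names(obj), schema$names)
  if (length(miss) || length(extra)) {
    stop("landmark schema mismatch in ", path, "; missing ", length(miss),
         " point(s): [", paste(miss, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  }
  m <- vapply(obj[schema$names], function(p) as.numeric(p$x), numeric(1))
  n <- vapply(obj[schema$names], function(p) as.numeric(p$y), numeric(1))
  out <- cbind(m = m, n = n)
  rownames(out) <- schema$names
  if (!all(is.finite(out))) stop("non-finite landmark coordinates in ", path)
  out
}

#' Write / read the canonical long-format landmark table
#'
#' The on-disk canonical form of one record is a long CSV with columns
#' `frame_index` (0-based), `point_name`, `m`, `n`.  Coordinates are written
#' with 17 significant digits so write-then-read round-trips exactly.
#'
#' @param seq A `landmark_sequence`.
#' @param path CSV file path.
#' @return `write_landmark_table` returns `path` invisibly;
#'   `read_landmark_table` returns a `landmark_sequence`.
#' @export
write_landmark_table <- function(seq, path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  N <- n_frames(seq)
  pn <- dimnames(seq$coords)[[2]]
  dt <- data.table::data.table(
    frame_index = rep(0:(N - 1), each = length(pn)),
    point_name = rep(pn, N),
    m = sprintf("%.17g", as.vector(t(seq$coords[, , 1]))),
    n = sprintf("%.17g", as.vector(t(seq$coords[, , 2])))
  )
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmark_table
#' @param subject_id,record_id,label,frame_interval_s Metadata to attach to
#'   the sequence read back (the table itself stores only coordinates).
#' @param schema A [face_schema()].
#' @export
read_landmark_table <- function(path, subject_id = "", record_id = "",
                                label = "control", frame_interval_s = 0.1,
                                schema = face_schema()) {
  dt <- as.data.frame(data.table::fread(path, colClasses = list(
    integer = "frame_index", character = c("point_name", "m", "n"))))
  req <- c("frame_index", "point_name", "m", "n")
  if (!all(req %in% names(dt))) {
    stop("landmark table ", path, " must have columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(dt[c("frame_index", "point_name")])) {
    stop("duplicate (frame_index, point_name) rows in ", path)
  }
  fidx <- sort(unique(dt$frame_index))
  if (!identical(fidx, 0:(length(fidx) - 1L))) {
    stop("frame indices must be consecutive from 0 in ", path)
  }
  N <- length(fidx)
  P <- length(schema$names)
  if (nrow(dt) != N * P) {
    stop("expected ", N * P, " rows (", N, " frames x ", P, " points) in ",
         path, ", found ", nrow(dt))
  }
  ord <- order(dt$frame_index, match(dt$point_name, schema$names))
  dt <- dt[ord, ]
  coords <- array(NA_real_, c(N, P, 2),
                  dimnames = list(NULL, schema$names, c("m", "n")))
  coords[, , 1] <- matrix(as.numeric(dt$m), N, P, byrow = TRUE)
  coords[, , 2] <- matrix(as.numeric(dt$n), N, P, byrow = TRUE)
  landmark_sequence(coords, subject_id, record_id, label, frame_interval_s,
                    schema)
}

#' Load a dataset of landmark sequences from a manifest
#'
#' The manifest is a CSV with one row per record and columns `subject_id`,
#' `record_id`, `label`, `frame_interval` and `path`.  `path` (relative to
#' the manifest's directory unless absolute) is either a landmark-table CSV
#' or a glob matching one Face++-dialect JSON file per frame (sorted
#' lexicographically into frame order).
#'
#' @param manifest Manifest CSV path.
#' @param schema A [face_schema()].
#' @return List of `landmark_sequence`, one per manifest row.
#' @export
load_dataset <- function(manifest, schema = face_schema()) {
  mf <- as.data.frame(data.table::fread(manifest, colClasses = "character"))
  req <- c("subject_id", "record_id", "label", "frame_interval", "path")
  if (!all(req %in% names(mf))) {
    stop("manifest must have columns ", paste(req, collapse = ", "))
  }
  base <- dirname(normalizePath(manifest))
  lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    p <- row$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    if (grepl("[*?]", p)) {
      files <- sort(Sys.glob(p))
      if (!length(files)) {
        stop("no frame files match '", row$path, "' for record ",
             row$record_id)
      }
      frames <- lapply(files, read_faceplusplus_json, schema = schema)
      landmark_sequence(frames, row$subject_id, row$record_id, row$label,
                        as.numeric(row$frame_interval), schema)
    } else {
      if (!file.exists(p)) {
        stop("landmark table '", row$path, "' not found for record ",
             row$record_id)
      }
      read_landmark_table(p, row$subject_id, row$record_id, row$label,
                          as.numeric(row$frame_interval), schema)
    }
  })
}

#' Write a cohort to disk in the canonical layout
#'
#' Writes one landmark-table CSV per record plus a `manifest.csv` that
#' [load_dataset()] can read back.
#'
#' @param seqs List of `landmark_sequence`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seqs, function(s) {
    f <- paste0(s$record_id, ".csv")
    write_landmark_table(s, file.path(dir, f))
    data.table::data.table(subject_id = s$subject_id, record_id = s$record_id,
                           label = s$label,
                           frame_interval = s$frame_interval_s, path = f)
  })
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(data.table::rbindlist(rows), mpath)
  invisible(mpath)
}
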