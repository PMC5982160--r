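# Sequence readers/writers: CSV and JSON dialects.
#
# CSV dialect: UTF-8, LF, "." decimal separator. Header lines
#   #fps=<float>
#   #coords=meters
#   #label=<name>        (optional)
# then one row per (frame, joint): frame_index,timestamp,joint,x,y,z
# with frame_index counting from 0 and joint a name from joint_names().
#
# JSON dialect: {fps, label, frames:[{t, positions:{JOINT:[x,y,z], ...}}, ...]}
#
# Numbers are written with 17 significant digits so that a write/read round
# trip reproduces the sequence bit-exactly in either dialect.

.num17 <- function(x) sprintf("%.17g", x)

#' Read a skeleton sequence from file
#'
#' @param path Path to a file in the CSV or JSON dialect (see Details).
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @param joints Joints each frame must contain; defaults to all 20. Pass a
#'   subset to accept partially tracked recordings.
#' @return A [skeleton_sequence()].
#' @details The CSV dialect has header lines `#fps=<float>`,
#'   `#coords=meters` and optionally `#label=<name>`, followed by rows
#'   `frame_index,timestamp,joint,x,y,z`. The JSON dialect is an object
#'   `{fps, label, frames:[{t, positions:{JOINT:[x,y,z],...}},...]}`.
#'   Malformed rows, unknown joint names and non-increasing timestamps each
#'   raise a distinct error naming the offending line or frame.
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, format = c("auto", "csv", "json"),
                          joints = joint_names()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  switch(format,
    csv = .read_sequence_csv(path, joints),
    json = .read_sequence_json(path, joints)
  )
}

.read_sequence_csv <- function(path, joints) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- grepl("^#", lines)
  kv <- sub("^#", "", lines[header])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  if (!"fps" %in% keys) {
    stop("CSV header missing #fps= line", call. = FALSE)
  }
  fps <- suppressWarnings(as.numeric(vals[match("fps", keys)]))
  if (is.na(fps)) stop("unparseable #fps= header", call. = FALSE)
  label <- if ("label" %in% keys) vals[match("label", keys)] else NULL

  data_idx <- which(!header & nzchar(trimws(lines)))
  if (length(data_idx) == 0L) {
    return(skeleton_sequence(list(), fps, label))
  }
  parts <- strsplit(lines[data_idx], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", data_idx[bad[1L]],
      ": expected 6 comma-separated fields",
      call. = FALSE
    )
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  jnames <- m[, 3L]
  unknown <- which(!jnames %in% KINECT_JOINTS)
  if (length(unknown) > 0L) {
    stop("unknown joint name \"", jnames[unknown[1L]], "\" at line ",
      data_idx[unknown[1L]],
      call. = FALSE
    )
  }
  num <- suppressWarnings(apply(m[, c(1L, 2L, 4L, 5L, 6L), drop = FALSE],
    2L, as.numeric
  ))
  num <- matrix(num, ncol = 5L)
  nn <- which(!stats::complete.cases(num))
  if (length(nn) > 0L) {
    stop("malformed row at line ", data_idx[nn[1L]], ": non-numeric field",
      call. = FALSE
    )
  }
  fidx <- num[, 1L]
  frames <- list()
  for (fi in unique(fidx)) {
    rows <- which(fidx == fi)
    ts <- unique(num[rows, 2L])
    if (length(ts) != 1L) {
      stop("inconsistent timestamps within frame ", fi, " at line ",
        data_idx[rows[1L]],
        call. = FALSE
      )
    }
    pos <- num[rows, 3:5, drop = FALSE]
    rownames(pos) <- jnames[rows]
    frames[[length(frames) + 1L]] <- skeleton_frame(pos, ts, joints = joints)
  }
  ts_all <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (length(ts_all) > 1L && any(diff(ts_all) <= 0)) {
    k <- which(diff(ts_all) <= 0)[1L]
    stop("non-increasing timestamps between frames ", k - 1L, " and ", k,
      " (first offending data line ", data_idx[which(fidx == unique(fidx)[k + 1L])[1L]],
      ")",
      call. = FALSE
    )
  }
  skeleton_sequence(frames, fps, label)
}

.read_sequence_json <- function(path, joints) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
    simplifyDataFrame = FALSE
  )
  .sequence_from_obj(obj, joints)
}

# build a skeleton_sequence from a parsed JSON object {fps, label, frames}
.sequence_from_obj <- function(obj, joints) {
  if (is.null(obj$fps)) stop("JSON sequence missing fps", call. = FALSE)
  label <- obj$label
  frames <- lapply(seq_along(obj$frames), function(i) {
    fr <- obj$frames[[i]]
    if (is.null(fr$t) || is.null(fr$positions)) {
      stop("malformed frame ", i, ": needs t and positions", call. = FALSE)
    }
    jn <- names(fr$positions)
    unknown <- setdiff(jn, KINECT_JOINTS)
    if (length(unknown) > 0L) {
      stop("unknown joint name \"", unknown[1L], "\" in frame ", i,
        call. = FALSE
      )
    }
    pos <- do.call(rbind, fr$positions)
    rownames(pos) <- jn
    skeleton_frame(pos, fr$t, joints = joints)
  })
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop("non-increasing timestamps at frame ", which(diff(ts) <= 0)[1L] + 1L,
      call. = FALSE
    )
  }
  skeleton_sequence(frames, obj$fps, label)
}

#' Write a skeleton sequence to file
#'
#' Writes the CSV or JSON dialect read by [read_sequence()]; numbers carry
#' 17 significant digits so the round trip is bit-exact.
#'
#' @param seq A [skeleton_sequence()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  switch(format,
    csv = .write_sequence_csv(seq, path),
    json = .write_sequence_json(seq, path)
  )
  invisible(path)
}

.write_sequence_csv <- function(seq, path) {
  header <- c(
    paste0("#fps=", .num17(seq$fps)),
    "#coords=meters"
  )
  if (!is.null(seq$label)) header <- c(header, paste0("#label=", seq$label))
  rows <- character(0)
  for (i in seq_along(seq$frames)) {
    fr <- seq$frames[[i]]
    pos <- fr$positions
    rows <- c(rows, paste(
      i - 1L, .num17(fr$timestamp), rownames(pos),
      .num17(pos[, 1L]), .num17(pos[, 2L]), .num17(pos[, 3L]),
      sep = ","
    ))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
}

.write_sequence_json <- function(seq, path) {
  frame_json <- vapply(seq$frames, function(fr) {
    pos <- fr$positions
    joints <- vapply(seq_len(nrow(pos)), function(j) {
      sprintf(
        "\"%s\":[%s,%s,%s]", rownames(pos)[j],
        .num17(pos[j, 1L]), .num17(pos[j, 2L]), .num17(pos[j, 3L])
      )
    }, character(1))
    sprintf(
      "{\"t\":%s,\"positions\":{%s}}", .num17(fr$timestamp),
      paste(joints, collapse = ",")
    )
  }, character(1))
  label_json <- if (is.null(seq$label)) {
    "null"
  } else {
    paste0("\"", gsub("\"", "\\\\\"", seq$label), "\"")
  }
  txt <- sprintf(
    "{\"fps\":%s,\"label\":%s,\"frames\":[%s]}",
    .num17(seq$fps), label_json, paste(frame_json, collapse = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
}
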