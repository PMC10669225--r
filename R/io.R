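#' Read and write trajectories
#'
#' CSV layout: two comment header lines `# frame: <name>` and
#' `# unit: mm`, then columns `t,x,y,z`. JSON carries the same fields in an
#' object. Writers emit 12 significant digits so a write/read roundtrip is
#' lossless at that precision.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @export
read_trajectory <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(x$unit, "mm"))
      stop("format-error: trajectory JSON must declare unit 'mm'")
    pts <- as_row_matrix(x$points)
    return(trajectory(as.numeric(x$t), pts, frame = x$frame,
                      label = if (is.null(x$label)) "" else x$label))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  frame <- sub("^#\\s*frame:\\s*", "", grep("frame:", hdr, value = TRUE)[1])
  unit <- sub("^#\\s*unit:\\s*", "", grep("unit:", hdr, value = TRUE)[1])
  if (is.na(unit) || !nzchar(unit) || unit != "mm")
    stop("format-error: trajectory CSV must declare '# unit: mm'")
  if (is.na(frame) || !nzchar(frame))
    stop("format-error: trajectory CSV must declare '# frame: <name>'")
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(sprintf("format-error: missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(!stats::complete.cases(df[need]) |
                 !vapply(seq_len(nrow(df)),
                         function(i) all(is.finite(as.numeric(df[i, need]))),
                         logical(1)))
  if (length(bad))
    stop(sprintf("format-error: malformed rows at lines: %s",
                 paste(bad + 1L + length(hdr), collapse = ", ")))
  if (any(diff(df$t) < 0))
    stop("format-error: timestamps out of order")
  trajectory(df$t, as.matrix(df[c("x", "y", "z")]), frame = frame)
}

#' @rdname read_trajectory
#' @param traj a `trajectory`.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "json") {
    jsonlite::write_json(
      list(frame = traj$frame, unit = "mm", label = traj$label,
           t = traj$t,
           points = apply(traj$points, 1, as.numeric, simplify = FALSE)),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame: %s", traj$frame), "# unit: mm",
               "t,x,y,z"), con)
  writeLines(sprintf("%.12g,%.12g,%.12g,%.12g", traj$t,
                     traj$points[, 1], traj$points[, 2], traj$points[, 3]),
             con)
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

# jsonlite may simplify a list of row vectors to a matrix already
as_row_matrix <- function(x) {
  m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  dimnames(m) <- NULL
  m
}

#' Read and write anatomical landmarks as JSON
#'
#' JSON object with explicit `unit` ("mm") and `frame` fields plus the four
#' landmark vectors and the anterior-point kind.
#'
#' @param path file path.
#' @export
read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$unit, "mm"))
    stop("format-error: landmark JSON must declare unit 'mm'")
  anatomical_landmarks(condyle_right = as.numeric(x$condyle_right),
                       condyle_left = as.numeric(x$condyle_left),
                       anterior_point = as.numeric(x$anterior_point),
                       incisal_point = as.numeric(x$incisal_point),
                       anterior_point_kind = x$anterior_point_kind,
                       frame = x$frame)
}

#' @rdname read_landmarks_json
#' @param landmarks an `anatomical_landmarks` object.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(
    list(unit = "mm", frame = landmarks$frame,
         anterior_point_kind = landmarks$anterior_point_kind,
         condyle_right = landmarks$condyle_right,
         condyle_left = landmarks$condyle_left,
         anterior_point = landmarks$anterior_point,
         incisal_point = landmarks$incisal_point),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Triangle mesh container
#' @param vertices N x 3 matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- rbind(vertices)
  faces <- rbind(faces)
  storage.mode(faces) <- "integer"
  if (!nrow(vertices) || ncol(vertices) != 3L)
    stop("format-error: mesh has no vertices")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("format-error: face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

weld_vertices <- function(V, F, tol = 1e-6) {
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  tri_mesh(V[first, , drop = FALSE],
           matrix(remap[F], ncol = 3L))
}

#' Read a surface mesh (STL or PLY)
#'
#' ASCII and binary STL dialects plus ASCII PLY are accepted; STL facets
#' are welded into an indexed mesh at a 1e-6 mm vertex tolerance.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"` or `"auto"` (from the extension).
#' @return A `tri_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  if (file.size(path) == 0) stop("format-error: empty mesh file")
  if (format == "ply") return(read_ply(path))
  # STL: binary unless the file starts with 'solid' and parses as ASCII
  head <- readBin(path, "raw", n = 5L)
  if (identical(rawToChar(head), "solid")) {
    m <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("format-error: ASCII STL vertex count is not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop("format-error: malformed ASCII STL vertex")
  F <- matrix(seq_len(nrow(nums)), ncol = 3L, byrow = TRUE)
  weld_vertices(nums, F)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + n_tri * 50
  if (sz < expected)
    stop(sprintf("format-error: truncated binary STL (need %d bytes, have %d; truncation at byte offset %d)",
                 expected, sz, sz))
  V <- matrix(0, n_tri * 3L, 3L)
  for (i in seq_len(n_tri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    V[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  weld_vertices(V, matrix(seq_len(n_tri * 3L), ncol = 3L, byrow = TRUE))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1], "ply") || !any(grepl("^format ascii", lines)))
    stop("format-error: only ASCII PLY is supported")
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("format-error: PLY header not terminated")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf_line <- grep("^element face", lines, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line[1])) else 0L
  if (is.na(nv) || length(lines) < hdr_end + nv + nf)
    stop("format-error: truncated PLY body")
  vparse <- strsplit(trimws(lines[(hdr_end + 1):(hdr_end + nv)]), "\\s+")
  V <- t(vapply(vparse, function(x) as.numeric(x[1:3]), numeric(3)))
  F <- matrix(integer(0), 0L, 3L)
  if (nf > 0) {
    fparse <- strsplit(trimws(lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]),
                       "\\s+")
    F <- t(vapply(fparse, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  }
  tri_mesh(V, F)
}

#' Write an ASCII STL mesh
#' @param mesh a `tri_mesh`.
#' @param path file path.
#' @export
write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid artikin", con)
  for (i in seq_len(nrow(mesh$faces))) {
    v <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid artikin", con)
  invisible(path)
}

#' Write a binary STL mesh
#' @param mesh a `tri_mesh`.
#' @param path file path.
#' @export
write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    v <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, t(v))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

#' Read and write marker pose streams
#'
#' CSV layout: a `t` column followed by 16 row-major entries per transform,
#' first the camera<-upper-marker transform (`up_00..up_33`) then the
#' camera<-lower-marker transform (`low_00..low_33`).
#'
#' @param path file path.
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  up_cols <- sprintf("up_%d%d", rep(0:3, each = 4), rep(0:3, 4))
  low_cols <- sprintf("low_%d%d", rep(0:3, each = 4), rep(0:3, 4))
  if (!all(c("t", up_cols, low_cols) %in% names(df)))
    stop("format-error: stream CSV must carry t plus up_ij and low_ij columns")
  mk <- function(row, cols, from) {
    T <- framed_transform(matrix(as.numeric(row[cols]), 4, 4, byrow = TRUE),
                          from = from, to = "camera")
    T
  }
  cam_up <- lapply(seq_len(nrow(df)),
                   function(i) mk(df[i, ], up_cols, "marker_up"))
  cam_low <- lapply(seq_len(nrow(df)),
                    function(i) mk(df[i, ], low_cols, "marker_low"))
  marker_pose_stream(df$t, cam_up, cam_low)
}

#' @rdname read_stream_csv
#' @param stream a `marker_pose_stream`.
#' @export
write_stream_csv <- function(stream, path) {
  n <- length(stream$t)
  M <- matrix(0, n, 33)
  M[, 1] <- stream$t
  for (i in seq_len(n)) {
    M[i, 2:17] <- as.vector(t(stream$cam_up[[i]]$matrix))
    M[i, 18:33] <- as.vector(t(stream$cam_low[[i]]$matrix))
  }
  cols <- c("t",
            sprintf("up_%d%d", rep(0:3, each = 4), rep(0:3, 4)),
            sprintf("low_%d%d", rep(0:3, each = 4), rep(0:3, 4)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(M, 1, function(r) paste(sprintf("%.15g", r),
                                           collapse = ",")), con)
  invisible(path)
}

#' Run configuration
#'
#' Tunable tolerances and defaults shared by the CLI subcommands; round-trips
#' unchanged through a plain `key = value` text file.
#'
#' @param ... overrides of the defaults.
#' @export
run_config <- function(...) {
  cfg <- list(ik_tol = 1e-8, icp_tol = 1e-6, bisect_tol = 1e-4,
              proxy_radius = 0.3, proxy_spacing = 0.5,
              nurbs_degree = 3, clearance = 0.01,
              seed = 1, out_dir = ".", log_level = "info")
  dots <- list(...)
  cfg[names(dots)] <- dots
  num <- c("ik_tol", "icp_tol", "bisect_tol", "proxy_radius",
           "proxy_spacing", "clearance")
  for (k in num)
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      stop(sprintf("invalid-argument: tolerance '%s' must be > 0", k))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path file path of a `key = value` config file.
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v))
      as.numeric(v)
    else v
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  writeLines(vapply(names(unclass(cfg)), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.numeric(v)) sprintf("%.12g", v) else v)
  }, character(1)), path)
  invisible(path)
}
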