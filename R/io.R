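# Readers and writers for the surface formats 3D reconstruction tools
# export (PLY ascii/binary-little-endian, STL ascii/binary, OBJ, XYZ).
# Meshes are converted to point clouds by vertex extraction with
# duplicate-vertex dedup; faces are ignored.

detect_format <- function(path, format = "auto") {
  format <- tolower(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "stl", "obj", "xyz", "txt"))
    return(if (ext == "txt") "xyz" else ext)
  stop("cannot determine point-cloud format of: ", path, call. = FALSE)
}

finite_or_die <- function(m, path) {
  if (!all(is.finite(m)))
    stop("non-finite coordinates (NaN/Inf) in: ", path, call. = FALSE)
  m
}

dedup_vertices <- function(m, tol = 1e-6) {
  key <- paste(round(m[, 1] / tol), round(m[, 2] / tol), round(m[, 3] / tol))
  m[!duplicated(key), , drop = FALSE]
}

#' Read a point cloud or mesh surface
#'
#' Supported formats: PLY (ascii and binary little-endian), STL (ascii and
#' binary), OBJ (`v` records), and plain whitespace-separated XYZ. Meshes
#' are converted to clouds by vertex extraction (duplicate vertices within
#' 1e-6 mm merged); connectivity is discarded. Units are assumed to be mm.
#'
#' @param path input file.
#' @param format `"auto"` (by extension) or one of `"ply"`, `"stl"`,
#'   `"obj"`, `"xyz"`.
#' @param dedup merge duplicate vertices (default TRUE for mesh formats).
#' @param label optional label for the resulting cloud.
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = "auto", dedup = TRUE,
                             label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- detect_format(path, format)
  m <- switch(format,
              ply = read_ply(path),
              stl = read_stl(path),
              obj = read_obj(path),
              xyz = read_xyz(path),
              stop("unsupported format: ", format, call. = FALSE))
  if (nrow(m) == 0L) stop("no geometry found in: ", path, call. = FALSE)
  finite_or_die(m, path)
  if (dedup && format %in% c("stl", "obj", "ply")) m <- dedup_vertices(m)
  point_cloud(m, label = label)
}

read_xyz <- function(path) {
  df <- read.table(path, header = FALSE)
  if (ncol(df) < 3L) stop("XYZ file needs at least 3 columns: ", path,
                          call. = FALSE)
  as.matrix(df[, 1:3])
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v <- lines[grepl("^v\\s", lines)]
  if (length(v) == 0L) return(matrix(numeric(0), 0, 3))
  parts <- strsplit(trimws(sub("^v\\s+", "", v)), "\\s+")
  do.call(rbind, lapply(parts, function(p) as.numeric(p[1:3])))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header: ", path,
                               call. = FALSE)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!grepl("^ply", header[1]))
    stop("not a PLY file: ", path, call. = FALSE)
  fmt <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format (only ascii and binary_little_endian): ",
         path, call. = FALSE)
  ve <- grep("^element vertex", header)
  if (length(ve) == 0L) stop("PLY file has no vertex element: ", path,
                             call. = FALSE)
  nv <- as.integer(strsplit(trimws(header[ve[1]]), "\\s+")[[1]][3])
  # properties of the vertex element (up to the next element line)
  after <- header[(ve[1] + 1L):length(header)]
  nxt <- grep("^element|^end_header", after)[1]
  props <- grep("^property", after[seq_len(nxt - 1L)], value = TRUE)
  ptypes <- vapply(strsplit(trimws(props), "\\s+"), `[`, character(1), 2L)
  pnames <- vapply(strsplit(trimws(props), "\\s+"), `[`, character(1), 3L)
  xyz_idx <- match(c("x", "y", "z"), pnames)
  if (any(is.na(xyz_idx)))
    stop("PLY vertex element lacks x/y/z properties: ", path, call. = FALSE)
  if (binary) {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[ptypes]
    if (any(is.na(sz)))
      stop("unsupported PLY property type in: ", path, call. = FALSE)
    stride <- sum(sz)
    raw <- readBin(con, "raw", n = nv * stride)
    if (length(raw) < nv * stride)
      stop("truncated PLY payload: ", path, call. = FALSE)
    offs <- cumsum(c(0L, sz))[seq_along(sz)]
    read_col <- function(j) {
      type <- ptypes[j]
      width <- sz[j]
      starts <- (seq_len(nv) - 1L) * stride + offs[j]
      idx <- rep(starts, each = width) + seq_len(width)
      col_raw <- raw[idx]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(col_raw, what, n = nv, size = width, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    m <- cbind(read_col(xyz_idx[1]), read_col(xyz_idx[2]),
               read_col(xyz_idx[3]))
  } else {
    txt <- readLines(con, n = -1L, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nv) stop("truncated PLY payload: ", path, call. = FALSE)
    rows <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[xyz_idx])))
  }
  m
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(512, sz))
  close(con)
  printable <- head_raw >= as.raw(9) & head_raw < as.raw(127)
  head_txt <- rawToChar(head_raw[printable])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    v <- grep("^\\s*vertex\\s", lines, value = TRUE)
    parts <- strsplit(trimws(sub("^\\s*vertex\\s+", "", v)), "\\s+")
    do.call(rbind, lapply(parts, function(p) as.numeric(p[1:3])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    m <- matrix(NA_real_, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)  # attribute byte count
      m[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
    m
  }
}

#' Write a point cloud
#'
#' @param cloud a [point_cloud()] or N x 3 matrix.
#' @param path output file; format from extension unless given.
#' @param format `"auto"`, `"ply"`, or `"xyz"`.
#' @param binary for PLY: write binary little-endian instead of ascii.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = "auto", binary = FALSE) {
  m <- as_cloud_matrix(cloud)
  format <- detect_format(path, format)
  if (format == "xyz") {
    write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (format == "ply") {
    header <- c("ply",
                sprintf("format %s 1.0",
                        if (binary) "binary_little_endian" else "ascii"),
                sprintf("element vertex %d", nrow(m)),
                "property double x", "property double y", "property double z",
                "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(header, con, sep = "\n")
      writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(header, con)
      writeLines(apply(m, 1L, function(r)
        paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = " ")), con)
    }
  } else {
    stop("unsupported output format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Read a case bundle description
#'
#' A YAML file tying one case together: the six cloud files (two epochs x
#' femur reference / proximal pin / distal pin), the nominal pin lengths,
#' and optional hook hints and landmark file. Schema:
#' ```yaml
#' case_id: case-01
#' postop:   {femur_ref: f0.ply, proximal_pin: p0.ply, distal_pin: d0.ply}
#' followup: {femur_ref: f1.ply, proximal_pin: p1.ply, distal_pin: d1.ply}
#' proximal: {length_mm: 80, hook_hint: [0, 1, 0]}
#' distal:   {length_mm: 90}
#' landmarks: landmarks.json   # optional
#' ```
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return list of class `"case_bundle"` with loaded clouds and metadata.
#' @export
read_case_bundle <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  clouds <- list()
  for (epoch in c("postop", "followup")) {
    if (is.null(y[[epoch]]))
      stop("case bundle missing section: ", epoch, call. = FALSE)
    clouds[[epoch]] <- lapply(
      stats::setNames(nm = c("femur_ref", "proximal_pin", "distal_pin")),
      function(role) {
        f <- y[[epoch]][[role]]
        if (is.null(f))
          stop(sprintf("case bundle missing %s/%s", epoch, role),
               call. = FALSE)
        read_point_cloud(resolve(f), label = role)
      })
  }
  pins <- lapply(stats::setNames(nm = c("proximal", "distal")), function(nm) {
    p <- y[[nm]]
    list(length_mm = if (is.null(p$length_mm)) NA_real_ else p$length_mm,
         hook_hint = if (is.null(p$hook_hint)) NULL else as.numeric(p$hook_hint))
  })
  structure(list(case_id = y$case_id %||% "case",
                 postop = clouds$postop, followup = clouds$followup,
                 pins = pins,
                 landmarks = if (!is.null(y$landmarks))
                   resolve(y$landmarks) else NULL),
            class = "case_bundle")
}

#' Write a migration report
#'
#' Serializes a [pin_migration()] report as versioned JSON plus CSV
#' renderings: one per-pin summary table (relative angle and endpoint
#' movements), one per-axis displacement-component table, and one
#' registration-quality table. CSV numbers are rounded (half-even) to two
#' decimal places, the convention for reporting such measurements.
#'
#' @param report a `"pin_migration"` object.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pin_migration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "migration_report.json"),
             summary = file.path(dir, "pin_summary.csv"),
             components = file.path(dir, "pin_components.csv"),
             quality = file.path(dir, "registration_quality.csv"))
  jsonlite::write_json(report_to_list(report), paths["json"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  s <- report$summary_table
  s[-1] <- lapply(s[-1], round, digits = 2)
  write.csv(s, paths["summary"], row.names = FALSE)
  comp <- report$component_table
  comp[-(1:2)] <- lapply(comp[-(1:2)], round, digits = 2)
  write.csv(comp, paths["components"], row.names = FALSE)
  q <- quality_to_list(report$quality)
  qdf <- data.frame(metric = names(q), value = round(unlist(q), 2))
  write.csv(qdf, paths["quality"], row.names = FALSE)
  invisible(paths)
}

report_to_list <- function(report) {
  list(schema_version = "1.0",
       case_id = report$case_id,
       registration = list(
         iterations = report$icp$iterations_run,
         converged = report$icp$converged,
         final_cost_mm2 = report$icp$cost_trace[report$icp$iterations_run],
         rotation = report$icp$transform$rotation,
         translation = report$icp$transform$translation),
       quality = quality_to_list(report$quality),
       scale_factors = report$scale_factors,
       pins = lapply(report$pins, function(p) {
         list(relative_angle_deg = p$relative_angle_deg,
              top_movement_mm = p$top_movement_mm,
              bottom_movement_mm = p$bottom_movement_mm,
              top_components_mm = as.list(p$top_components_mm),
              bottom_components_mm = as.list(p$bottom_components_mm))
       }))
}

#' Read back a JSON migration report
#'
#' @param path JSON file written by [write_report()].
#' @return the parsed report list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
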