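#' Read and write triangle meshes (PLY, OBJ, OFF)
#'
#' Plain-text readers and writers for the three common triangle-mesh
#' interchange formats (ascii PLY, Wavefront OBJ, OFF). Only vertex
#' positions and triangular faces are handled.
#'
#' @param mesh a [tri_mesh()].
#' @param path file path; the extension (`.ply`, `.obj`, `.off`) selects
#'   the format unless `format` is given.
#' @param format optional explicit format, one of `"ply"`, `"obj"`,
#'   `"off"`.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns a
#'   [tri_mesh()].
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- format %||% tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  lines <- switch(format,
    ply = c(
      "ply", "format ascii 1.0",
      paste("element vertex", nrow(v)),
      "property float x", "property float y", "property float z",
      paste("element face", nrow(f)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    ),
    obj = c(
      sprintf("v %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    ),
    off = c(
      "OFF",
      paste(nrow(v), nrow(f), 0),
      sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    ),
    stop("unknown mesh format: ", format)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  switch(format,
    ply = {
      end <- which(lines == "end_header")[1]
      nv <- as.integer(sub("element vertex ", "",
                           grep("^element vertex", lines, value = TRUE)[1]))
      nf <- as.integer(sub("element face ", "",
                           grep("^element face", lines, value = TRUE)[1]))
      vb <- utils::read.table(text = lines[end + seq_len(nv)])
      fb <- utils::read.table(text = lines[end + nv + seq_len(nf)])
      tri_mesh(as.matrix(vb[, 1:3]), as.matrix(fb[, 2:4]) + 1L)
    },
    obj = {
      vl <- grep("^v ", lines, value = TRUE)
      fl <- grep("^f ", lines, value = TRUE)
      vb <- utils::read.table(text = sub("^v ", "", vl))
      fparts <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p) {
        as.integer(sub("/.*$", "", p))
      })
      tri_mesh(as.matrix(vb[, 1:3]), do.call(rbind, fparts))
    },
    off = {
      stopifnot(trimws(lines[1]) == "OFF")
      counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
      vb <- utils::read.table(text = lines[2 + seq_len(counts[1])])
      fb <- utils::read.table(text = lines[2 + counts[1] + seq_len(counts[2])])
      tri_mesh(as.matrix(vb[, 1:3]), as.matrix(fb[, 2:4]) + 1L)
    },
    stop("unknown mesh format: ", format)
  )
}
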