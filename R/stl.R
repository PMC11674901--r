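#' Write meshes to a multi-solid ASCII STL file
#'
#' The canonical interchange format of the pipeline: one `solid <name>`
#' block per mesh.  Binary STL cannot carry names, so labeled multi-part
#' models always travel as ASCII.
#'
#' @param meshes a named list of [trimesh] objects, or a single mesh.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(meshes, path) {
  if (inherits(meshes, "trimesh")) meshes <- list(meshes)
  if (is.null(names(meshes)) || any(names(meshes) == ""))
    names(meshes) <- vapply(seq_along(meshes), function(i) {
      nm <- meshes[[i]]$name
      if (nzchar(nm)) nm else paste0("solid", i)
    }, "")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    fn <- face_normals(m)
    V <- m$vertices
    F <- m$faces
    writeLines(paste0("solid ", nm), con)
    if (nrow(F) > 0) {
      v1 <- V[F[, 1], , drop = FALSE]
      v2 <- V[F[, 2], , drop = FALSE]
      v3 <- V[F[, 3], , drop = FALSE]
      block <- sprintf(
        paste0("facet normal %.9e %.9e %.9e\n outer loop\n",
               "  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n",
               "  vertex %.9e %.9e %.9e\n endloop\nendfacet"),
        fn[, 1], fn[, 2], fn[, 3],
        v1[, 1], v1[, 2], v1[, 3],
        v2[, 1], v2[, 2], v2[, 3],
        v3[, 1], v3[, 2], v3[, 3])
      writeLines(block, con)
    }
    writeLines(paste0("endsolid ", nm), con)
  }
  invisible(path)
}

#' Read a (multi-solid) ASCII STL file
#'
#' Facet vertices are welded back into indexed meshes; solid names are
#' preserved.
#'
#' @param path input file.
#' @return named list of [trimesh] objects.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  starts <- grep("^solid", lines)
  ends <- grep("^endsolid", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed STL: unbalanced solid/endsolid")
  out <- list()
  for (k in seq_along(starts)) {
    nm <- sub("^solid\\s*", "", lines[starts[k]])
    body <- lines[starts[k]:ends[k]]
    vl <- body[startsWith(body, "vertex")]
    if (length(vl) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
    xyz <- matrix(scan(text = sub("^vertex\\s+", "", vl), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
    nfc <- nrow(xyz) / 3
    F <- matrix(seq_len(nrow(xyz)), ncol = 3, byrow = TRUE)
    m <- weld_vertices(trimesh(xyz, F, name = nm), tol = 1e-9)
    out[[if (nzchar(nm)) nm else paste0("solid", k)]] <- m
  }
  out
}

#' Write a single mesh to binary STL
#' @param mesh a [trimesh].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", paste0("fpdgen ", mesh$name)))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  dat <- t(cbind(fn, V[F[, 1], ], V[F[, 2], ], V[F[, 3], ]))
  raw48 <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
  # interleave the 2-byte attribute word after each 48-byte facet record
  rec <- matrix(as.raw(0), 50, nrow(mesh$faces))
  rec[1:48, ] <- matrix(raw48, 48, nrow(mesh$faces))
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a binary STL file
#' @param path input file.
#' @return a [trimesh] (vertices welded).
#' @export
read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nfc <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- matrix(readBin(con, "raw", nfc * 50), 50, nfc)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", nfc * 12, size = 4,
                  endian = "little")
  vals <- matrix(vals, 12, nfc)
  xyz <- matrix(NA_real_, nfc * 3, 3)
  for (k in 1:3)
    xyz[seq(k, nfc * 3, by = 3), ] <- t(vals[(3 * k + 1):(3 * k + 3), ,
                                             drop = FALSE])
  F <- matrix(seq_len(nfc * 3), ncol = 3, byrow = TRUE)
  weld_vertices(trimesh(xyz, F, name = "binary_stl"), tol = 1e-9)
}
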