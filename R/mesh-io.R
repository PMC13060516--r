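#' Read a triangle mesh from OBJ or GLB
#'
#' Reads Wavefront OBJ (ASCII) or glTF 2.0 binary (GLB) files into a
#' [trimesh]. Non-triangular polygons are fan-triangulated; duplicate-position
#' vertices are kept distinct so that vertex indexing in stored annotations is
#' preserved; degenerate faces are dropped with a warning. GLB files must
#' contain a single mesh primitive (the single-primitive convention of the
#' survey models); multi-primitive files are rejected.
#'
#' @param path file path.
#' @param format `"obj"` or `"glb"`; inferred from the file extension when
#'   missing.
#' @return a [trimesh].
#' @export
load_mesh <- function(path, format = c("auto", "obj", "glb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  switch(format,
         obj = read_obj(path),
         glb = read_glb(path),
         stop("unknown mesh format: ", format))
}

#' Write a triangle mesh to OBJ or GLB
#'
#' Round-trips through [load_mesh()] with exact face indices; OBJ coordinates
#' are written with 17 significant digits (exact double round-trip), GLB
#' stores float32 positions.
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @inheritParams load_mesh
#' @export
save_mesh <- function(mesh, path, format = c("auto", "obj", "glb")) {
  if (!is_trimesh(mesh)) stop("not a trimesh")
  if (nrow(mesh$faces) == 0L) stop("refusing to write a mesh with no faces")
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  switch(format,
         obj = write_obj(mesh, path),
         glb = write_glb(mesh, path),
         stop("unknown mesh format: ", format))
  invisible(NULL)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L)
    stop("OBJ file has no geometry: ", path)
  vparts <- strsplit(sub("^v\\s+", "", vl), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  faces <- list()
  for (line in fl) {
    toks <- strsplit(sub("^f\\s+", "", line), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1L))
    idx <- ifelse(idx < 0L, nrow(verts) + 1L + idx, idx)  # negative = relative
    if (length(idx) < 3L) stop("face with fewer than 3 vertices")
    # fan triangulation of polygons
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  trimesh(verts, do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  # 17 significant digits: decimal text round-trips doubles exactly
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
}

# --- minimal glTF 2.0 binary (GLB) codec: one mesh, one primitive ----------

GLB_MAGIC <- 0x46546C67  # "glTF"
CT_FLOAT <- 5126L
CT_UBYTE <- 5121L
CT_USHORT <- 5123L
CT_UINT <- 5125L

read_glb <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 12L) stop("truncated GLB file: ", path)
  u32 <- function(off) {  # little-endian uint32 at byte offset (0-based)
    sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (u32(0) != GLB_MAGIC) stop("not a GLB file: ", path)
  total <- u32(8)
  off <- 12
  json <- NULL; bin <- raw(0)
  while (off < total) {
    clen <- u32(off); ctype <- u32(off + 4)
    chunk <- raw[(off + 8 + 1):(off + 8 + clen)]
    if (ctype == 0x4E4F534A) json <- rawToChar(chunk)        # "JSON"
    else if (ctype == 0x004E4942) bin <- chunk               # "BIN\0"
    off <- off + 8 + clen
  }
  if (is.null(json)) stop("GLB missing JSON chunk")
  g <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (length(g$meshes) < 1L) stop("GLB contains no mesh")
  prims <- g$meshes[[1]]$primitives
  if (length(g$meshes) > 1L || length(prims) != 1L)
    stop("GLB must contain exactly one mesh primitive")
  prim <- prims[[1]]
  pos <- glb_accessor(g, bin, prim$attributes$POSITION)
  if (is.null(prim$indices)) stop("GLB primitive has no indices")
  idx <- glb_accessor(g, bin, prim$indices)
  trimesh(matrix(pos, ncol = 3, byrow = TRUE),
          matrix(as.integer(idx) + 1L, ncol = 3, byrow = TRUE))
}

glb_accessor <- function(g, bin, i) {
  acc <- g$accessors[[i + 1L]]
  bv <- g$bufferViews[[acc$bufferView + 1L]]
  off <- (if (is.null(bv$byteOffset)) 0L else bv$byteOffset) +
    (if (is.null(acc$byteOffset)) 0L else acc$byteOffset)
  ncomp <- switch(acc$type, SCALAR = 1L, VEC2 = 2L, VEC3 = 3L, VEC4 = 4L,
                  stop("unsupported accessor type ", acc$type))
  n <- acc$count * ncomp
  con <- rawConnection(bin[(off + 1):length(bin)])
  on.exit(close(con))
  ct <- acc$componentType
  if (ct == CT_FLOAT) readBin(con, "double", n = n, size = 4, endian = "little")
  else if (ct == CT_UINT) readBin(con, "integer", n = n, size = 4, endian = "little")
  else if (ct == CT_USHORT) readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little")
  else if (ct == CT_UBYTE) as.integer(readBin(con, "raw", n = n))
  else stop("unsupported componentType ", ct)
}

write_glb <- function(mesh, path) {
  pos <- as.numeric(t(mesh$vertices))
  idx <- as.integer(t(mesh$faces)) - 1L
  pos_bytes <- writeBin(pos, raw(), size = 4, endian = "little")
  idx_bytes <- writeBin(idx, raw(), size = 4, endian = "little")
  pad4 <- function(x, fill = as.raw(0)) {
    if (length(x) %% 4) c(x, rep(fill, 4 - length(x) %% 4)) else x
  }
  pos_bytes <- pad4(pos_bytes)
  bin <- c(pos_bytes, pad4(idx_bytes))
  mins <- apply(mesh$vertices, 2, min)
  maxs <- apply(mesh$vertices, 2, max)
  g <- list(
    asset = list(version = "2.0", generator = "fieldmorph"),
    scene = 0L, scenes = list(list(nodes = list(0L))),
    nodes = list(list(mesh = 0L)),
    meshes = list(list(primitives = list(list(
      attributes = list(POSITION = 1L), indices = 0L, mode = 4L)))),
    accessors = list(
      list(bufferView = 1L, componentType = CT_UINT, count = length(idx),
           type = "SCALAR"),
      list(bufferView = 0L, componentType = CT_FLOAT,
           count = nrow(mesh$vertices), type = "VEC3",
           min = as.list(mins), max = as.list(maxs))),
    bufferViews = list(
      list(buffer = 0L, byteOffset = 0L, byteLength = length(pos_bytes),
           target = 34962L),
      list(buffer = 0L, byteOffset = length(pos_bytes),
           byteLength = length(idx_bytes), target = 34963L)),
    buffers = list(list(byteLength = length(bin))))
  json_raw <- charToRaw(jsonlite::toJSON(g, auto_unbox = TRUE, digits = NA))
  json_raw <- pad4(json_raw, charToRaw(" "))
  u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  out <- c(u32raw(GLB_MAGIC), u32raw(2L),
           u32raw(12L + 8L + length(json_raw) + 8L + length(bin)),
           u32raw(length(json_raw)), u32raw(0x4E4F534A), json_raw,
           u32raw(length(bin)), u32raw(0x004E4942), bin)
  writeBin(out, path)
}
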