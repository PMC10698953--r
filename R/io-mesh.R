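#' Read / write surface meshes (PLY, VTK PolyData, OBJ)
#'
#' ASCII formats with full-precision coordinates, so a write/read
#' round trip reproduces vertex arrays bit-exactly. PLY and VTK carry
#' named per-vertex scalar fields (e.g. S2S distances, coefficient
#' maps); OBJ carries geometry only. Dispatch is on file extension.
#'
#' @param path file path ending in .ply, .vtk or .obj.
#' @return \code{readMesh}: a \linkS4class{TriangleMesh}; scalar
#'   fields, if present, are attached as the \code{"scalars"}
#'   attribute (named list).
#' @export
readMesh <- function(path) {
    switch(tolower(tools::file_ext(path)),
           ply = .read_ply(path),
           vtk = .read_vtk(path),
           obj = .read_obj(path),
           stop("unsupported mesh format: ", path))
}

#' @rdname readMesh
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param scalars optional named list of per-vertex numeric vectors.
#' @export
writeMesh <- function(mesh, path, scalars = NULL) {
    if (!is.null(scalars)) {
        if (is.null(names(scalars)) || any(names(scalars) == ""))
            stop("scalar fields must be named")
        bad <- lengths(scalars) != nVertices(mesh)
        if (any(bad))
            stop("scalar field length mismatch: ",
                 paste(names(scalars)[bad], collapse = ", "))
    }
    switch(tolower(tools::file_ext(path)),
           ply = .write_ply(mesh, path, scalars),
           vtk = .write_vtk(mesh, path, scalars),
           obj = .write_obj(mesh, path),
           stop("unsupported mesh format: ", path))
    invisible(path)
}

.num <- function(x) sprintf("%.17g", x)

.write_ply <- function(mesh, path, scalars) {
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y",
             "property double z")
    for (nm in names(scalars))
        hdr <- c(hdr, paste("property double", nm))
    hdr <- c(hdr, paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    vt <- cbind(v, if (length(scalars))
        do.call(cbind, scalars) else NULL)
    writeLines(apply(vt, 1, function(r) paste(.num(r), collapse = " ")),
               con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

.read_ply <- function(path) {
    lines <- readLines(path)
    if (lines[1] != "ply") stop("not a PLY file: ", path)
    if (!grepl("ascii", lines[2]))
        stop("only ASCII PLY is supported: ", path)
    endh <- match("end_header", lines)
    hdr <- lines[seq_len(endh)]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", hdr, value = TRUE)))
    vstart <- grep("^element vertex", hdr)
    vend <- grep("^element (face|end)", hdr)
    vend <- min(vend[vend > vstart], endh)
    props <- sub("^property \\S+ ", "",
                 grep("^property (float|double)", hdr[vstart:vend],
                      value = TRUE))
    vlines <- lines[(endh + 1):(endh + nv)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    flines <- lines[(endh + nv + 1):(endh + nv + nf)]
    fl <- strsplit(trimws(flines), "\\s+")
    for (i in seq_along(fl)) {
        if (length(fl[[i]]) != 4L || fl[[i]][1] != "3")
            stop("malformed face at line ", endh + nv + i, " of ", path)
    }
    faces <- matrix(as.integer(unlist(fl)), ncol = 4, byrow = TRUE)[,
        2:4, drop = FALSE] + 1L
    if (any(is.na(faces)) || any(faces < 1L) || any(faces > nv))
        stop("face index out of range in ", path)
    mesh <- TriangleMesh(vals[, 1:3, drop = FALSE], faces)
    if (length(props) > 3) {
        sc <- lapply(seq(4, length(props)), function(j) vals[, j])
        names(sc) <- props[-(1:3)]
        attr(mesh, "scalars") <- sc
    }
    mesh
}

.write_vtk <- function(mesh, path, scalars) {
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "nephroShape surface",
                 "ASCII", "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "double")), con)
    writeLines(apply(v, 1, function(r) paste(.num(r), collapse = " ")),
               con)
    writeLines(paste("POLYGONS", nrow(f), 4L * nrow(f)), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    if (length(scalars)) {
        writeLines(paste("POINT_DATA", nrow(v)), con)
        for (nm in names(scalars)) {
            writeLines(c(paste("SCALARS", nm, "double 1"),
                         "LOOKUP_TABLE default"), con)
            writeLines(.num(scalars[[nm]]), con)
        }
    }
}

.read_vtk <- function(path) {
    lines <- readLines(path)
    if (!grepl("^# vtk DataFile", lines[1]))
        stop("not a legacy VTK file: ", path)
    pts_i <- grep("^POINTS", lines)[1]
    nv <- as.integer(strsplit(lines[pts_i], "\\s+")[[1]][2])
    coords <- as.numeric(unlist(strsplit(trimws(
        lines[(pts_i + 1):(pts_i + nv)]), "\\s+")))
    v <- matrix(coords, ncol = 3, byrow = TRUE)
    pol_i <- grep("^POLYGONS", lines)[1]
    nf <- as.integer(strsplit(lines[pol_i], "\\s+")[[1]][2])
    fl <- strsplit(trimws(lines[(pol_i + 1):(pol_i + nf)]), "\\s+")
    for (i in seq_along(fl))
        if (length(fl[[i]]) != 4L || fl[[i]][1] != "3")
            stop("malformed polygon at line ", pol_i + i, " of ", path)
    faces <- matrix(as.integer(unlist(fl)), ncol = 4,
                    byrow = TRUE)[, 2:4, drop = FALSE] + 1L
    mesh <- TriangleMesh(v, faces)
    sc_i <- grep("^SCALARS", lines)
    if (length(sc_i)) {
        sc <- list()
        for (i in sc_i) {
            nm <- strsplit(lines[i], "\\s+")[[1]][2]
            sc[[nm]] <- as.numeric(lines[(i + 2):(i + 1 + nv)])
        }
        attr(mesh, "scalars") <- sc
    }
    mesh
}

.write_obj <- function(mesh, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("v", .num(mesh@vertices[, 1]),
                     .num(mesh@vertices[, 2]), .num(mesh@vertices[, 3])),
               con)
    writeLines(paste("f", mesh@faces[, 1], mesh@faces[, 2],
                     mesh@faces[, 3]), con)
}

.read_obj <- function(path) {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                         `[`, 2:4))), ncol = 3,
                byrow = TRUE)
    fidx <- lapply(strsplit(fl, "\\s+"), function(x)
        as.integer(sub("/.*", "", x[2:4])))
    TriangleMesh(v, do.call(rbind, fidx))
}

#' Read / write CSV tables (UTF-8, comma, header row)
#'
#' @param path file path.
#' @return \code{readTable}: a data.frame.
#' @export
readTable <- function(path) {
    utils::read.csv(path, fileEncoding = "UTF-8",
                    check.names = FALSE)
}

#' @rdname readTable
#' @param x a data.frame or matrix.
#' @export
writeTable <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
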