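gmsh_type_names <- c("1" = "line", "2" = "triangle", "3" = "quadrangle",
                     "4" = "tetrahedron", "5" = "hexahedron", "6" = "prism",
                     "7" = "pyramid", "15" = "point")

#' Write a mesh (and optional element data) as Gmsh ASCII v2.2
#'
#' Tetrahedra are written with their tissue label as both physical and
#' geometrical tag; element-wise scalar fields (e.g. Ex/Ey/Ez/Enorm)
#' are appended as `$ElementData` blocks, mirroring the post-processing
#' format used by Gmsh-based field viewers.
#'
#' @param mesh A `head_mesh`.
#' @param path Output file.
#' @param element_data Optional named list of per-element numeric
#'   vectors.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path, element_data = NULL) {
  nn <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nn)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nn),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(m),
                     mesh$element_label, mesh$element_label,
                     mesh$elements[, 1L], mesh$elements[, 2L],
                     mesh$elements[, 3L], mesh$elements[, 4L]), con)
  writeLines("$EndElements", con)
  for (nm in names(element_data)) {
    v <- element_data[[nm]]
    stopifnot(length(v) == m)
    writeLines(c("$ElementData", "1", paste0("\"", nm, "\""), "1", "0.0",
                 "3", "0", "1", as.character(m)), con)
    writeLines(sprintf("%d %.9g", seq_len(m), v), con)
    writeLines("$EndElementData", con)
  }
  invisible(path)
}

#' Read a Gmsh ASCII v2.2 tetrahedral mesh
#'
#' Only tetrahedral volume meshes are supported; any other element
#' type is rejected by name. Physical tags become tissue labels.
#'
#' @param path Input file.
#' @param shells Optional shell/conductivity table to attach (the file
#'   itself carries only labels).
#' @return A `head_mesh` (without the phantom parameterization; point
#'   location falls back to the generic search) with any `$ElementData`
#'   blocks in `$element_data`.
#' @export
read_msh <- function(path, shells = NULL) {
  lines <- readLines(path)
  sec <- function(tag) {
    i0 <- match(paste0("$", tag), lines)
    i1 <- match(paste0("$End", tag), lines)
    if (is.na(i0) || is.na(i1)) stop("missing $", tag, " section in ", path)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sec("MeshFormat")[1L]), "\\s+")[[1L]]
  if (!startsWith(fmt[1L], "2.")) {
    stop("unsupported msh format version ", fmt[1L], " (need ASCII 2.x)")
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1L])
  ndm <- matrix(scan(text = nd[-1L], quiet = TRUE), ncol = 4L, byrow = TRUE)
  stopifnot(nrow(ndm) == nn)
  o <- order(ndm[, 1L])
  nodes <- ndm[o, 2:4, drop = FALSE]
  colnames(nodes) <- c("x", "y", "z")
  if (!all(ndm[o, 1L] == seq_len(nn))) stop("non-contiguous node ids")

  elines <- sec("Elements")
  m <- as.integer(elines[1L])
  elines <- elines[-1L]
  stopifnot(length(elines) == m)
  first3 <- t(vapply(strsplit(trimws(elines), "\\s+"),
                     function(x) as.integer(x[1:3]), integer(3L)))
  types <- unique(first3[, 2L])
  bad <- setdiff(types, 4L)
  if (length(bad) > 0L) {
    nmz <- gmsh_type_names[as.character(bad)]
    nmz[is.na(nmz)] <- paste0("type ", bad[is.na(nmz)])
    stop("unsupported element type(s) in ", path, ": ",
         paste(nmz, collapse = ", "), " (only tetrahedra are supported)")
  }
  parts <- strsplit(trimws(elines), "\\s+")
  ntags <- first3[, 3L]
  elements <- matrix(0L, m, 4L)
  labels <- integer(m)
  for (i in seq_len(m)) {
    p <- as.integer(parts[[i]])
    nt <- p[3L]
    labels[i] <- if (nt >= 1L) p[4L] else 1L
    elements[i, ] <- p[(4L + nt):(7L + nt)]
  }
  # element data blocks
  ed <- list()
  idx <- which(lines == "$ElementData")
  for (i0 in idx) {
    at <- i0 + 1L
    nstr <- as.integer(lines[at]); name <- gsub("\"", "", lines[at + 1L])
    at <- at + 1L + nstr
    nreal <- as.integer(lines[at]); at <- at + 1L + nreal
    nint <- as.integer(lines[at])
    nent <- as.integer(lines[at + nint])
    at <- at + nint + 1L
    vals <- matrix(scan(text = lines[at:(at + nent - 1L)], quiet = TRUE),
                   ncol = 2L, byrow = TRUE)
    v <- numeric(m)
    v[vals[, 1L]] <- vals[, 2L]
    ed[[name]] <- v
  }
  mesh <- structure(list(
    nodes = nodes, elements = elements, element_label = labels,
    shells = shells, r_levels = NULL, resolution = NA_real_,
    volumes = NULL, param = NULL), class = "head_mesh")
  v <- tet_signed_volumes(nodes, elements)
  neg <- v < 0
  if (any(neg)) {
    tmp <- mesh$elements[neg, 3L]
    mesh$elements[neg, 3L] <- mesh$elements[neg, 4L]
    mesh$elements[neg, 4L] <- tmp
    v[neg] <- -v[neg]
  }
  mesh$volumes <- v
  mesh$surface <- extract_surface(mesh)
  if (length(ed)) mesh$element_data <- ed
  mesh
}
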