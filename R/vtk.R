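#' Write a tetrahedral mesh with data arrays as a VTK unstructured grid
#'
#' ASCII .vtu (VTK XML UnstructuredGrid). TET4 cells are VTK type 10,
#' TET10 cells type 24 (corner nodes then edge midsides in the order
#' (0,1),(1,2),(0,2),(0,3),(1,3),(2,3), matching the mesh's own ordering).
#'
#' @param mesh A `tet_mesh`.
#' @param path Output path (.vtu).
#' @param cell_data Named list of per-element numeric/character vectors.
#' @param point_data Named list of per-node numeric vectors or n x 3 matrices.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  vtk_type <- if (mesh$order == 2) 24L else 10L

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE), collapse = " ")

  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elements - 1L, 1, function(r) paste(r, collapse = " ")), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ne) * npe, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(vtk_type, ne), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.character(v)) v <- as.integer(factor(v))
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(format(as.numeric(v), digits = 10, trim = TRUE),
                       collapse = " "), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      ncomp <- if (is.matrix(v)) ncol(v) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncomp)
      if (is.matrix(v)) writeLines(apply(v, 1, num), con)
      else writeLines(paste(format(as.numeric(v), digits = 10, trim = TRUE),
                            collapse = " "), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
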