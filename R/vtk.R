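# Minimal legacy ASCII VTK unstructured-grid support. Only what the
# degradation workflow needs: POINTS, CELLS, CELL_TYPES and SCALARS arrays
# under CELL_DATA. Binary VTK and XML (.vtu) are out of scope.

#' Read a scaffold field from a legacy ASCII VTK unstructured grid
#'
#' Cell-data arrays `volume` and `max_principal_strain` are required.
#' Element ids are the 1-based cell order. Shared-face adjacency is inferred
#' from the mesh: two cells are neighbors when they share at least three
#' nodes (a triangular or larger face; legacy 3D cells only).
#'
#' @param path Path to the `.vtk` file.
#' @return A [scaffold_field()] carrying the mesh geometry, so snapshots can
#'   be written back as VTK (see [write_scaffold_vtk()]).
#' @export
read_scaffold_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L || !grepl("^# vtk DataFile", lines[1]))
    stop("not a legacy VTK file: ", path, call. = FALSE)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ASCII legacy VTK is supported", call. = FALSE)
  if (!grepl("UNSTRUCTURED_GRID", lines[4]))
    stop("only UNSTRUCTURED_GRID datasets are supported", call. = FALSE)

  toks <- scan_tokens(lines[-(1:4)])
  pos <- 1L
  expect <- function(word) {
    if (toupper(toks[pos]) != word)
      stop("malformed VTK: expected ", word, " near token ", pos,
           call. = FALSE)
    pos <<- pos + 1L
  }
  take_num <- function(k) {
    out <- as.numeric(toks[pos:(pos + k - 1L)])
    if (anyNA(out)) stop("malformed VTK numeric block", call. = FALSE)
    pos <<- pos + k
    out
  }

  expect("POINTS")
  n_pts <- as.integer(toks[pos]); pos <- pos + 2L   # count, dtype
  points <- matrix(take_num(3L * n_pts), ncol = 3, byrow = TRUE)

  expect("CELLS")
  n_cells <- as.integer(toks[pos])
  total <- as.integer(toks[pos + 1L]); pos <- pos + 2L
  raw <- as.integer(take_num(total))
  cells <- vector("list", n_cells)
  i <- 1L
  for (ci in seq_len(n_cells)) {
    k <- raw[i]
    cells[[ci]] <- raw[(i + 1L):(i + k)]
    i <- i + k + 1L
  }

  expect("CELL_TYPES")
  pos <- pos + 1L                                    # count
  cell_types <- as.integer(take_num(n_cells))

  arrays <- list()
  while (pos <= length(toks)) {
    word <- toupper(toks[pos])
    if (word == "CELL_DATA") {
      pos <- pos + 2L
    } else if (word == "POINT_DATA") {
      break                                          # not needed
    } else if (word == "SCALARS") {
      name <- toks[pos + 1L]
      pos <- pos + 3L                                # SCALARS name dtype
      if (grepl("^[0-9]+$", toks[pos])) pos <- pos + 1L  # numComponents
      if (toupper(toks[pos]) == "LOOKUP_TABLE") pos <- pos + 2L
      arrays[[name]] <- take_num(n_cells)
    } else {
      pos <- pos + 1L
    }
  }
  for (nm in c("volume", "max_principal_strain"))
    if (is.null(arrays[[nm]]))
      stop("VTK file lacks required cell-data array '", nm, "'",
           call. = FALSE)

  elements <- data.frame(element_id = seq_len(n_cells),
                         volume = arrays$volume,
                         max_principal_strain = arrays$max_principal_strain)
  extra <- setdiff(names(arrays), c("volume", "max_principal_strain"))
  for (nm in extra) elements[[nm]] <- arrays[[nm]]
  scaffold_field(elements,
                 edges = shared_face_edges(cells),
                 mesh = list(points = points, cells = cells,
                             cell_types = cell_types))
}

scan_tokens <- function(lines) {
  unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "[[:space:]]+"),
         use.names = FALSE)
}

# cells sharing >= 3 nodes share a (triangular or larger) face
shared_face_edges <- function(cells) {
  node <- unlist(cells, use.names = FALSE)
  cell <- rep(seq_along(cells), lengths(cells))
  by_node <- split(cell, node)
  pairs <- do.call(rbind, lapply(by_node, function(cs) {
    if (length(cs) < 2L) return(NULL)
    t(utils::combn(sort(cs), 2L))
  }))
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  key <- paste(pairs[, 1], pairs[, 2])
  counts <- table(key)
  shared <- names(counts)[counts >= 3L]
  if (!length(shared)) return(matrix(integer(0), ncol = 2))
  out <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  matrix(as.integer(out), ncol = 2)
}

#' Write a degradation snapshot as legacy ASCII VTK
#'
#' Requires a field read from VTK (carrying mesh geometry). Writes the mesh
#' with cell-data arrays `max_principal_strain`, `volume`, `degree` and
#' `alive` so snapshots can be inspected in ParaView.
#'
#' @param field A [scaffold_field()] with a `mesh` component.
#' @param path Output path.
#' @param state Optional [scaffold_state()]; if omitted, a pristine state is
#'   written.
#' @return `path`, invisibly.
#' @export
write_scaffold_vtk <- function(field, path, state = NULL) {
  stopifnot(inherits(field, "scaffold_field"))
  if (is.null(field$mesh))
    stop("field carries no mesh geometry; use write_scaffold_csv()",
         call. = FALSE)
  if (is.null(state)) state <- scaffold_state(field)
  check_state_field(state, field)
  m <- field$mesh
  n_cells <- length(m$cells)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("scaffold degradation state t=%g days",
                       state$time_days),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(m$points))), con)
  utils::write.table(m$points, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", n_cells,
                     n_cells + sum(lengths(m$cells))), con)
  writeLines(vapply(m$cells, function(v)
    paste(c(length(v), v), collapse = " "), ""), con)
  writeLines(sprintf("CELL_TYPES %d", n_cells), con)
  writeLines(as.character(m$cell_types), con)
  writeLines(sprintf("CELL_DATA %d", n_cells), con)
  write_scalar <- function(name, values, dtype = "float") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, dtype),
                 "LOOKUP_TABLE default",
                 format(values, trim = TRUE, scientific = FALSE,
                        digits = 9)), con)
  }
  write_scalar("max_principal_strain",
               field$elements$max_principal_strain)
  write_scalar("volume", field$elements$volume)
  write_scalar("degree", state$degree)
  write_scalar("alive", as.integer(state$alive), dtype = "int")
  invisible(path)
}
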