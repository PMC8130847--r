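#' Construct a scaffold field
#'
#' The substrate of the degradation simulator: per-element volume and
#' maximum principal strain, plus shared-face adjacency between elements.
#' Compressive (negative) principal strains do not drive the degradation law
#' and are clamped to zero with a warning.
#'
#' @param elements Data frame with columns `element_id` (unique integers),
#'   `volume` (mm^3, > 0) and `max_principal_strain` (dimensionless,
#'   finite). Optional columns (e.g. `role`, `ring_id` from the synthetic
#'   generator) are retained.
#' @param edges Two-column matrix or data frame of undirected adjacency
#'   pairs of element ids (shared-face neighbors). May have zero rows for
#'   fields of isolated elements.
#' @param mesh Optional mesh geometry (as produced by the VTK reader): a
#'   list with `points` (n x 3 matrix) and `cells` (list of 0-based node
#'   index vectors), used only to write geometry-carrying snapshots.
#' @return An object of class `scaffold_field`.
#' @export
scaffold_field <- function(elements, edges = NULL, mesh = NULL) {
  if (!is.data.frame(elements))
    stop("'elements' must be a data frame", call. = FALSE)
  need <- c("element_id", "volume", "max_principal_strain")
  miss <- setdiff(need, names(elements))
  if (length(miss))
    stop("elements are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(elements) == 0L)
    stop("scaffold field must contain at least one element", call. = FALSE)
  ids <- elements$element_id
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    stop("duplicate element id(s) at row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(elements$volume)) || any(elements$volume <= 0)) {
    bad <- which(!is.finite(elements$volume) | elements$volume <= 0)
    stop("non-positive or non-finite volume at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(elements$max_principal_strain)))
    stop("non-finite strain in field", call. = FALSE)
  n_neg <- sum(elements$max_principal_strain < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative principal strain(s) clamped to 0 ",
            "(compression does not drive the degradation law)",
            call. = FALSE)
    elements$max_principal_strain <- pmax(0, elements$max_principal_strain)
  }
  if (is.null(edges)) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L)
      stop("'edges' must have two columns", call. = FALSE)
    storage.mode(edges) <- "integer"
    if (nrow(edges)) {
      unknown <- setdiff(c(edges), ids)
      if (length(unknown))
        stop("adjacency refers to unknown element id(s): ",
             paste(utils::head(unknown, 5L), collapse = ", "),
             call. = FALSE)
      if (any(edges[, 1] == edges[, 2]))
        stop("self-adjacency is not allowed", call. = FALSE)
      # undirected: canonical order, drop duplicates (symmetrizes listings)
      edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                            pmax(edges[, 1], edges[, 2])))
    }
  }
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(list(elements = elements, edges = edges, mesh = mesh),
            class = "scaffold_field")
}

#' @export
print.scaffold_field <- function(x, ...) {
  e <- x$elements
  cat("Scaffold field: ", nrow(e), " elements, ", nrow(x$edges),
      " adjacency pairs", if (!is.null(x$mesh)) ", with mesh geometry",
      "\n", sep = "")
  cat(sprintf("  total volume %.4g mm^3; strain range [%.4g, %.4g]\n",
              sum(e$volume), min(e$max_principal_strain),
              max(e$max_principal_strain)))
  invisible(x)
}

#' Read a scaffold field from disk
#'
#' Two dialects are supported. CSV: header
#' `element_id,volume,max_principal_strain,neighbors`, where `neighbors` is
#' a semicolon-separated list of adjacent element ids (empty for isolated
#' elements). Legacy ASCII VTK: an `UNSTRUCTURED_GRID` with cell-data
#' arrays `volume` and `max_principal_strain`; adjacency is inferred from
#' shared faces (cells sharing >= 3 nodes).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"vtk"`; by default guessed from the extension.
#' @return A [scaffold_field()].
#' @export
read_scaffold_field <- function(path, format = c("auto", "csv", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk" else "csv"
  if (format == "vtk") return(read_scaffold_vtk(path))

  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neighbors = "character"))
  need <- c("element_id", "volume", "max_principal_strain", "neighbors")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  edges <- parse_neighbor_lists(df$element_id, df$neighbors)
  scaffold_field(df[setdiff(names(df), "neighbors")], edges = edges)
}

parse_neighbor_lists <- function(ids, neighbors) {
  neighbors[is.na(neighbors)] <- ""
  parts <- strsplit(neighbors, ";", fixed = TRUE)
  from <- rep(ids, lengths(parts))
  to <- suppressWarnings(as.integer(trimws(unlist(parts))))
  keep <- !is.na(to)
  if (any(!keep & nzchar(trimws(unlist(parts)))))
    stop("unparseable neighbor id in CSV", call. = FALSE)
  cbind(from = from[keep], to = to[keep])
}

#' Write a scaffold field to CSV
#'
#' Inverse of the CSV dialect of [read_scaffold_field()].
#'
#' @param field A [scaffold_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_csv <- function(field, path) {
  stopifnot(inherits(field, "scaffold_field"))
  ids <- field$elements$element_id
  adj <- split(c(field$edges[, 2], field$edges[, 1]),
               factor(c(field$edges[, 1], field$edges[, 2]), levels = ids))
  df <- field$elements
  df$neighbors <- vapply(adj, function(v) paste(sort(v), collapse = ";"), "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Initialize the degradation state of a scaffold field
#'
#' @param field A [scaffold_field()].
#' @param time_days Starting time, days.
#' @param coeffs Kinetic coefficients (for the initial fracture strain).
#' @return An object of class `scaffold_state` with per-element `degree`,
#'   `fracture_strain` and `alive` flags, aligned with `field$elements`.
#' @export
scaffold_state <- function(field, time_days = 0,
                           coeffs = degradation_coefficients()) {
  stopifnot(inherits(field, "scaffold_field"))
  coeffs <- as_degradation_coefficients(coeffs)
  n <- nrow(field$elements)
  structure(list(time_days = time_days,
                 degree = rep(0, n),
                 fracture_strain = rep(coeffs$epsilon0, n),
                 alive = rep(TRUE, n),
                 dead_mass = 0),
            class = "scaffold_state")
}

#' @export
print.scaffold_state <- function(x, ...) {
  cat(sprintf(paste0("Scaffold state at t = %.4g days: %d/%d alive, ",
                     "mean degree %.3f, dead mass %.4g\n"),
              x$time_days, sum(x$alive), length(x$alive),
              mean(x$degree), x$dead_mass))
  invisible(x)
}

check_state_field <- function(state, field) {
  if (!inherits(state, "scaffold_state"))
    stop("'state' must be a scaffold_state", call. = FALSE)
  if (!inherits(field, "scaffold_field"))
    stop("'field' must be a scaffold_field", call. = FALSE)
  if (length(state$alive) != nrow(field$elements))
    stop("state and field describe different numbers of elements",
         call. = FALSE)
  invisible(TRUE)
}

#' Mass loss ratio of a degradation state
#'
#' Mass of absorbed (dead) elements over total scaffold mass, assuming unit
#' density so volumes stand in for masses.
#'
#' @param state A [scaffold_state()].
#' @param field The matching [scaffold_field()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 1))
#' mass_loss_ratio(scaffold_state(f), f)   # 0 before any death
#' @export
mass_loss_ratio <- function(state, field) {
  check_state_field(state, field)
  sum(field$elements$volume[!state$alive]) / sum(field$elements$volume)
}

#' Mass-weighted strain histogram
#'
#' Bins the elements' maximum principal strains and reports the mass
#' fraction falling in each bin. Elements below the lowest or above the
#' highest edge are collected in open end bins, so the fractions always sum
#' to 1. The default edges are the representative strain levels used to
#' stratify the scaffold's mass-loss analysis.
#'
#' @param field A [scaffold_field()].
#' @param bin_edges Strictly monotone numeric vector of bin edges
#'   (ascending or descending).
#' @return Data frame with columns `lower`, `upper` (bin bounds, open ends
#'   are infinite) and `mass_fraction`.
#' @export
strain_histogram <- function(field,
                             bin_edges = c(0.29, 0.16, 0.098, 0.067,
                                           0.047, 0.036)) {
  stopifnot(inherits(field, "scaffold_field"))
  check_numeric(bin_edges, "bin_edges")
  if (length(bin_edges) < 1L)
    stop("at least one bin edge is required", call. = FALSE)
  d <- diff(bin_edges)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("'bin_edges' must be strictly monotone", call. = FALSE)
  edges <- sort(bin_edges)
  strain <- field$elements$max_principal_strain
  vol <- field$elements$volume
  idx <- findInterval(strain, edges)            # 0 .. length(edges)
  mass <- vapply(seq_len(length(edges) + 1L) - 1L,
                 function(b) sum(vol[idx == b]), 0)
  data.frame(lower = c(-Inf, edges),
             upper = c(edges, Inf),
             mass_fraction = mass / sum(vol))
}

field_graph <- function(field, alive = NULL) {
  ids <- as.character(field$elements$element_id)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(field$edges), ncol = 2), directed = FALSE)
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  if (!is.null(alive))
    g <- igraph::induced_subgraph(g, ids[alive])
  g
}

#' Detect strut discontinuity from element deaths
#'
#' Computes the connected components of the alive-element adjacency graph
#' and compares their count with the fully-alive baseline. An increase means
#' the scaffold has fragmented (strut discontinuity).
#'
#' @param field A [scaffold_field()].
#' @param state Optional [scaffold_state()]; if omitted all elements are
#'   treated as alive (the baseline).
#' @return A list with `n_components` (alive graph), `baseline_components`
#'   (fully alive graph), `fragmented` (logical), and `components`, a list
#'   of element-id vectors, one per alive component (largest first).
#' @export
detect_discontinuity <- function(field, state = NULL) {
  stopifnot(inherits(field, "scaffold_field"))
  g0 <- field_graph(field)
  base <- igraph::components(g0)$no
  if (is.null(state)) {
    alive <- rep(TRUE, nrow(field$elements))
  } else {
    check_state_field(state, field)
    alive <- state$alive
  }
  ga <- field_graph(field, alive = alive)
  comp <- igraph::components(ga)
  members <- split(igraph::V(ga)$name, comp$membership)
  members <- members[order(-lengths(members))]
  list(n_components = comp$no,
       baseline_components = base,
       fragmented = comp$no > base,
       components = lapply(unname(members), as.integer))
}
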