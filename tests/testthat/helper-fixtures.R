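# Independent bisection oracle for the fracture time: finds t such that
# degradation_degree(strain, t) reaches 1 - strain/epsilon0, without using
# the closed-form inversion under test.
bisect_fracture_time <- function(strain, coeffs = degradation_coefficients(),
                                 hi = 1e5, tol = 1e-9) {
  target <- 1 - strain / coeffs$epsilon0
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (degradation_degree(strain, mid, coeffs) < target) lo <- mid
    else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# a path of n unit-volume elements: 1-2-3-...-n
path_field <- function(n = 5, strain = 0.1) {
  scaffold_field(
    data.frame(element_id = 1:n, volume = 1,
               max_principal_strain = rep_len(strain, n)),
    edges = cbind(1:(n - 1), 2:n))
}

# a ring (cycle) of n unit-volume elements
ring_field <- function(n = 8, strain = 0.1) {
  scaffold_field(
    data.frame(element_id = 1:n, volume = 1,
               max_principal_strain = rep_len(strain, n)),
    edges = cbind(1:n, c(2:n, 1)))
}

# mark the given elements dead in a fresh state
kill_elements <- function(field, dead_ids, time_days = 0) {
  st <- scaffold_state(field, time_days)
  st$alive[match(dead_ids, field$elements$element_id)] <- FALSE
  st$dead_mass <- sum(field$elements$volume[!st$alive])
  st
}

# legacy ASCII VTK fixture: two unit-cube hexahedra sharing a face,
# written by hand so the reader is tested independently of the writer
write_two_hex_vtk <- function(path, strains = c(0.1, 0.3),
                              volumes = c(1, 1)) {
  writeLines(c(
    "# vtk DataFile Version 3.0", "two hexes", "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    "POINTS 12 float",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "0 0 1", "1 0 1", "1 1 1", "0 1 1",
    "2 0 0", "2 1 0", "2 0 1", "2 1 1",
    "CELLS 2 18",
    "8 0 1 2 3 4 5 6 7",
    "8 1 8 9 2 5 10 11 6",
    "CELL_TYPES 2", "12", "12",
    "CELL_DATA 2",
    "SCALARS volume float 1", "LOOKUP_TABLE default",
    as.character(volumes),
    "SCALARS max_principal_strain float 1", "LOOKUP_TABLE default",
    as.character(strains)), path)
  path
}

table1 <- degradation_coefficients()
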