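# evaluate code under a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification for a synthetic stent-like strain field
#'
#' Describes a coarse ring-and-link scaffold topology: `n_rings` zig-zag
#' rings of `peaks_per_ring` crowns joined by link chains, with strain
#' levels reproducing the qualitative structure of a deployed scaffold —
#' highest strains at the crowns (outer surface of the U-bends),
#' intermediate at the links, lowest in the straight strut bodies.
#' Per-element strains get multiplicative lognormal scatter so they stay
#' positive.
#'
#' @param n_rings Number of rings (>= 1).
#' @param peaks_per_ring Crowns per ring (default 6, evenly distributed).
#' @param elements_per_strut Body elements between consecutive crowns
#'   (default 3).
#' @param links_per_pair Link chains between consecutive rings (default 3).
#' @param elements_per_link Elements per link chain (default 2).
#' @param crown_strain,link_strain,body_strain Median maximum principal
#'   strain at crowns (default 0.3), links (0.1) and strut bodies (0.03).
#' @param volume Element volume in mm^3 (default 0.005, of the order of a
#'   strut segment with a 150 x 190 micron cross-section).
#' @param sigma_log Lognormal scatter of strains on the log scale
#'   (default 0.15).
#' @param seed RNG seed for reproducible generation (default 1).
#' @return An object of class `stent_field_spec`.
#' @export
stent_field_spec <- function(n_rings = 3, peaks_per_ring = 6,
                             elements_per_strut = 3, links_per_pair = 3,
                             elements_per_link = 2,
                             crown_strain = 0.3, link_strain = 0.1,
                             body_strain = 0.03,
                             volume = 0.005, sigma_log = 0.15, seed = 1) {
  counts <- c(n_rings = n_rings, peaks_per_ring = peaks_per_ring,
              elements_per_strut = elements_per_strut,
              links_per_pair = links_per_pair,
              elements_per_link = elements_per_link)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all size parameters must be positive integers", call. = FALSE)
  if (links_per_pair > peaks_per_ring)
    stop("'links_per_pair' cannot exceed 'peaks_per_ring'", call. = FALSE)
  strains <- c(crown_strain, link_strain, body_strain)
  if (any(!is.finite(strains)) || any(strains < 0))
    stop("strain levels must be finite and >= 0", call. = FALSE)
  if (volume <= 0) stop("'volume' must be > 0", call. = FALSE)
  if (sigma_log < 0) stop("'sigma_log' must be >= 0", call. = FALSE)
  structure(list(n_rings = n_rings, peaks_per_ring = peaks_per_ring,
                 elements_per_strut = elements_per_strut,
                 links_per_pair = links_per_pair,
                 elements_per_link = elements_per_link,
                 crown_strain = crown_strain, link_strain = link_strain,
                 body_strain = body_strain, volume = volume,
                 sigma_log = sigma_log, seed = seed),
            class = "stent_field_spec")
}

#' Generate a synthetic stent-like scaffold field
#'
#' Builds the ring-and-link adjacency graph of [stent_field_spec()] and
#' assigns strains by structural role with seeded lognormal scatter.
#' Deterministic for a fixed spec and seed. The output passes
#' [scaffold_field()] validation and carries `role` and `ring_id` columns.
#'
#' @param spec A [stent_field_spec()].
#' @return A [scaffold_field()].
#' @examples
#' f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 42))
#' table(f$elements$role)
#' @export
generate_stent_field <- function(spec = stent_field_spec()) {
  stopifnot(inherits(spec, "stent_field_spec"))
  p <- spec$peaks_per_ring
  eps <- spec$elements_per_strut
  ring_len <- p * (1 + eps)          # crowns + bodies per ring cycle

  id <- integer(0); role <- character(0); ring_id <- integer(0)
  edges <- NULL
  next_id <- 1L
  crown_ids <- matrix(NA_integer_, nrow = spec$n_rings, ncol = p)

  for (r in seq_len(spec$n_rings)) {
    ring_ids <- next_id:(next_id + ring_len - 1L)
    next_id <- next_id + ring_len
    pos_role <- rep(c("crown", rep("body", eps)), p)
    crown_ids[r, ] <- ring_ids[pos_role == "crown"]
    id <- c(id, ring_ids)
    role <- c(role, pos_role)
    ring_id <- c(ring_id, rep(r, ring_len))
    # ring cycle edges
    edges <- rbind(edges, cbind(ring_ids, c(ring_ids[-1], ring_ids[1])))
  }
  # link chains joining evenly spaced crowns of consecutive rings
  link_slots <- unique(round(seq(1, p, length.out = spec$links_per_pair + 1)
                             [seq_len(spec$links_per_pair)]))
  for (r in seq_len(spec$n_rings - 1L)) {
    for (s in link_slots) {
      chain <- next_id:(next_id + spec$elements_per_link - 1L)
      next_id <- next_id + spec$elements_per_link
      id <- c(id, chain)
      role <- c(role, rep("link", length(chain)))
      ring_id <- c(ring_id, rep(NA_integer_, length(chain)))
      path <- c(crown_ids[r, s], chain, crown_ids[r + 1L, s])
      edges <- rbind(edges, cbind(path[-length(path)], path[-1]))
    }
  }

  base <- c(crown = spec$crown_strain, link = spec$link_strain,
            body = spec$body_strain)[role]
  strain <- with_seed(spec$seed,
                      base * stats::rlnorm(length(base), meanlog = 0,
                                           sdlog = spec$sigma_log))
  elements <- data.frame(element_id = id,
                         volume = spec$volume,
                         max_principal_strain = unname(strain),
                         role = role,
                         ring_id = ring_id)
  scaffold_field(elements, edges = edges)
}

#' Generate a synthetic degradation-experiment dataset
#'
#' Forward-simulates pre-stretch degradation records on a full factorial
#' design of strains and times: the observed degree is the closed-form
#' degradation degree plus seeded Gaussian noise, clipped to `[0, 1]`. The
#' default design mirrors the calibration experiment: pre-stretch strains
#' 0, 0.2 and 0.4, sampled at 3, 10, 20 and 30 days.
#'
#' @param coeffs Kinetic coefficients used as ground truth.
#' @param strains,times Design levels (strain, days).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   degree, `>= 0`.
#' @param seed RNG seed (default 1; ignored when `noise_sd = 0`).
#' @return A validated records data frame
#'   (`strain`, `time_days`, `degree`).
#' @examples
#' generate_degradation_dataset(noise_sd = 0)
#' @export
generate_degradation_dataset <- function(coeffs = degradation_coefficients(),
                                         strains = c(0, 0.2, 0.4),
                                         times = c(3, 10, 20, 30),
                                         noise_sd = 0, seed = 1) {
  coeffs <- as_degradation_coefficients(coeffs)
  if (length(strains) == 0L || length(times) == 0L)
    stop("'strains' and 'times' must be non-empty", call. = FALSE)
  check_numeric(strains, "strains")
  check_numeric(times, "times")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be a single number >= 0", call. = FALSE)
  design <- expand.grid(strain = strains, time_days = times,
                        KEEP.OUT.ATTRS = FALSE)
  degree <- degradation_degree(design$strain, design$time_days, coeffs)
  if (noise_sd > 0)
    degree <- with_seed(seed,
                        degree + stats::rnorm(length(degree), 0, noise_sd))
  design$degree <- pmin(1, pmax(0, degree))
  validate_degradation_records(design)
}
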