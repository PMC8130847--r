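#' Simulation control parameters
#'
#' @param coeffs Kinetic coefficients, a [degradation_coefficients()].
#' @param dt Time step in days (default 0.5).
#' @param horizon Total simulated time in days (default 180, six months at
#'   30 days per month).
#' @param snapshot_interval Days between recorded trajectory rows and
#'   snapshots (default 30, monthly); must be a multiple of `dt`.
#' @param accumulation Damage accumulation rule passed to
#'   [advance_damage()]: `"equivalent_time"` (default) or `"global_time"`.
#'   The two coincide while the strain field is frozen.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(coeffs = degradation_coefficients(),
                              dt = 0.5, horizon = 180,
                              snapshot_interval = 30,
                              accumulation = c("equivalent_time",
                                               "global_time")) {
  coeffs <- as_degradation_coefficients(coeffs)
  accumulation <- match.arg(accumulation)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number of days", call. = FALSE)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < dt)
    stop("'horizon' must be >= dt", call. = FALSE)
  ratio <- snapshot_interval / dt
  if (!is.numeric(snapshot_interval) || snapshot_interval <= 0 ||
      abs(ratio - round(ratio)) > 1e-9)
    stop("'snapshot_interval' must be a positive multiple of dt",
         call. = FALSE)
  structure(list(coeffs = coeffs, dt = dt, horizon = horizon,
                 snapshot_interval = snapshot_interval,
                 accumulation = accumulation),
            class = "simulation_config")
}

#' Scaffold-capacity surrogate
#'
#' A reduced-order stand-in for the radial support the scaffold provides to
#' the artery (the full quantity is a contact force and needs a finite
#' element contact solution, which is out of scope here). Defined as the
#' alive mass fraction, gated by structural topology: if the alive adjacency
#' graph has lost every closed loop (the circumferential ring paths of a
#' stent topology are its cycles), the scaffold can no longer carry hoop
#' load and the capacity is 0. Fields whose adjacency is empty from the
#' start (isolated point clouds) carry no topological information and skip
#' the gate.
#'
#' @param state A [scaffold_state()].
#' @param field The matching [scaffold_field()].
#' @return Capacity in `[0, 1]`; non-increasing along a simulation.
#' @export
capacity_surrogate <- function(state, field) {
  check_state_field(state, field)
  if (!any(state$alive)) return(0)
  alive_frac <- 1 - mass_loss_ratio(state, field)
  if (nrow(field$edges) == 0L) return(alive_frac)
  ga <- field_graph(field, alive = state$alive)
  has_cycle <- igraph::ecount(ga) >=
    igraph::vcount(ga) - igraph::components(ga)$no + 1L
  if (!has_cycle) return(0)
  alive_frac
}

#' Run the strain-driven degradation simulation
#'
#' Time-steps the degradation degree of every alive element under its
#' (frozen) maximum principal strain, updates the fracture strain, and
#' removes elements whose fracture strain has decayed to their strain
#' (element death). Deaths are applied simultaneously at the end of each
#' step, so results do not depend on element ordering. The strain field is
#' frozen by default — deployment strains change little during degradation —
#' but `strain_update` accepts externally recomputed fields per snapshot.
#'
#' @param field A [scaffold_field()].
#' @param config A [simulation_config()].
#' @param strain_update Optional `function(time_days, strain)` returning an
#'   updated strain vector, called at each snapshot time.
#' @param keep_snapshots Keep full per-element snapshot states (default
#'   TRUE; disable for large fields).
#' @return An object of class `degradation_sim`: a list with
#'   \describe{
#'     \item{trajectory}{data frame per snapshot: `time_days`,
#'       `time_months`, `mass_loss_ratio`, `n_components`, `capacity`,
#'       `n_alive`, `n_dead`.}
#'     \item{events}{data frame of fracture events: `element_id`,
#'       `time_days`, `strain`, `degree`.}
#'     \item{fracture_curve}{the closed-form fracture-time curve t*(strain)
#'       evaluated over the field's strain range, for plotting.}
#'     \item{snapshots}{list of [scaffold_state()] objects (if kept).}
#'     \item{field, config}{the inputs.}
#'   }
#' @examples
#' f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 7))
#' sim <- run_degradation(f, simulation_config(dt = 1, horizon = 60))
#' sim$trajectory
#' @export
run_degradation <- function(field, config = simulation_config(),
                            strain_update = NULL, keep_snapshots = TRUE) {
  stopifnot(inherits(field, "scaffold_field"),
            inherits(config, "simulation_config"))
  coeffs <- config$coeffs
  strain <- field$elements$max_principal_strain
  if (any(!is.finite(strain)))
    stop("non-finite strain in field; aborting", call. = FALSE)
  n <- length(strain)
  ids <- field$elements$element_id
  vol <- field$elements$volume

  degree <- rep(0, n)
  alive <- rep(TRUE, n)
  death_time <- rep(NA_real_, n)
  dt <- config$dt
  n_steps <- ceiling(config$horizon / dt - 1e-9)
  snap_every <- round(config$snapshot_interval / dt)

  make_state <- function(t) {
    structure(list(time_days = t, degree = degree,
                   fracture_strain = coeffs$epsilon0 * (1 - degree),
                   alive = alive,
                   dead_mass = sum(vol[!alive])),
              class = "scaffold_state")
  }
  snapshot_row <- function(t) {
    st <- make_state(t)
    data.frame(time_days = t, time_months = t / 30,
               mass_loss_ratio = mass_loss_ratio(st, field),
               n_components = detect_discontinuity(field, st)$n_components,
               capacity = capacity_surrogate(st, field),
               n_alive = sum(alive), n_dead = sum(!alive))
  }

  traj <- vector("list", n_steps %/% snap_every + 2L)
  snaps <- if (keep_snapshots) list() else NULL
  traj[[1L]] <- snapshot_row(0)
  if (keep_snapshots) snaps[["0"]] <- make_state(0)
  ti <- 2L

  for (step in seq_len(n_steps)) {
    t_now <- (step - 1L) * dt
    if (any(alive)) {
      idx <- which(alive)
      degree[idx] <- advance_damage(degree[idx], strain[idx], dt, coeffs,
                                    mode = config$accumulation,
                                    t_now = t_now)
      # death: fracture strain has decayed to the element strain
      eps_t <- coeffs$epsilon0 * (1 - degree[idx])
      dying <- idx[eps_t <= strain[idx] + 1e-12]
      if (length(dying)) {
        alive[dying] <- FALSE
        death_time[dying] <- t_now + dt
      }
    }
    if (step %% snap_every == 0L) {
      t <- step * dt
      traj[[ti]] <- snapshot_row(t)
      if (keep_snapshots) snaps[[format(t)]] <- make_state(t)
      ti <- ti + 1L
      if (!is.null(strain_update)) {
        strain <- strain_update(t, strain)
        check_numeric(strain, "updated strain")
        strain <- pmax(0, strain)
      }
    }
  }
  if (n_steps %% snap_every != 0L) {     # horizon not on a snapshot grid
    traj[[ti]] <- snapshot_row(n_steps * dt)
    if (keep_snapshots) snaps[[format(n_steps * dt)]] <-
        make_state(n_steps * dt)
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  dead <- which(!alive)
  events <- data.frame(element_id = ids[dead],
                       time_days = death_time[dead],
                       strain = field$elements$max_principal_strain[dead],
                       degree = degree[dead])
  events <- events[order(events$time_days, events$element_id), ]
  rownames(events) <- NULL

  rng <- range(field$elements$max_principal_strain)
  curve_strain <- seq(max(rng[1], 1e-3), max(rng[2], 1e-3), length.out = 100)
  fracture_curve <- data.frame(strain = curve_strain,
                               fracture_time_days =
                                 fracture_time(curve_strain, coeffs))
  fracture_curve$fracture_time_months <-
    fracture_curve$fracture_time_days / 30

  structure(list(trajectory = trajectory, events = events,
                 fracture_curve = fracture_curve,
                 snapshots = snaps, field = field, config = config),
            class = "degradation_sim")
}

#' @export
print.degradation_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf(paste0("Degradation simulation: %d elements, dt = %g d, ",
                     "horizon = %g d\n"),
              nrow(x$field$elements), x$config$dt, x$config$horizon))
  cat(sprintf("  %d fracture events; final mass loss %.1f%%, capacity %.2f, %d component(s)\n",
              nrow(x$events), 100 * last$mass_loss_ratio, last$capacity,
              last$n_components))
  invisible(x)
}

#' @export
summary.degradation_sim <- function(object, ...) {
  object$trajectory
}

#' Plot the degradation trajectory
#'
#' Base-graphics view of the mass-loss ratio and capacity surrogate versus
#' time in months.
#'
#' @param x A `degradation_sim`.
#' @param ... Passed to [plot()].
#' @export
plot.degradation_sim <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$time_months, 100 * tr$mass_loss_ratio, type = "b",
                 xlab = "time (months)", ylab = "%",
                 ylim = c(0, 100), pch = 16, ...)
  graphics::lines(tr$time_months, 100 * tr$capacity, type = "b",
                  lty = 2, pch = 1)
  graphics::legend("right", legend = c("mass loss ratio", "capacity"),
                   lty = c(1, 2), pch = c(16, 1), bty = "n")
  invisible(x)
}
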