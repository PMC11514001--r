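## Simulation engine: damped-dynamics geometry optimization, Nose-Hoover
## NVT molecular dynamics and rigid coordinate scans, driven only by the
## potential's predicted energies and forces. Works identically with a
## fitted dimer_gpr and with the analytic oracle_spec.

.atom_masses <- function() .kMASS[.kELEMENTS]

.flat <- function(m) as.vector(t(m))                 # 6x3 -> 18, atom-major
.unflat <- function(x) matrix(x, 6, 3, byrow = TRUE)

#' Construct a hydrogen-bonded dimer geometry
#'
#' Equilibrium-like monomers arranged in a near-linear O1-H2...O4 hydrogen
#' bond; handy as a starting structure for optimization, dynamics and
#' scans.
#'
#' @param roo O1-O4 distance, Angstrom.
#' @param r_oh O-H bond length, Angstrom.
#' @param theta H-O-H angle, degrees.
#' @return a \code{dimer_geometry}.
#' @export
hbonded_dimer <- function(roo = 2.95, r_oh = 0.9572, theta = 104.52) {
  th <- theta * pi / 180
  ## donor: H2 along +x towards O4
  O1 <- c(0, 0, 0)
  H2 <- c(r_oh, 0, 0)
  H3 <- r_oh * c(cos(th), sin(th), 0)
  ## acceptor: bisector of H-O-H along +x, hydrogens fanned out in xz
  O4 <- c(roo, 0, 0)
  half <- th / 2
  H5 <- O4 + r_oh * c(cos(half), 0, sin(half))
  H6 <- O4 + r_oh * c(cos(half), 0, -sin(half))
  dimer_geometry(rbind(O1, H2, H3, O4, H5, H6))
}

#' Locate the surrogate potential's bound dimer minimum
#'
#' Independent of any learned model: a 1D scan of the surrogate energy
#' along the symmetric hydrogen-bonded approach selects the bound well,
#' followed by full 18-coordinate quasi-Newton refinement on the analytic
#' surrogate energy and forces.
#'
#' @param spec an \code{oracle_spec}.
#' @return list with \code{geometry} (a \code{dimer_geometry}) and
#'   \code{energy} (kJ/mol).
#' @export
oracle_minimum <- function(spec = oracle_spec()) {
  grid <- seq(2.3, 3.8, by = 0.05)
  es <- vapply(grid, function(r) oracle_total_energy(hbonded_dimer(r), spec),
               numeric(1))
  start <- hbonded_dimer(grid[which.min(es)])
  fn <- function(x) oracle_total_energy(dimer_geometry(.unflat(x)), spec)
  gr <- function(x) -.flat(oracle_forces(dimer_geometry(.unflat(x)), spec))
  fit <- optim(.flat(.as_coord_matrix(start)), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  g <- dimer_geometry(.unflat(fit$par))
  list(geometry = g, energy = fit$value)
}

#' Settings for geometry optimization
#'
#' @param method \code{"damped"} (velocity-projection damped dynamics,
#'   default) or \code{"lbfgs"} (quasi-Newton on the predicted energy).
#' @param dt damped-dynamics time step, fs.
#' @param max_steps step limit.
#' @param fmax convergence threshold on the maximum force component,
#'   kJ/mol/Angstrom.
#' @param max_disp cap on any per-step coordinate displacement, Angstrom.
#' @return a list of settings.
#' @export
opt_settings <- function(method = c("damped", "lbfgs"), dt = 0.5,
                         max_steps = 10000L, fmax = 1.0, max_disp = 0.1) {
  list(method = match.arg(method), dt = dt,
       max_steps = as.integer(max_steps), fmax = fmax, max_disp = max_disp)
}

#' Geometry optimization on the predicted potential energy surface
#'
#' Damped-dynamics descent: velocities follow the forces but are
#' projected onto the current force direction and zeroed whenever they
#' oppose it, so the energy trace decreases after damping events.
#' Converges when every force component falls below \code{fmax}.
#'
#' @param potential a \code{dimer_gpr} or \code{oracle_spec}.
#' @param start starting \code{dimer_geometry}.
#' @param settings an [opt_settings()] list.
#' @return an object of class \code{dimer_opt} with \code{geometry}
#'   (final), \code{energy_trace} (kJ/mol, one entry per evaluated step),
#'   \code{steps}, \code{converged}, \code{final_fmax}.
#' @export
optimize_geometry <- function(potential, start, settings = opt_settings()) {
  x <- .flat(.as_coord_matrix(start))
  mvec <- rep(.atom_masses(), each = 3)
  v <- numeric(18)
  trace <- numeric(0)
  last_valid <- x
  steps <- 0L
  repeat {
    g <- dimer_geometry(.unflat(x))
    e <- total_energy(potential, g)
    F <- .flat(forces(potential, g))
    if (!all(is.finite(c(e, F)))) {
      warning("non-finite energy/force during optimization; returning last valid frame")
      x <- last_valid
      break
    }
    last_valid <- x
    trace <- c(trace, e)
    fmax_now <- max(abs(F))
    if (fmax_now <= settings$fmax || steps >= settings$max_steps) break
    if (settings$method == "lbfgs") {
      fn <- function(z) total_energy(potential, dimer_geometry(.unflat(z)))
      gr <- function(z) -.flat(forces(potential, dimer_geometry(.unflat(z))))
      fit <- optim(x, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = settings$max_steps))
      x <- fit$par
      g <- dimer_geometry(.unflat(x))
      trace <- c(trace, fit$value)
      F <- .flat(forces(potential, g))
      steps <- steps + fit$counts[1]
      fmax_now <- max(abs(F))
      break
    }
    a <- F / (mvec * .kE_KIN)
    v <- v + settings$dt * a
    P <- sum(v * F)
    v <- if (P > 0) F * (P / sum(F * F)) else numeric(18)
    dx <- settings$dt * v
    s <- max(abs(dx))
    if (s > settings$max_disp) dx <- dx * settings$max_disp / s
    x <- x + dx
    steps <- steps + 1L
  }
  g <- dimer_geometry(.unflat(x))
  F <- .flat(forces(potential, g))
  structure(list(geometry = g,
                 energy_trace = trace,
                 steps = steps,
                 converged = max(abs(F)) <= settings$fmax,
                 final_fmax = max(abs(F))),
            class = "dimer_opt")
}

#' @export
print.dimer_opt <- function(x, ...) {
  cat(sprintf("Geometry optimization: %s in %d steps, E = %.4f kJ/mol, max|F| = %.3g kJ/mol/A\n",
              if (x$converged) "converged" else "NOT converged",
              x$steps, tail(x$energy_trace, 1), x$final_fmax))
  invisible(x)
}

## Nose-Hoover (chain length 1) half-step velocity/friction update
.nh_half <- function(v, xi, mvec, dt2, NfkT, Q) {
  ke2 <- sum(mvec * v^2) * .kE_KIN            # 2 * KE
  G <- (ke2 - NfkT) / Q
  xi <- xi + dt2 / 2 * G
  s <- exp(-dt2 * xi)
  v <- v * s
  ke2 <- ke2 * s^2
  G <- (ke2 - NfkT) / Q
  xi <- xi + dt2 / 2 * G
  list(v = v, xi = xi)
}

#' NVT molecular dynamics with a Nose-Hoover thermostat
#'
#' Velocity-Verlet integration with a single Nose-Hoover thermostat
#' (chain length 1) applied in half-steps around the Verlet update.
#' Initial velocities are drawn from the Maxwell-Boltzmann distribution
#' at the target temperature with the centre-of-mass drift removed.
#' Kinetic temperature uses 3N - 3 = 15 degrees of freedom.
#'
#' @param potential a \code{dimer_gpr} or \code{oracle_spec}.
#' @param start starting \code{dimer_geometry}.
#' @param temperature target temperature, K.
#' @param dt time step, fs.
#' @param n_steps number of steps.
#' @param tau thermostat coupling time constant, fs.
#' @param thermostat logical; \code{FALSE} runs plain NVE velocity Verlet.
#' @param seed integer seed for the initial velocities.
#' @param record_every store every k-th frame (scalars are stored for
#'   every recorded frame).
#' @return an object of class \code{dimer_trajectory}: lists \code{times}
#'   (fs), \code{positions} and \code{velocities} (6 x 3 matrices),
#'   vectors \code{potential_energy}, \code{kinetic_energy},
#'   \code{temperature} (K), \code{xi} (thermostat friction, 1/fs).
#' @export
run_nvt <- function(potential, start, temperature = 298, dt = 1,
                    n_steps = 1000L, tau = 100, thermostat = TRUE,
                    seed = 1L, record_every = 1L) {
  stopifnot(dt > 0, n_steps >= 1, tau > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  mvec <- rep(.atom_masses(), each = 3)
  Nf <- 15
  NfkT <- Nf * .kBOLTZ * temperature
  Q <- NfkT * tau^2

  x <- .flat(.as_coord_matrix(start))
  v <- rnorm(18, sd = sqrt(.kBOLTZ * temperature / (mvec * .kE_KIN)))
  ## remove centre-of-mass drift
  vm <- .unflat(v)
  mm <- .atom_masses()
  vcom <- colSums(vm * mm) / sum(mm)
  v <- .flat(sweep(vm, 2, vcom))
  xi <- 0

  g <- dimer_geometry(.unflat(x))
  F <- .flat(forces(potential, g))
  e <- total_energy(potential, g)
  a <- F / (mvec * .kE_KIN)

  nrec <- floor(n_steps / record_every) + 1L
  times <- numeric(nrec); pe <- numeric(nrec); ke <- numeric(nrec)
  temp <- numeric(nrec); xis <- numeric(nrec)
  pos <- vector("list", nrec); vel <- vector("list", nrec)
  rec <- function(k, t) {
    times[k] <<- t
    pos[[k]] <<- .unflat(x); vel[[k]] <<- .unflat(v)
    kin <- 0.5 * sum(mvec * v^2) * .kE_KIN
    pe[k] <<- e; ke[k] <<- kin
    temp[k] <<- 2 * kin / (Nf * .kBOLTZ)
    xis[k] <<- xi
  }
  k <- 1L
  rec(k, 0)
  for (step in seq_len(n_steps)) {
    if (thermostat) {
      nh <- .nh_half(v, xi, mvec, dt / 2, NfkT, Q)
      v <- nh$v; xi <- nh$xi
    }
    v <- v + 0.5 * dt * a
    x <- x + dt * v
    g <- dimer_geometry(.unflat(x))
    e <- total_energy(potential, g)
    F <- .flat(forces(potential, g))
    if (!all(is.finite(c(e, F))))
      stop(sprintf("non-finite energy/force at step %d (t = %.1f fs)",
                   step, step * dt))
    a <- F / (mvec * .kE_KIN)
    v <- v + 0.5 * dt * a
    if (thermostat) {
      nh <- .nh_half(v, xi, mvec, dt / 2, NfkT, Q)
      v <- nh$v; xi <- nh$xi
    }
    if (step %% record_every == 0L) {
      k <- k + 1L
      rec(k, step * dt)
    }
  }
  structure(list(times = times[seq_len(k)],
                 positions = pos[seq_len(k)],
                 velocities = vel[seq_len(k)],
                 potential_energy = pe[seq_len(k)],
                 kinetic_energy = ke[seq_len(k)],
                 temperature = temp[seq_len(k)],
                 xi = xis[seq_len(k)],
                 dt = dt, target_temperature = temperature,
                 thermostat = thermostat, tau = tau, seed = seed),
            class = "dimer_trajectory")
}

#' @export
print.dimer_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, dt = %g fs, %s\n",
              length(x$times), x$dt,
              if (x$thermostat)
                sprintf("NVT %g K (Nose-Hoover, tau = %g fs)",
                        x$target_temperature, x$tau)
              else "NVE"))
  cat(sprintf("mean temperature: %.1f K; total energy drift (linear fit): %.4g kJ/mol\n",
              mean(x$temperature), energy_drift(x)))
  invisible(x)
}

#' Total-energy drift of a trajectory
#'
#' Slope of a linear fit of total (potential + kinetic) energy against
#' time, multiplied by the trajectory duration: the standard secular
#' drift measure, insensitive to the bounded oscillation a symplectic
#' integrator shows within a period.
#'
#' @param trajectory a \code{dimer_trajectory}.
#' @return drift over the full run, kJ/mol.
#' @export
energy_drift <- function(trajectory) {
  et <- trajectory$potential_energy + trajectory$kinetic_energy
  t <- trajectory$times
  if (length(t) < 2) return(0)
  slope <- coef(lm.fit(cbind(1, t), et))[2]
  as.numeric(slope * (max(t) - min(t)))
}

#' Write a trajectory as multi-frame XYZ plus a scalar log
#'
#' @param trajectory a \code{dimer_trajectory}.
#' @param xyz_path output XYZ path.
#' @param log_path optional path for a tab-separated per-frame log
#'   (time fs, potential/kinetic energy kJ/mol, temperature K, xi 1/fs).
#' @return invisibly, \code{xyz_path}.
#' @export
write_trajectory <- function(trajectory, xyz_path, log_path = NULL) {
  geoms <- lapply(trajectory$positions, dimer_geometry)
  write_xyz(geoms, xyz_path,
            comment = sprintf("t=%.3f fs E=%.6f kJ/mol T=%.2f K",
                              trajectory$times,
                              trajectory$potential_energy,
                              trajectory$temperature))
  if (!is.null(log_path)) {
    df <- data.frame(time_fs = trajectory$times,
                     E_pot = trajectory$potential_energy,
                     E_kin = trajectory$kinetic_energy,
                     T_K = trajectory$temperature,
                     xi = trajectory$xi)
    write.table(df, log_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(xyz_path)
}

#' Rigid scan along the O1-O4 coordinate
#'
#' Holds both monomers internally rigid at the base geometry and
#' translates molecule B along the O1-O4 unit vector so the O1-O4
#' distance takes each grid value; records the predicted (and optionally
#' reference) energy at each point.
#'
#' @param potential a \code{dimer_gpr} or \code{oracle_spec}.
#' @param base base \code{dimer_geometry} (defines the internal monomer
#'   geometries and the scan direction).
#' @param r_min,r_max scan range of the O1-O4 distance, Angstrom.
#' @param step grid spacing, Angstrom.
#' @param reference optional \code{oracle_spec} evaluated alongside.
#' @return an object of class \code{scan_profile}: data frame with
#'   columns \code{r} (Angstrom), \code{energy} and optionally
#'   \code{reference} (kJ/mol).
#' @export
scan_coordinate <- function(potential, base, r_min, r_max, step = 0.1,
                            reference = NULL) {
  stopifnot(r_min <= r_max, step > 0)
  m <- .as_coord_matrix(base)
  u <- m[4, ] - m[1, ]
  r0 <- sqrt(sum(u^2))
  u <- u / r0
  grid <- if (r_min == r_max) r_min else seq(r_min, r_max, by = step)
  geoms <- lapply(grid, function(r) {
    mm <- m
    mm[4:6, ] <- sweep(m[4:6, , drop = FALSE], 2, -(r - r0) * u)
    dimer_geometry(mm)
  })
  contacts <- vapply(geoms, min_separation, numeric(1), mode = "any")
  if (any(contacts < 0.5))
    stop(sprintf("scan grid creates contacts below 0.5 Angstrom (min %.3f)",
                 min(contacts)))
  e <- vapply(geoms, function(g) total_energy(potential, g), numeric(1))
  out <- data.frame(r = grid, energy = e)
  if (!is.null(reference))
    out$reference <- vapply(geoms, oracle_total_energy, numeric(1),
                            spec = reference)
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' @export
plot.scan_profile <- function(x, ...) {
  plot(x$r, x$energy, type = "l",
       xlab = "O1-O4 distance (Angstrom)", ylab = "energy (kJ/mol)", ...)
  if (!is.null(x$reference)) {
    lines(x$r, x$reference, lty = 2)
    legend("topright", legend = c("predicted", "reference"),
           lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
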