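#' Configuration for the synthetic dimer dataset generator
#'
#' The generator draws water dimer configurations uniformly: each monomer's
#' two O-H bond lengths and its H-O-H angle are drawn independently and
#' uniformly from the configured ranges, each monomer receives an
#' independent orientation uniform over the rotation group (random unit
#' quaternion), and molecule B's oxygen is placed at a distance drawn
#' uniformly from \code{separation_range} along a uniformly random
#' direction from O1. Geometries with intermolecular contacts below
#' \code{min_contact} are rejected and regenerated until exactly
#' \code{n_geometries} accepted geometries exist.
#'
#' Defaults emulate the published dimer dataset design: 100,000 geometries
#' with oxygen-oxygen separations anywhere between 2.0 and 5.5 Angstrom,
#' monomer distortions generously bracketing thermal motion at 298 K.
#'
#' @param n_geometries number of accepted geometries to produce.
#' @param separation_range length-2 numeric, Angstrom; default \code{c(2.0, 5.5)}.
#' @param separation_mode \code{"OO"} (the O1-O4 distance is the sampled
#'   separation; default) or \code{"any"} (the sampled value is rescaled so the
#'   minimum intermolecular distance equals it).
#' @param bond_range O-H bond length range, Angstrom; default \code{c(0.85, 1.10)}.
#' @param angle_range H-O-H angle range, degrees; default \code{c(95, 115)}.
#' @param min_contact minimum allowed intermolecular atom-atom distance,
#'   Angstrom; default 1.4.
#' @param seed integer seed; a fixed seed makes the dataset bitwise reproducible.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_geometries = 100000L,
                             separation_range = c(2.0, 5.5),
                             separation_mode = c("OO", "any"),
                             bond_range = c(0.85, 1.10),
                             angle_range = c(95, 115),
                             min_contact = 1.4,
                             seed = 1L) {
  separation_mode <- match.arg(separation_mode)
  stopifnot(n_geometries >= 1,
            length(separation_range) == 2, separation_range[1] > 0,
            separation_range[1] <= separation_range[2],
            length(bond_range) == 2, bond_range[1] > 0,
            bond_range[1] <= bond_range[2],
            length(angle_range) == 2, angle_range[1] > 0,
            angle_range[1] <= angle_range[2], angle_range[2] < 180,
            min_contact >= 0)
  structure(list(n_geometries = as.integer(n_geometries),
                 separation_range = as.numeric(separation_range),
                 separation_mode = separation_mode,
                 bond_range = as.numeric(bond_range),
                 angle_range = as.numeric(angle_range),
                 min_contact = as.numeric(min_contact),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' The WD24-style preset
#'
#' Convenience wrapper for [generator_config()] at the published dataset's
#' study conditions: 100,000 geometries, separations 2.0--5.5 Angstrom.
#'
#' @param n_geometries dataset size; default 100,000.
#' @param seed integer seed.
#' @param ... overrides passed to [generator_config()].
#' @return a \code{generator_config}.
#' @export
wd24_config <- function(n_geometries = 100000L, seed = 1L, ...) {
  generator_config(n_geometries = n_geometries, seed = seed, ...)
}

#' Sample one distorted water monomer in its canonical local frame
#'
#' O at the origin, first H on the +x axis at a bond length drawn uniformly
#' from the bond range, second H in the xy-plane at an independently drawn
#' bond length and an H-O-H angle drawn uniformly from the angle range.
#'
#' @param config a \code{generator_config}.
#' @return 3 x 3 coordinate matrix (rows O, H, H), Angstrom.
#' @export
sample_monomer <- function(config) {
  u <- runif(3)
  .monomer_from_uniforms(u, config)
}

.monomer_from_uniforms <- function(u, config) {
  r1 <- config$bond_range[1] + u[1] * diff(config$bond_range)
  r2 <- config$bond_range[1] + u[2] * diff(config$bond_range)
  th <- (config$angle_range[1] + u[3] * diff(config$angle_range)) * pi / 180
  rbind(c(0, 0, 0),
        c(r1, 0, 0),
        c(r2 * cos(th), r2 * sin(th), 0))
}

## uniform rotation from 4 standard normals (normalized quaternion)
.rotation_from_normals <- function(z) {
  q <- z / sqrt(sum(z^2))
  .quat_to_rot(q)
}

#' Sample one dimer configuration
#'
#' Two independently sampled monomers, each independently and uniformly
#' oriented; molecule B's oxygen placed at a separation drawn uniformly
#' from the configured range along a uniformly random direction. Both
#' molecules are exchangeable in distribution, so either can act as the
#' hydrogen-bond donor or acceptor.
#'
#' @param config a \code{generator_config}.
#' @return a \code{dimer_geometry} (unfiltered).
#' @export
sample_dimer <- function(config) {
  draws <- list(u = runif(7), z = rnorm(11))
  .dimer_from_draws(draws$u, draws$z, config)
}

## fixed draw layout per candidate: u[1:3] monomer A, u[4:6] monomer B,
## u[7] separation; z[1:4], z[5:8] orientation quaternions, z[9:11] direction
.dimer_from_draws <- function(u, z, config) {
  ma <- .monomer_from_uniforms(u[1:3], config)
  mb <- .monomer_from_uniforms(u[4:6], config)
  Ra <- .rotation_from_normals(z[1:4])
  Rb <- .rotation_from_normals(z[5:8])
  ma <- ma %*% t(Ra)
  mb <- mb %*% t(Rb)
  sep <- config$separation_range[1] + u[7] * diff(config$separation_range)
  dir <- z[9:11]
  dir <- dir / sqrt(sum(dir^2))
  g <- rbind(ma, sweep(mb, 2, -sep * dir))
  if (config$separation_mode == "any") {
    ## rescale the displacement so the closest intermolecular contact
    ## equals the sampled separation
    gm <- dimer_geometry(g)
    cur <- min_separation(gm, "any")
    g <- rbind(ma, sweep(mb, 2, -sep * (sep / cur) * dir))
  }
  dimer_geometry(g)
}

#' Accept/reject filter for generated geometries
#'
#' Rejects a geometry when (a) any intermolecular atom-atom distance is
#' below \code{min_contact}, or (b) any intramolecular O-H bond falls
#' outside the configured distortion range inflated by 10 percent.
#'
#' @param g a \code{dimer_geometry}.
#' @param config a \code{generator_config}.
#' @return a list with \code{accept} (logical) and \code{reason}
#'   (\code{NA}, \code{"close contact"} or \code{"bond out of range"}).
#' @export
filter_geometry <- function(g, config) {
  m <- .as_coord_matrix(g)
  if (min_separation(g, "any") < config$min_contact)
    return(list(accept = FALSE, reason = "close contact"))
  lo <- config$bond_range[1] * 0.9
  hi <- config$bond_range[2] * 1.1
  bonds <- c(sqrt(sum((m[2, ] - m[1, ])^2)), sqrt(sum((m[3, ] - m[1, ])^2)),
             sqrt(sum((m[5, ] - m[4, ])^2)), sqrt(sum((m[6, ] - m[4, ])^2)))
  if (any(bonds < lo | bonds > hi))
    return(list(accept = FALSE, reason = "bond out of range"))
  list(accept = TRUE, reason = NA_character_)
}

#' Generate a synthetic dimer dataset
#'
#' Draws candidates with [sample_dimer()] and applies [filter_geometry()],
#' topping up by rejection sampling until exactly \code{n_geometries}
#' accepted geometries exist. The whole run is driven by one seeded RNG
#' stream, so a fixed config + seed reproduces the dataset bitwise.
#'
#' @param config a \code{generator_config}.
#' @return an object of class \code{dimer_dataset}: a list with
#'   \code{geometries} (list of \code{dimer_geometry}) and \code{config}.
#' @examples
#' d <- generate_dataset(generator_config(n_geometries = 5, seed = 7))
#' length(d$geometries)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_geometries
  geoms <- vector("list", n)
  attempted <- 0L
  for (i in seq_len(n)) {
    u <- runif(7)
    z <- rnorm(11)
    repeat {
      attempted <- attempted + 1L
      g <- .dimer_from_draws(u, z, config)
      if (filter_geometry(g, config)$accept) break
      if (attempted >= 100L && i < attempted / 100)
        stop(sprintf(
          "filter rejection rate above 99%% (%d accepted of %d attempts): check min_contact/ranges",
          i - 1L, attempted))
      ## redraw monomers, orientations and direction; the sampled
      ## separation u[7] is kept so the separation marginal stays
      ## exactly uniform after filtering
      u[1:6] <- runif(6)
      z <- rnorm(11)
    }
    geoms[[i]] <- g
  }
  structure(list(geometries = geoms, config = config),
            class = "dimer_dataset")
}

#' @export
print.dimer_dataset <- function(x, ...) {
  cat(sprintf("Dimer dataset: %d geometries (seed %d, separations %.2f-%.2f A, mode %s)\n",
              length(x$geometries), x$config$seed,
              x$config$separation_range[1], x$config$separation_range[2],
              x$config$separation_mode))
  invisible(x)
}

#' Random disjoint train/test split of a dataset
#'
#' Works on a plain \code{dimer_dataset} and on a \code{labeled_dataset}
#' (labels and stored forces follow their geometries).
#'
#' @param dataset a \code{dimer_dataset} or \code{labeled_dataset}.
#' @param n_train,n_test partition sizes; their sum must not exceed the
#'   dataset size.
#' @param seed integer seed for the partition.
#' @return a list with \code{train} and \code{test} of the same class as
#'   the input.
#' @export
split_dataset <- function(dataset, n_train, n_test, seed = 1L) {
  n <- length(dataset$geometries)
  if (n_train + n_test > n)
    stop(sprintf("insufficient geometries: need %d, have %d", n_train + n_test, n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  idx <- sample.int(n, n_train + n_test)
  mk <- function(i) {
    if (inherits(dataset, "labeled_dataset")) {
      structure(list(geometries = dataset$geometries[i],
                     atomic_energies = dataset$atomic_energies[i, , drop = FALSE],
                     total_energy = dataset$total_energy[i],
                     forces = if (is.null(dataset$forces)) NULL
                              else dataset$forces[i],
                     oracle_spec = dataset$oracle_spec),
                class = "labeled_dataset")
    } else {
      structure(list(geometries = dataset$geometries[i],
                     config = dataset$config),
                class = "dimer_dataset")
    }
  }
  list(train = mk(idx[seq_len(n_train)]),
       test = mk(idx[n_train + seq_len(n_test)]))
}

#' Histogram of intermolecular separations in a dataset
#'
#' Diagnostic for sampling uniformity over the separation range.
#'
#' @param dataset a \code{dimer_dataset}.
#' @param mode separation mode as in [min_separation()].
#' @param bins number of equal-width bins over the observed range.
#' @return a list with \code{breaks} (bin edges, Angstrom) and \code{counts};
#'   counts sum to the dataset size.
#' @export
distance_distribution <- function(dataset, mode = "OO", bins = 35L) {
  stopifnot(length(dataset$geometries) > 0)
  d <- vapply(dataset$geometries, min_separation, numeric(1), mode = mode)
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- hist(d, breaks = breaks, plot = FALSE, include.lowest = TRUE)$counts
  list(breaks = breaks, counts = counts)
}

## save/restore the global RNG state so seeded helpers do not clobber
## the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
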