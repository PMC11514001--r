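#' Analytic surrogate potential for the water dimer
#'
#' A smooth, cheap, flexible-water dimer potential used as the labelling
#' oracle for the learning pipeline: harmonic O-H bonds and H-O-H angles,
#' fixed point charges interacting through all nine intermolecular Coulomb
#' pairs, and one oxygen-oxygen 12-6 term. It has a hydrogen-bonded bound
#' minimum and an exact per-atom energy partition, so every downstream
#' stage (feature extraction, GPR training, forces, dynamics) can be
#' trained and validated against analytic energies, atomic energies and
#' forces without electronic-structure calculations.
#'
#' Defaults use widely adopted rigid-water charges (O -0.834 e, H +0.417 e)
#' and oxygen 12-6 parameters (well depth 0.6364 kJ/mol, contact distance
#' 3.1507 Angstrom), with flexible-water spring constants. Bond energy is
#' \code{bond_k * (r - bond_r0)^2} and angle energy
#' \code{angle_k * (theta - angle_theta0)^2}.
#'
#' @param bond_k O-H force constant, kJ/mol/A^2.
#' @param bond_r0 O-H equilibrium length, Angstrom.
#' @param angle_k H-O-H force constant, kJ/mol/rad^2.
#' @param angle_theta0 H-O-H equilibrium angle, radians.
#' @param q_O,q_H partial charges, e; must sum to zero per molecule.
#' @param lj_epsilon O-O well depth, kJ/mol.
#' @param lj_sigma O-O contact distance, Angstrom.
#' @param coulomb Coulomb constant, kJ*A/mol/e^2.
#' @return an object of class \code{oracle_spec}.
#' @export
oracle_spec <- function(bond_k = 2215.76,
                        bond_r0 = 0.9572,
                        angle_k = 158.78,
                        angle_theta0 = 104.52 * pi / 180,
                        q_O = -0.834, q_H = 0.417,
                        lj_epsilon = 0.6364,
                        lj_sigma = 3.1507,
                        coulomb = .kCOULOMB) {
  stopifnot(is.finite(c(bond_k, bond_r0, angle_k, angle_theta0,
                        q_O, q_H, lj_epsilon, lj_sigma, coulomb)))
  if (abs(q_O + 2 * q_H) > 1e-12)
    stop("charges must sum to zero per molecule (q_O + 2 q_H = 0)")
  structure(list(bond_k = bond_k, bond_r0 = bond_r0,
                 angle_k = angle_k, angle_theta0 = angle_theta0,
                 q_O = q_O, q_H = q_H,
                 lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
                 coulomb = coulomb),
            class = "oracle_spec")
}

## term bookkeeping shared by energy / partition / forces ---------------

.kBONDS <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 5L), c(4L, 6L))
.kANGLES <- rbind(c(2L, 1L, 3L), c(5L, 4L, 6L))  # end, vertex, end

.oracle_charges <- function(spec) {
  c(spec$q_O, spec$q_H, spec$q_H, spec$q_O, spec$q_H, spec$q_H)
}

## angle at vertex j between arms to i and k, plus d(theta)/d(r_i, r_j, r_k)
.angle_and_grad <- function(ri, rj, rk) {
  u <- ri - rj; v <- rk - rj
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  cth <- max(-1, min(1, sum(uh * vh)))
  th <- acos(cth)
  sth <- sqrt(max(1 - cth^2, 1e-24))
  gi <- (cth * uh - vh) / (nu * sth)
  gk <- (cth * vh - uh) / (nv * sth)
  list(theta = th, gi = gi, gj = -(gi + gk), gk = gk)
}

#' Surrogate atomic energies
#'
#' Exact per-atom partition of the surrogate potential: each bond term is
#' split half-half between its two atoms, each angle term is assigned to
#' the vertex oxygen, and each intermolecular pair term (Coulomb or 12-6)
#' is split half-half between its two atoms. The six atomic energies sum
#' to [oracle_total_energy()] exactly (to numerical round-off).
#'
#' @param g a \code{dimer_geometry}.
#' @param spec an \code{oracle_spec}.
#' @return named numeric vector of 6 atomic energies, kJ/mol.
#' @export
oracle_atomic_energies <- function(g, spec = oracle_spec()) {
  m <- .as_coord_matrix(g)
  e <- numeric(6)
  ## bonds
  for (b in seq_len(nrow(.kBONDS))) {
    i <- .kBONDS[b, 1]; j <- .kBONDS[b, 2]
    r <- sqrt(sum((m[i, ] - m[j, ])^2))
    if (r <= 0) stop("coincident atoms in bond term")
    eb <- spec$bond_k * (r - spec$bond_r0)^2
    e[i] <- e[i] + eb / 2
    e[j] <- e[j] + eb / 2
  }
  ## angles: vertex oxygen takes the whole term
  for (a in seq_len(nrow(.kANGLES))) {
    tri <- .kANGLES[a, ]
    th <- .angle_and_grad(m[tri[1], ], m[tri[2], ], m[tri[3], ])$theta
    e[tri[2]] <- e[tri[2]] + spec$angle_k * (th - spec$angle_theta0)^2
  }
  ## intermolecular Coulomb pairs
  q <- .oracle_charges(spec)
  pr <- .intermolecular_pairs()
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    r <- sqrt(sum((m[i, ] - m[j, ])^2))
    if (r <= 0) stop("coincident atoms in Coulomb term")
    ec <- spec$coulomb * q[i] * q[j] / r
    e[i] <- e[i] + ec / 2
    e[j] <- e[j] + ec / 2
  }
  ## O-O 12-6
  r <- sqrt(sum((m[1, ] - m[4, ])^2))
  sr6 <- (spec$lj_sigma / r)^6
  elj <- 4 * spec$lj_epsilon * (sr6^2 - sr6)
  e[1] <- e[1] + elj / 2
  e[4] <- e[4] + elj / 2
  names(e) <- .kATOM_LABELS
  e
}

#' Surrogate total energy
#'
#' Sum of 4 harmonic bond terms, 2 harmonic angle terms, 9 intermolecular
#' Coulomb pair terms and one O-O 12-6 term. Smooth in the coordinates;
#' tends to zero for undistorted monomers at large separation.
#'
#' @inheritParams oracle_atomic_energies
#' @return total energy, kJ/mol.
#' @examples
#' g <- dimer_geometry(rbind(
#'   c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.9266, 0),
#'   c(3, 0, 0), c(3.9572, 0, 0), c(2.76, 0.9266, 0)))
#' oracle_total_energy(g)
#' @export
oracle_total_energy <- function(g, spec = oracle_spec()) {
  sum(oracle_atomic_energies(g, spec))
}

#' Surrogate analytic forces
#'
#' Minus the analytic gradient of [oracle_total_energy()]. Net force and
#' net torque vanish (the potential depends on internal coordinates only).
#'
#' @inheritParams oracle_atomic_energies
#' @return 6 x 3 matrix of forces, kJ/mol/Angstrom.
#' @export
oracle_forces <- function(g, spec = oracle_spec()) {
  m <- .as_coord_matrix(g)
  F <- matrix(0, 6, 3)
  ## bonds: dE/dri = 2 k (r - r0) * (ri - rj)/r
  for (b in seq_len(nrow(.kBONDS))) {
    i <- .kBONDS[b, 1]; j <- .kBONDS[b, 2]
    dv <- m[i, ] - m[j, ]
    r <- sqrt(sum(dv^2))
    gmag <- 2 * spec$bond_k * (r - spec$bond_r0)
    gi <- gmag * dv / r
    F[i, ] <- F[i, ] - gi
    F[j, ] <- F[j, ] + gi
  }
  ## angles
  for (a in seq_len(nrow(.kANGLES))) {
    tri <- .kANGLES[a, ]
    ag <- .angle_and_grad(m[tri[1], ], m[tri[2], ], m[tri[3], ])
    pref <- 2 * spec$angle_k * (ag$theta - spec$angle_theta0)
    F[tri[1], ] <- F[tri[1], ] - pref * ag$gi
    F[tri[2], ] <- F[tri[2], ] - pref * ag$gj
    F[tri[3], ] <- F[tri[3], ] - pref * ag$gk
  }
  ## Coulomb: dE/dri = -C q q / r^3 * (ri - rj)
  q <- .oracle_charges(spec)
  pr <- .intermolecular_pairs()
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    dv <- m[i, ] - m[j, ]
    r <- sqrt(sum(dv^2))
    gi <- -spec$coulomb * q[i] * q[j] / r^3 * dv
    F[i, ] <- F[i, ] - gi
    F[j, ] <- F[j, ] + gi
  }
  ## O-O 12-6: dE/dr = 4 eps (-12 s^12/r^13 + 6 s^6/r^7)
  dv <- m[1, ] - m[4, ]
  r <- sqrt(sum(dv^2))
  sr6 <- (spec$lj_sigma / r)^6
  dEdr <- 4 * spec$lj_epsilon * (-12 * sr6^2 + 6 * sr6) / r
  gi <- dEdr * dv / r
  F[1, ] <- F[1, ] - gi
  F[4, ] <- F[4, ] + gi
  dimnames(F) <- list(.kATOM_LABELS, c("x", "y", "z"))
  F
}

#' Label a dataset with the surrogate oracle
#'
#' @param dataset a \code{dimer_dataset}.
#' @param spec an \code{oracle_spec}.
#' @param forces logical; also store analytic reference forces.
#' @return an object of class \code{labeled_dataset}: list with
#'   \code{geometries}, \code{atomic_energies} (n x 6 matrix, kJ/mol),
#'   \code{total_energy} (length n, kJ/mol), optionally \code{forces}
#'   (list of 6 x 3 matrices), plus the \code{oracle_spec} used.
#' @export
label_dataset <- function(dataset, spec = oracle_spec(), forces = FALSE) {
  geoms <- dataset$geometries
  n <- length(geoms)
  ae <- matrix(NA_real_, n, 6, dimnames = list(NULL, .kATOM_LABELS))
  fl <- if (forces) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ei <- tryCatch(oracle_atomic_energies(geoms[[i]], spec),
                   error = function(e)
                     stop(sprintf("labelling failed at geometry %d: %s",
                                  i, conditionMessage(e))))
    ae[i, ] <- ei
    if (forces) fl[[i]] <- oracle_forces(geoms[[i]], spec)
  }
  structure(list(geometries = geoms,
                 atomic_energies = ae,
                 total_energy = rowSums(ae),
                 forces = fl,
                 oracle_spec = spec),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dimer dataset: %d geometries%s\n",
              length(x$geometries),
              if (!is.null(x$forces)) " (with reference forces)" else ""))
  cat(sprintf("total energy range: [%.2f, %.2f] kJ/mol\n",
              min(x$total_energy), max(x$total_energy)))
  invisible(x)
}

#' Write a labeled dataset to delimited text
#'
#' One row per geometry: 18 coordinates (atom-major x,y,z), 6 atomic
#' energies, the total energy, and optionally 18 force components.
#'
#' @param labeled a \code{labeled_dataset}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_labeled <- function(labeled, path) {
  n <- length(labeled$geometries)
  X <- t(vapply(labeled$geometries,
                function(g) as.vector(t(.as_coord_matrix(g))), numeric(18)))
  colnames(X) <- paste0(rep(.kATOM_LABELS, each = 3), "_", c("x", "y", "z"))
  df <- data.frame(X, check.names = FALSE)
  ae <- labeled$atomic_energies
  colnames(ae) <- paste0("E_", .kATOM_LABELS)
  df <- cbind(df, ae, E_total = labeled$total_energy)
  if (!is.null(labeled$forces)) {
    Fm <- t(vapply(labeled$forces, function(f) as.vector(t(f)), numeric(18)))
    colnames(Fm) <- paste0("F_", rep(.kATOM_LABELS, each = 3), "_",
                           c("x", "y", "z"))
    df <- cbind(df, Fm)
  }
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled dataset written by [write_labeled()]
#'
#' @param path CSV path.
#' @param spec the \code{oracle_spec} to attach as provenance (not re-applied).
#' @return a \code{labeled_dataset}.
#' @export
read_labeled <- function(path, spec = oracle_spec()) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  n <- nrow(df)
  geoms <- vector("list", n)
  for (i in seq_len(n))
    geoms[[i]] <- dimer_geometry(matrix(as.numeric(df[i, 1:18]), 6, 3,
                                        byrow = TRUE))
  ae <- as.matrix(df[, paste0("E_", .kATOM_LABELS)])
  colnames(ae) <- .kATOM_LABELS
  fcols <- grep("^F_", names(df), value = TRUE)
  fl <- NULL
  if (length(fcols) == 18L) {
    fl <- lapply(seq_len(n), function(i)
      matrix(as.numeric(df[i, fcols]), 6, 3, byrow = TRUE,
             dimnames = list(.kATOM_LABELS, c("x", "y", "z"))))
  }
  structure(list(geometries = geoms, atomic_energies = ae,
                 total_energy = df$E_total, forces = fl, oracle_spec = spec),
            class = "labeled_dataset")
}
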