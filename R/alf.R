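## Atomic Local Frame (ALF) descriptors.
##
## Each atom A gets a local right-handed frame from two reference atoms
## X1, X2: x-hat along (X1 - A), z-hat along (X1 - A) x (X2 - A),
## y-hat = z-hat x x-hat. The 3N-6 = 12 features of atom A are
## [ R(A-X1), R(A-X2), angle X1-A-X2,
##   then for each of the 3 non-frame atoms in ascending global index:
##   r, theta in [0, pi], phi in (-pi, pi] ] (spherical coordinates in the
## local frame). Features are invariant under global rotation and
## translation; phi is azimuthal and is treated periodically by the kernel.

## covalent connectivity of the dimer (O-H bonds only)
.kNEIGHBORS <- list(c(2L, 3L), 1L, 1L, c(5L, 6L), 4L, 4L)

#' Assign the Atomic Local Frame reference atoms for one atom
#'
#' The x-axis atom is the bonded neighbour of highest atomic mass, ties
#' broken by lowest global index; the xy-plane atom is the next atom by
#' the same priority, extending breadth-first to neighbours-of-neighbours
#' when the atom has fewer than two bonded neighbours. Connectivity is the
#' fixed covalent O-H bonding of the dimer, so the assignment is identical
#' for every geometry.
#'
#' @param atom atom index, 1..6, in the fixed ordering O1 H2 H3 O4 H5 H6.
#' @return a list with \code{origin}, \code{x_axis}, \code{xy_plane}
#'   (atom indices).
#' @examples
#' assign_alf(1)  # O1: x-axis H2, xy-plane H3
#' assign_alf(2)  # H2: x-axis O1, xy-plane H3 (neighbour-of-neighbour)
#' @export
assign_alf <- function(atom) {
  stopifnot(atom %in% 1:6)
  mass <- .kMASS[.kELEMENTS]
  prio <- function(cand) cand[order(-mass[cand], cand)]
  nb <- .kNEIGHBORS[[atom]]
  cand <- prio(nb)
  if (length(cand) < 2L) {
    ## breadth-first extension: neighbours of neighbours, excluding seen atoms
    nxt <- sort(unique(unlist(.kNEIGHBORS[nb])))
    nxt <- setdiff(nxt, c(atom, nb))
    cand <- c(cand, prio(nxt))
  }
  if (length(cand) < 2L)
    stop("cannot assign ALF: fewer than two reference candidates")
  list(origin = atom, x_axis = cand[1], xy_plane = cand[2])
}

## cached ALF assignments and non-frame atom lists for the fixed dimer
.alf_all <- function() {
  lapply(1:6, function(a) {
    alf <- assign_alf(a)
    alf$non_frame <- sort(setdiff(1:6, c(alf$origin, alf$x_axis, alf$xy_plane)))
    alf
  })
}

.kALF <- NULL  # populated at load time

.onLoad <- function(libname, pkgname) {
  assign(".kALF", .alf_all(), envir = parent.env(environment()))
}

.get_alf <- function(atom) {
  if (is.null(.kALF)) .alf_all()[[atom]] else .kALF[[atom]]
}

## skew(s) %*% d = s x d
.skew <- function(s) {
  matrix(c(0, -s[3], s[2],
           s[3], 0, -s[1],
           -s[2], s[1], 0), 3, 3, byrow = TRUE)
}

## frame axes and intermediates for atom A; errors on a degenerate frame
.alf_frame <- function(m, alf) {
  a <- m[alf$origin, ]; b <- m[alf$x_axis, ]; cc <- m[alf$xy_plane, ]
  u <- b - a; v <- cc - a
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10 * nu * nv)
    stop("degenerate ALF frame: origin, x-axis and xy-plane atoms are collinear")
  xh <- u / nu
  zh <- n / nn
  yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
          zh[3] * xh[1] - zh[1] * xh[3],
          zh[1] * xh[2] - zh[2] * xh[1])
  list(a = a, u = u, v = v, nu = nu, nv = nv, n = n, nn = nn,
       xh = xh, yh = yh, zh = zh)
}

#' Compute the 12 ALF features of one atom
#'
#' @param g a \code{dimer_geometry}.
#' @param atom atom index, 1..6.
#' @param alf optional ALF assignment (defaults to [assign_alf()] for
#'   \code{atom}).
#' @return numeric vector of length 12 (3N - 6 for N = 6): two frame
#'   distances (Angstrom), the frame angle (rad), then (r, theta, phi) for
#'   each non-frame atom in ascending global index. theta lies in
#'   \code{[0, pi]}, phi in \code{(-pi, pi]}.
#' @export
compute_features <- function(g, atom, alf = NULL) {
  if (is.null(alf)) alf <- .get_alf(atom)
  m <- .as_coord_matrix(g)
  fr <- .alf_frame(m, alf)
  ang <- .angle_and_grad(m[alf$x_axis, ], fr$a, m[alf$xy_plane, ])$theta
  feats <- c(fr$nu, fr$nv, ang)
  for (p in alf$non_frame) {
    w <- m[p, ] - fr$a
    r <- sqrt(sum(w^2))
    xl <- sum(w * fr$xh); yl <- sum(w * fr$yh); zl <- sum(w * fr$zh)
    theta <- acos(max(-1, min(1, zl / r)))
    phi <- atan2(yl, xl)
    feats <- c(feats, r, theta, phi)
  }
  feats
}

#' Feature matrix of a whole dimer
#'
#' @param g a \code{dimer_geometry}.
#' @return 6 x 12 matrix; row i holds the ALF features of atom i.
#' @export
dimer_features <- function(g) {
  t(vapply(1:6, function(a) compute_features(g, a), numeric(12)))
}

## indices of the azimuthal (phi) dimensions in the 12-feature layout
.kPHI_DIMS <- c(6L, 9L, 12L)

#' Analytic Jacobian of one atom's ALF features
#'
#' Exact partial derivatives of the 12 features with respect to all 18
#' Cartesian coordinates (atom-major x,y,z column ordering). Because the
#' features are rigid-motion invariant, every row annihilates the six
#' infinitesimal translation and rotation generators.
#'
#' @inheritParams compute_features
#' @return 12 x 18 numeric matrix, units 1/Angstrom-free mix (Angstrom
#'   features: dimensionless rows; angular features: rad/Angstrom).
#' @export
feature_jacobian <- function(g, atom, alf = NULL) {
  if (is.null(alf)) alf <- .get_alf(atom)
  m <- .as_coord_matrix(g)
  fr <- .alf_frame(m, alf)
  iA <- alf$origin; iB <- alf$x_axis; iC <- alf$xy_plane
  cols <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  J <- matrix(0, 12L, 18L)

  uh <- fr$u / fr$nu; vh <- fr$v / fr$nv
  ## row 1: R(A-X1)
  J[1, cols(iB)] <- uh
  J[1, cols(iA)] <- -uh
  ## row 2: R(A-X2)
  J[2, cols(iC)] <- vh
  J[2, cols(iA)] <- -vh
  ## row 3: frame angle X1-A-X2
  ag <- .angle_and_grad(m[iB, ], fr$a, m[iC, ])
  J[3, cols(iB)] <- ag$gi
  J[3, cols(iA)] <- ag$gj
  J[3, cols(iC)] <- ag$gk

  ## axis derivative matrices (3x3, d axis / d position of atom q)
  I3 <- diag(3)
  Pu <- (I3 - tcrossprod(uh)) / fr$nu
  Pn <- (I3 - tcrossprod(fr$zh)) / fr$nn
  Sv <- .skew(fr$v); Su <- .skew(fr$u)
  dxh <- list()  # by atom index
  dxh[[iB]] <- Pu
  dxh[[iA]] <- -Pu
  dzh <- list()
  dzh[[iB]] <- -Pn %*% Sv        # dn/du = -skew(v)
  dzh[[iC]] <- Pn %*% Su
  dzh[[iA]] <- Pn %*% (Sv - Su)
  Sx <- .skew(fr$xh); Sz <- .skew(fr$zh)
  dyh <- list()
  for (q in unique(c(iA, iB, iC))) {
    Dz <- if (q <= length(dzh) && !is.null(dzh[[q]])) dzh[[q]] else matrix(0, 3, 3)
    Dx <- if (q <= length(dxh) && !is.null(dxh[[q]])) dxh[[q]] else matrix(0, 3, 3)
    dyh[[q]] <- -Sx %*% Dz + Sz %*% Dx
  }

  row <- 4L
  for (p in alf$non_frame) {
    w <- m[p, ] - fr$a
    r <- sqrt(sum(w^2))
    wh <- w / r
    xl <- sum(w * fr$xh); yl <- sum(w * fr$yh); zl <- sum(w * fr$zh)
    rho2 <- xl^2 + yl^2
    rho <- sqrt(rho2)

    ## d r: depends on p and A only
    dr <- matrix(0, 1, 18)
    dr[, cols(p)] <- wh
    dr[, cols(iA)] <- dr[, cols(iA)] - wh
    J[row, ] <- dr

    ## local components: d(w . axis) = axis^T dw + w^T d(axis)
    dcomp <- function(axis, daxis_list) {
      d <- matrix(0, 1, 18)
      d[, cols(p)] <- axis
      d[, cols(iA)] <- d[, cols(iA)] - axis
      for (q in unique(c(iA, iB, iC))) {
        Dq <- if (q <= length(daxis_list) && !is.null(daxis_list[[q]]))
          daxis_list[[q]] else NULL
        if (!is.null(Dq))
          d[, cols(q)] <- d[, cols(q)] + as.numeric(w %*% Dq)
      }
      d
    }
    dxl <- dcomp(fr$xh, dxh)
    dyl <- dcomp(fr$yh, dyh)
    dzl <- dcomp(fr$zh, dzh)

    ## theta = acos(zl / r); d theta = (zl dr - r dzl) / (r rho)
    J[row + 1L, ] <- (zl * dr - r * dzl) / (r * rho)
    ## phi = atan2(yl, xl); d phi = (xl dyl - yl dxl) / rho^2
    J[row + 2L, ] <- (xl * dyl - yl * dxl) / rho2
    row <- row + 3L
  }
  J
}

#' Jacobians for all six atoms of a dimer
#'
#' @param g a \code{dimer_geometry}.
#' @return list of six 12 x 18 matrices.
#' @export
dimer_jacobians <- function(g) {
  lapply(1:6, function(a) feature_jacobian(g, a))
}
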