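#' @importFrom stats coef dist lm.fit optim predict quantile residuals rnorm runif sd simulate var
#' @importFrom graphics abline hist legend lines
#' @importFrom utils capture.output read.table tail write.table
NULL

## fixed atom ordering of the dimer; molecule A = atoms 1:3, molecule B = 4:6
.kATOM_LABELS <- c("O1", "H2", "H3", "O4", "H5", "H6")
.kELEMENTS <- c("O", "H", "H", "O", "H", "H")
.kMOL_A <- 1:3
.kMOL_B <- 4:6

#' Construct a water dimer geometry
#'
#' A dimer geometry is a 6 x 3 numeric matrix of Cartesian coordinates in
#' Angstrom with the mandatory atom ordering O1 H2 H3 O4 H5 H6. Atoms 1--3
#' form molecule A, atoms 4--6 molecule B. The ordering is load-bearing:
#' per-atom models, features and labels all identify atoms positionally.
#'
#' @param coords 6 x 3 numeric matrix (rows = atoms, columns = x, y, z), Angstrom.
#' @return an object of class \code{dimer_geometry}.
#' @examples
#' g <- dimer_geometry(rbind(
#'   c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
#'   c(3, 0, 0), c(3.96, 0, 0), c(2.76, 0.93, 0)))
#' print(g)
#' @export
dimer_geometry <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !identical(dim(coords), c(6L, 3L)))
    stop("coords must be a 6 x 3 numeric matrix")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] <= 0))
    stop("coincident atoms: all pairwise distances must be positive")
  dimnames(coords) <- list(.kATOM_LABELS, c("x", "y", "z"))
  structure(coords, class = "dimer_geometry")
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat("Water dimer geometry (Angstrom):\n")
  m <- unclass(x)
  print(round(m, 6))
  cat(sprintf("|O1-O4| = %.4f Angstrom\n", sqrt(sum((m[1, ] - m[4, ])^2))))
  invisible(x)
}

#' Elements of the fixed dimer ordering
#'
#' @return character vector \code{c("O","H","H","O","H","H")}.
#' @export
dimer_elements <- function() .kELEMENTS

.as_coord_matrix <- function(g) {
  m <- unclass(g)
  attr(m, "class") <- NULL
  m
}

## all 9 intermolecular atom pairs (i in molecule A, j in molecule B)
.intermolecular_pairs <- function() {
  as.matrix(expand.grid(i = .kMOL_A, j = .kMOL_B))
}

#' Minimum intermolecular separation of a dimer
#'
#' @param g a \code{dimer_geometry}.
#' @param mode \code{"OO"}: the O1--O4 distance; \code{"OH"}: the minimum over
#'   the 4 intermolecular O...H pairs; \code{"any"}: the minimum over all 9
#'   intermolecular pairs.
#' @return distance in Angstrom.
#' @examples
#' g <- dimer_geometry(rbind(
#'   c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
#'   c(3, 0, 0), c(3.96, 0, 0), c(2.76, 0.93, 0)))
#' min_separation(g, "OO")
#' @export
min_separation <- function(g, mode = c("OO", "OH", "any")) {
  mode <- match.arg(mode)
  m <- .as_coord_matrix(g)
  pd <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  switch(mode,
    OO = pd(1L, 4L),
    OH = min(pd(1L, 5L), pd(1L, 6L), pd(4L, 2L), pd(4L, 3L)),
    any = {
      A <- m[.kMOL_A, , drop = FALSE]
      B <- m[.kMOL_B, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      sqrt(max(min(d2), 0))
    })
}

#' Read dimer geometries from a multi-frame XYZ file
#'
#' Standard XYZ layout per frame: an atom-count line ("6"), a comment line,
#' then one "element x y z" line per atom. The element sequence must match
#' the fixed ordering O H H O H H; anything else is rejected.
#'
#' @param path path to an XYZ file.
#' @return a list of \code{dimer_geometry} objects in file order.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ## drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n != 6L)
      stop(sprintf("line %d: malformed count line (expected 6, got '%s')",
                   i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("line %d: truncated frame", i))
    coords <- matrix(NA_real_, 6L, 3L)
    for (a in 1:6) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("line %d: expected 'element x y z'", ln))
      if (toupper(tok[1]) != .kELEMENTS[a])
        stop(sprintf(
          "line %d: element '%s' violates the fixed ordering O H H O H H (expected %s)",
          ln, tok[1], .kELEMENTS[a]))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        stop(sprintf("line %d: non-numeric coordinate", ln))
      coords[a, ] <- xyz
    }
    out[[length(out) + 1L]] <- dimer_geometry(coords)
    i <- i + 2L + n
  }
  out
}

#' Write dimer geometries to a multi-frame XYZ file
#'
#' Coordinates are written with 15 significant digits so that a
#' write-then-read round trip reproduces coordinates to better than
#' 1e-12 Angstrom.
#'
#' @param geometries a \code{dimer_geometry} or a list of them.
#' @param path output file path.
#' @param comment comment line(s); recycled over frames.
#' @return invisibly, the path.
#' @export
write_xyz <- function(geometries, path, comment = "") {
  if (inherits(geometries, "dimer_geometry")) geometries <- list(geometries)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(geometries) == 0L) return(invisible(path))
  comment <- rep_len(comment, length(geometries))
  for (k in seq_along(geometries)) {
    m <- .as_coord_matrix(geometries[[k]])
    writeLines(c("6", comment[k]), con)
    writeLines(sprintf("%s %.15g %.15g %.15g",
                       .kELEMENTS, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Minimum RMSD under optimal rigid superposition (Kabsch)
#'
#' Superimposes \code{candidate} onto \code{reference} with the optimal
#' proper rotation and translation (Kabsch algorithm, reflections excluded)
#' and returns the residual unweighted root-mean-square deviation.
#'
#' @param reference,candidate \code{dimer_geometry} objects, or plain n x 3
#'   coordinate matrices with matching row counts.
#' @return RMSD in Angstrom (non-negative, symmetric in its arguments).
#' @examples
#' g <- dimer_geometry(rbind(
#'   c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
#'   c(3, 0, 0), c(3.96, 0, 0), c(2.76, 0.93, 0)))
#' kabsch_rmsd(g, g)  # 0
#' @export
kabsch_rmsd <- function(reference, candidate) {
  elem_of <- function(x) {
    if (inherits(x, "dimer_geometry")) .kELEMENTS else rownames(x)
  }
  er <- elem_of(reference); ec <- elem_of(candidate)
  if (!is.null(er) && !is.null(ec) && !identical(er, ec))
    stop("mismatched element sequences")
  P <- .as_coord_matrix(reference)
  Q <- .as_coord_matrix(candidate)
  if (!identical(dim(P), dim(Q)))
    stop("mismatched atom counts")
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Q, P)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)    # proper rotation only
  Qr <- Q %*% t(R)
  sqrt(sum((P - Qr)^2) / nrow(P))
}

## random proper rotation matrix from a uniform quaternion
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  .quat_to_rot(q)
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Apply a rigid motion to a geometry
#'
#' @param g a \code{dimer_geometry}.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation vector, Angstrom.
#' @return the transformed \code{dimer_geometry}.
#' @export
transform_geometry <- function(g, rotation = diag(3), translation = c(0, 0, 0)) {
  m <- .as_coord_matrix(g)
  dimer_geometry(sweep(m %*% t(rotation), 2, -translation))
}
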