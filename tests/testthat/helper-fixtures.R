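## Shared fixtures, memoized per test session. Everything is generated in
## code at run time; seeds are fixed so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## a well-behaved hydrogen-bonded reference geometry
equilibrium_dimer <- function() hbonded_dimer()

random_geometries <- function(n, seed = 99) {
  generate_dataset(generator_config(n_geometries = n, seed = seed))$geometries
}

## a larger unlabeled sample for distributional checks
fixture_big_dataset <- function() memo("big_dataset", function() {
  generate_dataset(generator_config(n_geometries = 20000, seed = 6))
})

## small labeled dataset + trained potential shared by engine/model tests
fixture_labeled <- function() memo("labeled", function() {
  d <- generate_dataset(generator_config(n_geometries = 200, seed = 101))
  label_dataset(d, forces = TRUE)
})

fixture_split <- function() memo("split", function() {
  split_dataset(fixture_labeled(), 150, 50, seed = 7)
})

fixture_potential <- function() memo("potential", function() {
  fit_dimer_gpr(fixture_split()$train,
                train_config(restarts = 2, maxit = 60, seed = 7))
})

## independent differentiation oracle: 5-point central stencil, accurate to
## O(h^4) truncation, used wherever analytic derivatives are validated
fd_gradient_18 <- function(f, x, h = 2e-3) {
  g <- numeric(18)
  for (i in 1:18) {
    pp <- function(k) { z <- x; z[i] <- z[i] + k * h; f(z) }
    g[i] <- (-pp(2) + 8 * pp(1) - 8 * pp(-1) + pp(-2)) / (12 * h)
  }
  g
}

fd_forces <- function(potential, g, h = 2e-3) {
  x0 <- as.vector(t(unclass(g)))
  en <- function(x) total_energy(potential, dimer_geometry(matrix(x, 6, 3, byrow = TRUE)))
  matrix(-fd_gradient_18(en, x0, h), 6, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
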