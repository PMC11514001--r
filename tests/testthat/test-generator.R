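test_that("monomer sampling covers the configured ranges uniformly", {
  cfg <- generator_config(n_geometries = 1, bond_range = c(0.85, 1.10),
                          angle_range = c(95, 115), seed = 1)
  set.seed(10)
  n <- 10000
  bonds <- matrix(NA_real_, n, 2)
  angles <- numeric(n)
  for (i in seq_len(n)) {
    m <- sample_monomer(cfg)
    bonds[i, ] <- c(sqrt(sum((m[2, ] - m[1, ])^2)),
                    sqrt(sum((m[3, ] - m[1, ])^2)))
    u <- m[2, ] - m[1, ]; v <- m[3, ] - m[1, ]
    angles[i] <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  expect_gte(min(bonds), 0.85)
  expect_lte(max(bonds), 1.10)
  expect_gte(min(angles), 95 - 1e-9)
  expect_lte(max(angles), 115 + 1e-9)
  ## mean of a uniform is the midpoint; allow 3 standard errors
  se <- (115 - 95) / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(angles) - 105), 3 * se)
})

test_that("degenerate distortion ranges give a rigid monomer", {
  cfg <- generator_config(n_geometries = 1, bond_range = c(0.9572, 0.9572),
                          angle_range = c(104.52, 104.52), seed = 1)
  set.seed(2)
  m <- sample_monomer(cfg)
  expect_equal(sqrt(sum((m[2, ] - m[1, ])^2)), 0.9572)
  expect_equal(sqrt(sum((m[3, ] - m[1, ])^2)), 0.9572)
})

test_that("sampled separations have uniform support on the configured range", {
  cfg <- generator_config(n_geometries = 1, seed = 1)
  set.seed(5)
  seps <- replicate(2000, min_separation(sample_dimer(cfg), "OO"))
  expect_gte(min(seps), 2.0)
  expect_lte(max(seps), 5.5)
})

test_that("dataset generation is bitwise reproducible from config + seed", {
  cfg <- generator_config(n_geometries = 50, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(
    lapply(d1$geometries, unclass), lapply(d2$geometries, unclass))
})

test_that("generated datasets satisfy the contact filter and filtering is idempotent", {
  cfg <- generator_config(n_geometries = 300, seed = 9)
  d <- generate_dataset(cfg)
  contacts <- vapply(d$geometries, min_separation, numeric(1), mode = "any")
  expect_gte(min(contacts), cfg$min_contact)
  verdicts <- vapply(d$geometries,
                     function(g) filter_geometry(g, cfg)$accept, logical(1))
  expect_true(all(verdicts))
  ## brute-force recheck of both filter clauses
  for (g in d$geometries[1:50]) {
    m <- unclass(g)
    inter <- as.vector(outer(1:3, 4:6, Vectorize(
      function(i, j) sqrt(sum((m[i, ] - m[j, ])^2)))))
    expect_gte(min(inter), cfg$min_contact)
    bonds <- c(sqrt(sum((m[2, ] - m[1, ])^2)), sqrt(sum((m[3, ] - m[1, ])^2)),
               sqrt(sum((m[5, ] - m[4, ])^2)), sqrt(sum((m[6, ] - m[4, ])^2)))
    expect_true(all(bonds >= 0.85 * 0.9 & bonds <= 1.10 * 1.1))
  }
})

test_that("close contacts are rejected with a reason", {
  cfg <- generator_config(n_geometries = 1, seed = 1)
  ## H...H intermolecular contact at 0.8 Angstrom
  m <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
             c(2.5, 1.3, 0), c(1.76, 0.7, 0.45), c(3.2, 2.0, 0))
  g <- dimer_geometry(m)
  expect_lt(min_separation(g, "any"), 1.4)
  verdict <- filter_geometry(g, cfg)
  expect_false(verdict$accept)
  expect_identical(verdict$reason, "close contact")
  ok <- hbonded_dimer(3.0)
  expect_true(filter_geometry(ok, cfg)$accept)
})

test_that("train/test split is disjoint, exhaustive at full size, and seeded", {
  d <- generate_dataset(generator_config(n_geometries = 3, seed = 3))
  sp <- split_dataset(d, 2, 1, seed = 5)
  key <- function(g) paste(signif(unclass(g), 12), collapse = ",")
  tr <- vapply(sp$train$geometries, key, character(1))
  te <- vapply(sp$test$geometries, key, character(1))
  expect_length(tr, 2)
  expect_length(te, 1)
  expect_length(intersect(tr, te), 0)
  expect_setequal(c(tr, te), vapply(d$geometries, key, character(1)))
  sp2 <- split_dataset(d, 2, 1, seed = 5)
  expect_identical(lapply(sp$train$geometries, unclass),
                   lapply(sp2$train$geometries, unclass))
  expect_error(split_dataset(d, 3, 1, seed = 1), "insufficient")
})

test_that("separation distribution is flat after filtering", {
  d <- fixture_big_dataset()
  seps <- vapply(d$geometries, min_separation, numeric(1), mode = "OO")
  counts <- hist(seps, breaks = seq(2.0, 5.5, length.out = 21),
                 plot = FALSE, include.lowest = TRUE)$counts
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  h <- distance_distribution(d, "OO", bins = 35)
  expect_identical(sum(h$counts), length(d$geometries))
  expect_lt(max(h$counts) / min(h$counts), 1.5)
})

test_that("either molecule acts as hydrogen-bond donor equally often", {
  d <- fixture_big_dataset()
  donor_is_A <- vapply(d$geometries, function(g) {
    m <- unclass(g)
    pd <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
    ## shortest intermolecular O...H: does it involve one of A's hydrogens?
    min(pd(4, 2), pd(4, 3)) < min(pd(1, 5), pd(1, 6))
  }, logical(1))
  se <- sqrt(0.25 / length(donor_is_A))
  expect_lt(abs(mean(donor_is_A) - 0.5), 3 * se)
})

test_that("swapping molecule labels leaves the separation distribution unchanged", {
  d <- generate_dataset(generator_config(n_geometries = 500, seed = 13))
  seps <- vapply(d$geometries, min_separation, numeric(1), mode = "OO")
  swapped <- vapply(d$geometries, function(g) {
    m <- unclass(g)
    min_separation(dimer_geometry(m[c(4, 5, 6, 1, 2, 3), ]), "OO")
  }, numeric(1))
  expect_equal(seps, swapped)
})

test_that("distance_distribution handles a single geometry", {
  d <- generate_dataset(generator_config(n_geometries = 1, seed = 2))
  h <- distance_distribution(d, "OO", bins = 5)
  expect_identical(sum(h$counts), 1L)
  expect_identical(sum(h$counts > 0), 1L)
})
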