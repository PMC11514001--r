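#' Fit a per-atom Gaussian process dimer potential
#'
#' The central fitting function of the package. For each of the six atoms
#' of the water dimer it computes ALF features of every training geometry
#' and trains an exact GPR model on that atom's energies; the six models
#' together form the dimer potential, whose total energy is the sum of the
#' six atomic predictions and whose Cartesian forces follow from the
#' models' feature-space gradients chained through the analytic feature
#' Jacobians.
#'
#' @param data a \code{labeled_dataset} (see [label_dataset()]).
#' @param config a [train_config()].
#' @param verbose print a line per trained atom.
#' @return an object of class \code{dimer_gpr} with components
#'   \code{models} (six \code{atomic_gpr_model}s), \code{config},
#'   \code{train} (training features and labels, kept for residuals),
#'   and \code{feature_version}.
#' @seealso [predict.dimer_gpr()], [optimize_geometry()], [run_nvt()],
#'   [scan_coordinate()]
#' @examples
#' \donttest{
#' d <- generate_dataset(generator_config(n_geometries = 40, seed = 3))
#' lab <- label_dataset(d)
#' pot <- fit_dimer_gpr(lab, train_config(restarts = 1, maxit = 20))
#' predict(pot, d$geometries[[1]])
#' }
#' @export
fit_dimer_gpr <- function(data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$geometries)
  feats <- lapply(1:6, function(a)
    t(vapply(data$geometries, function(g) compute_features(g, a), numeric(12))))
  models <- vector("list", 6)
  for (a in 1:6) {
    models[[a]] <- train_atomic_model(feats[[a]], data$atomic_energies[, a],
                                      config = config, atom = a)
    if (verbose)
      cat(sprintf("trained %s: LML %.2f, prior mean %.3f kJ/mol\n",
                  .kATOM_LABELS[a], models[[a]]$lml,
                  models[[a]]$hp$prior_mean))
  }
  structure(list(models = models, config = config,
                 train = list(features = feats,
                              atomic_energies = data$atomic_energies,
                              total_energy = data$total_energy),
                 feature_version = "alf12-v1"),
            class = "dimer_gpr")
}

#' @export
print.dimer_gpr <- function(x, ...) {
  cat(sprintf("Per-atom GPR dimer potential (%d training geometries)\n",
              x$models[[1]]$n_train))
  cat(sprintf("prior means (kJ/mol): %s\n",
              paste(sprintf("%s %.2f", .kATOM_LABELS,
                            vapply(x$models, function(m) m$hp$prior_mean,
                                   numeric(1))),
                    collapse = ", ")))
  cat(sprintf("sum of prior means: %.3f kJ/mol (far-field total energy)\n",
              prior_mean_total(x)))
  invisible(x)
}

#' Sum of the six atomic prior means
#'
#' Far from all training data every atomic prediction reverts to its prior
#' mean, so this sum is the model's far-field total energy.
#'
#' @param potential a \code{dimer_gpr}.
#' @return kJ/mol.
#' @export
prior_mean_total <- function(potential) {
  sum(vapply(potential$models, function(m) m$hp$prior_mean, numeric(1)))
}

#' Predict energies or forces from a fitted dimer potential
#'
#' @param object a \code{dimer_gpr}.
#' @param newdata a \code{dimer_geometry}, a list of them, or a
#'   \code{dimer_dataset} / \code{labeled_dataset}.
#' @param type \code{"total"} (total energy, kJ/mol), \code{"atomic"}
#'   (n x 6 matrix of atomic energies), or \code{"forces"} (a 6 x 3
#'   matrix per geometry, kJ/mol/Angstrom).
#' @param ... unused.
#' @return see \code{type}; for a single geometry, \code{"forces"} returns
#'   one matrix, otherwise a list of matrices.
#' @export
predict.dimer_gpr <- function(object, newdata,
                              type = c("total", "atomic", "forces"), ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "dimer_geometry")
  geoms <- if (single) list(newdata)
           else if (!is.null(newdata$geometries)) newdata$geometries
           else newdata
  if (type == "forces") {
    out <- lapply(geoms, function(g) forces(object, g))
    return(if (single) out[[1]] else out)
  }
  ae <- matrix(NA_real_, length(geoms), 6,
               dimnames = list(NULL, .kATOM_LABELS))
  for (a in 1:6) {
    Fa <- t(vapply(geoms, function(g) compute_features(g, a), numeric(12)))
    ae[, a] <- predict_energy(object$models[[a]], Fa)
  }
  if (type == "atomic") ae else rowSums(ae)
}

#' Total predicted energy of one geometry
#'
#' Exactly the sum of the six atomic model predictions. An
#' \code{oracle_spec} may be passed instead of a fitted potential, in
#' which case the surrogate energy is returned (useful for running the
#' engine directly on the oracle).
#'
#' @param potential a \code{dimer_gpr} or an \code{oracle_spec}.
#' @param g a \code{dimer_geometry}.
#' @return kJ/mol.
#' @export
total_energy <- function(potential, g) {
  if (inherits(potential, "oracle_spec"))
    return(oracle_total_energy(g, potential))
  sum(vapply(1:6, function(a)
    predict_energy(potential$models[[a]], compute_features(g, a)),
    numeric(1)))
}

#' Predicted Cartesian forces of one geometry
#'
#' Chain rule through every atom's analytic feature Jacobian:
#' \code{F = -sum_a t(J_a) \%*\% d mu_a / d features}. Every atomic model
#' depends on all 18 coordinates, so each contributes to every atom's
#' force. An \code{oracle_spec} may be passed instead, returning the
#' surrogate's analytic forces.
#'
#' @param potential a \code{dimer_gpr} or an \code{oracle_spec}.
#' @param g a \code{dimer_geometry}.
#' @return 6 x 3 matrix of forces, kJ/mol/Angstrom.
#' @export
forces <- function(potential, g) {
  if (inherits(potential, "oracle_spec"))
    return(oracle_forces(g, potential))
  grad <- numeric(18)
  for (a in 1:6) {
    f <- compute_features(g, a)
    gfeat <- predict_gradient(potential$models[[a]], f)
    J <- feature_jacobian(g, a)
    grad <- grad + as.numeric(crossprod(J, gfeat))
  }
  matrix(-grad, 6, 3, byrow = TRUE,
         dimnames = list(.kATOM_LABELS, c("x", "y", "z")))
}

#' @export
coef.dimer_gpr <- function(object, ...) {
  out <- t(vapply(object$models, function(m)
    c(m$hp$l, sf2 = m$hp$sf2, sn2 = m$hp$sn2, prior_mean = m$hp$prior_mean),
    numeric(15)))
  rownames(out) <- .kATOM_LABELS
  colnames(out)[1:12] <- paste0("l", 1:12)
  out
}

#' @export
residuals.dimer_gpr <- function(object, ...) {
  n <- nrow(object$train$atomic_energies)
  res <- matrix(NA_real_, n, 6, dimnames = list(NULL, .kATOM_LABELS))
  for (a in 1:6) {
    pred <- predict_energy(object$models[[a]], object$train$features[[a]])
    res[, a] <- object$train$atomic_energies[, a] - pred
  }
  res
}

#' @export
summary.dimer_gpr <- function(object, ...) {
  res <- residuals(object)
  tab <- data.frame(
    atom = .kATOM_LABELS,
    n = vapply(object$models, function(m) m$n_train, integer(1)),
    prior_mean = vapply(object$models, function(m) m$hp$prior_mean, numeric(1)),
    signal_sd = sqrt(vapply(object$models, function(m) m$hp$sf2, numeric(1))),
    noise_sd = sqrt(vapply(object$models, function(m) m$hp$sn2, numeric(1))),
    train_mae = colMeans(abs(res)),
    lml = vapply(object$models, function(m) m$lml, numeric(1)))
  structure(list(table = tab, prior_mean_total = prior_mean_total(object)),
            class = "summary.dimer_gpr")
}

#' @export
print.summary.dimer_gpr <- function(x, ...) {
  cat("Per-atom GPR dimer potential\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("sum of prior means: %.3f kJ/mol\n", x$prior_mean_total))
  invisible(x)
}

#' S-curve plot of prediction errors
#'
#' Plots the cumulative error distribution (absolute error vs percentile
#' of geometries at or below that error) of the potential on a labeled
#' test set, the standard accuracy display for ML potentials.
#'
#' @param x a \code{dimer_gpr}.
#' @param newdata a \code{labeled_dataset} to evaluate; defaults to the
#'   training set (optimistic).
#' @param log logarithmic x axis (default TRUE).
#' @param ... passed to \code{plot}.
#' @return invisibly, the [s_curve()] of total-energy errors.
#' @export
plot.dimer_gpr <- function(x, newdata = NULL, log = TRUE, ...) {
  if (is.null(newdata)) {
    err <- abs(rowSums(residuals(x)))
  } else {
    pred <- predict(x, newdata)
    err <- abs(pred - newdata$total_energy)
  }
  sc <- s_curve(err)
  plot(pmax(sc$errors, 1e-12), sc$percentiles,
       type = "s", log = if (log) "x" else "",
       xlab = "|total energy error| (kJ/mol)",
       ylab = "percentile of geometries (%)", ...)
  abline(v = .kCHEM_ACC, lty = 2)
  invisible(sc)
}

#' Simulate short NVT dynamics from a fitted potential
#'
#' Convenience wrapper around [run_nvt()]: \code{nsim} is the number of
#' 1 fs steps at 298 K from a hydrogen-bonded start.
#'
#' @param object a \code{dimer_gpr}.
#' @param nsim number of steps.
#' @param seed integer seed for the initial velocities.
#' @param start starting \code{dimer_geometry}; default a hydrogen-bonded
#'   equilibrium-like dimer.
#' @param temperature target temperature, K.
#' @param ... passed to [run_nvt()].
#' @return a \code{dimer_trajectory}.
#' @export
simulate.dimer_gpr <- function(object, nsim = 1000, seed = 1L,
                               start = NULL, temperature = 298, ...) {
  if (is.null(start)) start <- hbonded_dimer()
  run_nvt(object, start, temperature = temperature, dt = 1,
          n_steps = nsim, seed = seed, ...)
}
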