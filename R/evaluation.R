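#' S-curve of absolute prediction errors
#'
#' Sorts the absolute errors ascending and attaches cumulative
#' percentiles: the i-th sorted error gets percentile 100*i/n. Tied
#' errors share the highest applicable percentile, matching the reading
#' "percentile of samples displaying this error or less".
#'
#' @param errors non-negative absolute errors.
#' @return an object of class \code{s_curve}: list with \code{errors}
#'   (sorted ascending) and \code{percentiles} (strictly positive,
#'   reaching exactly 100).
#' @export
s_curve <- function(errors) {
  if (length(errors) == 0) stop("empty error vector")
  if (any(errors < 0)) stop("errors must be non-negative")
  e <- sort(errors)
  structure(list(errors = e,
                 percentiles = 100 * seq_along(e) / length(e)),
            class = "s_curve")
}

#' @export
print.s_curve <- function(x, ...) {
  cat(sprintf("S-curve over %d errors: median %.4g, 90th pct %.4g, max %.4g\n",
              length(x$errors),
              quantile(x$errors, 0.5, names = FALSE),
              quantile(x$errors, 0.9, names = FALSE),
              max(x$errors)))
  invisible(x)
}

#' Mean absolute error
#'
#' @param predictions,references numeric vectors of equal length.
#' @return mean of \code{|predictions - references|}.
#' @export
mae <- function(predictions, references) {
  if (length(predictions) != length(references))
    stop("length mismatch")
  stopifnot(length(predictions) >= 1)
  mean(abs(predictions - references))
}

#' Percentage of errors within a threshold
#'
#' Consistent with the S-curve ordinate at the same abscissa.
#'
#' @param errors absolute errors.
#' @param threshold non-negative threshold (default: chemical accuracy,
#'   4.184 kJ/mol).
#' @return percentage in [0, 100].
#' @export
fraction_within <- function(errors, threshold = chemical_accuracy()) {
  stopifnot(threshold >= 0)
  100 * mean(errors <= threshold)
}

#' Per-atom, per-component force MAE table
#'
#' @param predicted,reference lists of 6 x 3 force matrices (one per
#'   frame), matching lengths.
#' @return 6 x 3 matrix of MAEs (rows O1..H6, columns x, y, z),
#'   kJ/mol/Angstrom, averaged over frames.
#' @export
force_component_report <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("frame count mismatch")
  stopifnot(length(predicted) >= 1)
  acc <- matrix(0, 6, 3)
  for (i in seq_along(predicted)) {
    p <- as.matrix(predicted[[i]]); r <- as.matrix(reference[[i]])
    if (!identical(dim(p), c(6L, 3L)) || !identical(dim(r), c(6L, 3L)))
      stop("force matrices must be 6 x 3")
    acc <- acc + abs(p - r)
  }
  out <- acc / length(predicted)
  dimnames(out) <- list(.kATOM_LABELS, c("x", "y", "z"))
  out
}

#' Accuracy report of a fitted potential on a labeled test set
#'
#' @param potential a \code{dimer_gpr}.
#' @param test a \code{labeled_dataset}.
#' @param forces also compare forces against the dataset's stored
#'   reference forces (requires \code{test$forces}).
#' @return an object of class \code{dimer_eval}: per-atom MAEs,
#'   total-energy MAE, fractions within 1 kJ/mol and within chemical
#'   accuracy, max error, the total-energy \code{s_curve}, and (when
#'   requested) the [force_component_report()].
#' @export
evaluate_potential <- function(potential, test, forces = FALSE) {
  ae_pred <- predict(potential, test, type = "atomic")
  per_atom_mae <- vapply(1:6, function(a)
    mae(ae_pred[, a], test$atomic_energies[, a]), numeric(1))
  names(per_atom_mae) <- .kATOM_LABELS
  tot_pred <- rowSums(ae_pred)
  err <- abs(tot_pred - test$total_energy)
  fr <- NULL
  if (forces) {
    if (is.null(test$forces))
      stop("test set has no stored reference forces")
    fp <- predict(potential, test, type = "forces")
    fr <- force_component_report(fp, test$forces)
  }
  structure(list(per_atom_mae = per_atom_mae,
                 total_mae = mean(err),
                 within_1kj = fraction_within(err, 1),
                 within_chemacc = fraction_within(err, chemical_accuracy()),
                 max_error = max(err),
                 s_curve = s_curve(err),
                 force_mae = fr,
                 n = length(err)),
            class = "dimer_eval")
}

#' @export
print.dimer_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d geometries\n", x$n))
  cat("per-atom MAE (kJ/mol):",
      paste(sprintf("%s %.3f", names(x$per_atom_mae), x$per_atom_mae),
            collapse = ", "), "\n")
  cat(sprintf("total-energy MAE: %.3f kJ/mol; max error %.3f kJ/mol\n",
              x$total_mae, x$max_error))
  cat(sprintf("within 1 kJ/mol: %.1f%%; within chemical accuracy (4.184 kJ/mol): %.1f%%\n",
              x$within_1kj, x$within_chemacc))
  if (!is.null(x$force_mae)) {
    cat("force-component MAE (kJ/mol/A):\n")
    print(round(x$force_mae, 4))
  }
  invisible(x)
}
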