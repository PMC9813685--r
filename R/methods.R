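#' @export
print.charge_flip <- function(x, ...) {
  cat("Charge-flipping phase retrieval\n")
  cat(sprintf("  %d independent reflections, %d iterations%s\n",
              n_reflections(x$refl), x$control$iterations,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cons <- c(if (x$control$real_f) "real F",
            if (!is.null(x$control$v_p)) sprintf("v_p = %g", x$control$v_p),
            if (!is.null(x$control$symmetry)) "symmetry-projected init")
  if (length(cons)) cat("  constraints:", paste(cons, collapse = ", "), "\n")
  cat(sprintf("  best I_rho %.6g at iteration %d\n", x$i_rho, x$iteration))
  invisible(x)
}

#' Summarise a retrieval fit
#'
#' Computes the plausibility indicators of the best map — `I_rho`, `I_K`
#' and the convex-volume fraction `|C|/N` — and, when a phased reference is
#' supplied, the `R_p` agreement score.
#'
#' @param object a `"charge_flip"` object.
#' @param reference optional phased [reflection_set()] with the true phases.
#' @param ... unused.
#' @return an object of class `"summary.charge_flip"`.
#' @export
summary.charge_flip <- function(object, reference = NULL, ...) {
  mask <- convex_region(object$density)
  out <- list(fit = object,
              i_rho = object$i_rho,
              i_k = i_k(object$density),
              convex_fraction = mean(mask),
              r_p = NULL)
  if (!is.null(reference)) out$r_p <- r_p(fitted_phases(object), reference)
  structure(out, class = "summary.charge_flip")
}

#' @export
print.summary.charge_flip <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  indicators: I_rho %.6g, I_K %.4g, |C|/N %.4g\n",
              x$i_rho, x$i_k, x$convex_fraction))
  if (!is.null(x$r_p))
    cat(sprintf("  R_p %.4g (%s, shift %s) -> %s\n",
                x$r_p$r_p, if (x$r_p$babinet) "Babinet twin" else "direct",
                paste(signif(x$r_p$shift, 4), collapse = " "),
                if (x$r_p$r_p < 0.1) "success (R_p < 0.1)" else "no match"))
  invisible(x)
}

#' @export
coef.charge_flip <- function(object, ...) {
  stats::setNames(object$phases,
                  apply(object$refl$hkl, 1, paste, collapse = ","))
}

#' @export
fitted.charge_flip <- function(object, ...) object$density

#' Plot a retrieval trace
#'
#' Top panel: the density-range indicator `I_rho` per iteration (log scale),
#' with the adopted minimum marked.  Bottom panel: the periodic `k_f` and
#' `k_t` schedules.
#'
#' @param x a `"charge_flip"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.charge_flip <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iteration, tr$i_rho, type = "l", log = "y",
                 xlab = "", ylab = expression(I[rho]), ...)
  graphics::points(x$iteration, x$i_rho, pch = 19, col = "red")
  graphics::plot(tr$iteration, tr$k_t, type = "l",
                 ylim = range(tr$k_f, tr$k_t),
                 xlab = "iteration", ylab = "parameter")
  graphics::lines(tr$iteration, tr$k_f, lty = 2, col = "darkorange")
  graphics::legend("topright", c(expression(k[t]), expression(k[f])),
                   lty = 1:2, col = c("black", "darkorange"), bty = "n")
  invisible(x)
}

#' @export
print.charge_flip_set <- function(x, ...) {
  ir <- vapply(x$results, `[[`, 0, "i_rho")
  cat(sprintf("Charge-flipping: %d independent runs\n", length(x$results)))
  cat(sprintf("  best I_rho %.6g (seed %d); spread %.6g-%.6g\n",
              ir[1], x$results[[1]]$seed, min(ir), max(ir)))
  invisible(x)
}

#' Summarise independent retrieval runs
#'
#' Per-run indicators and, with a reference, per-run `R_p` plus the count
#' of successes (`R_p < 0.1`) — the customary benchmark summary (successes
#' out of the number of runs, minimum `R_p`).
#'
#' @param object a `"charge_flip_set"`.
#' @param reference optional phased [reflection_set()].
#' @param threshold success threshold on `R_p`.
#' @param ... unused.
#' @return an object of class `"summary.charge_flip_set"` with a `table`
#'   data frame (seed, i_rho, i_k, r_p) and `n_success`/`min_r_p` when a
#'   reference is given.
#' @export
summary.charge_flip_set <- function(object, reference = NULL,
                                    threshold = 0.1, ...) {
  tab <- data.frame(
    seed = vapply(object$results, `[[`, 0L, "seed"),
    i_rho = vapply(object$results, `[[`, 0, "i_rho"))
  tab$i_k <- vapply(object$results, function(f) i_k(f$density), 0)
  n_success <- min_r_p <- NULL
  if (!is.null(reference)) {
    tab$r_p <- vapply(object$results,
                      function(f) r_p(fitted_phases(f), reference)$r_p, 0)
    n_success <- sum(tab$r_p < threshold)
    min_r_p <- min(tab$r_p)
  }
  structure(list(table = tab, n_success = n_success, min_r_p = min_r_p,
                 threshold = threshold, runs = nrow(tab)),
            class = "summary.charge_flip_set")
}

#' @export
print.summary.charge_flip_set <- function(x, ...) {
  cat(sprintf("%d independent runs\n", x$runs))
  if (!is.null(x$n_success))
    cat(sprintf("  R_p < %g: %d of %d; min R_p %.4g\n",
                x$threshold, x$n_success, x$runs, x$min_r_p))
  print(utils::head(x$table[order(x$table$i_rho), ], 10), row.names = FALSE)
  invisible(x)
}
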