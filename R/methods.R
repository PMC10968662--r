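# S3 methods for the fitted model object.

#' @export
print.driver_gcn <- function(x, ...) {
  cat("GCN-CRF driver-gene model\n")
  cat(sprintf("  features: %d  hidden: %d  CRF: alpha=%g beta=%g T=%d\n",
              x$n_features, x$config$hidden_dim, x$config$crf_alpha,
              x$config$crf_beta, x$config$crf_iterations))
  cat(sprintf("  trained %d epochs (lr %g, weight decay %g, dropout %g, positive weight %g)\n",
              x$config$epochs, x$config$learning_rate, x$config$weight_decay,
              x$config$dropout, x$config$positive_weight))
  tr <- x$loss_trace
  cat(sprintf("  loss: %.4f -> %.4f (l_crf %.4f, l_theta %.4f at last epoch)\n",
              tr$l_total[1L], tr$l_total[nrow(tr)],
              tr$l_crf[nrow(tr)], tr$l_theta[nrow(tr)]))
  invisible(x)
}

#' @export
summary.driver_gcn <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  out <- list(
    n_features = object$n_features,
    hidden_dim = object$config$hidden_dim,
    n_parameters = n_par,
    epochs = object$config$epochs,
    seed = object$seed,
    initial_loss = object$loss_trace$l_total[1L],
    final_loss = object$loss_trace$l_total[nrow(object$loss_trace)],
    final_l_crf = object$loss_trace$l_crf[nrow(object$loss_trace)],
    final_l_theta = object$loss_trace$l_theta[nrow(object$loss_trace)],
    cv = object$cv
  )
  class(out) <- "summary.driver_gcn"
  out
}

#' @export
print.summary.driver_gcn <- function(x, ...) {
  cat("GCN-CRF driver-gene model summary\n")
  cat(sprintf("  %d input features -> %d hidden units -> 1 output (%d parameters)\n",
              x$n_features, x$hidden_dim, x$n_parameters))
  cat(sprintf("  trained %d epochs (seed %d): l_total %.4f -> %.4f\n",
              x$epochs, x$seed, x$initial_loss, x$final_loss))
  cat(sprintf("  final components: l_crf %.4f, l_theta %.4f\n",
              x$final_l_crf, x$final_l_theta))
  if (!is.null(x$cv)) {
    cat("  grid search (mean CV AUPR):\n")
    print(x$cv, row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted parameter tensors
#' @param object a `driver_gcn`.
#' @param ... unused.
#' @return named list: `W1`, `W2` (GCN layer weights), `Wt`, `a`
#'   (attention transform and scoring vector).
#' @export
coef.driver_gcn <- function(object, ...) object$params

#' Plot the training loss trace
#'
#' Draws l_total, l_CRF and l_theta per epoch on a log10 y axis.
#'
#' @param x a `driver_gcn`.
#' @param ... forwarded to [graphics::matplot()].
#' @export
plot.driver_gcn <- function(x, ...) {
  tr <- x$loss_trace
  graphics::matplot(seq_len(nrow(tr)), tr, type = "l", lty = 1,
                    col = c("black", "steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", log = "y", ...)
  graphics::legend("topright", legend = c("l_total", "l_crf", "l_theta"),
                   col = c("black", "steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
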