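#' Exact Shapley feature attribution for a fitted regressor
#'
#' Computes exact Shapley values by full coalition enumeration. The value of
#' a coalition S for a sample x is the mean model prediction over the
#' background rows with the features in S taken from x and the rest from the
#' background row. The attribution of feature j averages its marginal
#' contribution over all coalitions with the standard Shapley weights
#' `|S|! (p - |S| - 1)! / p!`. Efficiency holds exactly: per sample the
#' attributions sum to `f(x) - baseline`, where the baseline is the mean
#' prediction over the background set.
#'
#' Enumeration is exponential in the number of features; it is limited to
#' `p <= 15` (32768 coalitions). For wider matrices a sampling approximation
#' would be needed, which this package deliberately does not provide.
#'
#' @param predict_fun Function mapping a numeric feature matrix to a numeric
#'   prediction vector (wrap a fitted model, e.g.
#'   `function(X) predict(fit, X)`).
#' @param X_explain Matrix of rows to explain.
#' @param X_background Matrix of background rows (same columns).
#' @return A `shapley_report`: `phi` (samples x features matrix of
#'   attributions, in the model's response units), `baseline`, and
#'   `global_importance` (mean absolute attribution per feature, sorted
#'   decreasingly).
#' @export
shapley_importance <- function(predict_fun, X_explain, X_background) {
  X_explain <- as.matrix(X_explain)
  X_background <- as.matrix(X_background)
  p <- ncol(X_explain)
  if (ncol(X_background) != p) stop_bad_arg("background column count differs")
  if (p > 15L) {
    stop_bad_arg("exact enumeration limited to p <= 15 features; ",
                 "use a sampling approximation for wider matrices (not provided)")
  }
  n <- nrow(X_explain); b <- nrow(X_background)
  n_coal <- 2^p
  # coalition membership matrix: n_coal x p, row i = binary expansion of i-1
  member <- matrix(FALSE, n_coal, p)
  for (j in seq_len(p)) {
    member[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  sizes <- rowSums(member)
  # Shapley weight for a coalition S not containing j: |S|!(p-|S|-1)!/p!
  lfac <- lgamma(seq_len(p + 1))  # lfac[k+1] = log(k!)
  # w_of_size[s+1] is the weight for |S| = s, s = 0..p-1
  w_of_size <- exp(lfac[1:p] + lfac[p:1] - lfac[p + 1])

  phi <- matrix(0, n, p, dimnames = list(rownames(X_explain), colnames(X_explain)))
  v_full <- numeric(n)
  baseline <- mean(predict_fun(X_background))

  for (i in seq_len(n)) {
    x <- X_explain[i, ]
    # hybrid matrix: for every coalition, b rows of background with S replaced
    hyb <- X_background[rep(seq_len(b), times = n_coal), , drop = FALSE]
    coal_of_row <- rep(seq_len(n_coal), each = b)
    for (j in seq_len(p)) {
      sel <- member[coal_of_row, j]
      hyb[sel, j] <- x[j]
    }
    preds <- predict_fun(hyb)
    v <- rowsum(as.numeric(preds), coal_of_row) / b  # value per coalition
    v_full[i] <- v[n_coal]
    for (j in seq_len(p)) {
      without <- !member[, j]
      s_idx <- which(without)
      with_idx <- s_idx + bitwShiftL(1L, j - 1L)  # S union {j}
      wts <- w_of_size[sizes[s_idx] + 1L]
      phi[i, j] <- sum(wts * (v[with_idx] - v[s_idx]))
    }
  }
  gi <- sort(colMeans(abs(phi)), decreasing = TRUE)
  structure(list(phi = phi, baseline = baseline, prediction = v_full,
                 global_importance = gi),
            class = "shapley_report")
}

#' @export
print.shapley_report <- function(x, ...) {
  cat(sprintf("<shapley_report> %d samples, baseline %.3f\n",
              nrow(x$phi), x$baseline))
  cat("global importance (mean |phi|):\n")
  print(round(x$global_importance, 4))
  invisible(x)
}
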