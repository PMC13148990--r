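#' A small recurrent network with tanh dynamics
#'
#' Units evolve as `h_t = tanh(x_t + W h_{t-1})`. Trained on a two-timestep
#' reversal task, the recurrent weights implement a form of lateral
#' inhibition that flips the population's input tuning between the first and
#' second timestep — a candidate mechanism for fast axis reversal.
#'
#' @param n_units Number of units.
#' @param init_sd S.d. of the initial recurrent weights (kept small so the
#'   untrained network is near-memoryless).
#' @param seed Integer seed.
#' @return An `rnn_model` with fields `W` (units x units) and `n_units`.
#' @export
rnn_create <- function(n_units = 100, init_sd = 0.1 / sqrt(n_units), seed = 1) {
  W <- with_seed(seed, matrix(rnorm(n_units^2, sd = init_sd), n_units))
  structure(list(W = W, n_units = n_units), class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("<rnn_model> %d units, |W|_F = %.3f\n", x$n_units,
              sqrt(sum(x$W^2))))
  invisible(x)
}

#' @rdname rnn_create
#' @param model An `rnn_model`.
#' @param h_prev Previous activation vector.
#' @param x Input vector.
#' @export
rnn_step <- function(model, h_prev, x) {
  if (length(h_prev) != model$n_units || length(x) != model$n_units) {
    abort("dimension mismatch")
  }
  tanh(x + as.vector(model$W %*% h_prev))
}

#' Random linear-gradient input patterns
#'
#' The training inputs are random linear gradients across the unit index:
#' `x_i = a * (i/n) + b` with `a, b` standard normal (`type = "index"`), or a
#' linearly graded magnitude along a random unit direction
#' (`type = "direction"`): `x = a * (i/n) * u + b * u` for a random unit
#' vector `u`.
#'
#' @param n Number of units.
#' @param type Gradient interpretation.
#' @param scale S.d. of the random slope and offset. The default keeps most
#'   inputs inside the tanh output range, so the reversed gradient is a
#'   representable target.
#' @return Input vector of length `n`.
#' @export
rnn_gradient_input <- function(n, type = c("index", "direction"), scale = 0.5) {
  type <- match.arg(type)
  ramp <- seq_len(n) / n
  if (type == "index") {
    rnorm(1, sd = scale) * ramp + rnorm(1, sd = scale)
  } else {
    u <- rnorm(n); u <- u / sqrt(sum(u^2))
    (rnorm(1, sd = scale) * ramp + rnorm(1, sd = scale)) * u * sqrt(n)
  }
}

# analytic loss and gradient of the two-step task: h1 = tanh(x), h2 =
# tanh(x + W h1), L = mean((h2 - y)^2). h0 = 0, so h1 does not depend on W
# and the unrolled chain rule has a single term.
rnn_loss_grad <- function(W, x, y) {
  h1 <- tanh(x)
  pre2 <- x + as.vector(W %*% h1)
  h2 <- tanh(pre2)
  err <- h2 - y
  delta2 <- (2 / length(y)) * err * (1 - h2^2)
  list(loss = mean(err^2), grad = outer(delta2, h1), h1 = h1, h2 = h2)
}

#' Train the reversal (or identity) task with Adam
#'
#' Runs the network for two timesteps with the same random linear gradient as
#' input at both steps and minimizes the mean squared error between the
#' output at time 2 and the reversed input (`target = "reversal"`, y = -x) or
#' the input itself (`target = "identity"`, a control that should not produce
#' tuning reversal). One fresh gradient per iteration (batch size 1),
#' hand-derived backprop through the two unrolled steps, Adam updates.
#'
#' @param model An `rnn_model`.
#' @param n_iter Training iterations.
#' @param lr Adam learning rate.
#' @param target Task target.
#' @param gradient_type Input generator type (see [rnn_gradient_input()]).
#' @param seed Integer seed (controls the gradient stream).
#' @return An `rnn_fit`: the trained `model`, `loss` history (length
#'   `n_iter`), `target`, `baseline_loss` (expected loss of the untrained
#'   network over 200 held-out gradients) and `loss_reduction`
#'   (1 - final loss, smoothed over 100 iterations, / baseline loss).
#' @export
train_reversal <- function(model, n_iter = 10000, lr = 0.001,
                           target = c("reversal", "identity"),
                           gradient_type = "index", seed = 1) {
  target <- match.arg(target)
  W <- model$W
  m <- v <- matrix(0, nrow(W), ncol(W))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(n_iter)
  baseline <- NA_real_
  with_seed(seed, {
    baseline <- mean(vapply(1:200, function(i) {
      x <- rnn_gradient_input(model$n_units, gradient_type)
      rnn_loss_grad(W, x, if (target == "reversal") -x else x)$loss
    }, numeric(1)))
    for (it in seq_len(n_iter)) {
      x <- rnn_gradient_input(model$n_units, gradient_type)
      y <- if (target == "reversal") -x else x
      lg <- rnn_loss_grad(W, x, y)
      if (!is.finite(lg$loss)) {
        abort(sprintf("training diverged (loss not finite) at iteration %d, seed %d",
                      it, seed))
      }
      loss[it] <- lg$loss
      m <- b1 * m + (1 - b1) * lg$grad
      v <- b2 * v + (1 - b2) * lg$grad^2
      mhat <- m / (1 - b1^it); vhat <- v / (1 - b2^it)
      W <- W - lr * mhat / (sqrt(vhat) + eps)
    }
  })
  smooth_n <- min(100, n_iter)
  structure(
    list(model = structure(list(W = W, n_units = model$n_units),
                           class = "rnn_model"),
         loss = loss, target = target, baseline_loss = baseline,
         loss_reduction = 1 - mean(tail(loss, smooth_n)) / baseline),
    class = "rnn_fit"
  )
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat(sprintf("<rnn_fit> %s task: loss %.4f -> %.4f (reduction %.1f%%)\n",
              x$target, x$baseline_loss, mean(tail(x$loss, 100)),
              100 * x$loss_reduction))
  invisible(x)
}

#' @rdname train_reversal
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @method glance rnn_fit
#' @export
glance.rnn_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target, n_iter = length(x$loss),
    initial_loss = x$baseline_loss,
    final_loss = mean(tail(x$loss, 100)),
    loss_reduction = x$loss_reduction
  )
}

# minimum-norm least-squares tuning of responses to probe inputs (the probes
# span a low-dimensional manifold, so the pseudoinverse is the right solve)
pinv_tuning <- function(X, h) {
  sv <- svd(sweep(X, 2, colMeans(X)))
  tol <- max(sv$d) * 1e-10
  keep <- sv$d > tol
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% (h - mean(h))) / sv$d[keep])
}

#' Tuning reversal analysis of a trained network
#'
#' Probes the network with fresh random gradients, fits each unit's linear
#' tuning to the probe inputs at timesteps 1 and 2 (minimum-norm least
#' squares), and reports the per-unit cosine between the two tunings and the
#' population mean. A negative mean cosine is the reversal signature.
#'
#' @param model An `rnn_model` (typically `fit$model`).
#' @param n_probe Number of probe gradients.
#' @param gradient_type Probe generator type.
#' @param seed Integer seed.
#' @return List: `per_unit` tibble (`unit`, `tuning_cosine`) and
#'   `mean_cosine`.
#' @export
reversal_analysis <- function(model, n_probe = 200, gradient_type = "index",
                              seed = 99) {
  n <- model$n_units
  with_seed(seed, {
    X <- t(vapply(seq_len(n_probe),
                  function(i) rnn_gradient_input(n, gradient_type), numeric(n)))
    H1 <- t(apply(X, 1, function(x) tanh(x)))
    H2 <- t(vapply(seq_len(n_probe),
                   function(i) rnn_step(model, H1[i, ], X[i, ]), numeric(n)))
    cosines <- vapply(seq_len(n), function(u) {
      t1 <- pinv_tuning(X, H1[, u]); t2 <- pinv_tuning(X, H2[, u])
      cosine_sim(as.vector(t1), as.vector(t2))
    }, numeric(1))
    list(per_unit = tibble::tibble(unit = seq_len(n), tuning_cosine = cosines),
         mean_cosine = mean(cosines, na.rm = TRUE))
  })
}
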