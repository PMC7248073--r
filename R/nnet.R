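#' Elliott sigmoid activations
#'
#' The Elliott function is a cheap sigmoid: the symmetric variant
#' `s*x / (1 + |s*x|)` maps to (-1, 1) and is used in the hidden layers;
#' the positive variant `0.5 * s*x / (1 + |s*x|) + 0.5` maps to (0, 1)
#' and is used at the output, whose target (the selection trend) is
#' rescaled to \[0, 1\]. The small default slope (0.1) keeps units far from
#' saturation.
#'
#' @param x Numeric input.
#' @param slope Slope parameter `s`.
#' @return Activation value(s).
#' @export
elliott <- function(x, slope = 0.1) {
  sx <- slope * x
  sx / (1 + abs(sx))
}

#' @rdname elliott
#' @export
elliott_pos <- function(x, slope = 0.1) 0.5 * elliott(x, slope) + 0.5

#' @noRd
elliott_deriv <- function(x, slope = 0.1) slope / (1 + abs(slope * x))^2

#' @noRd
elliott_pos_deriv <- function(x, slope = 0.1) 0.5 * elliott_deriv(x, slope)

# Weight matrices ((n_in + 1) x n_out, last row = bias), small uniform init.
#' @noRd
mlp_init <- function(n_in, hidden, seed, init_range = 0.5) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(stats::runif((sizes[l] + 1L) * sizes[l + 1L],
                        -init_range, init_range),
           sizes[l] + 1L, sizes[l + 1L]))
}

# Forward pass; optional per-layer dropout masks (inverted dropout:
# surviving units scaled by 1/(1-p) so prediction needs no rescaling).
#' @noRd
mlp_forward <- function(W, X, slope, masks = NULL) {
  L <- length(W)
  Z <- A <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- cbind(a, 1) %*% W[[l]]
    if (l < L) {
      act <- elliott(z, slope)
      if (!is.null(masks)) act <- sweep(act, 2, masks[[l]], "*")
    } else {
      act <- elliott_pos(z, slope)
    }
    Z[[l]] <- z; A[[l]] <- act
    a <- act
  }
  list(Z = Z, A = A, out = a)
}

# Full-batch gradient of the MSE loss via backprop.
#' @noRd
mlp_grad <- function(W, X, y, slope, masks = NULL) {
  n <- nrow(X)
  fw <- mlp_forward(W, X, slope, masks)
  L <- length(W)
  grads <- vector("list", L)
  delta <- (2 / n) * (fw$out - y) * elliott_pos_deriv(fw$Z[[L]], slope)
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1) X else fw$A[[l - 1]]
    grads[[l]] <- crossprod(cbind(a_prev, 1), delta)
    if (l > 1) {
      delta <- (delta %*% t(W[[l]][-nrow(W[[l]]), , drop = FALSE])) *
        elliott_deriv(fw$Z[[l - 1]], slope)
      if (!is.null(masks)) delta <- sweep(delta, 2, masks[[l - 1]], "*")
    }
  }
  list(grads = grads, mse = mean((fw$out - y)^2))
}

#' Train one feedforward summary network with RPROP-
#'
#' Architecture: four hidden layers of five Elliott units (slope 0.1) and
#' a (0, 1) Elliott output, trained full-batch with the sign-based
#' resilient-propagation variant without backtracking (RPROP-): each
#' weight keeps its own step size, grown by 1.2 while the gradient sign
#' is stable and halved when it flips. Optional dropout perturbs each
#' iteration's gradient. Training stops when the clean (dropout-free)
#' training MSE reaches `target_error` or after `max_iter` iterations.
#'
#' @param X Matrix of standardised summaries (rows = simulations).
#' @param y Target vector scaled to \[0, 1\].
#' @param hidden Hidden layer sizes (default `c(5, 5, 5, 5)`).
#' @param slope Elliott slope (default 0.1).
#' @param dropout Per-unit dropout probability on hidden layers
#'   (default 0.1).
#' @param max_iter Iteration cap (default 10000).
#' @param target_error Stop when training MSE is at or below this
#'   (default 0.01). The error is evaluated on the (dropout-perturbed)
#'   pass used for the gradient, before the iteration's weight update.
#' @param seed RNG seed (weight init and dropout).
#' @param backend `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation; same RNG stream and update order, kept for
#'   cross-checking the compiled core).
#' @return List of class `summary_net`: weights `W`, `slope`, training
#'   `mse`, iterations used.
#' @export
train_mlp <- function(X, y, hidden = c(5, 5, 5, 5), slope = 0.1,
                      dropout = 0.1, max_iter = 10000, target_error = 0.01,
                      seed = 1, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y >= 0 & y <= 1))
  W <- mlp_init(ncol(X), hidden, seed)   # also seeds the dropout stream
  if (backend == "cpp") {
    res <- .rprop_train_cpp(W, X, y, slope, dropout, max_iter, target_error)
    if (isTRUE(res$diverged)) stop("non-finite loss during training")
    return(structure(list(W = res$W, slope = slope, mse = res$mse,
                          iterations = res$iterations, hidden = hidden),
                     class = "summary_net"))
  }
  L <- length(W)
  step <- lapply(W, function(w) matrix(0.1, nrow(w), ncol(w)))
  prev_sign <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  eta_plus <- 1.2; eta_minus <- 0.5; step_max <- 50; step_min <- 1e-6
  mse <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    masks <- if (dropout > 0) {
      lapply(hidden, function(h)
        (stats::runif(h) >= dropout) / (1 - dropout))
    } else NULL
    bp <- mlp_grad(W, X, y, slope, masks)
    if (!is.finite(bp$mse)) stop("non-finite loss during training")
    mse <- bp$mse
    if (mse <= target_error) break
    for (l in seq_len(L)) {
      g <- bp$grads[[l]]
      sgn <- sign(g)
      prod_sign <- sgn * prev_sign[[l]]
      step[[l]] <- pmin(pmax(
        step[[l]] * ifelse(prod_sign > 0, eta_plus,
                           ifelse(prod_sign < 0, eta_minus, 1)),
        step_min), step_max)
      W[[l]] <- W[[l]] - sgn * step[[l]]
      prev_sign[[l]] <- sgn
    }
  }
  structure(list(W = W, slope = slope, mse = mse, iterations = it,
                 hidden = hidden), class = "summary_net")
}

#' @export
print.summary_net <- function(x, ...) {
  cat(sprintf("summary_net: %s hidden units, training MSE %.4g (%d iter)\n",
              paste(x$hidden, collapse = "-"), x$mse, x$iterations))
  invisible(x)
}

#' Predict with a trained summary network
#' @param object A `summary_net`.
#' @param newdata Matrix of standardised summaries.
#' @param ... Unused.
#' @return Numeric vector of predictions in (0, 1).
#' @export
predict.summary_net <- function(object, newdata, ...) {
  newdata <- as_summary_matrix(newdata)
  as.vector(mlp_forward(object$W, newdata, object$slope)$out)
}

# a bare vector is one dataset's summary row, not a column
#' @noRd
as_summary_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Train the ensemble of neural summary statistics
#'
#' Trains `n_nets` independently initialised networks on the reference
#' table, each mapping the standardised leaf-mean summaries to the
#' selection trend rescaled to \[0, 1\]; the consensus prediction (mean of
#' the nets) is the scalar summary statistic used by the ABC step. A net
#' whose training hits a non-finite loss is restarted with the next seed.
#'
#' @param ref An `abc_reference` from [generate_reference_table()].
#' @param n_nets Ensemble size (default 10).
#' @param seed Base seed; net `k` uses `seed + k`.
#' @inheritParams train_mlp
#' @return List of class `summary_ensemble`: `nets`, `priors`, gamma
#'   scaling constants.
#' @export
train_summary_ensemble <- function(ref, n_nets = 10, hidden = c(5, 5, 5, 5),
                                   slope = 0.1, dropout = 0.1,
                                   max_iter = 10000, target_error = 0.01,
                                   seed = 1) {
  g <- ref$priors$gamma
  y <- (ref$theta$gamma - g[1]) / (g[2] - g[1])
  nets <- vector("list", n_nets)
  s <- seed
  for (k in seq_len(n_nets)) {
    repeat {
      s <- s + 1L
      net <- tryCatch(
        train_mlp(ref$std, y, hidden = hidden, slope = slope,
                  dropout = dropout, max_iter = max_iter,
                  target_error = target_error, seed = s),
        error = function(e) {
          message("net restart (seed ", s, "): ", conditionMessage(e))
          NULL
        })
      if (!is.null(net)) break
    }
    nets[[k]] <- net
  }
  structure(list(nets = nets, priors = ref$priors,
                 gamma_range = g), class = "summary_ensemble")
}

#' Consensus neural summary of standardised summaries
#' @param object A `summary_ensemble`.
#' @param newdata Matrix of standardised summaries (rows = datasets).
#' @param consensus Average the nets (default) or return the per-net
#'   matrix.
#' @param ... Unused.
#' @return Vector of consensus summaries (or matrix if
#'   `consensus = FALSE`).
#' @export
predict.summary_ensemble <- function(object, newdata, consensus = TRUE, ...) {
  newdata <- as_summary_matrix(newdata)
  preds <- vapply(object$nets, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  preds <- matrix(preds, nrow = nrow(newdata))
  if (consensus) rowMeans(preds) else preds
}
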