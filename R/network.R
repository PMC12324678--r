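# Recurrent policy/value network: an LSTM with 100 recurrent units feeding
# separate policy and value heads, each two fully connected tanh layers of 64
# units. Forward, backpropagation-through-time and the Adam optimizer are
# implemented directly in base R matrix code; gradients are cross-checked in
# the tests against finite differences and an independent scalar loss oracle.

#' Network architecture configuration
#'
#' @param n_input Observation length (48).
#' @param n_recurrent LSTM units (100).
#' @param n_hidden Width of each policy/value head layer (64).
#' @param n_actions Discrete actions (8: four direction moves, four
#'   adjacent-state selections).
#' @export
network_config <- function(n_input = 48L, n_recurrent = 100L,
                           n_hidden = 64L, n_actions = 8L) {
  list(n_input = as.integer(n_input), n_recurrent = as.integer(n_recurrent),
       n_hidden = as.integer(n_hidden), n_actions = as.integer(n_actions))
}

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize network parameters
#'
#' Xavier-uniform weights, zero biases, LSTM forget-gate bias 1, and a
#' small-scale policy output layer (so the initial policy is near uniform
#' over valid actions). Reproducible from `seed`.
#'
#' @param config A [network_config()]. @param seed Optional integer seed.
#' @return Named list of parameter matrices with attribute `config`.
#' @export
init_network <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ni <- config$n_input; nr <- config$n_recurrent
  nh <- config$n_hidden; na <- config$n_actions
  b <- numeric(4 * nr)
  b[(nr + 1):(2 * nr)] <- 1  # forget-gate bias
  params <- list(
    Wx = .xavier(ni, 4 * nr), Wh = .xavier(nr, 4 * nr), b = b,
    P1 = .xavier(nr, nh), pb1 = numeric(nh),
    P2 = .xavier(nh, nh), pb2 = numeric(nh),
    P3 = matrix(stats::rnorm(nh * na, 0, 0.01), nh, na), pb3 = numeric(na),
    V1 = .xavier(nr, nh), vb1 = numeric(nh),
    V2 = .xavier(nh, nh), vb2 = numeric(nh),
    V3 = matrix(stats::rnorm(nh, 0, 0.01), nh, 1), vb3 = 0
  )
  attr(params, "config") <- config
  params
}

#' Fresh (zero) recurrent state
#' @param params Network parameters. @param batch Batch size.
#' @export
initial_state <- function(params, batch = 1L) {
  nr <- attr(params, "config")$n_recurrent
  list(h = matrix(0, batch, nr), c = matrix(0, batch, nr))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM step for a batch. x: B x n_input; h, c: B x n_recurrent.
# lesion: integer unit indices whose cell and hidden state are forced to 0.
# Returns the new state plus gate caches for BPTT.
lstm_step <- function(params, x, h, c, lesion = NULL) {
  nr <- ncol(h)
  z <- x %*% params$Wx + h %*% params$Wh
  z <- z + rep(params$b, each = nrow(z))
  i <- .sigmoid(z[, 1:nr, drop = FALSE])
  f <- .sigmoid(z[, (nr + 1):(2 * nr), drop = FALSE])
  g <- tanh(z[, (2 * nr + 1):(3 * nr), drop = FALSE])
  o <- .sigmoid(z[, (3 * nr + 1):(4 * nr), drop = FALSE])
  c_new <- f * c + i * g
  if (!is.null(lesion) && length(lesion)) c_new[, lesion] <- 0
  tc <- tanh(c_new)
  h_new <- o * tc
  if (!is.null(lesion) && length(lesion)) h_new[, lesion] <- 0
  list(h = h_new, c = c_new, i = i, f = f, g = g, o = o, tc = tc,
       h_prev = h, c_prev = c, x = x)
}

# Two-layer tanh MLP heads over a stack of hidden states (N x n_recurrent).
heads_forward <- function(params, H) {
  n <- nrow(H)
  p1 <- tanh(H %*% params$P1 + rep(params$pb1, each = n))
  p2 <- tanh(p1 %*% params$P2 + rep(params$pb2, each = n))
  logits <- p2 %*% params$P3 + rep(params$pb3, each = n)
  v1 <- tanh(H %*% params$V1 + rep(params$vb1, each = n))
  v2 <- tanh(v1 %*% params$V2 + rep(params$vb2, each = n))
  value <- drop(v2 %*% params$V3) + params$vb3
  list(logits = logits, value = value, p1 = p1, p2 = p2, v1 = v1, v2 = v2)
}

#' Single-step network forward pass
#'
#' Deterministic: identical inputs and recurrent state give bit-identical
#' outputs. The recurrent state advances by one step.
#'
#' @param params Network parameters from [init_network()].
#' @param observation Length-48 vector, or a batch-by-48 matrix.
#' @param state Recurrent state from [initial_state()].
#' @param lesion Optional integer vector of unit indices whose cell and
#'   hidden activations are zeroed (see [apply_lesion()]).
#' @return List `logits` (batch x 8), `value` (length batch), `state`.
#' @export
forward <- function(params, observation, state = NULL, lesion = NULL) {
  cfg <- attr(params, "config")
  if (is.null(dim(observation))) observation <- matrix(observation, 1)
  if (ncol(observation) != cfg$n_input)
    stop("observation must have length ", cfg$n_input)
  if (is.null(state)) state <- initial_state(params, nrow(observation))
  st <- lstm_step(params, observation, state$h, state$c, lesion)
  hd <- heads_forward(params, st$h)
  list(logits = hd$logits, value = hd$value, state = list(h = st$h, c = st$c))
}

#' Mask invalid actions out of a logit vector
#'
#' Invalid slots are replaced by a large negative constant (-1e8) so their
#' softmax probability vanishes; valid slots pass through unchanged.
#'
#' @param logits Numeric vector or matrix of logits.
#' @param mask Logical vector/matrix of the same shape; at least one `TRUE`
#'   per row.
#' @export
mask_logits <- function(logits, mask, neg = -1e8) {
  if (is.null(dim(logits))) {
    if (!any(mask)) stop("all actions masked: no valid action")
    logits[!mask] <- neg
    return(logits)
  }
  if (any(rowSums(mask) == 0)) stop("all actions masked: no valid action")
  logits[!mask] <- neg
  logits
}

# Row-wise log-softmax (numerically stable).
log_softmax <- function(x) {
  m <- x[, 1]
  for (j in 2:ncol(x)) m <- pmax(m, x[, j])
  s <- x - m
  s - log(rowSums(exp(s)))
}

# --- Full-sequence forward/backward for PPO updates -------------------------

# Forward over a T-step rollout. xs: list of T matrices (B x n_input).
# resets: T x B logical; TRUE means the recurrent state is zeroed before
# consuming step t (episode boundary). Returns stacked hidden states, head
# outputs, and per-step caches for the backward pass.
seq_forward <- function(params, xs, resets, h0 = NULL, c0 = NULL,
                        lesion = NULL) {
  Tn <- length(xs); B <- nrow(xs[[1]])
  nr <- attr(params, "config")$n_recurrent
  h <- if (is.null(h0)) matrix(0, B, nr) else h0
  c <- if (is.null(c0)) matrix(0, B, nr) else c0
  caches <- vector("list", Tn)
  H <- matrix(0, Tn * B, nr)
  for (t in seq_len(Tn)) {
    rs <- resets[t, ]
    if (any(rs)) { h[rs, ] <- 0; c[rs, ] <- 0 }
    st <- lstm_step(params, xs[[t]], h, c, lesion)
    h <- st$h; c <- st$c
    caches[[t]] <- st
    H[((t - 1) * B + 1):(t * B), ] <- h
  }
  hd <- heads_forward(params, H)
  list(H = H, heads = hd, caches = caches, resets = resets)
}

# Backward pass: dlogits (T*B x 8) and dvalue (length T*B) to parameter
# gradients, truncating gradient flow at episode boundaries.
seq_backward <- function(params, fw, dlogits, dvalue) {
  cfg <- attr(params, "config")
  nr <- cfg$n_recurrent
  Tn <- length(fw$caches); B <- nrow(fw$caches[[1]]$h)
  hd <- fw$heads; H <- fw$H

  # Heads.
  dp2 <- tcrossprod(dlogits, params$P3) * (1 - hd$p2^2)
  dp1 <- tcrossprod(dp2, params$P2) * (1 - hd$p1^2)
  dv <- matrix(dvalue, ncol = 1)
  dv2 <- tcrossprod(dv, params$V3) * (1 - hd$v2^2)
  dv1 <- tcrossprod(dv2, params$V2) * (1 - hd$v1^2)
  grads <- list(
    P3 = crossprod(hd$p2, dlogits), pb3 = colSums(dlogits),
    P2 = crossprod(hd$p1, dp2), pb2 = colSums(dp2),
    P1 = crossprod(H, dp1), pb1 = colSums(dp1),
    V3 = crossprod(hd$v2, dv), vb3 = sum(dv),
    V2 = crossprod(hd$v1, dv2), vb2 = colSums(dv2),
    V1 = crossprod(H, dv1), vb1 = colSums(dv1)
  )
  dH_heads <- tcrossprod(dp1, params$P1) + tcrossprod(dv1, params$V1)

  dWx <- matrix(0, cfg$n_input, 4 * nr)
  dWh <- matrix(0, nr, 4 * nr)
  db <- numeric(4 * nr)
  dh_next <- matrix(0, B, nr); dc_next <- matrix(0, B, nr)
  for (t in Tn:1) {
    cc <- fw$caches[[t]]
    dh <- dH_heads[((t - 1) * B + 1):(t * B), , drop = FALSE] + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dh_next <- tcrossprod(dZ, params$Wh)
    dc_next <- dc_prev
    rs <- fw$resets[t, ]
    if (any(rs)) { dh_next[rs, ] <- 0; dc_next[rs, ] <- 0 }
  }
  grads$Wx <- dWx; grads$Wh <- dWh; grads$b <- db
  grads
}

# Global-norm gradient clipping (max norm 0.5 by default, per Table 2).
clip_gradients <- function(grads, max_norm = 0.5) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, function(g) g * (max_norm / total))
  attr(grads, "global_norm") <- min(total, max_norm)
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-5) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
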