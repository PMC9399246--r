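# Dense feed-forward networks with analytic backpropagation.
#
# All activations are stored as (units x batch) matrices. The critic's
# gradient penalty needs the parameter-gradient of an input-gradient norm;
# for piecewise-linear activations this double-backprop is exact because the
# second derivative of the activation vanishes almost everywhere, so the
# penalty gradient reduces to backpropagation through the forward-mode
# (Jacobian-vector product) chain. Hidden layers of the critic must therefore
# use "lrelu" or "linear" when the penalty is active.

act_fun <- function(name, z) {
  switch(name,
         linear = z,
         lrelu = ifelse(z > 0, z, 0.2 * z),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation: ", name))
}

# derivative of the activation given pre-activation z and activation a
act_grad <- function(name, z, a) {
  switch(name,
         linear = 1,
         lrelu = ifelse(z > 0, 1, 0.2),
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         stop("unknown activation: ", name))
}

# new network: sizes = c(n_in, h1, ..., n_out), acts = one name per layer
nn_new <- function(sizes, acts) {
  L <- length(sizes) - 1
  stopifnot(length(acts) == L)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1]
    sd <- sqrt(2 / n_in)
    layers[[l]] <- list(
      W = matrix(stats::rnorm(n_out * n_in, sd = sd), n_out, n_in),
      b = numeric(n_out),
      act = acts[l])
  }
  structure(list(layers = layers, sizes = sizes), class = "nn_net")
}

# forward pass; returns activations a[[0..L]] (1-based: a[[1]] = input) and z
nn_forward <- function(net, X) {
  L <- length(net$layers)
  a <- vector("list", L + 1)
  z <- vector("list", L)
  a[[1]] <- X
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    z[[l]] <- ly$W %*% a[[l]] + ly$b
    a[[l + 1]] <- act_fun(ly$act, z[[l]])
  }
  list(a = a, z = z)
}

nn_output <- function(net, X) {
  cache <- nn_forward(net, X)
  cache$a[[length(cache$a)]]
}

# backprop from dL/d a[[start_layer+1]]; returns per-layer W/b gradients
# (summed over the batch) for layers 1..start_layer and dL/d input;
# want_params/want_input skip the matrix products that are not used
nn_backward <- function(net, cache, dout, start_layer = length(net$layers),
                        want_params = TRUE, want_input = TRUE) {
  gW <- vector("list", start_layer)
  gb <- vector("list", start_layer)
  d <- dout
  for (l in seq(start_layer, 1)) {
    ly <- net$layers[[l]]
    dz <- d * act_grad(ly$act, cache$z[[l]], cache$a[[l + 1]])
    if (want_params) {
      gW[[l]] <- tcrossprod(dz, cache$a[[l]])
      gb[[l]] <- rowSums(dz)
    }
    if (l > 1 || want_input) d <- crossprod(ly$W, dz)
  }
  list(gW = gW, gb = gb, dinput = if (want_input) d)
}

# forward-mode directional derivative (JVP): t_L = (d net(x)/dx) %*% U
nn_jvp <- function(net, cache, U) {
  L <- length(net$layers)
  tl <- vector("list", L + 1)
  tl[[1]] <- U
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    s <- ly$W %*% tl[[l]]
    tl[[l + 1]] <- act_grad(ly$act, cache$z[[l]], cache$a[[l + 1]]) * s
  }
  tl
}

# exact parameter gradient of cvec %*% t_L for piecewise-linear activations
nn_jvp_backward <- function(net, cache, tl, cvec) {
  L <- length(net$layers)
  gW <- vector("list", L)
  gb <- vector("list", L)
  r <- cvec
  for (l in seq(L, 1)) {
    ly <- net$layers[[l]]
    if (!(ly$act %in% c("lrelu", "linear"))) {
      stop("gradient-penalty backprop requires piecewise-linear activations")
    }
    rt <- r * act_grad(ly$act, cache$z[[l]], cache$a[[l + 1]])
    gW[[l]] <- tcrossprod(rt, tl[[l]])
    gb[[l]] <- numeric(nrow(ly$W))  # biases do not enter the input-Jacobian
    if (l > 1) r <- crossprod(ly$W, rt)
  }
  list(gW = gW, gb = gb)
}

grads_zero <- function(net) {
  list(gW = lapply(net$layers, function(ly) ly$W * 0),
       gb = lapply(net$layers, function(ly) ly$b * 0))
}

grads_add <- function(g1, g2, scale = 1) {
  n <- length(g2$gW)
  for (l in seq_len(n)) {
    g1$gW[[l]] <- g1$gW[[l]] + scale * g2$gW[[l]]
    g1$gb[[l]] <- g1$gb[[l]] + scale * g2$gb[[l]]
  }
  g1
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(net, lr, beta1, beta2, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       mW = lapply(net$layers, function(ly) ly$W * 0),
       vW = lapply(net$layers, function(ly) ly$W * 0),
       mb = lapply(net$layers, function(ly) ly$b * 0),
       vb = lapply(net$layers, function(ly) ly$b * 0))
}

adam_step <- function(net, grads, st) {
  st$t <- st$t + 1L
  c1 <- 1 - st$beta1^st$t
  c2 <- 1 - st$beta2^st$t
  for (l in seq_along(net$layers)) {
    st$mW[[l]] <- st$beta1 * st$mW[[l]] + (1 - st$beta1) * grads$gW[[l]]
    st$vW[[l]] <- st$beta2 * st$vW[[l]] + (1 - st$beta2) * grads$gW[[l]]^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      st$lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + st$eps)
    st$mb[[l]] <- st$beta1 * st$mb[[l]] + (1 - st$beta1) * grads$gb[[l]]
    st$vb[[l]] <- st$beta2 * st$vb[[l]] + (1 - st$beta2) * grads$gb[[l]]^2
    net$layers[[l]]$b <- net$layers[[l]]$b -
      st$lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + st$eps)
  }
  list(net = net, state = st)
}
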