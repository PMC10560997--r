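# Thin R wrappers over the compiled conv/pool primitives plus the cheap
# elementwise ops (activations, 2x nearest upsampling) that stay in R.

conv_fw <- function(x, W, b, k) cpp_conv2d_fw(x, W, b, as.integer(k))
conv_bw <- function(x, W, gy, k) {
  out <- cpp_conv2d_bw(x, W, gy, as.integer(k))
  out$gb <- as.numeric(out$gb)
  out
}
pool_fw <- function(x) cpp_maxpool_fw(x)
pool_bw <- function(idx, gy, H, W) cpp_maxpool_bw(idx, gy, as.integer(H), as.integer(W))

# leaky ReLU (slope 0.2 on the negative side): with the 0.001-sd generator
# init, plain ReLU leaves enough units dead that some runs stay trapped
# predicting the majority class; the leak removes that failure mode
leak <- 0.2
relu <- function(a) {
  neg <- a < 0
  a[neg] <- a[neg] * leak
  a
}
relu_bw <- function(a, gy) gy * ifelse(a > 0, 1, leak)

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}
up2_bw <- function(gy) {
  d <- dim(gy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(2, d[1], by = 2)
  e1 <- seq(1, d[2], by = 2); e2 <- seq(2, d[2], by = 2)
  gy[o1, e1, , drop = FALSE] + gy[o2, e1, , drop = FALSE] +
    gy[o1, e2, , drop = FALSE] + gy[o2, e2, , drop = FALSE]
}

# softmax across the class (3rd) dimension of an H x W x C array
softmax3 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[3])
  mx <- m[, 1]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, dim = d)
}
# gradient wrt logits given gradient wrt probabilities
softmax3_bw <- function(probs, gp) {
  d <- dim(probs)
  p <- matrix(probs, ncol = d[3])
  g <- matrix(gp, ncol = d[3])
  array(p * (g - rowSums(p * g)), dim = d)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# instance normalisation (per channel, per image) with affine gain/bias;
# keeps activations O(1) independent of the weight-initialisation scale
instnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  sg <- sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, sg, "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, dim = d), xhat = xhat, sg = sg)
}

instnorm_bw <- function(cache, gamma, gy) {
  d <- dim(gy)
  g <- matrix(gy, ncol = d[3])
  xhat <- cache$xhat
  dgamma <- colSums(g * xhat)
  dbeta <- colSums(g)
  dxh <- sweep(g, 2, gamma, "*")
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(xhat, 2, colMeans(dxh * xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$sg, "/")
  list(gx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# promote H x W to H x W x 1; validate 3d
as_chw <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3)
  x
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}
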