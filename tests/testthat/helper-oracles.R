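# Independent brute-force oracles used to cross-check the package's
# closed-form implementations. Deliberately naive (loops, direct formulas).

oracle_elementwise_mean <- function(maps) {
  out <- array(0, dim = dim(maps[[1]]))
  for (i in seq_along(out)) {
    v <- 0
    for (m in maps) v <- v + m[i]
    out[i] <- v / length(maps)
  }
  out
}

# second-moment matrix at a single pixel, directly from the formula
oracle_u_pixel <- function(prob_vectors, tau) {
  C <- length(tau)
  N <- length(prob_vectors)
  mean_vec <- Reduce(`+`, prob_vectors) / N
  second <- matrix(0, C, C)
  for (p in prob_vectors) second <- second + outer(p, p)
  diag(1 / tau) + second / N - outer(mean_vec, mean_vec)
}

# exhaustive all-pairs nearest-boundary-distance ASSD
oracle_assd <- function(a, b, spacing = c(1, 1)) {
  bp <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- NULL
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < H) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < W) m[i, j + 1] else FALSE)
      if (i == 1 || i == H || j == 1 || j == W || !all(nb)) {
        out <- rbind(out, c(i, j))
      }
    }
    out
  }
  pa <- bp(a > 0); pb <- bp(b > 0)
  dmin <- function(p, q) {
    apply(p, 1, function(r) {
      min(sqrt(((q[, 1] - r[1]) * spacing[1])^2 + ((q[, 2] - r[2]) * spacing[2])^2))
    })
  }
  (mean(dmin(pa, pb)) + mean(dmin(pb, pa))) / 2
}

oracle_cce <- function(pred, target_onehot) {
  total <- 0
  H <- dim(pred)[1]; W <- dim(pred)[2]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    c_true <- which(target_onehot[i, j, ] == 1)
    total <- total - log(max(pred[i, j, c_true], 1e-12))
  }
  total / (H * W)
}

oracle_ece <- function(conf, correct, n_bins) {
  n <- length(conf)
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    sel <- if (b == 1) conf <= hi else conf > lo & conf <= hi
    if (!any(sel)) next
    total <- total + sum(sel) / n * abs(mean(correct[sel]) - mean(conf[sel]))
  }
  total
}

oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# tiny deterministic test image + mask pair
toy_masked_sample <- function(seed = 1, H = 16, W = 16, C = 3) {
  withr::with_seed(seed, {
    img <- matrix(runif(H * W), H, W)
    mask <- matrix(sample(0:(C - 1), H * W, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
                   H, W)
    image_sample(img, mask = mask, sample_id = sprintf("toy_%d", seed))
  })
}

random_prob_maps <- function(n, H = 4, W = 4, C = 3, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      e <- array(rexp(H * W * C), dim = c(H, W, C))
      s <- apply(e, c(1, 2), sum)
      e / array(rep(s, C), dim = c(H, W, C))
    })
  })
}
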