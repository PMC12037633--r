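# Literal per-node / per-pair loop oracles, kept deliberately free of the
# vectorized shortcuts used by the implementation.

oracle_gcn <- function(Ahat, X, Wc, B) {
  n <- nrow(X); fout <- ncol(Wc)
  out <- matrix(0, n, fout)
  prop <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) for (f in seq_len(ncol(X))) {
    prop[i, f] <- sum(Ahat[i, ] * X[, f])
  }
  for (i in seq_len(n)) for (k in seq_len(fout)) {
    z <- sum(prop[i, ] * Wc[, k]) + (if (is.matrix(B)) B[i, k] else B[k])
    out[i, k] <- max(z, 0)
  }
  out
}

oracle_gat_scores <- function(H, Wt, b, mask) {
  n <- nrow(H)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    hi <- as.numeric(tanh(crossprod(Wt, H[i, ]) + b))
    e <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (mask[i, j]) e[j] <- sum(as.numeric(crossprod(Wt, H[j, ])) * hi)
    }
    nb <- which(!is.na(e))
    ex <- exp(e[nb] - max(e[nb]))
    alpha[i, nb] <- ex / sum(ex)
  }
  alpha
}

oracle_gat_layer <- function(H, alpha) {
  n <- nrow(H); f <- ncol(H)
  out <- matrix(0, n, f)
  for (i in seq_len(n)) for (k in seq_len(f)) {
    out[i, k] <- max(sum(alpha[i, ] * H[, k]), 0)
  }
  out
}

oracle_bilinear <- function(Yl, Yd, Wl, Wd) {
  U <- Yl %*% Wl; V <- Yd %*% Wd
  out <- matrix(0, nrow(Yl), nrow(Yd))
  for (i in seq_len(nrow(Yl))) for (j in seq_len(nrow(Yd))) {
    out[i, j] <- sum(U[i, ] * V[j, ])
  }
  out
}

# Mann-Whitney pair counting: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random small graph instance for layer-level oracle tests
random_instance <- function(n, f, seed) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, 0.4), n, n)
  A <- ((A + t(A)) > 0) * 1
  diag(A) <- 0
  list(A = A,
       Ahat = normalize_adjacency(A),
       mask = (A + diag(n)) > 0,
       H = matrix(rnorm(n * f), n, f))
}

# parameter-vector helpers for finite-difference gradient checks
flatten_params <- function(p) unlist(unclass(p), use.names = FALSE)

unflatten_params <- function(vec, tmpl) {
  out <- utils::relist(vec, skeleton = unclass(tmpl))
  restore <- function(a, b) {
    if (is.list(b)) return(Map(restore, a, b))
    if (is.matrix(b)) a <- matrix(a, nrow(b), ncol(b))
    a
  }
  structure(restore(out, unclass(tmpl)), class = "lnclink_params")
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden = 6L, l1 = 4L, l2 = 4L, att_dim = 3L, r = 3L,
         epochs = 30L, topk = c(2L, 5L)),
    list(...)
  )
  do.call(lnclink_config, args)
}

tiny_dataset <- function(seed = 3L) {
  generate_synthetic(synthetic_spec(nl = 12, nd = 10, nm = 5, n_blocks = 2,
                                    density = 0.25, noise_rate = 0,
                                    seed = seed))$dataset
}
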