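test_that("gcn_layer matches hand products and the relu contract", {
  Ahat <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(Ahat, diag(2), diag(2)), matrix(0.5, 2, 2))
  X <- matrix(c(1, 2, 0, 3), 2, 2)
  expect_equal(gcn_layer(diag(2), X, diag(2)), X)  # identity propagation
  # all-negative pre-activation zeroes out
  expect_equal(gcn_layer(diag(2), X, -diag(2)), matrix(0, 2, 2))
  # per-feature offset broadcasts across nodes
  expect_equal(gcn_layer(diag(2), X, diag(2), B = c(1, 2)),
               X + rep(c(1, 2), each = 2))
  expect_error(gcn_layer(matrix(NaN, 2, 2), X, diag(2)), "non-finite")
})

test_that("attention reduces to the trivial cases", {
  H <- rbind(c(1, 0), c(1, 0), c(0, 2))
  Wt <- diag(2); b <- c(0, 0)
  mask <- matrix(TRUE, 3, 3)
  # identical features of nodes 1 and 2: equal scores among them
  a <- gat_scores(H[1:2, ], Wt, b, matrix(TRUE, 2, 2))
  expect_equal(unname(a), matrix(0.5, 2, 2))
  # singleton neighborhood gets full weight
  a1 <- gat_scores(H, Wt, b, diag(3) == 1)
  expect_equal(unname(a1), diag(3))
  expect_error(gat_scores(H, Wt, b, matrix(FALSE, 3, 3)), "empty neighborhood")
})

test_that("gat_layer aggregates convexly", {
  H <- rbind(c(2, 0), c(0, 4))
  expect_equal(gat_layer(H, diag(2)), H)
  expect_equal(gat_layer(H, matrix(0.5, 2, 2)), rbind(c(1, 2), c(1, 2)))
  Hneg <- rbind(c(-1, -2), c(-3, -4))
  expect_equal(gat_layer(Hneg, diag(2)), matrix(0, 2, 2))
})

test_that("layer implementations match literal loop oracles on random instances", {
  for (seed in 1:12) {
    inst <- random_instance(n = sample(4:10, 1), f = 3, seed = seed)
    Wc <- matrix(rnorm(3 * 4), 3, 4)
    B <- rnorm(4)
    expect_equal(gcn_layer(inst$Ahat, inst$H, Wc, B),
                 oracle_gcn(inst$Ahat, inst$H, Wc, B), tolerance = 1e-10)
    Wt <- matrix(rnorm(3 * 2), 3, 2)
    b <- rnorm(2)
    a <- gat_scores(inst$H, Wt, b, inst$mask)
    expect_equal(unname(a), oracle_gat_scores(inst$H, Wt, b, inst$mask),
                 tolerance = 1e-10)
    expect_equal(gat_layer(inst$H, a), oracle_gat_layer(inst$H, a),
                 tolerance = 1e-10)
  }
})

test_that("attention rows are stochastic over the support", {
  for (seed in 1:8) {
    inst <- random_instance(n = 8, f = 4, seed = 100 + seed)
    Wt <- matrix(rnorm(4 * 3), 4, 3)
    a <- gat_scores(inst$H, Wt, rnorm(3), inst$mask)
    expect_lt(max(abs(rowSums(a) - 1)), 1e-8)
    expect_true(all(a[!inst$mask] == 0))
  }
})

test_that("encode_view has the contracted shape and stays finite", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  views <- build_views(ds, cfg)
  params <- init_model_params(views, cfg, seed = 5)
  nl <- length(ds$lncrna_ids); nd <- length(ds$disease_ids)
  keep <- c(seq_len(nl), nl + length(ds$mirna_ids) + seq_len(nd))
  H1 <- encode_view(views$Ahat1, views$X1, views$support1, params$net1, keep)
  H2 <- encode_view(views$Ahat2, views$F1, views$support2, params$net2)
  expect_identical(dim(H1), c(nl + nd, cfg$l1))
  expect_identical(dim(H2), c(nl + nd, cfg$l2))
  expect_true(all(is.finite(H1)) && all(H1 >= 0))
  expect_true(all(is.finite(H2)) && all(H2 >= 0))
})

test_that("encoding is equivariant under node relabeling", {
  set.seed(11)
  n <- 9
  A <- matrix(rbinom(n * n, 1, 0.4), n, n)
  A <- ((A + t(A)) > 0) * 1; diag(A) <- 0
  X0 <- A + diag(n)
  vp <- list(W1 = matrix(rnorm(n * 5), n, 5) / 3, b1 = rnorm(5) / 10,
             Wt = matrix(rnorm(5 * 3), 5, 3), bt = rnorm(3) / 10,
             W2 = matrix(rnorm(5 * 4), 5, 4) / 3, b2 = rnorm(4) / 10)
  sup <- (A + diag(n)) > 0
  H <- encode_view(normalize_adjacency(A), X0, sup, vp)
  perm <- sample(n)
  # permuting nodes permutes both the graph and the feature columns, so the
  # first-layer weights must be permuted conformably
  vp_p <- vp
  vp_p$W1 <- vp$W1[perm, , drop = FALSE]
  Hp <- encode_view(normalize_adjacency(A[perm, perm]),
                    X0[perm, perm], sup[perm, perm], vp_p)
  expect_equal(Hp, H[perm, ], tolerance = 1e-10)
})

test_that("encode_view equals a literal per-node message-passing oracle", {
  for (seed in 1:5) {
    set.seed(200 + seed)
    n <- 7; f1 <- 4; fa <- 3; f2 <- 3
    A <- matrix(rbinom(n * n, 1, 0.5), n, n)
    A <- ((A + t(A)) > 0) * 1; diag(A) <- 0
    X0 <- matrix(rnorm(n * n), n, n)
    vp <- list(W1 = matrix(rnorm(n * f1), n, f1), b1 = rnorm(f1),
               Wt = matrix(rnorm(f1 * fa), f1, fa), bt = rnorm(fa),
               W2 = matrix(rnorm(f1 * f2), f1, f2), b2 = rnorm(f2))
    Ahat <- normalize_adjacency(A)
    sup <- (A + diag(n)) > 0
    H1 <- oracle_gcn(Ahat, X0, vp$W1, vp$b1)
    al <- oracle_gat_scores(H1, vp$Wt, vp$bt, sup)
    H2 <- oracle_gat_layer(H1, al)
    H3 <- oracle_gcn(Ahat, H2, vp$W2, vp$b2)
    expect_equal(encode_view(Ahat, X0, sup, vp), H3, tolerance = 1e-8)
  }
})

test_that("concatenation splits into lncRNA and disease blocks", {
  H1 <- matrix(1:12, 6, 2)
  H2 <- matrix(13:30, 6, 3)
  cc <- concat_embeddings(H1, H2, nl = 2)
  expect_identical(dim(cc$Y), c(6L, 5L))
  expect_identical(cc$Y[, 1:2], H1)
  expect_identical(nrow(cc$Yl), 2L)
  expect_identical(nrow(cc$Yd), 4L)
  expect_error(concat_embeddings(H1, matrix(0, 5, 2), 2), "row counts")
})
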