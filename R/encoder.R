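#' Initialize all trainable parameters
#'
#' Each view owns a GCN -> GAT -> GCN stack: first-layer weights mapping the
#' view's input width (its node count, since features equal adjacency) to
#' `hidden`, an attention projection `Wt` with offset `bt`, and second-layer
#' weights mapping `hidden` to the view's latent width (`l1` or `l2`). The
#' decoder owns two maps `Wl`, `Wd` sending the concatenated `l1 + l2`
#' embedding to `r` dimensions. Weights are Glorot-uniform, offsets zero;
#' fully determined by `config$seed`.
#'
#' @param views An `lnclink_views`.
#' @param config An `lnclink_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `lnclink_params`: a nested list with one
#'   entry per active view plus the decoder maps.
#' @export
init_model_params <- function(views, config = lnclink_config(),
                              seed = config$seed) {
  set.seed(seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  view_params <- function(n_in, l_out) {
    list(
      W1 = glorot(n_in, config$hidden), b1 = numeric(config$hidden),
      Wt = glorot(config$hidden, config$att_dim), bt = numeric(config$att_dim),
      W2 = glorot(config$hidden, l_out), b2 = numeric(l_out)
    )
  }
  params <- list()
  # fixed init order so "both" shares net1's draw with the net1 ablation
  if (views$view %in% c("both", "net1")) {
    params$net1 <- view_params(nrow(views$A1), config$l1)
  }
  if (views$view %in% c("both", "net2")) {
    params$net2 <- view_params(nrow(views$A2), config$l2)
  }
  width <- (views$view == "both") * 0  # placeholder, computed below
  width <- switch(views$view,
                  both = config$l1 + config$l2,
                  net1 = config$l1,
                  net2 = config$l2)
  params$Wl <- glorot(width, config$r)
  params$Wd <- glorot(width, config$r)
  structure(params, class = "lnclink_params")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' One spectral graph-convolution layer
#'
#' `relu(Ahat %*% X %*% Wc + B)` where `B` is a per-feature offset
#' broadcast across nodes (a length-`ncol(Wc)` vector, or a conforming
#' matrix accepted as-is).
#'
#' @param Ahat Normalized propagation matrix (n x n).
#' @param X Node feature matrix (n x f).
#' @param Wc Weight matrix (f x F).
#' @param B Offset: length-F vector or n x F matrix.
#' @return n x F activated feature matrix.
#' @export
gcn_layer <- function(Ahat, X, Wc, B = numeric(ncol(Wc))) {
  if (!all(is.finite(Ahat)) || !all(is.finite(X))) {
    stop("non-finite input to gcn_layer", call. = FALSE)
  }
  Z <- Ahat %*% X %*% Wc
  Z <- if (is.matrix(B)) Z + B else sweep(Z, 2, B, `+`)
  relu(Z)
}

#' Attention scores over graph neighborhoods
#'
#' Raw score of neighbor j on node i: `e_ij = (Wt' h_j) . tanh(Wt' h_i + b)`,
#' softmax-normalized over `j` in the neighborhood of `i` (the support of
#' `A + I`, so every node attends at least to itself). Edge weights do not
#' enter the scores; they only define the support.
#'
#' @param H Node feature matrix (n x f).
#' @param Wt Attention projection (f x k).
#' @param b Offset (length k).
#' @param neighbor_mask n x n logical matrix; `[i, j]` is `TRUE` when j is
#'   in i's neighborhood.
#' @return n x n attention matrix; row i is zero off-support and sums to 1.
#' @export
gat_scores <- function(H, Wt, b, neighbor_mask) {
  if (any(rowSums(neighbor_mask) == 0)) {
    stop("empty neighborhood in gat_scores (self-loops missing?)",
         call. = FALSE)
  }
  P <- H %*% Wt                       # P[j, ] = Wt' h_j
  M <- tanh(sweep(P, 2, b, `+`))      # M[i, ] = tanh(Wt' h_i + b)
  E <- tcrossprod(M, P)               # E[i, j] = <M[i, ], P[j, ]>
  E[!neighbor_mask] <- -Inf
  row_softmax(E)
}

row_softmax <- function(E) {
  mx <- apply(E, 1, max)
  W <- exp(E - mx)
  W[is.na(W)] <- 0  # -Inf - -Inf outside support of all-(-Inf) rows
  W / rowSums(W)
}

#' Aggregate neighbor features with attention weights
#'
#' `h'_i = relu(sum_j alpha_ij h_j)`; output width equals input width.
#'
#' @param H Node feature matrix (n x f).
#' @param attention n x n row-stochastic attention matrix.
#' @return n x f aggregated, activated feature matrix.
#' @export
gat_layer <- function(H, attention) {
  relu(attention %*% H)
}

# Full forward pass through one view's GCN -> GAT -> GCN stack.
# Returns the embedding plus every intermediate needed for backprop.
forward_view <- function(Ahat, X0, support, vp, AX0 = NULL) {
  if (is.null(AX0)) AX0 <- Ahat %*% X0
  Z1 <- sweep(AX0 %*% vp$W1, 2, vp$b1, `+`)
  H1 <- relu(Z1)
  P <- H1 %*% vp$Wt
  M <- tanh(sweep(P, 2, vp$bt, `+`))
  E <- tcrossprod(M, P)
  E[!support] <- -Inf
  alpha <- row_softmax(E)
  Hagg <- alpha %*% H1
  H2 <- relu(Hagg)
  AH2 <- Ahat %*% H2
  Z3 <- sweep(AH2 %*% vp$W2, 2, vp$b2, `+`)
  H3 <- relu(Z3)
  list(AX0 = AX0, Z1 = Z1, H1 = H1, P = P, M = M, alpha = alpha,
       Hagg = Hagg, H2 = H2, AH2 = AH2, Z3 = Z3, H3 = H3)
}

#' Encode one view into latent node embeddings
#'
#' Runs the GCN -> GAT -> GCN stack on a view. For the heterogeneous view
#' the miRNA rows are dropped from the output so both views yield one row
#' per lncRNA followed by one row per disease.
#'
#' @param Ahat Normalized propagation matrix.
#' @param X0 Initial node features (the view's adjacency).
#' @param support Logical neighborhood mask (`(A + I) > 0`).
#' @param view_params The view's parameter list from [init_model_params()]
#'   (elements `W1`, `b1`, `Wt`, `bt`, `W2`, `b2`).
#' @param keep_rows Optional integer vector of output rows to retain (used
#'   to drop miRNA rows from the heterogeneous view).
#' @return Embedding matrix, one row per retained node.
#' @export
encode_view <- function(Ahat, X0, support, view_params, keep_rows = NULL) {
  H3 <- forward_view(Ahat, X0, support, view_params)$H3
  if (!is.null(keep_rows)) H3 <- H3[keep_rows, , drop = FALSE]
  H3
}

#' Concatenate per-view embeddings and split into entity blocks
#'
#' Column-binds the two views' embeddings (both have `nl + nd` rows) and
#' splits the result into the lncRNA block `Yl` (first `nl` rows) and the
#' disease block `Yd` (last `nd` rows).
#'
#' @param H3_net1,H3_net2 Embedding matrices with `nl + nd` rows each;
#'   either may be `NULL` for the single-view ablations.
#' @param nl Number of lncRNA rows.
#' @return List with `Y`, `Yl`, `Yd`.
#' @export
concat_embeddings <- function(H3_net1, H3_net2, nl) {
  mats <- Filter(Negate(is.null), list(H3_net1, H3_net2))
  if (!length(mats)) stop("no embeddings to concatenate", call. = FALSE)
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1) {
    stop("embedding row counts differ: ", paste(nr, collapse = " vs "),
         call. = FALSE)
  }
  Y <- do.call(cbind, mats)
  list(Y = Y,
       Yl = Y[seq_len(nl), , drop = FALSE],
       Yd = Y[(nl + 1):nrow(Y), , drop = FALSE])
}
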