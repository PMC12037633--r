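#' Bilinear decoder
#'
#' Reconstructs the association score matrix from the concatenated
#' embeddings: `LD' = (Yl %*% Wl) %*% t(Yd %*% Wd)`. Higher scores mean
#' stronger predicted association; scores are left unsquashed because the
#' ranking metrics (AUC, AUPR, top-k) are invariant to monotone transforms.
#'
#' @param Yl,Yd lncRNA and disease embedding blocks (nl x w, nd x w).
#' @param Wl,Wd Decoder projections (w x r).
#' @return nl x nd score matrix.
#' @export
bilinear_decode <- function(Yl, Yd, Wl, Wd) {
  if (ncol(Yl) != nrow(Wl) || ncol(Yd) != nrow(Wd)) {
    stop("decoder shape mismatch: embeddings have width ", ncol(Yl),
         "/", ncol(Yd), " but maps expect ", nrow(Wl), "/", nrow(Wd),
         call. = FALSE)
  }
  tcrossprod(Yl %*% Wl, Yd %*% Wd)
}

#' Training masks for the cost-sensitive loss
#'
#' Splits all lncRNA-disease pairs into training positives (`omega_P`),
#' training negatives (`omega_N`) and excluded pairs (typically the test
#' fold, which belongs to neither mask and contributes nothing to the
#' loss).
#'
#' @param LD Binary association matrix (the *unmasked* labels).
#' @param test_mask Optional logical matrix marking pairs to exclude.
#' @return List of class `lnclink_masks` with binary matrices `omega_P`
#'   and `omega_N`.
#' @export
make_mask_pair <- function(LD, test_mask = NULL) {
  if (is.null(test_mask)) test_mask <- matrix(FALSE, nrow(LD), ncol(LD))
  omega_P <- (LD == 1) & !test_mask
  omega_N <- (LD == 0) & !test_mask
  structure(list(omega_P = omega_P * 1, omega_N = omega_N * 1),
            class = "lnclink_masks")
}

#' Class-balance parameter of the cost-sensitive loss
#'
#' `alpha = sum(omega_P) / (sum(omega_P) + sum(omega_N))`: the fraction of
#' training pairs that are positive. With the published dataset's counts
#' (2,697 positives, 96,183 negatives) this is about 0.0273, i.e. as
#' defined the positive class receives the numerically *smaller* weight;
#' the `alpha_mode = "complement"` config switch applies `1 - alpha` to
#' positives instead. See the vignette.
#'
#' @param masks An `lnclink_masks` pair.
#' @return A scalar in (0, 1).
#' @export
balance_alpha <- function(masks) {
  np <- sum(masks$omega_P)
  nn <- sum(masks$omega_N)
  if (np == 0 || nn == 0) {
    stop("balance_alpha needs at least one positive and one negative",
         call. = FALSE)
  }
  np / (np + nn)
}

# positive/negative weights implied by alpha and the alpha_mode switch
loss_weights <- function(alpha, alpha_mode) {
  switch(alpha_mode,
         literal = c(pos = alpha, neg = 1 - alpha),
         complement = c(pos = 1 - alpha, neg = alpha),
         stop("unknown alpha_mode: ", alpha_mode, call. = FALSE))
}

#' Cost-sensitive masked reconstruction loss
#'
#' `alpha * ||omega_P o (LD' - LD)||_F^2 +
#'  (1 - alpha) * ||omega_N o (LD' - LD)||_F^2`
#' where `o` is the entrywise product. Pairs outside both masks (the test
#' fold) contribute exactly zero regardless of their score.
#'
#' @param LD_prime Predicted score matrix.
#' @param LD Binary label matrix.
#' @param masks An `lnclink_masks` pair.
#' @param alpha Class-balance parameter (weight on the positive term).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(LD_prime, LD, masks, alpha) {
  stopifnot(identical(dim(LD_prime), dim(LD)))
  diff2 <- (LD_prime - LD)^2
  alpha * sum(masks$omega_P * diff2) + (1 - alpha) * sum(masks$omega_N * diff2)
}

#' Squared-norm regularization of the trainable parameters
#'
#' Sum of squared Frobenius norms of the decoder map `Wd`, every
#' graph-convolution weight, every attention weight, and all offset
#' vectors. The second decoder map `Wl` is deliberately not penalized,
#' matching the published regularizer.
#'
#' @param params An `lnclink_params` object.
#' @return Non-negative scalar.
#' @export
regularization_loss <- function(params) {
  total <- sum(params$Wd^2)
  for (v in intersect(c("net1", "net2"), names(params))) {
    vp <- params[[v]]
    total <- total + sum(vp$W1^2) + sum(vp$W2^2) + sum(vp$Wt^2) +
      sum(vp$b1^2) + sum(vp$b2^2) + sum(vp$bt^2)
  }
  total
}

#' Total training loss
#'
#' `L_total = L_rec + gamma_reg * L_reg`.
#'
#' @param rec Reconstruction loss value.
#' @param reg Regularization loss value.
#' @param gamma_reg Regularization weight.
#' @return Scalar.
#' @export
total_loss <- function(rec, reg, gamma_reg) {
  rec + gamma_reg * reg
}

# rows of a view's output embedding that correspond to lncRNAs + diseases
keep_rows_for <- function(view_name, views) {
  if (view_name == "net1") {
    c(seq_len(views$nl), views$nl + views$nm + seq_len(views$nd))
  } else {
    NULL
  }
}

active_views <- function(views) {
  switch(views$view, both = c("net1", "net2"), net1 = "net1", net2 = "net2")
}

view_inputs <- function(views, v) {
  if (v == "net1") {
    list(Ahat = views$Ahat1, X0 = views$X1, support = views$support1)
  } else {
    list(Ahat = views$Ahat2, X0 = views$F1, support = views$support2)
  }
}

# full forward pass; caches per-view intermediates for backprop
forward_model <- function(views, params, precomp = NULL) {
  caches <- list()
  embeds <- list()
  for (v in active_views(views)) {
    vi <- view_inputs(views, v)
    fv <- forward_view(vi$Ahat, vi$X0, vi$support, params[[v]],
                       AX0 = precomp[[v]])
    caches[[v]] <- fv
    keep <- keep_rows_for(v, views)
    embeds[[v]] <- if (is.null(keep)) fv$H3 else fv$H3[keep, , drop = FALSE]
  }
  cc <- concat_embeddings(embeds$net1, embeds$net2, views$nl)
  scores <- bilinear_decode(cc$Yl, cc$Yd, params$Wl, params$Wd)
  list(caches = caches, Yl = cc$Yl, Yd = cc$Yd, scores = scores)
}

#' Loss and analytic gradients of the full model
#'
#' Computes the total loss and its exact gradient with respect to every
#' trainable parameter by reverse-mode differentiation through the decoder,
#' the attention softmax and both graph-convolution layers. This is the
#' quantity the Adam loop descends; it is exposed so the gradients can be
#' verified against finite differences.
#'
#' @param views An `lnclink_views`.
#' @param params An `lnclink_params`.
#' @param LD Binary label matrix.
#' @param masks An `lnclink_masks` pair.
#' @param config An `lnclink_config`.
#' @param precomp Optional per-view precomputed `Ahat %*% X0` products
#'   (they are constant across epochs).
#' @return List with `loss`, `rec`, `reg`, `scores` and `grads` (same
#'   structure as `params`).
#' @export
model_loss_and_gradients <- function(views, params, LD, masks, config,
                                     precomp = NULL) {
  fw <- forward_model(views, params, precomp)
  alpha <- balance_alpha(masks)
  w <- loss_weights(alpha, config$alpha_mode)
  diff <- fw$scores - LD
  Wmat <- w["pos"] * masks$omega_P + w["neg"] * masks$omega_N
  rec <- sum(Wmat * diff^2)
  reg <- regularization_loss(params)
  g <- config$gamma_reg

  grads <- list()
  # decoder
  G <- 2 * Wmat * diff                    # dL/dLD'
  U <- fw$Yl %*% params$Wl
  V <- fw$Yd %*% params$Wd
  dU <- G %*% V
  dV <- crossprod(G, U)
  grads$Wl <- crossprod(fw$Yl, dU)        # Wl not regularized
  grads$Wd <- crossprod(fw$Yd, dV) + 2 * g * params$Wd
  dYl <- tcrossprod(dU, params$Wl)
  dYd <- tcrossprod(dV, params$Wd)
  dY <- rbind(dYl, dYd)

  # split concatenated gradient back into per-view column blocks
  col_at <- 0L
  for (v in active_views(views)) {
    vp <- params[[v]]
    fv <- fw$caches[[v]]
    wv <- ncol(fv$H3)
    dH3ld <- dY[, col_at + seq_len(wv), drop = FALSE]
    col_at <- col_at + wv
    keep <- keep_rows_for(v, views)
    if (is.null(keep)) {
      dH3 <- dH3ld
    } else {
      dH3 <- matrix(0, nrow(fv$H3), wv)
      dH3[keep, ] <- dH3ld
    }
    # second GCN
    dZ3 <- dH3 * (fv$Z3 > 0)
    gW2 <- crossprod(fv$AH2, dZ3) + 2 * g * vp$W2
    gb2 <- colSums(dZ3) + 2 * g * vp$b2
    dH2 <- views_ahat(views, v) %*% tcrossprod(dZ3, vp$W2)
    # attention aggregation
    dHagg <- dH2 * (fv$Hagg > 0)
    dalpha <- tcrossprod(dHagg, fv$H1)
    srow <- rowSums(dalpha * fv$alpha)
    dE <- fv$alpha * (dalpha - srow)
    dM <- dE %*% fv$P
    dP <- crossprod(dE, fv$M)               # from E = M P'
    dS <- dM * (1 - fv$M^2)
    gbt <- colSums(dS) + 2 * g * vp$bt
    dP <- dP + dS                           # S = P + 1 bt'
    gWt <- crossprod(fv$H1, dP) + 2 * g * vp$Wt
    dH1 <- tcrossprod(dP, vp$Wt) + crossprod(fv$alpha, dHagg)
    # first GCN
    dZ1 <- dH1 * (fv$Z1 > 0)
    gW1 <- crossprod(fv$AX0, dZ1) + 2 * g * vp$W1
    gb1 <- colSums(dZ1) + 2 * g * vp$b1
    grads[[v]] <- list(W1 = gW1, b1 = gb1, Wt = gWt, bt = gbt,
                       W2 = gW2, b2 = gb2)
  }
  grads <- grads[names(params)]  # mirror the parameter structure exactly
  list(loss = total_loss(rec, reg, g), rec = rec, reg = reg,
       scores = fw$scores, grads = grads)
}

views_ahat <- function(views, v) {
  if (v == "net1") views$Ahat1 else views$Ahat2
}

# recursive Adam state/update over the nested parameter list
adam_init <- function(params) {
  rapply(unclass(params), function(p) p * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_one <- function(p, gr, mm, vv) {
    mm <- beta1 * mm + (1 - beta1) * gr
    vv <- beta2 * vv + (1 - beta2) * gr^2
    mhat <- mm / (1 - beta1^t)
    vhat <- vv / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  walk <- function(p, gr, mm, vv) {
    if (is.list(p)) {
      out <- Map(walk, p, gr[names(p)], mm[names(p)], vv[names(p)])
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      step_one(p, gr, mm, vv)
    }
  }
  walk(unclass(params), grads, m, v)
}

#' Train the multiview graph autoencoder
#'
#' Full-batch gradient descent with Adam on the cost-sensitive
#' reconstruction loss plus the squared-norm regularizer. The whole graph
#' is one training sample, so every epoch is one forward/backward pass.
#'
#' @param views An `lnclink_views` built from the (fold-masked) dataset.
#' @param LD Binary label matrix used in the loss. Must itself be
#'   fold-masked during cross-validation.
#' @param masks An `lnclink_masks` pair.
#' @param config An `lnclink_config`.
#' @param seed Seed for parameter initialization; defaults to
#'   `config$seed`.
#' @return An object of class `lnclink_fit` with elements `params`,
#'   `scores` (nl x nd), `trace` (tibble: epoch, loss, rec, reg), `config`,
#'   `view`.
#' @examples
#' spec <- synthetic_spec(nl = 20, nd = 15, nm = 5, n_blocks = 2,
#'                        density = 0.2, seed = 1)
#' ds <- generate_synthetic(spec)$dataset
#' cfg <- lnclink_config(hidden = 16, l1 = 8, l2 = 8, att_dim = 8, r = 4,
#'                       epochs = 20)
#' views <- build_views(ds, cfg)
#' fit <- train_model(views, ds$LD, make_mask_pair(ds$LD), cfg)
#' tail(fit$trace)
#' @export
train_model <- function(views, LD, masks, config, seed = config$seed) {
  params <- init_model_params(views, config, seed)
  m <- adam_init(params)
  v <- adam_init(params)
  precomp <- list()
  for (vw in active_views(views)) {
    vi <- view_inputs(views, vw)
    precomp[[vw]] <- vi$Ahat %*% vi$X0
  }
  n_ep <- config$epochs
  trace <- matrix(NA_real_, n_ep, 3,
                  dimnames = list(NULL, c("loss", "rec", "reg")))
  for (ep in seq_len(n_ep)) {
    lg <- model_loss_and_gradients(views, params, LD, masks, config, precomp)
    if (!is.finite(lg$loss)) {
      stop("non-finite loss at epoch ", ep,
           " (try lowering learning_rate)", call. = FALSE)
    }
    trace[ep, ] <- c(lg$loss, lg$rec, lg$reg)
    upd <- adam_step(params, lg$grads, m, v, ep, config$learning_rate)
    params <- structure(upd$p, class = "lnclink_params")
    m <- upd$m
    v <- upd$v
  }
  final <- forward_model(views, params, precomp)
  scores <- final$scores
  dimnames(scores) <- dimnames(LD)
  structure(
    list(params = params, scores = scores,
         trace = tibble::tibble(epoch = seq_len(n_ep),
                                loss = trace[, "loss"],
                                rec = trace[, "rec"],
                                reg = trace[, "reg"]),
         config = config, view = views$view),
    class = "lnclink_fit"
  )
}

#' @export
print.lnclink_fit <- function(x, ...) {
  cat(sprintf("<lnclink_fit> view = %s; %d epochs; final loss %.4g\n",
              x$view, nrow(x$trace), x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' Export a fitted score matrix as a tidy table
#'
#' @param x An `lnclink_fit`.
#' @param LD Optional binary label matrix; adds a `known` column.
#' @param ... Unused.
#' @return A tibble: `lncrna`, `disease`, `score` (and `known`).
#' @method tidy lnclink_fit
#' @export
tidy.lnclink_fit <- function(x, LD = NULL, ...) {
  s <- x$scores
  out <- tibble::tibble(
    lncrna = rep(rownames(s) %||% as.character(seq_len(nrow(s))),
                 times = ncol(s)),
    disease = rep(colnames(s) %||% as.character(seq_len(ncol(s))),
                  each = nrow(s)),
    score = as.vector(s)
  )
  if (!is.null(LD)) out$known <- as.integer(as.vector(LD))
  out
}

#' @method glance lnclink_fit
#' @export
glance.lnclink_fit <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(view = x$view, epochs = n,
                 initial_loss = x$trace$loss[1],
                 final_loss = x$trace$loss[n],
                 final_rec = x$trace$rec[n],
                 final_reg = x$trace$reg[n])
}

#' Plot a training loss trace
#'
#' @param object An `lnclink_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnclink_fit
#' @export
autoplot.lnclink_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
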