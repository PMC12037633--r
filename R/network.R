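#' Build the association view (net2)
#'
#' The association view is a single weighted graph over the `nl + nd`
#' lncRNA and disease nodes whose adjacency doubles as the initial feature
#' matrix:
#' `A2 = F1 = [[LS, LD], [LD', DS]]`.
#' Row i < nl is the feature vector of lncRNA i (its similarity profile
#' followed by its disease association profile); row nl + j is the feature
#' vector of disease j.
#'
#' @param bundle An `lnclink_bundle`.
#' @param LD Binary nl x nd association matrix (fold-masked during CV).
#' @return List with `A2` and `F1` (identical matrices).
#' @export
build_association_view <- function(bundle, LD) {
  LS <- bundle$LS; DS <- bundle$DS
  if (nrow(LS) != nrow(LD) || nrow(DS) != ncol(LD)) {
    stop("shape mismatch: LS is ", nrow(LS), "x", ncol(LS),
         ", DS is ", nrow(DS), "x", ncol(DS),
         ", LD is ", nrow(LD), "x", ncol(LD), call. = FALSE)
  }
  A2 <- rbind(cbind(LS, LD), cbind(t(LD), DS))
  ids <- c(rownames(LD), colnames(LD))
  dimnames(A2) <- list(ids, ids)
  list(A2 = A2, F1 = A2)
}

#' Build the heterogeneous view (net1)
#'
#' Three node layers ordered (lncRNAs, miRNAs, diseases):
#' `A1 = [[LS, LM, LD], [LM', I, 0], [LD', 0, DS]]`.
#' miRNA-miRNA edges are self-loops only and miRNA-disease edges are absent;
#' the layer couples lncRNAs through shared miRNA interactions. Features
#' again equal the adjacency (`X1 = A1`), extending the association view's
#' features-equal-adjacency convention.
#'
#' @param bundle An `lnclink_bundle`.
#' @param LD Binary nl x nd association matrix.
#' @param LM Binary nl x nm association matrix (nm may be 0).
#' @return List with `A1` and `X1` (identical matrices).
#' @export
build_heterogeneous_view <- function(bundle, LD, LM) {
  LS <- bundle$LS; DS <- bundle$DS
  nl <- nrow(LD); nd <- ncol(LD); nm <- ncol(LM)
  if (nrow(LS) != nl || nrow(DS) != nd || nrow(LM) != nl) {
    stop("shape mismatch assembling heterogeneous view", call. = FALSE)
  }
  A1 <- rbind(
    cbind(LS, LM, LD),
    cbind(t(LM), diag(nrow = nm), matrix(0, nm, nd)),
    cbind(t(LD), matrix(0, nd, nm), DS)
  )
  ids <- c(rownames(LD), colnames(LM), colnames(LD))
  dimnames(A1) <- list(ids, ids)
  list(A1 = A1, X1 = A1)
}

#' Symmetrically normalized propagation matrix
#'
#' Adds self-loops and normalizes:
#' `Ahat = Dtilde^(-1/2) (A + I) Dtilde^(-1/2)` with
#' `Dtilde_ii = sum_j (A + I)_ij`. The result is symmetric, its eigenvalues
#' lie in \[-1, 1\], and `Dtilde^(1/2) 1` is an eigenvector with eigenvalue
#' 1.
#'
#' @param A Square non-negative adjacency matrix.
#' @return The propagation matrix, same shape as `A`.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  if (any(A < 0)) stop("adjacency has negative entries", call. = FALSE)
  At <- A + diag(nrow = nrow(A))
  d <- rowSums(At)
  inv_sqrt <- 1 / sqrt(d)  # d >= 1 thanks to self-loops
  Ahat <- At * tcrossprod(inv_sqrt)
  (Ahat + t(Ahat)) / 2
}

#' Assemble both views with their propagation matrices
#'
#' Convenience wrapper producing everything the encoder needs: both
#' adjacencies, both feature matrices, both normalized propagation matrices,
#' and the neighborhood supports (`(A + I) > 0`) used by the attention
#' layer.
#'
#' @param dataset An `lnclink_dataset` (fold-masked during CV).
#' @param config An `lnclink_config`.
#' @param semantic_DS Optional precomputed disease semantic similarity.
#' @param view `"both"`, `"net1"` or `"net2"`; ablations skip the unused
#'   view's construction entirely.
#' @return An object of class `lnclink_views`.
#' @export
build_views <- function(dataset, config = lnclink_config(),
                        semantic_DS = NULL, view = c("both", "net1", "net2")) {
  view <- match.arg(view)
  bundle <- build_similarity_bundle(dataset, config, semantic_DS)
  nl <- nrow(dataset$LD); nd <- ncol(dataset$LD); nm <- ncol(dataset$LM)
  out <- list(nl = nl, nd = nd, nm = nm, view = view, bundle = bundle)
  if (view %in% c("both", "net2")) {
    v2 <- build_association_view(bundle, dataset$LD)
    out$A2 <- v2$A2
    out$F1 <- v2$F1
    out$Ahat2 <- normalize_adjacency(v2$A2)
    out$support2 <- (v2$A2 + diag(nrow = nrow(v2$A2))) > 0
  }
  if (view %in% c("both", "net1")) {
    v1 <- build_heterogeneous_view(bundle, dataset$LD, dataset$LM)
    out$A1 <- v1$A1
    out$X1 <- v1$X1
    out$Ahat1 <- normalize_adjacency(v1$A1)
    out$support1 <- (v1$A1 + diag(nrow = nrow(v1$A1))) > 0
  }
  structure(out, class = "lnclink_views")
}

#' @export
print.lnclink_views <- function(x, ...) {
  cat(sprintf("<lnclink_views> view = %s; nl = %d, nm = %d, nd = %d\n",
              x$view, x$nl, x$nm, x$nd))
  invisible(x)
}
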