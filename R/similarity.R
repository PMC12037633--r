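#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between binary association profiles:
#' `K(i, j) = exp(-gamma * ||row_i - row_j||^2)` with the bandwidth
#' normalized by the mean squared profile norm,
#' `gamma = bandwidth_factor / mean_i(||row_i||^2)`. This is the standard
#' interaction-profile kernel used throughout the lncRNA/miRNA-disease
#' association literature.
#'
#' @param profiles n x m binary matrix; row i is entity i's association
#'   profile.
#' @param bandwidth_factor Positive scalar scaling the kernel width.
#' @return n x n symmetric matrix with unit diagonal, entries in (0, 1].
#' @examples
#' gip_kernel(rbind(c(1, 0), c(0, 1)))  # off-diagonal exp(-2)
#' @export
gip_kernel <- function(profiles, bandwidth_factor = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(is.numeric(bandwidth_factor), bandwidth_factor > 0)
  sq_norms <- rowSums(profiles^2)
  mean_sq <- mean(sq_norms)
  if (mean_sq == 0) {
    stop("all profiles are zero: GIP bandwidth undefined", call. = FALSE)
  }
  gamma <- bandwidth_factor / mean_sq
  # ||x_i - x_j||^2 = ||x_i||^2 + ||x_j||^2 - 2 <x_i, x_j>
  d2 <- outer(sq_norms, sq_norms, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # clamp tiny negatives from cancellation
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}

#' Cosine similarity between profile rows
#'
#' `C(i, j) = <row_i, row_j> / (||row_i|| ||row_j||)`. Rows with zero norm
#' have similarity 0 against every row, including themselves, so entities
#' with no recorded associations contribute no spurious similarity.
#'
#' @param profiles n x m numeric matrix.
#' @return n x n symmetric matrix with entries in \[0, 1\] for non-negative
#'   profiles.
#' @export
cosine_similarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  norms <- sqrt(rowSums(profiles^2))
  inv <- ifelse(norms > 0, 1 / norms, 0)
  C <- tcrossprod(profiles * inv)  # rows scaled, then gram matrix
  C <- (C + t(C)) / 2
  nz <- norms > 0
  diag(C)[nz] <- 1
  diag(C)[!nz] <- 0
  dimnames(C) <- list(rownames(profiles), rownames(profiles))
  C
}

#' Fuse two similarity matrices by weighted sum
#'
#' `S = w_gip * K + w_cos * C`, clipped to \[0, 1\]. With weights summing to
#' 1 and inputs in \[0, 1\] the combination is already in range and clipping
#' is a no-op.
#'
#' @param K,C Same-shape similarity matrices.
#' @param w_gip,w_cos Fusion weights.
#' @return Fused similarity matrix.
#' @export
fuse_similarities <- function(K, C, w_gip, w_cos) {
  if (!identical(dim(K), dim(C))) {
    stop("cannot fuse similarities of different shapes: ",
         paste(dim(K), collapse = "x"), " vs ",
         paste(dim(C), collapse = "x"), call. = FALSE)
  }
  S <- w_gip * K + w_cos * C
  S[S < 0] <- 0
  S[S > 1] <- 1
  S
}

#' Build the fused lncRNA and disease similarity matrices
#'
#' lncRNA similarity LS fuses the GIP kernel and cosine similarity of the
#' lncRNA association profiles (rows of LD) with weights `alpha1`/`alpha2`;
#' disease similarity DS fuses the GIP kernel of disease profiles (columns
#' of LD) with either a supplied precomputed semantic similarity or, by
#' default, the cosine similarity of disease profiles, with weights
#' `beta1`/`beta2`.
#'
#' @param dataset An `lnclink_dataset`. `LD` is the profile source; pass a
#'   fold-masked dataset during cross-validation so held-out associations
#'   never leak into the similarities.
#' @param config An `lnclink_config`.
#' @param semantic_DS Optional nd x nd precomputed disease semantic
#'   similarity, aligned to `dataset$disease_ids`.
#' @return An object of class `lnclink_bundle` with elements `LS` (nl x nl)
#'   and `DS` (nd x nd).
#' @export
build_similarity_bundle <- function(dataset, config = lnclink_config(),
                                    semantic_DS = NULL) {
  stopifnot(inherits(dataset, "lnclink_dataset"))
  LD <- dataset$LD
  LS <- fuse_similarities(gip_kernel(LD, config$gamma_l_prime),
                          cosine_similarity(LD),
                          config$alpha1, config$alpha2)
  d_profiles <- t(LD)
  d_second <- if (is.null(semantic_DS)) {
    cosine_similarity(d_profiles)
  } else {
    semantic_DS <- as.matrix(semantic_DS)
    nd <- ncol(LD)
    if (!identical(dim(semantic_DS), c(nd, nd))) {
      stop("semantic_DS must be ", nd, "x", nd, ", got ",
           paste(dim(semantic_DS), collapse = "x"), call. = FALSE)
    }
    if (!is.null(rownames(semantic_DS)) &&
        !identical(rownames(semantic_DS), dataset$disease_ids)) {
      stop("semantic_DS row labels do not match disease_ids", call. = FALSE)
    }
    semantic_DS
  }
  DS <- fuse_similarities(gip_kernel(d_profiles, config$gamma_d),
                          d_second, config$beta1, config$beta2)
  structure(list(LS = LS, DS = DS), class = "lnclink_bundle")
}

#' @export
print.lnclink_bundle <- function(x, ...) {
  cat(sprintf("<lnclink_bundle> LS %dx%d, DS %dx%d\n",
              nrow(x$LS), ncol(x$LS), nrow(x$DS), ncol(x$DS)))
  invisible(x)
}
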