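#' Specification of a synthetic association dataset
#'
#' Describes a planted-block generative model at the shape class of real
#' lncRNA-disease compendia: lncRNAs, miRNAs and diseases are partitioned
#' into co-modules, within-module pairs associate with high probability and
#' cross-module pairs with low probability (one tenth of the within rate),
#' calibrated so the overall association density hits the target; a small
#' fraction of entries is then flipped as noise.
#'
#' @param nl,nm,nd Numbers of lncRNAs, miRNAs and diseases.
#' @param n_blocks Number of planted co-modules.
#' @param density Target association density in \[0, 1\].
#' @param noise_rate Fraction of entries flipped after planting, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return An object of class `lnclink_synth_spec`.
#' @export
synthetic_spec <- function(nl = 60L, nd = 80L, nm = 20L, n_blocks = 4L,
                           density = 0.05, noise_rate = 0.02, seed = 0L) {
  spec <- list(nl = as.integer(nl), nd = as.integer(nd), nm = as.integer(nm),
               n_blocks = as.integer(n_blocks), density = density,
               noise_rate = noise_rate, seed = as.integer(seed))
  with(spec, {
    if (nl <= 0 || nd <= 0 || nm < 0 || n_blocks <= 0) {
      stop("entity counts must be positive (nm may be 0)", call. = FALSE)
    }
    if (density < 0 || density > 1 || noise_rate < 0 || noise_rate > 1) {
      stop("density and noise_rate must lie in [0, 1]", call. = FALSE)
    }
    if (n_blocks > min(nl, nd)) {
      stop("more blocks than lncRNAs or diseases", call. = FALSE)
    }
  })
  structure(spec, class = "lnclink_synth_spec")
}

#' Generate a synthetic dataset with planted low-rank block structure
#'
#' Entities are dealt into `n_blocks` balanced random modules. Each entity
#' also receives a multiplicative log-normal propensity (sdlog 1.25),
#' emulating the heavy-tailed degree distributions of real association
#' compendia, where a few hub lncRNAs carry dozens of associations and
#' most carry one or two. The association probability of a pair is
#' proportional to the product of the two propensities times a block
#' factor (1 within modules, 1/10 across), scaled so the expected overall
#' density hits the target; the matrix is therefore rank-one within and
#' across the block pattern. Bernoulli sampling realizes the matrix, after
#' which a fraction `noise_rate` of the planted associations is flipped
#' off and the same number of non-associations flipped on (balanced label
#' noise, density-preserving). Everything is driven by `spec$seed`, so
#' equal specs yield identical datasets.
#'
#' @param spec An `lnclink_synth_spec`.
#' @return List with `dataset` (an `lnclink_dataset`), `blocks` (named
#'   list of integer block labels for lncrna / mirna / disease) and
#'   `prob` (the generative lncRNA-disease probability matrix).
#' @examples
#' out <- generate_synthetic(synthetic_spec(nl = 30, nd = 40, nm = 10,
#'                                          n_blocks = 3, seed = 1))
#' out$dataset
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "lnclink_synth_spec"))
  set.seed(spec$seed)
  deal <- function(n) if (n > 0) sample(rep_len(seq_len(spec$n_blocks), n)) else integer(0)
  bl <- deal(spec$nl)
  bm <- deal(spec$nm)
  bd <- deal(spec$nd)
  sdlog <- 1.25  # degree heterogeneity of real compendia
  prop <- function(n) stats::rlnorm(n, 0, sdlog)
  ul <- prop(spec$nl)
  um <- prop(spec$nm)
  ud <- prop(spec$nd)

  plant <- function(brow, bcol, urow, ucol) {
    block <- ifelse(outer(brow, bcol, `==`), 1, 0.1)
    base <- outer(urow, ucol) * block
    if (spec$density == 0) {
      return(list(M = matrix(0, nrow(base), ncol(base)), P = base * 0))
    }
    f <- function(lc) mean(pmin(exp(lc) * base, 1)) - spec$density
    if (f(60) < 0) {
      stop(sprintf("infeasible density %.3g for this block pattern",
                   spec$density), call. = FALSE)
    }
    lc <- stats::uniroot(f, c(-60, 60), tol = 1e-12)$root
    P <- pmin(exp(lc) * base, 1)
    M <- (matrix(runif(length(P)), nrow(P)) < P) * 1
    if (spec$noise_rate > 0) {
      ones <- which(M == 1)
      zeros <- which(M == 0)
      k <- min(round(spec$noise_rate * length(ones)), length(zeros))
      if (k > 0) {
        M[sample(ones, k)] <- 0
        M[sample(zeros, k)] <- 1
      }
    }
    list(M = M, P = P)
  }
  ld <- plant(bl, bd, ul, ud)
  LD <- ld$M
  LM <- if (spec$nm > 0) plant(bl, bm, ul, um)$M else matrix(0, spec$nl, 0)

  pad_ids <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
  }
  lnc <- pad_ids("lnc", spec$nl)
  mir <- pad_ids("mir", spec$nm)
  dis <- pad_ids("dis", spec$nd)
  dataset <- assemble_dataset(LD, LM, lnc, dis, mir)
  list(dataset = dataset,
       blocks = list(lncrna = setNames(bl, lnc),
                     mirna = setNames(bm, mir),
                     disease = setNames(bd, dis)),
       prob = ld$P)
}

#' Write a synthetic dataset to disk in the package's exchange formats
#'
#' Emits the lncRNA-disease and lncRNA-miRNA TSV edge lists consumed by
#' [load_dataset()], plus a ground-truth block table (`blocks.tsv`:
#' entity, type, block).
#'
#' @param out A list from [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_synthetic <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ld_path <- file.path(dir, "lncrna_disease.tsv")
  write_edge_list(out$dataset$LD, ld_path)
  paths <- ld_path
  if (length(out$dataset$mirna_ids)) {
    lm_path <- file.path(dir, "lncrna_mirna.tsv")
    write_edge_list(out$dataset$LM, lm_path)
    paths <- c(paths, lm_path)
  }
  bl <- out$blocks
  block_df <- data.frame(
    entity = c(names(bl$lncrna), names(bl$mirna), names(bl$disease)),
    type = rep(c("lncrna", "mirna", "disease"),
               c(length(bl$lncrna), length(bl$mirna), length(bl$disease))),
    block = c(bl$lncrna, bl$mirna, bl$disease)
  )
  bl_path <- file.path(dir, "blocks.tsv")
  write.table(block_df, bl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, bl_path))
}
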