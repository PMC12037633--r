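#' Model and training configuration
#'
#' Bundles every tunable quantity of the pipeline: similarity fusion weights,
#' kernel bandwidth factors, encoder layer widths, decoder projection width,
#' regularization weight, optimizer settings and the random seed.
#'
#' The similarity fusion weights follow the published setting: the lncRNA
#' similarity is `alpha1 * GIP + alpha2 * cosine` with `alpha1 = 0.1`,
#' `alpha2 = 0.9`, and the disease similarity is `beta1 * GIP + beta2 *
#' cosine-or-semantic` with `beta1 = 0.2`, `beta2 = 0.8`. Both kernel
#' bandwidth factors default to 1 and the semantic decay factor `delta` to
#' 0.5; `delta` is only consumed when an externally computed semantic disease
#' similarity is built with it, the default pipeline carries it unused.
#'
#' @param delta Semantic decay factor for externally computed disease
#'   semantic similarity (unitless, default 0.5). Unused by the default
#'   similarity path.
#' @param gamma_d Disease GIP kernel width factor (default 1).
#' @param gamma_l_prime lncRNA GIP kernel bandwidth factor (default 1).
#' @param alpha1,alpha2 lncRNA similarity fusion weights (GIP, cosine).
#' @param beta1,beta2 Disease similarity fusion weights (GIP, cosine/semantic).
#' @param hidden Width of the first graph-convolution layer in each view.
#' @param l1,l2 Latent embedding widths of the heterogeneous view (net1) and
#'   the association view (net2).
#' @param att_dim Projection width of the attention scoring map.
#' @param r Decoder projection width: both decoder maps send the
#'   `l1 + l2` concatenated embedding to `r` dimensions.
#' @param gamma_reg Weight of the squared-norm regularization term
#'   (must be >= 0).
#' @param learning_rate Adam step size.
#' @param epochs Number of full-batch training epochs.
#' @param seed Integer seed controlling initialization, fold splits and the
#'   synthetic generator.
#' @param classification_threshold Fixed score threshold used when
#'   `threshold_rule = "fixed"`.
#' @param alpha_mode How the class-balance parameter enters the
#'   reconstruction loss: `"literal"` weights positives by
#'   `alpha = P / (P + N)` exactly as defined; `"complement"` weights them by
#'   `1 - alpha`, matching the stated intent of up-weighting the rare
#'   positive class. See the vignette for the discrepancy.
#' @param threshold_rule `"max_f1"` (default) binarizes scores at the
#'   threshold maximizing F1 on the pooled predictions; `"fixed"` uses
#'   `classification_threshold`.
#' @param topk Integer vector of k values for per-disease top-k recall.
#'
#' @return An object of class `lnclink_config` (a named list).
#' @examples
#' cfg <- lnclink_config(epochs = 50)
#' cfg$alpha1 + cfg$alpha2
#' @export
lnclink_config <- function(delta = 0.5,
                           gamma_d = 1,
                           gamma_l_prime = 1,
                           alpha1 = 0.1, alpha2 = 0.9,
                           beta1 = 0.2, beta2 = 0.8,
                           hidden = 128L,
                           l1 = 64L, l2 = 64L,
                           att_dim = 64L,
                           r = 32L,
                           gamma_reg = 1e-2,
                           learning_rate = 0.005,
                           epochs = 400L,
                           seed = 1L,
                           classification_threshold = 0.5,
                           alpha_mode = c("literal", "complement"),
                           threshold_rule = c("max_f1", "fixed"),
                           topk = c(30L, 90L, 150L, 210L)) {
  cfg <- list(
    delta = delta, gamma_d = gamma_d, gamma_l_prime = gamma_l_prime,
    alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
    hidden = as.integer(hidden), l1 = as.integer(l1), l2 = as.integer(l2),
    att_dim = as.integer(att_dim), r = as.integer(r),
    gamma_reg = gamma_reg, learning_rate = learning_rate,
    epochs = as.integer(epochs), seed = as.integer(seed),
    classification_threshold = classification_threshold,
    alpha_mode = match.arg(alpha_mode),
    threshold_rule = match.arg(threshold_rule),
    topk = as.integer(topk)
  )
  class(cfg) <- "lnclink_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  widths <- c(hidden = cfg$hidden, l1 = cfg$l1, l2 = cfg$l2,
              att_dim = cfg$att_dim, r = cfg$r, epochs = cfg$epochs)
  bad <- widths[!is.finite(widths) | widths <= 0 | widths != round(widths)]
  if (length(bad)) {
    stop("config fields must be positive integers: ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.finite(cfg$gamma_reg) || cfg$gamma_reg < 0) {
    stop("gamma_reg must be >= 0", call. = FALSE)
  }
  if (cfg$gamma_d <= 0 || cfg$gamma_l_prime <= 0) {
    stop("kernel bandwidth factors must be positive", call. = FALSE)
  }
  if (abs(cfg$alpha1 + cfg$alpha2 - 1) > 1e-8) {
    warning("alpha1 + alpha2 != 1 (got ", cfg$alpha1 + cfg$alpha2, ")",
            call. = FALSE)
  }
  if (abs(cfg$beta1 + cfg$beta2 - 1) > 1e-8) {
    warning("beta1 + beta2 != 1 (got ", cfg$beta1 + cfg$beta2, ")",
            call. = FALSE)
  }
  cfg
}

#' Read a configuration from a YAML file
#'
#' Keys match the argument names of [lnclink_config()]; unknown keys are an
#' error so typos never pass silently. Keys absent from the file keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return An `lnclink_config` object.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(lnclink_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(lnclink_config, raw)
}

#' @export
print.lnclink_config <- function(x, ...) {
  cat("<lnclink_config>\n")
  cat(sprintf("  similarity: alpha = (%g, %g), beta = (%g, %g), gip factors = (%g, %g)\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2,
              x$gamma_l_prime, x$gamma_d))
  cat(sprintf("  encoder: hidden %d -> attention %d -> (l1, l2) = (%d, %d); decoder r = %d\n",
              x$hidden, x$att_dim, x$l1, x$l2, x$r))
  cat(sprintf("  training: lr %g, epochs %d, gamma_reg %g, alpha_mode %s, seed %d\n",
              x$learning_rate, x$epochs, x$gamma_reg, x$alpha_mode, x$seed))
  invisible(x)
}
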