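#' Rank novel candidate lncRNAs for chosen diseases
#'
#' Trains the model on every known association (nothing held out), then
#' for each queried disease ranks the lncRNAs with no known association by
#' predicted score, descending, and returns the top `top_n`. Known pairs
#' are never returned: the table is a shortlist of novel candidates.
#'
#' @param dataset An `lnclink_dataset`.
#' @param diseases Character vector of disease identifiers to query.
#' @param config An `lnclink_config`.
#' @param top_n Number of candidates to return per disease.
#' @param view Which view(s) to use.
#' @param semantic_DS Optional precomputed disease semantic similarity.
#' @return A tibble: `disease`, `rank`, `lncrna`, `score`; scores are
#'   non-increasing within each disease.
#' @export
predict_candidates <- function(dataset, diseases,
                               config = lnclink_config(), top_n = 20L,
                               view = "both", semantic_DS = NULL) {
  stopifnot(inherits(dataset, "lnclink_dataset"))
  missing_ids <- setdiff(diseases, dataset$disease_ids)
  if (length(missing_ids)) {
    near <- vapply(missing_ids, function(q) {
      d <- utils::adist(q, dataset$disease_ids, ignore.case = TRUE)
      paste(dataset$disease_ids[order(d)][seq_len(min(3, length(d)))],
            collapse = ", ")
    }, character(1))
    stop("unknown disease id(s): ",
         paste(sprintf("'%s' (nearest: %s)", missing_ids, near),
               collapse = "; "), call. = FALSE)
  }
  views <- build_views(dataset, config, semantic_DS, view)
  masks <- make_mask_pair(dataset$LD)
  fit <- train_model(views, dataset$LD, masks, config)
  purrr::map_dfr(diseases, function(d) {
    j <- match(d, dataset$disease_ids)
    cand <- which(dataset$LD[, j] == 0)
    ord <- cand[order(-fit$scores[cand, j], cand)]
    top <- ord[seq_len(min(top_n, length(ord)))]
    tibble::tibble(disease = d, rank = seq_along(top),
                   lncrna = dataset$lncrna_ids[top],
                   score = fit$scores[top, j])
  })
}
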