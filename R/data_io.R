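#' Read a two-column TSV edge list into a binary incidence matrix
#'
#' Each line is `row_id<TAB>col_id`. The returned matrix has one row per
#' distinct row identifier and one column per distinct column identifier,
#' both sorted lexicographically (with `LC_COLLATE = "C"` semantics) so the
#' index order never depends on file row order. An entry is 1 iff the pair
#' occurs at least once; duplicate lines are idempotent.
#'
#' @param path Path to the TSV file.
#' @param row_domain,col_domain Labels used in error messages and as
#'   `dimnames` names (e.g. `"lncrna"`, `"disease"`).
#' @return A binary integer matrix with row/column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("l1\td1", "l2\td2"), tf)
#' load_edge_list(tf, "lncrna", "disease")
#' @export
load_edge_list <- function(path, row_domain = "row", col_domain = "col") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields, got %d",
                 bad[1], path, nfield[bad[1]]), call. = FALSE)
  }
  rows <- vapply(parts, `[[`, character(1), 1L)
  cols <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(rows)) || any(!nzchar(cols))) {
    bad <- which(!nzchar(rows) | !nzchar(cols))[1]
    stop(sprintf("malformed line %d in %s: empty identifier", bad, path),
         call. = FALSE)
  }
  row_ids <- sort_ids(unique(rows))
  col_ids <- sort_ids(unique(cols))
  M <- matrix(0L, length(row_ids), length(col_ids),
              dimnames = setNames(list(row_ids, col_ids),
                                  c(row_domain, col_domain)))
  M[cbind(match(rows, row_ids), match(cols, col_ids))] <- 1L
  M
}

# C-locale lexicographic sort: deterministic across platforms/locales
sort_ids <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

#' Write a binary matrix back out as a TSV edge list
#'
#' Inverse of [load_edge_list()]: one line per 1-entry, rows ordered by
#' (row id, col id). Loading the result reproduces the matrix exactly.
#'
#' @param M Binary matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(M, path) {
  idx <- which(M != 0, arr.ind = TRUE)
  ord <- order(rownames(M)[idx[, 1]], colnames(M)[idx[, 2]], method = "radix")
  idx <- idx[ord, , drop = FALSE]
  writeLines(paste(rownames(M)[idx[, 1]], colnames(M)[idx[, 2]], sep = "\t"),
             path)
  invisible(path)
}

#' Read / write a labeled dense matrix as CSV
#'
#' First row and first column carry labels; values are parsed as numerics.
#' Used for similarity matrices and debug dumps of adjacency blocks.
#'
#' @param path CSV path.
#' @return `read_matrix_csv`: a numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_matrix_csv
#' @param M Numeric matrix with dimnames.
#' @export
write_matrix_csv <- function(M, path) {
  write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Assemble and validate an association dataset
#'
#' Holds the two binary association matrices the model consumes: lncRNA x
#' disease (`LD`) and lncRNA x miRNA (`LM`), together with the identifier
#' vectors defining their row/column order. `LM` may have zero columns, in
#' which case the heterogeneous view degenerates to the association view's
#' node set.
#'
#' @param LD Binary lncRNA x disease matrix.
#' @param LM Binary lncRNA x miRNA matrix sharing `LD`'s row order (or
#'   `NULL` for no miRNA layer).
#' @param lncrna_ids,disease_ids,mirna_ids Identifier character vectors;
#'   taken from dimnames when omitted.
#' @return An object of class `lnclink_dataset`.
#' @examples
#' LD <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2,
#'              dimnames = list(c("l1", "l2", "l3"), c("d1", "d2")))
#' assemble_dataset(LD)
#' @export
assemble_dataset <- function(LD, LM = NULL,
                             lncrna_ids = rownames(LD),
                             disease_ids = colnames(LD),
                             mirna_ids = colnames(LM)) {
  LD <- as.matrix(LD)
  if (is.null(LM)) LM <- matrix(0L, nrow(LD), 0L)
  LM <- as.matrix(LM)
  if (is.null(lncrna_ids)) lncrna_ids <- paste0("l", seq_len(nrow(LD)))
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(ncol(LD)))
  if (is.null(mirna_ids)) mirna_ids <- if (ncol(LM)) paste0("m", seq_len(ncol(LM))) else character(0)

  check_binary <- function(M, label) {
    if (!all(M %in% c(0, 1))) {
      off <- which(!(M %in% c(0, 1)))[1]
      stop(sprintf("%s contains non-binary entry %g", label, M[off]),
           call. = FALSE)
    }
  }
  check_binary(LD, "LD")
  check_binary(LM, "LM")
  if (length(lncrna_ids) != nrow(LD)) {
    stop("lncRNA axis mismatch: ", length(lncrna_ids), " ids vs ",
         nrow(LD), " LD rows", call. = FALSE)
  }
  if (length(disease_ids) != ncol(LD)) {
    stop("disease axis mismatch: ", length(disease_ids), " ids vs ",
         ncol(LD), " LD columns", call. = FALSE)
  }
  if (nrow(LM) != nrow(LD)) {
    stop("lncRNA axis mismatch: LM has ", nrow(LM), " rows but LD has ",
         nrow(LD), call. = FALSE)
  }
  if (length(mirna_ids) != ncol(LM)) {
    stop("miRNA axis mismatch: ", length(mirna_ids), " ids vs ",
         ncol(LM), " LM columns", call. = FALSE)
  }
  for (ids in list(lncrna_ids, disease_ids, mirna_ids)) {
    if (anyDuplicated(ids)) {
      stop("duplicate identifiers: ", ids[duplicated(ids)][1], call. = FALSE)
    }
  }
  storage.mode(LD) <- "double"
  storage.mode(LM) <- "double"
  dimnames(LD) <- list(lncrna = lncrna_ids, disease = disease_ids)
  dimnames(LM) <- list(lncrna = lncrna_ids, mirna = mirna_ids)
  structure(
    list(lncrna_ids = lncrna_ids, disease_ids = disease_ids,
         mirna_ids = mirna_ids, LD = LD, LM = LM),
    class = "lnclink_dataset"
  )
}

#' Load a dataset from edge-list files
#'
#' Reads the lncRNA-disease edge list and (optionally) the lncRNA-miRNA edge
#' list, aligns the miRNA matrix onto the union of lncRNA identifiers seen in
#' either file, and validates the result.
#'
#' @param ld_path TSV edge list of lncRNA-disease associations.
#' @param lm_path Optional TSV edge list of lncRNA-miRNA associations.
#' @return An `lnclink_dataset`.
#' @export
load_dataset <- function(ld_path, lm_path = NULL) {
  LD <- load_edge_list(ld_path, "lncrna", "disease")
  if (is.null(lm_path)) return(assemble_dataset(LD))
  LM_raw <- load_edge_list(lm_path, "lncrna", "mirna")
  lnc_ids <- sort_ids(union(rownames(LD), rownames(LM_raw)))
  expand_rows <- function(M, ids) {
    out <- matrix(0L, length(ids), ncol(M),
                  dimnames = list(ids, colnames(M)))
    out[rownames(M), ] <- M
    out
  }
  assemble_dataset(expand_rows(LD, lnc_ids), expand_rows(LM_raw, lnc_ids))
}

#' Count unscored candidate lncRNA-disease pairs
#'
#' The number of pairs with no known association: `nl * nd - sum(LD)`. These
#' are the pairs the model ranks when proposing novel associations. At the
#' scale of the published dataset (240 lncRNAs, 412 diseases, 2,697 known
#' associations) this is 96,183.
#'
#' @param dataset An `lnclink_dataset`.
#' @return A single non-negative integer.
#' @export
count_candidates <- function(dataset) {
  stopifnot(inherits(dataset, "lnclink_dataset"))
  as.integer(length(dataset$LD) - sum(dataset$LD))
}

#' @export
print.lnclink_dataset <- function(x, ...) {
  cat(sprintf("<lnclink_dataset> %d lncRNAs x %d diseases (%d known associations, %.2f%% density)\n",
              nrow(x$LD), ncol(x$LD), sum(x$LD), 100 * mean(x$LD)))
  if (length(x$mirna_ids)) {
    cat(sprintf("  miRNA layer: %d miRNAs, %d lncRNA-miRNA associations\n",
                ncol(x$LM), sum(x$LM)))
  } else {
    cat("  no miRNA layer\n")
  }
  invisible(x)
}

#' Tidy an association dataset into an edge tibble
#'
#' @param x An `lnclink_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `lncrna`, `disease`, `known` (0/1), one row
#'   per lncRNA-disease pair.
#' @export
tidy.lnclink_dataset <- function(x, ...) {
  tibble::tibble(
    lncrna = rep(x$lncrna_ids, times = length(x$disease_ids)),
    disease = rep(x$disease_ids, each = length(x$lncrna_ids)),
    known = as.integer(as.vector(x$LD))
  )
}
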