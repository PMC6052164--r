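#' Read a delimited feature table into a data matrix
#'
#' Loads a CSV/TSV file with a header row (delimiter auto-detected). An
#' optional label column, named by `labels_col`, is removed from the feature
#' matrix and returned separately for evaluation. Sample identifiers come
#' from a column named `id` if present (also removed from the features),
#' otherwise 0-based row numbers are used.
#'
#' Every remaining cell must be a finite number; a non-numeric or missing
#' cell is a load error naming its row and column.
#'
#' @param path path to a delimited text file (UTF-8, `.` decimal point).
#' @param labels_col optional name of the ground-truth label column.
#' @return list with `values` (numeric matrix), `labels` (vector or NULL),
#'   `ids` (character vector of sample identifiers).
#' @export
read_data_matrix <- function(path, labels_col = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) < 1L || ncol(dt) < 1L) {
    stop(sprintf("input file is empty: %s", path), call. = FALSE)
  }
  ids <- if ("id" %in% names(dt)) {
    v <- as.character(dt[["id"]])
    dt[["id"]] <- NULL
    v
  } else {
    as.character(seq_len(nrow(dt)) - 1L)
  }
  labels <- NULL
  if (!is.null(labels_col)) {
    if (!labels_col %in% names(dt)) {
      stop(sprintf("label column '%s' not found (columns: %s)", labels_col,
                   paste(names(dt), collapse = ", ")), call. = FALSE)
    }
    labels <- dt[[labels_col]]
    dt[[labels_col]] <- NULL
  }
  if (ncol(dt) < 1L) {
    stop("no feature columns left after removing id/label columns",
         call. = FALSE)
  }
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      if (!is.na(bad)) {
        stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                     col[bad], bad, names(dt)[j]), call. = FALSE)
      }
      dt[[j]] <- num
    }
    if (anyNA(dt[[j]]) || !all(is.finite(dt[[j]]))) {
      bad <- which(!is.finite(dt[[j]]))[1L]
      stop(sprintf("missing or non-finite value at row %d, column '%s'",
                   bad, names(dt)[j]), call. = FALSE)
    }
  }
  list(values = as.matrix(dt), labels = labels, ids = ids)
}

# Write an assignment as a two-column CSV: sample id, 0-based cluster label.
write_assignment_csv <- function(ids, labels, path) {
  utils::write.csv(data.frame(id = ids, cluster = labels),
                   path, row.names = FALSE, quote = FALSE)
}

# Serialize an F-score report to a JSON-friendly list.
fscore_as_list <- function(rep) {
  list(macro_f = rep$macro_f,
       matching = rep$matching,
       per_class_f = as.list(rep$per_class_f),
       mapping = lapply(as.list(rep$mapping),
                        function(x) if (is.na(x)) NULL else x),
       class_labels = rep$table$class_labels,
       cluster_labels = rep$table$cluster_labels,
       counts = apply(rep$table$counts, 1L, identity, simplify = FALSE))
}

write_json_ <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
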