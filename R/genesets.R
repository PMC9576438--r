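#' Read a GMT-like gene-set file
#'
#' Each tab-separated row is `set-id <TAB> description <TAB> gene1 <TAB>
#' gene2 ...`. The description column is always present (writers that have
#' nothing to say emit `na`). Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return A named list of character vectors (one per entity), in
#'   lexicographic order of entity identifier, with the descriptions kept
#'   in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_rwrdr("gene-set file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop_rwrdr("empty gene-set file: ", path)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop_rwrdr(sprintf(
      "malformed gene-set row at line %d of %s: need id, description and >= 1 gene",
      data_idx[bad[1L]], path))
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop_rwrdr("duplicate gene-set identifier: ",
               ids[duplicated(ids)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  desc <- vapply(fields, `[[`, character(1L), 2L)
  names(sets) <- ids
  names(desc) <- ids
  ord <- lex_sort(ids)
  structure(sets[ord], descriptions = desc[ord])
}

#' Write a GMT-like gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional named character vector; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  ids <- lex_sort(names(sets))
  lines <- vapply(ids, function(id) {
    d <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a drug-disease association table
#'
#' @param drug,disease character vectors of equal length giving known
#'   (drug, disease) pairs. Duplicates are collapsed.
#' @return A data frame of class `association_table` with character columns
#'   `drug` and `disease`, rows sorted by (drug, disease).
#' @export
association_table <- function(drug = character(), disease = character()) {
  stopifnot(length(drug) == length(disease))
  df <- data.frame(drug = as.character(drug),
                   disease = as.character(disease),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$drug, df$disease, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("association_table", "data.frame")
  df
}

#' Read a drug-disease association table
#'
#' Tab-separated, one `drug-id <TAB> disease-id` pair per row; `#` lines are
#' comments; duplicate pairs are collapsed.
#'
#' @param path file path.
#' @return An [association_table].
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop_rwrdr("association file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) {
    return(association_table())
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop_rwrdr(sprintf(
      "malformed association row at line %d of %s: expected 2 fields, got %d",
      data_idx[bad[1L]], path, lengths(fields)[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  association_table(drug = m[, 1L], disease = m[, 2L])
}

#' Write a drug-disease association table
#'
#' @param assoc an [association_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  lines <- c("#drug\tdisease",
             if (nrow(assoc) > 0L)
               paste(assoc$drug, assoc$disease, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
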