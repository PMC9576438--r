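#' Pearson correlation of two stationary profiles
#'
#' Sample Pearson correlation over all network nodes. Profiles with zero
#' variance are rejected: a convergent restart walk on a connected graph
#' with `r < 1` cannot produce one, so a constant profile signals a
#' upstream problem.
#'
#' @param x,y `rwr_profile` objects or numeric vectors of equal length >= 3.
#' @return A correlation value in `[-1, 1]`.
#' @export
profile_cor <- function(x, y) {
  vx <- if (inherits(x, "rwr_profile")) x$values else as.numeric(x)
  vy <- if (inherits(y, "rwr_profile")) y$values else as.numeric(y)
  stopifnot(length(vx) == length(vy), length(vx) >= 3L)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop_rwrdr("zero variance profile")
  }
  stats::cor(vx, vy, method = "pearson")
}

#' Score every disease-drug pair
#'
#' Pearson correlation over the full cartesian product of disease and drug
#' stationary profiles. Entities with a constant profile are excluded with
#' a warning and listed in the `"excluded"` attribute.
#'
#' @param disease_profiles,drug_profiles named lists of `rwr_profile`
#'   objects (from [propagate_all]).
#' @return A `score_matrix`: numeric matrix, rows = sorted disease ids,
#'   columns = sorted drug ids.
#' @export
score_profiles <- function(disease_profiles, drug_profiles) {
  stopifnot(length(disease_profiles) > 0L, length(drug_profiles) > 0L)
  values <- function(p) if (inherits(p, "rwr_profile")) p$values else as.numeric(p)
  usable <- function(profiles) {
    ids <- lex_sort(names(profiles))
    const <- vapply(ids, function(id) stats::sd(values(profiles[[id]])) == 0,
                    logical(1L))
    if (any(const)) {
      warning("excluding constant profile(s): ",
              paste(ids[const], collapse = ", "))
    }
    ids[!const]
  }
  d_ids <- usable(disease_profiles)
  r_ids <- usable(drug_profiles)
  if (length(d_ids) == 0L || length(r_ids) == 0L) {
    stop_rwrdr("no usable profiles to score")
  }
  D <- vapply(d_ids, function(id) values(disease_profiles[[id]]),
              numeric(length(values(disease_profiles[[d_ids[1L]]]))))
  R <- vapply(r_ids, function(id) values(drug_profiles[[id]]),
              numeric(nrow(D)))
  S <- stats::cor(D, R, method = "pearson")
  dimnames(S) <- list(d_ids, r_ids)
  excluded <- c(setdiff(names(disease_profiles), d_ids),
                setdiff(names(drug_profiles), r_ids))
  structure(S, class = c("score_matrix", class(S)), excluded = excluded)
}

#' Threshold and rank candidate associations
#'
#' Returns every disease-drug pair scoring strictly above `threshold`,
#' flagged as known or novel against the supplied association table, sorted
#' by descending score with ties broken by (disease id, drug id).
#'
#' @param scores a `score_matrix` from [score_profiles].
#' @param threshold correlation cutoff in `(-1, 1)`; the reporting default
#'   used for candidate discovery is 0.8.
#' @param known an [association_table] of already-known pairs.
#' @return A data frame with columns `disease`, `drug`, `score`, `known`
#'   (logical); zero rows allowed.
#' @export
top_associations <- function(scores, threshold = 0.8,
                             known = association_table()) {
  stopifnot(threshold > -1, threshold < 1)
  idx <- which(scores > threshold, arr.ind = TRUE)
  out <- data.frame(
    disease = rownames(scores)[idx[, 1L]],
    drug    = colnames(scores)[idx[, 2L]],
    score   = scores[idx],
    stringsAsFactors = FALSE)
  key <- paste(out$drug, out$disease, sep = "\r")
  known_key <- paste(known$drug, known$disease, sep = "\r")
  out$known <- key %in% known_key
  out <- out[order(-out$score, out$disease, out$drug,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a score matrix as a long-format TSV
#'
#' One `disease <TAB> drug <TAB> pearson <TAB> known` row per pair.
#'
#' @param scores a `score_matrix`.
#' @param path output file path.
#' @param known an [association_table] used to fill the `known` flag.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, known = association_table()) {
  known_key <- paste(known$drug, known$disease, sep = "\r")
  lines <- c("#disease\tdrug\tpearson\tknown")
  for (d in rownames(scores)) {
    for (r in colnames(scores)) {
      flag <- paste(r, d, sep = "\r") %in% known_key
      lines <- c(lines, paste(d, r, fmt_num(scores[d, r]),
                              tolower(flag), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
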