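#' Split associations into cross-validation folds
#'
#' Uniform random partition of the association pairs into `k` folds whose
#' sizes differ by at most one, reproducible given `rng_seed`.
#'
#' @param assoc an [association_table] with at least `k` rows.
#' @param k number of folds, >= 2.
#' @param rng_seed integer seed.
#' @return An integer vector of fold labels (1..k), one per row of `assoc`.
#' @export
split_folds <- function(assoc, k, rng_seed) {
  n <- nrow(assoc)
  if (k < 2L) stop_rwrdr("k must be >= 2")
  if (n < k) stop_rwrdr("fewer association pairs (", n, ") than folds (", k, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  sample(rep_len(seq_len(k), n))
}

# save/restore the global RNG state so package RNG use never perturbs the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, with ties counted one half. Equal to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores_pos,scores_neg non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores_pos, scores_neg) {
  np <- length(scores_pos)
  nn <- length(scores_neg)
  if (np == 0L || nn == 0L) {
    stop_rwrdr("both positive and negative score sets must be non-empty")
  }
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# pair keys used to match (drug, disease) pairs against score-matrix cells
pair_key <- function(drug, disease) paste(drug, disease, sep = "\r")

# flatten a score matrix into a named vector keyed by pair_key
score_vector <- function(scores) {
  keys <- outer(colnames(scores), rownames(scores), pair_key)
  stats::setNames(as.numeric(t(scores)), as.vector(keys))
}

#' Unsupervised independent validation AUC
#'
#' Builds unaugmented direct seeds for every disease and drug (no
#' association information enters the model), propagates, scores all pairs,
#' and computes one global AUC with the known associations as positives and
#' every other disease-drug pair as a negative.
#'
#' @param net a [gene_network] (connected; see [largest_component]).
#' @param disease_sets,drug_sets named lists of gene sets.
#' @param assoc an [association_table] of known (positive) pairs.
#' @param cfg a [walk_config].
#' @return A single AUC value.
#' @export
independent_validation <- function(net, disease_sets, drug_sets, assoc,
                                   cfg = walk_config()) {
  A_prime <- transition_matrix(net)
  no_sup <- association_table()
  seeds_d <- build_seeds(disease_sets, no_sup, "disease", net)
  seeds_r <- build_seeds(drug_sets, no_sup, "drug", net)
  prof_d <- propagate_all(A_prime, seeds_d, cfg)
  prof_r <- propagate_all(A_prime, seeds_r, cfg)
  scores <- score_profiles(prof_d, prof_r)
  sv <- score_vector(scores)
  pos_keys <- pair_key(assoc$drug, assoc$disease)
  pos <- sv[names(sv) %in% pos_keys]
  neg <- sv[!names(sv) %in% pos_keys]
  if (length(pos) == 0L) stop_rwrdr("no known association pair was scored")
  if (length(neg) == 0L) {
    stop_rwrdr("every scored pair is a known association; AUC undefined")
  }
  auc_mw(pos, neg)
}

#' Supervised cross-validation of the association model
#'
#' The association table is randomly split into `k` folds (re-randomized for
#' each of `repeats` repeats). For every fold, disease and drug seeds are
#' augmented with the training-fold associations only ([build_seeds]), the
#' walk is propagated, all pairs are scored, and the fold's AUC is computed
#' with the held-out pairs as positives and all never-known pairs as
#' negatives; training pairs are excluded from the ranking. Per-disease AUC
#' ranks only that disease's row against its own never-known drugs.
#'
#' @inheritParams independent_validation
#' @param k number of folds (the standard protocol uses 10).
#' @param repeats number of repeats (the standard protocol uses 10, giving
#'   `k * repeats` AUC values).
#' @param t seed mixing weight, see [composite_seed].
#' @param rng_seed master integer seed; per-repeat fold seeds are derived
#'   from it deterministically.
#' @return An object of class `rwr_cv`: `auc` (repeats-by-k matrix, `NA`
#'   for unevaluable folds), `mean_auc`, `per_disease` (named mean AUC per
#'   disease), `config` (echo of r, t, k, repeats, tol, rng_seed).
#' @export
run_cv <- function(net, disease_sets, drug_sets, assoc, k = 10L,
                   repeats = 10L, cfg = walk_config(), t = 0.5,
                   rng_seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L, nrow(assoc) >= k)
  A_prime <- transition_matrix(net)
  all_known <- pair_key(assoc$drug, assoc$disease)
  auc_mat <- matrix(NA_real_, nrow = repeats, ncol = k,
                   dimnames = list(paste0("repeat", seq_len(repeats)),
                                   paste0("fold", seq_len(k))))
  per_dis <- list()
  prof_cache <- new.env(parent = emptyenv())
  cached_profiles <- function(seeds) {
    out <- list()
    for (id in names(seeds)) {
      key <- paste0(id, "|", paste(fmt_num(seeds[[id]]), collapse = ","))
      if (is.null(prof_cache[[key]])) {
        prof_cache[[key]] <- propagate(A_prime, seeds[[id]], cfg)
      }
      out[[id]] <- prof_cache[[key]]
    }
    out
  }
  for (rep_i in seq_len(repeats)) {
    fold_of <- split_folds(assoc, k, rng_seed + 7919L * rep_i)
    for (f in seq_len(k)) {
      train <- assoc[fold_of != f, , drop = FALSE]
      test <- assoc[fold_of == f, , drop = FALSE]
      seeds_d <- build_seeds(disease_sets, train, "disease", net,
                             partner_sets = drug_sets, t = t)
      seeds_r <- build_seeds(drug_sets, train, "drug", net,
                             partner_sets = disease_sets, t = t)
      prof_d <- cached_profiles(seeds_d)
      prof_r <- cached_profiles(seeds_r)
      scores <- score_profiles(prof_d, prof_r)
      sv <- score_vector(scores)
      test_keys <- pair_key(test$drug, test$disease)
      pos <- sv[names(sv) %in% test_keys]
      neg <- sv[!names(sv) %in% all_known]
      if (length(pos) == 0L || length(neg) == 0L) {
        warning(sprintf(
          "repeat %d fold %d not evaluable (no scored positive or negative)",
          rep_i, f))
        next
      }
      auc_mat[rep_i, f] <- auc_mw(pos, neg)
      # per-disease AUC over that disease's row only
      for (d in unique(test$disease)) {
        if (!d %in% rownames(scores)) next
        row <- scores[d, ]
        d_pos <- row[names(row) %in% test$drug[test$disease == d]]
        d_neg <- row[!pair_key(names(row), d) %in% all_known]
        if (length(d_pos) == 0L || length(d_neg) == 0L) next
        per_dis[[d]] <- c(per_dis[[d]], auc_mw(d_pos, d_neg))
      }
    }
  }
  per_disease <- vapply(per_dis, mean, numeric(1L))
  per_disease <- per_disease[lex_sort(names(per_disease))]
  structure(list(
    auc = auc_mat,
    mean_auc = mean(auc_mat, na.rm = TRUE),
    per_disease = per_disease,
    config = list(r = cfg$r, t = t, k = k, repeats = repeats,
                  tol = cfg$tol, rng_seed = rng_seed)
  ), class = "rwr_cv")
}

#' @export
print.rwr_cv <- function(x, ...) {
  cat(sprintf(
    "rwr_cv: %d-fold cross-validation, %d repeat(s)\n  mean AUC %.4f over %d values (r = %g, t = %g, seed = %d)\n",
    x$config$k, x$config$repeats, x$mean_auc, sum(!is.na(x$auc)),
    x$config$r, x$config$t, x$config$rng_seed))
  invisible(x)
}

#' @export
summary.rwr_cv <- function(object, ...) {
  v <- object$auc[!is.na(object$auc)]
  out <- list(mean = mean(v), sd = stats::sd(v), n = length(v),
              per_disease = object$per_disease, config = object$config)
  class(out) <- "summary.rwr_cv"
  out
}

#' @export
print.summary.rwr_cv <- function(x, ...) {
  cat(sprintf("AUC: mean %.4f, sd %.4f, n %d\nPer-disease AUC:\n",
              x$mean, x$sd, x$n))
  print(round(x$per_disease, 4))
  invisible(x)
}

#' Mean AUC by disease class
#'
#' Averages the per-disease cross-validation AUC within disease classes
#' (e.g. MeSH categories). A disease listed under several classes counts
#' only toward the first.
#'
#' @param cv an `rwr_cv` from [run_cv].
#' @param class_map named list mapping disease id to a character vector of
#'   class labels (first label wins).
#' @return A named numeric vector of class mean AUCs, sorted by class.
#' @export
auc_by_class <- function(cv, class_map) {
  stopifnot(length(class_map) > 0L, !is.null(names(class_map)))
  unknown <- setdiff(names(class_map), names(cv$per_disease))
  if (length(unknown) > 0L) {
    warning("disease id(s) without cross-validated AUC skipped: ",
            paste(unknown, collapse = ", "))
  }
  ids <- intersect(names(class_map), names(cv$per_disease))
  if (length(ids) == 0L) stop_rwrdr("no disease in class_map was evaluated")
  cls <- vapply(class_map[ids], `[[`, character(1L), 1L)
  means <- tapply(cv$per_disease[ids], cls, mean)
  out <- stats::setNames(as.numeric(means), names(means))
  out[lex_sort(names(out))]
}
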