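#' Fit the network-propagation association model
#'
#' The front door of the package: restricts the network to its largest
#' connected component, builds disease and drug seed distributions
#' (augmented with the supplied known associations, if any), runs the
#' restart random walk for every entity, and scores all disease-drug pairs
#' by Pearson correlation of the stationary profiles.
#'
#' @param network a [gene_network].
#' @param disease_sets,drug_sets named lists of gene sets (see
#'   [read_gene_sets]).
#' @param associations an [association_table] of known pairs used to
#'   augment the seeds; the empty default gives the unsupervised model.
#' @param r restart probability (see [walk_config]).
#' @param t seed mixing weight (see [composite_seed]).
#' @param tol,max_iter convergence control (see [walk_config]).
#' @return An object of class `rwr_fit` holding the connected network, the
#'   stationary profiles, the score matrix and a config echo.
#' @examples
#' study <- simulate_study(synthetic_config(rng_seed = 42))
#' fit <- rwr_fit(study$network, study$disease_sets, study$drug_sets,
#'                study$associations)
#' fit
#' head(predict(fit, threshold = 0.5))
#' @export
rwr_fit <- function(network, disease_sets, drug_sets,
                    associations = association_table(),
                    r = 0.7, t = 0.5, tol = 1e-6, max_iter = 1000L) {
  net <- largest_component(network)
  cfg <- walk_config(r = r, tol = tol, max_iter = max_iter)
  A_prime <- transition_matrix(net)
  seeds_d <- build_seeds(disease_sets, associations, "disease", net,
                         partner_sets = drug_sets, t = t)
  seeds_r <- build_seeds(drug_sets, associations, "drug", net,
                         partner_sets = disease_sets, t = t)
  prof_d <- propagate_all(A_prime, seeds_d, cfg)
  prof_r <- propagate_all(A_prime, seeds_r, cfg)
  scores <- score_profiles(prof_d, prof_r)
  structure(list(
    network = net,
    disease_profiles = prof_d,
    drug_profiles = prof_r,
    scores = scores,
    associations = associations,
    config = list(r = r, t = t, tol = tol, max_iter = max_iter,
                  supervised = nrow(associations) > 0L)
  ), class = "rwr_fit")
}

#' @export
print.rwr_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "rwr_fit: %s network propagation model\n",
    "  network: %d genes, %d interactions\n",
    "  entities: %d diseases x %d drugs (%d known associations)\n",
    "  walk: r = %g, t = %g, tol = %g\n"),
    if (x$config$supervised) "supervised" else "unsupervised",
    length(x$network$nodes), nrow(x$network$edges),
    nrow(x$scores), ncol(x$scores), nrow(x$associations),
    x$config$r, x$config$t, x$config$tol))
  invisible(x)
}

#' @export
summary.rwr_fit <- function(object, ...) {
  sv <- as.numeric(object$scores)
  known_key <- pair_key(object$associations$drug, object$associations$disease)
  all_key <- score_vector(object$scores)
  is_known <- names(all_key) %in% known_key
  out <- list(
    n_pairs = length(sv),
    score_quartiles = stats::quantile(sv, c(0, 0.25, 0.5, 0.75, 1)),
    mean_known = if (any(is_known)) mean(all_key[is_known]) else NA_real_,
    mean_other = mean(all_key[!is_known]),
    config = object$config)
  class(out) <- "summary.rwr_fit"
  out
}

#' @export
print.summary.rwr_fit <- function(x, ...) {
  cat(sprintf("Scores over %d disease-drug pairs:\n", x$n_pairs))
  print(round(x$score_quartiles, 4))
  cat(sprintf("mean score, known pairs: %.4f; other pairs: %.4f\n",
              x$mean_known, x$mean_other))
  invisible(x)
}

#' Ranked candidate associations from a fitted model
#'
#' @param object an `rwr_fit`.
#' @param threshold correlation cutoff passed to [top_associations].
#' @param ... unused.
#' @return A data frame of pairs scoring above the threshold, flagged
#'   known/novel, ranked by score.
#' @export
predict.rwr_fit <- function(object, threshold = 0.8, ...) {
  top_associations(object$scores, threshold = threshold,
                   known = object$associations)
}

#' Score distribution of a fitted model
#'
#' Histogram of all pairwise Pearson scores with the scores of known
#' associations overlaid as a rug.
#'
#' @param x an `rwr_fit`.
#' @param ... passed to [graphics::hist].
#' @export
plot.rwr_fit <- function(x, ...) {
  sv <- score_vector(x$scores)
  known_key <- pair_key(x$associations$drug, x$associations$disease)
  graphics::hist(as.numeric(sv), breaks = 30,
                 main = "Disease-drug profile correlations",
                 xlab = "Pearson correlation", ...)
  known <- sv[names(sv) %in% known_key]
  if (length(known) > 0L) graphics::rug(known, col = "red", lwd = 2)
  invisible(x)
}
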