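#' Seed vector from an entity's own genes
#'
#' Builds the normalized indicator distribution of `genes` over the network
#' nodes: every on-network gene gets equal mass, off-network genes are
#' dropped (their count is returned in the `"n_dropped"` attribute).
#'
#' @param genes character vector of gene identifiers.
#' @param net a [gene_network].
#' @return A named numeric vector aligned to the network node order, summing
#'   to 1, with attribute `n_dropped`.
#' @export
direct_seed <- function(genes, net) {
  stopifnot(length(genes) > 0L)
  genes <- unique(genes)
  hit <- genes %in% net$nodes
  if (!any(hit)) stop_rwrdr("no seed gene on network")
  v <- stats::setNames(numeric(n_nodes(net)), net$nodes)
  v[genes[hit]] <- 1
  v <- v / sum(v)
  attr(v, "n_dropped") <- sum(!hit)
  v
}

#' Seed vector aggregated over partner gene sets
#'
#' Sums the indicator vectors of the partner sets with multiplicity (a gene
#' appearing in k partner sets contributes k) and normalizes the total to 1.
#' This is how the target sets of all drugs known to treat a disease are
#' pooled into one distribution (and, symmetrically, the gene sets of all
#' diseases a drug treats).
#'
#' @param partner_gene_sets non-empty list of character vectors.
#' @param net a [gene_network].
#' @return A named numeric vector aligned to the node order, summing to 1.
#' @export
aggregate_partner_seed <- function(partner_gene_sets, net) {
  stopifnot(length(partner_gene_sets) > 0L)
  v <- stats::setNames(numeric(n_nodes(net)), net$nodes)
  for (genes in partner_gene_sets) {
    genes <- unique(genes)
    hit <- genes[genes %in% net$nodes]
    v[hit] <- v[hit] + 1
  }
  if (sum(v) == 0) stop_rwrdr("no partner gene on network")
  v / sum(v)
}

#' Mix the direct and partner seed distributions
#'
#' Returns `t * direct + (1 - t) * partner`. When the entity has no known
#' partners (`partner = NULL`, e.g. nothing associated to it in the training
#' fold) the direct seed is returned unchanged.
#'
#' @param direct seed vector from [direct_seed].
#' @param partner seed vector from [aggregate_partner_seed], or `NULL`.
#' @param t mixing weight in `[0, 1]`; the conventional default is 0.5.
#' @return A seed vector summing to 1.
#' @export
composite_seed <- function(direct, partner = NULL, t = 0.5) {
  stopifnot(t >= 0, t <= 1)
  if (is.null(partner)) {
    attr(direct, "n_dropped") <- NULL
    return(direct)
  }
  if (length(direct) != length(partner)) {
    stop_rwrdr("seed vector dimension mismatch: ",
               length(direct), " vs ", length(partner))
  }
  v <- t * as.numeric(direct) + (1 - t) * as.numeric(partner)
  names(v) <- names(direct)
  v
}

#' Build seed vectors for every disease or drug
#'
#' For each entity the direct seed over its own genes is mixed with the
#' aggregated seed of its association partners: a disease's partners are the
#' target sets of the drugs known to treat it, a drug's partners are the
#' gene sets of the diseases it is known to treat. Entities without partners
#' in `associations` fall back to their direct seed; entities with no
#' on-network gene are skipped with a warning.
#'
#' @param entities named list mapping entity id to gene set (as returned by
#'   [read_gene_sets]).
#' @param associations an [association_table]; may have zero rows (then
#'   every seed is the unaugmented direct seed).
#' @param side `"disease"` or `"drug"`: which column of `associations` the
#'   entity ids live in.
#' @param net a [gene_network].
#' @param partner_sets named list of the other side's gene sets, used to
#'   resolve partners; required when `associations` has rows.
#' @param t mixing weight passed to [composite_seed].
#' @return A named list of seed vectors in lexicographic entity order, with
#'   skipped entity ids in the `"skipped"` attribute.
#' @export
build_seeds <- function(entities, associations, side = c("disease", "drug"),
                        net, partner_sets = NULL, t = 0.5) {
  side <- match.arg(side)
  stopifnot(length(entities) > 0L, !is.null(names(entities)))
  own_col <- side
  other_col <- if (side == "disease") "drug" else "disease"
  out <- list()
  skipped <- character()
  for (id in lex_sort(names(entities))) {
    direct <- tryCatch(direct_seed(entities[[id]], net),
                       error = function(e) NULL)
    if (is.null(direct)) {
      warning(sprintf("entity '%s' has no gene on the network; skipped", id))
      skipped <- c(skipped, id)
      next
    }
    partner_ids <- associations[[other_col]][associations[[own_col]] == id]
    partner_ids <- lex_sort(unique(partner_ids))
    partner_ids <- partner_ids[partner_ids %in% names(partner_sets)]
    partner <- NULL
    if (length(partner_ids) > 0L) {
      partner <- tryCatch(
        aggregate_partner_seed(partner_sets[partner_ids], net),
        error = function(e) NULL)   # partners entirely off-network: fall back
    }
    out[[id]] <- composite_seed(direct, partner, t = t)
  }
  if (length(out) == 0L) stop_rwrdr("no entity yielded a seed vector")
  attr(out, "skipped") <- skipped
  out
}
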