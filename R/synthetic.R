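#' Configuration for the synthetic study generator
#'
#' Describes a synthetic interactome plus disease/drug gene sets with
#' plantable association signal. The defaults are the package's standard
#' fixture: a 100-node preferential-attachment network, 8 diseases with
#' connected 20-gene modules, 12 drugs with 3 targets each, 16 planted
#' true associations whose drugs draw targets from their disease's network
#' neighborhood with probability 0.9.
#'
#' @param n_nodes network size.
#' @param attach_m edges added per new node in preferential attachment.
#' @param n_diseases,n_drugs entity counts.
#' @param disease_module_size genes per disease module (connected subgraph).
#' @param targets_per_drug target-set size per drug.
#' @param n_planted number of planted true (drug, disease) associations.
#' @param p_in probability that a planted drug's target is drawn from its
#'   disease's module or the module's one-hop neighborhood (otherwise it is
#'   drawn uniformly from the network). `p_in = 0` removes all signal.
#' @param rng_seed integer seed; the whole generation is deterministic
#'   given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 100L, attach_m = 2L, n_diseases = 8L,
                             n_drugs = 12L, disease_module_size = 20L,
                             targets_per_drug = 3L, n_planted = 16L,
                             p_in = 0.9, rng_seed = 42L) {
  cfg <- list(n_nodes = as.integer(n_nodes), attach_m = as.integer(attach_m),
              n_diseases = as.integer(n_diseases),
              n_drugs = as.integer(n_drugs),
              disease_module_size = as.integer(disease_module_size),
              targets_per_drug = as.integer(targets_per_drug),
              n_planted = as.integer(n_planted), p_in = p_in,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_nodes > cfg$disease_module_size,
            cfg$p_in >= 0, cfg$p_in <= 1,
            cfg$n_planted <= cfg$n_diseases * cfg$n_drugs,
            cfg$n_nodes >= cfg$attach_m + 1L)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic scale-free network
#'
#' Connected preferential-attachment (Barabasi-Albert) graph with node
#' identifiers `g000001`, `g000002`, ... Preferential attachment is used
#' because random-walk behavior on real interactomes is hub-dominated and
#' the tests should exercise that regime.
#'
#' @param cfg a [synthetic_config].
#' @return A [gene_network], deterministic given `cfg$rng_seed`.
#' @export
generate_network <- function(cfg = synthetic_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$rng_seed)
  g <- igraph::sample_pa(cfg$n_nodes, power = 1, m = cfg$attach_m,
                         directed = FALSE, algorithm = "psumtree")
  e <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("g%06d", seq_len(cfg$n_nodes))
  net <- gene_network(cbind(ids[e[, 1L]], ids[e[, 2L]]), nodes = ids)
  comp <- igraph::components(as_igraph(net))
  if (comp$no != 1L) stop_rwrdr("generated network is not connected")
  net
}

#' Plant diseases, drugs and true associations on a network
#'
#' Each disease module is a connected subgraph (the first
#' `disease_module_size` nodes in breadth-first order from a random root),
#' encoding the locality assumption that makes network propagation
#' informative. `n_planted` (drug, disease) pairs are sampled; a planted
#' drug draws each target from the union of its diseases' modules and their
#' one-hop neighborhoods with probability `p_in`, otherwise uniformly from
#' the network. Drugs in no planted pair draw targets uniformly.
#'
#' @param net a [gene_network], typically from [generate_network].
#' @param cfg a [synthetic_config].
#' @return A list with `disease_sets`, `drug_sets` (named lists of gene
#'   sets) and `associations` (an [association_table] of the planted pairs).
#' @export
plant_entities <- function(net, cfg = synthetic_config()) {
  if (cfg$disease_module_size > n_nodes(net)) {
    stop_rwrdr("disease module larger than the network")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$rng_seed + 1L)
  g <- as_igraph(net)
  dis_ids <- sprintf("dis%03d", seq_len(cfg$n_diseases))
  drg_ids <- sprintf("drg%03d", seq_len(cfg$n_drugs))

  disease_sets <- lapply(seq_len(cfg$n_diseases), function(i) {
    root <- sample(net$nodes, 1L)
    ord <- igraph::bfs(g, root = root, order = TRUE)$order
    net$nodes[as.integer(ord)[seq_len(cfg$disease_module_size)]]
  })
  names(disease_sets) <- dis_ids

  grid_idx <- sample(cfg$n_diseases * cfg$n_drugs, cfg$n_planted)
  planted <- data.frame(
    drug = drg_ids[(grid_idx - 1L) %% cfg$n_drugs + 1L],
    disease = dis_ids[(grid_idx - 1L) %/% cfg$n_drugs + 1L],
    stringsAsFactors = FALSE)

  neighborhood <- function(module) {
    nb <- unique(unlist(igraph::adjacent_vertices(
      g, v = module)))
    unique(c(module, net$nodes[nb]))
  }
  drug_sets <- lapply(drg_ids, function(rid) {
    my_dis <- planted$disease[planted$drug == rid]
    pool <- if (length(my_dis) > 0L) {
      lex_sort(unique(unlist(lapply(disease_sets[my_dis], neighborhood))))
    } else character()
    targets <- character()
    for (s in seq_len(cfg$targets_per_drug)) {
      cand_pool <- setdiff(pool, targets)
      from_pool <- length(cand_pool) > 0L && stats::runif(1L) < cfg$p_in
      cand <- if (from_pool) cand_pool else setdiff(net$nodes, targets)
      targets <- c(targets, sample(cand, 1L))
    }
    lex_sort(targets)
  })
  names(drug_sets) <- drg_ids

  list(disease_sets = disease_sets, drug_sets = drug_sets,
       associations = association_table(planted$drug, planted$disease))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_network] then [plant_entities].
#'
#' @param cfg a [synthetic_config].
#' @return A list with `network`, `disease_sets`, `drug_sets`,
#'   `associations` and the `config` echo.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  ent <- plant_entities(net, cfg)
  c(list(network = net), ent, list(config = cfg))
}

#' Write a synthetic study to disk
#'
#' Writes the four files the readers consume: `network.tsv` (edge list),
#' `diseases.gmt` and `drugs.gmt` (gene sets), `associations.tsv`
#' (drug-disease pairs). The round trip through the readers is lossless.
#'
#' @param study a list from [simulate_study] (or the same components).
#' @param dir output directory, created if needed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_rwrdr("cannot create fixture directory: ", dir)
  paths <- c(network = file.path(dir, "network.tsv"),
             diseases = file.path(dir, "diseases.gmt"),
             drugs = file.path(dir, "drugs.gmt"),
             associations = file.path(dir, "associations.tsv"))
  write_edge_list(study$network, paths[["network"]])
  write_gene_sets(study$disease_sets, paths[["diseases"]])
  write_gene_sets(study$drug_sets, paths[["drugs"]])
  write_associations(study$associations, paths[["associations"]])
  invisible(paths)
}
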