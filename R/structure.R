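#' Fold a sequence into a maximum-pairing secondary structure
#'
#' A fallback folder for when no external (e.g. RNAfold) structures are
#' supplied: Nussinov base-pair maximisation over Watson-Crick and GU wobble
#' pairs with a minimum hairpin loop of 3 unpaired bases, with a fixed,
#' deterministic traceback. This optimises pair count, not free energy.
#'
#' @param sequence RNA string (length >= 4).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return A dot-bracket string of the same length.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  validate_rna(sequence)
  db <- nussinov_fold(sequence, as.integer(min_loop))
  validate_dotbracket(db, sequence)
  db
}

#' Build the single-molecule graph of a secondary structure
#'
#' Nodes are nucleotide positions 1..L; edges are the L-1 backbone bonds plus
#' one edge per base pair of the dot-bracket. The result is a simple,
#' connected, undirected igraph object.
#'
#' @param sequence RNA string.
#' @param structure Dot-bracket string of equal length.
#' @return An igraph graph with L vertices.
#' @export
structure_graph <- function(sequence, structure) {
  validate_rna(sequence)
  validate_dotbracket(structure, sequence)
  L <- nchar(sequence)
  backbone <- cbind(seq_len(L - 1L), seq_len(L - 1L) + 1L)
  pairs <- dotbracket_pairs(structure)
  edges <- rbind(backbone, pairs)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Names of the 24 network descriptors, in frozen order
#'
#' Summary statistics (A- mean, V-/Var- variance, N- count) over node- and
#' edge-level topological properties of the structure graph, plus global
#' descriptors. All names carry the `net.` prefix.
#'
#' @return Character vector of length 24.
#' @export
network_feature_names <- function() {
  paste0("net.", c(
    "A_degree", "V_degree", "A_closeness", "A_Nbetweenness", "Var_Vbetweenness",
    "A_Ebetweenness", "A_coreness", "V_coreness", "A_Burts", "A_hubscore",
    "A_cocitation", "A_bibliographic", "A_localtrans", "G_transitivity",
    "Densith", "Modularity", "Diameter", "Girth", "A_pathlength",
    "N_articulation", "N_motif3", "N_motif4", "A_eccentricity", "Max_coreness"
  ))
}

var0 <- function(x) {
  # population-style variance with a 0 fallback for a single value
  if (length(x) < 2L) return(0)
  stats::var(x)
}

offdiag_mean <- function(m) {
  if (nrow(m) < 2L) return(0)
  mean(m[row(m) != col(m)])
}

## HITS hub scores by power iteration on A A^T from a uniform start,
## normalised to max 1. Fixed start + tolerance make it bit-deterministic
## (ARPACK-based scores are not, on degenerate eigenspaces).
hits_hub_scores <- function(A) {
  M <- A %*% t(A)
  v <- rep(1, nrow(A))
  for (i in seq_len(500L)) {
    v2 <- as.vector(M %*% v)
    nv <- max(abs(v2))
    if (nv == 0) return(rep(0, nrow(A)))
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-13) {
      v <- v2
      break
    }
    v <- v2
  }
  v / max(v)
}

count_connected_subgraphs <- function(g, size) {
  counts <- igraph::motifs(g, size)
  sum(counts, na.rm = TRUE)
}

#' Compute the 24 topological descriptors of a structure graph
#'
#' Degree, betweenness (node and edge), closeness, coreness, Burt's
#' constraint, hub score, cocitation/bibliographic coupling, transitivity
#' (local mean and global), density, greedy modularity, diameter, girth
#' (0 for an acyclic graph), average path length, articulation points,
#' connected 3-/4-node subgraph counts, eccentricity. Local transitivity of
#' nodes with degree < 2 counts as 0. All computations are deterministic.
#'
#' @param g A connected, simple igraph graph (from [structure_graph()]).
#' @return Named numeric vector of length 24 (names from
#'   [network_feature_names()]).
#' @export
network_features <- function(g) {
  stopifnot(igraph::is_connected(g))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  ebtw <- igraph::edge_betweenness(g, directed = FALSE)
  core <- igraph::coreness(g)
  loc_trans <- igraph::transitivity(g, type = "localundirected")
  loc_trans[!is.finite(loc_trans)] <- 0
  girth <- igraph::girth(g, circle = FALSE)$girth
  if (!is.finite(girth)) girth <- 0
  comm <- igraph::cluster_fast_greedy(g)
  out <- c(
    mean(deg),
    var0(deg),
    mean(igraph::closeness(g)),
    mean(btw),
    var0(btw),
    mean(ebtw),
    mean(core),
    var0(core),
    mean(igraph::constraint(g)),
    mean(hits_hub_scores(as.matrix(igraph::as_adjacency_matrix(g)))),
    offdiag_mean(igraph::cocitation(g)),
    offdiag_mean(igraph::bibcoupling(g)),
    mean(loc_trans),
    ifelse(is.nan(tg <- igraph::transitivity(g, type = "global")), 0, tg),
    igraph::edge_density(g),
    igraph::modularity(comm),
    igraph::diameter(g, directed = FALSE),
    girth,
    igraph::mean_distance(g, directed = FALSE),
    length(igraph::articulation_points(g)),
    count_connected_subgraphs(g, 3L),
    count_connected_subgraphs(g, 4L),
    mean(igraph::eccentricity(g)),
    max(core)
  )
  names(out) <- network_feature_names()
  out
}

#' Structure features for a sequence
#'
#' Convenience wrapper: builds the structure graph (folding with
#' [fold_hairpin()] when no structure is given) and returns its 24
#' descriptors.
#'
#' @param sequence RNA string.
#' @param structure Optional dot-bracket; defaults to the Nussinov fold.
#' @return Named numeric vector of length 24.
#' @export
structure_features <- function(sequence, structure = NULL) {
  if (is.null(structure)) structure <- fold_hairpin(sequence)
  network_features(structure_graph(sequence, structure))
}
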