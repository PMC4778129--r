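#' Hamming distance between two allele profiles
#'
#' @param a,b equal-length integer vectors of allele ids.
#' @return Integer count of loci at which the profiles differ (0..l).
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in arity")
  sum(a != b)
}

# all-pairs profile Hamming distances (STs x STs)
.profile_dist_matrix <- function(registry) {
  l <- ncol(registry)
  d <- matrix(0L, nrow(registry), nrow(registry),
              dimnames = list(rownames(registry), rownames(registry)))
  for (k in seq_len(l)) d <- d + outer(registry[, k], registry[, k], "!=")
  d
}

#' Build the single-locus-variant (SLV) graph of a set of STs
#'
#' Nodes are STs; an undirected edge links two STs whose allele profiles
#' differ at exactly one locus (identical at the remaining loci). Node
#' weights carry isolate counts.
#'
#' @param registry integer matrix of distinct ST profiles (rownames = ST ids).
#' @param n_isolates optional named integer vector of isolate counts per ST
#'   (default 1 each).
#' @return An `igraph` graph with vertex attributes `name` (ST id) and
#'   `n_isolates`, and graph attribute `dlv` (the double-locus-variant count
#'   per ST, used in founder tie-breaking).
#' @export
build_slv_graph <- function(registry, n_isolates = NULL) {
  registry <- .as_profile_matrix(registry)
  if (is.null(rownames(registry)))
    rownames(registry) <- as.character(seq_len(nrow(registry)))
  if (anyDuplicated(rownames(registry))) stop("duplicate ST ids")
  key <- apply(registry, 1L, paste, collapse = "_")
  if (anyDuplicated(key)) stop("duplicate ST profiles in registry")
  if (is.null(n_isolates))
    n_isolates <- stats::setNames(rep(1L, nrow(registry)), rownames(registry))
  d <- .profile_dist_matrix(registry)
  adj <- d == 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$n_isolates <- as.integer(n_isolates[igraph::V(g)$name])
  igraph::V(g)$dlv <- as.integer(rowSums(d == 2L)[igraph::V(g)$name])
  g
}

#' Cluster STs into clonal complexes, doubletons and singletons
#'
#' Groups are the connected components of the SLV graph: components of three
#' or more STs are clonal complexes (CC), two-ST components are doubletons,
#' isolated STs singletons. For each CC the group founder is the ST with the
#' most SLVs, ties broken by larger double-locus-variant count, then larger
#' isolate count, then smaller ST id; subgroup founders are non-founder
#' members with at least two SLV links besides their link to the founder.
#'
#' @param graph an SLV graph from [build_slv_graph()].
#' @return List with `membership` (data.frame: st, group, group_type,
#'   is_founder, is_subgroup_founder, slv_degree, n_isolates) and `groups`
#'   (data.frame: group, group_type, n_sts, n_isolates, founder).
#' @export
cluster_groups <- function(graph) {
  comp <- igraph::components(graph)
  st <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  memb <- data.frame(st = st, group = comp$membership,
                     slv_degree = as.integer(deg),
                     n_isolates = igraph::V(graph)$n_isolates,
                     is_founder = FALSE, is_subgroup_founder = FALSE,
                     stringsAsFactors = FALSE)
  sizes <- as.integer(comp$csize)
  type_of <- function(k) if (k >= 3L) "CC" else if (k == 2L) "doubleton" else "singleton"
  grp <- data.frame(group = seq_along(sizes),
                    group_type = vapply(sizes, type_of, character(1)),
                    n_sts = sizes, n_isolates = NA_integer_,
                    founder = NA_character_, stringsAsFactors = FALSE)
  for (gid in grp$group) {
    rows <- which(memb$group == gid)
    grp$n_isolates[gid] <- as.integer(sum(memb$n_isolates[rows]))
    if (grp$group_type[gid] != "CC") next
    f <- predict_founders(graph, memb$st[rows])
    memb$is_founder[memb$st == f$founder] <- TRUE
    memb$is_subgroup_founder[memb$st %in% f$subgroup_founders] <- TRUE
    grp$founder[gid] <- f$founder
  }
  list(membership = memb, groups = grp)
}

#' Predict the founder and subgroup founders of one clonal complex
#'
#' @param graph the SLV graph.
#' @param members character vector of ST ids forming one CC (>= 3 STs).
#' @return List with `founder` (ST id) and `subgroup_founders` (character
#'   vector, possibly empty).
#' @export
predict_founders <- function(graph, members) {
  if (length(members) < 3L)
    stop("founder prediction applies to clonal complexes (>= 3 STs)")
  deg <- igraph::degree(graph, v = members)
  dlv <- stats::setNames(igraph::V(graph)$dlv, igraph::V(graph)$name)[members]
  n_iso <- stats::setNames(igraph::V(graph)$n_isolates,
                           igraph::V(graph)$name)[members]
  ord <- order(-deg, -dlv, -n_iso, as.integer(members))
  founder <- members[ord[1L]]
  others <- setdiff(members, founder)
  fneigh <- igraph::neighbors(graph, founder)$name
  own <- vapply(others, function(s) {
    d <- igraph::degree(graph, v = s)
    if (s %in% fneigh) d - 1L else d
  }, numeric(1))
  list(founder = founder,
       subgroup_founders = others[own >= 2])
}

#' Export a population-snapshot graph
#'
#' Writes the SLV graph with isolate-count node weights as GraphML and DOT,
#' the formats standard graph viewers read.
#'
#' @param graph the SLV graph.
#' @param path_graphml,path_dot output paths (`NULL` to skip either).
#' @return Invisibly, the written paths.
#' @export
export_snapshot <- function(graph, path_graphml = NULL, path_dot = NULL) {
  if (!is.null(path_graphml))
    igraph::write_graph(graph, path_graphml, format = "graphml")
  if (!is.null(path_dot))
    igraph::write_graph(graph, path_dot, format = "dot")
  invisible(c(path_graphml, path_dot))
}
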