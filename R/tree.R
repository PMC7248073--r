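#' Dated sample tree for the frequency simulator
#'
#' A rooted tree whose leaves are dated (ancient) samples and whose branch
#' lengths are measured in generations. Branch lengths are derived from
#' node ages in years BP and the generation time, so leaf ages are
#' consistent with cumulative branch lengths by construction.
#'
#' @param edges data.frame with character columns `parent`, `child`
#'   (node names).
#' @param ages Named numeric vector of node ages in years BP (every node
#'   in `edges` must appear; child ages must be younger than parents).
#' @param gen_time Generation time in years (default 29).
#' @return Object of class `sample_tree`: `nodes` (name, age_bp, is_leaf),
#'   `edges` (parent, child, dt in generations, topologically ordered),
#'   `root`, `leaves`, `gen_time`.
#' @export
sample_tree <- function(edges, ages, gen_time = 29) {
  stopifnot(all(c("parent", "child") %in% names(edges)))
  nodes <- union(edges$parent, edges$child)
  stopifnot(all(nodes %in% names(ages)))
  if (anyDuplicated(edges$child))
    stop("tree is not a tree: a node has two parents")
  root <- setdiff(edges$parent, edges$child)
  if (length(root) != 1) stop("tree must have exactly one root")
  dt <- (ages[edges$parent] - ages[edges$child]) / gen_time
  if (any(dt <= 0)) stop("every child must be strictly younger than its parent")
  # topological order: repeatedly emit edges whose parent is resolved
  ordered <- integer(0)
  resolved <- root
  remaining <- seq_len(nrow(edges))
  while (length(remaining)) {
    ready <- remaining[edges$parent[remaining] %in% resolved]
    if (!length(ready)) stop("tree contains a cycle or disconnected node")
    ordered <- c(ordered, ready)
    resolved <- c(resolved, edges$child[ready])
    remaining <- setdiff(remaining, ready)
  }
  edges <- data.frame(parent = edges$parent[ordered],
                      child = edges$child[ordered],
                      dt = unname(dt[ordered]), stringsAsFactors = FALSE)
  leaves <- setdiff(nodes, edges$parent)
  node_df <- data.frame(name = nodes, age_bp = unname(ages[nodes]),
                        is_leaf = nodes %in% leaves, stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = edges, root = root,
                 leaves = sort(leaves), gen_time = gen_time),
            class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("sample_tree: %d leaves, root at %s years BP (gen_time %g)\n",
              length(x$leaves), format(x$nodes$age_bp[x$nodes$name == x$root]),
              x$gen_time))
  cat("leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Default eight-leaf Upper-Palaeolithic sample tree
#'
#' A dated topology for eight well-known Upper-Palaeolithic/Mesolithic
#' Eurasian genomes (Ust'-Ishim, Mal'ta 1, Kostenki 14, Goyet Q116-1,
#' Vestonice 16, El Miron, Villabruna, Loschbour), following the published
#' clustering of these samples: Ust'-Ishim basal; Mal'ta 1 on its own
#' branch; Kostenki/Vestonice (Gravettian) and Goyet/El Miron
#' (Aurignacian-Magdalenian) related; Villabruna and Loschbour forming the
#' late cluster. Internal-node ages are plausible interpolations, not
#' published estimates — the object is a synthetic stand-in sufficient to
#' give each leaf a realistic age and shared drift path.
#'
#' @param gen_time Generation time in years (default 29).
#' @return A [sample_tree()].
#' @export
default_sample_tree <- function(gen_time = 29) {
  edges <- data.frame(
    parent = c("root", "root", "n1", "n1", "n2", "n2", "n3", "n3",
               "n4", "n4", "n5", "n5", "n6", "n6"),
    child = c("UstIshim", "n1", "Malta1", "n2", "Kostenski14", "n3",
              "Vestonice16", "n4", "GoyetQ116-1", "n5", "ElMiron", "n6",
              "Villabruna", "Loschbour"),
    stringsAsFactors = FALSE)
  ages <- c(root = 46400, UstIshim = 45000, n1 = 39000, Malta1 = 24000,
            n2 = 38000, Kostenski14 = 37500, n3 = 36000,
            Vestonice16 = 30000, n4 = 35500, "GoyetQ116-1" = 35000,
            n5 = 20000, ElMiron = 18700, n6 = 15000, Villabruna = 14000,
            Loschbour = 8000)
  sample_tree(edges, ages, gen_time = gen_time)
}

#' Convert a sample tree to an ape phylogeny
#'
#' Branch lengths of the returned `phylo` are in generations.
#'
#' @param tree A [sample_tree()].
#' @return An [ape::as.phylo] object.
#' @export
as_phylo <- function(tree) {
  nodes <- tree$nodes$name
  leaves <- tree$leaves
  internal <- c(tree$root, setdiff(nodes[!tree$nodes$is_leaf], tree$root))
  id <- c(seq_along(leaves), length(leaves) + seq_along(internal))
  names(id) <- c(leaves, internal)
  phy <- structure(list(
    edge = cbind(unname(id[tree$edges$parent]), unname(id[tree$edges$child])),
    edge.length = tree$edges$dt,
    Nnode = length(internal),
    tip.label = leaves,
    node.label = internal), class = "phylo")
  ape::reorder.phylo(phy)
}

#' Write / read a sample tree as Newick plus a JSON sidecar
#'
#' The Newick file stores topology and branch lengths (generations); the
#' sidecar stores the root age and generation time needed to reconstruct
#' node ages.
#'
#' @param tree A [sample_tree()].
#' @param path Output `.nwk` path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sample_tree <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  jsonlite::write_json(
    list(root = tree$root,
         root_age_bp = tree$nodes$age_bp[tree$nodes$name == tree$root],
         gen_time = tree$gen_time),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sample_tree
#' @export
read_sample_tree <- function(path) {
  phy <- ape::read.tree(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labs <- c(phy$tip.label, phy$node.label)
  edges <- data.frame(parent = labs[phy$edge[, 1]],
                      child = labs[phy$edge[, 2]],
                      dt = phy$edge.length, stringsAsFactors = FALSE)
  # reconstruct ages from the root down
  ages <- stats::setNames(rep(NA_real_, length(labs)), labs)
  ages[side$root] <- side$root_age_bp
  repeat {
    todo <- which(is.na(ages[edges$child]) & !is.na(ages[edges$parent]))
    if (!length(todo)) break
    ages[edges$child[todo]] <-
      ages[edges$parent[todo]] - edges$dt[todo] * side$gen_time
  }
  sample_tree(edges[c("parent", "child")], ages, gen_time = side$gen_time)
}
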