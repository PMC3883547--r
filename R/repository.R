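#' Construct a pathway repository
#'
#' A pathway repository is the annotation universe for signature analysis:
#' a set of uniquely identified pathways, each with a non-empty gene set,
#' plus an optional child--parent hierarchy (a DAG; a pathway may have
#' several parents, as in Reactome-style repositories).
#'
#' @param pathways named list of character vectors; names are pathway ids,
#'   values are member gene ids (duplicates are collapsed).
#' @param names optional named character vector of human-readable pathway
#'   descriptions; unnamed pathways fall back to their id.
#' @param hierarchy data frame with columns `child` and `parent`, both
#'   pathway ids present in `pathways`. May have zero rows (flat repository).
#' @return An object of class `pathway_repo`.
#' @export
pathway_repo <- function(pathways, names = NULL, hierarchy = empty_hierarchy()) {
  stopifnot(is.list(pathways))
  ids <- base::names(pathways)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every pathway must have a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ", ids[duplicated(ids)][1L], call. = FALSE)
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0L))
    stop("pathway with no genes: ",
         ids[lengths(pathways) == 0L][1L], call. = FALSE)
  if (is.null(names)) names <- stats::setNames(ids, ids)
  full <- stats::setNames(ids, ids)
  full[base::names(names)[base::names(names) %in% ids]] <-
    names[base::names(names) %in% ids]
  repo <- structure(
    list(pathways = pathways, names = full, hierarchy = empty_hierarchy()),
    class = "pathway_repo")
  if (nrow(hierarchy) > 0L) repo <- set_hierarchy(repo, hierarchy)
  repo
}

empty_hierarchy <- function() {
  data.frame(child = character(), parent = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.pathway_repo <- function(x, ...) {
  cat(sprintf("pathway_repo: %d pathways, %d distinct genes, %d hierarchy edges\n",
              length(x$pathways), length(unique(unlist(x$pathways, use.names = FALSE))),
              nrow(x$hierarchy)))
  invisible(x)
}

#' @rdname pathway_repo
#' @param x object to test.
#' @export
is.pathway_repo <- function(x) inherits(x, "pathway_repo")

pathway_ids <- function(repo) names(repo$pathways)

pathway_sizes <- function(repo) lengths(repo$pathways)

all_genes <- function(repo) {
  sort(unique(unlist(repo$pathways, use.names = FALSE)))
}

# Attach (and validate) hierarchy edges: endpoints known, graph acyclic.
set_hierarchy <- function(repo, edges) {
  edges <- data.frame(child = as.character(edges[[1L]]),
                      parent = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  known <- pathway_ids(repo)
  bad <- setdiff(unique(c(edges$child, edges$parent)), known)
  if (length(bad) > 0L)
    stop("hierarchy references unknown pathway id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  edges <- unique(edges)
  cyc <- find_cycle(edges)
  if (!is.null(cyc))
    stop("hierarchy contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  repo$hierarchy <- edges
  repo
}

# Kahn's algorithm over child->parent edges; returns one cycle (as a vector
# of ids, first repeated at the end) or NULL when the graph is acyclic.
find_cycle <- function(edges) {
  if (nrow(edges) == 0L) return(NULL)
  nodes <- unique(c(edges$child, edges$parent))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- nodes[indeg == 0L]
  remaining <- edges
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- remaining$child == v
    for (p in remaining$parent[out]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (nrow(remaining) == 0L) return(NULL)
  # walk the leftover subgraph until a node repeats
  walk <- remaining$child[1L]
  repeat {
    nxt <- remaining$parent[remaining$child == walk[length(walk)]][1L]
    if (nxt %in% walk) {
      cyc <- c(walk[which(walk == nxt)[1L]:length(walk)], nxt)
      return(cyc)
    }
    walk <- c(walk, nxt)
  }
}

#' Read a pathway repository from a GMT file
#'
#' One pathway per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed (a message reports the count);
#' duplicate pathway ids across lines are an error. Gene and pathway ids are
#' opaque, case-sensitive strings; no identifier translation is performed.
#'
#' @param path path to a tab-separated GMT file.
#' @return A [pathway_repo] with an empty hierarchy.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L))
    stop("GMT line ", which(n_fields < 3L)[1L],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id in GMT: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  descs <- vapply(fields, `[[`, character(1L), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(genes, function(g) length(g) - length(unique(g)),
                      integer(1L)))
  if (n_dup > 0L)
    message("read_gmt: collapsed ", n_dup, " duplicate gene annotation(s)")
  pathway_repo(stats::setNames(genes, ids), names = stats::setNames(descs, ids))
}

#' Write a pathway repository to a GMT file
#'
#' Inverse of [read_gmt()] (hierarchy edges are not part of the GMT format;
#' use [write_hierarchy()] for those). Rows and gene columns are written in
#' deterministic sorted order.
#'
#' @param repo a [pathway_repo].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(repo, path) {
  ids <- sort(pathway_ids(repo))
  lines <- vapply(ids, function(id) {
    paste(c(id, repo$names[[id]], sort(repo$pathways[[id]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway hierarchy and attach it to a repository
#'
#' The hierarchy file is a headerless two-column TSV, `child<TAB>parent`,
#' where the parent is the more general pathway (its gene set normally
#' contains the child's). Multiple parents are allowed; the graph must be
#' acyclic. An empty file leaves the repository flat.
#'
#' @param path path to the TSV file.
#' @param repo the [pathway_repo] the edges refer to.
#' @return `repo` with hierarchy edges attached.
#' @export
read_hierarchy <- function(path, repo) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(repo)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("hierarchy line ", which(lengths(parts) < 2L)[1L],
         " does not have two tab-separated columns", call. = FALSE)
  set_hierarchy(repo, data.frame(
    child = trimws(vapply(parts, `[[`, character(1L), 1L)),
    parent = trimws(vapply(parts, `[[`, character(1L), 2L)),
    stringsAsFactors = FALSE))
}

#' @rdname read_hierarchy
#' @export
write_hierarchy <- function(repo, path) {
  h <- repo$hierarchy[order(repo$hierarchy$child, repo$hierarchy$parent), ,
                      drop = FALSE]
  utils::write.table(h, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list
#'
#' One id per line; lines starting with `#` are ignored and surrounding
#' whitespace is stripped. Duplicates are removed (a message reports how
#' many) while preserving first-seen order.
#'
#' @param path path to a plain-text gene list.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) < length(lines))
    message("read_gene_list: dropped ", length(lines) - length(ids),
            " duplicate id(s)")
  ids
}

#' Bipartite gene--pathway graph of a repository
#'
#' Represents the annotation relation as a bipartite graph: gene nodes,
#' pathway nodes, and one edge per (gene, pathway) annotation. A gene's
#' degree is the number of pathways it is annotated in; a pathway's degree
#' is its size. Genes of degree one are pathway-unique genes (PUGs).
#'
#' @param repo a [pathway_repo].
#' @return An object of class `bipartite_graph`: list with `gene_nodes`,
#'   `pathway_nodes`, `edges` (data frame gene/pathway) and `incidence`
#'   (sparse genes x pathways 0/1 matrix).
#' @export
build_bipartite <- function(repo) {
  stopifnot(is.pathway_repo(repo))
  genes <- all_genes(repo)
  paths <- pathway_ids(repo)
  edges <- data.frame(
    gene = unlist(repo$pathways, use.names = FALSE),
    pathway = rep(paths, times = pathway_sizes(repo)),
    stringsAsFactors = FALSE)
  inc <- Matrix::sparseMatrix(
    i = match(edges$gene, genes),
    j = match(edges$pathway, paths),
    x = 1,
    dims = c(length(genes), length(paths)),
    dimnames = list(genes, paths))
  structure(list(gene_nodes = genes, pathway_nodes = paths,
                 edges = edges, incidence = inc),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("bipartite_graph: %d genes, %d pathways, %d annotation edges\n",
              length(x$gene_nodes), length(x$pathway_nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a bipartite annotation graph
#'
#' @param b a `bipartite_graph` from [build_bipartite()].
#' @param side `"gene"` or `"pathway"`.
#' @return Named integer vector of degrees.
#' @export
bipartite_degrees <- function(b, side = c("gene", "pathway")) {
  side <- match.arg(side)
  if (side == "gene") {
    stats::setNames(as.integer(Matrix::rowSums(b$incidence)), b$gene_nodes)
  } else {
    stats::setNames(as.integer(Matrix::colSums(b$incidence)), b$pathway_nodes)
  }
}
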