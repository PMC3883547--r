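#' Generate a synthetic pathway repository
#'
#' Builds repositories with fully controlled component sharing so that
#' signature compilation, enrichment testing and the simulation benchmark
#' can run self-contained. Each pathway first receives a private block of
#' genes drawn from a disjoint region of the gene pool (sizes uniform in
#' `size_range`), so every gene has bipartite degree 1 by construction.
#' Sharing is then injected through shared blocks: each of the
#' `n_shared_blocks` blocks consists of `block_size` fresh genes added to
#' `pathways_per_block` randomly chosen pathways, creating genes of degree
#' exactly `pathways_per_block` — the multifunctional-kinase situation where
#' a handful of genes recur across many pathways. With
#' `hierarchy_depth >= 2`, parent pathways are created as pure unions of
#' randomly grouped children (plus `parent_extra_genes` parent-only genes if
#' requested) and child--parent hierarchy edges are emitted, reproducing the
#' semantic redundancy of hierarchical repositories where every child gene
#' set is contained in its parent's.
#'
#' @param n_pathways number of base (leaf) pathways.
#' @param gene_pool size of the gene id pool; must accommodate all private
#'   and shared blocks.
#' @param size_range integer vector `c(min, max)` of private-block sizes;
#'   `min >= 2` is required for pair signatures to exist.
#' @param n_shared_blocks,block_size,pathways_per_block sharing structure
#'   (see above); `n_shared_blocks = 0` yields a sharing-free repository.
#' @param hierarchy_depth number of hierarchy levels; 0 or 1 means flat.
#' @param group_size number of children united under one parent.
#' @param parent_extra_genes parent-only genes added to each parent.
#' @param seed optional integer seed; generation is deterministic given it.
#' @return A [pathway_repo]; leaf pathways are named `PW###`, parents
#'   `Hd_###` with `d` the hierarchy level above the leaves.
#' @export
generate_repo <- function(n_pathways, gene_pool,
                          size_range = c(10, 30),
                          n_shared_blocks = 0, block_size = 5,
                          pathways_per_block = 2,
                          hierarchy_depth = 0, group_size = 3,
                          parent_extra_genes = 0, seed = NULL) {
  stopifnot(n_pathways >= 1, length(size_range) == 2L,
            size_range[1L] >= 1, size_range[1L] <= size_range[2L],
            n_shared_blocks >= 0, group_size >= 2)
  if (n_shared_blocks > 0 &&
      (pathways_per_block < 2 || pathways_per_block > n_pathways))
    stop("pathways_per_block must be in [2, n_pathways]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  size_choices <- seq.int(size_range[1L], size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                   replace = TRUE)]
  n_parents_max <- if (hierarchy_depth >= 2) {
    # generous upper bound on parent-only gene demand
    parent_extra_genes * n_pathways * hierarchy_depth
  } else 0
  need <- sum(sizes) + n_shared_blocks * block_size + n_parents_max
  if (need > gene_pool)
    stop("gene_pool too small: need at least ", need, " genes", call. = FALSE)

  pool <- sprintf("G%06d", sample.int(gene_pool))
  take <- local({
    used <- 0L
    function(n) {
      g <- pool[used + seq_len(n)]
      used <<- used + n
      g
    }
  })
  pathways <- lapply(sizes, take)
  names(pathways) <- sprintf("PW%03d", seq_len(n_pathways))
  for (b in seq_len(n_shared_blocks)) {
    block <- take(block_size)
    members <- sample.int(n_pathways, pathways_per_block)
    for (p in members) pathways[[p]] <- c(pathways[[p]], block)
  }

  hierarchy <- empty_hierarchy()
  if (hierarchy_depth >= 2) {
    children <- names(pathways)
    for (d in seq_len(hierarchy_depth - 1L)) {
      if (length(children) < 2L) break
      shuffled <- sample(children)
      grp <- split(shuffled,
                   ceiling(seq_along(shuffled) / group_size))
      parents <- character(length(grp))
      for (gi in seq_along(grp)) {
        pid <- sprintf("H%d_%03d", d + 1L, gi)
        genes <- unique(unlist(pathways[grp[[gi]]], use.names = FALSE))
        if (parent_extra_genes > 0) genes <- c(genes, take(parent_extra_genes))
        pathways[[pid]] <- genes
        parents[gi] <- pid
        hierarchy <- rbind(hierarchy,
                           data.frame(child = grp[[gi]], parent = pid,
                                      stringsAsFactors = FALSE))
      }
      children <- parents
    }
  }
  pathway_repo(pathways, hierarchy = hierarchy)
}
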