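#' One-mode projection of the gene--pathway graph onto genes
#'
#' Two genes are connected iff they are co-annotated in at least one pathway;
#' the edge value is the exact number of co-annotating pathways. Computed as
#' the sparse cross-product of the incidence matrix.
#'
#' @param b a `bipartite_graph` from [build_bipartite()].
#' @return Object of class `gene_projection`: list with `nodes` (gene ids)
#'   and `edges` (data frame `gene_a`, `gene_b`, `shared`; `gene_a < gene_b`).
#' @export
project_one_mode <- function(b) {
  stopifnot(inherits(b, "bipartite_graph"))
  S <- Matrix::tcrossprod(b$incidence)           # genes x genes shared counts
  S <- methods::as(Matrix::triu(S, k = 1L), "TsparseMatrix")
  edges <- data.frame(gene_a = b$gene_nodes[S@i + 1L],
                      gene_b = b$gene_nodes[S@j + 1L],
                      shared = as.integer(S@x),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$shared > 0L, , drop = FALSE]
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = b$gene_nodes, edges = edges),
            class = "gene_projection")
}

#' @export
print.gene_projection <- function(x, ...) {
  cat(sprintf("gene_projection: %d genes, %d co-annotation edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# ---- weighting schemes -------------------------------------------------

.scheme_registry <- new.env(parent = emptyenv())

#' Register a gene-pair weighting scheme
#'
#' A scheme maps the two constituent genes' pathway-membership counts
#' (i, j >= 1) to a reliability weight in (0, 1]. The default scheme,
#' `"reciprocal"`, is the average inverse membership
#' \eqn{w_{i,j} = (i + j) / (2 i j)}: a pair of two pathway-unique genes
#' scores 1, multifunctional pairs score lower.
#'
#' @param name scheme identifier.
#' @param fn vectorised function of `(i, j)` returning weights in (0, 1].
#' @export
register_weight_scheme <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .scheme_registry)
  invisible(name)
}

#' @rdname register_weight_scheme
#' @export
weight_schemes <- function() sort(ls(.scheme_registry))

register_weight_scheme("reciprocal", function(i, j) (i + j) / (2 * i * j))
register_weight_scheme("unit", function(i, j) rep(1, length(i)))
register_weight_scheme("min_inverse", function(i, j) 1 / pmax(i, j))

#' Weight of a gene-pair signature
#'
#' @param i,j numbers of pathways annotating the two constituent genes
#'   (positive integers; vectorised).
#' @param scheme registered scheme name (see [weight_schemes()]).
#' @return Numeric weights in (0, 1].
#' @examples
#' gps_weight(1, 1)  # 1
#' gps_weight(4, 3)  # 7/24
#' @export
gps_weight <- function(i, j, scheme = "reciprocal") {
  if (!exists(scheme, envir = .scheme_registry, inherits = FALSE))
    stop("unknown weighting scheme '", scheme, "'; registered schemes: ",
         paste(weight_schemes(), collapse = ", "), call. = FALSE)
  stopifnot(all(i >= 1), all(j >= 1))
  get(scheme, envir = .scheme_registry)(i, j)
}

# ---- signature identification ------------------------------------------

#' Find gene-pair signatures of a flat repository
#'
#' A gene pair is a signature of a pathway when the two genes are
#' co-annotated in exactly that one pathway (projection edge value 1).
#' When `include_self_pairs` is `TRUE`, every pathway-unique gene (PUG,
#' bipartite degree 1) additionally yields a self-pair signature for its
#' pathway.
#'
#' @param repo a [pathway_repo]; the hierarchy (if any) is ignored here —
#'   use [build_gps_db()] for the level-wise hierarchical compilation.
#' @param include_self_pairs emit PUG self-pairs (default `TRUE`).
#' @return Data frame `gene_a`, `gene_b`, `pathway`, `deg_a`, `deg_b` with
#'   `gene_a <= gene_b` (equality marks a self-pair). Degrees are bipartite
#'   gene degrees within `repo`.
#' @export
find_signatures <- function(repo, include_self_pairs = TRUE) {
  b <- build_bipartite(repo)
  deg <- bipartite_degrees(b, "gene")
  S <- Matrix::tcrossprod(b$incidence)
  out <- vector("list", length(repo$pathways) + 1L)
  k <- 0L
  for (pid in pathway_ids(repo)) {
    g <- sort(repo$pathways[[pid]])
    if (length(g) < 2L) next
    pr <- utils::combn(g, 2L)
    ia <- match(pr[1L, ], b$gene_nodes)
    ib <- match(pr[2L, ], b$gene_nodes)
    keep <- S[cbind(ia, ib)] == 1
    if (!any(keep)) next
    k <- k + 1L
    out[[k]] <- data.frame(gene_a = pr[1L, keep], gene_b = pr[2L, keep],
                           pathway = pid,
                           deg_a = as.integer(deg[pr[1L, keep]]),
                           deg_b = as.integer(deg[pr[2L, keep]]),
                           stringsAsFactors = FALSE)
  }
  if (include_self_pairs) {
    pugs <- names(deg)[deg == 1L]
    if (length(pugs) > 0L) {
      owner <- b$edges$pathway[match(pugs, b$edges$gene)]
      k <- k + 1L
      out[[k]] <- data.frame(gene_a = pugs, gene_b = pugs, pathway = owner,
                             deg_a = 1L, deg_b = 1L, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      pathway = character(), deg_a = integer(),
                      deg_b = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$pathway, res$gene_a, res$gene_b, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# drop a set of pathways (and their annotations) from a repository
drop_pathways <- function(repo, ids) {
  repo$pathways <- repo$pathways[setdiff(pathway_ids(repo), ids)]
  repo$names <- repo$names[names(repo$pathways)]
  h <- repo$hierarchy
  repo$hierarchy <- h[h$child %in% names(repo$pathways) &
                        h$parent %in% names(repo$pathways), , drop = FALSE]
  repo
}

#' Compile a signature database (offline phase)
#'
#' Turns a pathway repository into disjoint, weighted per-pathway gene-pair
#' signature (GPS) sets. For a flat repository this is a single pass of
#' [find_signatures()] plus weighting. For a hierarchical repository the
#' compilation is iterative and top-down: signatures are compiled at level 1
#' over the full repository; then all current root pathways (no parent among
#' the remaining pathways) are removed together with their annotations, the
#' level counter is incremented, and signatures are recompiled over the
#' survivors, exposing pairs that were previously masked by the more general
#' parents. Iteration stops when no hierarchy edges remain among the
#' survivors (which are then all assigned the final level). A given
#' (pair, pathway) signature is emitted only at the first level at which it
#' qualifies.
#'
#' @param repo a [pathway_repo].
#' @param scheme weighting scheme name (see [register_weight_scheme()]).
#' @param include_self_pairs emit weight-1 self-pair signatures for
#'   pathway-unique genes (default `TRUE`).
#' @param degrees `"level"` (default): the membership counts (i, j) feeding
#'   the weight are computed within the repository remaining at the level
#'   where the signature is emitted; `"global"`: always use full-repository
#'   degrees.
#' @return Object of class `gps_db`: list with `signatures` (data frame
#'   `gene_a`, `gene_b`, `pathway`, `weight`, `level`, `deg_a`, `deg_b`),
#'   `pathway_levels` (named integer: level at which each pathway was
#'   removed; all 1 for a flat repository), `pathway_names`, and `options`.
#' @export
build_gps_db <- function(repo, scheme = "reciprocal",
                         include_self_pairs = TRUE,
                         degrees = c("level", "global")) {
  stopifnot(is.pathway_repo(repo))
  degrees <- match.arg(degrees)
  gps_weight(1, 1, scheme)                       # validate scheme early
  global_deg <- bipartite_degrees(build_bipartite(repo), "gene")

  remaining <- repo
  level <- 1L
  emitted <- character(0L)
  chunks <- list()
  pathway_levels <- integer(0L)
  while (length(remaining$pathways) > 0L) {
    sig <- find_signatures(remaining, include_self_pairs = include_self_pairs)
    key <- paste(sig$gene_a, sig$gene_b, sig$pathway, sep = "\r")
    sig <- sig[!key %in% emitted, , drop = FALSE]
    emitted <- c(emitted, setdiff(key, emitted))
    if (nrow(sig) > 0L) {
      if (degrees == "global") {
        sig$deg_a <- as.integer(global_deg[sig$gene_a])
        sig$deg_b <- as.integer(global_deg[sig$gene_b])
      }
      self <- sig$gene_a == sig$gene_b
      sig$weight <- ifelse(self, 1, gps_weight(sig$deg_a, sig$deg_b, scheme))
      sig$level <- level
      chunks[[level]] <- sig
    }
    ids <- pathway_ids(remaining)
    h <- remaining$hierarchy
    if (nrow(h) == 0L) {                         # flat remainder: all done
      pathway_levels[ids] <- level
      break
    }
    roots <- setdiff(ids, unique(h$child))       # no parent among survivors
    pathway_levels[roots] <- level
    remaining <- drop_pathways(remaining, roots)
    level <- level + 1L
  }
  sigs <- if (length(chunks) > 0L) do.call(rbind, chunks) else
    data.frame(gene_a = character(), gene_b = character(),
               pathway = character(), deg_a = integer(), deg_b = integer(),
               weight = numeric(), level = integer(),
               stringsAsFactors = FALSE)
  sigs <- sigs[, c("gene_a", "gene_b", "pathway", "weight", "level",
                   "deg_a", "deg_b")]
  sigs <- sigs[order(sigs$pathway, sigs$gene_a, sigs$gene_b,
                     method = "radix"), , drop = FALSE]
  rownames(sigs) <- NULL
  structure(list(signatures = sigs,
                 pathway_levels = pathway_levels[pathway_ids(repo)],
                 pathway_names = repo$names,
                 options = list(scheme = scheme,
                                include_self_pairs = include_self_pairs,
                                degrees = degrees)),
            class = "gps_db")
}

#' @export
print.gps_db <- function(x, ...) {
  cat(sprintf(
    "gps_db: %d signatures (%d self-pairs) for %d pathways, %d level(s)\n",
    nrow(x$signatures), sum(x$signatures$gene_a == x$signatures$gene_b),
    length(x$pathway_levels), max(c(1L, x$signatures$level))))
  invisible(x)
}

#' @rdname build_gps_db
#' @param db a `gps_db`.
#' @export
max_level <- function(db) max(c(1L, db$signatures$level))

# Per-pathway and universe weight sums of possible signatures at
# level <= `level`, optionally restricted to a background gene set
# (a signature with any constituent gene outside the background is
# excluded from the universe).
gps_possible <- function(db, level = max_level(db), background = NULL) {
  s <- db$signatures[db$signatures$level <= level, , drop = FALSE]
  if (!is.null(background))
    s <- s[s$gene_a %in% background & s$gene_b %in% background, ,
           drop = FALSE]
  per <- vapply(split(s$weight, s$pathway), sum, numeric(1L))
  list(per_pathway = per, universe = sum(s$weight), signatures = s)
}

#' Write / read a compiled signature database
#'
#' Two files are produced: `<prefix>.gps.tsv` with one signature per row
#' (deterministic order: pathway, then pair), and `<prefix>.meta.json`
#' holding the compilation options, pathway levels and pathway names.
#'
#' @param db a `gps_db` from [build_gps_db()].
#' @param prefix output path prefix.
#' @return `prefix` (write) or the restored `gps_db` (read).
#' @export
write_gps_db <- function(db, prefix) {
  utils::write.table(db$signatures, paste0(prefix, ".gps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(options = db$options,
               pathway_levels = as.list(db$pathway_levels),
               pathway_names = as.list(db$pathway_names))
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_gps_db
#' @export
read_gps_db <- function(prefix) {
  tsv <- paste0(prefix, ".gps.tsv")
  js <- paste0(prefix, ".meta.json")
  if (!file.exists(tsv) || !file.exists(js))
    stop("missing signature database files for prefix: ", prefix,
         call. = FALSE)
  sigs <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character", "numeric", "integer",
                                           "integer", "integer"))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  structure(list(signatures = sigs,
                 pathway_levels = unlist(meta$pathway_levels),
                 pathway_names = unlist(meta$pathway_names),
                 options = meta$options),
            class = "gps_db")
}
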