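#' Classic individual-gene over-representation analysis
#'
#' The traditional ORA comparator: for each pathway, k is the number of
#' query genes in the pathway, n the pathway size, m the query size and N
#' the number of annotated genes (all restricted to the background when one
#' is given), tested with the upper-tail hypergeometric. Sorting, ranking,
#' adjustment and export contracts match [run_sigora()]; the conventional
#' significance rule for this baseline is a Benjamini--Hochberg FDR of at
#' most 0.05, hence the different defaults.
#'
#' @param repo a [pathway_repo].
#' @param query character vector of gene ids.
#' @param background optional character vector of assayed gene ids; the
#'   universe becomes its intersection with the annotated genes.
#' @param mtc,significance,full_table as in [run_sigora()]
#'   (defaults `"bh"`, 0.05).
#' @return An `enrichment_table` data frame (see [run_sigora()]); raw and
#'   rounded parameters coincide since all sums are integer counts.
#' @export
run_ig_ora <- function(repo, query, background = NULL,
                       mtc = "bh", significance = 0.05,
                       full_table = FALSE) {
  stopifnot(is.pathway_repo(repo))
  universe <- all_genes(repo)
  if (!is.null(background)) universe <- intersect(universe, background)
  query <- unique(as.character(query))
  used <- intersect(query, universe)
  if (length(used) == 0L)
    stop("query has no overlap with the annotated universe (",
         length(query), " id(s) supplied)", call. = FALSE)
  if (length(used) < length(query))
    message("run_ig_ora: dropped ", length(query) - length(used),
            " query id(s) outside the universe")
  sets <- lapply(repo$pathways, intersect, universe)
  n <- lengths(sets)
  keep <- n > 0L
  sets <- sets[keep]
  n <- n[keep]
  k <- vapply(sets, function(g) length(intersect(g, used)), integer(1L))
  tab <- data.frame(pathway = names(sets),
                    raw_k = as.numeric(k), raw_n = as.numeric(n),
                    raw_m = length(used), raw_N = length(universe),
                    k = as.integer(k), n = as.integer(n),
                    m = length(used), N = length(universe),
                    stringsAsFactors = FALSE)
  tab$p_raw <- hyper_upper_tail(tab$k, tab$n, tab$m, tab$N)
  tab$name <- unname(repo$names[tab$pathway])
  tab$genes <- vapply(sets, function(g)
    paste(sort(intersect(g, used)), collapse = ";"), character(1L))
  tab <- finish_table(tab, mtc, significance, full_table)
  class(tab) <- c("enrichment_table", class(tab))
  tab
}
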