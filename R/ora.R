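#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with mass
#' \eqn{C(m, x) C(N - m, n - x) / C(N, n)}: `n` draws from a universe of
#' size `N` containing `m` marked items. Computed through the distribution
#' function (`stats::phyper`, evaluated in log-space internally) and clamped
#' to [0, 1]. `k = 0` returns exactly 1.
#'
#' @param k,n,m,N non-negative integers (vectorised, recycled) with
#'   `k <= min(n, m)` and `n, m <= N`.
#' @return Numeric vector of tail probabilities.
#' @export
hyper_upper_tail <- function(k, n, m, N) {
  v <- cbind(k = k, n = n, m = m, N = N)
  k <- v[, "k"]; n <- v[, "n"]; m <- v[, "m"]; N <- v[, "N"]
  if (any(k < 0)) stop("violated: k >= 0", call. = FALSE)
  if (any(n > N)) stop("violated: n <= N", call. = FALSE)
  if (any(m > N)) stop("violated: m <= N", call. = FALSE)
  if (any(k > pmin(n, m))) stop("violated: k <= min(n, m)", call. = FALSE)
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  p[k == 0] <- 1
  unname(pmin(pmax(p, 0), 1))
}

#' Adjust p-values for multiple testing
#'
#' Thin validated wrapper mapping this package's method names onto
#' [stats::p.adjust()]: `"bonferroni"` (min(1, p * T), the default
#' correction throughout), `"bh"` (Benjamini--Hochberg step-up FDR) and
#' `"none"`. Output order matches input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"`, `"bh"` or `"none"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  switch(method,
         bonferroni = stats::p.adjust(p, "bonferroni"),
         bh = stats::p.adjust(p, "BH"),
         none = p)
}

# Rounding strategies for weight sums. "nearest" rounds half away from zero
# (platform-stable, unlike round()'s half-to-even); "phyper_compat" mirrors
# R's phyper handling of non-integer input: successes (k) rounded down, all
# remaining parameters to the nearest integer.
round_half_up <- function(x) floor(x + 0.5)

round_params <- function(raw, rounding) {
  f <- switch(rounding,
              nearest = round_half_up,
              floor = floor,
              ceiling = ceiling,
              phyper_compat = NULL,
              stop("unknown rounding strategy: ", rounding, call. = FALSE))
  if (rounding == "phyper_compat") {
    list(k = floor(raw$k), n = round_half_up(raw$n),
         m = round_half_up(raw$m), N = round_half_up(raw$N))
  } else {
    list(k = f(raw$k), n = f(raw$n), m = f(raw$m), N = f(raw$N))
  }
}

#' Match precompiled signatures against a query gene list
#'
#' A pair signature is present iff both constituent genes are in the query;
#' a self-pair is present iff its gene is. Signatures above the level
#' threshold are ignored, and when a background is supplied any signature
#' with a constituent gene outside the background is excluded from both the
#' present and the possible sets. Query ids not appearing in any considered
#' signature are dropped with a message; an empty query after filtering is
#' an error.
#'
#' @param db a `gps_db` from [build_gps_db()].
#' @param query character vector of gene ids.
#' @param level hierarchy-level threshold; signatures at levels up to this
#'   value are considered (default: all levels).
#' @param background optional character vector of assayed gene ids.
#' @return List: `present` (signature rows present in the query),
#'   `possible` (all considered signature rows), `per_pathway_possible`,
#'   `universe`, `query_used`.
#' @export
match_signatures <- function(db, query, level = max_level(db),
                             background = NULL) {
  stopifnot(inherits(db, "gps_db"))
  query <- unique(as.character(query))
  poss <- gps_possible(db, level = level, background = background)
  sig_genes <- unique(c(poss$signatures$gene_a, poss$signatures$gene_b))
  used <- intersect(query, sig_genes)
  dropped <- length(query) - length(used)
  if (length(used) == 0L)
    stop("query has no overlap with signature genes (",
         length(query), " id(s) supplied, ", dropped, " dropped)",
         call. = FALSE)
  if (dropped > 0L)
    message("match_signatures: dropped ", dropped,
            " query id(s) absent from the considered signatures")
  s <- poss$signatures
  present <- s[s$gene_a %in% used & s$gene_b %in% used, , drop = FALSE]
  list(present = present, possible = s,
       per_pathway_possible = poss$per_pathway,
       universe = poss$universe, query_used = used)
}

#' Build weighted hypergeometric test parameters
#'
#' For each pathway with a non-empty possible signature set: `raw_k` is the
#' weight sum of its present signatures, `raw_n` the weight sum of its
#' possible signatures, `raw_m` the weight sum of all present signatures,
#' and `raw_N` the universe weight sum; the integer parameters (k, n, m, N)
#' are the rounded sums.
#'
#' @param matched result of [match_signatures()].
#' @param rounding `"nearest"` (half away from zero; default), `"floor"`,
#'   `"ceiling"`, or `"phyper_compat"` (k floored, the rest to nearest).
#' @return Data frame, one row per testable pathway, with raw and rounded
#'   parameters.
#' @export
build_parameters <- function(matched, rounding = "nearest") {
  per_poss <- matched$per_pathway_possible
  ids <- names(per_poss)
  per_pres <- vapply(split(matched$present$weight, matched$present$pathway),
                     sum, numeric(1L))
  raw <- list(
    k = unname(ifelse(ids %in% names(per_pres), per_pres[ids], 0)),
    n = unname(per_poss),
    m = sum(matched$present$weight),
    N = matched$universe)
  rnd <- round_params(raw, rounding)
  data.frame(pathway = ids,
             raw_k = raw$k, raw_n = raw$n, raw_m = raw$m, raw_N = raw$N,
             k = rnd$k, n = rnd$n, m = rnd$m, N = rnd$N,
             stringsAsFactors = FALSE)
}

# shared ordering / ranking / MTC / filtering for both engines
finish_table <- function(tab, mtc, significance, full_table) {
  tab$p_bonferroni <- adjust_pvalues(tab$p_raw, "bonferroni")
  tab$p_bh <- adjust_pvalues(tab$p_raw, "bh")
  o <- order(tab$p_raw, -tab$k, tab$pathway, method = "radix")
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  p_sel <- switch(mtc, bonferroni = tab$p_bonferroni, bh = tab$p_bh,
                  none = tab$p_raw,
                  stop("unknown MTC method: ", mtc, call. = FALSE))
  tab$significant <- p_sel <= significance
  if (full_table) tab else tab[tab$significant, , drop = FALSE]
}

#' Signature over-representation analysis of a gene list
#'
#' The online phase: matches the precompiled signature database against a
#' query list, sums signature weights into weighted hypergeometric
#' parameters (see [build_parameters()]), computes upper-tail p-values,
#' adjusts them (Bonferroni and Benjamini--Hochberg are both reported) and
#' ranks the pathways by raw p-value (ties: larger k first, then pathway id).
#' The recommended significance rule is a Bonferroni-corrected p-value of at
#' most 0.001 — the weighted pair universe is orders of magnitude larger
#' than a gene universe, so p-values run far smaller than in individual-gene
#' ORA and a stricter cut-off is appropriate.
#'
#' @inheritParams match_signatures
#' @param rounding see [build_parameters()].
#' @param mtc column used by the significance filter: `"bonferroni"`
#'   (default), `"bh"`, or `"none"`.
#' @param significance cut-off applied to the `mtc` column (default 0.001).
#' @param full_table return all tested pathways instead of only the
#'   significant ones.
#' @return Data frame of class `enrichment_table`, one row per tested
#'   pathway: `pathway`, `name`, parameters, `p_raw`, `p_bonferroni`,
#'   `p_bh`, `rank`, `significant`, and `genes` (semicolon-joined sorted
#'   genes involved in present signatures). The present signature rows are
#'   attached as attribute `"present"`; present PUG self-pair genes per
#'   pathway as attribute `"present_pugs"`.
#' @export
run_sigora <- function(db, query, level = max_level(db), background = NULL,
                       rounding = "nearest", mtc = "bonferroni",
                       significance = 0.001, full_table = FALSE) {
  matched <- match_signatures(db, query, level = level,
                              background = background)
  tab <- build_parameters(matched, rounding = rounding)
  tab$p_raw <- hyper_upper_tail(tab$k, tab$n, tab$m, tab$N)
  nm <- db$pathway_names[tab$pathway]
  tab$name <- ifelse(is.na(nm), tab$pathway, nm)
  pres <- matched$present
  genes_by_pw <- lapply(split(c(pres$gene_a, pres$gene_b),
                              c(pres$pathway, pres$pathway)),
                        function(g) sort(unique(g)))
  tab$genes <- vapply(tab$pathway, function(p) {
    g <- genes_by_pw[[p]]
    if (is.null(g)) "" else paste(g, collapse = ";")
  }, character(1L))
  tab <- finish_table(tab, mtc, significance, full_table)
  attr(tab, "present") <- pres
  pugs <- pres[pres$gene_a == pres$gene_b, , drop = FALSE]
  attr(tab, "present_pugs") <- split(pugs$gene_a, pugs$pathway)
  class(tab) <- c("enrichment_table", class(tab))
  tab
}

#' Export an enrichment table to CSV
#'
#' @param rows an `enrichment_table` from [run_sigora()] or [run_ig_ora()].
#' @param path output CSV path.
#' @param include_genes include the semicolon-joined evidence gene column.
#' @return `path`, invisibly.
#' @export
export_results <- function(rows, path, include_genes = FALSE) {
  cols <- c("pathway", "name", "k", "n", "m", "N",
            "p_raw", "p_bonferroni", "p_bh", "rank")
  if (include_genes) cols <- c(cols, "genes")
  out <- as.data.frame(rows)[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to: ", path, call. = FALSE)
  invisible(path)
}
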