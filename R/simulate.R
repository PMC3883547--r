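#' Sample a simulated differential-expression query
#'
#' Draws `n_pathways` pathways uniformly without replacement from the
#' eligible pathways (size at least `min_size`), then marks a fraction
#' `alpha` of each chosen pathway's genes as differentially expressed:
#' `max(1, round(alpha * size))` genes sampled uniformly without replacement
#' (rounding half away from zero). The query is the union of the sampled
#' genes.
#'
#' @param repo a [pathway_repo].
#' @param n_pathways number of pathways to plant (default 5).
#' @param alpha fraction of each chosen pathway marked DE.
#' @param min_size eligibility threshold on pathway size.
#' @return List with `chosen` (pathway ids) and `query` (gene ids).
#' @export
sample_query <- function(repo, n_pathways = 5, alpha = 0.5, min_size = 5) {
  stopifnot(is.pathway_repo(repo), alpha > 0, alpha <= 1)
  eligible <- pathway_ids(repo)[pathway_sizes(repo) >= min_size]
  if (length(eligible) < n_pathways)
    stop("only ", length(eligible), " eligible pathway(s) of size >= ",
         min_size, "; need ", n_pathways, call. = FALSE)
  chosen <- sample(eligible, n_pathways)
  query <- unique(unlist(lapply(chosen, function(p) {
    g <- repo$pathways[[p]]
    sample(g, max(1L, round_half_up(alpha * length(g))))
  }), use.names = FALSE))
  list(chosen = chosen, query = query)
}

#' Score one simulation replicate
#'
#' A significant pathway is a true positive if it is among the chosen
#' (planted) pathways and a false positive otherwise; chosen pathways not
#' called significant are false negatives. Precision is tp / |significant|
#' (`NA` when nothing is significant), recall tp / |chosen|, F1 their
#' harmonic mean. `avg_rank` is the mean rank of the chosen pathways within
#' the full ranked table; a chosen pathway absent from the table (no
#' possible signatures) is assigned rank T + 1 where T is the table length.
#'
#' @param rows full ranked `enrichment_table` covering all tested pathways.
#' @param significant character vector of significant pathway ids.
#' @param chosen character vector of planted pathway ids.
#' @return One-row data frame of per-run metrics.
#' @export
score_run <- function(rows, significant, chosen) {
  tp <- length(intersect(significant, chosen))
  fp <- length(significant) - tp
  fn <- length(chosen) - tp
  precision <- if (length(significant) > 0L) tp / length(significant) else NA_real_
  recall <- tp / length(chosen)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_ else
    2 * precision * recall / (precision + recall)
  r <- rows$rank[match(chosen, rows$pathway)]
  r[is.na(r)] <- nrow(rows) + 1L
  data.frame(significant_count = length(significant),
             tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1,
             avg_rank = mean(r))
}

#' Simulation benchmark of an over-representation method
#'
#' Repeats, `replicates` times: plant `n_pathways` pathways via
#' [sample_query()], run the chosen method on the sampled query, record
#' which pathways it calls significant, and score the run with
#' [score_run()]. Per-method significance rules follow each method's own
#' recommendation by default: signature ORA at Bonferroni 0.001,
#' individual-gene ORA at Benjamini--Hochberg 0.05 (both overridable
#' through `method_options`). The signature database is compiled once and
#' reused across replicates. Results are reproducible for a fixed seed.
#'
#' Summary semantics: `mean_precision` averages only the replicates with at
#' least one significant call (their count is reported as
#' `replicates_used_for_precision`); `f1_of_means` is the harmonic mean of
#' `mean_precision` and `mean_recall`.
#'
#' @param repo a [pathway_repo].
#' @param method `"sigora"` or `"ig-ora"`.
#' @param n_pathways,alpha,min_size passed to [sample_query()].
#' @param replicates number of simulated gene lists (default 1000).
#' @param seed integer seed for the whole experiment.
#' @param method_options named list overriding method arguments
#'   (e.g. `level`, `rounding`, `mtc`, `significance`).
#' @return Object of class `sim_result`: list with `summary` (one-row data
#'   frame), `replicates` (per-run metrics), and `config`.
#' @export
run_simulation <- function(repo, method = c("sigora", "ig-ora"),
                           n_pathways = 5, alpha = 0.5, replicates = 1000,
                           seed = 1, min_size = 5, method_options = list()) {
  method <- match.arg(method)
  stopifnot(is.pathway_repo(repo))
  defaults <- if (method == "sigora")
    list(mtc = "bonferroni", significance = 0.001, rounding = "nearest",
         level = NULL, scheme = "reciprocal", include_self_pairs = TRUE)
  else
    list(mtc = "bh", significance = 0.05)
  opts <- utils::modifyList(defaults, method_options)

  db <- NULL
  if (method == "sigora") {
    db <- build_gps_db(repo, scheme = opts$scheme,
                       include_self_pairs = opts$include_self_pairs)
    if (is.null(opts$level)) opts$level <- max_level(db)
  }
  set.seed(seed)
  runs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    s <- sample_query(repo, n_pathways = n_pathways, alpha = alpha,
                      min_size = min_size)
    tab <- if (method == "sigora") {
      tryCatch(
        suppressMessages(run_sigora(db, s$query, level = opts$level,
                                    rounding = opts$rounding,
                                    mtc = opts$mtc,
                                    significance = opts$significance,
                                    full_table = TRUE)),
        error = function(e) NULL)   # query misses every signature gene
    } else {
      suppressMessages(run_ig_ora(repo, s$query, mtc = opts$mtc,
                                  significance = opts$significance,
                                  full_table = TRUE))
    }
    if (is.null(tab))
      tab <- data.frame(pathway = character(), rank = integer(),
                        significant = logical())
    runs[[r]] <- score_run(tab, tab$pathway[tab$significant], s$chosen)
  }
  reps <- do.call(rbind, runs)
  with_sig <- !is.na(reps$precision)
  mean_precision <- if (any(with_sig)) mean(reps$precision[with_sig]) else NA_real_
  mean_recall <- mean(reps$recall)
  f1_of_means <- if (is.na(mean_precision) ||
                     mean_precision + mean_recall == 0) NA_real_ else
    2 * mean_precision * mean_recall / (mean_precision + mean_recall)
  summary <- data.frame(
    method = method,
    mean_significant = mean(reps$significant_count),
    mean_recall = mean_recall,
    mean_precision = mean_precision,
    f1_of_means = f1_of_means,
    mean_avg_rank = mean(reps$avg_rank),
    replicates_used_for_precision = sum(with_sig),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, replicates = reps,
                 config = list(method = method, n_pathways = n_pathways,
                               alpha = alpha, replicates = replicates,
                               seed = seed, min_size = min_size,
                               method_options = opts)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %s, %d replicates (n = %d, alpha = %.2f)\n",
              x$config$method, x$config$replicates, x$config$n_pathways,
              x$config$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
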