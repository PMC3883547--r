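# Independent oracles used to cross-check the implementation. These share no
# code with the package internals: signature identification is re-derived by
# enumerating within-pathway gene pairs and tallying co-annotation counts
# with table(), and the hypergeometric tail is summed directly from the
# binomial-coefficient mass.

# All (pair, pathway) and PUG self-pair signatures of a flat repository,
# by brute-force enumeration.
brute_signatures <- function(repo, include_self_pairs = TRUE) {
  pair_key <- character(0)
  pair_pw <- character(0)
  for (pid in names(repo$pathways)) {
    g <- sort(repo$pathways[[pid]])
    if (length(g) >= 2L) {
      pr <- utils::combn(g, 2L)
      pair_key <- c(pair_key, paste(pr[1L, ], pr[2L, ], sep = "\r"))
      pair_pw <- c(pair_pw, rep(pid, ncol(pr)))
    }
  }
  counts <- table(pair_key)
  keep <- pair_key %in% names(counts)[counts == 1L]
  parts <- strsplit(pair_key[keep], "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[[`, character(1L), 1L),
    gene_b = vapply(parts, `[[`, character(1L), 2L),
    pathway = pair_pw[keep], stringsAsFactors = FALSE)
  if (include_self_pairs) {
    gene <- unlist(repo$pathways, use.names = FALSE)
    pw <- rep(names(repo$pathways), lengths(repo$pathways))
    deg <- table(gene)
    pug <- gene %in% names(deg)[deg == 1L]
    out <- rbind(out, data.frame(gene_a = gene[pug], gene_b = gene[pug],
                                 pathway = pw[pug], stringsAsFactors = FALSE))
  }
  out <- out[order(out$pathway, out$gene_a, out$gene_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Exact upper tail: sum_{x=k}^{min(n,m)} C(m,x) C(N-m,n-x) / C(N,n).
# Binomial coefficients are integer-exact in doubles for N <= 30.
hyper_tail_oracle <- function(k, n, m, N) {
  if (k > min(n, m)) return(0)
  x <- k:min(n, m)
  sum(choose(m, x) * choose(N - m, n - x)) / choose(N, n)
}

# small random flat repository with mixed sharing, for property tests
random_repo <- function(seed) {
  generate_repo(n_pathways = 8 + seed %% 25,
                gene_pool = 500,
                size_range = c(3, 10),
                n_shared_blocks = seed %% 5,
                block_size = 2 + seed %% 3,
                pathways_per_block = 2 + seed %% 3,
                seed = seed)
}

sig_key <- function(df) paste(df$gene_a, df$gene_b, df$pathway, sep = "\r")
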