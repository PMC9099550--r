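#' Thresholded Spearman correlation
#'
#' Rank correlation with mid-rank ties and a two-sided p-value (exact for
#' n <= 9 without ties, t-approximation otherwise). Pairs with a missing
#' member are dropped. The `recorded` value implements the zeroing rule:
#' rho is recorded only if p <= `p_cutoff`, otherwise 0. With fewer than
#' `min_n` complete pairs nothing is computed (`computed = FALSE`, distinct
#' from a recorded 0).
#'
#' @param x,y Paired numeric vectors.
#' @param p_cutoff Recording cutoff on the p-value (default 0.05).
#' @param min_n Minimum complete pairs (default 3).
#' @return List: `rho`, `p`, `recorded`, `n`, `computed`.
#' @export
spearman_thresholded <- function(x, y, p_cutoff = 0.05, min_n = 3) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n)
    return(list(rho = NA_real_, p = NA_real_, recorded = NA_real_,
                n = n, computed = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 9))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  list(rho = rho, p = p,
       recorded = if (is.finite(p) && p <= p_cutoff) rho else 0,
       n = n, computed = TRUE)
}

#' Pairwise recorded-rho matrix of a feature table
#'
#' Applies [spearman_thresholded()] to every pair of columns; the entry is
#' the recorded rho (0 when not significant, `NA` when not computable).
#'
#' @param features Numeric `data.frame`/matrix, observations in rows.
#' @param p_cutoff,min_n Passed to [spearman_thresholded()].
#' @return List: `recorded` and `p` (symmetric matrices).
#' @export
spearman_matrix <- function(features, p_cutoff = 0.05, min_n = 3) {
  X <- as.matrix(features)
  k <- ncol(X)
  rec <- pmat <- matrix(NA_real_, k, k,
                        dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k)) {
    rec[i, i] <- 1; pmat[i, i] <- 0
    for (j in seq_len(k)[-seq_len(i)]) {
      r <- spearman_thresholded(X[, i], X[, j], p_cutoff, min_n)
      rec[i, j] <- rec[j, i] <- r$recorded
      pmat[i, j] <- pmat[j, i] <- r$p
    }
  }
  list(recorded = rec, p = pmat)
}

#' Hierarchically cluster a correlation matrix
#'
#' Complete-linkage clustering on the Euclidean distances between rows (and
#' columns) of the recorded-rho matrix; constant rows carry no ordering
#' information and are placed last with a warning. Deterministic for fixed
#' input.
#'
#' @param r Numeric matrix of recorded correlation coefficients.
#' @return List: `matrix` (reordered), `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust` (NULL when fewer than 3 variable rows).
#' @export
correlation_cluster <- function(r) {
  r <- as.matrix(r)
  order_side <- function(m) {
    const <- apply(m, 1, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                     all(is.na(v)))
    if (any(const))
      warning(sum(const), " constant row(s)/column(s) placed last")
    idx <- which(!const)
    if (length(idx) < 3)
      return(list(order = c(idx, which(const)), hc = NULL))
    hc <- stats::hclust(stats::dist(m[idx, , drop = FALSE]),
                        method = "complete")
    list(order = c(idx[hc$order], which(const)), hc = hc)
  }
  ro <- order_side(r)
  co <- order_side(t(r))
  list(matrix = r[ro$order, co$order, drop = FALSE],
       row_order = ro$order, col_order = co$order,
       row_hclust = ro$hc, col_hclust = co$hc)
}

#' Rank gene products by signed correlation confidence
#'
#' Per transport metric, gene products are scored `(1 - p) * sign(rho)` and
#' sorted descending, so strong positive correlators top the list and
#' strong anti-correlators sink to the bottom. For a multi-metric list every
#' gene gets its best (minimum) per-metric rank as merged rank, and the list
#' is re-sorted by it.
#'
#' @param corr Named list (one element per metric) of `data.frame`s with
#'   columns `gene`, `rho`, `p` (e.g. rows of [spearman_thresholded()]
#'   results).
#' @param metrics Metrics to include (default: all in `corr`).
#' @return `data.frame` ordered for enrichment export: single metric ->
#'   `gene`, `score`; several metrics -> per-metric scores/ranks plus
#'   `merged_rank`.
#' @export
ranked_list <- function(corr, metrics = names(corr)) {
  if (!length(metrics)) stop("empty metric subset", call. = FALSE)
  if (!all(metrics %in% names(corr)))
    stop("unknown metric(s): ",
         paste(setdiff(metrics, names(corr)), collapse = ", "),
         call. = FALSE)
  score_one <- function(d) {
    s <- (1 - d$p) * sign(d$rho)
    o <- order(-s, d$gene)   # ties broken by gene name for determinism
    data.frame(gene = d$gene[o], score = s[o],
               rank = seq_along(o), stringsAsFactors = FALSE)
  }
  scored <- lapply(corr[metrics], score_one)
  if (length(metrics) == 1L)
    return(scored[[1]][, c("gene", "score")])
  genes <- sort(unique(unlist(lapply(scored, `[[`, "gene"))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  rk <- matrix(NA_real_, length(genes), length(metrics),
               dimnames = list(genes, metrics))
  for (m in metrics) {
    i <- match(scored[[m]]$gene, genes)
    out[[paste0("score_", m)]] <- NA_real_
    out[[paste0("score_", m)]][i] <- scored[[m]]$score
    out[[paste0("rank_", m)]] <- NA_real_
    out[[paste0("rank_", m)]][i] <- scored[[m]]$rank
    rk[i, m] <- scored[[m]]$rank
  }
  out$merged_rank <- apply(rk, 1, min, na.rm = TRUE)
  out[order(out$merged_rank, out$gene), , drop = FALSE]
}

#' Partition significant correlators by metric combination
#'
#' Classifies every gene product into the seven non-empty subsets of
#' \{TK, RMS, VDV\} according to which metrics it significantly correlates
#' with, positive and negative correlations tallied separately.
#'
#' @param tk,rms,vdv `data.frame`s with columns `gene` and `recorded` (the
#'   zeroed rho), sharing a gene universe.
#' @return Object of class `metric_overlaps`: `data.frame` with rownames
#'   `TK only`, ..., `TK + RMS + VDV` and columns `positive`, `negative`.
#' @export
count_metric_overlaps <- function(tk, rms, vdv) {
  genes <- sort(unique(c(tk$gene, rms$gene, vdv$gene)))
  rec <- function(d) {
    v <- stats::setNames(rep(0, length(genes)), genes)
    v[match(d$gene, genes)] <- ifelse(is.na(d$recorded), 0, d$recorded)
    v
  }
  m <- cbind(TK = rec(tk), RMS = rec(rms), VDV = rec(vdv))
  subsets <- list("TK only" = "TK", "RMS only" = "RMS", "VDV only" = "VDV",
                  "TK + RMS" = c("TK", "RMS"),
                  "RMS + VDV" = c("RMS", "VDV"),
                  "TK + VDV" = c("TK", "VDV"),
                  "TK + RMS + VDV" = c("TK", "RMS", "VDV"))
  count <- function(sgn) {
    hit <- if (sgn > 0) m > 0 else m < 0
    vapply(subsets, function(ss) {
      sum(apply(hit, 1, function(h)
        all(h[ss]) && !any(h[setdiff(colnames(m), ss)])))
    }, numeric(1))
  }
  structure(data.frame(positive = count(1), negative = count(-1),
                       row.names = names(subsets)),
            class = c("metric_overlaps", "data.frame"))
}

#' Per-metric totals of an overlap partition
#'
#' Each metric's total is the sum of the four subset counts that include it
#' (positives and negatives separately). When given printed subset counts
#' alongside printed totals, this is the internal-consistency accounting for
#' overlap tables.
#'
#' @param overlaps A `metric_overlaps` (or any data.frame with the same 7
#'   rownames and `positive`/`negative` columns).
#' @return `data.frame` with rows `Total TK`, `Total RMS`, `Total VDV`.
#' @export
metric_totals <- function(overlaps) {
  contrib <- list(
    TK = c("TK only", "TK + RMS", "TK + VDV", "TK + RMS + VDV"),
    RMS = c("RMS only", "TK + RMS", "RMS + VDV", "TK + RMS + VDV"),
    VDV = c("VDV only", "RMS + VDV", "TK + VDV", "TK + RMS + VDV"))
  out <- t(vapply(contrib, function(rs)
    c(positive = sum(overlaps[rs, "positive"]),
      negative = sum(overlaps[rs, "negative"])), numeric(2)))
  data.frame(out, row.names = paste("Total", names(contrib)))
}

#' Read a protein-interaction edge table
#'
#' TSV with columns `protein1 protein2 combined_score`.
#'
#' @param path TSV path.
#' @return `data.frame` of edges.
#' @export
read_string_edges <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(d)))
    stop("edge table must have columns ", paste(need, collapse = " "),
         call. = FALSE)
  bad <- which(is.na(suppressWarnings(as.numeric(d$combined_score))) |
                 !nzchar(d$protein1) | !nzchar(d$protein2))
  if (length(bad))
    stop("malformed edge record at line ", bad[1] + 1L, call. = FALSE)
  d$combined_score <- as.numeric(d$combined_score)
  d
}

#' Filter interaction edges by combined score
#'
#' Keeps edges with combined score >= `min_score` (boundary inclusive).
#' Scores supplied on the 0-1000 integer scale are detected (any score > 1)
#' and divided by 1000 first. Nodes left without any retained edge are
#' reported separately, mirroring network figures that omit proteins without
#' interaction partners.
#'
#' @param edges `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param min_score Threshold on the 0-1 scale (default 0.7).
#' @return List: `edges` (retained, scores on 0-1 scale), `isolated`
#'   (node names with no retained edge).
#' @export
filter_edges <- function(edges, min_score = 0.7) {
  sc <- edges$combined_score
  if (any(!is.finite(sc)))
    stop("non-numeric combined scores", call. = FALSE)
  if (any(sc > 1)) sc <- sc / 1000
  if (any(sc < 0 | sc > 1))
    stop("combined scores must lie in [0, 1] (or 0-1000)", call. = FALSE)
  keep <- sc >= min_score
  kept <- edges[keep, , drop = FALSE]
  kept$combined_score <- sc[keep]
  all_nodes <- unique(c(edges$protein1, edges$protein2))
  connected <- unique(c(kept$protein1, kept$protein2))
  list(edges = kept, isolated = sort(setdiff(all_nodes, connected)))
}

#' Community structure of a filtered interaction network
#'
#' Modularity-maximizing partition by deterministic greedy agglomeration
#' (the fast-greedy family used by community-clustering network apps).
#' Vertices are ordered lexicographically before clustering so ties break
#' reproducibly.
#'
#' @param edges `data.frame` with columns `protein1`, `protein2` (typically
#'   `filter_edges(...)$edges`).
#' @return `data.frame` (`node`, `community`) with attribute `modularity`.
#' @export
community_clusters <- function(edges) {
  if (!nrow(edges)) stop("empty edge set", call. = FALSE)
  nodes <- sort(unique(c(edges$protein1, edges$protein2)))
  g <- igraph::graph_from_data_frame(edges[, c("protein1", "protein2")],
                                     directed = FALSE,
                                     vertices = nodes)
  g <- igraph::simplify(g)
  cl <- igraph::cluster_fast_greedy(g)
  # cut the greedy merge dendrogram at maximal modularity; among tied cuts
  # prefer the coarsest partition (a clique is one community, not several)
  ks <- seq_len(igraph::vcount(g))
  qs <- vapply(ks, function(k)
    igraph::modularity(g, igraph::cut_at(cl, no = k)), numeric(1))
  kbest <- min(ks[qs >= max(qs) - 1e-12])
  memb <- igraph::cut_at(cl, no = kbest)
  names(memb) <- igraph::V(g)$name
  out <- data.frame(node = names(memb), community = as.integer(memb),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "modularity") <- max(qs)
  out
}

#' Greedy minimal term cover
#'
#' Picks the smallest greedy list of annotation terms explaining all
#' involved gene products: repeatedly selects the term covering the most
#' still-uncovered genes (ties broken alphabetically) until every coverable
#' gene is covered.
#'
#' @param term2genes Named list: term -> character vector of genes.
#' @param genes Genes to explain (default: union of all terms' genes).
#' @return Character vector of selected terms, in selection order.
#' @export
minimal_term_cover <- function(term2genes, genes = NULL) {
  if (is.null(genes)) genes <- unique(unlist(term2genes))
  uncovered <- unique(genes)
  chosen <- character(0)
  t2g <- lapply(term2genes, intersect, uncovered)
  while (length(uncovered)) {
    gain <- vapply(t2g, function(g) length(intersect(g, uncovered)),
                   numeric(1))
    if (max(gain) == 0) break
    best <- sort(names(gain)[gain == max(gain)])[1]
    chosen <- c(chosen, best)
    uncovered <- setdiff(uncovered, t2g[[best]])
    t2g[[best]] <- NULL
  }
  chosen
}

#' Write a two-column ranked list for enrichment upload
#'
#' @param rl A [ranked_list()] result.
#' @param path Output TSV path.
#' @export
write_ranked_list <- function(rl, path) {
  stopifnot(is.data.frame(rl))
  cols <- if ("score" %in% names(rl)) c("gene", "score") else
    c("gene", grep("^score_", names(rl), value = TRUE)[1])
  utils::write.table(rl[, cols], path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
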