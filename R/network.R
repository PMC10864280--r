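#' Spearman rank correlation with two-sided p-value
#'
#' rho is the Pearson correlation of mid-ranks (tie-corrected). The
#' two-sided p-value uses the exact null distribution for n < 10 when the
#' data are tie-free, and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Finite numeric vectors, equal length >= 4.
#' @return List: `rho`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n < 10L && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Bipartite genus-pathway Spearman correlation network
#'
#' Correlates every differential genus (CLR scale) with every differential
#' pathway over the requested sample population, adjusts all computed
#' p-values together by Benjamini-Hochberg, and retains edges with
#' `|rho| > rho_cutoff` and `q < q_cutoff`. Spearman is rank-based, so the
#' abundance scale of either side (CLR vs relative abundance) does not
#' change the result under monotone rescaling.
#'
#' @param genera_clr CLR genus matrix (samples x genera).
#' @param pathways Pathway abundance matrix (samples x pathways).
#' @param metadata Metadata whose `sample_id` rows define the population
#'   the correlation is computed in (e.g. `setup_samples(md, "d")`).
#' @param diff_genera,diff_pathways Character vectors of differential
#'   features to correlate (the screened hits from upstream layers).
#' @param rho_cutoff,q_cutoff Edge retention cutoffs (defaults 0.2 and
#'   0.05).
#' @return data.frame of class `correlation_network`: `source` (genus),
#'   `target` (pathway), `rho`, `p`, `q`, `sign`, importable as an edge
#'   table; all tested pairs (pre-filter) are kept in the `"all_pairs"`
#'   attribute and node degrees in `"degree"`. Empty differential sets
#'   yield an empty network with a warning.
#' @export
build_network <- function(genera_clr, pathways, metadata,
                          diff_genera, diff_pathways,
                          rho_cutoff = 0.2, q_cutoff = 0.05) {
  empty <- data.frame(source = character(0L), target = character(0L),
                      rho = numeric(0L), p = numeric(0L), q = numeric(0L),
                      sign = character(0L), stringsAsFactors = FALSE)
  class(empty) <- c("correlation_network", "data.frame")
  if (length(diff_genera) == 0L || length(diff_pathways) == 0L) {
    warning("empty differential feature set; returning an empty network")
    return(empty)
  }
  stopifnot(all(diff_genera %in% colnames(genera_clr)),
            all(diff_pathways %in% colnames(pathways)))
  g <- align_samples(genera_clr, metadata)[, diff_genera, drop = FALSE]
  pw <- align_samples(pathways, metadata)[, diff_pathways, drop = FALSE]
  grid <- expand.grid(source = diff_genera, target = diff_pathways,
                      stringsAsFactors = FALSE)
  res <- mapply(function(a, b) {
    s <- spearman_cor(g[, a], pw[, b])
    c(s$rho, s$p.value)
  }, grid$source, grid$target)
  grid$rho <- res[1L, ]
  grid$p <- res[2L, ]
  grid$q <- stats::p.adjust(grid$p, method = "BH")
  grid$sign <- ifelse(grid$rho >= 0, "+", "-")
  edges <- grid[abs(grid$rho) > rho_cutoff & grid$q < q_cutoff, ,
                drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- grid
  attr(edges, "degree") <- if (nrow(edges))
    sort(table(c(edges$source, edges$target)), decreasing = TRUE)
    else table(character(0L))
  class(edges) <- c("correlation_network", "data.frame")
  edges
}

#' Write a correlation network as a Cytoscape-importable edge table
#'
#' @param network A `correlation_network`.
#' @param path Output TSV path (columns source, target, rho, p, q, sign).
#' @export
write_edges <- function(network, path) {
  utils::write.table(as.data.frame(network)[, c("source", "target", "rho",
                                                "p", "q", "sign")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
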