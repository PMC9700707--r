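## STRING-style PPI edge-list handling: reading/normalizing exported edge
## lists, confidence-tier filtering, and local node/edge/degree summaries.
## Everything runs on the local export; no database is queried.

ppiCutoffs <- c(lowest = 0.15, medium = 0.4, high = 0.7, highest = 0.9)

#' Read a STRING-style protein-protein edge list
#'
#' Reads a delimited edge list (protein A, protein B, combined score),
#' canonicalizes symbols, rejects self-loops, deduplicates undirected
#' duplicates (A-B and B-A are one edge; the maximum score is kept), and
#' normalizes the score scale: STRING exports print combined scores either
#' in \code{[0, 1]} or as integers in \code{[0, 1000]}; if any raw score
#' exceeds 1, all scores are divided by 1000.
#'
#' @param path File path (TSV/CSV, delimiter sniffed).
#' @param column_map Named list with entries \code{a}, \code{b},
#'   \code{score} naming the columns.
#' @param delim Delimiter; \code{NULL} to sniff.
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{combined_score} (in \code{[0, 1]}).
#' @export
readEdgeList <- function(path,
                         column_map = list(a = "protein_a", b = "protein_b",
                                           score = "combined_score"),
                         delim = NULL) {
  df <- readDelimited(path, delim)
  if (nrow(df) == 0L)
    return(data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE))
  requireColumns(df, column_map[c("a", "b", "score")], path)
  normalizeEdges(data.frame(
    protein_a = toupper(trimws(as.character(df[[column_map$a]]))),
    protein_b = toupper(trimws(as.character(df[[column_map$b]]))),
    combined_score = as.numeric(df[[column_map$score]]),
    stringsAsFactors = FALSE))
}

#' Normalize and deduplicate an edge list
#'
#' Idempotent: applying it twice changes nothing. Scores above 1 trigger
#' the /1000 export-dialect rescale of the whole column; scores outside
#' \code{[0, 1000]} are malformed. Self-loops are dropped.
#'
#' @param edges data.frame with \code{protein_a}, \code{protein_b},
#'   \code{combined_score}.
#' @return Normalized, undirected-unique data.frame.
#' @export
normalizeEdges <- function(edges) {
  s <- edges$combined_score
  if (any(is.na(s)) || any(s < 0) || any(s > 1000))
    stop("malformed score: combined scores must lie in [0, 1] or [0, 1000]")
  if (any(s > 1)) s <- s / 1000
  edges$combined_score <- s
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  if (nrow(edges) == 0L) { rownames(edges) <- NULL; return(edges) }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(edges$combined_score, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[`, "", 1L),
                    protein_b = vapply(parts, `[`, "", 2L),
                    combined_score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter edges by confidence tier
#'
#' STRING convention: an edge belongs to a tier when its combined score
#' reaches the tier cutoff — 0.15 (lowest), 0.4 (medium), 0.7 (high),
#' 0.9 (highest), all inclusive. Edge counts are therefore non-increasing
#' from lowest to highest.
#'
#' @param edges Normalized edge data.frame.
#' @param level One of \code{"lowest"}, \code{"medium"}, \code{"high"},
#'   \code{"highest"}.
#' @return The surviving edges.
#' @examples
#' e <- data.frame(protein_a = c("APOB", "LPA"), protein_b = c("LPA", "CETP"),
#'                 combined_score = c(0.95, 0.41))
#' nrow(filterByConfidence(e, "highest"))
#' @export
filterByConfidence <- function(edges, level = c("medium", "lowest",
                                                "high", "highest")) {
  level <- match.arg(level)
  edges[edges$combined_score >= ppiCutoffs[[level]], , drop = FALSE]
}

#' Summarize a PPI network
#'
#' Node, edge and degree summary of a simple undirected graph, via igraph.
#' Panel genes without surviving edges can be supplied so they appear as
#' isolated nodes (degree 0), matching how a fixed query panel is shown.
#'
#' @param edges Normalized edge data.frame.
#' @param include_nodes Optional character vector of nodes to include even
#'   if isolated (e.g. the gene panel).
#' @return List with \code{n_nodes}, \code{n_edges}, \code{degree} (named
#'   integer vector).
#' @examples
#' tri <- data.frame(protein_a = c("A", "B", "A"),
#'                   protein_b = c("B", "C", "C"),
#'                   combined_score = c(0.9, 0.9, 0.9))
#' summarizePpi(tri)
#' @export
summarizePpi <- function(edges, include_nodes = NULL) {
  verts <- unique(c(edges$protein_a, edges$protein_b,
                    toupper(trimws(include_nodes))))
  if (length(verts) == 0L)
    return(list(n_nodes = 0L, n_edges = 0L,
                degree = setNames(integer(0), character(0))))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(name = verts))
  deg <- igraph::degree(g)
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       degree = setNames(as.integer(deg), names(deg)))
}

#' Tier profile of an edge list
#'
#' Edge counts surviving each confidence tier, lowest to highest.
#'
#' @param edges Normalized edge data.frame.
#' @return Named integer vector over the four tiers.
#' @export
tierProfile <- function(edges) {
  vapply(names(ppiCutoffs),
         function(l) nrow(filterByConfidence(edges, l)), integer(1))
}
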