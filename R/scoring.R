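## V-Score / P-Score / C-Score computation, the multi-target filter,
## and deterministic ranking.

#' V-Score: validated target coverage of the panel
#'
#' Number of distinct panel genes with at least one experimentally
#' validated interaction for each miRNA. A gene counts once even when
#' several validated databases confirm it (union semantics).
#'
#' @param x A [MirnaEvidence-class] object.
#' @param mirna_id Optional character vector; defaults to all rows. A miRNA
#'   absent from the matrix scores 0.
#' @return Named integer vector of V-Scores in \code{[0, G]}.
#' @export
vScore <- function(x, mirna_id = rownames(x)) {
  stopifnot(is(x, "MirnaEvidence"))
  v <- as.integer(rowSums(validatedEvidence(x)))
  names(v) <- rownames(x)
  out <- setNames(integer(length(mirna_id)), mirna_id)
  hit <- mirna_id %in% names(v)
  out[hit] <- v[mirna_id[hit]]
  out
}

#' P-Score: total prediction-tool support over the panel
#'
#' Sum over panel genes of the number of distinct computational tools
#' confirming each (miRNA, gene) pair.
#'
#' @inheritParams vScore
#' @return Named integer vector of P-Scores in \code{[0, D*G]}.
#' @export
pScore <- function(x, mirna_id = rownames(x)) {
  stopifnot(is(x, "MirnaEvidence"))
  p <- as.integer(rowSums(predictedCounts(x)))
  names(p) <- rownames(x)
  out <- setNames(integer(length(mirna_id)), mirna_id)
  hit <- mirna_id %in% names(p)
  out[hit] <- p[mirna_id[hit]]
  out
}

#' C-Score: combined consensus score
#'
#' \deqn{C = \frac{P}{D \cdot G} + \frac{V}{G}}
#' where D is the prediction-tool registry size and G the panel size. Each
#' term is bounded by 1, so C is bounded by 2: the maximum is attained when
#' all D tools confirm all G genes and validated evidence covers the whole
#' panel. Computed at full precision; round only for reporting.
#'
#' @param p P-Score(s), integer in \code{[0, D*G]}.
#' @param v V-Score(s), integer in \code{[0, G]}; recycled against \code{p}.
#' @param D Registry size (default 30).
#' @param G Panel size (default 7).
#' @return Numeric C-Score(s) in \code{[0, 2]}.
#' @examples
#' cScore(210, 7)            # 2, the maximum
#' cScore(23, 4)             # ~0.681
#' @export
cScore <- function(p, v, D = 30L, G = 7L) {
  if (length(G) != 1L || is.na(G) || G < 1)
    stop("configuration error: panel size G must be >= 1")
  if (length(D) != 1L || is.na(D) || D < 1)
    stop("configuration error: registry size D must be >= 1")
  if (any(p < 0) || any(p > D * G))
    stop(sprintf("domain error: P-Score must lie in [0, %d]", D * G))
  if (any(v < 0) || any(v > G))
    stop(sprintf("domain error: V-Score must lie in [0, %d]", G))
  p / (D * G) + v / G
}

#' Enumerate P-Scores consistent with a rounded C-Score
#'
#' Published C-Scores are typically printed at 2 decimals; given such a
#' value and a known V-Score this inverts the C-Score formula, returning
#' every integer P-Score in \code{[0, D*G]} whose C-Score rounds to the
#' printed value. Useful for reconstructing unpublished P-Scores.
#'
#' @param c_rounded The printed C-Score.
#' @param v Known V-Score.
#' @param D,G Registry and panel size.
#' @param digits Decimals of the printed value (default 2).
#' @return Integer vector of candidate P-Scores (possibly empty).
#' @export
invertCScore <- function(c_rounded, v, D = 30L, G = 7L, digits = 2L) {
  p <- 0:(D * G)
  p[round(cScore(p, v, D, G), digits) == c_rounded]
}

#' Count panel genes with any evidence
#'
#' A gene supports a miRNA when its validated flag is TRUE or its predicted
#' count is positive; this union count drives the multi-target filter.
#'
#' @param x A [MirnaEvidence-class] object.
#' @return Named integer vector.
#' @export
nTargetGenes <- function(x) {
  stopifnot(is(x, "MirnaEvidence"))
  n <- as.integer(rowSums(validatedEvidence(x) | predictedCounts(x) > 0L))
  setNames(n, rownames(x))
}

#' Score every miRNA in an evidence matrix
#'
#' Computes V-, P- and C-Scores, the evidenced-gene count, applies the
#' multi-target filter, and ranks. The multi-target filter keeps miRNAs
#' able to hit at least \code{min_target_genes} distinct panel genes
#' (validated or predicted evidence); the default 2 targets the
#' "more than one gene" selection rule under which single-gene miRNAs are
#' uninteresting for multi-pronged therapy.
#'
#' @param x A [MirnaEvidence-class] object.
#' @param min_target_genes Minimum evidenced panel genes (default 2); use 1
#'   to disable the filter.
#' @param report_decimals Decimals for the reported C-Score column (default
#'   2). Ranking always uses full precision.
#' @return A \code{DataFrame} ordered by rank with columns \code{mirna},
#'   \code{v_score}, \code{p_score}, \code{c_score} (full precision),
#'   \code{c_score_reported}, \code{n_target_genes}, \code{rank}, plus one
#'   \code{n_<gene>} column of per-gene predicted counts per panel gene.
#' @examples
#' ev <- buildEvidenceMatrix(atheroValidated(), atheroPredicted(),
#'                           atheroPanel(), toolRegistry(30))
#' head(scoreMirnas(ev))
#' @export
scoreMirnas <- function(x, min_target_genes = 2L, report_decimals = 2L) {
  stopifnot(is(x, "MirnaEvidence"))
  if (min_target_genes < 1L)
    stop("min_target_genes must be >= 1")
  v <- vScore(x); p <- pScore(x); ng <- nTargetGenes(x)
  keep <- ng >= min_target_genes
  cs <- cScore(p, v, D = registrySize(x), G = ncol(x))
  tab <- S4Vectors::DataFrame(
    mirna = rownames(x), v_score = unname(v), p_score = unname(p),
    c_score = unname(cs),
    c_score_reported = unname(round(cs, report_decimals)),
    n_target_genes = unname(ng), row.names = NULL)
  counts <- predictedCounts(x)
  for (g in colnames(x)) tab[[paste0("n_", g)]] <- counts[, g]
  tab <- tab[keep, , drop = FALSE]
  rankMirnas(tab)
}

#' Rank scored miRNAs deterministically
#'
#' Orders descending by full-precision C-Score; ties broken by higher
#' V-Score, then higher P-Score, then lexicographic miRNA id, giving a
#' total order and hence 1-based dense ranks.
#'
#' @param scores A data.frame/DataFrame with columns \code{mirna},
#'   \code{v_score}, \code{p_score}, \code{c_score}.
#' @return The same table, ordered, with a \code{rank} column (re)assigned.
#' @export
rankMirnas <- function(scores) {
  need <- c("mirna", "v_score", "p_score", "c_score")
  miss <- setdiff(need, colnames(scores))
  if (length(miss))
    stop(sprintf("scores table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  o <- order(-scores$c_score, -scores$v_score, -scores$p_score,
             scores$mirna, method = "radix")
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Apply the multi-target filter to a scored table
#'
#' Standalone form of the filter embedded in [scoreMirnas()]: retains rows
#' whose \code{n_target_genes} meets the threshold.
#'
#' @param scores Table with an \code{n_target_genes} column.
#' @param min_target_genes Threshold (default 2); 1 is the identity.
#' @return Filtered table.
#' @export
filterMultiTarget <- function(scores, min_target_genes = 2L) {
  if (!"n_target_genes" %in% colnames(scores))
    stop("scores table lacks 'n_target_genes'")
  if (min_target_genes < 1L)
    stop("min_target_genes must be >= 1")
  scores[scores$n_target_genes >= min_target_genes, , drop = FALSE]
}
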