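## Bundled example evidence for the atherosclerosis drug-target panel:
## the published multi-database search results for the top candidate
## miRNAs, re-entered as plain interaction records so examples and tests
## run without any database download.

#' Example validated interactions for the atherosclerosis panel
#'
#' The top ten miRNAs targeting more than one panel gene according to
#' experimentally validated databases, as interaction records. Source
#' attribution between the two database classes is illustrative (the
#' V-Score is a union over sources, so it does not affect any score).
#'
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{source_db}.
#' @seealso [atheroPredicted()], [atheroPanel()]
#' @export
atheroValidated <- function() {
  pairs <- list(
    "hsa-miR-124-3p"  = c("CETP", "APOB", "MTTP", "PCSK9"),
    "hsa-miR-16-5p"   = c("APOB", "PCSK9", "HMGCR"),
    "hsa-miR-191-5p"  = c("PCSK9", "APOB", "APOC3"),
    "hsa-miR-335-5p"  = c("PCSK9", "HMGCR"),
    "hsa-miR-29c-3p"  = c("PCSK9", "HMGCR"),
    "hsa-miR-27a-3p"  = c("MTTP", "PCSK9"),
    "hsa-miR-147a"    = c("PCSK9", "LPA"),
    "hsa-let-7b-5p"   = c("APOB", "PCSK9"),
    "hsa-miR-15b-5p"  = c("PCSK9", "HMGCR"),
    "hsa-miR-1915-3p" = c("PCSK9", "HMGCR"))
  df <- data.frame(
    mirna = rep(names(pairs), lengths(pairs)),
    gene = unlist(pairs, use.names = FALSE),
    stringsAsFactors = FALSE)
  # alternate sources deterministically; union semantics make this moot
  df$source_db <- rep_len(c("TarBase", "miRTarBase"), nrow(df))
  df
}

#' Example per-tool prediction counts for the atherosclerosis panel
#'
#' The top ten miRNAs by total computational-tool support (out of a
#' registry of 30 prediction tools), as a per-gene count matrix. Two rows
#' whose printed per-gene digits admit more than one reading are included
#' under a documented reconstruction; their row totals are unambiguous.
#'
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{predicted_count}.
#' @seealso [atheroValidated()], [expandPredictedCounts()]
#' @export
atheroPredicted <- function() {
  genes <- c("CETP", "APOB", "MTTP", "PCSK9", "HMGCR", "LPA", "APOC3")
  counts <- rbind(
    "hsa-miR-338-3p"  = c(5, 6, 5, 8, 16, 9, 8),     # P = 57
    "hsa-miR-211-5p"  = c(3, 6, 10, 7, 16, 3, 10),   # P = 55
    "hsa-miR-365a-3p" = c(9, 6, 6, 12, 15, 2, 2),    # P = 52
    "hsa-miR-149-5p"  = c(4, 1, 15, 13, 13, 2, 3),   # P = 51
    "hsa-miR-204-5p"  = c(2, 5, 8, 7, 16, 2, 10),    # P = 50
    "hsa-miR-335-5p"  = c(2, 2, 12, 12, 16, 2, 2),   # P = 48
    "hsa-miR-139-5p"  = c(3, 4, 6, 8, 20, 2, 4),     # P = 47
    "hsa-miR-143-3p"  = c(5, 4, 10, 12, 9, 2, 5),    # P = 47
    "hsa-miR-548c-3p" = c(25, 1, 4, 7, 1, 4, 4),     # P = 46 (reconstruction)
    "hsa-miR-1237-3p" = c(9, 9, 4, 7, 10, 3, 3))     # P = 45
  colnames(counts) <- genes
  long <- data.frame(
    mirna = rep(rownames(counts), times = ncol(counts)),
    gene = rep(genes, each = nrow(counts)),
    predicted_count = as.integer(counts),
    stringsAsFactors = FALSE)
  long[long$predicted_count > 0L, , drop = FALSE]
}

#' Expand per-gene counts into per-tool interaction records
#'
#' Turns a count table (\code{mirna}, \code{gene}, \code{predicted_count})
#' into one record per supporting tool by assigning, for each pair, that
#' many distinct tools from the registry. Which tools are chosen is
#' immaterial to every score; the first \code{count} registry tools are
#' used so the expansion is deterministic.
#'
#' @param counts data.frame with \code{mirna}, \code{gene},
#'   \code{predicted_count}.
#' @param registry Tool registry; every count must be <= D.
#' @return data.frame with columns \code{mirna}, \code{gene}, \code{tool}.
#' @export
expandPredictedCounts <- function(counts, registry = toolRegistry(30L)) {
  registry <- toolRegistry(registry)
  if (any(counts$predicted_count > length(registry)))
    stop("domain error: a predicted count exceeds the registry size")
  n <- counts$predicted_count
  data.frame(
    mirna = rep(counts$mirna, n),
    gene = rep(counts$gene, n),
    tool = registry[unlist(lapply(n, seq_len))],
    stringsAsFactors = FALSE)
}

#' Example evidence matrix for the atherosclerosis panel
#'
#' Convenience wrapper assembling [atheroValidated()] and
#' [atheroPredicted()] into a [MirnaEvidence-class] object over
#' [atheroPanel()] with a 30-tool registry.
#'
#' @return A [MirnaEvidence-class] object (19 miRNAs x 7 genes).
#' @examples
#' ev <- atheroEvidence()
#' scoreMirnas(ev)[, 1:5]
#' @export
atheroEvidence <- function() {
  reg <- toolRegistry(30L)
  buildEvidenceMatrix(atheroValidated(),
                      expandPredictedCounts(atheroPredicted(), reg),
                      atheroPanel(), reg)
}
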