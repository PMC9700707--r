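#' MirnaEvidence: per-(miRNA, gene) interaction evidence over a panel
#'
#' An S4 container extending \linkS4class{SummarizedExperiment}. Rows are
#' mature miRNAs (canonical identifiers), columns are the panel genes, and
#' two assays hold the evidence:
#' \describe{
#'   \item{\code{validated}}{logical; TRUE iff at least one experimentally
#'     validated database reports the (miRNA, gene) interaction.}
#'   \item{\code{predicted}}{integer; number of distinct computational
#'     prediction tools (out of the registry of size D) reporting the pair.}
#' }
#' The tool registry travels in \code{metadata(x)$registry}; its length D
#' bounds every predicted count.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots.
#' @aliases MirnaEvidence
#' @exportClass MirnaEvidence
setClass("MirnaEvidence", contains = "SummarizedExperiment")

setValidity("MirnaEvidence", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("validated", "predicted") %in% an))
    msg <- c(msg, "assays 'validated' and 'predicted' are required")
  reg <- S4Vectors::metadata(object)$registry
  if (is.null(reg) || length(reg) < 1L)
    msg <- c(msg, "metadata(x)$registry must name at least one prediction tool")
  if (length(msg) == 0L) {
    v <- SummarizedExperiment::assay(object, "validated")
    p <- SummarizedExperiment::assay(object, "predicted")
    if (!is.logical(v))
      msg <- c(msg, "'validated' assay must be logical")
    if (!all(p == as.integer(p)) || any(p < 0L))
      msg <- c(msg, "'predicted' assay must hold non-negative integers")
    if (any(p > length(reg)))
      msg <- c(msg, sprintf("predicted counts exceed registry size D = %d",
                            length(reg)))
    if (ncol(object) > 0L &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
      msg <- c(msg, "panel genes (colnames) must be unique and named")
    if (nrow(object) > 0L &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
      msg <- c(msg, "miRNA ids (rownames) must be unique and named")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaEvidence object
#'
#' Low-level constructor from already-canonical matrices; most users build
#' evidence with [buildEvidenceMatrix()] instead.
#'
#' @param validated Logical matrix, miRNAs x panel genes.
#' @param predicted Integer matrix of the same dimensions.
#' @param registry Character vector of prediction-tool names (size D).
#' @return A [MirnaEvidence-class] object.
#' @export
MirnaEvidence <- function(validated, predicted, registry) {
  stopifnot(identical(dim(validated), dim(predicted)))
  storage.mode(predicted) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(validated = validated, predicted = predicted))
  S4Vectors::metadata(se)$registry <- toolRegistry(registry)
  new("MirnaEvidence", se)
}

#' Declare a prediction-tool registry
#'
#' The registry is the closed universe of computational prediction tools
#' whose votes are counted; its size D is the per-gene ceiling of the
#' predicted count and the P-Score normalizer in the C-Score.
#'
#' @param tools Character vector of tool names, or a single integer n to get
#'   a generic registry \code{tool01..tooln}.
#' @return Character vector of unique tool names.
#' @examples
#' toolRegistry(30)
#' toolRegistry(c("TargetScan", "miRDB", "PITA"))
#' @export
toolRegistry <- function(tools = 30L) {
  if (is.numeric(tools) && length(tools) == 1L) {
    if (tools < 1) stop("registry size D must be >= 1")
    tools <- sprintf("tool%02d", seq_len(tools))
  }
  tools <- unique(trimws(as.character(tools)))
  if (length(tools) < 1L || any(!nzchar(tools)))
    stop("registry must name at least one tool")
  tools
}

#' @describeIn MirnaEvidence-class panel genes (column names)
#' @param x A MirnaEvidence object.
#' @export
panelGenes <- function(x) colnames(x)

#' @describeIn MirnaEvidence-class the prediction-tool registry
#' @export
registryTools <- function(x) S4Vectors::metadata(x)$registry

#' @describeIn MirnaEvidence-class registry size D
#' @export
registrySize <- function(x) length(registryTools(x))

#' @describeIn MirnaEvidence-class logical validated-evidence matrix
#' @export
validatedEvidence <- function(x) SummarizedExperiment::assay(x, "validated")

#' @describeIn MirnaEvidence-class integer predicted-tool-count matrix
#' @export
predictedCounts <- function(x) SummarizedExperiment::assay(x, "predicted")

setMethod("show", "MirnaEvidence", function(object) {
  cat(sprintf("MirnaEvidence: %d miRNA(s) x %d panel gene(s), D = %d tools\n",
              nrow(object), ncol(object), registrySize(object)))
  cat("panel:", paste(panelGenes(object), collapse = ", "), "\n")
  v <- sum(validatedEvidence(object))
  p <- sum(predictedCounts(object) > 0L)
  cat(sprintf("evidence: %d validated pair(s), %d predicted pair(s)\n", v, p))
})
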