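## Readers for miRNA-target evidence exports (TarBase/miRTarBase-style
## validated tables; one table per computational prediction tool) and
## assembly of the per-panel evidence matrix.

# Sniff tab vs comma from the header line; overridable.
sniffDelim <- function(path) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (length(hdr) == 0L) return("\t")
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0L) "\t" else ","
}

readDelimited <- function(path, delim = NULL) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot read '%s'", path))
  if (is.null(delim)) delim <- sniffDelim(path)
  read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(unlist(cols), names(df))
  if (length(miss))
    stop(sprintf("schema error: column(s) %s not found in '%s'",
                 paste(sQuote(miss), collapse = ", "), path))
}

#' Read a validated-interaction export
#'
#' Reads a delimited (TSV/CSV, sniffed) export of experimentally validated
#' miRNA-target interactions, canonicalizes identifiers, deduplicates on
#' (miRNA, gene, source database), and flags rows whose gene is off-panel.
#' Off-panel rows are retained so the same export can be re-scored against a
#' different panel.
#'
#' @param path File path.
#' @param panel Gene panel from [genePanel()].
#' @param column_map Named list with entries \code{mirna}, \code{gene},
#'   \code{source} naming the columns in the file.
#' @param aliases Gene alias map (see [canonicalizeGene()]).
#' @param delim Field delimiter; \code{NULL} to sniff.
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{source_db}, \code{on_panel}.
#' @export
readValidatedTable <- function(path, panel,
                               column_map = list(mirna = "mirna",
                                                 gene = "gene",
                                                 source = "source_db"),
                               aliases = defaultGeneAliases(),
                               delim = NULL) {
  df <- readDelimited(path, delim)
  requireColumns(df, column_map[c("mirna", "gene", "source")], path)
  if (nrow(df) == 0L)
    return(data.frame(mirna = character(), gene = character(),
                      source_db = character(), on_panel = logical(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    mirna     = canonicalizeMirna(df[[column_map$mirna]]),
    gene      = canonicalizeGene(df[[column_map$gene]], aliases),
    source_db = trimws(as.character(df[[column_map$source]])),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out$on_panel <- out$gene %in% panel
  rownames(out) <- NULL
  out
}

#' Read per-tool prediction exports
#'
#' Reads one delimited file per computational prediction tool. Each file is
#' attributed to exactly one registered tool; within a tool a (miRNA, gene)
#' pair contributes at most once regardless of how many rows repeat it.
#'
#' @param paths Named character vector: names are tool names, values paths.
#' @param registry Tool registry from [toolRegistry()].
#' @param panel Gene panel.
#' @param column_map Named list with entries \code{mirna} and \code{gene}.
#' @param aliases Gene alias map.
#' @param delim Delimiter; \code{NULL} to sniff per file.
#' @return data.frame with columns \code{mirna}, \code{gene}, \code{tool},
#'   \code{on_panel}, deduplicated on the triple.
#' @export
readPredictedTables <- function(paths, registry, panel,
                                column_map = list(mirna = "mirna",
                                                  gene = "gene"),
                                aliases = defaultGeneAliases(),
                                delim = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("registry error: each prediction file must be named by its tool")
  bad <- setdiff(names(paths), registry)
  if (length(bad))
    stop(sprintf("registry error: file(s) attributed to unregistered tool(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  parts <- lapply(names(paths), function(tool) {
    df <- readDelimited(paths[[tool]], delim)
    requireColumns(df, column_map[c("mirna", "gene")], paths[[tool]])
    if (nrow(df) == 0L)
      return(data.frame(mirna = character(), gene = character(),
                        tool = character(), stringsAsFactors = FALSE))
    unique(data.frame(
      mirna = canonicalizeMirna(df[[column_map$mirna]]),
      gene  = canonicalizeGene(df[[column_map$gene]], aliases),
      tool  = tool,
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, parts)
  out$on_panel <- out$gene %in% panel
  rownames(out) <- NULL
  out
}

#' Assemble the evidence matrix over a gene panel
#'
#' Restricts validated and predicted interaction records to the panel genes
#' and builds the [MirnaEvidence-class] matrix: the validated flag is the
#' union over validated databases; the predicted count is the number of
#' distinct registered tools confirming the pair.
#'
#' @param validated data.frame as returned by [readValidatedTable()] (or any
#'   frame with \code{mirna}, \code{gene}, \code{source_db}); may be empty.
#' @param predicted data.frame as returned by [readPredictedTables()] (or
#'   any frame with \code{mirna}, \code{gene}, \code{tool}); may be empty.
#' @param panel Gene panel (must be non-empty).
#' @param registry Tool registry.
#' @return A [MirnaEvidence-class] object with one row per miRNA seen in
#'   either input (on-panel evidence only).
#' @examples
#' pan <- atheroPanel()
#' val <- data.frame(mirna = "hsa-miR-124-3p", gene = "CETP",
#'                   source_db = "TarBase")
#' ev <- buildEvidenceMatrix(val, NULL, pan, toolRegistry(30))
#' vScore(ev)
#' @export
buildEvidenceMatrix <- function(validated, predicted, panel, registry) {
  if (length(panel) < 1L)
    stop("configuration error: empty gene panel")
  registry <- toolRegistry(registry)
  empty <- data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE)
  v <- if (is.null(validated) || nrow(validated) == 0L) empty else
    unique(data.frame(mirna = canonicalizeMirna(validated$mirna),
                      gene  = canonicalizeGene(validated$gene),
                      stringsAsFactors = FALSE))
  p <- if (is.null(predicted) || nrow(predicted) == 0L)
    cbind(empty, tool = character()) else
    unique(data.frame(mirna = canonicalizeMirna(predicted$mirna),
                      gene  = canonicalizeGene(predicted$gene),
                      tool  = as.character(predicted$tool),
                      stringsAsFactors = FALSE))
  if (nrow(p) && length(bad <- setdiff(unique(p$tool), registry)))
    stop(sprintf("registry error: unregistered tool(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  v <- v[v$gene %in% panel, , drop = FALSE]
  p <- p[p$gene %in% panel, , drop = FALSE]
  mirnas <- sort(unique(c(v$mirna, p$mirna)))
  vm <- matrix(FALSE, nrow = length(mirnas), ncol = length(panel),
               dimnames = list(mirnas, panel))
  pm <- matrix(0L, nrow = length(mirnas), ncol = length(panel),
               dimnames = list(mirnas, panel))
  if (nrow(v)) vm[cbind(v$mirna, v$gene)] <- TRUE
  if (nrow(p)) {
    tab <- table(p$mirna, p$gene)   # distinct tools per pair (rows unique)
    pm[rownames(tab), colnames(tab)] <- pm[rownames(tab), colnames(tab)] +
      matrix(as.integer(tab), nrow = nrow(tab))
  }
  MirnaEvidence(vm, pm, registry)
}

#' Write an evidence matrix as long-format TSV
#'
#' One row per (miRNA, gene) cell: \code{mirna}, \code{gene},
#' \code{validated} (TRUE/FALSE), \code{predicted_count}. A header comment
#' records the registry so [readEvidenceTable()] round-trips exactly.
#'
#' @param x A [MirnaEvidence-class] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeEvidenceTable <- function(x, path) {
  stopifnot(is(x, "MirnaEvidence"))
  long <- data.frame(
    mirna = rep(rownames(x), times = ncol(x)),
    gene = rep(colnames(x), each = nrow(x)),
    validated = as.vector(validatedEvidence(x)),
    predicted_count = as.vector(predictedCounts(x)),
    stringsAsFactors = FALSE)
  # gene order follows the panel so a round-trip preserves column order
  long <- long[order(long$mirna, match(long$gene, colnames(x))), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# registry: ",
                    paste(registryTools(x), collapse = ",")), con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a long-format evidence TSV
#'
#' Inverse of [writeEvidenceTable()]: reconstructs the
#' [MirnaEvidence-class] object, including the registry recorded in the
#' header comment (override with \code{registry}).
#'
#' @param path Path written by [writeEvidenceTable()].
#' @param registry Optional registry overriding the recorded one.
#' @return A [MirnaEvidence-class] object.
#' @export
readEvidenceTable <- function(path, registry = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(registry)) {
    hdr <- grep("^# registry:", lines, value = TRUE)
    if (length(hdr) != 1L)
      stop("schema error: no registry header; pass `registry`")
    registry <- strsplit(sub("^# registry:\\s*", "", hdr), ",")[[1]]
  }
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   stringsAsFactors = FALSE)
  requireColumns(df, list("mirna", "gene", "validated", "predicted_count"),
                 path)
  panel <- unique(df$gene)
  mirnas <- unique(df$mirna)
  vm <- matrix(FALSE, length(mirnas), length(panel),
               dimnames = list(mirnas, panel))
  pm <- matrix(0L, length(mirnas), length(panel),
               dimnames = list(mirnas, panel))
  vm[cbind(df$mirna, df$gene)] <- as.logical(df$validated)
  pm[cbind(df$mirna, df$gene)] <- as.integer(df$predicted_count)
  MirnaEvidence(vm, pm, toolRegistry(registry))
}
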