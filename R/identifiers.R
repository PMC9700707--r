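#' Canonicalize a mature miRNA identifier
#'
#' Maps identifiers that differ only in letter case onto a single canonical
#' form, so that \code{"HSA-MIR-124-3P"} and \code{"hsa-miR-124-3p"} denote
#' the same mature miRNA. The species prefix and the arm suffix
#' (\code{-3p}/\code{-5p}) are preserved: \code{hsa-miR-16-5p} and
#' \code{hsa-miR-16-3p} remain distinct. The canonical display form follows
#' miRBase convention: everything lowercase except the \code{miR} token
#' (\code{let} stays lowercase, as in \code{hsa-let-7b-5p}).
#'
#' @param raw_id Character vector of miRNA identifiers.
#' @return Character vector of canonical identifiers, same length.
#' @examples
#' canonicalizeMirna("HSA-MIR-124-3P")   # "hsa-miR-124-3p"
#' canonicalizeMirna("hsa-let-7b-5p")    # unchanged
#' @export
canonicalizeMirna <- function(raw_id) {
  if (!is.character(raw_id))
    stop("malformed identifier: miRNA ids must be character")
  x <- trimws(raw_id)
  if (length(x) == 0L || any(is.na(x)) || any(!nzchar(x)))
    stop("malformed identifier: empty or whitespace-only miRNA id")
  x <- tolower(x)
  # restore the conventional 'miR' capitalization of mature ids
  gsub("(^|-)mir(?=-|$)", "\\1miR", x, perl = TRUE)
}

#' Default gene-symbol alias map
#'
#' Some databases and papers use legacy apolipoprotein C-III spellings;
#' \code{APOCIII} and \code{APOC-III} are folded into the HGNC symbol
#' \code{APOC3}. Supply your own named vector (alias -> symbol) to extend.
#'
#' @return Named character vector mapping alias to canonical symbol.
#' @export
defaultGeneAliases <- function() {
  c(APOCIII = "APOC3", `APOC-III` = "APOC3")
}

#' Canonicalize gene symbols
#'
#' Uppercases, strips surrounding whitespace, and resolves aliases.
#'
#' @param genes Character vector of gene symbols.
#' @param aliases Named character vector (alias -> canonical), applied after
#'   uppercasing. Defaults to [defaultGeneAliases()].
#' @return Character vector of canonical symbols.
#' @examples
#' canonicalizeGene(c("apoc3", "APOCIII", " cetp "))
#' @export
canonicalizeGene <- function(genes, aliases = defaultGeneAliases()) {
  if (!is.character(genes))
    stop("gene symbols must be character")
  x <- toupper(trimws(genes))
  if (any(!nzchar(x)))
    stop("empty gene symbol")
  if (length(aliases)) {
    names(aliases) <- toupper(names(aliases))
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x
}

#' Construct a gene panel
#'
#' A gene panel is the fixed target-gene universe against which miRNAs are
#' scored: an ordered set of unique, canonical gene symbols.
#'
#' @param genes Character vector of gene symbols (a file path may be given
#'   instead: one symbol per line, \code{#} comments allowed).
#' @param aliases Alias map passed to [canonicalizeGene()].
#' @return Character vector of class-checked unique symbols.
#' @examples
#' genePanel(c("PCSK9", "apociii"))
#' @export
genePanel <- function(genes, aliases = defaultGeneAliases()) {
  if (length(genes) == 1L && file.exists(genes)) {
    genes <- readLines(genes, warn = FALSE)
    genes <- trimws(sub("#.*$", "", genes))
    genes <- genes[nzchar(genes)]
  }
  g <- unique(canonicalizeGene(genes, aliases))
  if (length(g) < 1L)
    stop("configuration error: gene panel must contain at least one gene")
  g
}

#' The atherosclerosis drug-target gene panel
#'
#' Seven genes whose inhibition lowers atherogenic lipoproteins and whose
#' efficacy as drug targets is supported by clinical trials: PCSK9
#' (inclisiran), HMGCR (statins), MTTP (lomitapide), APOC3 (volanesorsen),
#' LPA (apo(a) antisense), CETP (anacetrapib) and APOB (mipomersen).
#'
#' @return Character vector of 7 gene symbols.
#' @export
atheroPanel <- function() {
  c("PCSK9", "HMGCR", "MTTP", "APOC3", "LPA", "CETP", "APOB")
}
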