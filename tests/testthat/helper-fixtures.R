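# Shared fixtures and independent oracles used across the suite.

# Write a validated-interaction export file from a data.frame.
writeValidatedFile <- function(df, path = tempfile(fileext = ".tsv"),
                               sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Write one prediction export per tool from a (mirna, gene, tool) frame.
writePredictedFiles <- function(df, tools, dir = tempfile("pred")) {
  dir.create(dir)
  paths <- setNames(file.path(dir, paste0(tools, ".tsv")), tools)
  for (tl in tools) {
    sub <- df[df$tool == tl, c("mirna", "gene"), drop = FALSE]
    write.table(sub, paths[[tl]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  paths
}

# Independent brute-force oracle: count distinct (tool, mirna, gene)
# triples per pair and distinct validated genes per miRNA, straight from
# the raw record frames, without touching the evidence-matrix code path.
bruteForceScores <- function(validated, predicted, panel, D) {
  vt <- unique(validated[validated$gene %in% panel,
                         c("mirna", "gene"), drop = FALSE])
  pt <- unique(predicted[predicted$gene %in% panel,
                         c("mirna", "gene", "tool"), drop = FALSE])
  mirnas <- sort(unique(c(vt$mirna, pt$mirna)))
  v <- vapply(mirnas, function(m)
    length(unique(vt$gene[vt$mirna == m])), integer(1))
  p <- vapply(mirnas, function(m)
    nrow(pt[pt$mirna == m, , drop = FALSE]), integer(1))
  data.frame(mirna = mirnas, v = v, p = p,
             c = p / (D * length(panel)) + v / length(panel),
             stringsAsFactors = FALSE)
}

# Brute-force ranking comparator mirroring the documented sort key.
bruteForceOrder <- function(tab) {
  key <- function(i, j) {
    if (tab$c_score[i] != tab$c_score[j])
      return(tab$c_score[i] > tab$c_score[j])
    if (tab$v_score[i] != tab$v_score[j])
      return(tab$v_score[i] > tab$v_score[j])
    if (tab$p_score[i] != tab$p_score[j])
      return(tab$p_score[i] > tab$p_score[j])
    tab$mirna[i] < tab$mirna[j]
  }
  idx <- seq_len(nrow(tab))
  # insertion sort under the pairwise comparator
  for (i in idx[-1]) {
    j <- i
    while (j > 1 && key(idx[j], idx[j - 1])) {
      tmp <- idx[j]; idx[j] <- idx[j - 1]; idx[j - 1] <- tmp
      j <- j - 1
    }
  }
  idx
}

PANEL <- atheroPanel()
REG30 <- toolRegistry(30L)
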