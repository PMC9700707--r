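test_that("miRNA canonicalization is case-insensitive, arm-preserving", {
  expect_identical(canonicalizeMirna("HSA-MIR-124-3P"),
                   canonicalizeMirna("hsa-miR-124-3p"))
  expect_identical(canonicalizeMirna("hsa-miR-124-3p"), "hsa-miR-124-3p")
  expect_false(canonicalizeMirna("hsa-miR-16-5p") ==
                 canonicalizeMirna("hsa-miR-16-3p"))
  expect_identical(canonicalizeMirna("hsa-let-7b-5p"), "hsa-let-7b-5p")
  expect_identical(canonicalizeMirna(" hsa-miR-147a "), "hsa-miR-147a")
  expect_error(canonicalizeMirna(""), "malformed")
  expect_error(canonicalizeMirna("   "), "malformed")
})

test_that("gene canonicalization uppercases and resolves aliases", {
  expect_identical(canonicalizeGene("apoc3"), "APOC3")
  expect_identical(canonicalizeGene("APOCIII"), "APOC3")
  expect_identical(canonicalizeGene(" cetp "), "CETP")
  expect_identical(canonicalizeGene("FOO", aliases = c(FOO = "BAR")), "BAR")
  expect_error(canonicalizeGene(" "), "empty")
})

test_that("gene panel enforces uniqueness and non-emptiness", {
  expect_identical(genePanel(c("pcsk9", "PCSK9", "APOCIII")),
                   c("PCSK9", "APOC3"))
  expect_error(genePanel(character(0)), "configuration error")
  pf <- tempfile()
  writeLines(c("# panel", "PCSK9", "apob"), pf)
  expect_identical(genePanel(pf), c("PCSK9", "APOB"))
})

test_that("validated reader dedups, canonicalizes, flags off-panel", {
  df <- data.frame(
    mirna = c("HSA-MIR-124-3P", "hsa-miR-124-3p", "hsa-miR-9-5p"),
    gene = c("CETP", "cetp", "NOTCH1"),
    source_db = c("TarBase", "TarBase", "miRTarBase"))
  path <- writeValidatedFile(df)
  rec <- readValidatedTable(path, PANEL)
  expect_equal(nrow(rec), 2L)  # duplicate collapsed
  expect_true(rec$on_panel[rec$gene == "CETP"])
  expect_false(rec$on_panel[rec$gene == "NOTCH1"])
})

test_that("validated reader sniffs CSV and checks schema", {
  df <- data.frame(mirna = "hsa-miR-16-5p", gene = "apociii",
                   source_db = "TarBase")
  path <- writeValidatedFile(df, tempfile(fileext = ".csv"), sep = ",")
  rec <- readValidatedTable(path, PANEL)
  expect_identical(rec$gene, "APOC3")
  bad <- writeValidatedFile(data.frame(x = 1))
  expect_error(readValidatedTable(bad, PANEL), "schema error")
  expect_error(readValidatedTable(tempfile(), PANEL), "I/O error")
})

test_that("prediction reader dedups within tool and rejects unregistered tools", {
  reg <- toolRegistry(c("toolA", "toolB"))
  df <- data.frame(mirna = rep("hsa-miR-1-3p", 3),
                   gene = c("CETP", "CETP", "APOB"),
                   tool = c("toolA", "toolA", "toolB"))
  paths <- writePredictedFiles(df, c("toolA", "toolB"))
  rec <- readPredictedTables(paths, reg, PANEL)
  expect_equal(nrow(rec), 2L)  # within-tool duplicate collapsed
  expect_error(readPredictedTables(c(toolZ = paths[[1]]), reg, PANEL),
               "registry error")
})

test_that("evidence matrix has union-validated flags and distinct-tool counts", {
  reg <- toolRegistry(5L)
  val <- data.frame(mirna = rep("hsa-miR-1-3p", 2), gene = rep("CETP", 2),
                    source_db = c("TarBase", "miRTarBase"))
  prd <- data.frame(mirna = rep("hsa-miR-1-3p", 3),
                    gene = rep("APOB", 3), tool = c("tool01", "tool02", "tool03"))
  ev <- buildEvidenceMatrix(val, prd, PANEL, reg)
  expect_s4_class(ev, "MirnaEvidence")
  expect_true(validatedEvidence(ev)["hsa-miR-1-3p", "CETP"])
  expect_equal(predictedCounts(ev)["hsa-miR-1-3p", "APOB"], 3L)
  expect_equal(sum(predictedCounts(ev)), 3L)
  expect_equal(vScore(ev)[["hsa-miR-1-3p"]], 1L)
  expect_error(buildEvidenceMatrix(val, prd, character(0), reg),
               "configuration error")
})

test_that("empty evidence yields an all-(FALSE, 0) matrix", {
  ev <- buildEvidenceMatrix(NULL, NULL, PANEL, REG30)
  expect_equal(nrow(ev), 0L)
  expect_equal(ncol(ev), 7L)
  val <- data.frame(mirna = "hsa-miR-1-3p", gene = "CETP",
                    source_db = "TarBase")
  ev1 <- buildEvidenceMatrix(val, NULL, PANEL, REG30)
  expect_true(validatedEvidence(ev1)[1, "CETP"])
  expect_true(all(predictedCounts(ev1) == 0L))
  expect_equal(sum(validatedEvidence(ev1)), 1L)
})

test_that("predicted_count is invariant under row duplication", {
  reg <- toolRegistry(4L)
  prd <- data.frame(mirna = "hsa-miR-2-5p", gene = "LPA", tool = "tool01")
  ev1 <- buildEvidenceMatrix(NULL, prd, PANEL, reg)
  ev2 <- buildEvidenceMatrix(NULL, rbind(prd, prd, prd), PANEL, reg)
  expect_identical(predictedCounts(ev1), predictedCounts(ev2))
})

test_that("long-format TSV round-trips the evidence matrix exactly", {
  ev <- atheroEvidence()
  path <- tempfile(fileext = ".tsv")
  writeEvidenceTable(ev, path)
  back <- readEvidenceTable(path)
  expect_identical(validatedEvidence(back), validatedEvidence(ev))
  expect_identical(predictedCounts(back), predictedCounts(ev))
  expect_identical(registryTools(back), registryTools(ev))
  expect_identical(panelGenes(back), panelGenes(ev))
  # writing the re-read object reproduces the file byte for byte
  path2 <- tempfile(fileext = ".tsv")
  writeEvidenceTable(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("random exports: counts equal a brute-force recount", {
  reg <- toolRegistry(8L)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40L
    df <- unique(data.frame(
      mirna = sprintf("hsa-miR-%d-3p", sample(1:6, n, TRUE)),
      gene = sample(c(PANEL, "OFFP1"), n, TRUE),
      tool = sample(reg, n, TRUE)))
    paths <- writePredictedFiles(df, reg)
    rec <- readPredictedTables(paths, reg, PANEL)
    ev <- buildEvidenceMatrix(NULL, rec, PANEL, reg)
    oracle <- bruteForceScores(
      data.frame(mirna = character(), gene = character()), df, PANEL, 8L)
    expect_equal(unname(pScore(ev)[oracle$mirna]), oracle$p)
  }
})
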