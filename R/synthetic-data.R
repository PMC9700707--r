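## Seeded generators that plant ground truth in every input format the
## pipeline reads, so each stage (and the whole pipeline) can be tested
## without any database download or wet-lab data.

withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  force(code)
}

#' Plant a random evidence truth
#'
#' Draws, for each miRNA of a pool, a validated gene set and per-gene
#' predicted tool counts in \code{[0, D]} — the ground truth a synthetic
#' export realizes and the pipeline must recover exactly.
#'
#' @param panel Gene panel.
#' @param mirna_pool Character vector of miRNA ids (default: the bundled
#'   pool of [defaultMirnaPool()]).
#' @param registry Tool registry.
#' @param p_validated Probability a (miRNA, gene) pair is validated.
#' @param mean_count Mean of the (truncated) Poisson predicted count.
#' @param seed Integer seed.
#' @return List with \code{validated} (named list miRNA -> genes),
#'   \code{predicted} (integer matrix miRNA x gene), \code{seed}.
#' @export
randomTruth <- function(panel, mirna_pool = defaultMirnaPool(),
                        registry = toolRegistry(30L),
                        p_validated = 0.3, mean_count = 5, seed = 1L) {
  registry <- toolRegistry(registry)
  D <- length(registry)
  withSeed(seed, {
    pm <- matrix(pmin(stats::rpois(length(mirna_pool) * length(panel),
                                   mean_count), D),
                 nrow = length(mirna_pool),
                 dimnames = list(mirna_pool, panel))
    vm <- matrix(runif(length(pm)) < p_validated, nrow = nrow(pm),
                 dimnames = dimnames(pm))
    list(validated = apply(vm, 1L, function(r) panel[r], simplify = FALSE),
         predicted = pm, seed = seed)
  })
}

#' Default miRNA pool for synthetic evidence
#'
#' The candidate miRNAs of the bundled atherosclerosis example (top hits of
#' the validated and computational searches), so synthetic fixtures read
#' like real prioritization output.
#'
#' @return Character vector of 19 mature miRNA ids.
#' @export
defaultMirnaPool <- function() {
  sort(unique(c(atheroValidated()$mirna, atheroPredicted()$mirna)))
}

#' Write synthetic evidence exports realizing a planted truth
#'
#' Produces the exact file set the readers consume: one validated-
#' interaction TSV (each validated pair listed under one or two source
#' databases) and one TSV per registered tool, such that for every
#' (miRNA, gene) exactly \code{truth$predicted[mirna, gene]} distinct
#' tools list the pair. Tool subsets are sampled without replacement
#' (which tools are chosen is immaterial to all scores). Deterministic
#' under \code{truth$seed}.
#'
#' @param truth As returned by [randomTruth()].
#' @param registry Tool registry; every planted count must be <= D.
#' @param dir Output directory (created if needed).
#' @return List of paths: \code{validated} (file), \code{predicted}
#'   (named vector, one per tool), \code{truth} (JSON).
#' @export
generateEvidenceExports <- function(truth, registry = toolRegistry(30L),
                                    dir = tempfile("exports")) {
  registry <- toolRegistry(registry)
  D <- length(registry)
  if (any(truth$predicted > D) || any(truth$predicted < 0))
    stop("domain error: planted counts must lie in [0, D]")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- truth$predicted
  withSeed(truth$seed, {
    vrows <- do.call(rbind, lapply(names(truth$validated), function(m) {
      genes <- truth$validated[[m]]
      if (length(genes) == 0L) return(NULL)
      nsrc <- sample(1:2, length(genes), replace = TRUE)
      data.frame(mirna = rep(m, sum(nsrc)),
                 gene = rep(genes, nsrc),
                 source_db = unlist(lapply(nsrc, function(k)
                   sample(c("TarBase", "miRTarBase"), k))),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(vrows))
      vrows <- data.frame(mirna = character(), gene = character(),
                          source_db = character())
    prows <- list()
    for (m in rownames(pm)) for (g in colnames(pm)) {
      k <- pm[m, g]
      if (k > 0L)
        prows[[length(prows) + 1L]] <- data.frame(
          mirna = m, gene = g, tool = sample(registry, k),
          stringsAsFactors = FALSE)
    }
    prows <- if (length(prows)) do.call(rbind, prows) else
      data.frame(mirna = character(), gene = character(), tool = character())
  })
  vpath <- file.path(dir, "validated.tsv")
  write.table(vrows, vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ppaths <- setNames(file.path(dir, paste0(registry, ".tsv")), registry)
  for (tool in registry) {
    sub <- prows[prows$tool == tool, c("mirna", "gene"), drop = FALSE]
    write.table(sub, ppaths[[tool]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tpath <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = truth$seed,
         validated = truth$validated,
         predicted = as.data.frame(as.table(truth$predicted),
                                   stringsAsFactors = FALSE)),
    tpath, auto_unbox = TRUE, digits = NA)
  list(validated = vpath, predicted = ppaths, truth = tpath)
}

#' Generate a synthetic qPCR Ct table with planted fold changes
#'
#' Emulates the structure of a relative-quantification experiment: a
#' control group and treated groups, each with \code{n_bio} biological
#' replicates measured in \code{n_tech} technical replicates for every
#' target assay and the reference assay. The target Ct of a treated
#' sample is shifted by \code{-log2(fold)} relative to control, so the
#' 2^-ddCt pipeline recovers the planted fold exactly when
#' \code{noise_sd = 0}.
#'
#' @param planted_folds Named numeric vector (assay -> fold, all > 0) for
#'   the treated group, or a matrix assays x groups for several treated
#'   groups.
#' @param control_group,treated_groups Group labels.
#' @param reference_assay Reference assay name (default \code{"GAPDH"}).
#' @param n_bio,n_tech Biological / technical replicates (defaults 3, 3).
#' @param noise_sd Gaussian Ct noise, in cycles (default 0.1).
#' @param base_ct_reference,base_ct_target Baseline cycle thresholds.
#' @param seed Integer seed.
#' @return A validated Ct table data.frame.
#' @examples
#' ct <- generateCtTable(planted_folds = c(APOB = 0.29), seed = 7)
#' ddctFoldChange(ct, "APOB", "GAPDH", "control")
#' @export
generateCtTable <- function(planted_folds,
                            control_group = "control",
                            treated_groups = "treated",
                            reference_assay = "GAPDH",
                            n_bio = 3L, n_tech = 3L,
                            noise_sd = 0.1,
                            base_ct_reference = 18,
                            base_ct_target = 24,
                            seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(dim(planted_folds))) {
    planted_folds <- matrix(planted_folds,
                            ncol = length(treated_groups),
                            nrow = length(planted_folds),
                            dimnames = list(names(planted_folds),
                                            treated_groups))
  }
  if (any(planted_folds <= 0))
    stop("domain error: planted folds must be positive")
  assays <- rownames(planted_folds)
  if (reference_assay %in% assays)
    stop("reference assay cannot carry a planted fold")
  groups <- c(control_group, colnames(planted_folds))
  base_t <- setNames(rep_len(base_ct_target, length(assays)), assays)
  rows <- list()
  withSeed(seed, {
    for (g in groups) for (b in seq_len(n_bio)) {
      smp <- sprintf("%s_b%d", g, b)
      for (a in c(reference_assay, assays)) {
        mu <- if (a == reference_assay) base_ct_reference
        else if (g == control_group) base_t[[a]]
        else base_t[[a]] - log2(planted_folds[a, g])
        for (tr in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, group = g, bio_rep = b, tech_rep = tr,
            assay = a, ct = mu + rnorm(1L, 0, noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  validateCtTable(do.call(rbind, rows))
}

#' Generate a synthetic MTT plate with planted viability fractions
#'
#' Each well gets a reference-wavelength baseline absorbance (a630) and a
#' formazan signal proportional to the planted viability fraction on top
#' (a570 = a630 + signal). The control group carries fraction 1, so
#' [viabilityPercent()] recovers \code{100 * fraction}.
#'
#' @param planted_fractions Named numeric vector (group -> fraction > 0),
#'   or a matrix groups x timepoints.
#' @param timepoints Numeric vector of timepoints in hours (default
#'   \code{c(24, 48, 72)}).
#' @param control_group Control label (fraction 1 at every timepoint).
#' @param n_wells Wells per (group, timepoint) (default 6).
#' @param control_signal Mean control formazan signal (default 0.6).
#' @param baseline Mean a630 (default 0.05).
#' @param well_noise Relative (fractional) well-to-well noise (default
#'   0.02).
#' @param seed Integer seed.
#' @return A viability table data.frame.
#' @export
generateViabilityPlate <- function(planted_fractions,
                                   timepoints = c(24, 48, 72),
                                   control_group = "control",
                                   n_wells = 6L,
                                   control_signal = 0.6,
                                   baseline = 0.05,
                                   well_noise = 0.02,
                                   seed = 1L) {
  if (is.null(dim(planted_fractions))) {
    planted_fractions <- matrix(planted_fractions,
                                nrow = length(planted_fractions),
                                ncol = length(timepoints),
                                dimnames = list(names(planted_fractions),
                                                as.character(timepoints)))
  }
  if (any(planted_fractions < 0))
    stop("domain error: planted fractions must be non-negative")
  groups <- c(control_group, rownames(planted_fractions))
  frac <- rbind(matrix(1, 1, ncol(planted_fractions),
                       dimnames = list(control_group, colnames(planted_fractions))),
                planted_fractions)
  rows <- list()
  withSeed(seed, {
    for (g in groups) for (tp in colnames(frac)) {
      sig <- control_signal * frac[g, tp] *
        (1 + rnorm(n_wells, 0, well_noise))
      a630 <- baseline * (1 + rnorm(n_wells, 0, well_noise))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, timepoint = as.numeric(tp), well = seq_len(n_wells),
        a570 = a630 + sig, a630 = a630, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
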