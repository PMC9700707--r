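## Relative expression by the 2^-ddCt method with reference-gene
## normalization, ANOVA/Tukey group statistics on dCt, a Lilliefors
## normality check, and MTT viability normalization.

#' Validate a long-format Ct table
#'
#' A Ct table holds replicate-level qPCR cycle thresholds:
#' one row per (sample, group, biological replicate, technical replicate,
#' assay). Checks positivity/finiteness of Ct, uniqueness of
#' (sample, assay, technical replicate), and presence of the reference
#' assay in every group.
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{bio_rep}, \code{tech_rep}, \code{assay}, \code{ct}.
#' @param reference_assay Name of the reference (housekeeping) assay, e.g.
#'   \code{"GAPDH"} for mRNA or \code{"SNORD47"} for miRNA panels.
#' @return The table, invisibly, after validation.
#' @export
validateCtTable <- function(ct, reference_assay = NULL) {
  need <- c("sample", "group", "bio_rep", "tech_rep", "assay", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive and finite")
  key <- paste(ct$sample, ct$assay, ct$tech_rep)
  if (anyDuplicated(key))
    stop("duplicate (sample, assay, tech_rep) rows in Ct table")
  if (!is.null(reference_assay)) {
    has_ref <- tapply(ct$assay, ct$group,
                      function(a) reference_assay %in% a)
    if (!all(has_ref))
      stop(sprintf("normalization error: reference assay '%s' missing in group(s): %s",
                   reference_assay,
                   paste(names(has_ref)[!has_ref], collapse = ", ")))
  }
  invisible(ct)
}

#' Read a long-format Ct TSV
#'
#' @param path Delimited file (sniffed) with the columns of
#'   [validateCtTable()].
#' @param delim Delimiter; \code{NULL} to sniff.
#' @return Validated data.frame.
#' @export
readCtTable <- function(path, delim = NULL) {
  validateCtTable(readDelimited(path, delim))
}

# technical-replicate aggregation: arithmetic mean Ct per (sample, assay)
meanCtPerSample <- function(ct, assay_name) {
  sub <- ct[ct$assay == assay_name, , drop = FALSE]
  agg <- aggregate(ct ~ sample + group, data = sub, FUN = mean)
  agg
}

# dCt = Ct(target) - Ct(reference) per biological replicate (sample)
deltaCt <- function(ct, target_assay, reference_assay) {
  tgt <- meanCtPerSample(ct, target_assay)
  ref <- meanCtPerSample(ct, reference_assay)
  m <- merge(tgt, ref, by = c("sample", "group"),
             suffixes = c("_target", "_reference"))
  m$dct <- m$ct_target - m$ct_reference
  m[, c("sample", "group", "dct")]
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged to one Ct per (sample, assay); per
#' biological replicate dCt = Ct(target) - Ct(reference); per treated
#' replicate ddCt = dCt - mean dCt of the control group; fold = 2^-ddCt.
#' The reported fold change and SD are the mean and standard deviation of
#' the per-replicate folds (fold scale). Group significance is assessed on
#' the dCt values — the approximately normal scale — by one-way ANOVA with
#' Tukey HSD contrasts against the control, and annotated with the usual
#' tiers (\code{*} p < 0.05, \code{**} p < 0.01).
#'
#' @param ct Ct table (see [validateCtTable()]).
#' @param target_assay Assay to quantify.
#' @param reference_assay Housekeeping assay (e.g. \code{"GAPDH"},
#'   \code{"SNORD47"}).
#' @param control_group Name of the calibrator group.
#' @return data.frame, one row per treated group: \code{assay},
#'   \code{group}, \code{n} (biological replicates), \code{fold_change},
#'   \code{sd} (NA when n < 2, with a warning), \code{p_value} (Tukey vs
#'   control; NA when inference is impossible), \code{tier}.
#' @examples
#' ct <- generateCtTable(planted_folds = c(TRG = 0.5), noise_sd = 0,
#'                       seed = 1)
#' ddctFoldChange(ct, "TRG", "GAPDH", "control")
#' @export
ddctFoldChange <- function(ct, target_assay, reference_assay,
                           control_group) {
  validateCtTable(ct, reference_assay)
  if (!target_assay %in% ct$assay)
    stop(sprintf("assay '%s' absent from Ct table", target_assay))
  if (!control_group %in% ct$group)
    stop(sprintf("control group '%s' absent from Ct table", control_group))
  d <- deltaCt(ct, target_assay, reference_assay)
  ctrl <- d$dct[d$group == control_group]
  if (length(ctrl) < 1L)
    stop("control group has no biological replicates for this assay")
  d$ddct <- d$dct - mean(ctrl)
  d$fold <- 2^(-d$ddct)
  groups <- setdiff(unique(d$group), control_group)
  # Tukey contrasts vs control on dCt, when inference is possible
  pvals <- rep(NA_real_, length(groups)); names(pvals) <- groups
  tab <- table(d$group)
  if (length(tab) >= 2L && all(tab >= 2L) && sd(d$dct) > 0) {
    cmp <- groupCompare(split(d$dct, d$group), control_group)
    pvals[groups] <- cmp$p_vs_control[groups]
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    f <- d$fold[d$group == g]
    if (length(f) < 2L)
      warning(sprintf("group '%s': < 2 biological replicates, SD undefined", g))
    data.frame(assay = target_assay, group = g, n = length(f),
               fold_change = mean(f),
               sd = if (length(f) >= 2L) sd(f) else NA_real_,
               p_value = pvals[[g]],
               tier = significanceTier(pvals[[g]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

significanceTier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' One-way ANOVA with Tukey contrasts against a control
#'
#' Omnibus one-way ANOVA across groups plus Tukey honest-significant-
#' difference p-values for every group against the control. Intended to
#' run on dCt values (not folds).
#'
#' @param values Named list (or data.frame with \code{value}, \code{group})
#'   of numeric observations per group.
#' @param control_group Name of the control group.
#' @return List: \code{p_anova}, \code{p_vs_control} (named vector over
#'   non-control groups), \code{method}.
#' @examples
#' set.seed(1)
#' groupCompare(list(ctrl = rnorm(5), trt = rnorm(5, 2)), "ctrl")
#' @export
groupCompare <- function(values, control_group) {
  if (is.data.frame(values))
    values <- split(values$value, values$group)
  if (length(values) < 2L)
    stop("group comparison requires at least 2 groups")
  n <- lengths(values)
  if (any(n < 2L))
    stop(sprintf("degenerate input: group(s) %s have fewer than 2 observations",
                 paste(sQuote(names(values)[n < 2L]), collapse = ", ")))
  if (!control_group %in% names(values))
    stop(sprintf("control group '%s' not among groups", control_group))
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), n)))
  if (sd(df$value) == 0)
    stop("degenerate input: all observations identical")
  fit <- aov(value ~ group, data = df)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  others <- setdiff(names(values), control_group)
  p_vs <- vapply(others, function(g) {
    rn <- rownames(tk)
    hit <- rn == paste(g, control_group, sep = "-") |
      rn == paste(control_group, g, sep = "-")
    tk[hit, "p adj"][1]
  }, numeric(1))
  list(p_anova = p_anova, p_vs_control = p_vs,
       method = "one-way ANOVA + Tukey HSD")
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' Tests departure from a normal distribution with mean and SD estimated
#' from the sample, using the Lilliefors small-sample correction (the
#' appropriate form when parameters are estimated, unlike the plain KS
#' test). Requires n >= 5, the smallest size for which the correction is
#' defined.
#'
#' @param values Numeric vector.
#' @return The p-value.
#' @examples
#' set.seed(1); normalityCheck(rnorm(30))
#' @export
normalityCheck <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L)
    stop("insufficient data: normality check requires n >= 5")
  if (sd(values) == 0)
    stop("degenerate input: constant vector")
  nortest::lillie.test(values)$p.value
}

#' Validate an MTT absorbance table
#'
#' @param v data.frame with columns \code{group}, \code{timepoint},
#'   \code{well}, \code{a570}, \code{a630} (absorbances at the measurement
#'   and reference wavelengths).
#' @return The table invisibly; wells with negative background-corrected
#'   signal (a570 < a630) raise a warning and are flagged in attribute
#'   \code{"flagged_wells"}.
#' @export
validateViabilityTable <- function(v) {
  need <- c("group", "timepoint", "well", "a570", "a630")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop(sprintf("viability table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(v$a630 < 0) || any(!is.finite(v$a570)) || any(!is.finite(v$a630)))
    stop("absorbances must be finite and a630 non-negative")
  neg <- which(v$a570 < v$a630)
  if (length(neg)) {
    warning(sprintf("%d well(s) with negative background-corrected signal",
                    length(neg)))
    attr(v, "flagged_wells") <- neg
  }
  invisible(v)
}

#' MTT viability as percent of control
#'
#' Per well, signal = a570 - a630 (formazan absorbance minus reference-
#' wavelength background). Per (group, timepoint), viability is the mean
#' treated signal as a percentage of the mean control signal at the same
#' timepoint.
#'
#' @param v Viability table (see [validateViabilityTable()]).
#' @param control_group Name of the control group.
#' @return data.frame: \code{group}, \code{timepoint},
#'   \code{viability_percent}.
#' @examples
#' v <- generateViabilityPlate(planted_fractions = c(treated = 0.7),
#'                             well_noise = 0, seed = 1)
#' viabilityPercent(v, "control")
#' @export
viabilityPercent <- function(v, control_group) {
  validateViabilityTable(v)
  if (!control_group %in% v$group)
    stop(sprintf("control group '%s' absent", control_group))
  v$signal <- v$a570 - v$a630
  res <- expand.grid(group = setdiff(unique(v$group), control_group),
                     timepoint = unique(v$timepoint),
                     stringsAsFactors = FALSE)
  res$viability_percent <- mapply(function(g, tp) {
    ctrl <- v$signal[v$group == control_group & v$timepoint == tp]
    trt <- v$signal[v$group == g & v$timepoint == tp]
    if (length(ctrl) == 0L)
      stop(sprintf("normalization error: no control wells at timepoint %s", tp))
    mc <- mean(ctrl)
    if (mc <= 0)
      stop("normalization error: control mean signal <= 0")
    100 * mean(trt) / mc
  }, res$group, res$timepoint)
  res[order(res$group, res$timepoint), , drop = FALSE]
}
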