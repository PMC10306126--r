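## Cholinergic-subsystem analyses: pair enumeration within/between the
## basal forebrain and brainstem-thalamic cholinergic sets, average
## correlations, two-way ANOVA (type II) with Tukey post hoc comparisons,
## cholinergic x anatomic-group correlation profiles, and minimal
## addiction-network extraction.

## Regions repeatedly implicated in nicotine dependence and withdrawal;
## default partners for the minimal network alongside the cholinergic set.
.addictionRegions <- c("ACA", "ILA", "PL", "DP", "CP", "ACB", "BST",
                       "BLA", "CEA", "VTA", "IPN")

#' Enumerate cholinergic region pairs by category
#'
#' Builds unordered region pairs within the basal forebrain set, within the
#' brainstem-thalamic set, and between the two sets. With the default sets
#' (MA, NDB, SI vs MS, PPN, MH, LH) these number 3, 6 and 12.
#'
#' @param sets list with `basal_forebrain` and `brainstem_thalamic`
#'   character vectors (see [cholinergicSets()]).
#' @return named list of two-column matrices (`region_a`, `region_b`) for
#'   categories `within_basal_forebrain`, `within_brainstem_thalamic`,
#'   `between`.
#' @export
enumeratePairs <- function(sets = cholinergicSets()) {
  withinPairs <- function(s, label) {
    if (length(s) < 2L) {
      warning("set '", label, "' has fewer than 2 regions; no within pairs",
              call. = FALSE)
      return(matrix(character(), 0L, 2L,
                    dimnames = list(NULL, c("region_a", "region_b"))))
    }
    cmb <- t(utils::combn(s, 2L))
    colnames(cmb) <- c("region_a", "region_b")
    cmb
  }
  between <- as.matrix(expand.grid(region_a = sets$basal_forebrain,
                                   region_b = sets$brainstem_thalamic,
                                   stringsAsFactors = FALSE))
  list(within_basal_forebrain = withinPairs(sets$basal_forebrain,
                                            "basal_forebrain"),
       within_brainstem_thalamic = withinPairs(sets$brainstem_thalamic,
                                               "brainstem_thalamic"),
       between = between)
}

.pairValues <- function(corr, pairs) {
  r <- corr@r
  missing <- setdiff(unique(c(pairs)), rownames(r))
  if (length(missing))
    stop("pair member(s) absent from correlation matrix: ",
         paste(missing, collapse = ", "))
  r[pairs]
}

#' Average correlation over a set of region pairs
#'
#' Arithmetic mean of the raw Pearson r values (no Fisher transform, which
#' mirrors how subsystem averages are usually reported; set
#' `fisher = TRUE` to average on the z scale and back-transform).
#'
#' @param corr a [CorrelationMatrix-class].
#' @param pairs two-column character matrix of region pairs.
#' @param fisher average on the Fisher-z scale instead.
#' @return single numeric mean correlation.
#' @export
averageSubgroupR <- function(corr, pairs, fisher = FALSE) {
  if (!nrow(pairs)) stop("empty pair list: mean correlation undefined")
  v <- .pairValues(corr, pairs)
  if (fisher) tanh(mean(atanh(pmin(pmax(v, -0.999999), 0.999999))))
  else mean(v)
}

#' Long-format pair-level correlation sample
#'
#' One row per (treatment, category, region pair) with its correlation —
#' the observation unit for the two-way ANOVA: with the default sets this
#' is 21 pairs per treatment (3 + 6 + 12).
#'
#' @param corrList named list of [CorrelationMatrix-class] objects, one
#'   per treatment (names are the treatment labels).
#' @param sets cholinergic subsystem sets (see [cholinergicSets()]).
#' @return data.frame with columns `treatment`, `category`, `region_a`,
#'   `region_b`, `r`.
#' @export
pairCorrelationSamples <- function(corrList, sets = cholinergicSets()) {
  pairs <- enumeratePairs(sets)
  out <- list()
  for (tr in names(corrList)) {
    for (cat in names(pairs)) {
      pp <- pairs[[cat]]
      if (!nrow(pp)) next
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, category = cat,
        region_a = pp[, 1L], region_b = pp[, 2L],
        r = .pairValues(corrList[[tr]], pp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-way ANOVA with Tukey post hoc comparisons
#'
#' Fits `r ~ treatment * category` on pair-level correlations (type-II sums
#' of squares, valid for unbalanced layouts) and runs Tukey HSD across all
#' treatment-by-category cell means.
#'
#' @param samples data.frame with columns `treatment`, `category` and a
#'   response column.
#' @param response name of the response column (default `"r"`).
#' @return list with `effects` (data.frame: term, F, df1, df2, p),
#'   `cellMeans`, and `tukey` (the `treatment:category` component of
#'   [stats::TukeyHSD()]).
#' @export
anovaTwoWay <- function(samples, response = "r") {
  for (col in c("treatment", "category", response))
    if (!col %in% names(samples)) stop("missing column: ", col)
  samples$treatment <- factor(samples$treatment)
  samples$category <- factor(samples$category)
  if (nlevels(samples$treatment) < 2L || nlevels(samples$category) < 2L)
    stop("need at least 2 levels per factor")
  cellN <- table(samples$treatment, samples$category)
  if (any(cellN == 0L)) {
    empty <- which(cellN == 0L, arr.ind = TRUE)
    stop("empty cell(s): ",
         paste(rownames(cellN)[empty[, 1L]], colnames(cellN)[empty[, 2L]],
               sep = ":", collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~ treatment * category"))
  a <- nlevels(samples$treatment); b <- nlevels(samples$category)
  cellMeans <- stats::aggregate(samples[[response]],
                                by = list(treatment = samples$treatment,
                                          category = samples$category),
                                FUN = mean)
  names(cellMeans)[3L] <- "mean"
  if (stats::var(samples[[response]]) == 0) {
    ## constant response: nothing to attribute, F = 0 for every effect
    effects <- data.frame(
      term = c("treatment", "category", "treatment:category"),
      F = 0, df1 = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
      df2 = nrow(samples) - a * b, p = 1, stringsAsFactors = FALSE)
    cells <- interaction(cellMeans$treatment, cellMeans$category, sep = ":")
    pairs <- utils::combn(as.character(cells), 2L)
    np <- ncol(pairs)
    tukey <- data.frame(diff = rep(0, np), lwr = rep(0, np),
                        upr = rep(0, np), `p adj` = rep(1, np),
                        row.names = paste(pairs[2L, ], pairs[1L, ],
                                          sep = "-"), check.names = FALSE)
    return(list(effects = effects, cellMeans = cellMeans, tukey = tukey))
  }
  fit <- stats::lm(fml, data = samples)
  an <- car::Anova(fit, type = 2)
  dfRes <- an["Residuals", "Df"]
  terms <- setdiff(rownames(an), "Residuals")
  effects <- data.frame(term = terms,
                        F = an[terms, "F value"],
                        df1 = an[terms, "Df"],
                        df2 = dfRes,
                        p = an[terms, "Pr(>F)"],
                        row.names = NULL, stringsAsFactors = FALSE)
  ## a term with zero sum of squares explains nothing: F = 0 by convention
  ## (avoids 0/0 when the residual SS is also zero)
  zeroSS <- an[terms, "Sum Sq"] <= 0
  effects$F[zeroSS] <- 0
  effects$p[zeroSS] <- 1
  aovFit <- stats::aov(fml, data = samples)
  tk <- stats::TukeyHSD(aovFit, "treatment:category")[["treatment:category"]]
  list(effects = effects, cellMeans = cellMeans, tukey = as.data.frame(tk))
}

#' Cholinergic-region by anatomic-group correlation profile
#'
#' For each cholinergic region, the mean correlation with all member
#' regions of each of the nine anatomic groups (the region itself is
#' excluded, so a cholinergic region that is the sole member of its group
#' yields a missing cell).
#'
#' @param corr a [CorrelationMatrix-class].
#' @param meta region metadata data.frame from [readRegionMetadata()] (or
#'   one with columns `region_id`, `anatomic_group`, `cholinergic_group`).
#' @return long-format data.frame with columns `cholinergic_region`,
#'   `anatomic_group`, `mean_r`, `n_partners` (rows with no partners have
#'   `mean_r = NA`).
#' @export
cholinergicAnatomyProfile <- function(corr, meta) {
  r <- corr@r
  meta <- as.data.frame(meta)
  meta <- meta[meta$region_id %in% rownames(r), , drop = FALSE]
  chol <- meta$region_id[!is.na(meta$cholinergic_group)]
  if (!length(chol)) stop("no cholinergic regions present in the matrix")
  out <- expand.grid(cholinergic_region = chol,
                     anatomic_group = .anatomicGroups,
                     stringsAsFactors = FALSE)
  out$mean_r <- NA_real_
  out$n_partners <- 0L
  for (i in seq_len(nrow(out))) {
    members <- meta$region_id[!is.na(meta$anatomic_group) &
                                meta$anatomic_group == out$anatomic_group[i]]
    partners <- setdiff(members, out$cholinergic_region[i])
    out$n_partners[i] <- length(partners)
    if (length(partners))
      out$mean_r[i] <- mean(r[out$cholinergic_region[i], partners])
  }
  out
}

#' Induced minimal network
#'
#' Induced subgraph on a kept region set — by default the cholinergic
#' regions plus regions repeatedly implicated in nicotine addiction (ACA,
#' ILA, PL, DP, CP, ACB, BST, BLA, CEA, VTA, IPN). Isolated kept regions
#' are retained.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param keep character vector of region acronyms; must all be nodes.
#' @return A [ThresholdedNetwork-class] on the kept regions.
#' @export
minimalNetwork <- function(net,
                           keep = c(unlist(cholinergicSets(),
                                           use.names = FALSE),
                                    .addictionRegions)) {
  regions <- networkRegions(net)
  unknown <- setdiff(keep, regions)
  if (length(unknown))
    stop("unknown region(s) in keep: ", paste(unknown, collapse = ", "))
  sub <- igraph::induced_subgraph(net@graph, vids = keep)
  new("ThresholdedNetwork", graph = sub, threshold = net@threshold)
}
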