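#' @importFrom stats aov TukeyHSD
NULL

#' Fit a robust spike-in standard curve (Theil-Sen)
#'
#' Fits \code{log10(measured_signal)} against \code{log10(known_amount)}
#' with the Theil-Sen estimator: the slope is the median of all pairwise
#' slopes over pairs with distinct amounts, the intercept the median of
#' \code{y - slope * x}. Standards with zero or missing signal are excluded
#' and counted. The median-of-slopes fit tolerates gross outliers among the
#' standards, which matters for low-amount spike-ins near the detection
#' limit.
#'
#' @param spikeins data.frame with columns \code{standard_id},
#'   \code{known_amount} (> 0) and \code{measured_signal} (>= 0; 0 =
#'   undetected).
#' @return a [StandardCurve-class].
#' @examples
#' sp <- data.frame(standard_id = c("s1","s2","s3"),
#'                  known_amount = 10^c(1, 2, 3),
#'                  measured_signal = 10^c(1, 2, 3))
#' fitStandardCurve(sp)  # identity: slope 1, intercept 0
#' @export
fitStandardCurve <- function(spikeins) {
  need <- c("known_amount", "measured_signal")
  stopIfNot(all(need %in% names(spikeins)),
            "spike-in table needs columns %s", paste(need, collapse = ", "))
  amount <- spikeins$known_amount
  signal <- spikeins$measured_signal
  stopIfNot(all(amount > 0, na.rm = TRUE), "known amounts must be positive")
  usable <- is.finite(signal) & signal > 0
  nDropped <- sum(!usable)
  if (nDropped > 0)
    logNote("fitStandardCurve: %d standard(s) with zero/missing signal excluded",
            nDropped)
  x <- log10(amount[usable])
  y <- log10(signal[usable])
  if (length(x) < 2L)
    stop("insufficient data: need >= 2 standards with positive signal")
  if (length(unique(x)) < 2L)
    stop("degenerate fit: all usable standard amounts are identical")
  ij <- utils::combn(length(x), 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  keep <- dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  new("StandardCurve", slope = slope, intercept = intercept,
      nPointsUsed = length(x), nDropped = as.integer(nDropped),
      fitSpace = "log10-log10")
}

#' Estimate absolute protein concentrations from MS signals
#'
#' Inverts the standard curve per entity
#' (\eqn{10^{(\log_{10} s - intercept)/slope}}), optionally collapsing
#' isoform signals to genes by summation first, then rescales all
#' concentrations by one global factor so that their molar sum equals
#' \code{totalConcentration} (default 2 mM, the assumed total protein
#' concentration of the egg). Entities below \code{cutoff} are removed
#' *after* scaling. The inverse transform is monotone, so concentration
#' ranks mirror signal ranks.
#'
#' @param curve a [StandardCurve-class].
#' @param signals single-stage [StageExperiment-class] (or named numeric
#'   vector) of MS signals; zero/missing signals are dropped with a logged
#'   count.
#' @param totalConcentration target molar sum, mol/L (default \code{2e-3}).
#' @param cutoff concentration floor, mol/L (default \code{1e-8} = 0.01 uM);
#'   applied after global scaling.
#' @param isoformMap optional named character vector mapping entity
#'   (isoform) ids to gene ids; signals are summed per gene before
#'   conversion.
#' @param collapse how to collapse isoforms: \code{"sum"} (default) or
#'   \code{"max"}.
#' @param tfIds,smIds optional annotation id vectors used to set the
#'   \code{isTF} / \code{isSM} flags.
#' @return a [S4Vectors::DataFrame] with columns \code{entity},
#'   \code{concentration_nM}, \code{isTF}, \code{isSM}; its
#'   \code{metadata()} records the curve, the global scale factor, the
#'   molar sum before cutoff and drop counts.
#' @examples
#' cv <- new("StandardCurve", slope = 1, intercept = 0, nPointsUsed = 3L,
#'           nDropped = 0L, fitSpace = "log10-log10")
#' estimateConcentrations(cv, c(p1 = 1, p2 = 1, p3 = 2), cutoff = 0)
#' @export
estimateConcentrations <- function(curve, signals,
                                   totalConcentration = 2e-3,
                                   cutoff = 1e-8, isoformMap = NULL,
                                   collapse = c("sum", "max"),
                                   tfIds = NULL, smIds = NULL) {
  collapse <- match.arg(collapse)
  stopIfNot(is(curve, "StandardCurve"), "curve must be a StandardCurve")
  if (curve@slope == 0) stop("degenerate curve: slope is zero")
  stopIfNot(totalConcentration > 0, "totalConcentration must be positive")
  if (is(signals, "StageExperiment")) {
    stopIfNot(ncol(signals) == 1L,
              "signals must be a single-stage experiment")
    s <- stats::setNames(exprValues(signals)[, 1L], rownames(signals))
  } else {
    s <- signals
    stopIfNot(!is.null(names(s)), "signals must be named")
  }
  if (!is.null(isoformMap)) {
    un <- setdiff(names(s), names(isoformMap))
    if (length(un))
      stop("isoform map missing entries for: ", paste(un, collapse = ", "))
    gene <- isoformMap[names(s)]
    agg <- if (collapse == "sum") rowsum(s, gene, na.rm = TRUE) else
      vapply(split(s, gene), max, 0, na.rm = TRUE)
    s <- stats::setNames(as.numeric(agg), rownames(as.matrix(agg)))
  }
  usable <- is.finite(s) & s > 0
  if (any(!usable))
    logNote("estimateConcentrations: %d entit(ies) with zero/missing signal dropped",
            sum(!usable))
  s <- s[usable]
  if (!length(s)) stop("insufficient data: no usable signals")
  raw <- 10^((log10(s) - curve@intercept) / curve@slope)
  scaleFactor <- totalConcentration / sum(raw)
  conc <- raw * scaleFactor      # mol/L
  molarSumBeforeCutoff <- sum(conc)
  keep <- conc >= cutoff
  nCut <- sum(!keep)
  if (!any(keep))
    warning("all entities fall below the concentration cutoff; empty table")
  conc <- conc[keep]
  out <- S4Vectors::DataFrame(
    entity = names(conc),
    concentration_nM = unname(conc) * 1e9,
    isTF = if (is.null(tfIds)) rep(FALSE, length(conc)) else
      names(conc) %in% tfIds,
    isSM = if (is.null(smIds)) rep(FALSE, length(conc)) else
      names(conc) %in% smIds)
  S4Vectors::metadata(out) <- list(
    curve = curve, scaleFactor = scaleFactor,
    totalConcentration = totalConcentration, cutoff = cutoff,
    molarSumBeforeCutoff = molarSumBeforeCutoff,
    nDroppedSignals = sum(!usable), nBelowCutoff = nCut)
  out
}

#' Median concentration, optionally over an annotated subset
#'
#' @param table concentration table from [estimateConcentrations()] (any
#'   data.frame-like with \code{entity} and \code{concentration_nM}).
#' @param subset optional id vector (e.g. from [readAnnotationList()]);
#'   subset ids absent from the table are ignored and counted in a message.
#' @return median concentration in nM.
#' @examples
#' tab <- S4Vectors::DataFrame(entity = c("a","b","c"),
#'                             concentration_nM = c(10, 20, 30))
#' medianConcentration(tab)  # 20
#' @export
medianConcentration <- function(table, subset = NULL) {
  conc <- table$concentration_nM
  ids <- table$entity
  if (!is.null(subset)) {
    absent <- sum(!subset %in% ids)
    if (absent > 0)
      logNote("medianConcentration: %d subset id(s) absent from table", absent)
    keep <- ids %in% subset
    if (!any(keep))
      stop("insufficient data: no subset ids present in the table")
    conc <- conc[keep]
  }
  if (!length(conc)) stop("insufficient data: empty concentration table")
  stats::median(conc)
}

#' Test protein-complex stoichiometry against the bulk proteome
#'
#' For every complex with at least three detected subunits, compares the
#' subunits' log10 concentrations with the remaining proteome: a one-factor
#' analysis of variance across groups (each qualifying complex plus the
#' background group) followed by Tukey honest-significant-difference
#' comparisons of each complex against the background (studentized-range
#' procedure on group means with pooled variance). Complexes with fewer
#' than three detected subunits are excluded.
#'
#' @param table concentration table (\code{entity},
#'   \code{concentration_nM}).
#' @param catalog complex catalog as from [readComplexCatalog()].
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.01).
#' @return data.frame with one row per tested complex: \code{complexId},
#'   \code{nDetected}, \code{pAdj} (Tukey-adjusted p versus background),
#'   \code{meanLog10nM}, \code{significant}; subunit log10 concentrations
#'   are attached as attribute \code{"subunitLog10"} (named list). Empty
#'   (zero-row) result when no complex qualifies.
#' @examples
#' sim <- simulateComplexData(4, 5, withinSd = 0.1, globalSd = 1, seed = 2)
#' complexStoichiometryTest(sim$concentrations, sim$catalog)
#' @export
complexStoichiometryTest <- function(table, catalog, alpha = 0.01) {
  empty <- data.frame(complexId = character(), nDetected = integer(),
                      pAdj = numeric(), meanLog10nM = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!nrow(catalog)) return(empty)
  ids <- table$entity
  logc <- stats::setNames(log10(table$concentration_nM), ids)
  detected <- lapply(catalog$members, function(m) intersect(m, ids))
  # an entity annotated to several complexes stays with the first;
  # qualification (>= 3 detected subunits) is judged after that resolution
  grp <- rep("background", length(ids))
  names(grp) <- ids
  for (i in seq_along(detected)) {
    free <- detected[[i]][grp[detected[[i]]] == "background"]
    if (length(free) < length(detected[[i]]))
      warning("entity in multiple complexes; kept in first: ",
              paste(setdiff(detected[[i]], free), collapse = ", "))
    detected[[i]] <- free
    grp[free] <- catalog$complexId[i]
  }
  qual <- lengths(detected) >= 3L
  if (!any(qual)) return(empty)
  cxIds <- catalog$complexId[qual]
  members <- detected[qual]
  grp[!grp %in% c("background", cxIds)] <- "background"
  if (sum(grp == "background") < 2L)
    stop("insufficient data: background group too small")
  dat <- data.frame(logc = unname(logc), group = factor(unname(grp)))
  fit <- stats::aov(logc ~ group, data = dat)
  tk <- stats::TukeyHSD(fit)$group
  cmp <- rownames(tk)
  pAdj <- vapply(cxIds, function(cx) {
    hit <- cmp %in% c(paste0(cx, "-background"), paste0("background-", cx))
    tk[hit, "p adj"][1L]
  }, 0)
  res <- data.frame(
    complexId = cxIds,
    nDetected = lengths(members),
    pAdj = unname(pAdj),
    meanLog10nM = vapply(members, function(m) mean(logc[m]), 0),
    significant = unname(pAdj) < alpha,
    stringsAsFactors = FALSE)
  attr(res, "subunitLog10") <- stats::setNames(
    lapply(members, function(m) logc[m]), cxIds)
  res
}

#' Cumulative abundance curve
#'
#' Ranks values from highest to lowest and accumulates their share of the
#' total as a percentage; the final point is always 100%.
#'
#' @param values non-negative numeric vector (optionally named) with a
#'   positive sum.
#' @return data.frame with \code{rank}, \code{entity} (if named) and
#'   \code{cumulativePercent}.
#' @examples
#' cumulativeAbundance(c(a = 50, b = 30, c = 20))$cumulativePercent
#' @export
cumulativeAbundance <- function(values) {
  stopIfNot(all(values >= 0, na.rm = TRUE), "values must be non-negative")
  v <- values[!is.na(values)]
  if (!length(v) || sum(v) <= 0)
    stop("cumulative abundance undefined: values sum to zero")
  ord <- order(v, decreasing = TRUE)
  v <- v[ord]
  out <- data.frame(rank = seq_along(v),
                    cumulativePercent = cumsum(v) / sum(v) * 100)
  if (!is.null(names(v))) out$entity <- names(v)
  out
}
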