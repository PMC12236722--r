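#' Target-repression CDF and one-sided rank-sum test
#'
#' Compares the log2 fold-change distribution of a target gene set against
#' a background set, as in a cumulative-distribution plot of miRNA-target
#' derepression. Genes below the CPM floor are removed first (when a `cpm`
#' column is present); targets absent from the table after filtering are
#' dropped and reported. Significance is a one-sided Wilcoxon rank-sum
#' test (alternative: targets shifted toward lower fold-change), using the
#' normal approximation with tie correction and continuity correction, or
#' exact enumeration when both groups have at most `exactMax` genes and
#' the data are tie-free.
#'
#' @param foldChanges `data.frame` with columns `gene`, `log2fc` and
#'   optionally `cpm`.
#' @param targets character vector of target gene ids.
#' @param background character vector of background gene ids; default all
#'   non-target genes in the table.
#' @param cpmFloor minimum CPM (default 5) applied when `cpm` is present.
#' @param exactMax use exact enumeration when both group sizes are at most
#'   this (default 10).
#' @return List with `p.value`, `statistic` (rank-sum W of the target
#'   group), `method`, `nTarget`, `nBackground`, `droppedTargets`, and
#'   `curves`, a `data.frame` of the two empirical CDFs (`set`, `log2fc`,
#'   `cdf`).
#' @export
targetRepressionCdf <- function(foldChanges, targets, background = NULL,
                                cpmFloor = 5, exactMax = 10L) {
    stopifnot(all(c("gene", "log2fc") %in% names(foldChanges)))
    fc <- foldChanges
    if ("cpm" %in% names(fc)) fc <- fc[fc$cpm > cpmFloor, , drop = FALSE]
    fc <- fc[!duplicated(fc$gene), , drop = FALSE]
    droppedTargets <- setdiff(targets, fc$gene)
    targets <- intersect(targets, fc$gene)
    if (is.null(background)) background <- setdiff(fc$gene, targets)
    background <- intersect(background, fc$gene)
    x <- fc$log2fc[match(targets, fc$gene)]       # target fold-changes
    y <- fc$log2fc[match(background, fc$gene)]    # background fold-changes
    if (length(x) < 3L || length(y) < 3L)
        stop("need at least 3 genes in each set (have ",
             length(x), " and ", length(y), ")")
    exact <- length(x) <= exactMax && length(y) <= exactMax &&
        !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "less",
                           exact = exact, correct = TRUE))
    curves <- rbind(
        data.frame(set = "background", log2fc = sort(y),
                   cdf = seq_along(y) / length(y)),
        data.frame(set = "targets", log2fc = sort(x),
                   cdf = seq_along(x) / length(x)))
    list(p.value = wt$p.value, statistic = unname(wt$statistic),
         method = if (exact) "exact" else "normal-approximation",
         nTarget = length(x), nBackground = length(y),
         droppedTargets = droppedTargets, curves = curves)
}

#' Plot target-repression CDF curves
#'
#' @param cdf result of [targetRepressionCdf()].
#' @param main plot title.
#' @return `NULL`, invisibly; draws on the current device.
#' @export
plotRepressionCdf <- function(cdf, main = "Target repression") {
    cv <- cdf$curves
    plot(NA, xlim = range(cv$log2fc), ylim = c(0, 1),
         xlab = expression(log[2] ~ "fold change"),
         ylab = "Cumulative fraction", main = main)
    cols <- c(background = "grey40", targets = "dodgerblue3")
    for (s in names(cols)) {
        sub <- cv[cv$set == s, ]
        graphics::lines(stats::stepfun(sub$log2fc, c(0, sub$cdf)),
                        col = cols[[s]], do.points = FALSE, lwd = 2)
    }
    graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                     legend = sprintf("%s (n=%d)", names(cols),
                                      c(cdf$nBackground, cdf$nTarget)))
    graphics::mtext(sprintf("one-sided rank-sum P = %.3g", cdf$p.value),
                    side = 3, line = 0.2, cex = 0.8)
    invisible(NULL)
}
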