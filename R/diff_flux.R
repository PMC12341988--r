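#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over all points of the absolute difference between the
#' two empirical cumulative distribution functions. Used descriptively
#' (no p-value) to compare sampled flux distributions between
#' conditions.
#'
#' @param x,y nonempty numeric sample vectors.
#' @return the KS distance, in `[0, 1]`; symmetric in its arguments.
#' @export
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("ks_statistic: empty input")
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(Fx - Fy))
}

#' Log2 fold change of (absolute) medians
#'
#' \eqn{\log_2((|m_{alt}| + \epsilon) / (|m_{ref}| + \epsilon))}.
#' Absolute values keep the ratio defined when a flux reverses
#' direction between conditions; direction changes are reported
#' separately as sign flips by [differential_flux_table()].
#'
#' @param median_ref,median_alt medians of the two conditions.
#' @param epsilon pseudo-flux on the flux scale (default 1e-6
#'   mmol/gDW/h).
#' @return the fold change (dimensionless).
#' @export
log2_fold_change <- function(median_ref, median_alt, epsilon = 1e-6) {
  log2((abs(median_alt) + epsilon) / (abs(median_ref) + epsilon))
}

#' Differential flux table between two sampled conditions
#'
#' One record per shared reaction: medians under both conditions, the
#' KS distance between the sampled distributions, the log2 fold change
#' of absolute medians, a sign-flip flag, and a significance call using
#' fixed descriptive cutoffs (|log2FC| >= `lfc_cutoff` and
#' KS >= `ks_cutoff`). Reactions with both |medians| below `epsilon`
#' are marked quiescent and never called significant. No
#' multiple-testing correction is applied: the cutoffs are descriptive
#' screens, not hypothesis tests.
#'
#' @param ref,alt `flux_sample_set` objects; `ref` is the reference
#'   condition.
#' @param ks_cutoff KS significance cutoff (default 0.2).
#' @param lfc_cutoff fold-change cutoff (default 0.5).
#' @param epsilon pseudo-flux for the fold change (default 1e-6).
#' @return data frame of class `diff_flux_table` with columns
#'   `reaction`, `median_ref`, `median_alt`, `log2fc`, `ks`,
#'   `sign_flip`, `quiescent`, `significant`.
#' @export
differential_flux_table <- function(ref, alt, ks_cutoff = 0.2,
                                    lfc_cutoff = 0.5, epsilon = 1e-6) {
  shared <- intersect(ref$reactions, alt$reactions)
  if (!length(shared)) stop("no shared reactions between sample sets")
  if (length(shared) < length(union(ref$reactions, alt$reactions))) {
    warning("reaction sets differ; using the ", length(shared),
            "-reaction intersection")
  }
  rows <- lapply(shared, function(rid) {
    xs <- ref$samples[, rid]; ys <- alt$samples[, rid]
    m1 <- stats::median(xs); m2 <- stats::median(ys)
    lfc <- log2_fold_change(m1, m2, epsilon)
    ks <- ks_statistic(xs, ys)
    quiescent <- abs(m1) < epsilon && abs(m2) < epsilon
    data.frame(reaction = rid, median_ref = m1, median_alt = m2,
               log2fc = lfc, ks = ks,
               sign_flip = sign(m1) * sign(m2) < 0,
               quiescent = quiescent,
               significant = !quiescent && abs(lfc) >= lfc_cutoff &&
                 ks >= ks_cutoff)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diff_flux_table", class(out))
  out
}

#' Aggregate significant flux changes by pathway
#'
#' Sums the median flux change (alt - ref) of significant reactions per
#' subsystem, sorted by absolute total change. Reactions without a
#' subsystem label are grouped under `"unassigned"`.
#'
#' @param records a `diff_flux_table`.
#' @param model the `metabolic_model` providing subsystem labels.
#' @return data frame with columns `subsystem`, `total_flux_change`,
#'   `n_significant`.
#' @export
aggregate_by_pathway <- function(records, model) {
  sig <- records[records$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(subsystem = character(0),
                      total_flux_change = numeric(0),
                      n_significant = integer(0)))
  }
  subsys <- vapply(sig$reaction, function(rid) {
    s <- model$reactions[[rid]]$subsystem
    if (is.null(s) || !nzchar(s)) "unassigned" else s
  }, character(1))
  delta <- sig$median_alt - sig$median_ref
  agg <- stats::aggregate(list(total_flux_change = delta),
                          by = list(subsystem = subsys), FUN = sum)
  agg$n_significant <- as.integer(table(subsys)[agg$subsystem])
  agg[order(-abs(agg$total_flux_change)), , drop = FALSE]
}
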