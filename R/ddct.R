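# Relative gene expression by the delta-delta-Ct method with reference-gene
# normalisation and a calibrator group whose expression is taken as 1.

#' Per-sample delta-Ct against the reference gene
#'
#' Technical replicates (identical sample/gene) are averaged at the Ct level
#' first; then `dCt = Ct_target - Ct_reference` for every target gene in
#' every sample. Ct values outside the usual 10-40 cycle range are accepted
#' with a warning.
#'
#' @param ct long table with columns `sample`, `group`, `gene`, `Ct`.
#' @param reference_gene housekeeping gene name (must be present in every
#'   sample).
#' @return `data.frame(sample, group, gene, delta_ct)` for target genes only.
#' @export
delta_ct <- function(ct, reference_gene = "Oaz1") {
  stopifnot(is.data.frame(ct),
            all(c("sample", "group", "gene", "Ct") %in% names(ct)))
  if (any(!is.finite(ct$Ct))) stop("Ct values must be finite")
  if (any(ct$Ct < 10 | ct$Ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  # technical replicates -> one Ct per sample/gene
  agg <- aggregate(Ct ~ sample + group + gene, data = ct, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  miss <- setdiff(unique(agg$sample), ref$sample)
  if (length(miss))
    stop("reference gene '", reference_gene, "' missing in sample(s): ",
         paste(miss, collapse = ", "))
  tgt <- agg[agg$gene != reference_gene, ]
  if (!nrow(tgt)) stop("no target genes present")
  tgt$delta_ct <- tgt$Ct - ref$Ct[match(tgt$sample, ref$sample)]
  out <- tgt[order(tgt$group, tgt$gene, tgt$sample),
             c("sample", "group", "gene", "delta_ct")]
  rownames(out) <- NULL
  out
}

#' Fold changes by the delta-delta-Ct method
#'
#' `ddCt = dCt_sample - mean(dCt of the calibrator group)` per gene, and
#' `fold = 2^(-ddCt)` per sample (amplification efficiency fixed at 2).
#' Group folds are the arithmetic mean of the per-sample folds with their
#' SEM, matching the usual bar-plot convention; `aggregate_fn = "geometric"`
#' averages on the log2 scale instead.
#'
#' @param dct output of [delta_ct()].
#' @param calibrator calibrator group label (expression taken as 1).
#' @param aggregate_fn `"arithmetic"` or `"geometric"` group averaging.
#' @return `data.frame(group, gene, fold, sem, n)`.
#' @export
fold_change <- function(dct, calibrator,
                        aggregate_fn = c("arithmetic", "geometric")) {
  aggregate_fn <- match.arg(aggregate_fn)
  stopifnot(is.data.frame(dct),
            all(c("sample", "group", "gene", "delta_ct") %in% names(dct)))
  if (!calibrator %in% dct$group)
    stop("calibrator group '", calibrator, "' not present")
  out <- do.call(rbind, lapply(split(dct, dct$gene), function(g) {
    cal <- g$delta_ct[g$group == calibrator]
    if (!length(cal)) stop("empty calibrator for gene ", g$gene[1])
    g$fold <- 2^(-(g$delta_ct - mean(cal)))
    do.call(rbind, lapply(split(g, g$group), function(gg) {
      f <- gg$fold
      est <- if (aggregate_fn == "arithmetic") mean(f)
             else 2^mean(log2(f))
      data.frame(group = gg$group[1], gene = gg$gene[1], fold = est,
                 sem = if (length(f) > 1) sd(f) / sqrt(length(f)) else NA_real_,
                 n = length(f))
    }))
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$group), ]
}
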