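#' Assemble a count matrix object
#'
#' Panel-style expression counts with per-gene control classes and
#' per-sample condition labels.
#'
#' @param counts numeric matrix, genes x samples, non-negative.
#' @param gene_class character vector per gene: `endogenous`,
#'   `housekeeping`, `positive_control` or `negative_control`.
#' @param condition character vector per sample (e.g. U, T, TT, T_T, TTT,
#'   TIT, I).
#' @param replicate integer vector per sample.
#' @return `nfkb_counts` object.
#' @export
count_matrix <- function(counts, gene_class, condition,
                         replicate = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  classes <- c("endogenous", "housekeeping", "positive_control",
               "negative_control")
  if (!all(gene_class %in% classes))
    stop("gene_class must be one of: ", paste(classes, collapse = ", "))
  if (length(gene_class) != nrow(counts) ||
      length(condition) != ncol(counts))
    stop("annotation lengths do not match the matrix")
  for (cl in c("housekeeping", "positive_control", "negative_control"))
    if (!any(gene_class == cl)) stop("no genes of class ", cl)
  if (is.null(replicate)) replicate <- stats::ave(
    seq_along(condition), condition, FUN = seq_along)
  structure(list(counts = counts, gene_class = gene_class,
                 condition = condition, replicate = replicate),
            class = "nfkb_counts")
}

.geomean <- function(x) exp(mean(log(x + 0.5)))  # 0.5 offset tolerates zeros

#' Normalize panel counts
#'
#' Three-step normalization: (1) per-sample scaling by the ratio of the
#' grand geometric mean of the positive controls to the sample's; (2)
#' background correction, subtracting mean + 2 sd of the negative controls
#' and flooring at 0; (3) per-sample scaling by the housekeeping
#' geometric-mean ratio. Geometric means are computed on counts + 0.5.
#'
#' @param x an `nfkb_counts`.
#' @return List: `linear` (normalized matrix), `log2` (log2(x+1)),
#'   `scale_pos`, `scale_hk` (per-sample factors), `background` (per
#'   sample), plus the input annotations.
#' @export
normalize_counts <- function(x) {
  m <- x$counts
  pos <- x$gene_class == "positive_control"
  neg <- x$gene_class == "negative_control"
  hk <- x$gene_class == "housekeeping"
  gm_pos <- apply(m[pos, , drop = FALSE], 2, .geomean)
  if (any(gm_pos <= 0)) stop("zero geometric mean in positive controls")
  scale_pos <- .geomean_grand(gm_pos) / gm_pos
  m1 <- sweep(m, 2, scale_pos, `*`)
  bg <- apply(m1[neg, , drop = FALSE], 2,
              function(v) mean(v) + 2 * stats::sd(v))
  bg[is.na(bg)] <- 0
  m2 <- pmax(sweep(m1, 2, bg, `-`), 0)
  gm_hk <- apply(m2[hk, , drop = FALSE], 2, .geomean)
  if (any(gm_hk <= 0)) stop("zero geometric mean in housekeeping controls")
  scale_hk <- .geomean_grand(gm_hk) / gm_hk
  m3 <- sweep(m2, 2, scale_hk, `*`)
  list(linear = m3, log2 = log2(m3 + 1),
       scale_pos = scale_pos, scale_hk = scale_hk, background = bg,
       gene_class = x$gene_class, condition = x$condition,
       replicate = x$replicate)
}

.geomean_grand <- function(v) exp(mean(log(v)))

#' Median log2 fold changes per condition
#'
#' Per gene and condition, the median over replicate pairs of the log2
#' ratio of normalized counts versus the reference (untreated) condition.
#' Genes are ordered by hierarchical clustering of their fold-change
#' profiles for display.
#'
#' @param norm result of [normalize_counts()].
#' @param reference reference condition label, default `"U"`.
#' @param pseudo pseudocount added before the ratio, default 0.5.
#' @return Matrix genes x conditions (reference column dropped) of median
#'   log2 fold changes; attribute `order` is the clustering display order.
#'   A gene whose reference counts are all zero gets `NA`.
#' @export
fold_change_table <- function(norm, reference = "U", pseudo = 0.5) {
  if (!reference %in% norm$condition)
    stop("reference condition ", reference, " not present")
  conds <- setdiff(unique(norm$condition), reference)
  ref <- norm$linear[, norm$condition == reference, drop = FALSE]
  fc <- sapply(conds, function(cc) {
    trt <- norm$linear[, norm$condition == cc, drop = FALSE]
    nrep <- min(ncol(trt), ncol(ref))
    lr <- log2((trt[, seq_len(nrep), drop = FALSE] + pseudo) /
               (ref[, seq_len(nrep), drop = FALSE] + pseudo))
    apply(lr, 1, stats::median)
  })
  fc <- as.matrix(fc)
  rownames(fc) <- rownames(norm$linear)
  colnames(fc) <- conds
  allzero <- rowSums(ref) == 0
  fc[allzero, ] <- NA_real_
  sds <- apply(fc, 1, stats::sd)
  ok <- stats::complete.cases(fc) & !is.na(sds) & sds > 0
  ord <- seq_len(nrow(fc))
  if (sum(ok) > 2) {
    hc <- stats::hclust(stats::dist(fc[ok, , drop = FALSE]))
    ord <- c(which(ok)[hc$order], which(!ok))
  }
  attr(fc, "order") <- ord
  fc
}

#' Correlate gene fold changes with integrated NF-kB activity
#'
#' Pearson correlation, across conditions, between each gene's linear fold
#' change and the integrated nuclear NF-kB activity of the matched
#' condition.
#'
#' @param fc fold-change matrix from [fold_change_table()] (log2 scale;
#'   converted to linear internally).
#' @param activity named numeric: condition -> integrated nuclear NF-kB
#'   (AUC units); must cover at least 3 of the fold-change conditions.
#' @return Named numeric of per-gene correlations; zero-variance or
#'   missing genes are omitted and listed in attribute `flagged`.
#' @export
correlate_activity <- function(fc, activity) {
  conds <- intersect(colnames(fc), names(activity))
  if (length(conds) < 3) stop("need >= 3 matched conditions")
  a <- activity[conds]
  lin <- 2^fc[, conds, drop = FALSE]
  usable <- stats::complete.cases(lin) & apply(lin, 1, stats::sd) > 0
  r <- apply(lin[usable, , drop = FALSE], 1,
             function(v) stats::cor(v, a))
  attr(r, "flagged") <- rownames(fc)[!usable]
  r
}
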