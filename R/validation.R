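#' Match two label images and score their agreement
#'
#' Greedy one-to-one matching of reference (ground-truth) objects to
#' segmented objects by intersection size, with the Jaccard index
#' (intersection over union) per matched pair. Used to validate the
#' watershed segmentation against generator ground truth.
#'
#' @param reference,segmented Integer label matrices of one shape
#'   (0 = background).
#' @return List: `pairs` (data.frame `ref`, `seg`, `jaccard`), and
#'   `match_fraction(j)` — the fraction of reference objects matched
#'   one-to-one with Jaccard >= `j`.
#' @export
segmentation_overlap <- function(reference, segmented) {
  stopifnot(all(dim(reference) == dim(segmented)))
  g <- as.vector(reference); s <- as.vector(segmented)
  keep <- g > 0 & s > 0
  cnt <- table(g[keep], s[keep])
  area_g <- tabulate(g, nbins = max(g))
  area_s <- tabulate(s, nbins = max(s))
  idx <- which(cnt > 0, arr.ind = TRUE)
  inter <- as.integer(cnt[idx])
  ref_id <- as.integer(rownames(cnt))[idx[, 1]]
  seg_id <- as.integer(colnames(cnt))[idx[, 2]]
  ord <- order(inter, decreasing = TRUE)
  used_ref <- logical(max(g)); used_seg <- logical(max(s))
  pr <- integer(0); ps <- integer(0); pj <- numeric(0)
  for (q in ord) {
    r <- ref_id[q]; sg <- seg_id[q]
    if (used_ref[r] || used_seg[sg]) next
    used_ref[r] <- TRUE; used_seg[sg] <- TRUE
    pr <- c(pr, r); ps <- c(ps, sg)
    pj <- c(pj, inter[q] / (area_g[r] + area_s[sg] - inter[q]))
  }
  pairs <- data.frame(ref = pr, seg = ps, jaccard = pj)
  n_ref <- sum(area_g > 0)
  list(pairs = pairs,
       match_fraction = function(j = 0.8) sum(pairs$jaccard >= j) / n_ref)
}

#' Jaccard index of two binary masks
#'
#' @param a,b Logical matrices of one shape.
#' @return Intersection over union in \[0, 1\].
#' @export
mask_jaccard <- function(a, b) {
  if (inherits(a, "clone_mask")) a <- a$mask
  if (inherits(b, "clone_mask")) b <- b$mask
  sum(a & b) / sum(a | b)
}
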