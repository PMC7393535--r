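#' Rank-based AUC of a score separating two labelled groups
#'
#' The probability that a randomly chosen positive score exceeds a
#' randomly chosen negative score, with ties counted one half: the
#' normalised Mann-Whitney U statistic, computed from mid-ranks.
#'
#' @param pos Scores of the positive class (e.g. p-hat in MSI samples).
#' @param neg Scores of the negative class.
#' @return AUC in \[0, 1\].
#' @examples
#' rank_auc(c(0.3, 0.1), c(0.2, 0.1))  # 0.625
#' @export
rank_auc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("AUC undefined: one class is empty")
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Per-site discriminative AUC of the deletion slippage rate
#'
#' @param p_msi p-hat values of the site across MSI samples.
#' @param p_mss p-hat values across MSS samples.
#' @return AUC for p separating MSI from MSS at this site.
#' @export
site_auc <- function(p_msi, p_mss) rank_auc(p_msi, p_mss)

#' Discriminative power of every site across a labelled cohort
#'
#' For each site, collects p-hat from samples whose coverage passes the
#' rule m > `min_coverage` and computes the MSI-vs-MSS AUC. Sites where
#' either class has no covered sample are skipped (their AUC is
#' undefined, not 0.5).
#'
#' @param estimates Named list of per-sample estimate tables sharing
#'   one site list.
#' @param labels Data frame with `sample_id` and `label` in
#'   \{"MSI","MSS"\}; an optional `split` column restricts scoring to
#'   `split == "discovery"` rows so held-out samples never leak into
#'   site selection.
#' @param min_coverage Coverage rule (default 20).
#' @return Data frame: site identity columns, `auc`, `n_msi`, `n_mss`,
#'   sorted by descending AUC.
#' @export
site_auc_table <- function(estimates, labels, min_coverage = 20L) {
  if (!is.null(labels$split)) labels <- labels[labels$split == "discovery", ]
  labels <- labels[!is.na(labels$label) &
                     labels$sample_id %in% names(estimates), ]
  if (!all(labels$label %in% c("MSI", "MSS")))
    stop("labels must be 'MSI' or 'MSS'")
  msi_ids <- labels$sample_id[labels$label == "MSI"]
  mss_ids <- labels$sample_id[labels$label == "MSS"]
  if (!length(msi_ids) || !length(mss_ids))
    stop("need at least one labelled sample in each class")
  ref <- estimates[[1]]
  p_of <- function(ids) vapply(estimates[ids], function(e) e$p,
                               numeric(nrow(ref)))
  m_of <- function(ids) vapply(estimates[ids], function(e) e$m,
                               numeric(nrow(ref)))
  p1 <- matrix(p_of(msi_ids), nrow = nrow(ref))
  m1 <- matrix(m_of(msi_ids), nrow = nrow(ref))
  p0 <- matrix(p_of(mss_ids), nrow = nrow(ref))
  m0 <- matrix(m_of(mss_ids), nrow = nrow(ref))
  auc <- n_msi <- n_mss <- rep(NA_real_, nrow(ref))
  for (i in seq_len(nrow(ref))) {
    x1 <- p1[i, m1[i, ] > min_coverage & !is.na(p1[i, ])]
    x0 <- p0[i, m0[i, ] > min_coverage & !is.na(p0[i, ])]
    if (!length(x1) || !length(x0)) next
    auc[i] <- rank_auc(x1, x0)
    n_msi[i] <- length(x1); n_mss[i] <- length(x0)
  }
  keep <- !is.na(auc)
  out <- ref[keep, intersect(c("site_id", "chrom", "start", "motif", "n"),
                             names(ref)), drop = FALSE]
  out$auc <- auc[keep]
  out$n_msi <- as.integer(n_msi[keep])
  out$n_mss <- as.integer(n_mss[keep])
  out <- out[order(-out$auc, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select discriminative microsatellite sites (DMS)
#'
#' Retains sites whose AUC strictly exceeds the threshold, sorted by
#' descending AUC so the head of the table is the top-k panel.
#'
#' @param aucs Table from [site_auc_table()].
#' @param auc_threshold Strict lower bound on AUC (default 0.65; 0.75
#'   selects only strongly discriminative sites).
#' @param top_k Optionally keep at most the k best sites after
#'   thresholding.
#' @return Subset of `aucs`, descending by AUC.
#' @export
select_dms <- function(aucs, auc_threshold = 0.65, top_k = NULL) {
  out <- aucs[aucs$auc > auc_threshold, , drop = FALSE]
  out <- out[order(-out$auc), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Cohort-level MSI classification performance
#'
#' Ranks samples by MSI score and computes the MSI-vs-MSS AUC (the same
#' rank estimator as [site_auc()]), together with the ROC points swept
#' over all score thresholds.
#'
#' @param calls List of `msi_call` objects, or a data frame with
#'   `sample_id` and `msi_score`.
#' @param labels Data frame with `sample_id`, `label` in \{"MSI","MSS"\}.
#' @return List with `auc`, `n_msi`, `n_mss` and a `roc` data frame
#'   (threshold, tpr, fpr).
#' @export
evaluate_cohort <- function(calls, labels) {
  if (!is.data.frame(calls)) {
    calls <- data.frame(
      sample_id = vapply(calls, `[[`, character(1), "sample_id"),
      msi_score = vapply(calls, `[[`, numeric(1), "msi_score"),
      stringsAsFactors = FALSE)
  }
  df <- merge(calls, labels[, c("sample_id", "label")], by = "sample_id")
  df <- df[!is.na(df$label), , drop = FALSE]
  und <- is.na(df$msi_score)
  if (any(und)) {
    warning(sum(und), " labelled sample(s) with undefined MSI score excluded")
    df <- df[!und, , drop = FALSE]
  }
  pos <- df$msi_score[df$label == "MSI"]
  neg <- df$msi_score[df$label == "MSS"]
  if (!length(pos) || !length(neg))
    stop("cohort evaluation needs scored samples in both classes")
  thr <- c(Inf, sort(unique(df$msi_score), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)))
  list(auc = rank_auc(pos, neg), n_msi = length(pos), n_mss = length(neg),
       roc = roc)
}
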