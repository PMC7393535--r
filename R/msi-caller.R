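#' Classify one site as stable or unstable against its baseline entry
#'
#' A site is unstable when the tumor deletion-slippage rate strictly
#' exceeds the baseline threshold mu + 3 sigma.
#'
#' @param p Tumor slippage-rate estimate at the site.
#' @param threshold Baseline threshold (mu + n_sigma * sigma).
#' @return `"unstable"` or `"stable"` (vectorised).
#' @export
classify_site <- function(p, threshold) {
  ifelse(p > threshold, "unstable", "stable")
}

#' Call microsatellite instability for a single tumor sample
#'
#' Scores the tumor against a panel-of-normals baseline: every baseline
#' site with tumor coverage m > `min_coverage` is "covered"; a covered
#' site with p > threshold is "unstable"; the MSI score is the
#' percentage of unstable sites among covered sites. Sites in the tumor
#' but absent from the baseline are excluded from both numerator and
#' denominator.
#'
#' @param tumor Tumor estimate table from [estimate_all()] /
#'   [read_estimates()].
#' @param baseline Baseline table from [build_baseline()] /
#'   [read_baseline()].
#' @param min_coverage Tumor-side detection rule (strict m >
#'   min_coverage, mirroring the baseline inclusion rule). Default 20.
#' @param score_cutoff MSI-score percentage above which the binary
#'   label is "MSI" (default 10; a reporting convention, the score
#'   itself is the primary output).
#' @param sample_id Identifier echoed into the call.
#' @param check_hash Require the tumor and baseline site-list hashes to
#'   match (default TRUE; prevents cross-panel misuse).
#' @return Object of class `msi_call`: a list with `sample_id`,
#'   `sites_covered`, `sites_unstable`, `msi_score` (percent; `NA` with
#'   `score_defined = FALSE` when no site is covered), `label`,
#'   `score_cutoff` and the `per_site` verdict table.
#' @export
call_msi <- function(tumor, baseline, min_coverage = 20L, score_cutoff = 10,
                     sample_id = "sample", check_hash = TRUE) {
  th <- attr(tumor, "site_hash"); bh <- attr(baseline, "site_hash")
  if (check_hash && !is.null(th) && !is.null(bh) &&
      !is.na(th) && !is.na(bh) && !identical(th, bh))
    stop("site-list hash mismatch between tumor estimates and baseline; ",
         "the baseline was built from a different site list")
  hit <- match(baseline$site_id, tumor$site_id)
  if (anyNA(hit))
    message(sum(is.na(hit)), " baseline site(s) missing from the tumor table; excluded")
  bl <- baseline[!is.na(hit), , drop = FALSE]
  tu <- tumor[hit[!is.na(hit)], , drop = FALSE]
  covered <- tu$m > min_coverage & !is.na(tu$p)
  verdict <- rep("uncovered", nrow(bl))
  verdict[covered] <- classify_site(tu$p[covered], bl$threshold[covered])
  per_site <- data.frame(site_id = bl$site_id, p = tu$p,
                         threshold = bl$threshold, m = tu$m,
                         verdict = verdict, stringsAsFactors = FALSE)
  n_cov <- sum(covered)
  n_unst <- sum(verdict == "unstable")
  score <- if (n_cov > 0L) 100 * n_unst / n_cov else NA_real_
  structure(list(
    sample_id = sample_id,
    sites_covered = n_cov,
    sites_unstable = n_unst,
    msi_score = score,
    score_defined = n_cov > 0L,
    label = if (n_cov == 0L) NA_character_
            else if (score > score_cutoff) "MSI" else "MSS",
    score_cutoff = score_cutoff,
    min_coverage = min_coverage,
    per_site = per_site), class = "msi_call")
}

#' @export
print.msi_call <- function(x, ...) {
  cat("MSI call for sample", x$sample_id, "\n")
  cat("  covered sites  :", x$sites_covered, "\n")
  cat("  unstable sites :", x$sites_unstable, "\n")
  if (x$score_defined) {
    cat(sprintf("  MSI score      : %.2f%%\n", x$msi_score))
    cat(sprintf("  label          : %s (cutoff %.1f%%)\n",
                x$label, x$score_cutoff))
  } else {
    cat("  MSI score      : undefined (no covered sites)\n")
  }
  invisible(x)
}

#' Write MSI call outputs (summary + per-site verdicts)
#'
#' @param call `msi_call` object.
#' @param prefix Output path prefix; writes `<prefix>_summary.tsv` and
#'   `<prefix>_sites.tsv`.
#' @export
write_msi_call <- function(call, prefix) {
  sum_path <- paste0(prefix, "_summary.tsv")
  con <- file(sum_path, "w")
  writeLines("#slipmsi msi call v1", con)
  writeLines(sprintf("#params=min_coverage:%s score_cutoff:%s",
                     call$min_coverage, call$score_cutoff), con)
  writeLines("#sample_id\tsites_covered\tsites_unstable\tmsi_score\tlabel\tcutoff", con)
  writeLines(paste(call$sample_id, call$sites_covered, call$sites_unstable,
                   ifelse(call$score_defined,
                          format(call$msi_score, digits = 6), "."),
                   ifelse(is.na(call$label), ".", call$label),
                   call$score_cutoff, sep = "\t"), con)
  close(con)
  site_path <- paste0(prefix, "_sites.tsv")
  con <- file(site_path, "w")
  writeLines("#site_id\tp\tthreshold\tm\tverdict", con)
  ps <- call$per_site
  ps$p <- ifelse(is.na(ps$p), ".", format(ps$p, digits = 6))
  utils::write.table(ps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(sum_path, site_path))
}
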