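#' Build a panel-of-normals baseline of per-site slippage rates
#'
#' For each microsatellite, computes the mean and standard deviation of
#' the deletion slippage rate p across normal samples, and the
#' instability threshold mu + n_sigma * sigma. A site enters the
#' baseline only when its coverage exceeds `min_coverage` in strictly
#' more than `support_fraction` of the panel; mu and sigma are computed
#' over exactly the coverage-passing samples at that site.
#'
#' @param estimates List of per-normal-sample estimate tables (from
#'   [estimate_all()] or [read_estimates()]); all must share one site
#'   list.
#' @param min_coverage Reads required for a sample to support a site
#'   (strict: m > min_coverage). Default 20.
#' @param support_fraction Fraction of samples that must pass the
#'   coverage rule (strict majority by default: > 0.5).
#' @param n_sigma Threshold multiplier (default 3).
#' @param sd_type `"population"` (divide by k; the panel is treated as
#'   the reference population) or `"sample"` (k - 1).
#' @return Baseline table: site identity columns plus `mu`, `sigma`,
#'   `threshold`, `k`; carries the site-list hash as an attribute.
#' @export
build_baseline <- function(estimates, min_coverage = 20L,
                           support_fraction = 0.5, n_sigma = 3,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(estimates) < 2L)
    stop("a baseline needs at least 2 normal samples")
  ids <- estimates[[1]]$site_id
  for (e in estimates[-1]) {
    if (!identical(e$site_id, ids))
      stop("all normal-sample estimate tables must share one site list")
  }
  n_samp <- length(estimates)
  p_mat <- matrix(vapply(estimates, function(e) e$p, numeric(length(ids))),
                  nrow = length(ids))
  m_mat <- matrix(vapply(estimates, function(e) e$m, numeric(length(ids))),
                  nrow = length(ids))
  pass <- m_mat > min_coverage & !is.na(p_mat)
  k <- rowSums(pass)
  retained <- rowSums(m_mat > min_coverage) > support_fraction * n_samp
  dropped_low_k <- retained & k < 2L
  if (any(dropped_low_k))
    warning(sum(dropped_low_k),
            " site(s) dropped: fewer than 2 coverage-passing samples")
  retained <- retained & k >= 2L
  pm <- p_mat
  pm[!pass] <- NA_real_
  mu <- rowMeans(pm, na.rm = TRUE)
  ss <- rowSums((pm - mu)^2, na.rm = TRUE)
  sigma <- sqrt(ss / if (sd_type == "population") k else pmax(k - 1L, 1L))
  out <- estimates[[1]][retained, intersect(
    c("site_id", "chrom", "start", "motif", "n"),
    names(estimates[[1]])), drop = FALSE]
  out$mu <- mu[retained]
  out$sigma <- sigma[retained]
  out$threshold <- out$mu + n_sigma * out$sigma
  out$k <- as.integer(k[retained])
  attr(out, "site_hash") <- attr(estimates[[1]], "site_hash")
  attr(out, "params") <- list(min_coverage = min_coverage,
                              support_fraction = support_fraction,
                              n_sigma = n_sigma, sd_type = sd_type)
  rownames(out) <- NULL
  out
}

#' Write a baseline table to TSV
#'
#' The '#' header embeds the site-list hash and the build parameters so
#' a baseline cannot silently be applied across panels.
#'
#' @param baseline Baseline table from [build_baseline()].
#' @param path Output path.
#' @export
write_baseline <- function(baseline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pp <- attr(baseline, "params")
  writeLines("#slipmsi baseline v1", con)
  writeLines(paste0("#site_hash=", attr(baseline, "site_hash")), con)
  writeLines(sprintf("#params=min_coverage:%s support_fraction:%s n_sigma:%s sd_type:%s",
                     pp$min_coverage, pp$support_fraction, pp$n_sigma,
                     pp$sd_type), con)
  writeLines("#chrom\tstart\tmotif\tn\tmu\tsigma\tthreshold\tk", con)
  df <- data.frame(chrom = baseline$chrom, start = baseline$start + 1L,
                   motif = baseline$motif, n = baseline$n,
                   mu = baseline$mu, sigma = baseline$sigma,
                   threshold = baseline$threshold, k = baseline$k)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a baseline table written by [write_baseline()]
#'
#' @param path Baseline TSV path.
#' @return Baseline table with the site-list hash attribute restored.
#' @export
read_baseline <- function(path) {
  hash <- read_header_field(path, "site_hash")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "motif", "n", "mu",
                                        "sigma", "threshold", "k"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "numeric", "numeric",
                                         "numeric", "integer"))
  df$start <- df$start - 1L
  df$site_id <- paste(df$chrom, df$start, df$motif, sep = ":")
  attr(df, "site_hash") <- hash
  df
}

#' Write a per-sample estimate table to TSV
#'
#' @param est Estimate table from [estimate_all()].
#' @param path Output path.
#' @export
write_estimates <- function(est, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#slipmsi estimates v1", con)
  writeLines(paste0("#site_hash=", attr(est, "site_hash")), con)
  writeLines("#chrom\tstart\tmotif\tn\tp\tq\tm", con)
  num <- function(x) ifelse(is.na(x), ".", format(x, digits = 12))
  df <- data.frame(chrom = est$chrom, start = est$start + 1L,
                   motif = est$motif, n = est$n,
                   p = num(est$p), q = num(est$q), m = est$m)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an estimate table written by [write_estimates()]
#'
#' @param path Estimates TSV path.
#' @return Estimate table ('.' fields become `NA`).
#' @export
read_estimates <- function(path) {
  hash <- read_header_field(path, "site_hash")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = ".",
                          col.names = c("chrom", "start", "motif", "n",
                                        "p", "q", "m"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "numeric", "numeric",
                                         "integer"))
  df$start <- df$start - 1L
  df$site_id <- paste(df$chrom, df$start, df$motif, sep = ":")
  attr(df, "site_hash") <- hash
  df
}
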