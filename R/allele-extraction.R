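#' Extract observed repeat lengths at microsatellite sites from a BAM
#'
#' For each site, collects the repeat length (in whole motif copies)
#' observed in every read that spans the full tract plus at least
#' `anchor` bases of flank on both sides. Secondary, supplementary,
#' duplicate and QC-fail alignments are dropped, as are reads below the
#' mapping-quality floor. By default the tract is re-located inside the
#' read by exact match of the `anchor`-bp flanks (robust to alignment
#' ambiguity within the repeat); reads in which either flank anchor is
#' not found exactly are discarded. With `method = "cigar"` the repeat
#' length is instead derived by walking the CIGAR over the tract
#' interval.
#'
#' @param bam Path to a coordinate-sorted BAM with index, or a SAM file
#'   (converted on the fly).
#' @param sites Site table from [scan_reference()]/[read_sites()].
#' @param min_mapq Minimum mapping quality (default 20).
#' @param anchor Flank bases required to match on each side (default 5).
#' @param method `"flank"` (re-anchoring, default) or `"cigar"`.
#' @return Distribution table: one row per site in site-list order with
#'   the site identity columns, a `lengths` list-column of per-read
#'   repeat lengths, a `dist` string of "y:count" pairs (ascending y)
#'   and the supporting read count `m`. Sites with no spanning reads are
#'   kept with m = 0.
#' @export
extract_all <- function(bam, sites, min_mapq = 20L, anchor = 5L,
                        method = c("flank", "cigar")) {
  method <- match.arg(method)
  bam <- as_indexed_bam(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  present <- sites$chrom %in% names(hdr)
  if (any(!present))
    warning(sum(!present), " site(s) on chromosomes absent from the BAM header; skipped")
  lengths <- rep(list(integer(0)), nrow(sites))
  idx <- which(present)
  if (length(idx)) {
    # fetch reads overlapping the anchored window around each site
    mlen <- nchar(sites$motif)
    end0 <- sites$start + sites$n * mlen          # 0-based exclusive
    which_gr <- GenomicRanges::GRanges(
      sites$chrom[idx],
      IRanges::IRanges(pmax(sites$start[idx] + 1L - anchor, 1L),
                       end0[idx] + anchor))
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isDuplicate = FALSE,
                                    isNotPassingQualityControls = FALSE),
      what = c("pos", "cigar", "seq", "mapq"),
      which = which_gr)
    reads <- Rsamtools::scanBam(bam, param = param)
    for (j in seq_along(idx)) {
      i <- idx[j]
      lengths[[i]] <- site_read_lengths(reads[[j]], sites[i, ], end0[i],
                                        min_mapq, anchor, method)
    }
  }
  out <- sites
  out$lengths <- lengths
  out$m <- vapply(lengths, length, integer(1))
  out$dist <- vapply(lengths, format_dist_string, character(1))
  attr(out, "site_hash") <- site_list_hash(sites)
  out
}

#' Repeat-length distribution for one site
#'
#' Single-site convenience wrapper around [extract_all()].
#'
#' @inheritParams extract_all
#' @param site One-row site table.
#' @return Named integer count vector (names are observed lengths y).
#' @export
extract_site_distribution <- function(bam, site, min_mapq = 20L, anchor = 5L,
                                      method = c("flank", "cigar")) {
  d <- extract_all(bam, site[1, , drop = FALSE], min_mapq = min_mapq,
                   anchor = anchor, method = method)
  y <- d$lengths[[1]]
  tab <- table(factor(y, levels = sort(unique(y))))
  stats::setNames(as.integer(tab), names(tab))
}

site_read_lengths <- function(rd, site, end0, min_mapq, anchor, method) {
  if (length(rd$pos) == 0L) return(integer(0))
  keep <- !is.na(rd$mapq) & rd$mapq >= min_mapq
  out <- integer(0)
  mlen <- nchar(site$motif)
  for (r in which(keep)) {
    ref_start0 <- rd$pos[r] - 1L                       # 0-based
    ref_end0 <- ref_start0 + cigar_ref_width(rd$cigar[r])
    # spanning requirement: full tract plus anchors on both sides
    if (ref_start0 > site$start - anchor || ref_end0 < end0 + anchor) next
    y <- if (method == "flank")
      read_repeat_length_flank(as.character(rd$seq[r]), site, anchor,
                               expected_start = site$start - ref_start0 + 1L)
    else
      read_repeat_length_cigar(as.character(rd$seq[r]), rd$cigar[r],
                               ref_start0, site$start, end0, site$motif)
    if (!is.na(y)) out <- c(out, y)
  }
  out
}

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = len, op = op)
}

cigar_ref_width <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
}

# count complete leading motif copies of a string
leading_copies <- function(s, motif) {
  mlen <- nchar(motif)
  n <- 0L
  while (nchar(s) >= (n + 1L) * mlen &&
         substr(s, n * mlen + 1L, (n + 1L) * mlen) == motif)
    n <- n + 1L
  n
}

# re-locate the tract in the read by exact flank match and count
# copies; among left-anchor occurrences, the one whose implied tract
# start lies nearest the alignment-expected position (within one tract
# length of slack) wins, so repeated flank motifs elsewhere in the read
# cannot hijack the anchor
read_repeat_length_flank <- function(seq, site, anchor, expected_start) {
  la <- substr(site$left_flank, nchar(site$left_flank) - anchor + 1L,
               nchar(site$left_flank))
  ra <- substr(site$right_flank, 1L, anchor)
  if (nchar(la) < anchor || nchar(ra) < anchor) return(NA_integer_)
  slack <- site$n * nchar(site$motif)
  # lookahead so overlapping anchor occurrences are all seen
  pls <- gregexpr(paste0("(?=", la, ")"), seq, perl = TRUE)[[1]]
  if (pls[1] < 0) return(NA_integer_)
  impl_start <- pls + anchor                 # tract start implied by match
  off <- abs(impl_start - expected_start)
  cand <- impl_start[off <= slack][order(off[off <= slack])]
  for (tract_from in cand) {
    pr <- regexpr(ra, substr(seq, tract_from, nchar(seq)), fixed = TRUE)
    if (pr < 0) next
    tract <- substr(seq, tract_from, tract_from + pr - 2L)
    # non-motif inserted bases terminate copy counting; a candidate
    # whose tract starts with non-motif sequence is a spurious anchor
    # hit (e.g. a mutated flank), so the read is discarded instead of
    # being scored as a full deletion
    y <- leading_copies(tract, site$motif)
    if (y > 0L || nchar(tract) == 0L) return(y)
  }
  NA_integer_
}

# walk the CIGAR and collect the read bases aligned within the tract
# interval [start0, end0); insertions anywhere in [start0, end0] count,
# since aligners may left- or right-align a tract indel onto a boundary
read_repeat_length_cigar <- function(seq, cigar, ref_start0, start0, end0,
                                     motif) {
  co <- cigar_ops(cigar)
  ref <- ref_start0
  qry <- 0L
  tract <- character(0)
  for (i in seq_along(co$op)) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "=", "X")) {
      ov_from <- max(ref, start0); ov_to <- min(ref + len, end0)
      if (ov_from < ov_to) {
        q_from <- qry + (ov_from - ref)
        tract <- c(tract, substr(seq, q_from + 1L, q_from + (ov_to - ov_from)))
      }
      ref <- ref + len; qry <- qry + len
    } else if (op == "I") {
      if (ref >= start0 && ref <= end0)
        tract <- c(tract, substr(seq, qry + 1L, qry + len))
      qry <- qry + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } else if (op == "S") {
      qry <- qry + len
    }
    # H and P consume neither sequence
  }
  leading_copies(paste(tract, collapse = ""), motif)
}

# accept SAM transparently; index the BAM if needed
as_indexed_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  path
}

format_dist_string <- function(y) {
  if (length(y) == 0L) return(".")
  tab <- table(y)
  paste(paste0(names(tab), ":", as.integer(tab)), collapse = " ")
}

parse_dist_string <- function(s) {
  if (is.na(s) || s == "." || s == "") return(integer(0))
  parts <- strsplit(strsplit(s, " ", fixed = TRUE)[[1]], ":", fixed = TRUE)
  y <- as.integer(vapply(parts, `[`, character(1), 1L))
  k <- as.integer(vapply(parts, `[`, character(1), 2L))
  rep(y, times = k)
}

#' Write a per-sample distribution table to TSV
#'
#' Site identity columns followed by the "y:count" distribution string
#' and m. Round-trips with [read_distributions()].
#'
#' @param dists Distribution table from [extract_all()].
#' @param path Output path.
#' @export
write_distributions <- function(dists, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#slipmsi distributions v1", con)
  writeLines(paste0("#site_hash=", attr(dists, "site_hash")), con)
  writeLines("#chrom\tstart\tmotif\tn\tdist\tm", con)
  dist <- if (!is.null(dists$dist)) dists$dist
          else vapply(dists$lengths, format_dist_string, character(1))
  df <- data.frame(chrom = dists$chrom, start = dists$start + 1L,
                   motif = dists$motif, n = dists$n,
                   dist = dist, m = dists$m)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a distribution table written by [write_distributions()]
#'
#' @param path Distribution TSV path.
#' @return Distribution table with `lengths` restored.
#' @export
read_distributions <- function(path) {
  hash <- read_header_field(path, "site_hash")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "motif", "n",
                                        "dist", "m"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "character", "integer"))
  df$start <- df$start - 1L
  df$site_id <- paste(df$chrom, df$start, df$motif, sep = ":")
  df$lengths <- lapply(df$dist, parse_dist_string)
  attr(df, "site_hash") <- hash
  df
}

read_header_field <- function(path, field) {
  lines <- readLines(path, n = 10L)
  hit <- grep(paste0("^#", field, "="), lines, value = TRUE)
  if (length(hit)) sub(paste0("^#", field, "="), "", hit[1]) else NA_character_
}
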