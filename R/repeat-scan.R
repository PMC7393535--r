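#' Scan a reference genome for microsatellite loci
#'
#' Finds every maximal tandem repeat of a primitive 1-5 bp motif meeting
#' the per-motif-length minimum copy number. Scanning is
#' case-insensitive; runs are broken at ambiguity codes (N etc.), which
#' cannot be genotyped. A homopolymer embedded in a longer-motif repeat
#' is reported independently at each motif length.
#'
#' @param fasta Path to a FASTA file (plain or bgzipped), or a
#'   [Biostrings::DNAStringSet].
#' @param min_repeats Named or positional integer vector of minimum
#'   complete motif copies per motif length 1..5. Default: homopolymers
#'   need 5 copies, motif lengths 2-5 need 3.
#' @param flank_len Length of the recorded flanking context (bp).
#' @param max_motif Longest motif length to scan (<= 5).
#' @return Data frame of sites sorted by (chrom, start): `chrom`,
#'   `start` (0-based first repeat base), `motif`, `n` (complete copies),
#'   `left_flank`, `right_flank`, and a `site_id` key
#'   ("chrom:start:motif"). Coordinates are 0-based internally; the TSV
#'   writer emits 1-based starts.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "GGAAAAATT"))
#' scan_reference(ref)
#' @export
scan_reference <- function(fasta, min_repeats = c(5L, 3L, 3L, 3L, 3L),
                           flank_len = 5L, max_motif = 5L) {
  seqs <- load_fasta(fasta)
  if (length(min_repeats) < max_motif)
    stop("'min_repeats' must give a minimum for every motif length scanned")
  res <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    res[[s]] <- scan_one_sequence(names(seqs)[s],
                                  toupper(as.character(seqs[[s]])),
                                  min_repeats, flank_len, max_motif)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      motif = character(), n = integer(),
                      left_flank = character(), right_flank = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, nchar(out$motif)), , drop = FALSE]
  out$site_id <- paste(out$chrom, out$start, out$motif, sep = ":")
  rownames(out) <- NULL
  out
}

load_fasta <- function(fasta) {
  if (methods::is(fasta, "DNAStringSet")) return(fasta)
  if (!file.exists(fasta)) stop("FASTA not readable: ", fasta)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop("malformed FASTA '", fasta, "': ",
                                            conditionMessage(e)))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

scan_one_sequence <- function(chrom, seq, min_repeats, flank_len, max_motif) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  if (!all(valid))
    message("sequence ", chrom, ": skipping windows containing ambiguity codes")
  sites <- list()
  for (k in seq_len(min(max_motif, max(1L, L %/% 2L)))) {
    if (L < 2L * k) next
    # period-k positions: base i equals base i+k and both are unambiguous
    match_k <- chars[seq_len(L - k)] == chars[(k + 1L):L] &
      valid[seq_len(L - k)] & valid[(k + 1L):L]
    r <- rle(match_k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      tract_start <- starts[h]                 # 1-based
      tract_len <- r$lengths[h] + k            # bases with period k
      n <- tract_len %/% k
      if (n < min_repeats[k]) next
      motif <- substr(seq, tract_start, tract_start + k - 1L)
      if (!is_primitive(motif)) next
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = chrom,
        start = tract_start - 1L,              # 0-based
        motif = motif,
        n = n,
        left_flank = flank_of(seq, tract_start - flank_len, tract_start - 1L),
        right_flank = flank_of(seq, tract_start + n * k,
                               tract_start + n * k + flank_len - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(sites)) do.call(rbind, sites) else NULL
}

# a motif is primitive when no proper divisor of its length is a period
is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, k %/% d) == motif) return(FALSE)
  }
  TRUE
}

flank_of <- function(seq, from, to) {
  from <- max(from, 1L); to <- min(to, nchar(seq))
  if (from > to) return("")
  substr(seq, from, to)
}

#' Write a microsatellite site list to TSV
#'
#' Columns: chrom, start (1-based inclusive), motif, n, left_flank,
#' right_flank, preceded by a '#'-prefixed header. Round-trips exactly
#' with [read_sites()].
#'
#' @param sites Site table from [scan_reference()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#slipmsi sites v1"), con)
  writeLines("#chrom\tstart\tmotif\tn\tleft_flank\tright_flank", con)
  df <- sites
  df$start <- df$start + 1L     # 1-based on disk
  utils::write.table(
    df[, c("chrom", "start", "motif", "n", "left_flank", "right_flank")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a site list written by [write_sites()]
#'
#' @param path Site-list TSV path.
#' @return Site table with 0-based `start` and a `site_id` key.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "motif", "n",
                                        "left_flank", "right_flank"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "character", "character"))
  df$start <- df$start - 1L
  df$site_id <- paste(df$chrom, df$start, df$motif, sep = ":")
  df
}

#' Content hash of a site list's identity columns
#'
#' Baselines embed this hash so they can only be applied to estimate
#' tables produced from the identical site list.
#'
#' @param sites Site table.
#' @return Hex MD5 string.
#' @export
site_list_hash <- function(sites) {
  key <- paste(sites$chrom, sites$start, sites$motif, sites$n,
               sep = ":", collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(key, tf)
  unname(tools::md5sum(tf))
}
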