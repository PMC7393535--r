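#' Specification of a synthetic microsatellite cohort
#'
#' Bundles every knob of the fixture generator: the planted site panel,
#' the per-site slippage rates of the normal state, the MSI effect, and
#' the sequencing depth model. Defaults describe a compact but
#' realistic desk-scale cohort: mostly homopolymers, normal-state
#' deletion slippage rising with repeat length from 0.1% to 5% per
#' unit, insertion slippage one fifth of that, a five-fold elevation of
#' deletion slippage at 30% of sites in MSI samples, and mean 50x
#' spanning-read coverage.
#'
#' @param n_sites Number of planted microsatellites.
#' @param motif_mix Proportions of motif lengths 1-5.
#' @param n_range List of c(min, max) reference copy numbers per motif
#'   length.
#' @param n_normals,n_msi,n_mss Sample counts per role.
#' @param p_range Normal-state per-unit deletion probability at the
#'   smallest / largest repeat count (linearly interpolated in n, with
#'   20% multiplicative jitter).
#' @param q_over_p Insertion rate as a fraction of the deletion rate.
#' @param msi_effect Multiplicative elevation of p at MSI target sites.
#' @param msi_fraction Fraction of sites that are MSI targets.
#' @param coverage Mean spanning-read count per site (Poisson).
#' @param purity Fraction of tumor-derived reads in tumor samples.
#' @param spacer_len Non-repetitive spacer between planted repeats (bp).
#' @param flank_len Recorded flank length (bp).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sites = 500L,
                        motif_mix = c(0.6, 0.2, 0.1, 0.05, 0.05),
                        n_range = list(c(8L, 20L), c(4L, 10L), c(3L, 8L),
                                       c(3L, 6L), c(3L, 5L)),
                        n_normals = 20L, n_msi = 20L, n_mss = 20L,
                        p_range = c(0.001, 0.05), q_over_p = 0.2,
                        msi_effect = 5, msi_fraction = 0.3,
                        coverage = 50, purity = 1.0,
                        spacer_len = 25L, flank_len = 5L) {
  stopifnot(n_sites >= 0, length(motif_mix) == 5L, all(motif_mix >= 0),
            coverage > 0, purity >= 0, purity <= 1, msi_effect >= 1,
            msi_fraction >= 0, msi_fraction <= 1, spacer_len >= 20L)
  structure(list(n_sites = as.integer(n_sites),
                 motif_mix = motif_mix / sum(motif_mix),
                 n_range = n_range, n_normals = as.integer(n_normals),
                 n_msi = as.integer(n_msi), n_mss = as.integer(n_mss),
                 p_range = p_range, q_over_p = q_over_p,
                 msi_effect = msi_effect, msi_fraction = msi_fraction,
                 coverage = coverage, purity = purity,
                 spacer_len = as.integer(spacer_len),
                 flank_len = as.integer(flank_len)),
            class = "cohort_spec")
}

BASES <- c("A", "C", "G", "T")

# random spacer that cannot seed a scannable repeat: consecutive bases
# differ at lags 1 and 2 (hard), and avoid lags 3-5 when possible
# (soft), killing homopolymer and dinucleotide runs outright and making
# longer-motif runs vanishingly rare
random_spacer <- function(len, prev = character(0), first_not = NULL,
                          last_not = NULL) {
  out <- character(len)
  ctx <- prev
  for (i in seq_len(len)) {
    hard <- utils::tail(ctx, 2L)
    soft <- utils::tail(ctx, 5L)
    cand <- setdiff(BASES, hard)
    if (i == 1L && !is.null(first_not)) cand <- setdiff(cand, first_not)
    if (i == len && !is.null(last_not)) cand <- setdiff(cand, last_not)
    pref <- setdiff(cand, soft)
    pick <- if (length(pref)) pref else cand
    out[i] <- pick[sample.int(length(pick), 1L)]
    ctx <- c(ctx, out[i])
  }
  paste(out, collapse = "")
}

# TRUE when the spacer, scanned together with the flanking tract
# context, contributes no scannable repeat: every detected run must lie
# entirely inside one of the neighbouring tracts
junction_ok <- function(prev_ctx, sp, next_ctx) {
  test <- paste0(prev_ctx, sp, next_ctx)
  found <- scan_one_sequence("j", test, min_repeats = c(5L, rep(3L, 4L)),
                             flank_len = 0L, max_motif = 5L)
  if (is.null(found)) return(TRUE)
  lo <- nchar(prev_ctx)
  hi <- lo + nchar(sp)
  ends <- found$start + found$n * nchar(found$motif)
  all(ends <= lo | found$start >= hi)
}

# spacer that survives the junction check against both neighbours
safe_spacer <- function(len, prev_tract, next_tract, first_not, last_not,
                        max_tries = 50L) {
  prev_ctx <- substr(prev_tract, max(1L, nchar(prev_tract) - 14L),
                     nchar(prev_tract))
  next_ctx <- substr(next_tract, 1L, 15L)
  prev <- strsplit(prev_ctx, "")[[1]]
  for (i in seq_len(max_tries)) {
    sp <- random_spacer(len, prev = prev, first_not = first_not,
                        last_not = last_not)
    if (junction_ok(prev_ctx, sp, next_ctx)) return(sp)
  }
  sp   # final whole-sequence verification still guards this path
}

random_motif <- function(k) {
  repeat {
    m <- paste(sample(BASES, k, replace = TRUE), collapse = "")
    if (is_primitive(m)) return(m)
  }
}

#' Generate a synthetic reference with planted microsatellites
#'
#' Builds one chromosome of non-repetitive spacer sequence with
#' `n_sites` maximal microsatellites planted at known positions, each
#' annotated with its ground-truth normal-state slippage rates and an
#' MSI-target flag. The assembled chromosome is verified against
#' [scan_reference()] so the truth table and the scanner agree exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return List with `ref` (a [Biostrings::DNAStringSet]) and `sites`:
#'   the scan-format truth table extended with `p`, `q` (normal state)
#'   and `msi_target`.
#' @export
generate_reference <- function(spec, seed = NULL) {
  with_seed(seed, generate_reference_impl(spec))
}

generate_reference_impl <- function(spec, max_tries = 10L) {
  for (try in seq_len(max_tries)) {
    S <- spec$n_sites
    klens <- if (S > 0L)
      sample(1:5, S, replace = TRUE, prob = spec$motif_mix) else integer(0)
    motifs <- vapply(klens, random_motif, character(1))
    ns <- vapply(klens, function(k) {
      r <- spec$n_range[[k]]
      sample(seq(r[1], r[2]), 1L)
    }, integer(1))
    # minimum copies so the default scanner finds every planted site
    ns <- pmax(ns, ifelse(klens == 1L, 5L, 3L))
    tracts <- vapply(seq_len(max(S, 1L)),
                     function(i) if (S > 0L) strrep(motifs[i], ns[i]) else "",
                     character(1))
    chunks <- character(2L * S + 1L)
    starts <- integer(S)
    pos <- 0L
    for (i in seq_len(S)) {
      sp <- safe_spacer(spec$spacer_len,
                        prev_tract = if (i > 1L) tracts[i - 1L] else "",
                        next_tract = tracts[i],
                        first_not = if (i > 1L)
                          substr(motifs[i - 1L], 1L, 1L) else NULL,
                        last_not = substr(motifs[i], klens[i], klens[i]))
      chunks[2L * i - 1L] <- sp
      pos <- pos + nchar(sp)
      starts[i] <- pos                              # 0-based tract start
      chunks[2L * i] <- tracts[i]
      pos <- pos + nchar(tracts[i])
    }
    chunks[2L * S + 1L] <- safe_spacer(
      spec$spacer_len, prev_tract = if (S > 0L) tracts[S] else "",
      next_tract = "",
      first_not = if (S > 0L) substr(motifs[S], 1L, 1L) else NULL,
      last_not = NULL)
    seq <- paste(chunks, collapse = "")
    ref <- Biostrings::DNAStringSet(stats::setNames(seq, "chrS"))
    truth <- data.frame(
      chrom = rep("chrS", S), start = starts, motif = motifs, n = ns,
      left_flank = vapply(seq_len(S), function(i)
        flank_of(seq, starts[i] + 1L - spec$flank_len, starts[i]),
        character(1)),
      right_flank = vapply(seq_len(S), function(i)
        flank_of(seq, starts[i] + ns[i] * klens[i] + 1L,
                 starts[i] + ns[i] * klens[i] + spec$flank_len),
        character(1)),
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$chrom, truth$start, nchar(truth$motif)), ,
                   drop = FALSE]
    truth$site_id <- paste(truth$chrom, truth$start, truth$motif, sep = ":")
    scanned <- scan_reference(ref, flank_len = spec$flank_len)
    if (identical(scanned$site_id, truth$site_id) &&
        identical(scanned$n, truth$n)) {
      truth <- scanned        # adopt scanner's column order / flanks
      break
    }
    if (try == max_tries)
      stop("could not assemble a reference whose scan matches the truth ",
           "list; reduce n_sites or increase spacer_len")
  }
  # ground-truth slippage rates: p rises linearly with n inside each
  # motif-length class, with 20% jitter; q is a fixed fraction of p
  S <- nrow(truth)
  klen <- nchar(truth$motif)
  p <- numeric(S)
  for (k in unique(klen)) {
    r <- spec$n_range[[k]]
    f <- if (r[2] > r[1]) (truth$n[klen == k] - r[1]) / (r[2] - r[1]) else 0.5
    f <- pmin(pmax(f, 0), 1)
    p[klen == k] <- spec$p_range[1] + diff(spec$p_range) * f
  }
  p <- p * stats::runif(S, 0.8, 1.2)
  truth$p <- pmin(p, 0.5)
  truth$q <- truth$p * spec$q_over_p
  truth$msi_target <- stats::runif(S) < spec$msi_fraction
  list(ref = ref, sites = truth)
}

# role-specific per-site parameters; elevation clamped so p + q <= 0.9
role_params <- function(truth, spec, role) {
  p <- truth$p; q <- truth$q
  if (role == "msi") {
    el <- truth$msi_target
    p[el] <- pmin(truth$p[el] * spec$msi_effect, 0.9 - q[el])
  }
  list(p = p, q = q)
}

#' Simulate one sample's allele-length distributions (no reads)
#'
#' Fast distribution-level shortcut: for each site, draws spanning-read
#' repeat lengths directly from the renormalised slippage pmf at the
#' role's parameters, skipping read synthesis entirely. Tumor roles mix
#' tumor-parameter and normal-parameter reads binomially at the given
#' purity.
#'
#' @param truth Truth table from [generate_reference()] (or any site
#'   table with `n`, `p`, `q` and, for `role = "msi"`, `msi_target`).
#' @param spec A [cohort_spec()].
#' @param role `"normal"`, `"mss"` or `"msi"`.
#' @param purity Tumor purity; defaults to the value in the cohort
#'   specification.
#' @param depth_scale Multiplier on mean coverage (depth downsampling).
#' @param seed Optional integer seed.
#' @return Distribution table as produced by [extract_all()] (with a
#'   `lengths` list-column).
#' @export
generate_sample_dists <- function(truth, spec, role = c("normal", "mss", "msi"),
                                  purity = NULL, depth_scale = 1,
                                  seed = NULL) {
  role <- match.arg(role)
  if (is.null(purity)) purity <- spec$purity
  with_seed(seed, {
    S <- nrow(truth)
    tum <- role_params(truth, spec, role)
    lengths <- vector("list", S)
    for (i in seq_len(S)) {
      m <- stats::rpois(1L, spec$coverage * depth_scale)
      if (m == 0L) { lengths[[i]] <- integer(0); next }
      m_t <- if (role == "msi" && purity < 1)
        stats::rbinom(1L, m, purity) else m
      y <- integer(0)
      if (m_t > 0L)
        y <- draw_lengths(truth$n[i], tum$p[i], tum$q[i], m_t)
      if (m - m_t > 0L)
        y <- c(y, draw_lengths(truth$n[i], truth$p[i], truth$q[i], m - m_t))
      lengths[[i]] <- y
    }
    out <- truth[, c("chrom", "start", "motif", "n", "left_flank",
                     "right_flank", "site_id")]
    out$lengths <- lengths
    out$m <- vapply(lengths, length, integer(1))
    attr(out, "site_hash") <- site_list_hash(truth)
    out
  })
}

draw_lengths <- function(n, p, q, m) {
  tab <- repeat_length_pmf_table(n, p, q)
  sample(0:(2L * n), m, replace = TRUE, prob = tab)
}

#' Simulate a whole cohort and return per-sample slippage estimates
#'
#' Generates normal, MSS-tumor and MSI-tumor samples over one truth
#' panel and estimates (p, q) per site per sample. This is the
#' model-level pipeline (no reads; see [generate_sample_bam()] for the
#' alignment-level path).
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param truth Optional pre-built truth table (from
#'   [generate_reference()]); by default a fresh reference is planted.
#' @param depth_scale Coverage multiplier applied to every sample.
#' @return List with `truth`, `estimates` (named list of per-sample
#'   estimate tables), and `labels` (sample_id, role, label, split).
#' @export
generate_cohort <- function(spec, seed = NULL, truth = NULL,
                            depth_scale = 1) {
  with_seed(seed, {
    if (is.null(truth)) truth <- generate_reference_impl(spec)$sites
    hash <- site_list_hash(truth)
    roles <- c(rep("normal", spec$n_normals), rep("mss", spec$n_mss),
               rep("msi", spec$n_msi))
    ids <- sprintf("%s_%02d", roles, stats::ave(seq_along(roles), roles,
                                                FUN = seq_along))
    estimates <- vector("list", length(roles))
    names(estimates) <- ids
    for (s in seq_along(roles)) {
      d <- generate_sample_dists(truth, spec, roles[s],
                                 depth_scale = depth_scale)
      estimates[[s]] <- estimate_all(d)
      attr(estimates[[s]], "site_hash") <- hash
    }
    labels <- data.frame(
      sample_id = ids, role = roles,
      label = ifelse(roles == "msi", "MSI",
                     ifelse(roles == "mss", "MSS", NA_character_)),
      split = "discovery", stringsAsFactors = FALSE)
    list(truth = truth, estimates = estimates, labels = labels)
  })
}

#' Write a simulated sample as an aligned, indexed BAM
#'
#' Synthesises error-free spanning reads for every site: each read
#' carries `pad` bases of true flanking sequence on both sides of a
#' tract of the drawn repeat length, with the length change encoded as
#' an insertion or deletion in the CIGAR at the tract. Reads are
#' written as SAM, then coordinate-sorted and indexed.
#'
#' @inheritParams generate_sample_dists
#' @param ref Reference `DNAStringSet` from [generate_reference()].
#' @param path Output BAM path (without or with `.bam`).
#' @param pad Flanking bases per side carried by each read (default 15;
#'   must be at least the extraction anchor).
#' @return List with `bam` (path), and `read_truth`: per-read
#'   data frame (qname, site_id, y).
#' @export
generate_sample_bam <- function(truth, ref, spec, path,
                                role = c("normal", "mss", "msi"),
                                purity = NULL, depth_scale = 1,
                                pad = 15L, seed = NULL) {
  role <- match.arg(role)
  dists <- generate_sample_dists(truth, spec, role = role, purity = purity,
                                 depth_scale = depth_scale, seed = seed)
  chrom_seq <- as.character(ref[["chrS"]])
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(ref))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, Biostrings::width(ref[nm])),
               con)
  qn <- 0L
  rt_q <- character(0); rt_site <- character(0); rt_y <- integer(0)
  for (i in seq_len(nrow(truth))) {
    ys <- dists$lengths[[i]]
    if (!length(ys)) next
    st <- truth$start[i]                      # 0-based tract start
    k <- nchar(truth$motif[i]); n <- truth$n[i]
    left <- substr(chrom_seq, st - pad + 1L, st)
    right <- substr(chrom_seq, st + n * k + 1L, st + n * k + pad)
    pos1 <- st - pad + 1L                     # 1-based alignment start
    for (y in ys) {
      qn <- qn + 1L
      qname <- sprintf("r%06d", qn)
      seqr <- paste0(left, strrep(truth$motif[i], y), right)
      cigar <- if (y < n)
        sprintf("%dM%dD%dM", pad + y * k, (n - y) * k, pad)
      else if (y > n)
        sprintf("%dM%dI%dM", pad + n * k, (y - n) * k, pad)
      else
        sprintf("%dM", 2L * pad + n * k)
      writeLines(paste(qname, 0L, truth$chrom[i], pos1, 60L, cigar,
                       "*", 0L, 0L, seqr, "*", sep = "\t"), con)
      rt_q <- c(rt_q, qname); rt_site <- c(rt_site, truth$site_id[i])
      rt_y <- c(rt_y, y)
    }
  }
  close(con)
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  list(bam = bam,
       read_truth = data.frame(qname = rt_q, site_id = rt_site, y = rt_y,
                               stringsAsFactors = FALSE))
}
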