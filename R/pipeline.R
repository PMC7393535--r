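#' Run one pipeline stage from a configuration list
#'
#' Thin programmatic equivalent of the command-line interface: executes
#' scan, extract, estimate, baseline, msi, dms, simulate or evaluate
#' with file inputs and outputs. Every output carries a '#' header
#' echoing the effective parameters; reruns with identical inputs and
#' seed are byte-identical. A stage failure aborts with the stage named
#' and leaves its partial output under a `.partial` suffix.
#'
#' @param config Named list: `stage` plus the stage's parameters
#'   (paths, thresholds, `seed`). Unset parameters take the package
#'   defaults (coverage rule 20, 3-sigma threshold, AUC threshold 0.65,
#'   anchor 5, score cutoff 10).
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(config) {
  stage <- config$stage
  if (is.null(stage) ||
      !stage %in% c("scan", "extract", "estimate", "baseline", "msi",
                    "dms", "simulate", "evaluate"))
    stop("config$stage must be one of scan/extract/estimate/baseline/",
         "msi/dms/simulate/evaluate")
  get_or <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  need <- function(name) {
    v <- config[[name]]
    if (is.null(v)) stop("stage '", stage, "' requires config parameter '",
                         name, "'")
    v
  }
  out_paths <- tryCatch(switch(stage,
    scan = {
      sites <- scan_reference(
        need("reference"),
        min_repeats = c(get_or("min_homopolymer", 5L),
                        rep(get_or("min_repeats", 3L), 4L)),
        flank_len = get_or("flank_len", 5L))
      write_atomic(need("output"), function(p) write_sites(sites, p))
    },
    extract = {
      sites <- read_sites(need("sites"))
      d <- extract_all(need("bam"), sites,
                       min_mapq = get_or("min_mapq", 20L),
                       anchor = get_or("anchor", 5L),
                       method = get_or("method", "flank"))
      write_atomic(need("output"), function(p) write_distributions(d, p))
    },
    estimate = {
      d <- read_distributions(need("distributions"))
      est <- estimate_all(d)
      write_atomic(need("output"), function(p) write_estimates(est, p))
    },
    baseline = {
      paths <- if (!is.null(config$normals_manifest))
        readLines(config$normals_manifest) else need("normals")
      ests <- lapply(paths, read_estimates)
      bl <- build_baseline(ests,
                           min_coverage = get_or("min_coverage", 20L),
                           support_fraction = get_or("support_fraction", 0.5),
                           n_sigma = get_or("n_sigma", 3))
      write_atomic(need("output"), function(p) write_baseline(bl, p))
    },
    msi = {
      tumor_path <- need("tumor"); bl_path <- need("baseline")
      out_prefix <- need("output")
      tumor <- read_estimates(tumor_path)
      bl <- read_baseline(bl_path)
      call <- call_msi(tumor, bl,
                       min_coverage = get_or("min_coverage", 20L),
                       score_cutoff = get_or("cutoff", 10),
                       sample_id = get_or("sample_id", "sample"))
      write_msi_call(call, out_prefix)
    },
    dms = {
      paths <- if (!is.null(config$estimates_manifest))
        readLines(config$estimates_manifest) else need("estimates")
      if (is.null(names(paths)))
        names(paths) <- sub("\\.[^.]*$", "", basename(paths))
      ests <- lapply(paths, read_estimates)
      labels <- utils::read.table(need("labels"), header = TRUE, sep = "\t",
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
      aucs <- site_auc_table(ests, labels,
                             min_coverage = get_or("min_coverage", 20L))
      dms <- select_dms(aucs, get_or("auc_threshold", 0.65))
      out <- need("output")
      write_atomic(out, function(p) {
        con <- file(p, "w")
        writeLines("#slipmsi site aucs v1", con)
        writeLines("#chrom\tstart\tmotif\tn\tauc\tn_msi\tn_mss", con)
        df <- data.frame(aucs$chrom, aucs$start + 1L, aucs$motif, aucs$n,
                         aucs$auc, aucs$n_msi, aucs$n_mss)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        close(con)
      })
      # DMS panel in scan format, directly usable as a restricted site list
      panel_path <- paste0(sub("\\.tsv$", "", out), "_panel.tsv")
      ref_sites <- read_sites(need("sites"))
      write_atomic(panel_path, function(p)
        write_sites(ref_sites[ref_sites$site_id %in% dms$site_id, ], p))
      c(out, panel_path)
    },
    simulate = {
      spec <- do.call(cohort_spec, config$cohort %||% list())
      outdir <- need("outdir")
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      gen <- generate_reference(spec, seed = get_or("seed", NULL))
      fa <- file.path(outdir, "reference.fa")
      Biostrings::writeXStringSet(gen$ref, fa)
      write_sites(gen$sites, file.path(outdir, "truth_sites.tsv"))
      cohort <- generate_cohort(spec, seed = get_or("seed", NULL),
                                truth = gen$sites)
      for (id in names(cohort$estimates))
        write_estimates(cohort$estimates[[id]],
                        file.path(outdir, paste0(id, ".est.tsv")))
      utils::write.table(cohort$labels, file.path(outdir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(config, file.path(outdir, "run_config.json"),
                           auto_unbox = TRUE, null = "null")
      outdir
    },
    evaluate = {
      calls <- utils::read.table(need("calls"), header = TRUE, sep = "\t",
                                 comment.char = "#",
                                 stringsAsFactors = FALSE)
      labels <- utils::read.table(need("labels"), header = TRUE, sep = "\t",
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
      ev <- evaluate_cohort(calls, labels)
      out <- need("output")
      write_atomic(out, function(p) {
        con <- file(p, "w")
        writeLines("#slipmsi cohort evaluation v1", con)
        writeLines(sprintf("#auc=%.6f n_msi=%d n_mss=%d", ev$auc, ev$n_msi,
                           ev$n_mss), con)
        writeLines("#threshold\ttpr\tfpr", con)
        utils::write.table(ev$roc, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        close(con)
      })
      out
    }),
    error = function(e) stop("pipeline stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  invisible(out_paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write via a .partial temp name so interrupted runs never leave a
# truncated file under the final name
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}
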