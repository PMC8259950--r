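# File I/O and the end-to-end pipeline driver.

#' Read promoters from a FASTA file
#'
#' Headers must be `GENE|TSS_OFFSET` (e.g. `>MMP12|-1`): the offset of the
#' sequence's 3'-most base relative to the transcription start site.
#' Sequences are uppercased; ambiguity codes and duplicate gene+offset
#' combinations are rejected.
#'
#' @param path FASTA file path.
#' @return Named list of [promoter_sequence()] objects, in file order.
#' @export
read_promoter_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  headers <- names(xs)
  out <- vector("list", length(xs))
  seen <- character(0)
  for (i in seq_along(xs)) {
    parts <- strsplit(headers[i], "|", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.integer(parts[2L])))) {
      stop("record ", i, ": header must be GENE|TSS_OFFSET, got '",
           headers[i], "'", call. = FALSE)
    }
    key <- toupper(headers[i])
    if (key %in% seen) {
      stop("duplicate promoter record: ", headers[i], call. = FALSE)
    }
    seen <- c(seen, key)
    sq <- toupper(as.character(xs[[i]]))
    if (grepl("[^ACGT]", sq)) {
      stop("record ", i, " (", parts[1L],
           "): sequence contains non-ACGT characters", call. = FALSE)
    }
    out[[i]] <- promoter_sequence(parts[1L], sq, as.integer(parts[2L]))
  }
  names(out) <- vapply(out, function(p) p$gene_symbol, character(1L))
  out
}

#' Write promoters to a FASTA file
#'
#' @param promoters List of [promoter_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(promoters, function(p) p$sequence, character(1L)))
  names(seqs) <- vapply(promoters, function(p) {
    paste0(p$gene_symbol, "|", p$tss_offset)
  }, character(1L))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a SNP table
#'
#' TSV with columns `snp_id, gene, offset, ref, alt` (empty `ref`/`alt`
#' denote pure insertions/deletions).
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("snp_id", "gene", "offset", "ref", "alt")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("SNP table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cn in c("snp_id", "gene", "ref", "alt")) {
    df[[cn]] <- as.character(df[[cn]])
    df[[cn]][is.na(df[[cn]])] <- ""
  }
  df
}

#' Read a DEG table
#'
#' TSV with columns `dataset_id, domestic_label, wild_label, tissue, gene,
#' log2fc, p_adj` (only `gene`, `log2fc`, `p_adj` are required).
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("gene", "log2fc", "p_adj")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("DEG table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end chain on file or in-memory inputs: score both
#' alleles of every SNP, classify the verdicts into disease-direction
#' markers, tally them per gene category, test the tallies for neutral
#' drift vs selection, and (if a DEG table is supplied) cross-validate the
#' marker directions against domestic-vs-wild expression divergence.
#' Reports are written as TSV/JSON into `out_dir` along with a log
#' recording package version, seed and a parameter-file digest; reruns with
#' the same config are byte-identical.
#'
#' @param config Named list (or YAML file path) with entries: `promoters`
#'   (FASTA path or list), `snps` (TSV path or data.frame), `annotations`
#'   (TSV path or [gene_catalog()]), optional `degs` (TSV path or
#'   data.frame), optional `params` (YAML path), `out_dir`, optional
#'   `alpha`, `p_threshold`, `seed`.
#' @return Invisible list with `comparisons`, `markers`, `tally`,
#'   `selection`, and `crossval` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  for (key in c("promoters", "snps", "annotations")) {
    if (is.null(config[[key]])) {
      stop("config lacks required entry '", key, "'", call. = FALSE)
    }
    if (is.character(config[[key]]) && !file.exists(config[[key]])) {
      stop("config entry '", key, "' points to a missing file: ",
           config[[key]], call. = FALSE)
    }
  }
  if (!is.null(config$degs) && is.character(config$degs) &&
      !file.exists(config$degs)) {
    stop("config entry 'degs' points to a missing file: ", config$degs,
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config lacks 'out_dir'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params_path <- config$params %||%
    system.file("extdata", "affinity_params.yaml", package = "tbpsnp")
  params <- load_affinity_params(params_path)
  if (!is.null(config$alpha)) params$alpha <- config$alpha
  model <- tbp_model(params = params)

  promoters <- if (is.character(config$promoters)) {
    read_promoter_fasta(config$promoters)
  } else config$promoters
  snps <- if (is.character(config$snps)) read_snp_table(config$snps)
          else config$snps
  catalog <- if (is.character(config$annotations)) {
    load_annotations(config$annotations)
  } else config$annotations

  comparisons <- compare_snp_table(promoters, snps, model)
  markers <- classify_markers(comparisons, catalog)
  tally <- tally_markers(markers)
  selection <- summarize_selection(tally, alpha = params$alpha)
  write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
  write_tsv(markers, file.path(out_dir, "markers.tsv"))
  write_tsv(as.data.frame(tally), file.path(out_dir, "tally.tsv"))
  write_tsv(as.data.frame(selection), file.path(out_dir, "selection.tsv"))

  crossval <- NULL
  if (!is.null(config$degs)) {
    degs <- if (is.character(config$degs)) read_deg_table(config$degs)
            else config$degs
    crossval <- crossval_report(degs, catalog, alpha = params$alpha,
                                p_threshold = config$p_threshold %||% 0.05)
    cv_df <- data.frame(
      lineage = rownames(crossval$table),
      aggravate = crossval$table[, "aggravate"],
      relieve = crossval$table[, "relieve"],
      binom_p = c(crossval$binom_p_domestic, crossval$binom_p_wild),
      chi2 = c(crossval$chi2_stat, NA), chi2_p = c(crossval$chi2_p, NA),
      fisher_p = c(crossval$fisher_p_two_sided, NA)
    )
    write_tsv(cv_df, file.path(out_dir, "crossval.tsv"))
    jsonlite::write_json(
      list(table = crossval$table, chi2_stat = crossval$chi2_stat,
           chi2_p = crossval$chi2_p,
           chi2_yates_stat = crossval$chi2_yates_stat,
           fisher_p_two_sided = crossval$fisher_p_two_sided,
           binom_p_domestic = crossval$binom_p_domestic,
           binom_p_wild = crossval$binom_p_wild,
           n_pairs = crossval$n_pairs),
      file.path(out_dir, "crossval.json"), auto_unbox = TRUE, digits = NA
    )
  }

  log_lines <- c(
    paste0("tbpsnp version: ",
           as.character(utils::packageVersion("tbpsnp"))),
    paste0("seed: ", config$seed %||% "none"),
    paste0("alpha: ", params$alpha),
    paste0("params file: ", params_path),
    paste0("params md5: ", unname(tools::md5sum(params_path))),
    paste0("n promoters: ", length(promoters)),
    paste0("n snps: ", nrow(snps))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(comparisons = comparisons, markers = markers, tally = tally,
                 selection = selection, crossval = crossval))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
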