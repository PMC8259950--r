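# Gene annotation catalog: maps expression deficit/excess to disease
# direction (aggravate / relieve) per gene, and tallies marker counts per
# functional category.

CATEGORIES <- c("comorbid_clinical", "ra_associated", "immunostimulatory",
                "immunosuppressive")
EFFECTS <- c("aggravate", "relieve")

#' Load a gene annotation catalog
#'
#' Reads a TSV with columns `gene, category, deficit_effect, excess_effect,
#' note`: for each gene, the disease-direction consequence of its
#' underexpression (deficit) and overexpression (excess). Gene symbols are
#' matched case-insensitively downstream; duplicate symbols are rejected.
#' A gene may map both states to the same direction.
#'
#' @param path TSV path; defaults to the packaged catalog covering the
#'   cross-validated ortholog genes plus MMP12.
#' @return `data.frame` of class `gene_catalog`.
#' @export
load_annotations <- function(path = system.file("extdata", "gene_annotations.tsv",
                                                package = "tbpsnp")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("gene", "category", "deficit_effect", "excess_effect")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"note" %in% names(raw)) raw$note <- ""
  gene_catalog(raw[, c(needed, "note")])
}

#' Build a gene catalog from a data frame
#'
#' @param df `data.frame` with columns `gene, category, deficit_effect,
#'   excess_effect` and optionally `note`.
#' @return `data.frame` of class `gene_catalog`, keyed by uppercased symbol.
#' @export
gene_catalog <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"note" %in% names(df)) df$note <- ""
  key <- toupper(df$gene)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicate gene(s) in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_eff <- !(df$deficit_effect %in% EFFECTS) | !(df$excess_effect %in% EFFECTS)
  if (any(bad_eff)) {
    stop("unknown effect token for gene(s): ",
         paste(df$gene[bad_eff], collapse = ", "),
         " (must be 'aggravate' or 'relieve')", call. = FALSE)
  }
  bad_cat <- !(df$category %in% CATEGORIES)
  if (any(bad_cat)) {
    stop("unknown category for gene(s): ",
         paste(df$gene[bad_cat], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- key
  class(df) <- c("gene_catalog", "data.frame")
  df
}

catalog_lookup <- function(catalog, gene) {
  i <- match(toupper(gene), rownames(catalog))
  if (is.na(i)) {
    stop("gene '", gene, "' not found in the annotation catalog",
         call. = FALSE)
  }
  catalog[i, , drop = FALSE]
}

#' Classify an allele comparison as a disease-direction marker
#'
#' Maps the expression verdict of [compare_alleles()] to a disease
#' direction through the gene's annotation: a `deficiency` call takes the
#' gene's `deficit_effect`, an `excess` call its `excess_effect`, and an
#' `insignificant` call maps to no direction.
#'
#' @param cmp An `allele_comparison` (or a list with `snp_id`,
#'   `gene_symbol`, `decision`, `site_direction`).
#' @param catalog A [gene_catalog()].
#' @return `data.frame` row of class `marker_record`: snp_id, gene,
#'   category, decision, site_direction, ra_direction
#'   (`"up"` = aggravate, `"down"` = relieve, `"none"`).
#' @export
classify_marker <- function(cmp, catalog) {
  ann <- catalog_lookup(catalog, cmp$gene_symbol)
  ra_direction <- switch(cmp$decision,
    deficiency = if (ann$deficit_effect == "aggravate") "up" else "down",
    excess = if (ann$excess_effect == "aggravate") "up" else "down",
    insignificant = "none",
    stop("unknown decision: ", cmp$decision, call. = FALSE)
  )
  out <- data.frame(snp_id = cmp$snp_id, gene = cmp$gene_symbol,
                    category = ann$category, decision = cmp$decision,
                    site_direction = cmp$site_direction,
                    ra_direction = ra_direction, stringsAsFactors = FALSE)
  class(out) <- c("marker_record", "data.frame")
  out
}

#' Classify a batch of allele comparisons
#'
#' @param comparisons Either a list of `allele_comparison` objects or the
#'   `data.frame` from [compare_snp_table()].
#' @param catalog A [gene_catalog()].
#' @return `data.frame` of marker records.
#' @export
classify_markers <- function(comparisons, catalog) {
  if (is.data.frame(comparisons)) {
    comparisons <- lapply(seq_len(nrow(comparisons)), function(i) {
      list(snp_id = comparisons$snp_id[i], gene_symbol = comparisons$gene[i],
           decision = comparisons$decision[i],
           site_direction = comparisons$site_direction[i])
    })
  }
  out <- do.call(rbind, lapply(comparisons, classify_marker, catalog = catalog))
  rownames(out) <- NULL
  out
}

#' Tally marker counts per functional category
#'
#' For each gene category, counts: `n_genes` (genes with at least one
#' examined SNP), `n_snps` (SNPs examined), `n_sig` (significant markers),
#' `n_improve` / `n_damage` (significant markers improving / damaging the
#' TBP-site), and `n_aggravate` / `n_relieve` (markers predicted to worsen
#' / relieve the disease). Insignificant records contribute to `n_snps`
#' only. By construction `n_improve + n_damage = n_sig` and
#' `n_aggravate + n_relieve = n_sig`.
#'
#' @param records Marker records from [classify_markers()].
#' @param categories Categories to report; defaults to all four.
#' @return `data.frame` of class `marker_tally`, one row per category.
#' @export
tally_markers <- function(records, categories = CATEGORIES) {
  rows <- lapply(categories, function(cat) {
    r <- records[records$category == cat, , drop = FALSE]
    sig <- r[r$decision != "insignificant", , drop = FALSE]
    data.frame(
      category = cat,
      n_genes = length(unique(toupper(r$gene))),
      n_snps = nrow(r),
      n_sig = nrow(sig),
      n_improve = sum(sig$site_direction == "improved"),
      n_damage = sum(sig$site_direction == "damaged"),
      n_aggravate = sum(sig$ra_direction == "up"),
      n_relieve = sum(sig$ra_direction == "down"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("marker_tally", "data.frame")
  out
}

#' Invert the disease directions of a catalog
#'
#' Swaps every aggravate/relieve assignment; useful for symmetry checks.
#'
#' @param catalog A [gene_catalog()].
#' @return The inverted catalog.
#' @export
invert_catalog <- function(catalog) {
  flip <- function(x) ifelse(x == "aggravate", "relieve", "aggravate")
  catalog$deficit_effect <- flip(catalog$deficit_effect)
  catalog$excess_effect <- flip(catalog$excess_effect)
  catalog
}
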