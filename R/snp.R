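# Allele editing and wt/min affinity comparison.

#' Specify a promoter variant
#'
#' A substitution or indel within the promoter window, given by its 5'-most
#' affected offset relative to the TSS. For a pure insertion `ref_allele`
#' is empty (`alt_allele` is inserted immediately 5' of `offset`); for a
#' pure deletion `alt_allele` is empty.
#'
#' @param snp_id Variant identifier (free text, e.g. an rs number).
#' @param offset 5'-most affected position relative to the TSS (negative).
#' @param ref_allele Reference (ancestral) bases at `offset`; may be `""`.
#' @param alt_allele Minor-allele bases; may be `""`.
#' @return Object of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, offset, ref_allele, alt_allele) {
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (!nzchar(ref_allele) && !nzchar(alt_allele)) {
    stop("ref and alt alleles cannot both be empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", ref_allele) || grepl("[^ACGT]", alt_allele)) {
    stop("alleles must be over {A,C,G,T}", call. = FALSE)
  }
  structure(list(snp_id = as.character(snp_id), offset = as.integer(offset),
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "snp_spec")
}

# offset relative to TSS -> 1-based index into the sequence string
offset_to_index <- function(seq, offset) {
  offset - seq$tss_offset + nchar(seq$sequence)
}

#' Edit a variant into a promoter sequence
#'
#' Returns the minor-allele promoter: the reference bases at the variant's
#' offset are replaced by the alternate bases. Indels change the sequence
#' length; no re-padding to 70 bp is performed, mirroring free-text editing
#' of the minor-allele sequence.
#'
#' @param seq A [promoter_sequence()].
#' @param snp A [snp_spec()].
#' @param L Minimum length the edited promoter must keep (the model window
#'   length); default 15.
#' @return The edited [promoter_sequence()].
#' @export
apply_variant <- function(seq, snp, L = 15L) {
  idx <- offset_to_index(seq, snp$offset)
  n <- nchar(seq$sequence)
  nref <- nchar(snp$ref_allele)
  if (idx < 1L || idx + max(nref, 1L) - 1L > n) {
    stop("variant ", snp$snp_id, " at offset ", snp$offset,
         " lies outside the promoter window", call. = FALSE)
  }
  if (nref > 0L) {
    observed <- substr(seq$sequence, idx, idx + nref - 1L)
    if (observed != snp$ref_allele) {
      stop("reference mismatch for ", snp$snp_id, " at offset ", snp$offset,
           ": expected ", snp$ref_allele, ", promoter has ", observed,
           call. = FALSE)
    }
  }
  edited <- paste0(substr(seq$sequence, 1L, idx - 1L), snp$alt_allele,
                   substr(seq$sequence, idx + nref, n))
  if (nchar(edited) < L) {
    stop("edited sequence shorter than the model window", call. = FALSE)
  }
  # the edited allele keeps the TSS anchor: bases 3' of the edit stay put
  promoter_sequence(seq$gene_symbol, edited, seq$tss_offset)
}

#' Fisher Z comparison of two affinity estimates
#'
#' `z = |wt - min| / sqrt(se_wt^2 + se_min^2)`, converted to a two-sided
#' p-value from the standard normal tail, `p = 2 * (1 - Phi(z))`, clamped
#' to (0, 1]. If both standard errors are zero while the values differ the
#' comparison is degenerate (infinite Z): `p = 0` is returned with a
#' `degenerate` flag and a warning.
#'
#' @param wt,min [estimate_affinity()] results (or lists with `value` and
#'   `stderr`) for the ancestral and minor alleles.
#' @return List with `z`, `p_value`, `degenerate`.
#' @examples
#' fisher_z_compare(list(value = 6, stderr = 0.1), list(value = 5, stderr = 0.1))
#' @export
fisher_z_compare <- function(wt, min) {
  delta <- abs(wt$value - min$value)
  denom <- sqrt(wt$stderr^2 + min$stderr^2)
  if (denom == 0) {
    if (delta == 0) {
      return(list(z = 0, p_value = 1, degenerate = FALSE))
    }
    warning("both standard errors are zero with differing values: infinite Z")
    return(list(z = Inf, p_value = 0, degenerate = TRUE))
  }
  z <- delta / denom
  p <- 2 * stats::pnorm(-z)
  if (p > 1) p <- 1
  if (p <= 0) p <- .Machine$double.xmin   # clamp into (0, 1]
  list(z = z, p_value = p, degenerate = FALSE)
}

#' Compare the two promoter alleles of a SNP
#'
#' Scores the ancestral promoter and its minor-allele edit with
#' [estimate_affinity()], computes the Fisher Z-score and p-value of their
#' difference, and emits the decision at `model$params$alpha`:
#' `"deficiency"` if the minor allele significantly lowers the affinity
#' (predicting underexpression), `"excess"` if it raises it, otherwise
#' `"insignificant"`. `site_direction` records the sign of the change
#' regardless of significance (`damaged` / `improved` / `unchanged`).
#'
#' @param seq A [promoter_sequence()] carrying the ancestral allele.
#' @param snp A [snp_spec()].
#' @param model A [tbp_model()].
#' @return Object of class `allele_comparison`.
#' @export
compare_alleles <- function(seq, snp, model = tbp_model()) {
  wt_est <- estimate_affinity(seq, model)
  min_seq <- apply_variant(seq, snp, L = model$params$L)
  min_est <- estimate_affinity(min_seq, model)
  fz <- fisher_z_compare(wt_est, min_est)
  alpha <- model$params$alpha
  significant <- fz$p_value < alpha
  decision <- if (!significant) {
    "insignificant"
  } else if (min_est$value < wt_est$value) "deficiency" else "excess"
  site_direction <- if (min_est$value < wt_est$value) {
    "damaged"
  } else if (min_est$value > wt_est$value) "improved" else "unchanged"
  structure(
    list(snp_id = snp$snp_id, gene_symbol = seq$gene_symbol,
         wt = wt_est, min = min_est, z = fz$z, p_value = fz$p_value,
         degenerate = fz$degenerate, alpha = alpha,
         decision = decision, site_direction = site_direction),
    class = "allele_comparison"
  )
}

#' @export
print.allele_comparison <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$snp_id, x$gene_symbol))
  cat(sprintf("  wt : -ln(KD) = %.3f +/- %.3f\n", x$wt$value, x$wt$stderr))
  cat(sprintf("  min: -ln(KD) = %.3f +/- %.3f\n", x$min$value, x$min$stderr))
  cat(sprintf("  Z = %.3f, p = %.3g -> %s (site %s)\n",
              x$z, x$p_value, x$decision, x$site_direction))
  invisible(x)
}

#' Batch allele comparison over a SNP table
#'
#' @param promoters Named list of [promoter_sequence()] (names or
#'   gene_symbols matched against `snps$gene`).
#' @param snps `data.frame` with columns `snp_id, gene, offset, ref, alt`
#'   (as read by [read_snp_table()]).
#' @param model A [tbp_model()].
#' @return `data.frame` with one row per SNP: snp_id, gene, wt_value, wt_se,
#'   min_value, min_se, z, p, decision, site_direction.
#' @export
compare_snp_table <- function(promoters, snps, model = tbp_model()) {
  genes <- vapply(promoters, function(p) p$gene_symbol, character(1L))
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    g <- as.character(snps$gene[i])
    j <- match(toupper(g), toupper(genes))
    if (is.na(j)) stop("no promoter for gene ", g, call. = FALSE)
    cmp <- compare_alleles(
      promoters[[j]],
      snp_spec(snps$snp_id[i], snps$offset[i], snps$ref[i], snps$alt[i]),
      model
    )
    data.frame(snp_id = cmp$snp_id, gene = g,
               wt_value = cmp$wt$value, wt_se = cmp$wt$stderr,
               min_value = cmp$min$value, min_se = cmp$min$stderr,
               z = cmp$z, p = cmp$p_value, decision = cmp$decision,
               site_direction = cmp$site_direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
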