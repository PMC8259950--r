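# Core TBP-promoter affinity estimator.
#
# The model mirrors a three-step picture of TBP-promoter complex formation
# (TBP slides along DNA, is retarded at a TBP-site, and the complex is fixed
# by DNA bending): a non-specific baseline plus sequence-specific terms read
# from an L-bp window, scanned over every position of both strands.  The
# reported affinity is the best window's score, interpreted on the -ln(KD)
# scale, with an uncertainty delta taken as the sample standard error of the
# top-K window scores.

#' Construct a promoter sequence
#'
#' A 70-bp (canonically) core-promoter sequence anchored to the
#' transcription start site (TSS). `tss_offset` is the offset of the
#' 3'-most base relative to the TSS (default -1), so a 70-bp sequence
#' spans offsets -70..-1.
#'
#' @param gene_symbol Gene symbol the promoter belongs to.
#' @param sequence Nucleotide string over A/C/G/T (lowercase accepted,
#'   normalized to uppercase). Ambiguity codes are rejected.
#' @param tss_offset Offset of the last base relative to the TSS; negative.
#' @return Object of class `promoter_sequence`.
#' @examples
#' p <- promoter_sequence("TEST", strrep("ACGTTATAAA", 7))
#' @export
promoter_sequence <- function(gene_symbol, sequence, tss_offset = -1L) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("promoter '", gene_symbol,
         "' contains characters outside {A,C,G,T}", call. = FALSE)
  }
  structure(
    list(gene_symbol = as.character(gene_symbol), sequence = sequence,
         tss_offset = as.integer(tss_offset), strand_label = "sense"),
    class = "promoter_sequence"
  )
}

#' @export
print.promoter_sequence <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<promoter %s: %d bp, offsets %d..%d>\n", x$gene_symbol, n,
              x$tss_offset - n + 1L, x$tss_offset))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over A/C/G/T (case-insensitive).
#' @return Uppercase reverse complement.
#' @export
reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCATGCA",
         paste(rev(strsplit(as.character(x), "", fixed = TRUE)[[1L]]),
               collapse = ""))
}

#' Bundle the TBP affinity model
#'
#' The model object carries the position-weight matrix, the dinucleotide
#' property scales and the term weights; it is the fitting-free estimator
#' behind [estimate_affinity()] and [compare_alleles()]. With no arguments
#' it loads the packaged calibrated defaults.
#'
#' @param pwm A [load_pwm()] object (default: packaged TATA matrix).
#' @param scales A [load_dinuc_scales()] object (default: packaged scales).
#' @param params An [affinity_params()] object (default: packaged calibrated
#'   parameter file).
#' @return Object of class `tbp_model`.
#' @examples
#' m <- tbp_model()
#' coef(m)
#' @export
tbp_model <- function(pwm = load_pwm(), scales = load_dinuc_scales(),
                      params = load_affinity_params()) {
  if (!inherits(pwm, "tbp_pwm")) stop("pwm must be a 'tbp_pwm'", call. = FALSE)
  if (!inherits(scales, "dinuc_scales")) {
    stop("scales must be 'dinuc_scales'", call. = FALSE)
  }
  if (!inherits(params, "affinity_params")) {
    stop("params must be 'affinity_params'", call. = FALSE)
  }
  if (params$L != pwm$length) {
    stop("params$L (", params$L, ") does not match PWM length (",
         pwm$length, ")", call. = FALSE)
  }
  structure(list(pwm = pwm, scales = scales, params = params),
            class = "tbp_model")
}

#' @export
print.tbp_model <- function(x, ...) {
  cat("TBP-promoter affinity model\n")
  cat("  footprint L =", x$params$L,
      "| strands:", if (x$params$scan_both_strands) "both" else "sense", "\n")
  cat("  consensus:", paste(pwm_consensus(x$pwm), collapse = ""), "\n")
  cat("  weights: ", paste(sprintf("%s=%.3g",
      c("w0", "w_pwm", "w_ta", "w_mg", "w_melt"),
      unlist(x$params[c("w0", "w_pwm", "w_ta", "w_mg", "w_melt")])),
      collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.tbp_model <- function(object, ...) {
  unlist(object$params[c("w0", "w_pwm", "w_ta", "w_mg", "w_melt")])
}

# integer encoding A=1 C=2 G=3 T=4; stops on anything else
encode_seq <- function(sequence) {
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], BASES)
  if (anyNA(codes)) stop("sequence contains non-ACGT characters", call. = FALSE)
  codes
}

# scores of every L-window of an encoded sequence (single strand)
scan_scores <- function(codes, model) {
  p <- model$params
  L <- p$L
  n <- length(codes)
  n_win <- n - L + 1L
  w <- model$pwm$weights
  # PWM term: rolling sum of per-position log-frequencies
  per_pos <- w[cbind(rep.int(seq_len(L), n_win),
                     codes[rep(seq_len(L), n_win) +
                           rep(seq_len(n_win) - 1L, each = L)])]
  pwm_term <- colSums(matrix(per_pos, nrow = L))
  # dinucleotide terms: rolling means over the L-1 steps of each window
  di <- 4L * (codes[-n] - 1L) + codes[-1L]
  roll_mean <- function(v) {
    cs <- c(0, cumsum(v))
    (cs[(L - 1L) + seq_len(n_win)] - cs[seq_len(n_win)]) / (L - 1L)
  }
  s <- model$scales
  unname(p$w0 + p$w_pwm * pwm_term +
         p$w_ta   * roll_mean(s$ta_richness[di]) +
         p$w_mg   * roll_mean(s$minor_groove_width[di]) +
         p$w_melt * roll_mean(s$melting[di]))
}

#' Score a single window
#'
#' Evaluates the affinity model on one window of exactly the footprint
#' length: `S = w0 + w_pwm * PWM + w_ta * mean(ta_richness) +
#' w_mg * mean(minor_groove_width) + w_melt * mean(melting)`, the
#' dinucleotide means running over the window's L-1 steps.
#'
#' @param window Nucleotide string of length `model$params$L`.
#' @param model A [tbp_model()].
#' @param explain If `TRUE`, attach the four term contributions as an
#'   attribute `"terms"`.
#' @return Numeric score (-ln(KD) scale).
#' @export
window_score <- function(window, model, explain = FALSE) {
  p <- model$params
  codes <- encode_seq(toupper(window))
  if (length(codes) != p$L) {
    stop("window must have length L = ", p$L, call. = FALSE)
  }
  s <- scan_scores(codes, model)
  if (explain) {
    di <- 4L * (codes[-length(codes)] - 1L) + codes[-1L]
    terms <- c(
      w0 = p$w0,
      pwm = p$w_pwm * sum(model$pwm$weights[cbind(seq_len(p$L), codes)]),
      ta = p$w_ta * mean(model$scales$ta_richness[di]),
      mg = p$w_mg * mean(model$scales$minor_groove_width[di]),
      melt = p$w_melt * mean(model$scales$melting[di])
    )
    attr(s, "terms") <- terms
  }
  s
}

#' Estimate TBP-binding affinity of a promoter
#'
#' Scans every footprint-length window on the sense strand and (by default)
#' the reverse complement, and reports the highest window score as the
#' promoter's -ln(KD) estimate, together with its uncertainty delta (the
#' sample standard error of the top-K window scores) and the best site's
#' 5'-most offset relative to the TSS. Ties are broken toward the sense
#' strand, then the smallest (most 5') offset.
#'
#' @param seq A [promoter_sequence()] (or plain string, taken as a promoter
#'   ending at offset -1).
#' @param model A [tbp_model()].
#' @return Object of class `affinity_estimate`: `value`, `stderr`,
#'   `best_offset`, `best_strand`, and the vector of all window scores in
#'   `scores` (named by strand).
#' @export
estimate_affinity <- function(seq, model = tbp_model()) {
  if (is.character(seq)) seq <- promoter_sequence("?", seq)
  p <- model$params
  n <- nchar(seq$sequence)
  if (n < p$L) {
    stop("sequence shorter than the model window (", n, " < ", p$L, ")",
         call. = FALSE)
  }
  codes <- encode_seq(seq$sequence)
  n_win <- n - p$L + 1L
  offsets <- seq$tss_offset - n + seq_len(n_win)        # 5'-most base offset
  sense <- scan_scores(codes, model)
  if (p$scan_both_strands) {
    rc <- 5L - rev(codes)
    minus_rev <- scan_scores(rc, model)
    # window starting at position s on the reverse complement covers the
    # same bases as the sense window starting at n - s - L + 2
    minus <- rev(minus_rev)
    all_scores <- c(sense, minus)
    strand <- rep(c("+", "-"), each = n_win)
    all_offsets <- c(offsets, offsets)
  } else {
    all_scores <- sense
    strand <- rep("+", n_win)
    all_offsets <- offsets
  }
  ord <- order(-all_scores, strand != "+", all_offsets)
  best <- ord[1L]
  k <- min(p$top_k_for_se, length(all_scores))
  top <- sort(all_scores, decreasing = TRUE)[seq_len(k)]
  se <- if (k >= 2L) stats::sd(top) / sqrt(k) else 0
  if (!is.finite(se)) se <- 0
  structure(
    list(value = all_scores[best], stderr = se,
         best_offset = all_offsets[best], best_strand = strand[best],
         scores = stats::setNames(all_scores, strand),
         window_offsets = all_offsets, n_windows = length(all_scores)),
    class = "affinity_estimate"
  )
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("-ln(KD) = %.3f +/- %.3f (best site at %d, strand %s)\n",
              x$value, x$stderr, x$best_offset, x$best_strand))
  invisible(x)
}

#' Predict affinities for a set of promoters
#'
#' @param object A [tbp_model()].
#' @param newdata List of [promoter_sequence()] objects (e.g. from
#'   [read_promoter_fasta()] or [gen_promoters()]).
#' @param ... Unused.
#' @return `data.frame` with one row per promoter: gene, value, stderr,
#'   best_offset, best_strand.
#' @export
predict.tbp_model <- function(object, newdata, ...) {
  stopifnot(is.list(newdata))
  rows <- lapply(newdata, function(pr) {
    est <- estimate_affinity(pr, object)
    data.frame(gene = pr$gene_symbol, value = est$value, stderr = est$stderr,
               best_offset = est$best_offset, best_strand = est$best_strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
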