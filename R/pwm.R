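BASES <- c("A", "C", "G", "T")
# row-major order: index of XY is 4 * (X - 1) + Y with A=1 .. T=4
DINUCS <- paste0(rep(BASES, each = 4L), rep(BASES, times = 4L))

#' Load a TBP position-weight matrix from a count table
#'
#' Reads a tab-separated table of per-position base counts (or frequencies)
#' with columns `A C G T`, one row per position of the TBP footprint, and
#' converts it to log-frequency weights with an additive pseudocount.
#'
#' @param path Path to the TSV file. Defaults to the packaged TATA-box
#'   matrix, a consensus-derived synthetic default whose first eight rows
#'   carry the canonical TATAWAWR core (realized TATAAAAG) followed by a
#'   GC-rich downstream context.
#' @param pseudocount Additive pseudocount applied to every cell before the
#'   log-frequency transform. Default 0.5.
#' @return An object of class `tbp_pwm`: list with `weights` (L x 4 matrix
#'   of log-frequencies, columns A/C/G/T), `background` (base frequencies,
#'   uniform by default) and `length`.
#' @examples
#' pwm <- load_pwm()
#' pwm$length
#' @export
load_pwm <- function(path = system.file("extdata", "tbp_pwm.tsv", package = "tbpsnp"),
                     pseudocount = 0.5) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(BASES %in% names(raw))) {
    stop("PWM file must have columns A, C, G, T: ", path, call. = FALSE)
  }
  mat <- as.matrix(raw[, BASES])
  if (nrow(mat) < 4L) {
    stop("PWM must have at least 4 rows, got ", nrow(mat), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(mat) | apply(mat, 1L, function(r) any(!is.finite(r)) || any(r < 0)))
  if (length(bad)) {
    stop("malformed PWM row ", bad[1L], ": non-numeric or negative cell", call. = FALSE)
  }
  counts <- mat + pseudocount
  weights <- log(counts / rowSums(counts))
  dimnames(weights) <- list(NULL, BASES)
  structure(
    list(weights = weights, background = rep(0.25, 4L), length = nrow(weights)),
    class = "tbp_pwm"
  )
}

#' @export
print.tbp_pwm <- function(x, ...) {
  cons <- apply(x$weights, 1L, function(r) BASES[which.max(r)])
  cat("TBP position-weight matrix, L =", x$length, "\n")
  cat("Consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' Per-row consensus (argmax) bases of a PWM
#'
#' @param pwm A [load_pwm()] object.
#' @return Character vector of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  apply(pwm$weights, 1L, function(r) BASES[which.max(r)])
}

#' Load dinucleotide property scales
#'
#' Reads the tab-separated table mapping each of the 16 dinucleotides to
#' unit-normalized structural/thermodynamic properties used by the affinity
#' model: TA-richness, B-DNA minor-groove width, and melting propensity
#' (derived from nearest-neighbour duplex stabilities; higher = melts more
#' readily). All scales are normalized to `[0, 1]`.
#'
#' @param path Path to the TSV (columns: `dinuc` plus one column per scale).
#'   Defaults to the packaged scales.
#' @return Object of class `dinuc_scales`: named list of named numeric
#'   16-vectors, one per scale.
#' @export
load_dinuc_scales <- function(path = system.file("extdata", "dinuc_scales.tsv",
                                                 package = "tbpsnp")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"dinuc" %in% names(raw)) {
    stop("scales file must have a 'dinuc' column", call. = FALSE)
  }
  if (!setequal(raw$dinuc, DINUCS) || anyDuplicated(raw$dinuc)) {
    stop("scales file must list each of the 16 dinucleotides exactly once",
         call. = FALSE)
  }
  scale_cols <- setdiff(names(raw), "dinuc")
  if (!length(scale_cols)) stop("no scale columns found", call. = FALSE)
  out <- lapply(scale_cols, function(cn) {
    v <- raw[[cn]]
    if (any(!is.finite(v))) stop("non-finite value in scale ", cn, call. = FALSE)
    stats::setNames(as.numeric(v), raw$dinuc)[DINUCS]
  })
  names(out) <- scale_cols
  structure(out, class = "dinuc_scales")
}

#' Affinity model parameters
#'
#' Bundles the tunable parameters of the sliding-window TBP-affinity model:
#' the non-specific baseline `w0` (in -ln(KD) units), the weights of the
#' PWM and dinucleotide-context terms, the footprint length `L`, strand
#' handling, the number of top-scoring windows used for the standard error,
#' and the significance level used for allele decisions.
#'
#' @param w0 Non-specific TBP-DNA affinity baseline, -ln(KD) units.
#' @param w_pwm,w_ta,w_mg,w_melt Term weights (PWM log-frequency sum,
#'   mean TA-richness, mean minor-groove width, mean melting propensity).
#' @param L Window (TBP footprint) length, >= 4.
#' @param scan_both_strands Scan the reverse complement as well.
#' @param top_k_for_se Number of top window scores whose sample standard
#'   error is reported as the estimate's uncertainty delta; >= 2.
#' @param alpha Significance level for deficiency/excess decisions.
#' @return Object of class `affinity_params`.
#' @export
affinity_params <- function(w0 = 23, w_pwm = 0.4, w_ta = 0.35, w_mg = 0.15,
                            w_melt = 0.25, L = 15L, scan_both_strands = TRUE,
                            top_k_for_se = 20L, alpha = 0.05) {
  L <- as.integer(L)
  top_k_for_se <- as.integer(top_k_for_se)
  if (L < 4L) stop("L must be >= 4", call. = FALSE)
  if (top_k_for_se < 2L) stop("top_k_for_se must be >= 2", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(w0 = w0, w_pwm = w_pwm, w_ta = w_ta, w_mg = w_mg, w_melt = w_melt,
         L = L, scan_both_strands = isTRUE(scan_both_strands),
         top_k_for_se = top_k_for_se, alpha = alpha),
    class = "affinity_params"
  )
}

#' Load affinity model parameters from a YAML file
#'
#' @param path YAML file; defaults to the packaged calibrated parameter file.
#' @return An [affinity_params()] object.
#' @export
load_affinity_params <- function(path = system.file("extdata", "affinity_params.yaml",
                                                    package = "tbpsnp")) {
  y <- yaml::read_yaml(path)
  affinity_params(
    w0 = y$w0, w_pwm = y$w_pwm, w_ta = y$w_ta, w_mg = y$w_mg,
    w_melt = y$w_melt, L = y$L, scan_both_strands = y$scan_both_strands,
    top_k_for_se = y$top_k_for_se, alpha = y$alpha
  )
}
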