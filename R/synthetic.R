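# Seeded synthetic-data generators and exact in-package fixtures.
#
# The generators emulate the pipeline's inputs end to end: random-background
# 70-bp promoters with a TATA box of tunable strength planted at a fixed
# offset, SNP sets of known effect class (damage / improve / neutral), and
# domestic-vs-wild DEG tables with configurable direction and effect
# fractions.  Every generator is a pure function of its spec (fixed seed in,
# identical corpus out).

TATA_CONSENSUS <- "TATAAAAG"

#' Specification for the synthetic corpus
#'
#' @param seed Integer seed; the whole corpus is a pure function of the spec.
#' @param n_promoters Number of promoters to generate.
#' @param background_gc GC content of the i.i.d. background, in (0, 1).
#' @param box_strength Fraction of the 8 consensus positions planted
#'   (1 = full TATAAAAG box, 0 = no planting).
#' @param box_offset 5'-most offset of the planted box relative to the TSS.
#' @param n_damage,n_improve,n_neutral SNP counts per effect class.
#' @param deg_n_genes Number of genes in the synthetic DEG table.
#' @param deg_frac_domestic_excess Fraction of DEGs upregulated in the
#'   domestic lineage (log2fc > 0).
#' @param deg_frac_aggravate Probability that the expression state reached
#'   by the domestic lineage maps to "aggravate" in the paired annotation
#'   catalog (the wild state gets the complementary direction); 0.5 = no
#'   lineage-effect association.
#' @param deg_frac_significant Fraction of DEG records drawn with
#'   `p_adj <= 0.05` (the rest exercise the filter).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_promoters = 50L, background_gc = 0.5,
                           box_strength = 1, box_offset = -30L,
                           n_damage = 0L, n_improve = 0L, n_neutral = 0L,
                           deg_n_genes = 30L, deg_frac_domestic_excess = 0.5,
                           deg_frac_aggravate = 0.5,
                           deg_frac_significant = 0.8) {
  stopifnot(background_gc > 0, background_gc < 1,
            box_strength >= 0, box_strength <= 1,
            deg_frac_domestic_excess >= 0, deg_frac_domestic_excess <= 1,
            deg_frac_aggravate >= 0, deg_frac_aggravate <= 1,
            deg_frac_significant >= 0, deg_frac_significant <= 1)
  structure(
    list(seed = as.integer(seed), n_promoters = as.integer(n_promoters),
         background_gc = background_gc, box_strength = box_strength,
         box_offset = as.integer(box_offset),
         n_damage = as.integer(n_damage), n_improve = as.integer(n_improve),
         n_neutral = as.integer(n_neutral),
         deg_n_genes = as.integer(deg_n_genes),
         deg_frac_domestic_excess = deg_frac_domestic_excess,
         deg_frac_aggravate = deg_frac_aggravate,
         deg_frac_significant = deg_frac_significant),
    class = "synthetic_spec"
  )
}

#' Generate synthetic 70-bp promoters with planted TATA boxes
#'
#' Background bases are i.i.d. at the spec's GC content; the TATAAAAG
#' consensus is planted at `box_offset`, with `box_strength` controlling
#' the fraction of its 8 positions actually written (the planted subset is
#' drawn per promoter). Ground truth (planted positions) is attached to
#' each promoter as the attribute `"ground_truth"`.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of [promoter_sequence()] objects (`SYN0001`, ...).
#' @export
gen_promoters <- function(spec) {
  n <- 70L
  tss <- -1L
  box_len <- nchar(TATA_CONSENSUS)
  box_idx <- spec$box_offset - tss + n   # index of the box's 5'-most base
  if (spec$box_strength > 0 &&
      (box_idx < 1L || box_idx + box_len - 1L > n)) {
    stop("box_offset places the TATA box outside the promoter window",
         call. = FALSE)
  }
  set.seed(spec$seed)
  gc <- spec$background_gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cons <- strsplit(TATA_CONSENSUS, "")[[1L]]
  n_plant <- round(spec$box_strength * box_len)
  out <- vector("list", spec$n_promoters)
  for (i in seq_len(spec$n_promoters)) {
    bases <- sample(BASES, n, replace = TRUE, prob = probs)
    planted <- integer(0)
    if (n_plant > 0L) {
      planted <- sort(sample.int(box_len, n_plant))
      bases[box_idx + planted - 1L] <- cons[planted]
    }
    pr <- promoter_sequence(sprintf("SYN%04d", i),
                            paste(bases, collapse = ""), tss)
    attr(pr, "ground_truth") <- list(
      box_offset = spec$box_offset,
      planted_positions = planted,
      box_index = box_idx
    )
    out[[i]] <- pr
  }
  names(out) <- vapply(out, function(p) p$gene_symbol, character(1L))
  out
}

# worst/best scoring base of a PWM row
pwm_worst_base <- function(pwm, row) BASES[which.min(pwm$weights[row, ])]
pwm_best_base <- function(pwm, row) BASES[which.max(pwm$weights[row, ])]

#' Generate SNPs of known effect class on synthetic promoters
#'
#' Three classes, each carrying its ground-truth label in the `class`
#' column: `damage` mutates a planted consensus box position to the
#' PWM-worst base; `improve` mutates an off-consensus position inside the
#' best-window footprint to the PWM-best base (preferring unplanted box
#' positions when `box_strength < 1`); `neutral` substitutes a base at
#' least `neutral_margin` bp away from every top-scoring window footprint.
#' Reference alleles always match the generated promoter.
#'
#' @param spec A [synthetic_spec()] with `n_damage`, `n_improve`,
#'   `n_neutral` set.
#' @param promoters Output of [gen_promoters()] on the same spec.
#' @param model The [tbp_model()] used to locate top windows.
#' @param neutral_top_k Number of top-scoring windows a neutral SNP must
#'   keep clear of (default 3).
#' @param neutral_margin Minimum distance in bp from those footprints
#'   (default 10).
#' @return `data.frame` with columns `snp_id, gene, offset, ref, alt,
#'   class`.
#' @export
gen_snps <- function(spec, promoters, model = tbp_model(),
                     neutral_top_k = 3L, neutral_margin = 10L) {
  set.seed(spec$seed + 1L)
  n_seq <- length(promoters)
  L <- model$params$L
  rows <- list()
  pick_promoter <- function(i) promoters[[((i - 1L) %% n_seq) + 1L]]
  # damage: planted consensus position -> PWM-worst base of that row
  for (i in seq_len(spec$n_damage)) {
    pr <- pick_promoter(i)
    gt <- attr(pr, "ground_truth")
    if (!length(gt$planted_positions)) {
      stop("damage SNPs need planted box positions (box_strength > 0)",
           call. = FALSE)
    }
    row <- sample(gt$planted_positions, 1L)
    idx <- gt$box_index + row - 1L
    ref <- substr(pr$sequence, idx, idx)
    alt <- pwm_worst_base(model$pwm, row)
    if (alt == ref) alt <- setdiff(BASES, ref)[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sprintf("dmg%04d", i), gene = pr$gene_symbol,
      offset = gt$box_offset + row - 1L, ref = ref, alt = alt,
      class = "damage", stringsAsFactors = FALSE)
  }
  # improve: off-consensus position inside the best window -> PWM-best base
  for (i in seq_len(spec$n_improve)) {
    pr <- pick_promoter(i + spec$n_damage)
    gt <- attr(pr, "ground_truth")
    est <- estimate_affinity(pr, model)
    start_idx <- est$best_offset - pr$tss_offset + nchar(pr$sequence)
    cand <- integer(0)
    for (row in seq_len(L)) {
      idx <- start_idx + row - 1L
      if (idx < 1L || idx > nchar(pr$sequence)) next
      if (substr(pr$sequence, idx, idx) != pwm_best_base(model$pwm, row)) {
        cand <- c(cand, row)
      }
    }
    if (!length(cand)) {
      stop("no improvable position in the best window of ", pr$gene_symbol,
           call. = FALSE)
    }
    row <- if (length(cand) == 1L) cand else sample(cand, 1L)
    idx <- start_idx + row - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sprintf("imp%04d", i), gene = pr$gene_symbol,
      offset = est$best_offset + row - 1L,
      ref = substr(pr$sequence, idx, idx),
      alt = pwm_best_base(model$pwm, row),
      class = "improve", stringsAsFactors = FALSE)
  }
  # neutral: substitution far from every top-scoring window footprint
  made_neutral <- 0L
  attempt <- 0L
  while (made_neutral < spec$n_neutral) {
    attempt <- attempt + 1L
    if (attempt > 20L * max(1L, spec$n_neutral)) {
      stop("insufficient eligible positions for neutral SNPs", call. = FALSE)
    }
    pr <- pick_promoter(attempt + spec$n_damage + spec$n_improve)
    est <- estimate_affinity(pr, model)
    ord <- order(-est$scores)
    top_off <- unique(est$window_offsets[ord][seq_len(min(neutral_top_k,
                                                          length(ord)))])
    n <- nchar(pr$sequence)
    offsets <- (pr$tss_offset - n + 1L):pr$tss_offset
    eligible <- offsets
    for (o in top_off) {
      eligible <- eligible[eligible < o - neutral_margin |
                           eligible > o + L - 1L + neutral_margin]
    }
    if (!length(eligible)) next
    off <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    idx <- off - pr$tss_offset + n
    ref <- substr(pr$sequence, idx, idx)
    made_neutral <- made_neutral + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sprintf("neu%04d", made_neutral), gene = pr$gene_symbol,
      offset = off, ref = ref, alt = sample(setdiff(BASES, ref), 1L),
      class = "neutral", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic domestic-vs-wild DEG table with ground truth
#'
#' DEG signs are drawn per `deg_frac_domestic_excess`; adjusted p-values
#' are drawn with `deg_frac_significant` of records at or below 0.05. A
#' paired annotation catalog is generated so that the expression state
#' reached by the domestic lineage aggravates disease with probability
#' `deg_frac_aggravate` (the wild state gets the complementary
#' direction), giving a tunable lineage-effect association for
#' parameter-recovery checks.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `degs` (data.frame: dataset_id, domestic_label,
#'   wild_label, tissue, gene, log2fc, p_adj), `catalog` (a
#'   [gene_catalog()]) and `truth` (per-gene domestic effect drawn).
#' @export
gen_deg_table <- function(spec) {
  set.seed(spec$seed + 2L)
  n <- spec$deg_n_genes
  genes <- sprintf("Sg%04d", seq_len(n))
  up <- stats::runif(n) < spec$deg_frac_domestic_excess
  log2fc <- ifelse(up, 1, -1) * (0.2 + stats::rexp(n, rate = 1))
  sig <- stats::runif(n) < spec$deg_frac_significant
  p_adj <- ifelse(sig, stats::runif(n, 0, 0.05),
                  stats::runif(n, 0.0501, 1))
  dom_aggr <- stats::runif(n) < spec$deg_frac_aggravate
  dom_state <- ifelse(up, "excess", "deficit")
  excess_effect <- ifelse(dom_state == "excess",
                          ifelse(dom_aggr, "aggravate", "relieve"),
                          ifelse(dom_aggr, "relieve", "aggravate"))
  deficit_effect <- ifelse(excess_effect == "aggravate",
                           "relieve", "aggravate")
  degs <- data.frame(
    dataset_id = "synthetic", domestic_label = "domestic",
    wild_label = "wild", tissue = "synthetic", gene = genes,
    log2fc = log2fc, p_adj = p_adj, stringsAsFactors = FALSE
  )
  catalog <- gene_catalog(data.frame(
    gene = toupper(genes), category = "comorbid_clinical",
    deficit_effect = deficit_effect, excess_effect = excess_effect,
    note = "synthetic", stringsAsFactors = FALSE
  ))
  list(degs = degs, catalog = catalog,
       truth = data.frame(gene = genes, domestic_aggravates = dom_aggr,
                          stringsAsFactors = FALSE))
}

#' Ortholog-pair fixture: the published 11-gene comparison
#'
#' The 11 domestic-vs-wild DEG records paired with human disease-direction
#' annotations, transcribed exactly as printed (log2 fold changes, adjusted
#' p-values, per-state effect directions), covering tame-vs-aggressive fox
#' pituitary, domesticated-vs-wild rabbit, guinea-pig-vs-cavy frontal
#' cortex, and dog-vs-wolf blood datasets.
#'
#' @return List with `degs` (11-row data.frame) and `catalog` (the matching
#'   [gene_catalog()] rows).
#' @export
fixture_table3 <- function() {
  degs <- data.frame(
    dataset_id = c(rep("fox_pituitary", 5L), "rabbit_cortex",
                   rep("guineapig_cortex", 4L), "dog_blood"),
    domestic_label = c(rep("tame fox", 5L), "domestic rabbit",
                       rep("guinea pig", 4L), "dog"),
    wild_label = c(rep("aggressive fox", 5L), "wild rabbit",
                   rep("cavy", 4L), "wolf"),
    tissue = c(rep("pituitary", 5L), "frontal cortex",
               rep("frontal cortex", 4L), "blood"),
    gene = c("Esr2", "Il1r2", "Il9r", "Npy", "Tgfb2", "F7",
             "Ccr6", "Cetp", "Il1b", "Pdyn", "Hbbl"),
    log2fc = c(-0.3, -0.4, 0.4, 0.4, 0.5, -2.7, 2.2, 2.1, 2.3, 0.9, -5.9),
    p_adj = c(0.05, 0.05, 0.05, 1e-2, 1e-2, 0.05, 0.05, 1e-3, 1e-2, 1e-2,
              1e-8),
    stringsAsFactors = FALSE
  )
  catalog <- load_annotations()
  human <- c("ESR2", "IL1R2", "IL9R", "NPY", "TGFB2", "F7", "CCR6", "CETP",
             "IL1B", "PDYN", "HBB")
  list(degs = degs, catalog = gene_catalog(as.data.frame(catalog[human, ])))
}

#' Dataset-size fixture: the seven published DEG corpora
#'
#' @return `data.frame` with one row per RNA-Seq dataset (domestic label,
#'   wild label, tissue, number of DEGs); the counts sum to 1740.
#' @export
fixture_table1 <- function() {
  data.frame(
    dataset_id = c("guineapig_cortex", "pig_cortex", "rabbit_cortex",
                   "rat_cortex", "dog_cortex", "dog_blood",
                   "fox_pituitary"),
    domestic_label = c("guinea pig", "pig", "domesticated rabbit",
                       "tame rat", "dog", "dog", "tame fox"),
    wild_label = c("cavy", "boar", "wild rabbit", "aggressive rat", "wolf",
                   "wolf", "aggressive fox"),
    tissue = c(rep("frontal cortex", 5L), "blood", "pituitary"),
    n_degs = c(883L, 30L, 17L, 20L, 13L, 450L, 327L),
    stringsAsFactors = FALSE
  )
}
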