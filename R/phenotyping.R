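#' @importFrom stats t.test
NULL

#' Classify MBOA degradation strength
#'
#' Percent degraded is `100 * (1 - sample / control)` relative to the
#' no-bacteria control. Classes: `strong` when more than 90% is degraded,
#' `non` when less than 30% is degraded, `weak` in between (boundaries 90
#' and 30 fall into `weak` and `non` respectively; the `strong` inequality
#' is strict).
#'
#' @param sample_conc compound concentration(s) after incubation.
#' @param control_conc matching no-bacteria control concentration (> 0).
#' @return character vector in `strong`/`weak`/`non`.
#' @examples
#' classifyDegrader(20, 500)   # "strong" (96% degraded)
#' classifyDegrader(300, 500)  # "weak"   (40%)
#' classifyDegrader(450, 500)  # "non"    (10%)
#' @export
classifyDegrader <- function(sample_conc, control_conc) {
  if (any(control_conc <= 0)) stop("control concentration must be > 0")
  if (any(sample_conc < 0)) stop("concentrations must be >= 0")
  degraded <- 100 * (1 - sample_conc / control_conc)
  ifelse(degraded > 90, "strong", ifelse(degraded < 30, "non", "weak"))
}

#' Classify AMPO-former strength
#'
#' Expressed as percent of the maximal AMPO producer in the assay:
#' `strong` above 10%, `non` below 0.1%, `weak` in the closed band
#' [0.1%, 10%] (three strict inequalities cannot tile the line; the
#' boundaries are assigned to `weak`).
#'
#' @param sample_ampo AMPO concentration(s).
#' @param max_ampo maximal AMPO concentration in the assay (> 0).
#' @return character vector in `strong`/`weak`/`non`.
#' @examples
#' classifyAmpoFormer(15, 100)    # "strong"
#' classifyAmpoFormer(5, 100)     # "weak"
#' classifyAmpoFormer(0.05, 100)  # "non"
#' @export
classifyAmpoFormer <- function(sample_ampo, max_ampo) {
  if (any(max_ampo <= 0)) stop("max AMPO must be > 0")
  if (any(sample_ampo < 0)) stop("concentrations must be >= 0")
  pct <- 100 * sample_ampo / max_ampo
  ifelse(pct > 10, "strong", ifelse(pct < 0.1, "non", "weak"))
}

#' Classify a metabolite assay table
#'
#' Applies [classifyDegrader()] (MBOA remaining vs the no-bacteria
#' control) and [classifyAmpoFormer()] (AMPO vs the assay maximum over
#' non-control samples) to a long-format metabolite table, and calls the
#' binary phenotype `positive` for strong AMPO-formers.
#'
#' @param tab data.frame with columns `strain_id`, `compound`
#'   (`MBOA`/`AMPO`/...), `concentration`, `is_control`.
#' @return [S4Vectors::DataFrame] with `strain_id`, `degrader_class`,
#'   `ampo_class`, `phenotype_call`.
#' @export
classifyMetaboliteTable <- function(tab) {
  stopifnot(all(c("strain_id", "compound", "concentration", "is_control")
                %in% colnames(tab)))
  ctrl <- tab[tab$is_control & tab$compound == "MBOA", "concentration"]
  if (length(ctrl) != 1)
    stop("exactly one no-bacteria control MBOA level expected")
  samp <- tab[!tab$is_control, , drop = FALSE]
  mboa <- samp[samp$compound == "MBOA", , drop = FALSE]
  ampo <- samp[samp$compound == "AMPO", , drop = FALSE]
  max_ampo <- max(ampo$concentration)
  sid <- unique(samp$strain_id)
  DataFrame(
    strain_id = sid,
    degrader_class = classifyDegrader(
      mboa$concentration[match(sid, mboa$strain_id)], ctrl),
    ampo_class = classifyAmpoFormer(
      ampo$concentration[match(sid, ampo$strain_id)], max_ampo),
    phenotype_call = ifelse(classifyAmpoFormer(
      ampo$concentration[match(sid, ampo$strain_id)], max_ampo) == "strong",
      "positive", "negative"))
}

#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over the recorded time span
#' (OD x hours).
#'
#' @param times hours, strictly increasing, length >= 2.
#' @param od OD600 readings, same length.
#' @return the AUC.
#' @examples
#' growthAUC(c(0, 10), c(0.5, 0.5))  # 5
#' @export
growthAUC <- function(times, od) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (length(times) != length(od)) stop("times and od must match")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  sum(diff(times) * (od[-1] + od[-n]) / 2)
}

#' Growth benefit relative to a control condition
#'
#' For each strain, every treatment replicate AUC is normalized by the
#' mean control AUC of that strain; the ratios are tested against 1 with
#' a one-sample t-test (optionally on log ratios against 0) and p-values
#' are BH-adjusted across strains.
#'
#' @param auc_treatment named list: strain id -> numeric replicate AUCs
#'   under treatment (>= 2 each).
#' @param auc_control named list of matching control AUCs.
#' @param log_ratios test `log(ratio)` against 0 instead of the raw
#'   ratios against 1 (default FALSE).
#' @return [S4Vectors::DataFrame] with `strain_id`, `ratio` (mean),
#'   `p`, `p_adj`.
#' @export
growthBenefitTest <- function(auc_treatment, auc_control,
                              log_ratios = FALSE) {
  sids <- names(auc_treatment)
  stopifnot(!is.null(sids), setequal(sids, names(auc_control)))
  rows <- lapply(sids, function(sid) {
    tr <- auc_treatment[[sid]]
    ct <- auc_control[[sid]]
    if (length(tr) < 2 || length(ct) < 2)
      stop("strain ", sid, ": need >= 2 replicates in both conditions")
    if (mean(ct) == 0) stop("strain ", sid, ": zero control mean")
    ratio <- tr / mean(ct)
    v <- if (log_ratios) log(ratio) else ratio
    mu <- if (log_ratios) 0 else 1
    p <- if (stats::sd(v) == 0) as.numeric(mean(v) == mu)  # degenerate: 0 or 1
         else t.test(v, mu = mu)$p.value
    data.frame(strain_id = sid, ratio = mean(ratio), p = p)
  })
  out <- DataFrame(do.call(rbind, rows))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Glucose concentration carbon-equivalent to a compound
#'
#' Converts a compound concentration to the glucose concentration carrying
#' the same molar amount of carbon (glucose has 6 carbons), rounded to the
#' nearest integer.
#'
#' @param conc compound concentration (uM), >= 0.
#' @param carbons_per_molecule carbon atoms per molecule of the compound
#'   (>= 1; MBOA has 8).
#' @return glucose concentration (uM).
#' @examples
#' carbonEquivalentGlucose(500, 8)   # 667
#' carbonEquivalentGlucose(1250, 8)  # 1667
#' @export
carbonEquivalentGlucose <- function(conc, carbons_per_molecule) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (any(carbons_per_molecule < 1)) stop("carbons must be >= 1")
  round(conc * carbons_per_molecule / 6)
}

#' Strain abundance from an amplicon profile
#'
#' Sums the relative abundances of all amplicon sequence variants whose
#' full-length global-alignment identity to the strain's 16S marker is
#' strictly greater than 0.99.
#'
#' @param strain_marker_seq 16S nucleotide sequence of the strain.
#' @param asv_table data.frame with columns `asv_seq` and
#'   `relative_abundance` (percent, in [0, 100]).
#' @param min_identity exclusive identity cut-off (default 0.99).
#' @return summed relative abundance (percent); 0 for an empty table.
#' @export
estimateStrainAbundance <- function(strain_marker_seq, asv_table,
                                    min_identity = 0.99) {
  if (nrow(asv_table) == 0) return(0)
  stopifnot(all(c("asv_seq", "relative_abundance") %in% colnames(asv_table)))
  if (any(asv_table$relative_abundance < 0 |
          asv_table$relative_abundance > 100))
    stop("relative abundances must be in [0, 100]")
  aln <- pairwiseAlignment(DNAStringSet(asv_table$asv_seq),
                           strain_marker_seq, type = "global",
                           substitutionMatrix = .nt_submat(),
                           gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(pattern(aln)))
  ident <- nmatch(aln) / cols
  sum(asv_table$relative_abundance[ident > min_identity])
}
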